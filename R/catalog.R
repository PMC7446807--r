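## The curated TF collection: evidence-code vocabulary, file IO and
## descriptive summaries (domain architecture, roles, family frequencies).

#' Experimental evidence codes and their strength
#'
#' The 17 recognised evidence categories for a curated TF. Strong evidence
#' ties the regulator directly to its binding site (structures, footprints,
#' site mutations, ChIP and similar direct assays); weak evidence is
#' expression-level or inferential (extract binding, reporter-fusion
#' expression, mutant phenotypes, microarrays).
#'
#' @return data.frame with columns \code{code} and \code{strength}.
#' @examples
#' classifyEvidence("BPP")   # "strong"
#' classifyEvidence("GEA")   # "weak"
#' @export
evidenceCodes <- function() {
  data.frame(
    code = c("PDB", "BPP", "SM", "IDA", "APPH", "qRT-PCR", "OHR",
             "ChIP-seq", "PRM",
             "BCE", "GEA", "AS", "IEP", "IMP", "IGI", "RBM", "MIC"),
    strength = c(rep("strong", 9L), rep("weak", 8L)),
    stringsAsFactors = FALSE)
}

#' @rdname evidenceCodes
#' @param code evidence code (case-insensitive); anything outside the 17
#'   recognised codes is an error listing the valid ones.
#' @export
classifyEvidence <- function(code) {
  tab <- evidenceCodes()
  idx <- match(toupper(code), toupper(tab$code))
  if (anyNA(idx))
    stop("unknown evidence code(s): ",
         paste(unique(code[is.na(idx)]), collapse = ", "),
         "; valid codes: ", paste(tab$code, collapse = ", "))
  tab$strength[idx]
}

#' Read / write a curated TF catalog
#'
#' The catalog file is a TSV with columns \code{tf_id}, \code{species},
#' \code{pfams} (\code{;}-separated accessions, the first one taken as the
#' family unless a \code{family_pfam} column is present), \code{role} and
#' \code{evidence} (\code{;}-separated codes). Entries with no role map to
#' \code{"undefined"}.
#'
#' @param path path to the catalog TSV.
#' @return \code{readCatalog}: a [TFCatalog-class]. \code{writeCatalog}:
#'   \code{path}, invisibly.
#' @export
readCatalog <- function(path) {
  d <- readTsv(path)
  need <- c("tf_id", "species", "pfams", "role", "evidence")
  miss <- setdiff(need, colnames(d))
  if (length(miss))
    stop("catalog file missing column(s): ", paste(miss, collapse = ", "))
  pf <- lapply(strsplit(d$pfams, ";", fixed = TRUE),
               function(x) .stripVersion(trimws(x)))
  fam <- if ("family_pfam" %in% colnames(d)) .stripVersion(d$family_pfam)
         else vapply(pf, `[`, character(1), 1L)
  role <- ifelse(is.na(d$role) | d$role == "", "undefined", d$role)
  ev <- lapply(strsplit(d$evidence, ";", fixed = TRUE), trimws)
  new("TFCatalog", entries = S4Vectors::DataFrame(
    tf_id = d$tf_id, species = d$species, family_pfam = fam,
    all_pfams = IRanges::CharacterList(pf),
    n_domains = lengths(pf), role = role,
    evidence = IRanges::CharacterList(ev)))
}

#' @rdname readCatalog
#' @param catalog a \code{TFCatalog}.
#' @export
writeCatalog <- function(catalog, path) {
  e <- catalogEntries(catalog)
  writeTsv(data.frame(
    tf_id = e$tf_id, species = e$species,
    pfams = vapply(as.list(e$all_pfams), paste, character(1),
                   collapse = ";"),
    family_pfam = e$family_pfam, role = e$role,
    evidence = vapply(as.list(e$evidence), paste, character(1),
                      collapse = ";"),
    stringsAsFactors = FALSE), path)
}

.pctDistribution <- function(x, levels = NULL) {
  if (!length(x)) stop("empty catalog")
  f <- if (is.null(levels)) factor(x) else factor(x, levels = levels)
  cnt <- table(f)
  pct <- 100 * as.numeric(cnt) / sum(cnt)
  names(pct) <- names(cnt)
  pct
}

#' Summarise the domain-count architecture of a catalog
#'
#' Percentage of entries with 1, 2, 3, ... PFAM domains; percentages sum
#' to 100.
#'
#' @param catalog a [TFCatalog-class] with at least one entry.
#' @return named numeric vector (names = domain counts, values = percent).
#' @export
summarizeDomainArchitecture <- function(catalog) {
  e <- catalogEntries(catalog)
  .pctDistribution(e$n_domains)
}

#' Summarise the regulatory-role distribution of a catalog
#'
#' @param catalog a [TFCatalog-class] with at least one entry.
#' @return named numeric vector over
#'   activator/repressor/dual/undefined (percent, summing to 100).
#' @export
summarizeRoles <- function(catalog) {
  e <- catalogEntries(catalog)
  .pctDistribution(e$role, levels = .TF_ROLES)
}

#' Family frequency table of a catalog
#'
#' Percentage of catalog entries per PFAM family, sorted descending by
#' percentage with ties broken by accession.
#'
#' @param catalog a [TFCatalog-class] with at least one entry.
#' @return data.frame with columns \code{family_pfam}, \code{n},
#'   \code{percent}, ordered as above.
#' @export
familyFrequency <- function(catalog) {
  e <- catalogEntries(catalog)
  if (!nrow(e)) stop("empty catalog")
  cnt <- table(e$family_pfam)
  out <- data.frame(family_pfam = names(cnt), n = as.integer(cnt),
                    percent = 100 * as.integer(cnt) / sum(cnt),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$percent, out$family_pfam), , drop = FALSE]
  rownames(out) <- NULL
  out
}
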