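## Functional layering: EC (enzyme) annotation, virulence-factor orthology
## flags, and the per-family context/function summary table.

.EC_PATTERN <- "^([0-9]+)\\.([0-9]+|-)\\.([0-9]+|-)\\.([0-9]+|-)$"

#' Join EC annotations onto proteins
#'
#' Validates a two-column protein-to-EC table and flags enzyme-associated
#' proteins (at least one valid EC entry). EC strings must look like
#' \code{a.b.c.d} with digits or \code{-} placeholders and a top-level
#' class in 1–6; partial ECs (trailing \code{-}) still count as
#' enzyme-associated. Malformed rows are rejected with a diagnostic.
#'
#' @param proteinIds character vector of proteins under consideration.
#' @param ecTable data.frame with columns \code{protein_id}, \code{ec}.
#' @return data.frame with columns \code{protein_id}, \code{ec},
#'   \code{ec_class} (integer 1–6), restricted to \code{proteinIds};
#'   attribute \code{nRejected} counts rejected rows.
#' @examples
#' joinEC("p1", data.frame(protein_id = "p1", ec = "2.7.7.6"))
#' @export
joinEC <- function(proteinIds, ecTable) {
  m <- regmatches(ecTable$ec, regexec(.EC_PATTERN, ecTable$ec))
  cls <- vapply(m, function(h) if (length(h)) as.integer(h[2L]) else NA_integer_,
                integer(1))
  ok <- !is.na(cls) & cls >= 1L & cls <= 6L
  if (any(!ok))
    message(sum(!ok), " EC row(s) rejected (malformed or class outside 1-6)")
  keep <- ok & ecTable$protein_id %in% proteinIds
  out <- data.frame(protein_id = ecTable$protein_id[keep],
                    ec = ecTable$ec[keep], ec_class = cls[keep],
                    stringsAsFactors = FALSE)
  attr(out, "nRejected") <- sum(!ok)
  out
}

#' Distribution of EC classes
#'
#' Fraction of EC annotations in each of the six top-level classes
#' (1 oxidoreductases, 2 transferases, 3 hydrolases, 4 lyases,
#' 5 isomerases, 6 ligases). Fractions sum to 1.
#'
#' @param annotations data.frame from [joinEC()] (nonempty).
#' @return named numeric vector of length 6.
#' @export
ecClassDistribution <- function(annotations) {
  if (!nrow(annotations)) stop("empty EC annotation set")
  cnt <- table(factor(annotations$ec_class, levels = 1:6))
  out <- as.numeric(cnt) / sum(cnt)
  names(out) <- as.character(1:6)
  out
}

#' Flag virulence-associated proteins
#'
#' A protein is virulence-associated when it forms a reciprocal best hit
#' with any protein of the virulence-factor reference set, under the same
#' thresholds as ortholog detection (\code{e <= 1e-5}, coverage >= 70
#' percent on both sides). This is [findOrthologsRBH()] restricted to the
#' virulence reference.
#'
#' @param hitsAB similarity hits, proteome vs virulence reference.
#' @param hitsBA the reciprocal direction.
#' @param eMax,covMin thresholds passed to [findOrthologsRBH()].
#' @return character vector of flagged protein ids.
#' @export
flagVirulence <- function(hitsAB, hitsBA, eMax = 1e-5, covMin = 0.70) {
  pairs <- findOrthologsRBH(hitsAB, hitsBA, eMax = eMax, covMin = covMin)
  unique(pairs$a_id)
}

#' Per-family genomic-context and function table
#'
#' For the most abundant TF families (pooled across genomes), tabulates how
#' many member TFs sit divergently from a neighbor, how many lie in
#' multi-gene transcription units, and how many are enzyme- or
#' virulence-associated. Following the conventional presentation, the
#' divergent column is reported as a fraction of the family total while
#' the other columns are percentages. When neighbor flags are supplied the
#' same two annotations are also tabulated for the divergent partner genes.
#'
#' @param predictions a [TFPredictionSet-class].
#' @param contextCalls pooled context table ([classifyTFContext()] rows for
#'   all genomes, keyed by \code{tf_protein_id}).
#' @param ecFlags character vector of enzyme-associated protein ids.
#' @param vfFlags character vector of virulence-associated protein ids.
#' @param topK number of most abundant families to report (default 10).
#' @param families optional explicit family vector (overrides \code{topK}).
#' @param partnerProteins optional named character vector mapping gene id
#'   to protein id for partner genes; enables the neighbor columns.
#' @return data.frame with one row per family: \code{family_pfam},
#'   \code{total_tfs}, \code{n_divergent}, \code{frac_divergent},
#'   \code{n_in_tu}, \code{pct_in_tu}, \code{n_enzyme}, \code{pct_enzyme},
#'   \code{n_virulence}, \code{pct_virulence}, plus
#'   \code{n_neighbor_enzyme}/\code{pct_neighbor_enzyme} and
#'   \code{n_neighbor_virulence}/\code{pct_neighbor_virulence} when
#'   partners are resolvable. Ordered by \code{total_tfs} descending.
#' @export
familyContextTable <- function(predictions, contextCalls, ecFlags = character(),
                               vfFlags = character(), topK = 10L,
                               families = NULL, partnerProteins = NULL) {
  p <- tfPredictions(predictions)
  p <- p[!is.na(p$family_pfam), , drop = FALSE]
  if (is.null(families)) {
    cnt <- sort(table(p$family_pfam), decreasing = TRUE)
    families <- names(cnt)[seq_len(min(topK, length(cnt)))]
  }
  rel <- contextCalls$relation[match(p$protein_id,
                                     contextCalls$tf_protein_id)]
  partnerGene <- contextCalls$partner_gene_id[
    match(p$protein_id, contextCalls$tf_protein_id)]
  partnerProt <- if (is.null(partnerProteins)) rep(NA_character_, nrow(p))
                 else unname(partnerProteins[partnerGene])
  rows <- lapply(families, function(fam) {
    sel <- p$family_pfam == fam
    total <- sum(sel)
    if (total == 0L)
      warning("family ", fam, " has no predicted TFs")
    nDiv <- sum(sel & !is.na(rel) & rel == "divergent")
    nTU <- sum(sel & !is.na(rel) & rel == "in_tu")
    nEnz <- sum(sel & p$protein_id %in% ecFlags)
    nVir <- sum(sel & p$protein_id %in% vfFlags)
    divPartners <- partnerProt[sel & !is.na(rel) & rel == "divergent"]
    divPartners <- divPartners[!is.na(divPartners)]
    pct <- function(n) if (total) 100 * n / total else 0
    frac <- function(n) if (total) n / total else 0
    data.frame(
      family_pfam = fam, total_tfs = total,
      n_divergent = nDiv, frac_divergent = frac(nDiv),
      n_in_tu = nTU, pct_in_tu = pct(nTU),
      n_enzyme = nEnz, pct_enzyme = pct(nEnz),
      n_virulence = nVir, pct_virulence = pct(nVir),
      n_neighbor_enzyme = sum(divPartners %in% ecFlags),
      pct_neighbor_enzyme = pct(sum(divPartners %in% ecFlags)),
      n_neighbor_virulence = sum(divPartners %in% vfFlags),
      pct_neighbor_virulence = pct(sum(divPartners %in% vfFlags)),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$total_tfs, out$family_pfam), , drop = FALSE]
  rownames(out) <- NULL
  out
}
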