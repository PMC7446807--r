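## TF prediction: the domain route (TF-associated PFAM membership), the
## orthology route (reciprocal best hits against the curated collection),
## their merge with provenance, and per-genome censuses.

#' Call TFs from domain hits
#'
#' A protein is called a TF when it carries at least one hit to a
#' TF-associated PFAM family at \code{e_value <= eMax} (default
#' \code{1e-3}). Its family is the minimum-E-value qualifying hit, with
#' ties broken by higher bit score and then lexically by accession, so
#' calls are reproducible. Overlapping within-clan hits are all retained
#' upstream (clan-overlap reporting); only family assignment takes the
#' single best hit.
#'
#' @param hits data.frame of domain hits ([parseDomainHits()]).
#' @param tfPfams nonempty character vector of TF-associated PFAM
#'   accessions (version suffixes ignored).
#' @param eMax E-value inclusion threshold (inclusive).
#' @return data.frame with one row per called protein: \code{protein_id},
#'   \code{family_pfam}, \code{best_e}.
#' @examples
#' h <- data.frame(protein_id = "p1", pfam_acc = "PF00440",
#'                 e_value = 1e-10, bit_score = 80)
#' assignTFByDomain(h, "PF00440")
#' @export
assignTFByDomain <- function(hits, tfPfams, eMax = 1e-3) {
  if (!length(tfPfams)) stop("tfPfams must be nonempty")
  tfPfams <- .stripVersion(tfPfams)
  out <- data.frame(protein_id = character(), family_pfam = character(),
                    best_e = numeric(), stringsAsFactors = FALSE)
  if (is.null(hits) || !nrow(hits)) return(out)
  h <- hits[.stripVersion(hits$pfam_acc) %in% tfPfams &
              hits$e_value <= eMax, , drop = FALSE]
  if (!nrow(h)) return(out)
  if (is.null(h$bit_score)) h$bit_score <- 0
  h <- h[order(h$protein_id, h$e_value, -h$bit_score, h$pfam_acc), ,
         drop = FALSE]
  best <- h[!duplicated(h$protein_id), , drop = FALSE]
  data.frame(protein_id = best$protein_id,
             family_pfam = .stripVersion(best$pfam_acc),
             best_e = best$e_value, stringsAsFactors = FALSE)
}

.bestQualifyingHit <- function(hits, eMax, covMin, twoSided = TRUE) {
  cov <- if (twoSided) pmin(hits$query_cov, hits$subject_cov)
         else pmax(hits$query_cov, hits$subject_cov)
  h <- hits[hits$e_value <= eMax & cov >= covMin, , drop = FALSE]
  if (!nrow(h)) return(h)
  h <- h[order(h$query_id, -h$bit_score, h$e_value, h$subject_id), ,
         drop = FALSE]
  h[!duplicated(h$query_id), , drop = FALSE]
}

#' Find orthologs by reciprocal best hit
#'
#' A hit qualifies when \code{e_value <= eMax} and its coverage passes
#' \code{covMin} (by default both query and subject coverage must reach it;
#' \code{twoSided = FALSE} relaxes this to either side for sensitivity
#' analysis). A pair (a, b) is an ortholog pair when b is a's best
#' qualifying subject (maximum bit score; ties by minimum E-value, then
#' lexical subject id) and a is b's best qualifying subject in the
#' reciprocal table.
#'
#' @param hitsAB similarity hits with proteome A as query, B as subject
#'   ([parseSimilarityHits()] columns).
#' @param hitsBA the reciprocal direction.
#' @param eMax E-value threshold (default \code{1e-5}).
#' @param covMin minimum coverage fraction (default \code{0.70}).
#' @param twoSided require both-side coverage (default) or one-side only.
#' @return data.frame with columns \code{a_id}, \code{b_id}, one row per
#'   reciprocal-best pair; each id appears in at most one pair.
#' @export
findOrthologsRBH <- function(hitsAB, hitsBA, eMax = 1e-5, covMin = 0.70,
                             twoSided = TRUE) {
  empty <- data.frame(a_id = character(), b_id = character(),
                      stringsAsFactors = FALSE)
  if (is.null(hitsAB) || !nrow(hitsAB) || is.null(hitsBA) || !nrow(hitsBA))
    return(empty)
  bestAB <- .bestQualifyingHit(hitsAB, eMax, covMin, twoSided)
  bestBA <- .bestQualifyingHit(hitsBA, eMax, covMin, twoSided)
  if (!nrow(bestAB) || !nrow(bestBA)) return(empty)
  back <- bestBA$subject_id[match(bestAB$subject_id, bestBA$query_id)]
  keep <- !is.na(back) & back == bestAB$query_id
  out <- data.frame(a_id = bestAB$query_id[keep],
                    b_id = bestAB$subject_id[keep],
                    stringsAsFactors = FALSE)
  out[order(out$a_id), , drop = FALSE]
}

#' Merge domain-route and orthology-route TF calls
#'
#' Produces the provenance partition of the union of the two call sets:
#' proteins called only by domain membership (\code{domain_only}), only by
#' orthology against the curated collection (\code{orthology_only}), or by
#' both routes (\code{both}). The partition is disjoint and covers the
#' union exactly. Orthology-only calls carry no PFAM family (\code{NA})
#' since the domain route did not qualify one.
#'
#' @param domainCalls data.frame from [assignTFByDomain()].
#' @param orthoCalls character vector of protein ids called by orthology,
#'   or a data.frame with a \code{protein_id} (or \code{a_id}) column such
#'   as [findOrthologsRBH()] output.
#' @param genomeId genome identifier for the resulting predictions.
#' @return a [TFPredictionSet-class].
#' @export
mergePredictions <- function(domainCalls, orthoCalls, genomeId) {
  if (is.data.frame(orthoCalls)) {
    col <- intersect(c("protein_id", "a_id"), colnames(orthoCalls))[1L]
    if (is.na(col))
      stop("orthoCalls data.frame needs a protein_id or a_id column")
    orthoIds <- unique(orthoCalls[[col]])
  } else orthoIds <- unique(as.character(orthoCalls))
  domIds <- unique(domainCalls$protein_id)
  allIds <- sort(union(domIds, orthoIds))
  prov <- ifelse(allIds %in% domIds,
                 ifelse(allIds %in% orthoIds, "both", "domain_only"),
                 "orthology_only")
  fam <- domainCalls$family_pfam[match(allIds, domainCalls$protein_id)]
  bestE <- domainCalls$best_e[match(allIds, domainCalls$protein_id)]
  new("TFPredictionSet", predictions = S4Vectors::DataFrame(
    genome_id = rep(genomeId, length(allIds)), protein_id = allIds,
    family_pfam = fam, provenance = prov, best_e = bestE))
}

#' Combine prediction sets from several genomes
#'
#' @param ... \code{TFPredictionSet} objects.
#' @return a single [TFPredictionSet-class].
#' @export
combinePredictions <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1L]]) && !is(sets[[1L]], "TFPredictionSet"))
    sets <- sets[[1L]]
  tabs <- lapply(sets, function(s) s@predictions)
  new("TFPredictionSet", predictions = do.call(rbind, tabs))
}

#' Per-genome TF census
#'
#' Counts ORFs and predicted TFs per genome and reports TF density
#' (\code{n_tfs / n_orfs}, the fraction of a genome's gene products devoted
#' to transcriptional regulation).
#'
#' @param predictions a [TFPredictionSet-class].
#' @param genes \code{GRanges} of all genes across the same genomes, with
#'   mcols \code{protein_id} and \code{genome_id}; a prediction naming a
#'   protein absent from its genome's genes is an error.
#' @param divisionMap optional named character vector mapping genome id to
#'   taxonomic division.
#' @return data.frame with columns \code{genome_id}, \code{n_orfs},
#'   \code{n_tfs}, \code{tf_density}, \code{division}.
#' @export
tfCensus <- function(predictions, genes, divisionMap = NULL) {
  p <- tfPredictions(predictions)
  gid <- GenomicRanges::mcols(genes)$genome_id
  pid <- GenomicRanges::mcols(genes)$protein_id
  known <- paste(gid, pid)
  bad <- !(paste(p$genome_id, p$protein_id) %in% known)
  if (any(bad))
    stop("prediction for unknown protein ", p$protein_id[which(bad)[1L]],
         " in genome ", p$genome_id[which(bad)[1L]])
  genomes <- sort(unique(gid))
  nOrfs <- as.integer(table(factor(gid, levels = genomes)))
  nTfs <- as.integer(table(factor(p$genome_id, levels = genomes)))
  data.frame(genome_id = genomes, n_orfs = nOrfs, n_tfs = nTfs,
             tf_density = nTfs / nOrfs,
             division = if (is.null(divisionMap)) NA_character_
                        else unname(divisionMap[genomes]),
             stringsAsFactors = FALSE)
}

#' Genome prevalence of TF families
#'
#' For each PFAM family, the fraction of genomes in which at least one TF
#' of that family was predicted — e.g. a family found in 721 of 1351
#' genomes has 53.3 percent prevalence.
#'
#' @param predictions a [TFPredictionSet-class].
#' @param nGenomes total number of genomes surveyed; defaults to the number
#'   of distinct genomes in \code{predictions}.
#' @return data.frame with columns \code{family_pfam}, \code{n_genomes},
#'   \code{prevalence_pct}, descending by prevalence.
#' @export
familyPrevalence <- function(predictions, nGenomes = NULL) {
  p <- tfPredictions(predictions)
  if (is.null(nGenomes)) nGenomes <- length(unique(p$genome_id))
  p <- p[!is.na(p$family_pfam), , drop = FALSE]
  u <- unique(p[, c("family_pfam", "genome_id")])
  cnt <- table(u$family_pfam)
  out <- data.frame(family_pfam = names(cnt), n_genomes = as.integer(cnt),
                    prevalence_pct = 100 * as.integer(cnt) / nGenomes,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$prevalence_pct, out$family_pfam), , drop = FALSE]
  rownames(out) <- NULL
  out
}
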