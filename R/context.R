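## Genomic context of TF genes: transcription-unit prediction from strand
## and intergenic distance, divergent-pair detection, and distance
## histograms. Coordinates are 1-based inclusive throughout.

#' Intergenic distance between two ordered genes
#'
#' Number of bases strictly between an upstream (left) and downstream
#' (right) gene on the same replicon:
#' \code{start(downstream) - end(upstream) - 1}. Overlapping or abutting
#' genes get distance 0; overlaps are additionally flagged in
#' \code{attr(, "overlap")}. Vectorised over equal-length inputs.
#'
#' @param upstream,downstream \code{GRanges} of equal length, pairwise on
#'   the same replicon with \code{upstream} left of \code{downstream}.
#' @return integer vector of distances with logical attribute
#'   \code{"overlap"}.
#' @examples
#' a <- GenomicRanges::GRanges("chr1", IRanges::IRanges(100, 900))
#' b <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1001, 1800))
#' intergenicDistance(a, b)  # 100
#' @export
intergenicDistance <- function(upstream, downstream) {
  if (length(upstream) != length(downstream))
    stop("upstream and downstream must have equal length")
  if (!all(as.character(seqnames(upstream)) ==
             as.character(seqnames(downstream))))
    stop("genes must lie on the same replicon")
  d <- start(downstream) - end(upstream) - 1L
  overlap <- d < 0L
  d[d < 0L] <- 0L
  attr(d, "overlap") <- overlap
  d
}

.tuRunIds <- function(st, gaps, gapMax) {
  ## new run when strand changes or the gap to the previous gene exceeds
  ## gapMax; gaps[i] is the gap between gene i-1 and gene i (gaps[1] = NA)
  brk <- c(TRUE, st[-1L] != st[-length(st)] | gaps[-1L] > gapMax)
  cumsum(brk)
}

#' Predict transcription units from strand and intergenic distance
#'
#' Maximal runs of consecutive same-strand genes whose pairwise intergenic
#' gaps do not exceed \code{gapMax} are called one transcription unit (TU).
#' Every gene belongs to exactly one TU. With \code{circular = TRUE} and a
#' known replicon length (\code{seqlengths}), the first and last runs are
#' merged when they are same-strand and the wraparound gap qualifies.
#'
#' @param genes \code{GRanges} with mcol \code{gene_id}, sorted or sortable
#'   by (replicon, start); multiple replicons allowed.
#' @param gapMax maximum intra-TU intergenic distance in bp (default 50,
#'   the conventional prokaryotic operon-calling heuristic).
#' @param circular treat replicons as circular (needs seqlengths).
#' @return \code{DataFrame} with columns \code{tu_id}, \code{replicon_id},
#'   \code{strand}, \code{gene_ids} (CharacterList, in genome order) and
#'   \code{n_genes}.
#' @export
predictTUs <- function(genes, gapMax = 50L, circular = FALSE) {
  if (!length(genes))
    return(S4Vectors::DataFrame(tu_id = character(),
                                replicon_id = character(),
                                strand = character(),
                                gene_ids = IRanges::CharacterList(),
                                n_genes = integer()))
  genes <- genes[order(as.character(seqnames(genes)), start(genes))]
  out <- list()
  for (rep_id in unique(as.character(seqnames(genes)))) {
    g <- genes[as.character(seqnames(genes)) == rep_id]
    st <- as.character(strand(g))
    gaps <- c(NA_integer_, start(g)[-1L] - end(g)[-length(g)] - 1L)
    runs <- .tuRunIds(st, gaps, gapMax)
    if (circular && max(runs) > 1L) {
      slen <- GenomeInfoDb::seqlengths(genes)[rep_id]
      if (!is.na(slen)) {
        wrap <- slen - end(g)[length(g)] + start(g)[1L] - 1L
        if (st[1L] == st[length(st)] && wrap <= gapMax)
          runs[runs == max(runs)] <- 1L
      }
    }
    ids <- GenomicRanges::mcols(g)$gene_id
    for (r in unique(runs)) {
      memb <- ids[runs == r]
      out[[length(out) + 1L]] <- list(
        replicon_id = rep_id, strand = st[which(runs == r)[1L]],
        gene_ids = memb)
    }
  }
  S4Vectors::DataFrame(
    tu_id = sprintf("TU%05d", seq_along(out)),
    replicon_id = vapply(out, `[[`, character(1), "replicon_id"),
    strand = vapply(out, `[[`, character(1), "strand"),
    gene_ids = IRanges::CharacterList(lapply(out, `[[`, "gene_ids")),
    n_genes = lengths(lapply(out, `[[`, "gene_ids")))
}

#' Classify the genomic context of TF genes
#'
#' Each TF gene is placed in exactly one of three mutually exclusive
#' relations:
#' \describe{
#'   \item{divergent}{its upstream (promoter-proximal) neighbor lies on the
#'     opposite strand with both genes transcribed away from the shared
#'     intergenic region — a TF on \code{+} with its left neighbor on
#'     \code{-}, or a TF on \code{-} with its right neighbor on \code{+} —
#'     the classic regulator/target architecture. The shared intergenic
#'     distance is reported; overlapping promoters get distance 0 with an
#'     overlap flag.}
#'   \item{in_tu}{it shares a predicted transcription unit with at least
#'     one other gene (likely cotranscribed); the reported partner is the
#'     adjacent co-TU gene.}
#'   \item{isolated}{neither of the above.}
#' }
#' A divergent upstream neighbor can never be a co-TU member (opposite
#' strand), so the relations are exhaustive and exclusive by construction.
#' At a linear replicon edge the missing upstream neighbor simply cannot
#' support a divergent call and the remaining neighbor decides TU
#' membership; with \code{circular = TRUE} adjacency wraps around.
#'
#' @param tfGeneIds character vector of TF gene ids.
#' @param genes \code{GRanges} of all genes of the genome (mcols
#'   \code{gene_id}, \code{protein_id}).
#' @param tus TU table from [predictTUs()]; computed if \code{NULL}.
#' @param gapMax passed to [predictTUs()] when \code{tus} is \code{NULL}.
#' @param circular treat replicons as circular.
#' @return data.frame with columns \code{tf_gene_id}, \code{tf_protein_id},
#'   \code{relation}, \code{partner_gene_id}, \code{intergenic_bp},
#'   \code{overlap}.
#' @export
classifyTFContext <- function(tfGeneIds, genes, tus = NULL, gapMax = 50L,
                              circular = FALSE) {
  genes <- genes[order(as.character(seqnames(genes)), start(genes))]
  if (is.null(tus)) tus <- predictTUs(genes, gapMax, circular)
  ids <- GenomicRanges::mcols(genes)$gene_id
  missing <- setdiff(tfGeneIds, ids)
  if (length(missing))
    stop("TF gene(s) not present in annotation: ",
         paste(missing, collapse = ", "))
  gene2tu <- rep(tus$tu_id, lengths(tus$gene_ids))
  names(gene2tu) <- unlist(tus$gene_ids)
  tuSize <- stats::setNames(tus$n_genes, tus$tu_id)
  rep_ids <- as.character(seqnames(genes))
  st <- as.character(strand(genes))
  pid <- GenomicRanges::mcols(genes)$protein_id

  one <- function(gidx) {
    rep_id <- rep_ids[gidx]
    onRep <- which(rep_ids == rep_id)
    pos <- match(gidx, onRep)
    n <- length(onRep)
    upOff <- if (st[gidx] == "+") -1L else 1L
    upPos <- pos + upOff
    if (circular && n > 1L) upPos <- ((upPos - 1L) %% n) + 1L
    upIdx <- if (upPos >= 1L && upPos <= n) onRep[upPos] else NA_integer_
    if (!is.na(upIdx) && upIdx != gidx && st[upIdx] != st[gidx]) {
      ## order the pair left/right on the replicon for the distance
      left <- if (start(genes)[upIdx] <= start(genes)[gidx]) upIdx else gidx
      right <- if (left == gidx) upIdx else gidx
      d <- start(genes)[right] - end(genes)[left] - 1L
      ov <- d < 0L
      if (circular && upPos != pos + upOff) {
        ## wrapped neighbor: distance across the origin
        slen <- GenomeInfoDb::seqlengths(genes)[rep_id]
        d <- if (is.na(slen)) NA_integer_
             else slen - end(genes)[max(left, right)] +
               start(genes)[min(left, right)] - 1L
        ov <- !is.na(d) && d < 0L
      }
      if (!is.na(d) && d < 0L) d <- 0L
      return(data.frame(
        tf_gene_id = ids[gidx], tf_protein_id = pid[gidx],
        relation = "divergent", partner_gene_id = ids[upIdx],
        intergenic_bp = d, overlap = ov, stringsAsFactors = FALSE))
    }
    tu <- gene2tu[[ids[gidx]]]
    if (tuSize[[tu]] >= 2L) {
      memb <- unlist(tus$gene_ids[tus$tu_id == tu])
      mpos <- match(ids[gidx], memb)
      partner <- if (mpos > 1L) memb[mpos - 1L] else memb[mpos + 1L]
      return(data.frame(
        tf_gene_id = ids[gidx], tf_protein_id = pid[gidx],
        relation = "in_tu", partner_gene_id = partner,
        intergenic_bp = NA_integer_, overlap = FALSE,
        stringsAsFactors = FALSE))
    }
    data.frame(tf_gene_id = ids[gidx], tf_protein_id = pid[gidx],
               relation = "isolated", partner_gene_id = NA_character_,
               intergenic_bp = NA_integer_, overlap = FALSE,
               stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, lapply(match(tfGeneIds, ids), one))
  rownames(res) <- NULL
  res
}

#' Histogram of divergent intergenic distances
#'
#' Bins the intergenic distances of divergent TF/partner pairs into
#' half-open bins \code{[k*w, (k+1)*w)} and reports the fraction of pairs
#' separated by 100 bp or less (the hallmark of shared, compact regulatory
#' regions) as \code{attr(, "fracWithin100")}.
#'
#' @param calls context table from [classifyTFContext()] (only
#'   \code{relation == "divergent"} rows are used).
#' @param binWidth bin width in bp (default 50).
#' @return data.frame with columns \code{bin_start}, \code{count};
#'   attribute \code{fracWithin100}.
#' @export
divergentDistanceHistogram <- function(calls, binWidth = 50L) {
  d <- calls$intergenic_bp[calls$relation == "divergent"]
  d <- d[!is.na(d)]
  if (!length(d)) {
    out <- data.frame(bin_start = integer(), count = integer())
    attr(out, "fracWithin100") <- NA_real_
    return(out)
  }
  bin <- d %/% binWidth
  cnt <- table(factor(bin, levels = 0:max(bin)))
  out <- data.frame(bin_start = as.integer(names(cnt)) * binWidth,
                    count = as.integer(cnt))
  attr(out, "fracWithin100") <- mean(d <= 100L)
  out
}
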