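## Independent oracles and small fixture builders used across the suite.

## Exact upper-tail Fisher p by direct enumeration over all 2x2 tables
## with the observed margins, using only binomial coefficients.
bruteForceFisherUpper <- function(a, b, c, d) {
  row1 <- a + b; row2 <- c + d; col1 <- a + c
  N <- row1 + row2
  if (N == 0) return(1)
  ks <- max(0, col1 - row2):min(row1, col1)
  probs <- choose(row1, ks) * choose(row2, col1 - ks) / choose(N, col1)
  sum(probs[ks >= a])
}

## Exhaustive mutual-best enumeration over a similarity-hit table.
bruteForceRBH <- function(hitsAB, hitsBA, eMax = 1e-5, covMin = 0.70) {
  qual <- function(h) h[h$e_value <= eMax &
                          pmin(h$query_cov, h$subject_cov) >= covMin, ,
                        drop = FALSE]
  best <- function(h, q) {
    hh <- h[h$query_id == q, , drop = FALSE]
    if (!nrow(hh)) return(NA_character_)
    hh <- hh[order(-hh$bit_score, hh$e_value, hh$subject_id), ,
             drop = FALSE]
    hh$subject_id[1L]
  }
  ab <- qual(hitsAB); ba <- qual(hitsBA)
  pairs <- list()
  for (q in sort(unique(ab$query_id))) {
    s <- best(ab, q)
    if (!is.na(s) && identical(best(ba, s), q))
      pairs[[length(pairs) + 1L]] <- data.frame(a_id = q, b_id = s,
                                                stringsAsFactors = FALSE)
  }
  if (!length(pairs))
    return(data.frame(a_id = character(), b_id = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, pairs)
}

## Random two-direction similarity tables for RBH property tests.
randomSimPair <- function(nA = 20L, nB = 20L, density = 0.3) {
  aIds <- sprintf("a%02d", seq_len(nA))
  bIds <- sprintf("b%02d", seq_len(nB))
  grid <- expand.grid(query_id = aIds, subject_id = bIds,
                      stringsAsFactors = FALSE)
  keep <- runif(nrow(grid)) < density
  grid <- grid[keep, , drop = FALSE]
  n <- nrow(grid)
  mk <- function(g) {
    g$e_value <- 10^-runif(nrow(g), 2, 30)
    g$bit_score <- round(runif(nrow(g), 20, 400), 1)
    g$query_cov <- sample(150:300, nrow(g), replace = TRUE) / 300
    g$subject_cov <- sample(150:300, nrow(g), replace = TRUE) / 300
    g
  }
  ab <- mk(grid)
  ## independent reciprocal table over a random subset of the same pairs
  ba <- grid[sample(n, max(1L, round(0.8 * n))), , drop = FALSE]
  ba <- data.frame(query_id = ba$subject_id, subject_id = ba$query_id,
                   stringsAsFactors = FALSE)
  ba <- mk(ba)
  list(ab = ab, ba = ba)
}

## Compact GRanges builder: one replicon, genes given as (start, end,
## strand) triples in any order.
makeGenes <- function(starts, ends, strands, replicon = "chr1",
                      genome = "g1", seqlen = NA_integer_,
                      circular = FALSE) {
  gr <- GenomicRanges::GRanges(
    seqnames = replicon,
    ranges = IRanges::IRanges(starts, ends),
    strand = strands)
  GenomicRanges::mcols(gr)$gene_id <- sprintf("gene%02d", seq_along(gr))
  GenomicRanges::mcols(gr)$protein_id <- sprintf("p%02d", seq_along(gr))
  GenomicRanges::mcols(gr)$genome_id <- genome
  if (!is.na(seqlen))
    GenomeInfoDb::seqlengths(gr) <- seqlen
  if (circular)
    GenomeInfoDb::isCircular(gr) <- TRUE
  gr[order(GenomicRanges::start(gr))]
}

## Minimal in-code catalog builder.
makeCatalog <- function(families, roles = NULL, nDomains = NULL) {
  n <- length(families)
  if (is.null(roles)) roles <- rep("undefined", n)
  if (is.null(nDomains)) nDomains <- rep(1L, n)
  pf <- lapply(seq_len(n), function(i) {
    c(families[i], sprintf("PF97%03d", seq_len(nDomains[i] - 1L)))
  })
  new("TFCatalog", entries = S4Vectors::DataFrame(
    tf_id = sprintf("TF%03d", seq_len(n)),
    species = rep("Escherichia coli K-12", n),
    family_pfam = families,
    all_pfams = IRanges::CharacterList(pf),
    n_domains = as.integer(nDomains), role = roles,
    evidence = IRanges::CharacterList(as.list(rep("BPP", n)))))
}

## A small noise-free collection used by several recovery tests.
smallCollection <- function(seed = 11, nGenomes = 3L,
                            orfRange = c(150L, 400L),
                            domainFrac = 1, orthoFrac = 1) {
  generateCollection(generatorConfig(
    n_genomes = nGenomes, orf_range = orfRange,
    domain_detectable_frac = domainFrac,
    ortho_detectable_frac = orthoFrac, seed = seed))
}

## Run the prediction stage in-memory on a collection (domain + RBH +
## merge per genome), mirroring the file pipeline.
predictFromCollection <- function(coll, eMaxDom = 1e-3, eMaxOrtho = 1e-5,
                                  covMin = 0.70) {
  genes <- collectionGenes(coll)
  gm <- GenomicRanges::mcols(genes)
  sets <- lapply(sort(unique(gm$genome_id)), function(g) {
    pids <- gm$protein_id[gm$genome_id == g]
    dom <- coll@domainHits
    domCalls <- assignTFByDomain(dom[dom$protein_id %in% pids, ,
                                     drop = FALSE],
                                 coll@tfPfams, eMax = eMaxDom)
    ab <- coll@simCatalogAB
    ba <- coll@simCatalogBA
    ortho <- findOrthologsRBH(ab[ab$query_id %in% pids, , drop = FALSE],
                              ba[ba$subject_id %in% pids, , drop = FALSE],
                              eMax = eMaxOrtho, covMin = covMin)$a_id
    mergePredictions(domCalls, ortho, g)
  })
  combinePredictions(sets)
}
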