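test_that("intergenic distance counts bases strictly between genes", {
  up <- GenomicRanges::GRanges("chr1", IRanges::IRanges(100, 900))
  expect_equal(as.integer(intergenicDistance(
    up, GenomicRanges::GRanges("chr1", IRanges::IRanges(1001, 1800)))), 100L)
  expect_equal(as.integer(intergenicDistance(
    up, GenomicRanges::GRanges("chr1", IRanges::IRanges(901, 1800)))), 0L)
  ov <- intergenicDistance(
    up, GenomicRanges::GRanges("chr1", IRanges::IRanges(850, 1800)))
  expect_equal(as.integer(ov), 0L)
  expect_true(attr(ov, "overlap"))
  expect_error(intergenicDistance(
    up, GenomicRanges::GRanges("chr2", IRanges::IRanges(1001, 1800))),
    "same replicon")
})

test_that("TU prediction groups same-strand runs under the gap threshold", {
  ## gaps 20 and 30 on one strand -> a single 3-gene TU
  g1 <- makeGenes(c(1, 921, 1851), c(900, 1820, 2750), rep("+", 3))
  tus <- predictTUs(g1, gapMax = 50)
  expect_equal(nrow(tus), 1L)
  expect_equal(tus$n_genes, 3L)
  expect_equal(unlist(tus$gene_ids), paste0("gene0", 1:3),
               ignore_attr = TRUE)

  ## gap 500 splits
  g2 <- makeGenes(c(1, 1401), c(900, 2300), rep("+", 2))
  expect_equal(nrow(predictTUs(g2, gapMax = 50)), 2L)

  ## strand alternation always splits, even at tiny gaps
  g3 <- makeGenes(c(1, 911, 1821), c(900, 1810, 2720), c("+", "-", "+"))
  expect_equal(nrow(predictTUs(g3, gapMax = 50)), 3L)
})

test_that("TU prediction partitions every replicon's genes exactly once", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(5:40, 1)
    gaps <- sample(c(0:60, 200:400), n, replace = TRUE)
    starts <- cumsum(gaps + 900) - 900 + 1
    g <- makeGenes(starts, starts + 899,
                   sample(c("+", "-"), n, replace = TRUE))
    tus <- predictTUs(g, gapMax = 50)
    memb <- unlist(tus$gene_ids)
    expect_setequal(memb, GenomicRanges::mcols(g)$gene_id)
    expect_equal(length(memb), n)  # no duplicates
    ## within a TU: same strand and all internal gaps <= 50
    st <- setNames(as.character(GenomicRanges::strand(g)),
                   GenomicRanges::mcols(g)$gene_id)
    for (i in seq_len(nrow(tus))) {
      ids <- unlist(tus$gene_ids[i])
      expect_equal(length(unique(st[ids])), 1L)
      if (length(ids) > 1) {
        idx <- match(ids, GenomicRanges::mcols(g)$gene_id)
        gp <- GenomicRanges::start(g)[idx][-1] -
          GenomicRanges::end(g)[idx][-length(idx)] - 1
        expect_true(all(gp <= 50))
      }
    }
  }
})

test_that("circular replicons can merge the wraparound run", {
  g <- makeGenes(c(30, 1000, 2000), c(600, 1900, 2560),
                 c("+", "-", "+"), seqlen = 2600L, circular = TRUE)
  ## wrap gap = 2600 - 2560 + 30 - 1 = 69
  expect_equal(nrow(predictTUs(g, gapMax = 50, circular = TRUE)), 3L)
  expect_equal(nrow(predictTUs(g, gapMax = 100, circular = TRUE)), 2L)
})

test_that("context classification distinguishes divergent, in-TU and isolated TFs", {
  ## divergent: TF on + with left neighbor on -
  g1 <- makeGenes(c(100, 1000), c(900, 1800), c("-", "+"))
  call1 <- classifyTFContext("gene02", g1)
  expect_equal(call1$relation, "divergent")
  expect_equal(call1$partner_gene_id, "gene01")
  expect_equal(call1$intergenic_bp, 99L)

  ## mirrored geometry: TF on - with right neighbor on +
  g2 <- makeGenes(c(100, 1000), c(900, 1800), c("-", "+"))
  call2 <- classifyTFContext("gene01", g2)
  expect_equal(call2$relation, "divergent")

  ## convergent genes are NOT divergent (downstream-side neighbor)
  g3 <- makeGenes(c(100, 1000), c(900, 1800), c("+", "-"))
  expect_equal(classifyTFContext("gene01", g3)$relation, "isolated")
  expect_equal(classifyTFContext("gene02", g3)$relation, "isolated")

  ## cotranscription inside a same-strand run with small gaps
  g4 <- makeGenes(c(1, 911, 1821), c(900, 1810, 2720), rep("+", 3))
  call4 <- classifyTFContext("gene02", g4)
  expect_equal(call4$relation, "in_tu")
  expect_equal(call4$partner_gene_id, "gene01")

  ## lone gene on a replicon
  g5 <- makeGenes(100, 900, "+")
  expect_equal(classifyTFContext("gene01", g5)$relation, "isolated")

  expect_error(classifyTFContext("nope", g5), "nope")
})

test_that("overlapping divergent promoters get distance zero with an overlap flag", {
  g <- makeGenes(c(100, 850), c(900, 1700), c("-", "+"))
  call <- classifyTFContext("gene02", g)
  expect_equal(call$relation, "divergent")
  expect_equal(call$intergenic_bp, 0L)
  expect_true(call$overlap)
})

test_that("circular adjacency wraps the upstream neighbor across the origin", {
  ## TF at the start of the replicon on +; its left neighbor wraps to the
  ## last gene, which is on - => divergent across the origin
  g <- makeGenes(c(50, 2000, 3000), c(950, 2900, 3900), c("+", "+", "-"),
                 seqlen = 4000L, circular = TRUE)
  lin <- classifyTFContext("gene01", g, circular = FALSE)
  expect_false(lin$relation == "divergent")
  circ <- classifyTFContext("gene01", g, circular = TRUE)
  expect_equal(circ$relation, "divergent")
  expect_equal(circ$partner_gene_id, "gene03")
  ## wrap distance: 4000 - 3900 + 50 - 1 = 149
  expect_equal(circ$intergenic_bp, 149L)
})

test_that("context relations are exhaustive and mutually exclusive on generated genomes", {
  coll <- smallCollection(seed = 17, nGenomes = 2L)
  genes <- collectionGenes(coll)
  truth <- collectionTruth(coll)
  tfGenes <- truth$gene_id[truth$is_tf]
  calls <- classifyTFContext(tfGenes, genes, circular = TRUE)
  expect_equal(nrow(calls), length(tfGenes))
  expect_true(all(calls$relation %in% c("divergent", "in_tu", "isolated")))
  ## planted context is recovered exactly (gap distributions are separated
  ## from the TU threshold by construction)
  m <- merge(calls, truth, by.x = "tf_gene_id", by.y = "gene_id")
  expect_equal(m$relation, m$context_relation)
  ## divergent gaps match the planted gaps
  dv <- m[m$relation == "divergent", ]
  expect_equal(dv$intergenic_bp, dv$divergent_gap)
  ## no divergent call pairs genes within one TU
  tus <- predictTUs(genes, circular = TRUE)
  tuOf <- setNames(rep(tus$tu_id, lengths(tus$gene_ids)),
                   unlist(tus$gene_ids))
  dvp <- calls[calls$relation == "divergent", ]
  expect_true(all(tuOf[dvp$tf_gene_id] != tuOf[dvp$partner_gene_id]))
})

test_that("divergent distance histogram bins correctly and matches the geometric CDF", {
  calls <- data.frame(relation = "divergent",
                      intergenic_bp = c(10L, 60L, 110L))
  h <- divergentDistanceHistogram(calls, binWidth = 50)
  expect_equal(h$bin_start, c(0L, 50L, 100L))
  expect_equal(h$count, c(1L, 1L, 1L))
  expect_equal(attr(h, "fracWithin100"), 2 / 3)

  empty <- divergentDistanceHistogram(calls[0, ])
  expect_equal(nrow(empty), 0L)

  ## geometric gaps, mean 60: observed fraction <= 100 bp vs closed form
  set.seed(99)
  gaps <- rgeom(2000, 1 / 61)
  sim <- data.frame(relation = "divergent", intergenic_bp = gaps)
  frac <- attr(divergentDistanceHistogram(sim), "fracWithin100")
  expect_equal(frac, pgeom(100, 1 / 61), tolerance = 0.03 / pgeom(100, 1 / 61))
})
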