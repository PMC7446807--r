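test_that("domain route applies the E-value cutoff and deterministic tie-breaks", {
  tfp <- c("PF00126", "PF00440")
  h <- data.frame(
    protein_id = c("p1", "p2", "p3", "p3", "p4"),
    pfam_acc = c("PF00440", "PF00440", "PF00126", "PF00440", "PF00440"),
    e_value = c(1e-10, 1e-2, 1e-8, 1e-4, 1e-3),
    bit_score = c(80, 30, 60, 70, 25))
  calls <- assignTFByDomain(h, tfp)
  expect_setequal(calls$protein_id, c("p1", "p3", "p4"))
  expect_equal(calls$family_pfam[calls$protein_id == "p1"], "PF00440")
  ## p2 above threshold; boundary e-value 1e-3 (p4) is included
  expect_false("p2" %in% calls$protein_id)
  ## min-e-value wins regardless of accession order
  expect_equal(calls$family_pfam[calls$protein_id == "p3"], "PF00126")
  expect_equal(calls$best_e[calls$protein_id == "p3"], 1e-8)

  ## e-value tie resolved by bit score, then accession
  h2 <- data.frame(protein_id = "p5",
                   pfam_acc = c("PF00440", "PF00126"),
                   e_value = c(1e-6, 1e-6), bit_score = c(90, 50))
  expect_equal(assignTFByDomain(h2, tfp)$family_pfam, "PF00440")
  h3 <- data.frame(protein_id = "p6",
                   pfam_acc = c("PF00440", "PF00126"),
                   e_value = 1e-6, bit_score = 70)
  expect_equal(assignTFByDomain(h3, tfp)$family_pfam, "PF00126")

  expect_equal(nrow(assignTFByDomain(h[0, ], tfp)), 0L)
  expect_error(assignTFByDomain(h, character()), "nonempty")
})

test_that("reciprocal best hits require both directions and both-side coverage", {
  hit <- function(q, s, e = 1e-20, bit = 200, qc = 0.9, sc = 0.9)
    data.frame(query_id = q, subject_id = s, e_value = e, bit_score = bit,
               query_cov = qc, subject_cov = sc)
  ab <- rbind(hit("a1", "b1"), hit("a2", "b2", qc = 0.65, sc = 0.9),
              hit("a3", "b3"))
  ba <- rbind(hit("b1", "a1"), hit("b2", "a2", qc = 0.9, sc = 0.65))
  pairs <- findOrthologsRBH(ab, ba)
  expect_equal(pairs$a_id, "a1")   # a2 fails coverage; a3 one-directional
  expect_equal(pairs$b_id, "b1")

  ## one-sided coverage policy rescues the 0.65/0.9 pair
  pairs1 <- findOrthologsRBH(ab, ba, twoSided = FALSE)
  expect_setequal(pairs1$a_id, c("a1", "a2"))
})

test_that("RBH matches exhaustive mutual-best enumeration on random tables", {
  for (seed in 1:10) {
    set.seed(seed)
    sim <- randomSimPair(5L, 5L, density = 0.6)
    got <- findOrthologsRBH(sim$ab, sim$ba)
    want <- bruteForceRBH(sim$ab, sim$ba)
    expect_equal(got, want, ignore_attr = TRUE)
  }
})

test_that("RBH output is symmetric and each id appears in at most one pair", {
  for (seed in 1:5) {
    set.seed(100 + seed)
    sim <- randomSimPair(12L, 12L, density = 0.4)
    fwd <- findOrthologsRBH(sim$ab, sim$ba)
    rev <- findOrthologsRBH(sim$ba, sim$ab)
    expect_setequal(paste(fwd$a_id, fwd$b_id),
                    paste(rev$b_id, rev$a_id))
    expect_false(anyDuplicated(fwd$a_id) > 0)
    expect_false(anyDuplicated(fwd$b_id) > 0)
  }
})

test_that("relaxing thresholds never removes domain calls and only grows the qualifying hit set", {
  set.seed(42)
  h <- data.frame(protein_id = sprintf("p%d", 1:50),
                  pfam_acc = "PF00440",
                  e_value = 10^-runif(50, 1, 10), bit_score = 50)
  tight <- assignTFByDomain(h, "PF00440", eMax = 1e-5)
  wide <- assignTFByDomain(h, "PF00440", eMax = 1e-3)
  expect_true(all(tight$protein_id %in% wide$protein_id))

  ## the RBH qualifying-hit filter is monotone in both thresholds; queries
  ## with any qualifying hit at strict thresholds still have one when the
  ## thresholds are relaxed
  sim <- randomSimPair(15L, 15L, density = 0.5)
  qual <- function(e, cv) {
    ab <- sim$ab
    unique(ab$query_id[ab$e_value <= e &
                         pmin(ab$query_cov, ab$subject_cov) >= cv])
  }
  expect_true(all(qual(1e-10, 0.8) %in% qual(1e-5, 0.7)))
})

test_that("merge partitions the union of the two routes exactly", {
  dom <- data.frame(protein_id = c("A", "B"),
                    family_pfam = c("PF00440", "PF00126"),
                    best_e = c(1e-10, 1e-8))
  m <- mergePredictions(dom, c("B", "C"), "g1")
  p <- tfPredictions(m)
  expect_equal(p$provenance[p$protein_id == "A"], "domain_only")
  expect_equal(p$provenance[p$protein_id == "B"], "both")
  expect_equal(p$provenance[p$protein_id == "C"], "orthology_only")
  expect_true(is.na(p$family_pfam[p$protein_id == "C"]))

  m0 <- mergePredictions(dom, character(), "g1")
  expect_true(all(tfPredictions(m0)$provenance == "domain_only"))

  ## partition arithmetic invariant on random sets
  for (i in 1:10) {
    set.seed(i)
    domIds <- sample(letters, sample(0:20, 1))
    orthoIds <- sample(letters, sample(0:20, 1))
    dd <- data.frame(protein_id = domIds,
                     family_pfam = rep("PF00440", length(domIds)),
                     best_e = rep(1e-9, length(domIds)))
    cnt <- provenanceCounts(mergePredictions(dd, orthoIds, "g"))
    expect_equal(sum(cnt), length(union(domIds, orthoIds)))
    expect_equal(unname(cnt["both"]),
                 length(intersect(domIds, orthoIds)))
  }
})

test_that("census counts ORFs and TFs with density bounds respected", {
  genes <- makeGenes(seq(1, by = 1000, length.out = 10),
                     seq(900, by = 1000, length.out = 10),
                     rep("+", 10))
  dom <- data.frame(protein_id = c("p01", "p02"),
                    family_pfam = "PF00440", best_e = 1e-9)
  cen <- tfCensus(mergePredictions(dom, character(), "g1"), genes,
                  c(g1 = "gammaproteobacteria"))
  expect_equal(cen$n_orfs, 10L)
  expect_equal(cen$n_tfs, 2L)
  expect_equal(cen$tf_density, 0.2)
  expect_equal(cen$division, "gammaproteobacteria")

  none <- mergePredictions(dom[0, ], character(), "g1")
  expect_equal(tfCensus(none, genes)$tf_density, 0)

  allTf <- data.frame(protein_id = sprintf("p%02d", 1:10),
                      family_pfam = "PF00440", best_e = 1e-9)
  expect_equal(tfCensus(mergePredictions(allTf, character(), "g1"),
                        genes)$tf_density, 1)

  ghost <- data.frame(protein_id = "p99", family_pfam = "PF00440",
                      best_e = 1e-9)
  expect_error(tfCensus(mergePredictions(ghost, character(), "g1"), genes),
               "p99")
})

test_that("planted TFs are recovered with perfect precision/recall from noise-free evidence", {
  coll <- smallCollection(seed = 13, nGenomes = 3L,
                          domainFrac = 1, orthoFrac = 1)
  preds <- tfPredictions(predictFromCollection(coll))
  truth <- collectionTruth(coll)
  tfTruth <- truth[truth$is_tf, ]
  expect_setequal(preds$protein_id, tfTruth$protein_id)

  ## provenance matches the planted route-detectability flags
  m <- merge(preds, truth, by = "protein_id")
  expectProv <- ifelse(m$domain_detectable & m$orthology_detectable, "both",
                       ifelse(m$domain_detectable, "domain_only",
                              "orthology_only"))
  expect_equal(m$provenance, expectProv)
  ## domain-called families match the planted family labels
  domSel <- m$provenance %in% c("domain_only", "both")
  expect_equal(m$family_pfam[domSel], m$family[domSel])
})

test_that("family prevalence counts genomes with at least one family member", {
  p <- S4Vectors::DataFrame(
    genome_id = c("g1", "g1", "g2", "g3"),
    protein_id = c("a", "b", "c", "d"),
    family_pfam = c("PF04397", "PF04397", "PF04397", "PF00440"),
    provenance = "domain_only", best_e = 1e-9)
  prev <- familyPrevalence(new("TFPredictionSet", predictions = p),
                           nGenomes = 4L)
  expect_equal(prev$n_genomes[prev$family_pfam == "PF04397"], 2L)
  expect_equal(prev$prevalence_pct[prev$family_pfam == "PF04397"], 50)
})
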