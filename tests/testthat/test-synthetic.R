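test_that("generation is deterministic under a fixed seed", {
  c1 <- smallCollection(seed = 5, nGenomes = 2L)
  c2 <- smallCollection(seed = 5, nGenomes = 2L)
  expect_equal(collectionTruth(c1), collectionTruth(c2))
  expect_equal(as.data.frame(collectionGenes(c1)),
               as.data.frame(collectionGenes(c2)))
  expect_equal(c1@domainHits, c2@domainHits)
  expect_equal(c1@simCatalogAB, c2@simCatalogAB)
  d1 <- tempfile(); d2 <- tempfile()
  writeCollection(c1, d1); writeCollection(c2, d2)
  for (f in list.files(d1))
    expect_equal(unname(tools::md5sum(file.path(d1, f))),
                 unname(tools::md5sum(file.path(d2, f))),
                 label = f)
  ## a different seed changes the bundle
  c3 <- smallCollection(seed = 6, nGenomes = 2L)
  expect_false(identical(collectionTruth(c1), collectionTruth(c3)))
})

test_that("noise-free TF counts follow the power law deterministically", {
  pts <- generateScalingPoints(3, c(10000, 10000), a = 0.0007,
                               b = 1.5283, sigma = 0, seed = 1)
  expect_equal(pts$n_tfs, rep(round(0.0007 * 10000^1.5283), 3))
  expect_equal(pts$n_orfs, rep(10000L, 3))
})

test_that("every truth flag is realisable from the emitted evidence", {
  coll <- smallCollection(seed = 29, nGenomes = 3L,
                          domainFrac = 0.7, orthoFrac = 0.7)
  truth <- collectionTruth(coll)
  tf <- truth[truth$is_tf, ]
  dh <- coll@domainHits
  tfp <- coll@tfPfams
  qualifies <- dh$e_value <= 1e-3 & dh$pfam_acc %in% tfp
  hasQual <- tf$protein_id %in% dh$protein_id[qualifies]
  expect_equal(hasQual, tf$domain_detectable)

  ## non-TF proteins never carry a qualifying hit to a TF PFAM
  nonTf <- truth$protein_id[!truth$is_tf]
  expect_false(any(nonTf %in% dh$protein_id[qualifies]))

  ## orthology detectability realised through per-genome RBH
  for (g in unique(tf$genome_id)) {
    pids <- truth$protein_id[truth$genome_id == g]
    ab <- coll@simCatalogAB
    ba <- coll@simCatalogBA
    got <- findOrthologsRBH(ab[ab$query_id %in% pids, ],
                            ba[ba$subject_id %in% pids, ])$a_id
    want <- tf$protein_id[tf$genome_id == g & tf$orthology_detectable]
    expect_setequal(got, want)
    ## virulence flags likewise
    vab <- coll@simVFAB; vba <- coll@simVFBA
    gotV <- flagVirulence(vab[vab$query_id %in% pids, ],
                          vba[vba$subject_id %in% pids, ])
    wantV <- truth$protein_id[truth$genome_id == g & truth$virulence]
    expect_setequal(gotV, wantV)
  }
})

test_that("disabling divergent planting removes divergent context downstream", {
  coll <- generateCollection(generatorConfig(
    n_genomes = 2L, orf_range = c(150L, 300L), divergent_frac = 0,
    in_tu_frac = 0.5, seed = 3))
  truth <- collectionTruth(coll)
  expect_false(any(truth$context_relation %in% "divergent"))
  calls <- classifyTFContext(truth$gene_id[truth$is_tf],
                             collectionGenes(coll), circular = TRUE)
  expect_false(any(calls$relation == "divergent"))
})

test_that("the collection's empirical log-log slope converges to the configured exponent", {
  pts <- generateScalingPoints(2000, c(500, 12000), a = 7e-4, b = 1.5283,
                               sigma = 0.2, seed = 8)
  f <- fitScaling(pts)
  expect_equal(f$b[f$model == "power"], 1.5283,
               tolerance = 0.02 / 1.5283)
})

test_that("generator configuration is validated", {
  expect_error(generatorConfig(), "seed")
  expect_error(generatorConfig(divergent_frac = 1.4, seed = 1),
               "\\[0, 1\\]")
  expect_error(generatorConfig(divergent_frac = 0.6, in_tu_frac = 0.6,
                               seed = 1), "exceed 1")
  expect_error(generatorConfig(ec_class_freqs = rep(1, 6), seed = 1),
               "sum to 1")
  expect_error(generatorConfig(
    family_freqs = c(PF00001 = 0.9, PF00002 = 0.2), seed = 1),
    "at most 1")
})

test_that("division panels are generated under their declared models", {
  panel <- generateDivisionPanel(nGenomes = 30, seed = 4)
  models <- attr(panel, "models")
  expect_equal(length(unique(panel$division)), 8L)
  expect_setequal(unique(panel$division), names(models))
  expect_equal(unname(table(panel$division)[names(models)[1]]), 30L,
               ignore_attr = TRUE)

  ## noise-free panels are recovered 8/8
  quiet <- generateDivisionPanel(
    divisions = data.frame(
      division = sprintf("d%d", 1:8),
      model = rep(c("power", "linear"), each = 4),
      a = c(7e-4, 5e-4, 6e-4, 4e-4, -60, -40, -50, -45),
      b = c(1.5283, 1.55, 1.6, 1.7, 0.07, 0.05, 0.06, 0.055),
      sigma = 0),
    nGenomes = 30, orfRange = c(1000, 12000), seed = 9)
  sel <- selectModelPerDivision(quiet)
  expect_equal(stats::setNames(sel$model, sel$division),
               attr(quiet, "models")[sel$division])
})
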