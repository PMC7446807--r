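test_that("one-tailed Fisher p matches closed forms and enumeration", {
  ## all mass in one arrangement: P[X >= 5] with margins (5,5|5,5)
  expect_equal(fisherOneTailed(5, 0, 0, 5), 1 / choose(10, 5))
  ## a at its minimum given the margins -> upper tail is everything
  expect_equal(fisherOneTailed(0, 5, 5, 0), 1)
  expect_equal(fisherOneTailed(0, 0, 0, 0), 1)
  ## exhaustive enumeration for small margins
  for (r1 in 0:6) for (r2 in 0:6) for (c1 in 0:min(6, r1 + r2)) {
    for (a in max(0, c1 - r2):min(r1, c1)) {
      b <- r1 - a; cc <- c1 - a; d <- r2 - cc
      expect_equal(fisherOneTailed(a, b, cc, d),
                   bruteForceFisherUpper(a, b, cc, d),
                   tolerance = 1e-12)
    }
  }
  ## cross-check against the standard exact test on a few tables
  for (tbl in list(c(8, 2, 3, 7), c(1, 9, 5, 5), c(4, 4, 4, 4))) {
    ft <- fisher.test(matrix(tbl, 2, byrow = TRUE),
                      alternative = "greater")
    expect_equal(fisherOneTailed(tbl[1], tbl[2], tbl[3], tbl[4]),
                 ft$p.value, tolerance = 1e-10)
  }
  expect_error(fisherOneTailed(-1, 0, 0, 0), "nonnegative")
})

test_that("BH adjustment matches hand-computed step-up values and its invariants", {
  ## sorted p * m / rank = (.04, .04, .04, .04); cumulative min from the top
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  ## a hand-worked mixed case:
  ## sorted (.005,.01,.03,.5): *4/rank = .02,.02,.04,.5
  expect_equal(bhAdjust(c(0.03, 0.005, 0.5, 0.01)),
               c(0.04, 0.02, 0.5, 0.02))
  expect_equal(bhAdjust(0.123), 0.123)  # m = 1 identity
  set.seed(3)
  p <- runif(30)
  adj <- bhAdjust(p)
  expect_true(all(adj >= p))
  expect_true(all(diff(adj[order(p)]) >= -1e-15))  # monotone in sorted order
  ## order invariance
  perm <- sample(30)
  expect_equal(bhAdjust(p[perm]), adj[perm])
  expect_error(bhAdjust(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(bhAdjust(1.2), "\\(0, 1\\]")
})

test_that("enrichment composes Fisher + BH and respects the background contract", {
  fg <- sprintf("f%02d", 1:10)
  bg <- c(fg, sprintf("b%02d", 1:10))
  dom <- rbind(
    data.frame(protein_id = fg, pfam_acc = "PF11111"),
    data.frame(protein_id = sprintf("b%02d", 1:5), pfam_acc = "PF11111"),
    data.frame(protein_id = bg[seq(1, 20, 2)], pfam_acc = "PF22222"))
  res <- enrichNeighborPfams(fg, bg, dom, familyPfam = "PF00126")
  expect_equal(res$neighbor_pfam[1], "PF11111")
  top <- res[res$neighbor_pfam == "PF11111", ]
  expect_equal(top$p_value, fisherOneTailed(10, 0, 5, 5))
  expect_equal(c(top$a, top$b, top$c, top$d), c(10, 0, 5, 5))
  expect_equal(top$a + top$b + top$c + top$d, length(bg))
  expect_equal(res$fdr, bhAdjust(res$p_value))

  ## foreground = background -> nothing can be enriched
  same <- enrichNeighborPfams(bg, bg, dom)
  expect_true(all(same$p_value == 1))

  expect_error(enrichNeighborPfams(c(fg, "zz"), bg, dom), "subset")
})

test_that("GO terms are attached from a pfam2go mapping", {
  p2g <- data.frame(pfam_acc = "PF11111", go_id = "GO:0003677",
                    go_term = "DNA binding")
  dom <- data.frame(protein_id = c("f1", "f2"), pfam_acc = "PF11111")
  res <- enrichNeighborPfams(c("f1", "f2"), c("f1", "f2", "b1", "b2"),
                             dom, pfam2go = p2g)
  expect_match(res$go_terms[res$neighbor_pfam == "PF11111"], "GO:0003677")
})

test_that("a planted 5x enrichment is detected in at least 95% of replicates", {
  hits <- 0L
  for (seed in 1:200) {
    set.seed(seed)
    bg <- sprintf("g%03d", 1:500)
    fg <- bg[1:60]
    baseRate <- 0.05
    carriers <- c(bg[61:500][runif(440) < baseRate],
                  fg[runif(60) < 5 * baseRate])
    dom <- rbind(
      data.frame(protein_id = carriers, pfam_acc = "PFPLANT"),
      data.frame(protein_id = sample(bg, 50), pfam_acc = "PFNOISE1"),
      data.frame(protein_id = sample(bg, 50), pfam_acc = "PFNOISE2"))
    res <- enrichNeighborPfams(fg, bg, dom, alpha = 0.05)
    sig <- res$significant[res$neighbor_pfam == "PFPLANT"]
    if (length(sig) && sig) hits <- hits + 1L
  }
  expect_gte(hits, 190L)
})

test_that("scaling fits recover exact curves and noisy exponents", {
  x <- round(seq(600, 11000, length.out = 40))
  exact <- data.frame(n_orfs = x, n_tfs = 0.0007 * x^1.5283)
  fits <- fitScaling(exact)
  pw <- fits[fits$model == "power", ]
  expect_equal(pw$b, 1.5283, tolerance = 1e-6)
  expect_equal(pw$a, 0.0007, tolerance = 1e-6)
  expect_equal(pw$r2, 1, tolerance = 1e-12)
  expect_equal(pw$pearson_r, 1, tolerance = 1e-12)

  lin <- fitScaling(data.frame(n_orfs = x, n_tfs = 2 * x))
  lr <- lin[lin$model == "linear", ]
  expect_equal(lr$b, 2, tolerance = 1e-12)
  expect_equal(lr$r2, 1, tolerance = 1e-12)

  ## zero-TF points are excluded from the power fit with a warning
  withZero <- rbind(exact, data.frame(n_orfs = 500, n_tfs = 0))
  expect_warning(f0 <- fitScaling(withZero), "zero-TF")
  expect_equal(f0$n[f0$model == "power"], 40L)
  expect_equal(f0$n[f0$model == "linear"], 41L)

  pts <- generateScalingPoints(500, c(500, 12000), a = 7e-4, b = 1.5283,
                               sigma = 0.2, seed = 7)
  noisy <- fitScaling(pts)
  expect_equal(noisy$b[noisy$model == "power"], 1.5283,
               tolerance = 0.05 / 1.5283)
})

test_that("the log-log exponent estimator is unbiased within Monte-Carlo error", {
  bs <- vapply(1:500, function(seed) {
    pts <- generateScalingPoints(100, c(500, 12000), a = 7e-4, b = 1.5,
                                 sigma = 0.2, seed = seed)
    f <- fitScaling(pts)
    f$b[f$model == "power"]
  }, numeric(1))
  expect_equal(mean(bs), 1.5, tolerance = 0.01 / 1.5)
})

test_that("model selection picks the generating model and reports ambiguity", {
  panel <- generateDivisionPanel(
    divisions = data.frame(
      division = c("powerdiv", "lineardiv"),
      model = c("power", "linear"),
      a = c(7e-4, -20), b = c(1.5283, 0.03), sigma = c(0.2, 8)),
    nGenomes = 50, seed = 12)
  sel <- selectModelPerDivision(panel)
  expect_equal(sel$model[sel$division == "powerdiv"], "power")
  expect_equal(sel$model[sel$division == "lineardiv"], "linear")

  ## noise-free proportionality fits both models exactly -> ambiguous
  x <- round(seq(1000, 10000, length.out = 20))
  prop <- data.frame(division = "prop", n_orfs = x, n_tfs = 0.05 * x)
  expect_equal(selectModelPerDivision(prop)$model, "ambiguous")

  small <- data.frame(division = "tiny", n_orfs = x[1:5],
                      n_tfs = 0.05 * x[1:5])
  expect_warning(out <- selectModelPerDivision(small), "tiny")
  expect_equal(nrow(out), 0L)
})
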