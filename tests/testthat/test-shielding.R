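# The footprint-weighted mode-coverage statistic and replica statistics.

mkCoverage <- function(cov, ids = seq_along(cov), nFrames = 100L) {
  new("ResidueCoverage", residueIds = as.integer(ids),
      residueNames = rep("ALA", length(ids)), coverage = as.numeric(cov),
      cutoff = 0.3, nFrames = as.integer(nFrames))
}

test_that("mode coverage reproduces the hand-evaluated weighted mean", {
  fp <- modeFootprint("demo", c(1L, 2L), c(0.5, 1.0))
  rep1 <- mkCoverage(c(0.4, 0.2))
  r <- modeCoverage(list(rep1), fp)
  expect_equal(coverageMean(r), (0.5 * 0.4 + 1.0 * 0.2) / 1.5,
               tolerance = 1e-12)
  expect_equal(coverageMean(r), 0.26667, tolerance = 1e-4)
  expect_true(is.na(coverageSE(r)))
})

test_that("mode coverage respects bounds, scale invariance and zero-weight residues", {
  withr::with_seed(61, {
    for (k in 1:200) {
      n <- sample(2:12, 1)
      w <- runif(n)
      w[sample(n, 1)] <- runif(1, 0.2, 1)  # ensure one positive
      cv <- runif(n)
      fp <- modeFootprint("m", seq_len(n), w)
      r <- coverageMean(modeCoverage(list(mkCoverage(cv)), fp))
      active <- w > 0
      expect_gte(r, min(cv[active]) - 1e-12)
      expect_lte(r, max(cv[active]) + 1e-12)
      # uniform scaling of the weights cancels
      s <- runif(1, 0.01, 0.9)
      fps <- modeFootprint("m", seq_len(n), w * s)
      expect_equal(coverageMean(modeCoverage(list(mkCoverage(cv)), fps)), r,
                   tolerance = 1e-12)
      # appending a zero-weight residue changes nothing
      fp0 <- modeFootprint("m", c(seq_len(n), 99L), c(w, 0))
      cov0 <- mkCoverage(c(cv, runif(1)), c(seq_len(n), 99L))
      expect_equal(coverageMean(modeCoverage(list(cov0), fp0)), r,
                   tolerance = 1e-12)
    }
  })
  # degenerate extremes
  fp <- modeFootprint("m", 1:3, c(0.2, 0.5, 1))
  expect_equal(coverageMean(modeCoverage(list(mkCoverage(rep(1, 3))), fp)), 1)
  expect_equal(coverageMean(modeCoverage(list(mkCoverage(rep(0, 3))), fp)), 0)
})

test_that("replica mean and SE match the direct formulas", {
  fp <- modeFootprint("m", 1L, 1)
  withr::with_seed(71, {
    vals <- 0.5 + runif(15, -0.2, 0.2)
    reps <- lapply(vals, mkCoverage)
    r <- modeCoverage(reps, fp)
    expect_equal(coverageMean(r), mean(vals))
    expect_equal(coverageSE(r), sd(vals) / sqrt(15))
  })
})

test_that("missing footprint residues raise an error rather than silent zeros", {
  fp <- modeFootprint("m", c(1L, 7L), c(1, 1))
  expect_error(modeCoverage(list(mkCoverage(c(0.2, 0.3), ids = 1:2)), fp),
               regexp = "7", class = "gs_analysis_error")
  # all-zero footprints cannot be constructed
  expect_error(modeFootprint("m", 1:2, c(0, 0)))
})

test_that("key residue coverage reports replica mean and closed-form SE", {
  one <- keyResidueCoverage(list(mkCoverage(c(0.1, 0.9), ids = c(38L, 41L))),
                            38L)
  expect_equal(one$mean, 0.1)
  expect_true(is.na(one$se))
  two <- keyResidueCoverage(list(mkCoverage(0.2, ids = 38L),
                                 mkCoverage(0.4, ids = 38L)), 38L)
  expect_equal(two$mean, 0.3)
  expect_equal(two$se, 0.1)  # |0.2 - 0.4| / 2 * sqrt(2) / sqrt(2)
  # permuting replica order leaves the result unchanged
  reps <- lapply(c(0.1, 0.5, 0.7), mkCoverage, ids = 38L)
  expect_equal(keyResidueCoverage(reps, 38L),
               keyResidueCoverage(rev(reps), 38L))
  expect_error(keyResidueCoverage(reps, 999L), regexp = "999",
               class = "gs_analysis_error")
})

test_that("compareModes orders reports by mean coverage and pools SEs", {
  mk <- function(mode, vals) new("CoverageReport", mode = mode,
                                 perReplica = vals)
  withr::with_seed(81, {
    cryst <- mk("cryst", 0.51 + runif(5, -0.05, 0.05))
    par <- mk("parallel", 0.46 + runif(5, -0.05, 0.05))
    upr <- mk("upright", 0.30 + runif(5, -0.05, 0.05))
  })
  cmp <- compareModes(list(upr, cryst, par))
  expect_equal(cmp$order, c("cryst", "parallel", "upright"))
  expect_equal(cmp$pairs$diff[1],
               coverageMean(cryst) - coverageMean(par))
  expect_equal(cmp$pairs$pooled_se[1],
               sqrt(coverageSE(cryst)^2 + coverageSE(par)^2))
  # identical reports give zero difference
  cmp2 <- compareModes(list(cryst, cryst))
  expect_equal(cmp2$pairs$diff, 0)
  # mismatched replica counts are rejected
  short <- mk("x", c(0.1, 0.2))
  expect_error(compareModes(list(cryst, short)), class = "gs_analysis_error")
})

test_that("footprints round-trip through TSV", {
  fps <- toyFootprints()
  p <- tempfile(fileext = ".tsv")
  writeFootprints(fps, p)
  back <- readFootprints(p)
  expect_equal(names(back), names(fps))
  for (m in names(fps)) {
    expect_equal(residueIds(back[[m]]), residueIds(fps[[m]]))
    expect_equal(footprintWeights(back[[m]]), footprintWeights(fps[[m]]))
  }
})

test_that("the bundled example footprints load", {
  p <- system.file("extdata", "example_footprints.tsv",
                   package = "glycanshield")
  fps <- readFootprints(p)
  expect_setequal(names(fps), c("upright", "key_arginines"))
  expect_equal(sort(residueIds(fps$upright)),
               c(38L, 43L, 44L, 79L, 80L, 105L, 113L, 114L, 162L, 166L))
})
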