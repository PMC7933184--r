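# Combined and minimal CSP, titration classification.

test_that("combined CSP matches hand evaluation and is an even function", {
  expect_equal(combinedCSP(0, 0), 0)
  expect_equal(combinedCSP(0.1, 0.5, w = 0.2), sqrt(0.01 + 0.01))
  expect_equal(combinedCSP(0.1, 0.5, w = 0.2), 0.14142, tolerance = 1e-4)
  expect_equal(combinedCSP(-0.1, 0.5), combinedCSP(0.1, -0.5))
  expect_equal(combinedCSP(-0.1, -0.5), combinedCSP(0.1, 0.5))
  expect_error(combinedCSP(0.1, 0.5, w = -1), class = "gs_parameter_error")
  expect_error(combinedCSP(0.1, 0.5, w = 0), class = "gs_parameter_error")
})

test_that("identical free and bound lists give an all-zero profile", {
  free <- peakList("free", 1:5, "", dH_ppm = 7 + (1:5) / 10,
                   dN_ppm = 110 + 1:5)
  prof <- minimalCSPProfile(free, free)
  expect_equal(cspTable(prof)$csp_ppm, rep(0, 5))
  expect_equal(cspTable(prof)$assigned_csp_ppm, rep(0, 5))
})

test_that("a single moved peak is recovered and minimal CSP never exceeds assigned CSP", {
  free <- peakList("free", 1:6, "", dH_ppm = c(7, 7.5, 8, 8.5, 9, 9.5),
                   dN_ppm = c(105, 110, 115, 120, 125, 130))
  pb <- peakTable(free)
  pb$dH_ppm[3] <- pb$dH_ppm[3] + 0.1
  pb$dN_ppm[3] <- pb$dN_ppm[3] + 0.5
  bound <- peakList("bound", pb$residue_id, "", pb$dH_ppm, pb$dN_ppm)
  prof <- cspTable(minimalCSPProfile(free, bound))
  expect_equal(prof$csp_ppm[3], 0.14142, tolerance = 1e-4)
  expect_true(all(prof$csp_ppm <= prof$assigned_csp_ppm + 1e-12))
})

test_that("minimal CSP equals the brute-force minimum over all peak pairs", {
  withr::with_seed(103, {
    for (k in 1:30) {
      n <- sample(4:15, 1)
      free <- peakList("free", seq_len(n), "", runif(n, 6.5, 10),
                       runif(n, 100, 135))
      m <- sample(3:12, 1)
      bound <- peakList("bound", seq_len(m), "", runif(m, 6.5, 10),
                        runif(m, 100, 135))
      prof <- cspTable(minimalCSPProfile(free, bound))
      fp <- peakTable(free); bp <- peakTable(bound)
      for (i in seq_len(n)) {
        ref <- min(sqrt((fp$dH_ppm[i] - bp$dH_ppm)^2 +
                        (0.2 * (fp$dN_ppm[i] - bp$dN_ppm))^2))
        expect_equal(prof$csp_ppm[i], ref)
      }
    }
  })
})

test_that("the profile is invariant under a shared global reference offset", {
  withr::with_seed(107, {
    free <- peakList("free", 1:8, "", runif(8, 7, 9), runif(8, 105, 130))
    fp <- peakTable(free)
    bound <- peakList("bound", 1:8, "", fp$dH_ppm + rnorm(8, 0, 0.05),
                      fp$dN_ppm + rnorm(8, 0, 0.3))
    p0 <- cspTable(minimalCSPProfile(free, bound))$csp_ppm
    off <- c(0.37, -2.1)
    bp <- peakTable(bound)
    free2 <- peakList("free", 1:8, "", fp$dH_ppm + off[1], fp$dN_ppm + off[2])
    bound2 <- peakList("bound", 1:8, "", bp$dH_ppm + off[1],
                       bp$dN_ppm + off[2])
    p1 <- cspTable(minimalCSPProfile(free2, bound2))$csp_ppm
    expect_equal(p0, p1, tolerance = 1e-12)
  })
})

test_that("disappeared residues are flagged missing, empty bound pool errors", {
  free <- peakList("free", 1:3, "", c(7, 8, 9), c(110, 115, 120))
  bound <- peakList("bound", 1:3, "", c(7, 8, 9), c(110, 115, 120),
                    intensity = c(1, 0, 1), present = c(TRUE, FALSE, TRUE))
  prof <- cspTable(minimalCSPProfile(free, bound))
  expect_equal(prof$missing, c(FALSE, TRUE, FALSE))
  expect_true(is.na(prof$assigned_csp_ppm[2]))
  gone <- peakList("bound", integer(0), character(0), numeric(0), numeric(0))
  expect_error(minimalCSPProfile(free, gone), class = "gs_analysis_error")
})

mkTitration <- function(cspH, intensity = rep(1, length(cspH)),
                        secondary = FALSE) {
  # one residue followed over free + 3 points; cspH is the planted proton
  # offset at each titration point
  free <- peakList("free", 1L, "", 8, 115)
  series <- list(free)
  for (k in 1:3) {
    series[[k + 1L]] <- peakList(
      sprintf("HA %d:1", k), 1L, "", 8 + cspH[k], 115,
      intensity = intensity[k],
      secondary_dH = if (secondary) 8.05 else NA_real_,
      secondary_dN = if (secondary) 115.2 else NA_real_,
      present = intensity[k] > 0)
  }
  series
}

test_that("titration classifier implements the category definitions", {
  # full shift already at 1:1 with stable intensity -> instant_shift
  inst <- classifyTitration(mkTitration(c(0.14, 0.14, 0.14)))
  expect_equal(as.character(inst$category), "instant_shift")
  expect_false(inst$doubled)
  # collapsing intensity -> instant_disappearance
  gone <- classifyTitration(mkTitration(c(0, 0, 0),
                                        intensity = c(0.05, 0, 0)))
  expect_equal(as.character(gone$category), "instant_disappearance")
  # growing shift -> gradual_shift (0.03 / 0.12 < f_inst)
  grad <- classifyTitration(mkTitration(c(0.03, 0.07, 0.12)))
  expect_equal(as.character(grad$category), "gradual_shift")
  # below the perturbation floor -> unperturbed
  flat <- classifyTitration(mkTitration(c(0.005, 0.008, 0.01)))
  expect_equal(as.character(flat$category), "unperturbed")
  # populated secondary slot -> doubled
  dbl <- classifyTitration(mkTitration(c(0.14, 0.14, 0.14), secondary = TRUE))
  expect_true(dbl$doubled)
  expect_error(classifyTitration(mkTitration(c(0.1, 0.1, 0.1))[1:2]),
               class = "gs_analysis_error")
})

test_that("peak lists round-trip through TSV", {
  pl <- peakList("HA 1:1", c(38L, 43L), c("LYS", "SER"),
                 c(8.1, 7.9), c(118.2, 110.7), intensity = c(0.8, 1),
                 secondary_dH = c(8.15, NA), secondary_dN = c(118.4, NA))
  p <- tempfile(fileext = ".tsv")
  writePeakList(pl, p)
  back <- readPeakList(p, "HA 1:1")
  expect_equal(peakTable(back), peakTable(pl))
})
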