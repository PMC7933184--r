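# Generators: planted ground truth must round-trip through the analysis.

test_that("zero planted occlusion yields all-zero receptor coverage", {
  sc <- quickScenario(50L, seed = 19L, plantedOcclusion = setNames(numeric(0),
                                                                   character(0)))
  res <- genShieldedTrajectory(sc)
  covs <- coveragePerReplica(list(res$system), "entity receptor",
                             "entity glycan_*")
  expect_true(all(coverage(covs[[1]]) == 0))
})

test_that("planted occlusion fractions are recovered exactly by frame counting", {
  sc <- quickScenario(1000L, seed = 29L,
                      plantedOcclusion = c("25" = 0.5, "83" = 0.123,
                                           "160" = 0.999))
  res <- genShieldedTrajectory(sc)
  cv <- coverage(coveragePerReplica(list(res$system), "entity receptor",
                                    "entity glycan_*")[[1]])
  gt <- res$groundTruth$occlusion
  expect_equal(unname(cv[as.character(gt$residue_id)]), gt$exact_fraction)
  expect_equal(gt$exact_fraction, round(gt$planted_fraction * 1000) / 1000)
  # residues without planted occlusion stay untouched
  others <- setdiff(names(cv), as.character(gt$residue_id))
  expect_true(all(cv[others] == 0))
})

test_that("the scripted ligand schedule is the events ground truth", {
  sc <- shieldScenario(nFrames = 600L, seed = 37L,
                       schedule = data.frame(start_ns = c(5, 20, 40),
                                             end_ns = c(12, 33, 55)))
  res <- genShieldedTrajectory(sc)
  ev <- bindingEvents(res$system, "entity ligand_HA6_1", "entity receptor")
  expect_equal(nrow(ev), 3L)
  expect_equal(ev$duration_ns, res$groundTruth$schedule$duration_ns)
})

test_that("trajectory generation is reproducible by seed", {
  a <- genShieldedTrajectory(quickScenario(20L, seed = 41L))
  b <- genShieldedTrajectory(quickScenario(20L, seed = 41L))
  c <- genShieldedTrajectory(quickScenario(20L, seed = 42L))
  expect_identical(coordArray(a$system), coordArray(b$system))
  expect_false(identical(coordArray(a$system), coordArray(c$system)))
  # replicas differ in frames but share the exact planted fractions
  r2 <- genShieldedTrajectory(quickScenario(20L, seed = 41L), replicate = 2L)
  expect_false(identical(coordArray(a$system), coordArray(r2$system)))
  expect_equal(a$groundTruth$occlusion$exact_fraction,
               r2$groundTruth$occlusion$exact_fraction)
})

test_that("infeasible scenarios are rejected at construction", {
  expect_error(shieldScenario(seed = 1L, glycanBeads = 2L),
               class = "gs_generation_error")
  expect_error(shieldScenario(seed = 1L,
                              plantedOcclusion = c("41" = 1.2)),
               class = "gs_parameter_error")
  expect_error(shieldScenario(seed = 1L,
                              schedule = data.frame(start_ns = 10,
                                                    end_ns = 5000)),
               class = "gs_parameter_error")
  expect_error(shieldScenario(nFrames = 10L), "seed")
})

test_that("generated GRO files parse and analyses agree after reload", {
  dir <- tempfile("roundtrip_")
  sc <- shieldScenario(nFrames = 100L, seed = 43L,
                       schedule = data.frame(start_ns = 2, end_ns = 6))
  res <- genShieldedTrajectory(sc, dir = dir)
  top <- loadStructure(res$paths[["topology"]],
                       entityMap = res$paths[["entities"]])
  sys <- loadTrajectory(res$paths[["trajectory"]], top)
  expect_equal(nFrames(sys), 100L)
  cv <- coverage(coveragePerReplica(list(sys), "entity receptor",
                                    "entity glycan_*")[[1]])
  gt <- res$groundTruth$occlusion
  expect_equal(unname(cv[as.character(gt$residue_id)]), gt$exact_fraction)
  ev <- bindingEvents(sys, "entity ligand_HA6_1", "entity receptor")
  expect_equal(ev$duration_ns, res$groundTruth$schedule$duration_ns)
})

test_that("titration generator plants recoverable categories at zero noise", {
  res <- genTitrationPeaks(toyTitrationScenario(seed = 47L))
  cls <- classifyTitration(res$series)
  gt <- res$groundTruth
  expect_equal(as.character(cls$category), gt$category)
  expect_equal(cls$doubled, gt$doubled)
  # the planted instant perturbation reproduces the canonical minimal CSP
  prof <- cspTable(minimalCSPProfile(res$series[[1]], res$series[[2]]))
  i <- which(gt$residue_id == 43L)  # planted delta (0.1, 0.5)
  expect_equal(prof$csp_ppm[prof$residue_id == 43L], 0.14142,
               tolerance = 1e-4)
})

test_that("titration peak lists are reproducible by seed and sensitive to it", {
  a <- genTitrationPeaks(toyTitrationScenario(seed = 53L))
  b <- genTitrationPeaks(toyTitrationScenario(seed = 53L))
  c <- genTitrationPeaks(toyTitrationScenario(seed = 54L))
  expect_identical(peakTable(a$series[[2]]), peakTable(b$series[[2]]))
  expect_false(identical(peakTable(a$series[[2]]), peakTable(c$series[[2]])))
  # high noise warns that classifier recovery is not guaranteed
  expect_warning(toyTitrationScenario(seed = 1L, noise = 0.05),
                 regexp = "floor")
})
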