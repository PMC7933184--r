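# Ligand association/dissociation detection.

test_that("a scripted unbound-bound-unbound series yields exactly one event", {
  dt <- 0.1
  d <- c(rep(1.0, 50), rep(0.1, 100), rep(1.0, 50))  # 5 / 10 / 5 ns
  ev <- bindingEventsFromSeries(d, dt)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$duration_ns, 10)
  expect_equal(ev$start_ns, 5)
  expect_equal(ev$end_ns, 15)
})

test_that("a single-frame dip below the on-cutoff is filtered by the dwell time", {
  d <- rep(1.0, 100)
  d[50] <- 0.1
  ev <- bindingEventsFromSeries(d, dt = 0.1, minDwell = 1.0)
  expect_equal(nrow(ev), 0L)
})

test_that("equal cutoffs and zero dwell reduce to simple thresholding", {
  withr::with_seed(31, {
    for (k in 1:20) {
      d <- runif(200, 0, 0.8)
      ev <- bindingEventsFromSeries(d, dt = 0.1, onCutoff = 0.3,
                                    offCutoff = 0.3, minDwell = 0)
      r <- rle(d < 0.3)
      expect_equal(nrow(ev), sum(r$values))
      expect_equal(sum(ev$duration_ns), sum(r$lengths[r$values]) * 0.1)
    }
  })
})

test_that("event counts and durations equal the reference state machine on telegraph signals", {
  withr::with_seed(47, {
    for (k in 1:100) {
      # telegraph-like signal jumping between bound-ish and unbound-ish
      # levels, with occasional mid-zone excursions
      n <- sample(100:400, 1)
      state <- cumsum(rbinom(n, 1, 0.05)) %% 2
      d <- ifelse(state == 1, runif(n, 0.05, 0.25), runif(n, 0.55, 1.5))
      mid <- sample(n, size = max(1, n %/% 20))
      d[mid] <- runif(length(mid), 0.3, 0.5)
      dwell <- sample(c(0, 0.3, 0.5, 1.0), 1)
      ev <- bindingEventsFromSeries(d, dt = 0.1, minDwell = dwell)
      ref <- refBindingEvents(d, 0.1, 0.3, 0.5, dwell)
      expect_equal(nrow(ev), nrow(ref))
      expect_equal(ev$start_frame, ref$start_frame)
      expect_equal(ev$end_frame, ref$end_frame)
      expect_equal(ev$duration_ns, ref$duration_ns)
    }
  })
})

test_that("parameter and length preconditions are enforced", {
  expect_error(bindingEventsFromSeries(rep(1, 10), dt = 0.1, onCutoff = 0.5,
                                       offCutoff = 0.3),
               class = "gs_parameter_error")
  expect_error(bindingEventsFromSeries(rep(1, 5), dt = 0.1, minDwell = 1.0),
               class = "gs_analysis_error")
})

test_that("scripted binding episodes in a trajectory are recovered with exact durations", {
  res <- genShieldedTrajectory(shieldScenario(nFrames = 1000L, seed = 5L))
  ev <- bindingEvents(res$system, "entity ligand_HA6_1", "entity receptor")
  gt <- res$groundTruth$schedule
  expect_equal(nrow(ev), nrow(gt))
  expect_equal(ev$start_ns, gt$start_ns)
  expect_equal(ev$duration_ns, gt$duration_ns)
})
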