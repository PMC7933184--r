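# Shrake-Rupley SASA and buried interface areas.

singleAtomSystem <- function(r = 0.15) {
  makeSystem(matrix(c(0, 0, 0), 1), residue_id = 1L, entity = "A",
             radius = r)
}

pairSystem <- function(d, r = 0.15) {
  makeSystem(rbind(c(0, 0, 0), c(d, 0, 0)), residue_id = c(1L, 2L),
             entity = c("A", "B"), radius = r)
}

test_that("an isolated sphere matches the closed form", {
  s <- calcSASA(singleAtomSystem(), "all", probe = 0.14, nPoints = 960L)
  expect_equal(totalArea(s), 4 * pi * 0.29^2, tolerance = 5e-3)
  # probe 0 gives the bare vdW sphere
  s0 <- calcSASA(singleAtomSystem(), "all", probe = 0)
  expect_equal(totalArea(s0), 4 * pi * 0.15^2, tolerance = 5e-3)
})

test_that("coincident duplicate atoms expose the surface of a single sphere", {
  sys <- makeSystem(rbind(c(0, 0, 0), c(0, 0, 0)), residue_id = c(1L, 2L),
                    entity = "A", radius = 0.15)
  s <- calcSASA(sys, "all")
  expect_equal(totalArea(s), 4 * pi * 0.29^2, tolerance = 5e-3)
})

test_that("two overlapping spheres match the analytic cap formula within 1 percent", {
  R <- 0.29
  for (d in c(0.1, 0.25, 0.4, 0.55)) {
    s <- calcSASA(pairSystem(d), "all", nPoints = 960L)
    expect_equal(totalArea(s), twoSphereArea(R, d),
                 tolerance = 0.01)
  }
})

test_that("SASA decreases as two rigid bodies approach into contact", {
  areas <- vapply(c(1.0, 0.57, 0.45, 0.30, 0.15), function(d)
    totalArea(calcSASA(pairSystem(d), "all")), numeric(1))
  expect_true(all(diff(areas) <= areas[-length(areas)] * 0.01))
  expect_lt(areas[length(areas)], areas[1])
})

test_that("SASA is invariant under rigid motion when the point set rotates with the molecule", {
  withr::with_seed(91, {
    xyz <- matrix(runif(20 * 3, 0, 0.8), 20)
    sys <- makeSystem(xyz, residue_id = 1:20, entity = "A", radius = 0.15)
    pts <- spherePoints(960L)
    a0 <- atomAreas(calcSASA(sys, "all", points = pts))
    th <- 1.1
    R <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)), 3,
                byrow = TRUE)
    sys2 <- makeSystem(xyz %*% t(R) + 2, residue_id = 1:20, entity = "A",
                       radius = 0.15)
    a1 <- atomAreas(calcSASA(sys2, "all", points = pts %*% t(R)))
    expect_equal(a0, a1, tolerance = 1e-9)
  })
})

test_that("interface area is symmetric, zero for distant partners, analytic for a touching pair", {
  far <- pairSystem(5)
  expect_lt(abs(interfaceArea(far, "entity A", "entity B")), 0.01)
  near <- pairSystem(0.3)
  ab <- interfaceArea(near, "entity A", "entity B")
  ba <- interfaceArea(near, "entity B", "entity A")
  expect_identical(ab, ba)
  R <- 0.29; h <- R - 0.3 / 2
  expect_equal(ab, 2 * pi * R * h, tolerance = 0.01)
  # the un-halved convention doubles the value exactly
  expect_identical(interfaceArea(near, "entity A", "entity B",
                                 halved = FALSE), 2 * ab)
  expect_error(interfaceArea(near, "entity A", "entity A"),
               class = "gs_analysis_error")
})

test_that("interface converges with the sphere-point count", {
  withr::with_seed(97, {
    xyz <- rbind(matrix(runif(10 * 3, 0, 0.5), 10),
                 matrix(runif(10 * 3, 0, 0.5), 10) + 0.35)
    sys <- makeSystem(xyz, residue_id = 1:20,
                      entity = rep(c("A", "B"), each = 10), radius = 0.15)
    i1 <- interfaceArea(sys, "entity A", "entity B", nPoints = 960L)
    i2 <- interfaceArea(sys, "entity A", "entity B", nPoints = 1920L)
    expect_lt(abs(i2 - i1) / i1, 0.005)
  })
})

test_that("interface series aggregates replicas with mean and sample SE", {
  mk <- function(d) pairSystem(d)
  # planted identical replicas: SE exactly 0
  same <- interfaceSeries(list(mk(0.3), mk(0.3), mk(0.3)),
                          "entity A", "entity B")
  expect_equal(attr(same, "se"), 0)
  reps <- interfaceSeries(list(mk(0.25), mk(0.45)), "entity A", "entity B")
  v <- reps$area_nm2
  expect_equal(attr(reps, "mean"), mean(v))
  expect_equal(attr(reps, "se"), sd(v) / sqrt(2))
  # permutation invariance of the aggregate
  rev2 <- interfaceSeries(list(mk(0.45), mk(0.25)), "entity A", "entity B")
  expect_equal(attr(rev2, "mean"), attr(reps, "mean"))
  expect_equal(attr(rev2, "se"), attr(reps, "se"))
  expect_error(interfaceSeries(list(), "entity A", "entity B"),
               class = "gs_analysis_error")
})

test_that("SASA parameter preconditions are enforced", {
  sys <- singleAtomSystem()
  expect_error(calcSASA(sys, "all", nPoints = 16L),
               class = "gs_parameter_error")
  bad <- sys
  bad@atoms$radius <- NA_real_
  expect_error(calcSASA(bad, "all"), class = "gs_config_error")
})
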