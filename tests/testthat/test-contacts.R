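# Distances, contact fractions, contact matrices, surface maps.

twoAtomSystem <- function(p1, p2, box = NULL) {
  makeSystem(rbind(p1, p2), residue_id = c(1L, 2L), entity = c("grp", "tgt"),
             box = box)
}

test_that("minimum distances honor geometry and the minimum-image convention", {
  sys <- twoAtomSystem(c(0, 0, 0), c(0.3, 0, 0))
  s <- minDistancePerResidue(sys, "entity grp", "entity tgt")
  expect_equal(unname(distanceMatrix(s)[1, 1]), 0.3)
  # in a 1 nm cubic box the 0.9 separation wraps to 0.1
  sysp <- twoAtomSystem(c(0, 0, 0), c(0.9, 0, 0), box = c(1, 1, 1))
  sp <- minDistancePerResidue(sysp, "entity grp", "entity tgt")
  expect_equal(unname(distanceMatrix(sp)[1, 1]), 0.1)
})

test_that("overlapping group and target selections are rejected", {
  sys <- twoAtomSystem(c(0, 0, 0), c(0.3, 0, 0))
  expect_error(minDistancePerResidue(sys, "all", "entity tgt"),
               class = "gs_analysis_error")
})

test_that("both distance paths equal the all-pairs reference on random periodic systems", {
  withr::with_seed(101, {
    for (k in 1:20) {
      nA <- sample(5:25, 1); nB <- sample(5:25, 1)
      nf <- sample(2:4, 1)
      sys <- randomTwoGroupSystem(nA, nB, nf, periodic = (k %% 2 == 0))
      sb <- minDistancePerResidue(sys, "entity grp", "entity tgt",
                                  method = "brute")
      sc <- minDistancePerResidue(sys, "entity grp", "entity tgt",
                                  method = "cell")
      expect_identical(distanceMatrix(sb), distanceMatrix(sc))
      for (f in seq_len(nf)) {
        ref <- refMinDist(sys, residueIds(sb),
                          resolveSelection(sys, "entity tgt"), f)
        expect_lt(max(abs(distanceMatrix(sb)[f, ] - ref)), 1e-9)
      }
    }
  })
})

test_that("min distances are invariant under rigid rotation and translation", {
  withr::with_seed(7, {
    xyz <- matrix(runif(30 * 3, 0, 2), 30)
    sys <- makeSystem(xyz, residue_id = 1:30,
                      entity = c(rep("grp", 15), rep("tgt", 15)))
    s0 <- distanceMatrix(minDistancePerResidue(sys, "entity grp", "entity tgt"))
    th <- 0.83
    R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3,
                byrow = TRUE)
    xyz2 <- xyz %*% t(R) + matrix(c(3, -1, 2), 30, 3, byrow = TRUE)
    sys2 <- makeSystem(xyz2, residue_id = 1:30,
                       entity = c(rep("grp", 15), rep("tgt", 15)))
    s1 <- distanceMatrix(minDistancePerResidue(sys2, "entity grp", "entity tgt"))
    expect_lt(max(abs(s0 - s1)), 1e-9)
  })
})

test_that("contact fraction counts frames below the cutoff with strict inequality", {
  # distances [0.2, 0.4, 0.2, 0.4] at cutoff 0.3 -> 0.5
  xyz <- array(0, dim = c(2, 3, 4))
  for (f in 1:4) xyz[2, 1, f] <- c(0.2, 0.4, 0.2, 0.4)[f]
  sys <- makeSystem(xyz, residue_id = c(1L, 2L), entity = c("grp", "tgt"))
  s <- minDistancePerResidue(sys, "entity grp", "entity tgt")
  expect_equal(unname(coverage(contactFraction(s, 0.3))), 0.5)
  # ties (distance exactly at the cutoff) do not count as contact
  expect_equal(unname(coverage(contactFraction(s, 0.2))), 0)
  expect_equal(unname(coverage(contactFraction(s, 0.4000001))), 1)
  # bounds
  expect_equal(unname(coverage(contactFraction(s, 0.01))), 0)
  expect_equal(unname(coverage(contactFraction(s, 10))), 1)
})

test_that("contact fraction is monotone in the cutoff and matches direct counting", {
  withr::with_seed(11, {
    for (k in 1:10) {
      sys <- randomTwoGroupSystem(8, 8, 6)
      s <- minDistancePerResidue(sys, "entity grp", "entity tgt")
      dm <- distanceMatrix(s)
      cuts <- sort(runif(4, 0.1, 2))
      covs <- lapply(cuts, function(ct) coverage(contactFraction(s, ct)))
      for (j in seq_along(cuts)) {
        expect_equal(unname(covs[[j]]), unname(colMeans(dm < cuts[j])))
        if (j > 1) expect_true(all(covs[[j]] >= covs[[j - 1]]))
      }
    }
  })
})

test_that("pair contact counts match construction and brute-force enumeration", {
  # two single-atom entities 0.5 nm apart -> one pair within 0.6 nm
  sys <- twoAtomSystem(c(0, 0, 0), c(0.5, 0, 0))
  cm <- pairContactCounts(sys, c("grp", "tgt"))
  expect_equal(unname(contactCounts(cm)["grp", "tgt"]), 1)
  expect_equal(contactCounts(cm), t(contactCounts(cm)))
  # beyond the cutoff in every frame -> 0
  far <- twoAtomSystem(c(0, 0, 0), c(2, 0, 0))
  expect_equal(unname(contactCounts(pairContactCounts(far, c("grp", "tgt")))["grp", "tgt"]),
               0)
  withr::with_seed(23, {
    for (k in 1:10) {
      sys <- randomTwoGroupSystem(10, 12, 3)
      for (m in c("cell", "brute")) {
        cm <- pairContactCounts(sys, c("grp", "tgt"), cutoff = 0.6, method = m)
        ref <- mean(vapply(1:3, function(f)
          refPairCount(sys, resolveSelection(sys, "entity grp"),
                       resolveSelection(sys, "entity tgt"), 0.6, f),
          numeric(1)))
        expect_equal(unname(contactCounts(cm)["grp", "tgt"]), ref)
      }
    }
  })
})

test_that("surface distance map averages replicas and clamps for display", {
  mk <- function(d) {
    xyz <- array(0, dim = c(2, 3, 2))
    xyz[2, 1, ] <- d
    makeSystem(xyz, residue_id = c(1L, 2L), entity = c("grp", "tgt"))
  }
  one <- surfaceDistanceMap(list(mk(0.7)), "entity grp", "entity tgt")
  expect_equal(one$mean_nm, 0.7)
  expect_equal(one$clamped_nm, 0.7)
  two <- surfaceDistanceMap(list(mk(2.0)), "entity grp", "entity tgt")
  expect_equal(two$mean_nm, 2.0)
  expect_equal(two$clamped_nm, 1.5)
  # three replicas with planted means average arithmetically
  tri <- surfaceDistanceMap(list(mk(0.4), mk(0.8), mk(1.5)),
                            "entity grp", "entity tgt")
  expect_equal(tri$mean_nm, mean(c(0.4, 0.8, 1.5)))
  expect_equal(tri$n_replicas, 3)
})

test_that("surface distance map rejects replicas with mismatched residues", {
  a <- makeSystem(rbind(c(0, 0, 0), c(1, 0, 0)), residue_id = c(1L, 2L),
                  entity = c("grp", "tgt"))
  b <- makeSystem(rbind(c(0, 0, 0), c(1, 0, 0)), residue_id = c(5L, 2L),
                  entity = c("grp", "tgt"))
  expect_error(surfaceDistanceMap(list(a, b), "entity grp", "entity tgt"),
               class = "gs_analysis_error")
})
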