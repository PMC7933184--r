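## Shrake-Rupley solvent-accessible surface areas and buried interface
## areas. Sphere sample points come from a deterministic golden-section
## spiral (seedless), so results are bit-stable; SASA ignores periodic
## images (selections are assumed whole and unwrapped). Waters and ions
## should simply be left out of the selections.

#' Quasi-uniform unit sphere points (golden-section spiral)
#'
#' Deterministic point set used for Shrake-Rupley sampling; exposed so
#' callers can supply a rotated point set when checking rigid-motion
#' invariance.
#'
#' @param n number of points (>= 32 for SASA use).
#' @return n x 3 matrix of unit vectors.
#' @export
spherePoints <- function(n) {
  k <- seq_len(n) - 0.5
  z <- 1 - 2 * k / n
  phi <- pi * (3 - sqrt(5)) * k
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Samples points on each atom's probe-expanded sphere (radius r_i +
#' probe); a point is accessible when outside every other expanded sphere,
#' and the atom's area is the accessible fraction of 4 pi (r_i + probe)^2.
#' Points falling exactly on another sphere's surface are owned by the
#' lower-indexed atom, so coincident duplicate atoms do not double-count
#' surface.
#'
#' @param system a \linkS4class{MolecularSystem}.
#' @param selection atoms to include (selection string or atom ids); atoms
#'   outside the selection are ignored entirely, i.e. "A alone" semantics.
#' @param probe probe radius in nm (default 0.14, a water-sized probe).
#' @param nPoints sphere sample points per atom (default 960; minimum 32).
#' @param frame frame index.
#' @param points optional custom unit-vector matrix overriding
#'   [spherePoints()] (advanced; used for invariance checks).
#' @return a \linkS4class{SASAResult} (areas in nm^2).
#' @export
calcSASA <- function(system, selection, probe = 0.14, nPoints = 960L,
                     frame = 1L, points = NULL) {
  if (nPoints < 32) parameterError("nPoints must be >= 32 (got %d)", nPoints)
  if (probe < 0) parameterError("probe radius must be >= 0")
  ids <- resolveSelection(system, selection)
  idx <- match(ids, system@atoms$atom_id)
  radii <- system@atoms$radius[idx]
  if (anyNA(radii))
    configError("missing vdW radius for element(s): %s",
                paste(unique(system@atoms$element[idx][is.na(radii)]),
                      collapse = ", "))
  xyz <- frameCoords(system, frame)[idx, , drop = FALSE]
  pts <- if (is.null(points)) spherePoints(nPoints) else points
  areas <- .cpp_sasa(xyz, radii, probe, pts)
  methods::new("SASAResult", atomAreas = as.numeric(areas), probe = probe,
               nPoints = as.integer(nrow(pts)))
}

#' Buried interface area between two selections
#'
#' interface = (SASA(A alone) + SASA(B alone) - SASA(A union B)) / 2,
#' where "alone" removes the partner's atoms entirely. The halved value is
#' the per-face buried area; set \code{halved = FALSE} for the total
#' buried area.
#'
#' @param system a \linkS4class{MolecularSystem}.
#' @param partA,partB disjoint selections.
#' @param frame frame index.
#' @param probe,nPoints SASA parameters, see [calcSASA()].
#' @param halved divide by two (default TRUE).
#' @return interface area in nm^2 (>= 0 up to sampling noise).
#' @export
interfaceArea <- function(system, partA, partB, frame = 1L, probe = 0.14,
                          nPoints = 960L, halved = TRUE) {
  ia <- resolveSelection(system, partA)
  ib <- resolveSelection(system, partB)
  if (length(intersect(ia, ib)))
    analysisError("partA and partB selections overlap")
  sA <- totalArea(calcSASA(system, ia, probe, nPoints, frame))
  sB <- totalArea(calcSASA(system, ib, probe, nPoints, frame))
  sAB <- totalArea(calcSASA(system, sort(c(ia, ib)), probe, nPoints, frame))
  buried <- sA + sB - sAB
  if (halved) buried / 2 else buried
}

#' Replica-aggregated interface areas
#'
#' Evaluates the buried interface at a designated frame of each replica —
#' \code{at = "final"} takes the last frame, mirroring end-of-trajectory
#' interface comparisons; a numeric \code{at} averages the listed frames
#' within each replica — then reports per-replica values with mean and
#' sample standard error.
#'
#' @param replicaSystems non-empty list of \linkS4class{MolecularSystem}.
#' @param partA,partB disjoint selections.
#' @param at \code{"final"} or a vector of frame indices.
#' @param probe,nPoints,halved see [interfaceArea()].
#' @return data.frame with columns replica, area_nm2; attributes
#'   \code{mean}, \code{se} (NA for a single replica) and \code{at}.
#' @export
interfaceSeries <- function(replicaSystems, partA, partB, at = "final",
                            probe = 0.14, nPoints = 960L, halved = TRUE) {
  if (methods::is(replicaSystems, "MolecularSystem"))
    replicaSystems <- list(replicaSystems)
  if (!length(replicaSystems)) analysisError("empty replica list")
  per <- vapply(replicaSystems, function(sys) {
    fr <- if (identical(at, "final")) nFrames(sys) else frameSubset(sys, at)
    mean(vapply(fr, function(f)
      interfaceArea(sys, partA, partB, frame = f, probe = probe,
                    nPoints = nPoints, halved = halved), numeric(1)))
  }, numeric(1))
  out <- data.frame(replica = seq_along(per), area_nm2 = per)
  attr(out, "mean") <- mean(per)
  attr(out, "se") <- sampleSE(per)
  attr(out, "at") <- if (identical(at, "final")) "final"
                     else paste(at, collapse = ",")
  out
}
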