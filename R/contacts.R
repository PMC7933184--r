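## Distance, contact, coverage and surface-map computations.
##
## All distances use every atom of the selections (hydrogens included when
## present in the topology) and the minimum-image convention for periodic
## orthorhombic boxes. Contacts are strict "<" at the cutoff so results are
## deterministic under floating point.

## selection -> 0-based atom indices into the coordinate array
atomIndices0 <- function(system, sel, allowEmpty = FALSE) {
  ids <- resolveSelection(system, sel, allowEmpty = allowEmpty)
  match(ids, system@atoms$atom_id) - 1L
}

frameSubset <- function(system, frames) {
  nf <- nFrames(system)
  if (is.null(frames)) return(seq_len(nf))
  frames <- as.integer(frames)
  if (any(frames < 1 | frames > nf))
    analysisError("frame range outside 1..%d", nf)
  frames
}

## slice coords/box to a frame subset without copying when full
coordsForFrames <- function(system, frames) {
  nf <- nFrames(system)
  if (length(frames) == nf && all(frames == seq_len(nf)))
    list(coords = system@coords,
         box = if (isPeriodic(system)) system@box
               else matrix(0, nrow = nf, ncol = 3))
  else
    list(coords = system@coords[, , frames, drop = FALSE],
         box = if (isPeriodic(system))
                 system@box[frames, , drop = FALSE]
               else matrix(0, nrow = length(frames), ncol = 3))
}

#' Per-residue minimum distance to a target selection
#'
#' For every residue of the group selection and every frame, the minimum
#' distance (nm) between any atom of that residue and any atom of the
#' target — the quantity behind contact fractions and surface distance
#' maps. A cell-list neighbor search is used by default; it is exact and
#' equals the all-pairs computation (verified in the test suite).
#'
#' @param system a \linkS4class{MolecularSystem} with frames.
#' @param group selection for the residues to profile (e.g.
#'   \code{"entity receptor"}).
#' @param target selection for the partner (e.g. \code{"entity glycan_*"}).
#'   Must be disjoint from \code{group}: a shared atom would contribute
#'   zero self-distances and corrupt coverage.
#' @param frames frame indices (default: all).
#' @param method \code{"auto"} (default: all-pairs for small problems,
#'   grid otherwise), \code{"cell"} (grid-accelerated neighbor search) or
#'   \code{"brute"} (all-pairs reference path). Both paths are exact and
#'   agree bitwise.
#' @return a \linkS4class{ResidueDistanceSeries}.
#' @export
minDistancePerResidue <- function(system, group, target, frames = NULL,
                                  method = c("auto", "cell", "brute")) {
  method <- match.arg(method)
  gi <- atomIndices0(system, group)
  ti <- atomIndices0(system, target)
  if (length(intersect(gi, ti)))
    analysisError("group and target selections overlap (%d shared atoms)",
                  length(intersect(gi, ti)))
  if (method == "auto")
    method <- if (length(gi) * length(ti) <= 250000) "brute" else "cell"
  frames <- frameSubset(system, frames)
  cf <- coordsForFrames(system, frames)
  rid_per_atom <- system@atoms$residue_id[gi + 1L]
  resids <- sort(unique(rid_per_atom))
  resAtoms <- lapply(resids, function(r) gi[rid_per_atom == r])
  dm <- if (method == "brute")
    .cpp_min_dist_brute(as.numeric(cf$coords), dim(cf$coords), resAtoms,
                        ti, cf$box, isPeriodic(system))
  else
    .cpp_min_dist_cell(as.numeric(cf$coords), dim(cf$coords), resAtoms,
                       ti, cf$box, isPeriodic(system), 0.65)
  rn <- system@residues$residue_name[match(resids, system@residues$residue_id)]
  methods::new("ResidueDistanceSeries", residueIds = as.integer(resids),
               residueNames = rn, distances = dm,
               timePerFrame = system@timePerFrame)
}

#' Contact fraction (per-residue coverage) from a distance series
#'
#' The fraction of frames in which each residue's minimum distance to the
#' target is strictly below the cutoff — the per-residue coverage C_res.
#' The default 0.3 nm is the standard heavy-contact criterion used for
#' glycan and ligand coverage throughout the package.
#'
#' @param series a \linkS4class{ResidueDistanceSeries}.
#' @param cutoff contact cutoff in nm (default 0.3).
#' @return a \linkS4class{ResidueCoverage}. Coverage is non-decreasing in
#'   the cutoff.
#' @export
contactFraction <- function(series, cutoff = 0.3) {
  nf <- nrow(series@distances)
  if (nf < 1) analysisError("distance series has zero frames")
  cov <- colMeans(series@distances < cutoff)
  methods::new("ResidueCoverage", residueIds = series@residueIds,
               residueNames = series@residueNames, coverage = unname(cov),
               cutoff = cutoff, nFrames = as.integer(nf))
}

#' Glycan (or ligand) coverage per residue, one call per replica
#'
#' Convenience wrapper: minimum-distance series followed by
#' [contactFraction()] for each replica system, returning a list of
#' \linkS4class{ResidueCoverage} ready for [modeCoverage()].
#'
#' @param replicaSystems list of \linkS4class{MolecularSystem} replicas.
#' @param group,target selections as in [minDistancePerResidue()].
#' @param cutoff contact cutoff (nm).
#' @param frames frame indices (default: all).
#' @param method distance path, see [minDistancePerResidue()].
#' @return list of \linkS4class{ResidueCoverage}, one per replica.
#' @export
coveragePerReplica <- function(replicaSystems, group, target, cutoff = 0.3,
                               frames = NULL, method = "auto") {
  lapply(replicaSystems, function(sys)
    contactFraction(minDistancePerResidue(sys, group, target, frames = frames,
                                          method = method), cutoff = cutoff))
}

#' Mean atom-pair contact counts between entities
#'
#' Entry (i, j) is the mean over frames of the number of atom pairs — one
#' atom from entity i, one from entity j — closer than the cutoff (0.6 nm
#' by default, the inter-glycan contact criterion). With several replicas
#' the per-replica time means are averaged with equal weight; replicas of
#' unequal length are still weighted equally (with a warning).
#'
#' @param systems a \linkS4class{MolecularSystem} or list of replicas.
#' @param entities character vector of at least two entity labels.
#' @param cutoff contact cutoff (nm), default 0.6.
#' @param frames frame indices applied to every replica (default: all).
#' @param method \code{"auto"}, \code{"cell"} or \code{"brute"}.
#' @param count \code{"pairs"} (atom-pair counting, gmx-mindist semantics,
#'   default) or \code{"atoms"} (distinct atoms of either entity involved
#'   in at least one contact).
#' @return a \linkS4class{ContactMatrix}.
#' @export
pairContactCounts <- function(systems, entities, cutoff = 0.6, frames = NULL,
                              method = c("auto", "cell", "brute"),
                              count = c("pairs", "atoms")) {
  method <- match.arg(method)
  if (method == "auto") method <- "cell"
  count <- match.arg(count)
  if (methods::is(systems, "MolecularSystem")) systems <- list(systems)
  if (length(entities) < 2)
    analysisError("need at least two entities for a contact matrix")
  nf_each <- vapply(systems, nFrames, integer(1))
  if (length(unique(nf_each)) > 1)
    warning("replicas of unequal length are weighted equally")
  ne <- length(entities)
  acc <- matrix(0, ne, ne, dimnames = list(entities, entities))
  total_frames <- 0L
  for (sys in systems) {
    idx <- lapply(entities, function(e) {
      ii <- atomIndices0(sys, sprintf("entity %s", e), allowEmpty = TRUE)
      if (!length(ii)) selectionError("entity '%s' has zero atoms", e)
      ii
    })
    fr <- frameSubset(sys, frames)
    cf <- coordsForFrames(sys, fr)
    total_frames <- total_frames + length(fr)
    m <- matrix(0, ne, ne)
    for (i in seq_len(ne)) for (j in seq_len(ne)) {
      if (j < i) { m[i, j] <- m[j, i]; next }
      if (i == j) next  # self-contacts not defined for this map
      if (count == "pairs") {
        cnts <- if (method == "brute")
          .cpp_pair_count_brute(as.numeric(cf$coords), dim(cf$coords),
                                idx[[i]], idx[[j]], cutoff, cf$box,
                                isPeriodic(sys))
        else
          .cpp_pair_count_cell(as.numeric(cf$coords), dim(cf$coords),
                               idx[[i]], idx[[j]], cutoff, cf$box,
                               isPeriodic(sys))
        m[i, j] <- mean(cnts)
      } else {
        # distinct contacting atoms: per-atom min distance of i's atoms to
        # j (and vice versa), thresholded
        singles_i <- lapply(idx[[i]], function(a) a)
        singles_j <- lapply(idx[[j]], function(a) a)
        di <- .cpp_min_dist_brute(as.numeric(cf$coords), dim(cf$coords),
                                  singles_i, idx[[j]], cf$box, isPeriodic(sys))
        dj <- .cpp_min_dist_brute(as.numeric(cf$coords), dim(cf$coords),
                                  singles_j, idx[[i]], cf$box, isPeriodic(sys))
        m[i, j] <- mean(rowSums(di < cutoff) + rowSums(dj < cutoff))
      }
    }
    acc <- acc + m
  }
  methods::new("ContactMatrix", counts = acc / length(systems),
               cutoff = cutoff, nFrames = as.integer(total_frames),
               nReplicas = as.integer(length(systems)))
}

#' Replica-averaged surface distance map
#'
#' Per residue: the time-mean minimum distance to the target within each
#' replica, then the unweighted mean over replicas. A display column clamps
#' the mean into [clamp[1], clamp[2]] nm (the rendering window used for
#' distance-colored surfaces); the unclamped values are retained.
#'
#' @param replicaSystems list of \linkS4class{MolecularSystem} replicas
#'   (at least one) sharing the same residue set.
#' @param group,target selections as in [minDistancePerResidue()].
#' @param clamp two-element numeric, display clamp window in nm
#'   (default c(0.3, 1.5)).
#' @param frames frame indices (default: all).
#' @return data.frame with columns residue_id, residue_name, mean_nm,
#'   clamped_nm, n_replicas.
#' @export
surfaceDistanceMap <- function(replicaSystems, group, target,
                               clamp = c(0.3, 1.5), frames = NULL) {
  if (methods::is(replicaSystems, "MolecularSystem"))
    replicaSystems <- list(replicaSystems)
  if (!length(replicaSystems)) analysisError("need at least one replica")
  per <- lapply(replicaSystems, function(sys) {
    s <- minDistancePerResidue(sys, group, target, frames = frames)
    list(ids = s@residueIds, names = s@residueNames,
         mean = colMeans(s@distances))
  })
  ids <- per[[1]]$ids
  for (p in per)
    if (!identical(p$ids, ids))
      analysisError("replicas have mismatched residue sets")
  mm <- rowMeans(matrix(vapply(per, function(p) p$mean,
                               numeric(length(ids))), nrow = length(ids)))
  data.frame(residue_id = ids, residue_name = per[[1]]$names,
             mean_nm = unname(mm),
             clamped_nm = pmin(pmax(unname(mm), clamp[1]), clamp[2]),
             n_replicas = length(replicaSystems))
}
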