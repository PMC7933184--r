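## Synthetic fixture generators with exact planted ground truth.
##
## The trajectory generator plants per-residue glycan occlusion by exact
## frame-count construction: a residue with planted fraction p is touched
## by a glycan bead (within the 0.3 nm contact cutoff) in exactly
## round(p * n_frames) frames, the subset chosen by a seeded permutation.
## No polymer dynamics are simulated — ground truth exactness is the
## point. Receptor residues sit on a rigid lattice; glycan chains hang as
## bead strings above their attachment site and deploy single beads onto
## their assigned residues; a ligand chain follows a scripted
## bound/unbound schedule (bound: within 0.3 nm of the epitope; unbound:
## parked > 1.5 nm away).

#' Shielding scenario description
#'
#' Parameter bundle for [genShieldedTrajectory()]. Defaults describe the
#' bundled "toy-HABD" scenario: 150 receptor residues numbered 20-169,
#' glycan chains attached at residues 25, 57, 100, 110 and 120, and the
#' key binding residues 38/41/78/150/154/162 as the ligand epitope.
#'
#' @param nResidues number of receptor residues.
#' @param firstResidue first (author) residue number.
#' @param atomsPerResidue beads per receptor residue.
#' @param glycanSites attachment residue ids (one chain per site).
#' @param glycanBeads beads per glycan chain.
#' @param beadRadius glycan/ligand bead radius (nm).
#' @param plantedOcclusion named numeric: residue id -> target contact
#'   fraction in [0, 1].
#' @param ligandBeads beads of the diffusing ligand chain.
#' @param epitopeResidues residues the bound ligand touches.
#' @param schedule data.frame(start_ns, end_ns) of bound episodes.
#' @param nFrames trajectory length in frames.
#' @param dt frame spacing (ns).
#' @param seed mandatory RNG seed; identical seeds give bit-identical
#'   output.
#' @return a validated scenario (list of class \code{"ShieldScenario"}).
#' @export
shieldScenario <- function(nResidues = 150L, firstResidue = 20L,
                           atomsPerResidue = 2L,
                           glycanSites = c(25L, 57L, 100L, 110L, 120L),
                           glycanBeads = 8L, beadRadius = 0.15,
                           plantedOcclusion = toyPlantedOcclusion(),
                           ligandBeads = 3L,
                           epitopeResidues = c(38L, 41L, 78L, 150L, 154L, 162L),
                           schedule = data.frame(start_ns = c(10, 45, 80),
                                                 end_ns = c(30, 65, 95)),
                           nFrames = 1000L, dt = 0.1, seed) {
  if (missing(seed)) parameterError("scenario seed is mandatory")
  sc <- list(nResidues = as.integer(nResidues),
             firstResidue = as.integer(firstResidue),
             atomsPerResidue = as.integer(atomsPerResidue),
             glycanSites = as.integer(glycanSites),
             glycanBeads = as.integer(glycanBeads),
             beadRadius = as.numeric(beadRadius),
             plantedOcclusion = plantedOcclusion,
             ligandBeads = as.integer(ligandBeads),
             epitopeResidues = as.integer(epitopeResidues),
             schedule = schedule, nFrames = as.integer(nFrames),
             dt = as.numeric(dt), seed = as.integer(seed))
  resids <- seq(sc$firstResidue, length.out = sc$nResidues)
  occ_ids <- as.integer(names(sc$plantedOcclusion))
  if (any(sc$plantedOcclusion < 0 | sc$plantedOcclusion > 1))
    parameterError("planted occlusion fractions must lie in [0, 1]")
  if (!all(occ_ids %in% resids))
    parameterError("planted occlusion names residues outside the receptor")
  if (!all(sc$glycanSites %in% resids))
    parameterError("glycan attachment sites outside the receptor")
  if (nrow(sc$schedule) &&
      (any(sc$schedule$start_ns >= sc$schedule$end_ns) ||
       any(sc$schedule$end_ns > sc$nFrames * sc$dt)))
    parameterError("binding schedule must use ordered intervals inside the trajectory span")
  nchains <- length(sc$glycanSites)
  if (length(occ_ids) && ceiling(length(occ_ids) / nchains) > sc$glycanBeads)
    gs_error("gs_generation_error",
             "geometric infeasibility: %d occluded residues need more than %d beads per chain",
             length(occ_ids), sc$glycanBeads)
  class(sc) <- "ShieldScenario"
  sc
}

#' Default planted occlusion fractions of the toy scenario
#'
#' Higher occlusion over the arginine groove residues than over the
#' residues specific to the upright epitope, so the planted ground truth
#' carries the crystallographic > parallel > upright coverage ordering.
#'
#' @return named numeric vector (residue id -> fraction).
#' @export
toyPlantedOcclusion <- function() {
  c("41" = 0.80, "78" = 0.60, "150" = 0.55, "154" = 0.50,
    "105" = 0.35, "79" = 0.30, "80" = 0.30, "162" = 0.25, "114" = 0.25,
    "38" = 0.20, "113" = 0.20, "43" = 0.15, "44" = 0.15, "166" = 0.15)
}

#' Example binding-mode footprints of the toy scenario
#'
#' Binary membership footprints: the crystallographic mode over the key
#' arginines of the canonical groove, the upright mode over the
#' K38...E166 linear patch, and a parallel mode overlapping both.
#'
#' @return named list of \linkS4class{ModeFootprint}.
#' @export
toyFootprints <- function() {
  list(
    crystallographic = modeFootprint("crystallographic",
                                     c(41L, 78L, 150L, 154L)),
    parallel = modeFootprint("parallel", c(78L, 150L, 154L, 105L, 114L)),
    upright = modeFootprint("upright",
                            c(38L, 43L, 44L, 79L, 80L, 105L, 113L, 114L,
                              162L, 166L))
  )
}

## lattice layout shared by generator internals
scenarioLayout <- function(sc) {
  n <- sc$nResidues
  ncols <- ceiling(sqrt(n))
  idx <- seq_len(n) - 1L
  spacing <- 1.2
  z0 <- 5.0
  centers <- cbind(1.0 + (idx %% ncols) * spacing,
                   1.0 + (idx %/% ncols) * spacing,
                   z0)
  box <- c(max(centers[, 1]) + 2.0, max(centers[, 2]) + 2.0, 12.0)
  list(centers = centers, box = box, z0 = z0,
       resids = seq(sc$firstResidue, length.out = n))
}

#' Generate a shielded-receptor trajectory with planted ground truth
#'
#' Builds one replica of the scenario: a rigid receptor lattice, glycan
#' bead chains whose time-averaged occlusion of the planted residues is
#' exact by construction, and a ligand chain following the scripted
#' binding schedule. With \code{dir} set, the topology (GRO), trajectory
#' (multi-frame GRO), entity map (YAML) and ground-truth tables (TSV) are
#' written there.
#'
#' @param scenario a [shieldScenario()].
#' @param replicate replica index; shifts the internal seed so replicas
#'   differ in which frames are occluded while the planted fractions stay
#'   exact (and hence identical across replicas).
#' @param dir optional output directory.
#' @return list with elements \code{system} (a
#'   \linkS4class{MolecularSystem}), \code{groundTruth} (list of
#'   \code{occlusion} and \code{schedule} data.frames), and \code{paths}
#'   (written files, if any).
#' @export
genShieldedTrajectory <- function(scenario, replicate = 1L, dir = NULL) {
  sc <- scenario
  lay <- scenarioLayout(sc)
  nf <- sc$nFrames
  apr <- sc$atomsPerResidue
  nres <- sc$nResidues
  nchain <- length(sc$glycanSites)
  nglyc <- nchain * sc$glycanBeads
  nlig <- sc$ligandBeads
  natoms <- nres * apr + nglyc + nlig

  ## topology ------------------------------------------------------------
  rec_res <- rep(lay$resids, each = apr)
  gly_resid <- 500L + seq_len(nchain)
  lig_resid <- 601L
  atom_res <- c(rec_res, rep(gly_resid, each = sc$glycanBeads),
                rep(lig_resid, nlig))
  atom_name <- c(
    paste0("C", rep(seq_len(apr), times = nres)),
    paste0("G", rep(seq_len(sc$glycanBeads), times = nchain)),
    paste0("L", seq_len(nlig))
  )
  atoms <- data.frame(
    atom_id = seq_len(natoms), name = atom_name,
    element = "C",
    radius = c(rep(unname(vdwRadius("C")), nres * apr),
               rep(sc$beadRadius, nglyc + nlig)),
    residue_id = atom_res, stringsAsFactors = FALSE
  )
  residues <- data.frame(
    residue_id = c(lay$resids, gly_resid, lig_resid),
    residue_name = c(rep("ALA", nres), rep("GLC", nchain), "HA"),
    entity = c(rep("receptor", nres),
               sprintf("glycan_N%d", sc$glycanSites),
               "ligand_HA6_1"),
    stringsAsFactors = FALSE
  )
  if (nlig == 0L)
    residues <- residues[residues$entity != "ligand_HA6_1", , drop = FALSE]

  ## static receptor coordinates -----------------------------------------
  rec_xyz <- matrix(0, nres * apr, 3)
  off <- if (apr > 1) seq(-0.04, 0.04, length.out = apr) else 0
  for (r in seq_len(nres)) {
    rows <- (r - 1L) * apr + seq_len(apr)
    rec_xyz[rows, ] <- cbind(lay$centers[r, 1] + off, lay$centers[r, 2],
                             lay$centers[r, 3])
  }

  ## glycan parking positions: a bead string above the attachment site
  site_row <- match(sc$glycanSites, lay$resids)
  park <- matrix(0, nglyc, 3)
  for (g in seq_len(nchain)) {
    rows <- (g - 1L) * sc$glycanBeads + seq_len(sc$glycanBeads)
    park[rows, ] <- cbind(lay$centers[site_row[g], 1],
                          lay$centers[site_row[g], 2],
                          lay$z0 + 0.5 + 0.3 * seq_len(sc$glycanBeads))
  }

  ## occluded residue -> (chain, bead) assignment, round-robin over chains
  occ_ids <- as.integer(names(sc$plantedOcclusion))
  assign_chain <- integer(0); assign_bead <- integer(0)
  if (length(occ_ids)) {
    o <- order(occ_ids)
    assign_chain <- ((seq_along(occ_ids) - 1L) %% nchain) + 1L
    assign_bead <- ((seq_along(occ_ids) - 1L) %/% nchain) + 1L
    occ_ids <- occ_ids[o]
  }
  occ_p <- unname(sc$plantedOcclusion[as.character(occ_ids)])

  ## ligand poses ---------------------------------------------------------
  if (nlig > 0) {
    epi_row <- match(sc$epitopeResidues[seq_len(min(nlig,
                       length(sc$epitopeResidues)))], lay$resids)
    lig_bound <- cbind(lay$centers[epi_row, 1, drop = FALSE] - 0.15,
                       lay$centers[epi_row, 2, drop = FALSE],
                       lay$centers[epi_row, 3, drop = FALSE] + 0.10)
    if (nrow(lig_bound) < nlig) {  # surplus beads trail the last epitope bead
      extra <- nlig - nrow(lig_bound)
      lig_bound <- rbind(lig_bound,
                         cbind(lig_bound[nrow(lig_bound), 1] - 0.3 * seq_len(extra),
                               lig_bound[nrow(lig_bound), 2],
                               lig_bound[nrow(lig_bound), 3] + 0.4))
    }
    lig_park <- cbind(lay$centers[epi_row[1], 1] + 0.3 * (seq_len(nlig) - 1),
                      lay$centers[epi_row[1], 2],
                      lay$z0 - 2.0 - 0.3 * seq_len(nlig))
  } else {
    lig_bound <- lig_park <- NULL
  }

  ## frame schedule -------------------------------------------------------
  times <- (seq_len(nf) - 1L) * sc$dt
  bound_frame <- rep(FALSE, nf)
  if (nrow(sc$schedule))
    for (k in seq_len(nrow(sc$schedule)))
      bound_frame <- bound_frame |
        (times >= sc$schedule$start_ns[k] & times < sc$schedule$end_ns[k])

  ## seeded exact frame subsets for each occluded residue
  contact_frames <- withSeed(sc$seed + 7919L * as.integer(replicate), {
    lapply(seq_along(occ_ids), function(i) {
      ncf <- round(occ_p[i] * nf)
      sort(sample.int(nf, ncf))
    })
  })

  ## assemble coordinates -------------------------------------------------
  coords <- array(0, dim = c(natoms, 3, nf))
  gly0 <- nres * apr
  lig0 <- gly0 + nglyc
  occ_target <- lay$centers[match(occ_ids, lay$resids), , drop = FALSE]
  occ_target <- occ_target + matrix(rep(c(0.15, 0, 0.10), each = length(occ_ids)),
                                    ncol = 3)
  in_contact <- matrix(FALSE, nf, length(occ_ids))
  for (i in seq_along(occ_ids)) in_contact[contact_frames[[i]], i] <- TRUE
  base <- rbind(rec_xyz, park,
                if (nlig) lig_park else NULL)
  for (f in seq_len(nf)) {
    xyz <- base
    for (i in seq_along(occ_ids)) {
      if (in_contact[f, i]) {
        row <- gly0 + (assign_chain[i] - 1L) * sc$glycanBeads + assign_bead[i]
        xyz[row, ] <- occ_target[i, ]
      }
    }
    if (nlig && bound_frame[f])
      xyz[lig0 + seq_len(nlig), ] <- lig_bound
    coords[, , f] <- xyz
  }
  box <- matrix(rep(lay$box, each = nf), nrow = nf)
  system <- buildSystem(atoms, residues, coords, box, sc$dt)

  ## ground truth ---------------------------------------------------------
  occ_df <- data.frame(
    residue_id = occ_ids, planted_fraction = occ_p,
    n_contact_frames = vapply(contact_frames, length, integer(1)),
    exact_fraction = vapply(contact_frames, length, integer(1)) / nf
  )
  sched_df <- if (nrow(sc$schedule)) {
    sf <- vapply(seq_len(nrow(sc$schedule)), function(k)
      range(which(times >= sc$schedule$start_ns[k] &
                  times < sc$schedule$end_ns[k])), integer(2))
    data.frame(episode = seq_len(nrow(sc$schedule)),
               start_ns = sc$schedule$start_ns, end_ns = sc$schedule$end_ns,
               start_frame = sf[1, ], end_frame = sf[2, ],
               duration_ns = (sf[2, ] - sf[1, ] + 1L) * sc$dt)
  } else data.frame()

  paths <- character(0)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    p_top <- file.path(dir, "topology.gro")
    p_trj <- file.path(dir, "trajectory.gro")
    p_ent <- file.path(dir, "entities.yaml")
    p_occ <- file.path(dir, "ground_truth_occlusion.tsv")
    p_sch <- file.path(dir, "ground_truth_schedule.tsv")
    writeGRO(system, p_top, frames = 1L, title = "toy glycoprotein topology")
    writeGRO(system, p_trj, title = "toy glycoprotein trajectory")
    writeEntityMapYAML(system, p_ent)
    utils::write.table(occ_df, p_occ, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    utils::write.table(sched_df, p_sch, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    paths <- c(topology = p_top, trajectory = p_trj, entities = p_ent,
               occlusion = p_occ, schedule = p_sch)
  }
  list(system = system,
       groundTruth = list(occlusion = occ_df, schedule = sched_df),
       scenario = sc, paths = paths)
}

#' Generate a replica set of shielded trajectories
#'
#' @param scenario a [shieldScenario()].
#' @param nReplicas number of replicas; replica k uses a seed offset so
#'   occluded frame subsets differ while planted fractions remain exact.
#' @return list of results as returned by [genShieldedTrajectory()].
#' @export
genShieldedReplicas <- function(scenario, nReplicas = 15L) {
  lapply(seq_len(nReplicas), function(k)
    genShieldedTrajectory(scenario, replicate = k))
}

#' Titration scenario description
#'
#' @param residue_id integer residue ids.
#' @param category planted category per residue: one of
#'   \code{"instant_disappearance"}, \code{"instant_shift"},
#'   \code{"gradual_shift"}, \code{"unperturbed"}.
#' @param doubled logical, plant a doubled (secondary) signal.
#' @param dH_delta,dN_delta full perturbation per residue (ppm).
#' @param noise Gaussian shift noise SD (ppm); a warning is raised when it
#'   exceeds the default 0.02 ppm perturbation floor.
#' @param ratios ligand:protein molar ratios of the titration points.
#' @param seed mandatory RNG seed.
#' @return list of class \code{"TitrationScenario"}.
#' @export
titrationScenario <- function(residue_id, category,
                              doubled = rep(FALSE, length(residue_id)),
                              dH_delta, dN_delta, noise = 0,
                              ratios = c(1, 2, 3), seed) {
  if (missing(seed)) parameterError("scenario seed is mandatory")
  cats <- c("instant_disappearance", "instant_shift", "gradual_shift",
            "unperturbed")
  if (!all(category %in% cats))
    parameterError("unknown category: %s",
                   paste(setdiff(category, cats), collapse = ", "))
  if (noise > 0.02)
    warning("noise SD exceeds the 0.02 ppm perturbation floor; classifier recovery is not guaranteed")
  sc <- list(residue_id = as.integer(residue_id),
             category = as.character(category),
             doubled = as.logical(doubled),
             dH_delta = as.numeric(dH_delta),
             dN_delta = as.numeric(dN_delta),
             noise = as.numeric(noise), ratios = as.numeric(ratios),
             seed = as.integer(seed))
  class(sc) <- "TitrationScenario"
  sc
}

#' Default titration scenario
#'
#' A small residue panel covering every classifier category, with
#' perturbations well above the 0.02 ppm floor.
#'
#' @param seed RNG seed.
#' @param noise shift noise SD in ppm (default 0).
#' @return a [titrationScenario()].
#' @export
toyTitrationScenario <- function(seed, noise = 0) {
  titrationScenario(
    residue_id = c(38L, 40L, 43L, 44L, 23L, 105L, 140L, 39L, 50L, 60L),
    category = c("instant_disappearance", "instant_disappearance",
                 "instant_shift", "instant_shift", "gradual_shift",
                 "gradual_shift", "instant_shift", "gradual_shift",
                 "unperturbed", "unperturbed"),
    doubled = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE,
                FALSE, FALSE),
    dH_delta = c(0.10, 0.12, 0.10, 0.08, 0.06, 0.09, 0.11, 0.07, 0, 0),
    dN_delta = c(0.50, 0.40, 0.50, 0.45, 0.35, 0.40, 0.55, 0.30, 0, 0),
    noise = noise, seed = seed
  )
}

#' Generate synthetic HSQC titration peak lists
#'
#' The free list gets seeded random base shifts; each titration point
#' applies the planted perturbation according to the residue's category
#' (instant: full shift from the first point; gradual: shift scaled by
#' ratio / max ratio; disappearance: intensity to zero; doubled: secondary
#' peak populated), then adds Gaussian noise to all shifts.
#'
#' @param scenario a [titrationScenario()].
#' @param dir optional directory; peak lists and ground truth are written
#'   as TSV there.
#' @return list with \code{series} (list of \linkS4class{PeakList}, free
#'   condition first), \code{groundTruth} (data.frame) and \code{paths}.
#' @export
genTitrationPeaks <- function(scenario, dir = NULL) {
  sc <- scenario
  n <- length(sc$residue_id)
  out <- withSeed(sc$seed, {
    baseH <- stats::runif(n, 7.0, 9.5)
    baseN <- stats::runif(n, 105, 130)
    series <- list(peakList("free", sc$residue_id, "", baseH, baseN))
    maxr <- max(sc$ratios)
    for (k in seq_along(sc$ratios)) {
      scale <- vapply(sc$category, function(cat) switch(cat,
        instant_shift = 1.0,
        gradual_shift = sc$ratios[k] / maxr,
        instant_disappearance = 0.0,
        unperturbed = 0.0), numeric(1))
      dH <- baseH + sc$dH_delta * scale + stats::rnorm(n, 0, sc$noise)
      dN <- baseN + sc$dN_delta * scale + stats::rnorm(n, 0, sc$noise)
      gone <- sc$category == "instant_disappearance"
      sec_on <- sc$doubled
      series[[k + 1L]] <- peakList(
        sprintf("HA %g:1", sc$ratios[k]), sc$residue_id, "",
        dH, dN, intensity = ifelse(gone, 0, 1),
        secondary_dH = ifelse(sec_on, baseH + 0.5 * sc$dH_delta, NA_real_),
        secondary_dN = ifelse(sec_on, baseN + 0.5 * sc$dN_delta, NA_real_),
        present = !gone
      )
    }
    series
  })
  gt <- data.frame(residue_id = sc$residue_id, category = sc$category,
                   doubled = sc$doubled, dH_delta = sc$dH_delta,
                   dN_delta = sc$dN_delta)
  paths <- character(0)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- vapply(seq_along(out), function(k) {
      p <- file.path(dir, sprintf("peaks_%02d.tsv", k - 1L))
      writePeakList(out[[k]], p)
      p
    }, character(1))
    gtp <- file.path(dir, "ground_truth_titration.tsv")
    utils::write.table(gt, gtp, sep = "\t", row.names = FALSE, quote = FALSE)
    paths <- c(paths, ground_truth = gtp)
  }
  list(series = out, groundTruth = gt, scenario = sc, paths = paths)
}
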