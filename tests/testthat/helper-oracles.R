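# Independent reference implementations used as oracles. These are kept
# deliberately naive (vectorized R, direct definitions) and share no code
# with the package internals.

# build a MolecularSystem directly from pieces
makeSystem <- function(xyz, residue_id, entity, box = NULL, dt = 0.1,
                       radius = 0.17, name = NULL, residue_name = "ALA") {
  if (is.matrix(xyz)) xyz <- array(xyz, dim = c(nrow(xyz), 3, 1))
  n <- dim(xyz)[1]
  nf <- dim(xyz)[3]
  residue_id <- as.integer(rep_len(residue_id, n))
  atoms <- data.frame(atom_id = seq_len(n),
                      name = if (is.null(name)) paste0("C", seq_len(n)) else name,
                      element = "C", radius = rep_len(radius, n),
                      residue_id = residue_id, stringsAsFactors = FALSE)
  rids <- sort(unique(residue_id))
  residues <- data.frame(residue_id = rids,
                         residue_name = rep_len(residue_name, length(rids)),
                         entity = rep_len(entity, length(rids)),
                         stringsAsFactors = FALSE)
  boxm <- if (is.null(box)) matrix(numeric(0), 0, 3)
          else matrix(rep(box, each = nf), nrow = nf)
  new("MolecularSystem", atoms = atoms, residues = residues, coords = xyz,
      box = boxm, timePerFrame = dt)
}

# random two-group system: atoms of group A (one residue each) + target B
randomTwoGroupSystem <- function(nA, nB, nf, periodic = TRUE) {
  box <- runif(3, 1.5, 4)
  xyz <- array(runif(3 * (nA + nB) * nf, 0, max(box)),
               dim = c(nA + nB, 3, nf))
  ent <- c(rep("grp", nA), rep("tgt", nB))
  makeSystem(xyz, residue_id = seq_len(nA + nB), entity = ent,
             box = if (periodic) box else NULL)
}

# O(N^2) reference: per-frame min distance from each group residue's atoms
# to any target atom, minimum-image for orthorhombic boxes
refMinDist <- function(sys, groupResid, targetAtoms, frame) {
  at <- atomTable(sys)
  xyz <- frameCoords(sys, frame)
  per <- isPeriodic(sys)
  box <- if (per) boxLengths(sys)[frame, ] else NULL
  tI <- match(targetAtoms, at$atom_id)
  vapply(groupResid, function(r) {
    gI <- which(at$residue_id == r & !(at$atom_id %in% targetAtoms))
    best <- Inf
    for (a in gI) {
      d <- sweep(xyz[tI, , drop = FALSE], 2, xyz[a, ], "-")
      if (per) for (k in 1:3) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
      best <- min(best, sqrt(min(rowSums(d^2))))
    }
    best
  }, numeric(1))
}

# O(N^2) reference pair count below cutoff
refPairCount <- function(sys, atomsA, atomsB, cutoff, frame) {
  at <- atomTable(sys)
  xyz <- frameCoords(sys, frame)
  per <- isPeriodic(sys)
  box <- if (per) boxLengths(sys)[frame, ] else NULL
  iA <- match(atomsA, at$atom_id); iB <- match(atomsB, at$atom_id)
  cnt <- 0L
  for (a in iA) {
    d <- sweep(xyz[iB, , drop = FALSE], 2, xyz[a, ], "-")
    if (per) for (k in 1:3) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
    cnt <- cnt + sum(sqrt(rowSums(d^2)) < cutoff)
  }
  cnt
}

# reference binding-event machine: hysteresis states, then repeatedly merge
# the first run shorter than the dwell (leading run into its successor,
# interior/trailing runs into their predecessor) until stable
refBindingEvents <- function(d, dt, on, off, dwell) {
  n <- length(d)
  st <- logical(n)
  cur <- d[1] < on
  st[1] <- cur
  for (i in seq_len(n)[-1]) {
    if (!cur && d[i] < on) cur <- TRUE
    if (cur && d[i] > off) cur <- FALSE
    st[i] <- cur
  }
  minFrames <- if (dwell > 0 && dt > 0) ceiling(dwell / dt) else 1
  runs <- rle(st)
  repeat {
    if (length(runs$lengths) <= 1) break
    short <- which(runs$lengths < minFrames)
    if (!length(short)) break
    k <- short[1]
    into <- if (k == 1) 2L else k - 1L
    runs$values[k] <- runs$values[into]
    runs <- rle(inverse.rle(runs))
  }
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  keep <- which(runs$values)
  data.frame(start_frame = starts[keep], end_frame = ends[keep],
             duration_ns = runs$lengths[keep] * dt)
}

# naive linear-scan selection resolver for simple conjunctions used in the
# randomized selection tests
refResolve <- function(sys, entity = NULL, resid = NULL, name = NULL) {
  at <- atomTable(sys)
  rt <- residueTable(sys)
  keep <- rep(TRUE, nrow(at))
  if (!is.null(entity))
    keep <- keep & at$residue_id %in% rt$residue_id[rt$entity == entity]
  if (!is.null(resid)) keep <- keep & at$residue_id %in% resid
  if (!is.null(name)) keep <- keep & at$name == name
  sort(at$atom_id[keep])
}

# analytic SASA of two equal spheres (radius R after probe expansion) at
# center distance d: each loses a cap of height h = R - d/2
twoSphereArea <- function(R, d) {
  if (d >= 2 * R) return(2 * 4 * pi * R^2)
  h <- R - d / 2
  2 * (4 * pi * R^2) - 2 * (2 * pi * R * h)
}

# small toy scenario with an empty binding schedule (valid at any length)
quickScenario <- function(nFrames, seed, ...) {
  shieldScenario(nFrames = nFrames, seed = seed,
                 schedule = data.frame(start_ns = numeric(0),
                                       end_ns = numeric(0)), ...)
}
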