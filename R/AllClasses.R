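#' @import methods
#' @importFrom stats sd setNames
#' @importFrom utils read.table write.table head tail
NULL

#' MolecularSystem: topology plus coordinate frames
#'
#' Container for a molecular topology (atoms grouped into residues, residues
#' grouped into named entities such as \code{"receptor"}, \code{"glycan_N25"}
#' or \code{"ligand_HA6_1"}) together with zero or more coordinate frames and
#' their periodic box. All coordinates and box lengths are stored in nm and
#' frame spacing in ns, following GROMACS conventions; PDB Angstroms are
#' converted at the I/O boundary.
#'
#' @slot atoms data.frame with columns \code{atom_id} (integer, unique),
#'   \code{name}, \code{element}, \code{radius} (van der Waals radius, nm)
#'   and \code{residue_id} (author-assigned residue number).
#' @slot residues data.frame with columns \code{residue_id} (unique,
#'   author numbering kept as-is), \code{residue_name} and \code{entity}
#'   (the single entity each residue belongs to).
#' @slot coords numeric array of dimension n_atoms x 3 x n_frames (nm).
#' @slot box numeric matrix n_frames x 3 of orthorhombic box lengths (nm);
#'   a zero-row matrix marks a non-periodic system.
#' @slot timePerFrame numeric, trajectory sampling interval (ns).
#'
#' @seealso [loadStructure()], [loadTrajectory()], [resolveSelection()]
#' @export
setClass("MolecularSystem",
  representation(
    atoms = "data.frame",
    residues = "data.frame",
    coords = "array",
    box = "matrix",
    timePerFrame = "numeric"
  )
)

setValidity("MolecularSystem", function(object) {
  msgs <- character()
  at <- object@atoms
  rs <- object@residues
  need_at <- c("atom_id", "name", "element", "radius", "residue_id")
  need_rs <- c("residue_id", "residue_name", "entity")
  if (!all(need_at %in% names(at)))
    msgs <- c(msgs, "atoms must have columns atom_id, name, element, radius, residue_id")
  if (!all(need_rs %in% names(rs)))
    msgs <- c(msgs, "residues must have columns residue_id, residue_name, entity")
  if (length(msgs)) return(msgs)
  if (anyDuplicated(at$atom_id))
    msgs <- c(msgs, "duplicate atom_id")
  if (anyDuplicated(rs$residue_id))
    msgs <- c(msgs, "duplicate residue_id (a residue may belong to only one entity)")
  if (!all(at$residue_id %in% rs$residue_id))
    msgs <- c(msgs, "every atom must belong to a declared residue")
  dm <- dim(object@coords)
  if (length(dm) != 3 || dm[2] != 3)
    msgs <- c(msgs, "coords must be an n_atoms x 3 x n_frames array")
  else if (dm[1] != nrow(at))
    msgs <- c(msgs, "frame atom count differs from topology atom count")
  if (nrow(object@box) > 0) {
    if (ncol(object@box) != 3 || nrow(object@box) != dim(object@coords)[3])
      msgs <- c(msgs, "box must be n_frames x 3")
    else if (any(object@box <= 0))
      msgs <- c(msgs, "periodic box lengths must be strictly positive")
  }
  if (length(object@timePerFrame) != 1 || object@timePerFrame < 0)
    msgs <- c(msgs, "timePerFrame must be a single non-negative number (ns)")
  if (length(msgs)) msgs else TRUE
})

#' Per-residue minimum-distance time series
#'
#' For each residue of a group selection, the per-frame minimum distance (nm)
#' from any atom of the residue to any atom of a target selection, with the
#' minimum-image convention applied when the system is periodic.
#'
#' @slot residueIds integer, author residue numbers (column order).
#' @slot residueNames character, residue names.
#' @slot distances numeric matrix n_frames x n_residues (nm).
#' @slot timePerFrame numeric (ns).
#' @export
setClass("ResidueDistanceSeries",
  representation(
    residueIds = "integer",
    residueNames = "character",
    distances = "matrix",
    timePerFrame = "numeric"
  ),
  validity = function(object) {
    if (ncol(object@distances) != length(object@residueIds))
      return("distances must have one column per residue")
    if (any(object@distances < 0)) return("distances must be non-negative")
    TRUE
  }
)

#' Per-residue contact fraction (coverage)
#'
#' The fraction of frames in which each residue's minimum distance to the
#' target is below the cutoff — the per-residue coverage entering the
#' binding-mode shielding statistic.
#'
#' @slot residueIds integer residue numbers.
#' @slot residueNames character.
#' @slot coverage numeric in [0, 1].
#' @slot cutoff numeric contact cutoff (nm).
#' @slot nFrames integer frame count behind the fractions.
#' @export
setClass("ResidueCoverage",
  representation(
    residueIds = "integer",
    residueNames = "character",
    coverage = "numeric",
    cutoff = "numeric",
    nFrames = "integer"
  ),
  validity = function(object) {
    if (length(object@coverage) != length(object@residueIds))
      return("one coverage value per residue required")
    if (any(object@coverage < 0 | object@coverage > 1))
      return("coverage must lie in [0, 1]")
    if (object@nFrames < 1) return("nFrames must be positive")
    TRUE
  }
)

#' Entity-pair contact count matrix
#'
#' Mean (over frames, and over replicas when aggregated) number of atom
#' pairs within the cutoff for each pair of entities.
#'
#' @slot counts numeric matrix with entity labels as dimnames.
#' @slot cutoff numeric (nm).
#' @slot nFrames integer total frames averaged.
#' @slot nReplicas integer replicas averaged (1 for a single trajectory).
#' @export
setClass("ContactMatrix",
  representation(
    counts = "matrix",
    cutoff = "numeric",
    nFrames = "integer",
    nReplicas = "integer"
  ),
  validity = function(object) {
    if (any(object@counts < 0)) return("contact counts must be non-negative")
    TRUE
  }
)

#' Binding-mode footprint weights
#'
#' Per-residue weights describing how strongly each receptor residue is
#' contacted by the ligand in a named binding mode (crystallographic,
#' parallel, upright, ...). Weights live in [0, 1]; membership lists are the
#' binary special case.
#'
#' @slot mode character mode name.
#' @slot residueIds integer residue numbers (author numbering).
#' @slot weights numeric weights in [0, 1], at least one positive.
#' @export
setClass("ModeFootprint",
  representation(
    mode = "character",
    residueIds = "integer",
    weights = "numeric"
  ),
  validity = function(object) {
    if (length(object@weights) != length(object@residueIds))
      return("one weight per residue required")
    if (any(object@weights < 0 | object@weights > 1))
      return("footprint weights must lie in [0, 1]")
    if (!any(object@weights > 0))
      return("degenerate footprint: all weights zero")
    if (anyDuplicated(object@residueIds))
      return("duplicate residue in footprint")
    TRUE
  }
)

#' Replica-averaged mode coverage
#'
#' The footprint-weighted mean glycan coverage of one binding mode:
#' per-replica values, their mean and the standard error of the mean
#' (sample SD / sqrt(n)). With a single replica the SE is reported as NA.
#'
#' @slot mode character.
#' @slot perReplica numeric per-replica coverage values in [0, 1].
#' @export
setClass("CoverageReport",
  representation(
    mode = "character",
    perReplica = "numeric"
  ),
  validity = function(object) {
    if (length(object@perReplica) < 1) return("at least one replica required")
    if (any(object@perReplica < 0 | object@perReplica > 1))
      return("per-replica coverage must lie in [0, 1]")
    TRUE
  }
)

#' Shrake-Rupley solvent-accessible surface area
#'
#' @slot atomAreas numeric per-atom accessible area (nm^2).
#' @slot probe numeric probe radius (nm).
#' @slot nPoints integer sphere sample points per atom.
#' @export
setClass("SASAResult",
  representation(
    atomAreas = "numeric",
    probe = "numeric",
    nPoints = "integer"
  ),
  validity = function(object) {
    if (any(object@atomAreas < 0)) return("areas must be non-negative")
    TRUE
  }
)

#' HSQC peak list for one titration condition
#'
#' Residue-indexed backbone amide peaks: proton and nitrogen shifts (ppm),
#' an intensity, an optional secondary (doubled) peak slot and a presence
#' flag. Peaks without a residue assignment sit in an unassigned pool.
#'
#' @slot condition character label, e.g. \code{"free"} or \code{"HA 1:1"}.
#' @slot peaks data.frame with columns residue_id, residue_name, dH_ppm,
#'   dN_ppm, intensity, secondary_dH, secondary_dN, present.
#' @slot unassigned data.frame with columns dH_ppm, dN_ppm, intensity.
#' @export
setClass("PeakList",
  representation(
    condition = "character",
    peaks = "data.frame",
    unassigned = "data.frame"
  ),
  validity = function(object) {
    need <- c("residue_id", "residue_name", "dH_ppm", "dN_ppm", "intensity",
              "secondary_dH", "secondary_dN", "present")
    if (!all(need %in% names(object@peaks)))
      return(paste("peaks must have columns:", paste(need, collapse = ", ")))
    if (anyDuplicated(object@peaks$residue_id))
      return("at most one primary peak per residue (use the secondary slot)")
    TRUE
  }
)

#' Chemical shift perturbation profile
#'
#' Per-residue combined CSP (ppm). \code{method} records whether values are
#' direct assigned-peak CSPs or minimal-shift CSPs (minimum over the bound
#' peak pool); residues whose bound peak is missing are flagged, never
#' silently zero.
#'
#' @slot data data.frame with columns residue_id, residue_name, csp_ppm,
#'   assigned_csp_ppm (NA when the bound list is unassigned), missing.
#' @slot w numeric nitrogen scaling weight.
#' @slot method character, "assigned" or "minimal".
#' @export
setClass("CSPProfile",
  representation(
    data = "data.frame",
    w = "numeric",
    method = "character"
  ),
  validity = function(object) {
    ok <- object@data$csp_ppm[!object@data$missing]
    if (any(ok < 0, na.rm = TRUE)) return("CSP must be non-negative")
    TRUE
  }
)
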