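## Ligand association/dissociation event detection.
##
## A two-threshold hysteresis on the ligand-receptor minimum-distance
## series: the bound state is entered when the distance drops below
## on_cutoff and left when it rises above off_cutoff (>= on_cutoff), which
## suppresses flicker at a single threshold. A dwell filter then absorbs
## runs shorter than min_dwell into the already-confirmed preceding state
## (a too-short leading run is absorbed into the following run), scanning
## left to right. With off_cutoff = on_cutoff and min_dwell = 0 this
## reduces to plain thresholding.

## raw hysteresis states: TRUE = bound; ambiguous start (between the
## thresholds) counts as unbound
hysteresisStates <- function(d, onCutoff, offCutoff) {
  n <- length(d)
  st <- logical(n)
  cur <- d[1] < onCutoff
  st[1] <- cur
  for (i in seq_len(n)[-1]) {
    if (!cur && d[i] < onCutoff) cur <- TRUE
    else if (cur && d[i] > offCutoff) cur <- FALSE
    st[i] <- cur
  }
  st
}

## left-to-right dwell filter on a logical state vector
dwellFilter <- function(st, minFrames) {
  if (minFrames <= 1) return(st)
  r <- rle(st)
  vals <- r$values; lens <- r$lengths
  out_v <- logical(0); out_l <- integer(0)
  pending <- 0L  # undecided leading frames
  for (k in seq_along(vals)) {
    v <- vals[k]; l <- lens[k] + pending
    pending <- 0L
    if (l < minFrames && length(out_v) == 0) {
      pending <- l  # leading short run: give to whatever comes next
      next
    }
    if (lens[k] < minFrames && length(out_v) > 0) {
      # absorb into the confirmed preceding state
      out_l[length(out_l)] <- out_l[length(out_l)] + lens[k]
      next
    }
    if (length(out_v) && out_v[length(out_v)] == v) {
      out_l[length(out_l)] <- out_l[length(out_l)] + l
    } else {
      out_v <- c(out_v, v); out_l <- c(out_l, l)
    }
  }
  if (pending > 0) {  # everything was short; keep the first state
    out_v <- st[1]; out_l <- length(st)
  }
  inverse.rle(list(values = out_v, lengths = out_l))
}

#' Binding events from a distance series
#'
#' Low-level entry point operating directly on a minimum-distance vector;
#' see [bindingEvents()] for the trajectory-level interface.
#'
#' @param distances numeric vector of per-frame ligand-receptor minimum
#'   distances (nm).
#' @param dt frame spacing (ns).
#' @param onCutoff distance below which the bound state is entered (nm).
#' @param offCutoff distance above which it is left (nm); must be >=
#'   onCutoff.
#' @param minDwell minimum dwell time (ns); shorter bound and unbound
#'   intervals are merged into the surrounding state.
#' @param ligand label recorded in the output.
#' @return data.frame with columns ligand, start_frame, end_frame
#'   (1-based, inclusive), start_ns, end_ns, duration_ns; one row per
#'   association event. Attributes record the thresholds.
#' @export
bindingEventsFromSeries <- function(distances, dt, onCutoff = 0.3,
                                    offCutoff = 0.5, minDwell = 1.0,
                                    ligand = "ligand") {
  if (offCutoff < onCutoff)
    parameterError("off_cutoff (%g) must be >= on_cutoff (%g)",
                   offCutoff, onCutoff)
  if (minDwell < 0) parameterError("min_dwell must be >= 0")
  n <- length(distances)
  if (n < 1 || n * dt < minDwell)
    analysisError("trajectory (%.3g ns) shorter than min_dwell (%.3g ns)",
                  n * dt, minDwell)
  minFrames <- if (minDwell > 0 && dt > 0) ceiling(minDwell / dt) else 1L
  st <- dwellFilter(hysteresisStates(distances, onCutoff, offCutoff),
                    minFrames)
  r <- rle(st)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  ev <- data.frame(
    ligand = rep(ligand, length(keep)),
    start_frame = starts[keep], end_frame = ends[keep],
    start_ns = (starts[keep] - 1) * dt, end_ns = ends[keep] * dt,
    duration_ns = r$lengths[keep] * dt,
    stringsAsFactors = FALSE
  )
  attr(ev, "on_cutoff") <- onCutoff
  attr(ev, "off_cutoff") <- offCutoff
  attr(ev, "min_dwell") <- minDwell
  ev
}

#' Detect ligand association/dissociation events in a trajectory
#'
#' Computes the per-frame minimum distance between the ligand and receptor
#' selections, then applies two-threshold hysteresis with a dwell filter
#' (see [bindingEventsFromSeries()] for the exact semantics). The number of
#' rows is the association count.
#'
#' @param system a \linkS4class{MolecularSystem} with frames.
#' @param ligand,receptor disjoint selections.
#' @param onCutoff,offCutoff,minDwell hysteresis parameters (nm, nm, ns);
#'   defaults 0.3 / 0.5 / 1.0.
#' @param frames frame indices (default: all).
#' @return data.frame of events as in [bindingEventsFromSeries()].
#' @export
bindingEvents <- function(system, ligand, receptor, onCutoff = 0.3,
                          offCutoff = 0.5, minDwell = 1.0, frames = NULL) {
  li <- resolveSelection(system, ligand)
  ri <- resolveSelection(system, receptor)
  if (length(intersect(li, ri)))
    analysisError("ligand and receptor selections overlap")
  # single pseudo-residue holding every ligand atom -> one min-distance row
  gi <- match(li, system@atoms$atom_id) - 1L
  ti <- match(ri, system@atoms$atom_id) - 1L
  fr <- frameSubset(system, frames)
  cf <- coordsForFrames(system, fr)
  dm <- if (length(gi) * length(ti) <= 250000)
    .cpp_min_dist_brute(as.numeric(cf$coords), dim(cf$coords), list(gi),
                        ti, cf$box, isPeriodic(system))
  else
    .cpp_min_dist_cell(as.numeric(cf$coords), dim(cf$coords), list(gi),
                       ti, cf$box, isPeriodic(system), 0.65)
  lab <- if (is.character(ligand) && grepl("^entity [^ ]+$", ligand))
    sub("^entity ", "", ligand) else "ligand"
  bindingEventsFromSeries(dm[, 1], dt = system@timePerFrame,
                          onCutoff = onCutoff, offCutoff = offCutoff,
                          minDwell = minDwell, ligand = lab)
}
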