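## Chemical-shift-perturbation analysis of HSQC titrations.
##
## The combined CSP weights the nitrogen dimension by w (default 0.2, the
## conventional scaling that brings 15N shift ranges onto the 1H scale):
## sqrt(dH^2 + (w dN)^2). The minimal-shift variant takes, for each
## assigned free-state peak, the minimum combined CSP over the whole bound
## peak pool — usable when the bound spectrum is not assigned, and by
## construction never larger than the direct assigned-peak CSP.

#' Construct a PeakList
#'
#' @param condition condition label (e.g. \code{"free"}, \code{"HA 1:1"}).
#' @param residue_id integer residue ids.
#' @param residue_name residue names (default "").
#' @param dH_ppm,dN_ppm proton and nitrogen shifts (ppm).
#' @param intensity peak intensities (default 1).
#' @param secondary_dH,secondary_dN optional doubled-peak shifts (NA when
#'   the signal is single).
#' @param present logical presence flags (default TRUE).
#' @param unassigned optional data.frame (dH_ppm, dN_ppm, intensity) of
#'   peaks without residue assignment.
#' @return a \linkS4class{PeakList}.
#' @export
peakList <- function(condition, residue_id, residue_name = "",
                     dH_ppm, dN_ppm, intensity = 1,
                     secondary_dH = NA_real_, secondary_dN = NA_real_,
                     present = TRUE, unassigned = NULL) {
  n <- length(residue_id)
  peaks <- data.frame(
    residue_id = as.integer(residue_id),
    residue_name = rep_len(as.character(residue_name), n),
    dH_ppm = as.numeric(dH_ppm), dN_ppm = as.numeric(dN_ppm),
    intensity = rep_len(as.numeric(intensity), n),
    secondary_dH = rep_len(as.numeric(secondary_dH), n),
    secondary_dN = rep_len(as.numeric(secondary_dN), n),
    present = rep_len(as.logical(present), n),
    stringsAsFactors = FALSE
  )
  if (is.null(unassigned))
    unassigned <- data.frame(dH_ppm = numeric(0), dN_ppm = numeric(0),
                             intensity = numeric(0))
  methods::new("PeakList", condition = as.character(condition),
               peaks = peaks, unassigned = unassigned)
}

#' Read a peak list from TSV/CSV
#'
#' Columns: residue_id, residue_name, dH_ppm, dN_ppm, intensity and
#' optionally secondary_dH, secondary_dN, present. Rows with NA residue_id
#' go to the unassigned pool.
#'
#' @param path TSV (or CSV) file; delimiter inferred from the extension.
#' @param condition condition label for the list.
#' @return a \linkS4class{PeakList}.
#' @export
readPeakList <- function(path, condition) {
  if (!file.exists(path)) configError("peak list not found: %s", path)
  sep <- if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                          stringsAsFactors = FALSE)
  need <- c("residue_id", "dH_ppm", "dN_ppm")
  if (!all(need %in% names(df)))
    formatError("peak list needs columns: %s", paste(need, collapse = ", "))
  if (is.null(df$residue_name)) df$residue_name <- ""
  if (is.null(df$intensity)) df$intensity <- 1
  if (is.null(df$secondary_dH)) df$secondary_dH <- NA_real_
  if (is.null(df$secondary_dN)) df$secondary_dN <- NA_real_
  if (is.null(df$present)) df$present <- TRUE
  una <- df[is.na(df$residue_id), c("dH_ppm", "dN_ppm", "intensity")]
  df <- df[!is.na(df$residue_id), , drop = FALSE]
  peakList(condition, df$residue_id, df$residue_name, df$dH_ppm, df$dN_ppm,
           df$intensity, df$secondary_dH, df$secondary_dN, df$present,
           unassigned = una)
}

#' Write a peak list to TSV
#' @param x a \linkS4class{PeakList}.
#' @param path output TSV.
#' @return invisibly, the path.
#' @export
writePeakList <- function(x, path) {
  df <- x@peaks
  if (nrow(x@unassigned)) {
    ua <- data.frame(residue_id = NA_integer_, residue_name = "",
                     dH_ppm = x@unassigned$dH_ppm,
                     dN_ppm = x@unassigned$dN_ppm,
                     intensity = x@unassigned$intensity,
                     secondary_dH = NA_real_, secondary_dN = NA_real_,
                     present = TRUE)
    df <- rbind(df, ua)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# condition: %s", x@condition), con)
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Combined 1H/15N chemical shift perturbation
#'
#' sqrt(dH^2 + (w dN)^2), vectorized; an even function of both shift
#' differences.
#'
#' @param dH proton shift difference (ppm).
#' @param dN nitrogen shift difference (ppm).
#' @param w nitrogen weight (> 0; default 0.2).
#' @return combined CSP (ppm).
#' @examples
#' combinedCSP(0.1, 0.5)  # 0.14142...
#' @export
combinedCSP <- function(dH, dN, w = 0.2) {
  if (length(w) != 1 || !is.finite(w) || w <= 0)
    parameterError("nitrogen weight w must be a positive scalar")
  sqrt(dH^2 + (w * dN)^2)
}

## pool of all peak positions in a bound list: primary (present) peaks,
## populated secondary slots and the unassigned pool
boundPeakPool <- function(bound) {
  p <- bound@peaks
  pool <- data.frame(dH = p$dH_ppm[p$present], dN = p$dN_ppm[p$present])
  sec <- !is.na(p$secondary_dH)
  if (any(sec))
    pool <- rbind(pool, data.frame(dH = p$secondary_dH[sec],
                                   dN = p$secondary_dN[sec]))
  if (nrow(bound@unassigned))
    pool <- rbind(pool, data.frame(dH = bound@unassigned$dH_ppm,
                                   dN = bound@unassigned$dN_ppm))
  pool
}

#' Minimal chemical shift perturbation profile
#'
#' For each assigned residue of the free spectrum, the minimum combined
#' CSP over every peak of the bound spectrum (assigned, doubled and
#' unassigned pools together) — the minimal-shift method for bound spectra
#' without assignments. When the bound list is residue-assigned the direct
#' same-residue CSP is reported alongside; residues whose bound signal is
#' absent are flagged missing (their direct CSP is NA). The profile is
#' invariant under a global reference offset applied to both spectra.
#'
#' @param free assigned \linkS4class{PeakList} of the free state.
#' @param bound \linkS4class{PeakList} of the bound state (may be fully
#'   unassigned).
#' @param w nitrogen weight, see [combinedCSP()].
#' @return a \linkS4class{CSPProfile}.
#' @export
minimalCSPProfile <- function(free, bound, w = 0.2) {
  fp <- free@peaks[free@peaks$present, , drop = FALSE]
  pool <- boundPeakPool(bound)
  if (!nrow(pool)) analysisError("bound peak pool is empty")
  minimal <- vapply(seq_len(nrow(fp)), function(i)
    min(combinedCSP(fp$dH_ppm[i] - pool$dH, fp$dN_ppm[i] - pool$dN, w)),
    numeric(1))
  bp <- bound@peaks
  pos <- match(fp$residue_id, bp$residue_id)
  have_direct <- !is.na(pos) & bp$present[ifelse(is.na(pos), 1L, pos)]
  direct <- rep(NA_real_, nrow(fp))
  direct[have_direct] <- combinedCSP(
    fp$dH_ppm[have_direct] - bp$dH_ppm[pos[have_direct]],
    fp$dN_ppm[have_direct] - bp$dN_ppm[pos[have_direct]], w)
  dat <- data.frame(
    residue_id = fp$residue_id, residue_name = fp$residue_name,
    csp_ppm = minimal, assigned_csp_ppm = direct,
    missing = !have_direct, stringsAsFactors = FALSE
  )
  methods::new("CSPProfile", data = dat, w = w, method = "minimal")
}

#' Classify per-residue titration responses
#'
#' Operationalizes the qualitative spectral categories of an HSQC
#' titration: a residue whose signal intensity collapses below
#' \code{f_gone} of its free intensity is an \code{instant_disappearance};
#' otherwise, if the final combined CSP reaches the perturbation floor,
#' the residue is an \code{instant_shift} when the CSP at the first
#' titration point is already \code{f_inst} of the final CSP, else a
#' \code{gradual_shift}; below the floor it is \code{unperturbed}. A
#' residue is \code{doubled} when its secondary peak slot is populated at
#' any titration point. Thresholds are recorded in the output attributes.
#'
#' @param series list of \linkS4class{PeakList}: the free condition first,
#'   then the titration points in increasing ligand ratio (>= 3 lists in
#'   total).
#' @param f_inst instant fraction (default 0.8).
#' @param f_gone disappearance intensity fraction (default 0.1).
#' @param floor minimum final CSP (ppm) to call a perturbation
#'   (default 0.02).
#' @param w nitrogen weight for the combined CSP.
#' @return data.frame with columns residue_id, residue_name, category
#'   (factor: instant_disappearance, instant_shift, gradual_shift,
#'   unperturbed), doubled (logical), csp_first, csp_final,
#'   intensity_final_rel.
#' @export
classifyTitration <- function(series, f_inst = 0.8, f_gone = 0.1,
                              floor = 0.02, w = 0.2) {
  if (length(series) < 3)
    analysisError("need >= 3 titration points including the free condition")
  free <- series[[1]]
  if (!nrow(free@peaks))
    analysisError("free condition has no assigned peaks")
  titr <- series[-1]
  fp <- free@peaks
  n <- nrow(fp)
  csp <- matrix(NA_real_, n, length(titr))
  intr <- matrix(NA_real_, n, length(titr))
  doubled <- rep(FALSE, n)
  for (k in seq_along(titr)) {
    p <- titr[[k]]@peaks
    pos <- match(fp$residue_id, p$residue_id)
    ok <- !is.na(pos)
    csp[ok, k] <- combinedCSP(fp$dH_ppm[ok] - p$dH_ppm[pos[ok]],
                              fp$dN_ppm[ok] - p$dN_ppm[pos[ok]], w)
    intr[ok, k] <- p$intensity[pos[ok]] /
      ifelse(fp$intensity[ok] > 0, fp$intensity[ok], 1)
    intr[ok & !p$present[ifelse(is.na(pos), 1L, pos)], k] <- 0
    doubled <- doubled | (ok & !is.na(p$secondary_dH[pos]))
  }
  last <- ncol(csp)
  category <- character(n)
  for (i in seq_len(n)) {
    gone <- !is.na(intr[i, last]) && intr[i, last] < f_gone
    if (gone) { category[i] <- "instant_disappearance"; next }
    cf <- csp[i, last]
    if (is.na(cf) || cf < floor) { category[i] <- "unperturbed"; next }
    c1 <- csp[i, 1]
    category[i] <- if (!is.na(c1) && c1 >= f_inst * cf) "instant_shift"
                   else "gradual_shift"
  }
  out <- data.frame(
    residue_id = fp$residue_id, residue_name = fp$residue_name,
    category = factor(category, levels = c("instant_disappearance",
                                           "instant_shift", "gradual_shift",
                                           "unperturbed")),
    doubled = doubled,
    csp_first = csp[, 1], csp_final = csp[, last],
    intensity_final_rel = intr[, last],
    stringsAsFactors = FALSE
  )
  attr(out, "thresholds") <- c(f_inst = f_inst, f_gone = f_gone,
                               floor = floor, w = w)
  out
}
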