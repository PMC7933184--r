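## Per-binding-mode glycan coverage with replica statistics.
##
## The mode coverage is a footprint-weighted mean of per-residue glycan
## contact fractions, computed within each replica and then averaged over
## replicas:
##
##   C_mode(rep) = sum_res w_res * C_res(rep) / sum_res w_res
##
## where w_res is the ligand footprint weight of the residue in that
## binding mode and C_res(rep) the glycan coverage of the residue in the
## replica. The report carries the replica mean and the standard error of
## the mean (sample SD, ddof 1, divided by sqrt(n)).

#' Construct a binding-mode footprint
#'
#' @param mode mode name, e.g. \code{"crystallographic"}.
#' @param residueIds integer residue ids (author numbering).
#' @param weights per-residue ligand-contact weights in [0, 1]; defaults to
#'   1 for each residue (a binary membership footprint).
#' @return a \linkS4class{ModeFootprint}.
#' @export
modeFootprint <- function(mode, residueIds, weights = rep(1, length(residueIds))) {
  methods::new("ModeFootprint", mode = as.character(mode),
               residueIds = as.integer(residueIds),
               weights = as.numeric(weights))
}

#' Read binding-mode footprints from TSV
#'
#' Expects columns \code{mode}, \code{residue_id}, \code{weight}
#' (comment lines starting with \code{#} ignored).
#'
#' @param path TSV file.
#' @return named list of \linkS4class{ModeFootprint}, one per mode.
#' @export
readFootprints <- function(path) {
  if (!file.exists(path)) configError("footprint file not found: %s", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  need <- c("mode", "residue_id", "weight")
  if (!all(need %in% names(df)))
    formatError("footprint TSV needs columns: %s", paste(need, collapse = ", "))
  out <- lapply(split(df, df$mode), function(d)
    modeFootprint(d$mode[1], d$residue_id, d$weight))
  out[unique(df$mode)]
}

#' Write footprints to TSV
#' @param footprints list of \linkS4class{ModeFootprint}.
#' @param path output TSV.
#' @return invisibly, the path.
#' @export
writeFootprints <- function(footprints, path) {
  df <- do.call(rbind, lapply(footprints, function(fp)
    data.frame(mode = fp@mode, residue_id = fp@residueIds,
               weight = fp@weights)))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Per-binding-mode glycan coverage with replica statistics
#'
#' Evaluates the footprint-weighted mean of per-residue glycan coverage in
#' each replica and reports the replica mean and standard error. The
#' result is invariant to uniform scaling of the footprint weights and is
#' always bounded by the smallest and largest per-residue coverage entering
#' the weighted mean.
#'
#' @param coveragePerReplica list of \linkS4class{ResidueCoverage}, one per
#'   replica (equal-length replicas assumed; all are weighted equally).
#' @param footprint a \linkS4class{ModeFootprint}. Every residue with a
#'   positive weight must be present in every replica — a missing residue
#'   is an error, never a silent zero.
#' @return a \linkS4class{CoverageReport}.
#' @examples
#' rc <- new("ResidueCoverage", residueIds = c(1L, 2L),
#'           residueNames = c("ALA", "GLY"), coverage = c(0.4, 0.2),
#'           cutoff = 0.3, nFrames = 100L)
#' fp <- modeFootprint("demo", c(1L, 2L), c(0.5, 1.0))
#' coverageMean(modeCoverage(list(rc), fp))  # (0.5*0.4 + 1*0.2) / 1.5
#' @export
modeCoverage <- function(coveragePerReplica, footprint) {
  if (methods::is(coveragePerReplica, "ResidueCoverage"))
    coveragePerReplica <- list(coveragePerReplica)
  if (!length(coveragePerReplica)) analysisError("no replicas supplied")
  w <- footprint@weights
  ids <- footprint@residueIds
  active <- w > 0
  per <- vapply(seq_along(coveragePerReplica), function(k) {
    rc <- coveragePerReplica[[k]]
    pos <- match(ids, rc@residueIds)
    miss <- ids[active & is.na(pos)]
    if (length(miss))
      analysisError("replica %d lacks footprint residues: %s", k,
                    paste(miss, collapse = ", "))
    cvals <- rc@coverage[pos]
    cvals[is.na(cvals)] <- 0  # zero-weight residues may be absent
    sum(w * cvals) / sum(w)
  }, numeric(1))
  methods::new("CoverageReport", mode = footprint@mode, perReplica = per)
}

#' Replica mean and SE of coverage for selected key residues
#'
#' @param coveragePerReplica list of \linkS4class{ResidueCoverage}.
#' @param residues integer residue ids; each must be present in every
#'   replica.
#' @return data.frame with columns residue_id, residue_name, mean, se,
#'   n_replicas (se is NA with a single replica).
#' @export
keyResidueCoverage <- function(coveragePerReplica, residues) {
  if (methods::is(coveragePerReplica, "ResidueCoverage"))
    coveragePerReplica <- list(coveragePerReplica)
  residues <- as.integer(residues)
  vals <- vapply(coveragePerReplica, function(rc) {
    pos <- match(residues, rc@residueIds)
    if (anyNA(pos))
      analysisError("unknown residue(s): %s",
                    paste(residues[is.na(pos)], collapse = ", "))
    rc@coverage[pos]
  }, numeric(length(residues)))
  vals <- matrix(vals, nrow = length(residues))
  rn <- coveragePerReplica[[1]]@residueNames[
    match(residues, coveragePerReplica[[1]]@residueIds)]
  data.frame(residue_id = residues, residue_name = rn,
             mean = rowMeans(vals),
             se = apply(vals, 1, sampleSE),
             n_replicas = length(coveragePerReplica))
}

#' Order binding modes by coverage and tabulate pairwise differences
#'
#' Sorts the reports by replica-mean coverage (descending) and lists each
#' pairwise difference with a pooled standard error
#' sqrt(se_a^2 + se_b^2). All reports must come from the same replica set
#' (equal replica counts enforced).
#'
#' @param reports list of \linkS4class{CoverageReport} (>= 2).
#' @return list with elements \code{table} (mode, mean, se, sorted
#'   descending), \code{order} (mode names, most covered first) and
#'   \code{pairs} (mode_a, mode_b, diff, pooled_se).
#' @export
compareModes <- function(reports) {
  if (length(reports) < 2) analysisError("need at least two mode reports")
  ns <- vapply(reports, function(r) length(r@perReplica), integer(1))
  if (length(unique(ns)) > 1)
    analysisError("reports have mismatched replica counts: %s",
                  paste(ns, collapse = ", "))
  tab <- data.frame(
    mode = vapply(reports, modeName, character(1)),
    mean = vapply(reports, coverageMean, numeric(1)),
    se = vapply(reports, coverageSE, numeric(1))
  )
  tab <- tab[order(-tab$mean), , drop = FALSE]
  rownames(tab) <- NULL
  combs <- utils::combn(nrow(tab), 2)
  pairs <- data.frame(
    mode_a = tab$mode[combs[1, ]], mode_b = tab$mode[combs[2, ]],
    diff = tab$mean[combs[1, ]] - tab$mean[combs[2, ]],
    pooled_se = sqrt(tab$se[combs[1, ]]^2 + tab$se[combs[2, ]]^2)
  )
  list(table = tab, order = tab$mode, pairs = pairs)
}

#' Format coverage reports as a percent table
#'
#' One row per mode with \code{"mean +/- SE"} percent strings, mirroring
#' the usual presentation of mode-coverage tables.
#'
#' @param reports list of \linkS4class{CoverageReport}.
#' @param label optional column label (e.g. the glycoform name).
#' @return data.frame with columns mode, coverage_pct, se_pct, formatted.
#' @export
coverageTable <- function(reports, label = "coverage") {
  df <- data.frame(
    mode = vapply(reports, modeName, character(1)),
    coverage_pct = 100 * vapply(reports, coverageMean, numeric(1)),
    se_pct = 100 * vapply(reports, coverageSE, numeric(1))
  )
  df$formatted <- ifelse(is.na(df$se_pct),
                         sprintf("%.0f (SE n/a)", df$coverage_pct),
                         sprintf("%.0f +/- %.0f", df$coverage_pct, df$se_pct))
  attr(df, "label") <- label
  df
}
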