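## Orchestration of the analysis stages from a YAML run configuration,
## exposed to the shell by the thin exec/glycanshield wrapper. Each stage
## writes TSV artifacts with parameter-recording header comments plus a
## JSON provenance sidecar (parameters, seed, package version, input
## hashes). Primary outputs are byte-identical across reruns with the same
## config; timestamps live only in the sidecar.

PIPELINE_COMMANDS <- c("simulate", "coverage", "surface-map", "contacts",
                       "interface", "events", "csp", "classify")

allowedConfigKeys <- c(
  "seed", "output_dir", "scenario", "topology", "trajectories",
  "entity_map", "group", "target", "cutoff", "contact_cutoff", "entities",
  "footprints", "key_residues", "ligand", "receptor", "on_cutoff",
  "off_cutoff", "min_dwell", "sasa", "interface", "nmr", "time_per_frame"
)

readRunConfig <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) configError("config file not found: %s", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) configError("config must be a YAML mapping")
  unknown <- setdiff(names(config), allowedConfigKeys)
  if (length(unknown))
    configError("unknown config key(s): %s", paste(unknown, collapse = ", "))
  config
}

requireKeys <- function(config, keys, command) {
  miss <- keys[vapply(keys, function(k) is.null(config[[k]]), logical(1))]
  if (length(miss))
    configError("command '%s' needs config key(s): %s", command,
                paste(miss, collapse = ", "))
}

checkPathsExist <- function(paths) {
  bad <- paths[!file.exists(paths)]
  if (length(bad))
    configError("input file(s) not found: %s", paste(bad, collapse = ", "))
}

writeTSVWithHeader <- function(df, path, header, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(config))
    header <- c(list(config_hash = attr(config, "hash") %||% "unhashed"),
                header)
  for (k in names(header))
    writeLines(sprintf("# %s: %s", k, paste(header[[k]], collapse = " ")), con)
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

configHash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(config[order(names(config))], tmp)
  unname(tools::md5sum(tmp))
}

writeProvenance <- function(outDir, command, config, params, outputs) {
  inputs <- unlist(config[c("topology", "trajectories", "entity_map",
                            "footprints")], use.names = FALSE)
  inputs <- inputs[!is.null(inputs) & file.exists(as.character(inputs))]
  side <- list(
    command = command,
    package = "glycanshield",
    version = as.character(utils::packageVersion("glycanshield")),
    config_hash = configHash(config),
    parameters = params,
    input_md5 = if (length(inputs))
      as.list(tools::md5sum(as.character(inputs))) else list(),
    outputs = as.list(outputs),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(side, file.path(outDir, sprintf("%s_provenance.json",
                                                       command)),
                       auto_unbox = TRUE, pretty = TRUE)
}

loadReplicaSystems <- function(config) {
  requireKeys(config, c("topology", "trajectories", "entity_map"), "analysis")
  checkPathsExist(c(config$topology, unlist(config$trajectories)))
  sys0 <- loadStructure(config$topology, entityMap = config$entity_map,
                        allowUnassigned = TRUE)
  lapply(unlist(config$trajectories), function(p)
    loadTrajectory(p, sys0, timePerFrame = config$time_per_frame))
}

#' Run one pipeline stage from a YAML configuration
#'
#' Stages: \code{simulate} (write the toy scenario's trajectory replicas
#' and ground truth), \code{coverage} (per-residue glycan coverage and
#' per-mode coverage report), \code{surface-map} (replica-mean distance
#' map with display clamp), \code{contacts} (entity-pair contact matrix),
#' \code{interface} (replica interface areas), \code{events} (ligand
#' binding events), \code{csp} (minimal CSP profile) and \code{classify}
#' (titration categories). Configuration validation failures raise
#' \code{gs_config_error}; analysis failures raise \code{gs_analysis_error}
#' (the CLI maps these to exit codes 2 and 1).
#'
#' @param command one of the stage names above.
#' @param config path to a YAML config, or an equivalent named list.
#' @param outDir output directory (overrides \code{output_dir} in the
#'   config; defaults to \code{"."}).
#' @param seed optional seed overriding the config seed.
#' @return invisibly, a named character vector of written artifact paths.
#' @export
runPipeline <- function(command, config, outDir = NULL, seed = NULL) {
  command <- match.arg(command, PIPELINE_COMMANDS)
  config <- readRunConfig(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  attr(config, "hash") <- configHash(config)
  outDir <- outDir %||% config$output_dir %||% "."
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  outputs <- switch(
    command,
    "simulate" = pipelineSimulate(config, outDir),
    "coverage" = pipelineCoverage(config, outDir),
    "surface-map" = pipelineSurfaceMap(config, outDir),
    "contacts" = pipelineContacts(config, outDir),
    "interface" = pipelineInterface(config, outDir),
    "events" = pipelineEvents(config, outDir),
    "csp" = pipelineCSP(config, outDir),
    "classify" = pipelineClassify(config, outDir)
  )
  writeProvenance(outDir, command, config, outputs$params, outputs$files)
  invisible(outputs$files)
}

pipelineSimulate <- function(config, outDir) {
  requireKeys(config, "seed", "simulate")
  ov <- config$scenario %||% list()
  nrep <- ov$n_replicas %||% 1L
  sc <- shieldScenario(
    nFrames = ov$n_frames %||% 1000L,
    dt = ov$dt %||% 0.1,
    glycanBeads = ov$glycan_beads %||% 8L,
    atomsPerResidue = ov$atoms_per_residue %||% 2L,
    seed = config$seed
  )
  files <- character(0)
  for (k in seq_len(nrep)) {
    sub <- file.path(outDir, sprintf("replica_%02d", k))
    res <- genShieldedTrajectory(sc, replicate = k, dir = sub)
    files <- c(files, res$paths)
  }
  fp_path <- file.path(outDir, "footprints.tsv")
  writeFootprints(toyFootprints(), fp_path)
  files <- c(files, footprints = fp_path)
  list(files = files,
       params = list(seed = sc$seed, n_frames = sc$nFrames, dt = sc$dt,
                     n_replicas = nrep))
}

pipelineCoverage <- function(config, outDir) {
  requireKeys(config, c("footprints", "group", "target"), "coverage")
  checkPathsExist(config$footprints)
  systems <- loadReplicaSystems(config)
  cutoff <- config$cutoff %||% 0.3
  covs <- coveragePerReplica(systems, config$group, config$target,
                             cutoff = cutoff)
  fps <- readFootprints(config$footprints)
  reports <- lapply(fps, function(fp) modeCoverage(covs, fp))
  tab <- coverageTable(reports)
  hdr <- list(cutoff_nm = cutoff, n_replicas = length(systems),
              group = config$group, target = config$target)
  p1 <- writeTSVWithHeader(tab, file.path(outDir, "coverage_report.tsv"),
                           hdr, config)
  resmean <- keyResidueCoverage(covs, residueIds(covs[[1]]))
  p2 <- writeTSVWithHeader(resmean,
                           file.path(outDir, "residue_coverage.tsv"), hdr,
                           config)
  list(files = c(report = p1, residues = p2),
       params = c(hdr, list(modes = names(fps))))
}

pipelineSurfaceMap <- function(config, outDir) {
  requireKeys(config, c("group", "target"), "surface-map")
  systems <- loadReplicaSystems(config)
  sm <- surfaceDistanceMap(systems, config$group, config$target)
  hdr <- list(clamp_nm = "0.3 1.5", n_replicas = length(systems))
  p <- writeTSVWithHeader(sm, file.path(outDir, "surface_distance_map.tsv"),
                          hdr, config)
  list(files = c(surface_map = p), params = hdr)
}

pipelineContacts <- function(config, outDir) {
  systems <- loadReplicaSystems(config)
  ents <- unlist(config$entities) %||%
    grep("^glycan_", entityNames(systems[[1]]), value = TRUE)
  cutoff <- config$contact_cutoff %||% 0.6
  cm <- pairContactCounts(systems, ents, cutoff = cutoff)
  df <- data.frame(entity = rownames(contactCounts(cm)),
                   contactCounts(cm), check.names = FALSE)
  hdr <- list(cutoff_nm = cutoff, n_replicas = length(systems))
  p <- writeTSVWithHeader(df, file.path(outDir, "contact_matrix.tsv"), hdr,
                          config)
  list(files = c(contacts = p), params = hdr)
}

pipelineInterface <- function(config, outDir) {
  requireKeys(config, "interface", "interface")
  ic <- config$interface
  requireKeys(ic, c("part_a", "part_b"), "interface")
  systems <- loadReplicaSystems(config)
  sasa <- config$sasa %||% list()
  rep <- interfaceSeries(systems, ic$part_a, ic$part_b,
                         at = ic$at %||% "final",
                         probe = sasa$probe %||% 0.14,
                         nPoints = sasa$n_points %||% 960L,
                         halved = ic$halved %||% TRUE)
  hdr <- list(part_a = ic$part_a, part_b = ic$part_b,
              at = attr(rep, "at"), probe_nm = sasa$probe %||% 0.14,
              n_points = sasa$n_points %||% 960L,
              mean_nm2 = sprintf("%.6f", attr(rep, "mean")),
              se_nm2 = sprintf("%.6f", attr(rep, "se")))
  p <- writeTSVWithHeader(rep, file.path(outDir, "interface_areas.tsv"), hdr,
                          config)
  list(files = c(interface = p), params = hdr)
}

pipelineEvents <- function(config, outDir) {
  requireKeys(config, c("ligand", "receptor"), "events")
  systems <- loadReplicaSystems(config)
  onc <- config$on_cutoff %||% 0.3
  offc <- config$off_cutoff %||% 0.5
  dwell <- config$min_dwell %||% 1.0
  evs <- do.call(rbind, lapply(seq_along(systems), function(k) {
    ev <- bindingEvents(systems[[k]], config$ligand, config$receptor,
                        onCutoff = onc, offCutoff = offc, minDwell = dwell)
    if (nrow(ev)) cbind(replica = k, ev) else NULL
  }))
  if (is.null(evs))
    evs <- data.frame(replica = integer(0), ligand = character(0),
                      start_frame = integer(0), end_frame = integer(0),
                      start_ns = numeric(0), end_ns = numeric(0),
                      duration_ns = numeric(0))
  hdr <- list(on_cutoff_nm = onc, off_cutoff_nm = offc, min_dwell_ns = dwell)
  p <- writeTSVWithHeader(evs, file.path(outDir, "binding_events.tsv"), hdr,
                          config)
  list(files = c(events = p), params = hdr)
}

pipelineCSP <- function(config, outDir) {
  requireKeys(config, "nmr", "csp")
  nm <- config$nmr
  requireKeys(nm, c("free", "bound"), "csp")
  checkPathsExist(c(nm$free, nm$bound))
  w <- nm$w %||% 0.2
  prof <- minimalCSPProfile(readPeakList(nm$free, "free"),
                            readPeakList(nm$bound, "bound"), w = w)
  hdr <- list(w = w, method = "minimal")
  p <- writeTSVWithHeader(cspTable(prof),
                          file.path(outDir, "csp_profile.tsv"), hdr, config)
  list(files = c(csp = p), params = hdr)
}

pipelineClassify <- function(config, outDir) {
  requireKeys(config, "nmr", "classify")
  nm <- config$nmr
  requireKeys(nm, "titration", "classify")
  paths <- unlist(nm$titration)
  checkPathsExist(paths)
  series <- lapply(seq_along(paths), function(k)
    readPeakList(paths[k], if (k == 1) "free" else sprintf("point_%d", k - 1)))
  res <- classifyTitration(series,
                           f_inst = nm$f_inst %||% 0.8,
                           f_gone = nm$f_gone %||% 0.1,
                           floor = nm$floor %||% 0.02,
                           w = nm$w %||% 0.2)
  hdr <- as.list(attr(res, "thresholds"))
  p <- writeTSVWithHeader(res, file.path(outDir, "titration_categories.tsv"),
                          hdr, config)
  list(files = c(categories = p), params = hdr)
}
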