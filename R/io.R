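## Structure and trajectory I/O.
##
## Internal units are nm (coordinates, boxes) and ns (times), matching the
## GROMACS convention; PDB Angstroms are converted on read/write. PDB and
## DCD go through bio3d; GRO (single- and multi-frame) has a reader/writer
## here since no installed package provides one.

GRO_ATOM_FMT <- "%5d%-5s%5s%5d%8.3f%8.3f%8.3f"

## parse all frames of a (possibly multi-frame) GRO file
parseGRO <- function(path) {
  lines <- readLines(path)
  frames <- list()
  atoms0 <- NULL
  i <- 1L
  nline <- length(lines)
  while (i <= nline) {
    if (!nzchar(trimws(lines[i])) && i == nline) break
    title <- lines[i]
    if (i + 1L > nline)
      formatError("GRO parse failure at line %d: missing atom count", i + 1L)
    nat <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    if (is.na(nat) || nat < 1)
      formatError("GRO parse failure at line %d: bad atom count '%s'",
                  i + 1L, trimws(lines[i + 1L]))
    if (i + 1L + nat + 1L > nline)
      formatError("truncated GRO frame starting at line %d (last complete frame: %d)",
                  i, length(frames))
    al <- lines[(i + 2L):(i + 1L + nat)]
    resid <- suppressWarnings(as.integer(substr(al, 1, 5)))
    resname <- trimws(substr(al, 6, 10))
    atname <- trimws(substr(al, 11, 15))
    atid <- suppressWarnings(as.integer(substr(al, 16, 20)))
    x <- suppressWarnings(as.numeric(substr(al, 21, 28)))
    y <- suppressWarnings(as.numeric(substr(al, 29, 36)))
    z <- suppressWarnings(as.numeric(substr(al, 37, 44)))
    bad <- which(is.na(resid) | is.na(x) | is.na(y) | is.na(z))
    if (length(bad))
      formatError("GRO parse failure at line %d: malformed atom record",
                  i + 1L + bad[1])
    boxline <- as.numeric(strsplit(trimws(lines[i + 2L + nat]), "\\s+")[[1]])
    if (length(boxline) >= 9 && any(abs(boxline[4:9]) > 1e-9))
      formatError("triclinic box in '%s' (line %d): only orthorhombic boxes are supported",
                  path, i + 2L + nat)
    if (length(boxline) < 3 || any(is.na(boxline[1:3])))
      formatError("GRO parse failure at line %d: bad box line", i + 2L + nat)
    tm <- NA_real_
    if (grepl("t=", title)) {
      tm <- suppressWarnings(as.numeric(sub(".*t=\\s*([-0-9.eE+]+).*", "\\1",
                                            title)))
    }
    if (is.null(atoms0))
      atoms0 <- data.frame(residue_id = resid, residue_name = resname,
                           name = atname, atom_id = atid,
                           stringsAsFactors = FALSE)
    else if (nat != nrow(atoms0))
      formatError("frame %d of '%s' has %d atoms, topology has %d",
                  length(frames) + 1L, path, nat, nrow(atoms0))
    frames[[length(frames) + 1L]] <- list(
      xyz = cbind(x, y, z), box = boxline[1:3], time_ps = tm)
    i <- i + nat + 3L
    while (i <= nline && !nzchar(trimws(lines[i]))) i <- i + 1L
  }
  if (!length(frames)) formatError("no frames found in '%s'", path)
  list(atoms = atoms0, frames = frames)
}

## parse an entity map given as a named list (label -> residue spec) or a
## YAML file of the same shape; specs may be integer vectors or strings
## like "20-169" / "20:169" / "25, 57, 100"
parseEntityMap <- function(entityMap) {
  if (is.character(entityMap) && length(entityMap) == 1 &&
      file.exists(entityMap))
    entityMap <- yaml::read_yaml(entityMap)
  if (!is.list(entityMap) || is.null(names(entityMap)) ||
      any(!nzchar(names(entityMap))))
    configError("entity_map must be a named list of residue ranges")
  lapply(entityMap, function(spec) {
    if (is.numeric(spec)) return(as.integer(spec))
    if (is.list(spec)) spec <- unlist(spec)
    if (is.numeric(spec)) return(as.integer(spec))
    out <- integer()
    for (tok in unlist(strsplit(as.character(spec), ","))) {
      tok <- trimws(tok)
      if (grepl("^-?[0-9]+\\s*[-:]\\s*-?[0-9]+$", tok)) {
        ab <- as.integer(strsplit(tok, "[-:]")[[1]])
        out <- c(out, seq(ab[1], ab[2]))
      } else if (grepl("^-?[0-9]+$", tok)) {
        out <- c(out, as.integer(tok))
      } else configError("cannot parse residue range token '%s'", tok)
    }
    out
  })
}

assignEntities <- function(residues, entityMap, allowUnassigned = FALSE) {
  emap <- parseEntityMap(entityMap)
  residues$entity <- NA_character_
  for (label in names(emap)) {
    hit <- residues$residue_id %in% emap[[label]]
    clash <- hit & !is.na(residues$entity)
    if (any(clash))
      configError("residue %s assigned to both '%s' and '%s'",
                  paste(residues$residue_id[clash], collapse = ","),
                  residues$entity[which(clash)[1]], label)
    residues$entity[hit] <- label
  }
  if (anyNA(residues$entity)) {
    if (!allowUnassigned)
      configError("residues not covered by entity_map: %s (set allowUnassigned = TRUE to place them in 'unassigned')",
                  paste(head(residues$residue_id[is.na(residues$entity)], 10),
                        collapse = ", "))
    residues$entity[is.na(residues$entity)] <- "unassigned"
  }
  residues
}

buildSystem <- function(atoms, residues, coords, box, timePerFrame) {
  methods::new("MolecularSystem", atoms = atoms, residues = residues,
               coords = coords, box = box, timePerFrame = timePerFrame)
}

#' Load a structure file into a MolecularSystem
#'
#' Reads a PDB (via bio3d, Angstrom coordinates converted to nm) or GRO
#' (nm) file, assigns each residue to exactly one entity from the entity
#' map, and attaches van der Waals radii from the bundled Bondi table.
#'
#' @param path path to a PDB or GRO file.
#' @param format \code{"auto"} (by extension), \code{"pdb"} or \code{"gro"}.
#' @param entityMap named list mapping entity labels (e.g. \code{"receptor"},
#'   \code{"glycan_N25"}) to residue ids — integer vectors or range strings
#'   such as \code{"20-169"} — or the path of a YAML file with that layout.
#'   A residue in two entities is a configuration error.
#' @param allowUnassigned if TRUE, residues not covered by the map fall into
#'   an \code{"unassigned"} entity instead of raising an error.
#' @param timePerFrame sampling interval in ns recorded for appended
#'   trajectory frames (default 0 for a static structure).
#' @return a single-frame \linkS4class{MolecularSystem} (first model/frame
#'   of the file).
#' @seealso [loadTrajectory()], [resolveSelection()]
#' @export
loadStructure <- function(path, format = c("auto", "pdb", "gro"), entityMap,
                          allowUnassigned = FALSE, timePerFrame = 0) {
  format <- match.arg(format)
  if (!file.exists(path)) configError("file not found: %s", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, pdb = "pdb", ent = "pdb", gro = "gro",
                     formatError("cannot infer structure format from extension '.%s'", ext))
  }
  if (format == "gro") {
    g <- parseGRO(path)
    atoms <- g$atoms
    xyz <- g$frames[[1]]$xyz
    box <- matrix(g$frames[[1]]$box, nrow = 1)
  } else {
    pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE, multi = FALSE),
                    error = function(e) formatError("PDB parse failure in '%s': %s",
                                                    path, conditionMessage(e)))
    a <- pdb$atom
    atoms <- data.frame(residue_id = as.integer(a$resno),
                        residue_name = a$resid, name = a$elety,
                        atom_id = as.integer(a$eleno),
                        stringsAsFactors = FALSE)
    xyz <- cbind(a$x, a$y, a$z) / 10  # Angstrom -> nm
    box <- matrix(numeric(0), nrow = 0, ncol = 3)
  }
  elem <- if (format == "pdb" && !is.null(pdb$atom$elesy) &&
              any(nzchar(trimws(pdb$atom$elesy))))
    toupper(trimws(pdb$atom$elesy)) else elementFromName(atoms$name)
  elem[!nzchar(elem)] <- elementFromName(atoms$name[!nzchar(elem)])
  atomdf <- data.frame(atom_id = atoms$atom_id, name = atoms$name,
                       element = elem,
                       radius = unname(vdwRadius(elem)),
                       residue_id = atoms$residue_id,
                       stringsAsFactors = FALSE)
  resdf <- unique(atoms[, c("residue_id", "residue_name")])
  if (anyDuplicated(resdf$residue_id))
    formatError("residue id reused with different names in '%s'", path)
  resdf <- assignEntities(resdf, entityMap, allowUnassigned)
  coords <- array(xyz, dim = c(nrow(atomdf), 3, 1))
  buildSystem(atomdf, resdf, coords, box, as.numeric(timePerFrame))
}

#' Append trajectory frames to a MolecularSystem
#'
#' Supports multi-frame GRO, multi-model PDB and DCD (via bio3d). Frames
#' replace the single structure frame when \code{replace = TRUE} (default:
#' the structure frame is dropped and only trajectory frames are kept).
#'
#' @param path trajectory file.
#' @param system the topology \linkS4class{MolecularSystem}.
#' @param format \code{"auto"}, \code{"gro"}, \code{"pdb"} or \code{"dcd"}.
#' @param timePerFrame frame spacing in ns; when NULL it is taken from GRO
#'   title times where available, else defaults to the system's value.
#' @param replace drop the structure's own frames first (default TRUE).
#' @return the system with trajectory frames attached.
#' @export
loadTrajectory <- function(path, system, format = c("auto", "gro", "pdb", "dcd"),
                           timePerFrame = NULL, replace = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) configError("file not found: %s", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, gro = "gro", pdb = "pdb", dcd = "dcd",
                     formatError("cannot infer trajectory format from extension '.%s'", ext))
  }
  nat <- nAtoms(system)
  if (format == "gro") {
    g <- parseGRO(path)
    if (nrow(g$atoms) != nat)
      formatError("trajectory has %d atoms, topology has %d",
                  nrow(g$atoms), nat)
    nf <- length(g$frames)
    coords <- array(0, dim = c(nat, 3, nf))
    box <- matrix(0, nrow = nf, ncol = 3)
    for (f in seq_len(nf)) {
      coords[, , f] <- g$frames[[f]]$xyz
      box[f, ] <- g$frames[[f]]$box
    }
    times <- vapply(g$frames, function(fr) fr$time_ps, numeric(1))
    if (is.null(timePerFrame)) {
      timePerFrame <- if (length(times) > 1 && !anyNA(times))
        (times[2] - times[1]) / 1000  # GRO titles carry ps
      else system@timePerFrame
    }
  } else if (format == "pdb") {
    pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE, multi = TRUE),
                    error = function(e) formatError("PDB parse failure in '%s': %s",
                                                    path, conditionMessage(e)))
    xyz <- pdb$xyz
    if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1)
    if (ncol(xyz) != 3 * nat)
      formatError("trajectory has %d atoms, topology has %d",
                  ncol(xyz) / 3, nat)
    nf <- nrow(xyz)
    coords <- array(0, dim = c(nat, 3, nf))
    for (f in seq_len(nf))
      coords[, , f] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE) / 10
    box <- matrix(numeric(0), nrow = 0, ncol = 3)
    if (is.null(timePerFrame)) timePerFrame <- system@timePerFrame
  } else {  # dcd
    xyz <- tryCatch(bio3d::read.dcd(path, verbose = FALSE),
                    error = function(e) formatError("DCD read failure in '%s': %s",
                                                    path, conditionMessage(e)))
    if (ncol(xyz) != 3 * nat)
      formatError("trajectory has %d atoms, topology has %d",
                  ncol(xyz) / 3, nat)
    nf <- nrow(xyz)
    coords <- array(0, dim = c(nat, 3, nf))
    for (f in seq_len(nf))
      coords[, , f] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE) / 10
    box <- matrix(numeric(0), nrow = 0, ncol = 3)
    if (is.null(timePerFrame)) timePerFrame <- system@timePerFrame
  }
  if (nrow(box) > 0 && isPeriodic(system) == FALSE && nFrames(system) > 0) {
    # topology was non-periodic; trajectory box wins
  }
  if (!replace) {
    if (isPeriodic(system) != (nrow(box) > 0))
      formatError("cannot mix periodic and non-periodic frames")
    coords <- array(c(system@coords, coords),
                    dim = c(nat, 3, nFrames(system) + dim(coords)[3]))
    if (nrow(box) > 0) box <- rbind(system@box, box)
  }
  buildSystem(system@atoms, system@residues, coords, box,
              as.numeric(timePerFrame))
}

#' Write a MolecularSystem to (multi-frame) GRO
#'
#' Coordinates are written in nm at the format's \code{\%8.3f} precision;
#' frame times (ns, from \code{timePerFrame}) go into the title lines in ps
#' as GROMACS does. Non-periodic systems get a zero box line.
#'
#' @param system a \linkS4class{MolecularSystem}.
#' @param path output file.
#' @param frames frame indices to write (default: all).
#' @param title title prefix for each frame block.
#' @return invisibly, the path.
#' @export
writeGRO <- function(system, path, frames = seq_len(nFrames(system)),
                     title = "glycanshield system") {
  at <- system@atoms
  con <- file(path, "w")
  on.exit(close(con))
  for (f in frames) {
    t_ps <- (f - 1) * system@timePerFrame * 1000
    writeLines(sprintf("%s t= %.4f", title, t_ps), con)
    writeLines(sprintf("%5d", nAtoms(system)), con)
    xyz <- frameCoords(system, f)
    writeLines(sprintf(GRO_ATOM_FMT,
                       at$residue_id %% 100000L,
                       substr(system@residues$residue_name[
                         match(at$residue_id, system@residues$residue_id)], 1, 5),
                       substr(at$name, 1, 5),
                       at$atom_id %% 100000L,
                       xyz[, 1], xyz[, 2], xyz[, 3]), con)
    b <- if (isPeriodic(system)) system@box[f, ] else c(0, 0, 0)
    writeLines(sprintf("%10.5f%10.5f%10.5f", b[1], b[2], b[3]), con)
  }
  invisible(path)
}

#' Export per-residue values as a PDB B-factor column
#'
#' Writes one frame of the system as PDB (nm converted to Angstrom) with a
#' per-residue value (e.g. coverage or mean distance) in the B-factor
#' column, for surface rendering in molecular viewers.
#'
#' @param system a \linkS4class{MolecularSystem}.
#' @param values named numeric vector, names = residue ids; residues not
#'   named get 0.
#' @param path output PDB path.
#' @param frame frame index to write.
#' @return invisibly, the path.
#' @export
writeBFactorPDB <- function(system, values, path, frame = 1L) {
  at <- system@atoms
  xyz <- frameCoords(system, frame) * 10
  b <- values[as.character(at$residue_id)]
  b[is.na(b)] <- 0
  rn <- system@residues$residue_name[match(at$residue_id,
                                           system@residues$residue_id)]
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(xyz)),
                   resno = at$residue_id, resid = substr(rn, 1, 3),
                   eleno = at$atom_id, elety = at$name,
                   b = round(as.numeric(b), 2))
  invisible(path)
}

#' Read/write the footprint and entity-map artifacts
#'
#' \code{writeEntityMapYAML} writes the entity assignment of a system as a
#' YAML entity map usable by [loadStructure()].
#'
#' @param system a \linkS4class{MolecularSystem}.
#' @param path output YAML path.
#' @return invisibly, the path.
#' @export
writeEntityMapYAML <- function(system, path) {
  emap <- lapply(entityResidues(system), function(ids) as.integer(ids))
  yaml::write_yaml(emap, path)
  invisible(path)
}
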