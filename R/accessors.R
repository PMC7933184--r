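## Accessors and show methods. Slot access from user code is discouraged;
## everything downstream goes through these.

#' @rdname MolecularSystem-class
#' @param x,object a \linkS4class{MolecularSystem}
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))
#' @rdname MolecularSystem-class
#' @export
setMethod("nAtoms", "MolecularSystem", function(x) nrow(x@atoms))

#' @rdname MolecularSystem-class
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
#' @rdname MolecularSystem-class
#' @export
setMethod("nFrames", "MolecularSystem", function(x) dim(x@coords)[3])

#' @rdname MolecularSystem-class
#' @export
setGeneric("atomTable", function(x) standardGeneric("atomTable"))
#' @rdname MolecularSystem-class
#' @export
setMethod("atomTable", "MolecularSystem", function(x) x@atoms)

#' @rdname MolecularSystem-class
#' @export
setGeneric("residueTable", function(x) standardGeneric("residueTable"))
#' @rdname MolecularSystem-class
#' @export
setMethod("residueTable", "MolecularSystem", function(x) x@residues)

#' @rdname MolecularSystem-class
#' @export
setGeneric("entityNames", function(x) standardGeneric("entityNames"))
#' @rdname MolecularSystem-class
#' @export
setMethod("entityNames", "MolecularSystem",
          function(x) sort(unique(x@residues$entity)))

#' @rdname MolecularSystem-class
#' @details \code{entityResidues} returns the entity map as a named list of
#'   residue-id vectors.
#' @export
setGeneric("entityResidues", function(x) standardGeneric("entityResidues"))
#' @rdname MolecularSystem-class
#' @export
setMethod("entityResidues", "MolecularSystem", function(x) {
  split(x@residues$residue_id, x@residues$entity)
})

#' @rdname MolecularSystem-class
#' @param frame frame index (1-based)
#' @export
setGeneric("frameCoords", function(x, frame = 1L) standardGeneric("frameCoords"))
#' @rdname MolecularSystem-class
#' @export
setMethod("frameCoords", "MolecularSystem", function(x, frame = 1L) {
  stopifnot(frame >= 1, frame <= nFrames(x))
  m <- x@coords[, , frame, drop = FALSE]
  dim(m) <- dim(m)[1:2]
  colnames(m) <- c("x", "y", "z")
  m
})

#' @rdname MolecularSystem-class
#' @export
setGeneric("coordArray", function(x) standardGeneric("coordArray"))
#' @rdname MolecularSystem-class
#' @export
setMethod("coordArray", "MolecularSystem", function(x) x@coords)

#' @rdname MolecularSystem-class
#' @export
setGeneric("isPeriodic", function(x) standardGeneric("isPeriodic"))
#' @rdname MolecularSystem-class
#' @export
setMethod("isPeriodic", "MolecularSystem", function(x) nrow(x@box) > 0)

#' @rdname MolecularSystem-class
#' @export
setGeneric("boxLengths", function(x) standardGeneric("boxLengths"))
#' @rdname MolecularSystem-class
#' @export
setMethod("boxLengths", "MolecularSystem", function(x) x@box)

#' @rdname MolecularSystem-class
#' @export
setGeneric("timePerFrame", function(x) standardGeneric("timePerFrame"))
#' @rdname MolecularSystem-class
#' @export
setMethod("timePerFrame", "MolecularSystem", function(x) x@timePerFrame)

setMethod("show", "MolecularSystem", function(object) {
  cat("MolecularSystem:", nAtoms(object), "atoms,",
      nrow(object@residues), "residues,",
      length(entityNames(object)), "entities,",
      nFrames(object), "frame(s)\n")
  cat("  entities:", paste(entityNames(object), collapse = ", "), "\n")
  if (isPeriodic(object)) {
    b <- object@box[1, ]
    cat(sprintf("  periodic box (frame 1): %.3f x %.3f x %.3f nm\n",
                b[1], b[2], b[3]))
  } else cat("  non-periodic\n")
  if (nFrames(object) > 1)
    cat(sprintf("  time per frame: %g ns\n", timePerFrame(object)))
})

## --- shared residue-indexed accessors -----------------------------------

#' Residue ids of a residue-indexed result
#' @param x a ResidueDistanceSeries, ResidueCoverage, or ModeFootprint
#' @export
setGeneric("residueIds", function(x) standardGeneric("residueIds"))
#' @rdname residueIds
#' @export
setMethod("residueIds", "ResidueDistanceSeries", function(x) x@residueIds)
#' @rdname residueIds
#' @export
setMethod("residueIds", "ResidueCoverage", function(x) x@residueIds)
#' @rdname residueIds
#' @export
setMethod("residueIds", "ModeFootprint", function(x) x@residueIds)

#' Distance matrix (frames x residues, nm) of a ResidueDistanceSeries
#' @param x a \linkS4class{ResidueDistanceSeries}
#' @export
setGeneric("distanceMatrix", function(x) standardGeneric("distanceMatrix"))
#' @rdname distanceMatrix
#' @export
setMethod("distanceMatrix", "ResidueDistanceSeries", function(x) {
  m <- x@distances
  colnames(m) <- as.character(x@residueIds)
  m
})

setMethod("show", "ResidueDistanceSeries", function(object) {
  cat("ResidueDistanceSeries:", ncol(object@distances), "residues x",
      nrow(object@distances), "frames (nm)\n")
})

#' Coverage values of a ResidueCoverage, named by residue id
#' @param x a \linkS4class{ResidueCoverage}
#' @export
setGeneric("coverage", function(x) standardGeneric("coverage"))
#' @rdname coverage
#' @export
setMethod("coverage", "ResidueCoverage", function(x)
  setNames(x@coverage, x@residueIds))

#' Contact cutoff (nm) recorded in a result
#' @param x a ResidueCoverage or ContactMatrix
#' @export
setGeneric("contactCutoff", function(x) standardGeneric("contactCutoff"))
#' @rdname contactCutoff
#' @export
setMethod("contactCutoff", "ResidueCoverage", function(x) x@cutoff)
#' @rdname contactCutoff
#' @export
setMethod("contactCutoff", "ContactMatrix", function(x) x@cutoff)

setMethod("show", "ResidueCoverage", function(object) {
  cat(sprintf("ResidueCoverage: %d residues, cutoff %g nm, %d frames\n",
              length(object@residueIds), object@cutoff, object@nFrames))
  cat(sprintf("  coverage range: %.3f - %.3f\n",
              min(object@coverage), max(object@coverage)))
})

#' Contact count matrix (entities x entities)
#' @param x a \linkS4class{ContactMatrix}
#' @export
setGeneric("contactCounts", function(x) standardGeneric("contactCounts"))
#' @rdname contactCounts
#' @export
setMethod("contactCounts", "ContactMatrix", function(x) x@counts)

setMethod("show", "ContactMatrix", function(object) {
  cat(sprintf("ContactMatrix: %d entities, cutoff %g nm, %d frames, %d replica(s)\n",
              nrow(object@counts), object@cutoff, object@nFrames,
              object@nReplicas))
  print(round(object@counts, 2))
})

## --- footprints / coverage reports --------------------------------------

#' Mode name of a footprint or coverage report
#' @param x a ModeFootprint or CoverageReport
#' @export
setGeneric("modeName", function(x) standardGeneric("modeName"))
#' @rdname modeName
#' @export
setMethod("modeName", "ModeFootprint", function(x) x@mode)
#' @rdname modeName
#' @export
setMethod("modeName", "CoverageReport", function(x) x@mode)

#' Footprint weights named by residue id
#' @param x a \linkS4class{ModeFootprint}
#' @export
setGeneric("footprintWeights", function(x) standardGeneric("footprintWeights"))
#' @rdname footprintWeights
#' @export
setMethod("footprintWeights", "ModeFootprint", function(x)
  setNames(x@weights, x@residueIds))

setMethod("show", "ModeFootprint", function(object) {
  cat(sprintf("ModeFootprint '%s': %d residues, weight sum %.3f\n",
              object@mode, length(object@residueIds), sum(object@weights)))
})

#' Per-replica coverage values of a CoverageReport
#' @param x a \linkS4class{CoverageReport}
#' @export
setGeneric("replicaValues", function(x) standardGeneric("replicaValues"))
#' @rdname replicaValues
#' @export
setMethod("replicaValues", "CoverageReport", function(x) x@perReplica)

#' Replica-mean coverage of a CoverageReport (fraction in [0, 1])
#' @param x a \linkS4class{CoverageReport}
#' @export
setGeneric("coverageMean", function(x) standardGeneric("coverageMean"))
#' @rdname coverageMean
#' @export
setMethod("coverageMean", "CoverageReport", function(x) mean(x@perReplica))

#' Standard error of the replica-mean coverage (NA for one replica)
#' @param x a \linkS4class{CoverageReport}
#' @export
setGeneric("coverageSE", function(x) standardGeneric("coverageSE"))
#' @rdname coverageSE
#' @export
setMethod("coverageSE", "CoverageReport", function(x) {
  n <- length(x@perReplica)
  if (n < 2) return(NA_real_)
  sd(x@perReplica) / sqrt(n)
})

setMethod("show", "CoverageReport", function(object) {
  n <- length(object@perReplica)
  se <- coverageSE(object)
  cat(sprintf("CoverageReport '%s': %.1f%% %s (n = %d replicas)\n",
              object@mode, 100 * coverageMean(object),
              if (is.na(se)) "(SE n/a)" else sprintf("+/- %.1f%%", 100 * se),
              n))
})

## --- SASA ---------------------------------------------------------------

#' Per-atom accessible areas (nm^2)
#' @param x a \linkS4class{SASAResult}
#' @export
setGeneric("atomAreas", function(x) standardGeneric("atomAreas"))
#' @rdname atomAreas
#' @export
setMethod("atomAreas", "SASAResult", function(x) x@atomAreas)

#' Total accessible area of the selection (nm^2)
#' @param x a \linkS4class{SASAResult}
#' @export
setGeneric("totalArea", function(x) standardGeneric("totalArea"))
#' @rdname totalArea
#' @export
setMethod("totalArea", "SASAResult", function(x) sum(x@atomAreas))

setMethod("show", "SASAResult", function(object) {
  cat(sprintf("SASAResult: %d atoms, total %.3f nm^2 (probe %g nm, %d points)\n",
              length(object@atomAreas), totalArea(object), object@probe,
              object@nPoints))
})

## --- NMR ----------------------------------------------------------------

#' Peak table of a PeakList
#' @param x a \linkS4class{PeakList}
#' @export
setGeneric("peakTable", function(x) standardGeneric("peakTable"))
#' @rdname peakTable
#' @export
setMethod("peakTable", "PeakList", function(x) x@peaks)

#' Unassigned peak pool of a PeakList
#' @param x a \linkS4class{PeakList}
#' @export
setGeneric("unassignedPeaks", function(x) standardGeneric("unassignedPeaks"))
#' @rdname unassignedPeaks
#' @export
setMethod("unassignedPeaks", "PeakList", function(x) x@unassigned)

#' Condition label of a PeakList
#' @param x a \linkS4class{PeakList}
#' @export
setGeneric("conditionLabel", function(x) standardGeneric("conditionLabel"))
#' @rdname conditionLabel
#' @export
setMethod("conditionLabel", "PeakList", function(x) x@condition)

setMethod("show", "PeakList", function(object) {
  cat(sprintf("PeakList '%s': %d assigned peaks (%d present), %d unassigned\n",
              object@condition, nrow(object@peaks),
              sum(object@peaks$present), nrow(object@unassigned)))
})

#' CSP table of a CSPProfile
#' @param x a \linkS4class{CSPProfile}
#' @export
setGeneric("cspTable", function(x) standardGeneric("cspTable"))
#' @rdname cspTable
#' @export
setMethod("cspTable", "CSPProfile", function(x) x@data)

setMethod("show", "CSPProfile", function(object) {
  ok <- !object@data$missing
  cat(sprintf("CSPProfile (%s, w = %g): %d residues, %d missing, max CSP %.4f ppm\n",
              object@method, object@w, nrow(object@data), sum(!ok),
              if (any(ok)) max(object@data$csp_ppm[ok]) else NA))
})
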