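#' Van der Waals radii by element (nm)
#'
#' Bondi van der Waals radii for the elements occurring in protein,
#' glycan and nucleic-acid systems, in nm. Used for SASA computations and
#' assigned to atoms on structure load. Elements missing from the table get
#' NA and trigger a configuration error when a SASA is requested.
#'
#' @param element character vector of element symbols (case-insensitive).
#' @return named numeric vector of radii (nm); NA for unknown elements.
#' @examples
#' vdwRadius(c("C", "N", "O"))
#' @export
vdwRadius <- function(element) {
  tab <- c(
    H = 0.120, C = 0.170, N = 0.155, O = 0.152, S = 0.180,
    P = 0.180, F = 0.147, CL = 0.175, BR = 0.185, I = 0.198,
    NA_ = 0.227, K = 0.275, MG = 0.173, CA = 0.231, ZN = 0.139,
    FE = 0.194, MN = 0.205, SE = 0.190
  )
  names(tab)[names(tab) == "NA_"] <- "NA"
  out <- tab[toupper(element)]
  names(out) <- element
  out
}

## best-effort element from a PDB/GRO atom name when no element column exists
elementFromName <- function(name) {
  nm <- toupper(trimws(name))
  two <- substr(nm, 1, 2)
  known2 <- c("CL", "BR", "MG", "ZN", "FE", "MN", "SE")
  ifelse(two %in% known2, two,
         ifelse(substr(nm, 1, 1) %in% c("H", "C", "N", "O", "S", "P", "F", "I"),
                substr(nm, 1, 1), substr(nm, 1, 1)))
}
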