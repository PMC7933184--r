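## internal helpers

gs_error <- function(class, fmt, ...) {
  stop(structure(
    class = c(class, "gs_error", "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}

configError <- function(fmt, ...) gs_error("gs_config_error", fmt, ...)
formatError <- function(fmt, ...) gs_error("gs_format_error", fmt, ...)
selectionError <- function(fmt, ...) gs_error("gs_selection_error", fmt, ...)
analysisError <- function(fmt, ...) gs_error("gs_analysis_error", fmt, ...)
parameterError <- function(fmt, ...) gs_error("gs_parameter_error", fmt, ...)

## run code under a fixed RNG seed, restoring the caller's RNG state
withSeed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

## sample standard error of the mean; NA for n < 2
sampleSE <- function(x) {
  n <- length(x)
  if (n < 2) return(NA_real_)
  stats::sd(x) / sqrt(n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
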