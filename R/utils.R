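# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Signal a classed photoHGT error
#'
#' All user-facing errors carry a subclass (e.g. "photoHGT_domain_error")
#' so callers and tests can distinguish failure modes.
#' @noRd
ph_stop <- function(class, msg, call = sys.call(-1)) {
  stop(errorCondition(msg,
    class = c(paste0("photoHGT_", class), "photoHGT_error"),
    call = call
  ))
}

ph_warn <- function(class, msg) {
  warning(warningCondition(msg,
    class = c(paste0("photoHGT_", class), "photoHGT_warning")
  ))
}

#' Normalize a completeness/contamination value to a fraction
#'
#' Quality estimates are reported either as fractions (0.87) or as percent
#' (87, CheckM table style). Values in (1, 100] are auto-scaled to fractions
#' with a warning; values > 100 are rejected.
#' @noRd
normalize_fraction <- function(x, what = "value", warn = TRUE) {
  if (!is.numeric(x) || anyNA(x)) {
    ph_stop("invalid_quality_error", sprintf("%s must be numeric and non-missing", what))
  }
  scaled <- x > 1 & x <= 100
  if (any(x > 100) || any(x < 0)) {
    ph_stop("invalid_quality_error", sprintf("%s outside [0, 100]: %s", what,
      paste(format(x[x > 100 | x < 0]), collapse = ", ")))
  }
  if (any(scaled)) {
    if (warn) {
      ph_warn("scale", sprintf(
        "%s value(s) in (1, 100] interpreted as percent and divided by 100", what))
    }
    x[scaled] <- x[scaled] / 100
  }
  x
}

#' Evaluate code with a temporary RNG seed, restoring global RNG state
#' @noRd
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
      ph_stop("domain_error", "seed must be a single non-missing number")
    }
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (had) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

#' Short, stable hash of an R object (provenance stamps in reports)
#' @noRd
config_hash <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(paste(deparse(x), collapse = "\n"), tf)
  unname(tools::md5sum(tf))
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == floor(x)
}
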