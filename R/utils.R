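#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `code` with the global random-number generator seeded to `seed`, then
#' restores the previous RNG state. All stochastic operations in the package
#' route through this helper so that a single integer seed determines every
#' draw and no global state leaks between stages.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
withSeed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Derive a stage seed from a master seed
#'
#' Fixed-offset derivation keeps stage RNG streams decoupled while everything
#' still flows from one integer. Result always fits a 32-bit signed integer.
#'
#' @param seed master integer seed.
#' @param offset small non-negative integer identifying the stage.
#' @keywords internal
deriveSeed <- function(seed, offset) {
  s <- (abs(as.numeric(seed)) %% 1000003) * 1009 + as.numeric(offset)
  as.integer(s %% 2147483647)
}

# scalar validators ---------------------------------------------------------

isCount <- function(x, positive = TRUE) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x) &&
    (if (positive) x >= 1 else x >= 0)
}

isFraction <- function(x, openLeft = FALSE, openRight = FALSE) {
  is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (openLeft) x > 0 else x >= 0) &&
    (if (openRight) x < 1 else x <= 1)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# spot-key helper: unique string per (slide, row, col) ----------------------
spotKey <- function(slide, row, col) paste(slide, row, col, sep = "\r")
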