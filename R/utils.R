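`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
is_verbose <- function(verbose = NULL) {
  if (!is.null(verbose)) isTRUE(verbose) else isTRUE(getOption("rkcca.verbose", TRUE))
}

#' Emit a status message unless quiet
#' @noRd
vmessage <- function(..., verbose = NULL) {
  if (is_verbose(verbose)) message(...)
}

#' Run code under a temporary RNG seed, restoring the caller's stream
#'
#' Keeps package-internal randomness (synthetic data, CV splits) from
#' perturbing the user's global random stream, and makes results a pure
#' function of the supplied seed.
#' @noRd
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

#' Derive a 32-bit sub-seed from (seed, iteration)
#' @noRd
derive_seed <- function(seed, iteration) {
  (abs(as.numeric(seed)) + 104729 * as.numeric(iteration)) %% 2147483646 + 1
}

#' Pearson correlation that maps zero-variance input to 0 with a warning
#' @noRd
safe_cor <- function(x, y, what = "column") {
  sx <- stats::sd(x)
  sy <- stats::sd(y)
  if (!is.finite(sx) || !is.finite(sy) || sx == 0 || sy == 0) {
    warning("zero-variance ", what, ": correlation recorded as 0", call. = FALSE)
    return(0)
  }
  stats::cor(x, y)
}
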