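# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Index of the grid point nearest a named wavenumber
#'
#' Resolves any named wavenumber (1003, 1462, ...) to a grid index.
#' Ties between two equidistant grid points are broken toward the lower
#' wavenumber.
#'
#' @param wavenumbers sorted numeric vector of grid wavenumbers (cm^-1)
#' @param target target wavenumber (cm^-1)
#' @return integer index into `wavenumbers`
#' @keywords internal
nearest_index <- function(wavenumbers, target) {
  d <- abs(wavenumbers - target)
  # which.min returns the first (lowest-wavenumber) minimum on ties
  which.min(d)
}

assert_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("`%s` must be positive", name), call. = FALSE)
  invisible(x)
}

# run `expr` under a fixed seed when `seed` is given, without disturbing the
# caller's RNG state; `seed = NULL` leaves the RNG stream alone
with_seed_maybe <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}
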