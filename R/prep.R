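# Preprocessing chain: cosmic-ray removal, iterative restrained polynomial
# baseline subtraction, range truncation and reference-peak normalisation.

#' Baseline-correction configuration
#'
#' @param polynomial_order order of the fitted background polynomial
#'   (default 11)
#' @param noise_tolerance one-sided exclusion threshold as a multiple of
#'   the residual SD (default 1.5)
#' @param max_iterations iteration cap for the restrained fit (default 100)
#' @return object of class `baseline_config`
#' @export
baseline_config <- function(polynomial_order = 11, noise_tolerance = 1.5,
                            max_iterations = 100) {
  if (polynomial_order < 0) stop("order must be >= 0", call. = FALSE)
  assert_scalar_number(noise_tolerance, "noise_tolerance", positive = TRUE)
  structure(list(polynomial_order = as.integer(polynomial_order),
                 noise_tolerance = noise_tolerance,
                 max_iterations = as.integer(max_iterations)),
            class = "baseline_config")
}

#' Remove cosmic-ray spikes from a spectrum
#'
#' Intensity excursions whose full width above half their local prominence
#' spans at most `max_feature_width` grid points are replaced by linear
#' interpolation across their footprint; broader (genuine) peaks are left
#' untouched. Detection runs on the input intensities; all replacements are
#' applied to a copy, so overlapping footprints are handled consistently.
#'
#' @param s a `raman_spectrum`
#' @param max_feature_width maximum spike width in grid points (default 2)
#' @param min_prominence ignore excursions with prominence at or below this
#'   value (default 0: every narrow excursion is treated as a spike)
#' @return despiked `raman_spectrum`
#' @export
remove_cosmic_rays <- function(s, max_feature_width = 2, min_prominence = 0) {
  if (max_feature_width < 1) stop("max_feature_width must be >= 1",
                                  call. = FALSE)
  y <- s$intensity
  n <- length(y)
  out <- y
  for (i in 2:(n - 1L)) {
    if (!(y[i] > y[i - 1L] && y[i] >= y[i + 1L])) next  # not a local max
    l <- i; while (l > 1L && y[l - 1L] < y[l]) l <- l - 1L
    r <- i; while (r < n && y[r + 1L] < y[r]) r <- r + 1L
    prominence <- y[i] - max(y[l], y[r])
    if (prominence <= min_prominence) next
    half <- y[i] - prominence / 2
    a <- i; while (a > l && y[a - 1L] > half) a <- a - 1L
    b <- i; while (b < r && y[b + 1L] > half) b <- b + 1L
    if (b - a + 1L > max_feature_width) next
    lo <- max(a - 1L, 1L); hi <- min(b + 1L, n)
    fill <- stats::approx(x = s$wavenumber[c(lo, hi)], y = y[c(lo, hi)],
                          xout = s$wavenumber[a:b])$y
    out[a:b] <- fill
  }
  spectrum(s$wavenumber, out, sample_id = s$meta$sample_id,
           map_id = s$meta$map_id, class = s$meta$class)
}

#' Subtract an iteratively restrained polynomial baseline
#'
#' Fits a polynomial of order `cfg$polynomial_order` to the spectrum,
#' iteratively excluding points lying more than
#' `noise_tolerance x residual SD` above the current polynomial (the
#' peaks; Raman bands are positive, so exclusion is one-sided) and refits
#' until the excluded set is stable or `max_iterations` is reached. The
#' final polynomial is subtracted. A pure polynomial input of order up to
#' `polynomial_order` is annihilated.
#'
#' @param s a `raman_spectrum`
#' @param cfg a [baseline_config()]
#' @return baseline-subtracted `raman_spectrum` with attributes
#'   `baseline` (the fitted background), `converged` (logical) and
#'   `iterations`
#' @export
subtract_baseline <- function(s, cfg = baseline_config()) {
  y <- s$intensity
  n <- length(y)
  ord <- cfg$polynomial_order
  if (n <= ord + 1L)
    stop("spectrum must have more than polynomial_order + 1 points",
         call. = FALSE)
  # orthogonal polynomial basis for numerical stability at high order
  basis <- cbind(1, if (ord > 0) stats::poly(s$wavenumber, degree = ord))
  included <- rep(TRUE, n)
  converged <- FALSE
  iter <- 0L
  fitted_full <- rep(0, n)
  repeat {
    iter <- iter + 1L
    fit <- stats::lm.fit(basis[included, , drop = FALSE], y[included])
    cf <- fit$coefficients
    cf[is.na(cf)] <- 0
    fitted_full <- drop(basis %*% cf)
    r <- y - fitted_full
    sigma <- stats::sd(r[included])
    # an (almost) interpolating fit: nothing left to exclude
    if (!is.finite(sigma) || sigma <= 1e-10 * max(abs(y), 1)) {
      converged <- TRUE; break
    }
    new_included <- r <= cfg$noise_tolerance * sigma
    if (sum(new_included) <= ord + 1L) { converged <- TRUE; break }
    if (identical(new_included, included)) { converged <- TRUE; break }
    if (iter >= cfg$max_iterations) break
    included <- new_included
  }
  out <- spectrum(s$wavenumber, y - fitted_full,
                  sample_id = s$meta$sample_id, map_id = s$meta$map_id,
                  class = s$meta$class)
  attr(out, "baseline") <- fitted_full
  attr(out, "converged") <- converged
  attr(out, "iterations") <- iter
  if (!converged)
    warning("baseline fit did not converge within max_iterations",
            call. = FALSE)
  out
}

#' Truncate a spectrum to a wavenumber range
#'
#' @param s a `raman_spectrum`
#' @param lo,hi inclusive range bounds, cm^-1 (defaults 690 and 1655)
#' @return truncated `raman_spectrum` (metadata preserved)
#' @export
truncate_spectrum <- function(s, lo = 690, hi = 1655) {
  if (lo >= hi) stop("lo must be < hi", call. = FALSE)
  keep <- s$wavenumber >= lo & s$wavenumber <= hi
  if (sum(keep) < 2L)
    stop(sprintf("no spectral points in [%g, %g] cm^-1", lo, hi),
         call. = FALSE)
  spectrum(s$wavenumber[keep], s$intensity[keep],
           sample_id = s$meta$sample_id, map_id = s$meta$map_id,
           class = s$meta$class)
}

#' Normalise a spectrum at a reference wavenumber
#'
#' Divides all intensities by the intensity at the grid point nearest
#' `ref_wavenumber` (ties toward the lower wavenumber), so the output
#' reference intensity is exactly 1.
#'
#' @param s a `raman_spectrum`
#' @param ref_wavenumber reference peak position, cm^-1 (default 1003)
#' @return normalised `raman_spectrum`
#' @export
normalize_at <- function(s, ref_wavenumber = 1003) {
  i <- nearest_index(s$wavenumber, ref_wavenumber)
  ref <- s$intensity[i]
  if (!is.finite(ref) || ref <= 0)
    stop(sprintf(
      "cannot normalise: intensity at %g cm^-1 is %g (must be positive)",
      s$wavenumber[i], ref), call. = FALSE)
  spectrum(s$wavenumber, s$intensity / ref, sample_id = s$meta$sample_id,
           map_id = s$meta$map_id, class = s$meta$class)
}

#' Run the full preprocessing chain over a dataset
#'
#' Cosmic-ray removal, baseline subtraction, truncation and (optionally)
#' 1003 cm^-1 normalisation, applied per spectrum in that order.
#'
#' @param ds a `raman_dataset`
#' @param cosmic_width spike width threshold in grid points (default 2)
#' @param cfg a [baseline_config()]
#' @param lo,hi truncation range (defaults 690 and 1655 cm^-1)
#' @param normalize reference wavenumber for normalisation, or `NULL` to
#'   skip (classification uses non-normalised intensities)
#' @return preprocessed `raman_dataset`
#' @export
preprocess_dataset <- function(ds, cosmic_width = 2,
                               cfg = baseline_config(), lo = 690, hi = 1655,
                               normalize = NULL) {
  f <- function(s) {
    s <- remove_cosmic_rays(s, max_feature_width = cosmic_width)
    s <- suppressWarnings(subtract_baseline(s, cfg))
    s <- truncate_spectrum(s, lo, hi)
    if (!is.null(normalize)) s <- normalize_at(s, normalize)
    s
  }
  map_spectra(ds, f)
}
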