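# Derived statistics: peak intensities, peak ratios, the cellulose
# crystallinity index, Simpson's-rule region areas, trend fits, RGB channel
# means and instrument closed forms.

#' Spectral region specification
#' @param name region name
#' @param lo,hi bounds in cm^-1, with 690 <= lo < hi <= 1655
#' @return object of class `region_spec`
#' @export
region_spec <- function(name, lo, hi) {
  if (!(lo < hi)) stop("lo must be < hi", call. = FALSE)
  if (lo < 690 || hi > 1655)
    stop("region must lie within [690, 1655] cm^-1", call. = FALSE)
  structure(list(name = name, lo = lo, hi = hi), class = "region_spec")
}

#' The four fingerprint regions
#'
#' 860-970 (cellulose crystallinity), 980-1055 (polyene rocking),
#' 1095-1170 (carotenoid/chlorophyll) and 1205-1335 cm^-1 (glucose/pectin).
#'
#' @return list of [region_spec()]s
#' @export
default_regions <- function() {
  list(region_spec("860-970", 860, 970),
       region_spec("980-1055", 980, 1055),
       region_spec("1095-1170", 1095, 1170),
       region_spec("1205-1335", 1205, 1335))
}

#' The four default peak-intensity ratios
#' @return list of `c(a, b)` pairs for I(a)/I(b)
#' @export
default_ratios <- function() {
  list(c(700, 1147), c(898, 1606), c(1003, 1525), c(1226, 1456))
}

#' Peak intensity at (or near) a wavenumber
#'
#' With `window = 0` the intensity at the nearest grid point is returned;
#' with `window > 0` the maximum intensity within `wavenumber +/- window`.
#'
#' @param s a `raman_spectrum`
#' @param wavenumber target, cm^-1 (must lie within the grid span)
#' @param window half-window, cm^-1 (default 0)
#' @return intensity, a.u.
#' @export
peak_intensity <- function(s, wavenumber, window = 0) {
  w <- s$wavenumber
  if (wavenumber < min(w) || wavenumber > max(w))
    stop(sprintf("wavenumber %g cm^-1 outside grid span [%g, %g]",
                 wavenumber, min(w), max(w)), call. = FALSE)
  if (window <= 0)
    return(s$intensity[nearest_index(w, wavenumber)])
  sel <- w >= wavenumber - window & w <= wavenumber + window
  max(s$intensity[sel])
}

#' Peak intensity ratio I(a) / I(b)
#'
#' @param s a `raman_spectrum`
#' @param a,b peak wavenumbers, cm^-1
#' @param window half-window passed to [peak_intensity()]
#' @return dimensionless ratio
#' @export
peak_ratio <- function(s, a, b, window = 0) {
  ib <- peak_intensity(s, b, window)
  if (ib == 0)
    stop(sprintf("zero denominator intensity at %g cm^-1", b),
         call. = FALSE)
  peak_intensity(s, a, window) / ib
}

#' Raman-derived cellulose crystallinity index
#'
#' X_c = I_1481 / (I_1462 + I_1481), the ratio of the crystalline
#' (1481 cm^-1) to total (amorphous 1462 cm^-1 + crystalline) cellulose
#' CH2 band intensities, read at the nearest grid points.
#'
#' @param s a `raman_spectrum`
#' @return X_c, dimensionless (in \[0, 1\] for non-negative intensities)
#' @export
crystallinity <- function(s) {
  i1462 <- peak_intensity(s, 1462)
  i1481 <- peak_intensity(s, 1481)
  if (i1462 + i1481 == 0)
    stop("zero denominator: I(1462) + I(1481) = 0", call. = FALSE)
  i1481 / (i1462 + i1481)
}

# composite Simpson on a uniform grid; with an even number of points the
# final interval falls back to the trapezoid rule
simpson_integrate <- function(x, y) {
  n <- length(x)
  total <- 0
  n_simpson <- if (n %% 2L == 1L) n else n - 1L
  if (n_simpson >= 3L)
    for (i in seq(1L, n_simpson - 2L, by = 2L)) {
      h <- (x[i + 2L] - x[i]) / 2
      total <- total + h / 3 * (y[i] + 4 * y[i + 1L] + y[i + 2L])
    }
  if (n %% 2L == 0L)
    total <- total + (x[n] - x[n - 1L]) * (y[n] + y[n - 1L]) / 2
  total
}

#' Simpson's-rule area of a spectral region
#'
#' Composite Simpson integral over the grid points inside the region; an
#' odd interval count is handled by the trapezoid rule on the final
#' interval.
#'
#' @param s a `raman_spectrum`
#' @param region a [region_spec()], or `NULL` for the full grid
#' @return area, a.u. x cm^-1
#' @export
simpson_area <- function(s, region = NULL) {
  if (is.null(region)) {
    sel <- rep(TRUE, length(s$wavenumber))
  } else {
    sel <- s$wavenumber >= region$lo & s$wavenumber <= region$hi
  }
  if (sum(sel) < 3L)
    stop("need at least 3 grid points inside the region", call. = FALSE)
  simpson_integrate(s$wavenumber[sel], s$intensity[sel])
}

#' Relative region area
#'
#' Region area divided by the full-range (690-1655 cm^-1, or the full
#' grid) area.
#'
#' @param s a `raman_spectrum`
#' @param region a [region_spec()]
#' @return dimensionless fraction
#' @export
relative_region_area <- function(s, region) {
  full <- simpson_area(s, NULL)
  if (full == 0) stop("zero full-range area", call. = FALSE)
  simpson_area(s, region) / full
}

#' Fit a linear or exponential trend
#'
#' Linear: ordinary least squares. Exponential: nonlinear least squares of
#' `y = A * exp(b * x)` initialised from the log-linear fit (falls back to
#' the log-linear estimate if the NLS step fails). R^2 is computed on the
#' original scale as `1 - SS_res / SS_tot`.
#'
#' @param x covariate (e.g. senescence stage index)
#' @param y response values
#' @param model `"linear"` or `"exponential"` (exponential requires y > 0)
#' @return object of class `trend_fit` with `model`, `parameters`,
#'   `r_squared` and `fitted`
#' @export
fit_trend <- function(x, y, model = c("linear", "exponential")) {
  model <- match.arg(model)
  if (length(x) != length(y) || length(x) < 3L)
    stop("need at least 3 (x, y) points", call. = FALSE)
  if (stats::var(x) == 0) stop("degenerate x: all values equal",
                               call. = FALSE)
  if (model == "linear") {
    fit <- stats::lm(y ~ x)
    params <- c(intercept = unname(stats::coef(fit)[1L]),
                slope = unname(stats::coef(fit)[2L]))
    fitted <- unname(stats::fitted(fit))
  } else {
    if (any(y <= 0))
      stop("exponential fit requires strictly positive y", call. = FALSE)
    lf <- stats::lm(log(y) ~ x)
    start <- list(A = exp(unname(stats::coef(lf)[1L])),
                  b = unname(stats::coef(lf)[2L]))
    fit <- tryCatch(
      suppressWarnings(
        stats::nls(y ~ A * exp(b * x), start = start,
                   control = stats::nls.control(maxiter = 200,
                                                warnOnly = TRUE))),
      error = function(e) NULL)
    if (is.null(fit)) {
      params <- c(A = start$A, b = start$b)
      fitted <- start$A * exp(start$b * x)
    } else {
      cf <- stats::coef(fit)
      params <- c(A = unname(cf["A"]), b = unname(cf["b"]))
      fitted <- params["A"] * exp(params["b"] * x)
      names(fitted) <- NULL
    }
  }
  ss_res <- sum((y - fitted)^2)
  ss_tot <- sum((y - mean(y))^2)
  structure(list(model = model, parameters = params,
                 r_squared = 1 - ss_res / ss_tot, fitted = fitted),
            class = "trend_fit")
}

#' Per-channel means of an RGB image
#'
#' @param image array h x w x 3 with values in \[0, 255\]
#' @param mask optional logical h x w matrix selecting pixels
#' @return named numeric `c(mean_r, mean_g, mean_b)`
#' @export
rgb_channel_means <- function(image, mask = NULL) {
  d <- dim(image)
  if (is.null(d) || length(d) != 3L || d[3] != 3L || d[1] < 1L || d[2] < 1L)
    stop("image must be a non-empty h x w x 3 array", call. = FALSE)
  if (is.null(mask)) mask <- matrix(TRUE, d[1], d[2])
  if (!identical(dim(mask), d[1:2]))
    stop("mask shape must match the image", call. = FALSE)
  if (!any(mask)) stop("empty mask", call. = FALSE)
  out <- vapply(1:3, function(ch) mean(image[, , ch][mask]), numeric(1))
  names(out) <- c("mean_r", "mean_g", "mean_b")
  out
}

#' Diffraction-limited laser spot size
#'
#' `1.22 * lambda / NA`, converted to micrometres and reported to two
#' decimals (e.g. 830 nm at NA 0.4 gives 2.53 um).
#'
#' @param wavelength_nm laser wavelength, nm
#' @param numerical_aperture objective NA, in (0, 1]
#' @return spot diameter, um
#' @export
spot_size <- function(wavelength_nm, numerical_aperture) {
  assert_scalar_number(wavelength_nm, "wavelength_nm", positive = TRUE)
  if (!is.numeric(numerical_aperture) || numerical_aperture <= 0 ||
      numerical_aperture > 1)
    stop("numerical_aperture must be in (0, 1]", call. = FALSE)
  round(1.22 * wavelength_nm / numerical_aperture / 1000, 2)
}

#' Total integration time per scan
#'
#' @param acquisition_s single-acquisition time, s
#' @param accumulations accumulation count
#' @return total time, s
#' @export
total_integration_time <- function(acquisition_s, accumulations) {
  assert_scalar_number(acquisition_s, "acquisition_s", positive = TRUE)
  assert_scalar_number(accumulations, "accumulations", positive = TRUE)
  acquisition_s * accumulations
}

#' Per-spectrum analytics table for a dataset
#'
#' Computes region areas, relative areas, the default peak ratios and the
#' crystallinity index for every spectrum.
#'
#' @param ds a `raman_dataset` (typically baseline-subtracted)
#' @param regions list of [region_spec()]s (default [default_regions()])
#' @param ratios list of `c(a, b)` pairs (default [default_ratios()])
#' @return data.frame keyed by `sample_id` and `class`
#' @export
analytics_table <- function(ds, regions = default_regions(),
                            ratios = default_ratios()) {
  rows <- lapply(seq_len(n_spectra(ds)), function(i) {
    s <- get_spectrum(ds, i)
    rec <- list(sample_id = s$meta$sample_id, class = s$meta$class)
    for (rg in regions) {
      rec[[paste0("area_", rg$name)]] <- simpson_area(s, rg)
      rec[[paste0("relarea_", rg$name)]] <- relative_region_area(s, rg)
    }
    for (rt in ratios)
      rec[[sprintf("ratio_%d_%d", rt[1], rt[2])]] <-
        peak_ratio(s, rt[1], rt[2])
    rec$crystallinity <- crystallinity(s)
    as.data.frame(rec, check.names = FALSE)
  })
  do.call(rbind, rows)
}
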