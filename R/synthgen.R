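# Synthetic leaf-spectrum generator
#
# The generator emulates the statistical structure the downstream analyses
# assume: six senescence classes on a 690-1655 cm^-1 grid, Lorentzian peak
# templates, class-dependent global intensity scaling mimicking residual
# chlorophyll-a fluorescence, a monotone amorphous -> crystalline cellulose
# shift, an additive smooth baseline, Gaussian noise and sparse cosmic-ray
# spikes, with spectra organised into 10-acquisition maps.

peak_template_base <- function() {
  # center (cm^-1), base amplitude (relative a.u.), FWHM (cm^-1).
  # The crowded CH2 scissoring cluster (1451-1494) is given narrower bands
  # so the amorphous/crystalline cellulose doublet at 1462/1481 stays
  # resolved, as it must be for the crystallinity index to be readable.
  data.frame(
    center = c(700, 744, 854, 898, 907, 917, 1003, 1020, 1048, 1128, 1147,
               1157, 1218, 1226, 1272, 1288, 1309, 1328, 1343, 1355, 1451,
               1456, 1462, 1481, 1494, 1525, 1606),
    amplitude = c(0.30, 0.40, 0.25, 0.45, 0.40, 0.35, 1.00, 0.30, 0.30, 0.35,
                  0.45, 0.90, 0.30, 0.35, 0.40, 0.30, 0.25, 0.55, 0.30, 0.25,
                  0.25, 0.25, 0.80, 0.80, 0.25, 0.95, 0.50),
    fwhm = c(rep(12, 20), 8, 8, 8, 8, 8, 12, 12))
}

# per-class multipliers over the base peak table; columns follow
# senescence_classes() order. Tuned to the qualitative between-class trends:
# carotenoid/chlorophyll bands decay toward SOL; 907/1020/1128/1272 grow
# toward SOL; 854 rises to ModSOL then falls; the 1481:1462 amplitude ratio
# rises monotonically so that the crystallinity index increases HOL -> SOL,
# reaching 0.594 for SOL.
class_multiplier_table <- function() {
  m <- rbind(
    `700`  = c(1.00, 1.00, 0.95, 0.90, 0.75, 0.60),
    `744`  = c(1.00, 0.95, 0.90, 0.80, 0.55, 0.35),
    `854`  = c(1.00, 1.00, 1.05, 1.20, 1.50, 0.70),
    `898`  = c(0.50, 0.55, 0.60, 1.00, 1.80, 3.20),
    `907`  = c(0.20, 0.20, 0.25, 0.50, 1.00, 3.50),
    `917`  = c(1.00, 1.00, 1.00, 1.00, 1.00, 1.00),
    `1003` = c(1.00, 1.05, 0.95, 0.85, 0.70, 0.85),
    `1020` = c(0.30, 0.30, 0.35, 0.70, 1.30, 3.00),
    `1048` = c(1.00, 1.00, 1.00, 1.05, 1.10, 1.30),
    `1128` = c(0.40, 0.40, 0.45, 0.80, 1.40, 3.00),
    `1147` = c(1.00, 1.05, 0.95, 0.75, 0.50, 0.35),
    `1157` = c(1.00, 1.05, 0.95, 0.80, 0.60, 0.45),
    `1218` = c(1.00, 1.00, 1.00, 1.00, 0.80, 0.70),
    `1226` = c(1.00, 1.00, 0.95, 0.90, 0.70, 1.10),
    `1272` = c(0.30, 0.30, 0.35, 0.60, 1.60, 4.50),
    `1288` = c(1.00, 1.00, 1.00, 1.10, 1.30, 1.80),
    `1309` = c(1.00, 1.00, 0.95, 0.90, 0.80, 0.90),
    `1328` = c(1.00, 1.00, 0.95, 0.85, 0.70, 0.90),
    `1343` = c(1.00, 1.00, 1.00, 1.00, 1.00, 1.30),
    `1355` = c(1.00, 1.00, 1.00, 1.00, 1.05, 1.30),
    `1451` = c(1.00, 1.00, 1.00, 1.00, 1.10, 1.50),
    `1456` = c(1.00, 1.00, 1.00, 1.00, 1.10, 1.40),
    `1462` = c(1.00, 1.00, 1.00, 1.00, 1.00, 1.00),
    # amplitude-ratio crystallinity 0.170/0.176/0.182/0.190/0.258/0.594
    `1481` = c(0.20482, 0.21359, 0.22249, 0.23457, 0.34771, 1.46305),
    `1494` = c(1.00, 1.00, 0.95, 0.85, 0.60, 0.30),
    `1525` = c(1.00, 1.05, 0.90, 0.75, 0.45, 0.50),
    `1606` = c(1.00, 1.00, 1.00, 0.95, 0.85, 1.00))
  colnames(m) <- senescence_classes()
  m
}

# global intensity scale ~ residual chlorophyll-a fluorescence, expressed
# as the target spectrum maximum (a.u.). HOL / MinSOL-H / ModSOL-H use the
# per-class maxima; MinSOL / ModSOL use the two low-intensity cluster
# statistics; SOL is a two-component mixture (its bimodal intensity mode).
fluorescence_defaults <- function(class_label) {
  switch(class_label,
    "HOL"      = list(mean = 3375.18, sd = 541.57, weight = 1),
    "MinSOL-H" = list(mean = 5317.59, sd = 542.38, weight = 1),
    "ModSOL-H" = list(mean = 4239.02, sd = 718.79, weight = 1),
    "MinSOL"   = list(mean = 3571.92, sd = 551.66, weight = 1),
    "ModSOL"   = list(mean = 1341.41, sd = 518.55, weight = 1),
    "SOL"      = list(mean = c(9942.69, 14493.02), sd = c(2224.98, 2345.05),
                      weight = c(0.52, 0.48)),
    stop("unknown class label: ", class_label, call. = FALSE))
}

#' Construct a senescence-class spectral template
#'
#' @param class_label one of [senescence_classes()]
#' @param peaks data.frame with columns `center` (cm^-1), `amplitude`
#'   (a.u.), `fwhm` (cm^-1) and `multiplier` (dimensionless)
#' @param fluorescence_scale list with `mean`, `sd` and `weight` (a.u.);
#'   more than one component gives a mixture of target spectrum maxima
#' @param baseline_coeffs polynomial coefficients of the smooth background
#'   in the scaled coordinate u = (nu - 690) / 965, relative to the peak sum
#' @param noise_sd additive Gaussian noise SD (a.u.)
#' @param spike_rate expected cosmic-ray spikes per spectrum (Poisson rate)
#' @return object of class `class_template`
#' @export
class_template <- function(class_label, peaks, fluorescence_scale,
                           baseline_coeffs = c(0.12, 0.10, -0.06),
                           noise_sd = 20, spike_rate = 0.3) {
  if (!class_label %in% senescence_classes())
    stop("unknown class label: ", class_label, call. = FALSE)
  need <- c("center", "amplitude", "fwhm", "multiplier")
  if (!all(need %in% names(peaks)))
    stop("peaks must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(peaks$center < 690 | peaks$center > 1655))
    stop("every peak center must lie in [690, 1655] cm^-1", call. = FALSE)
  if (any(peaks$amplitude < 0) || any(peaks$fwhm < 0) ||
      any(peaks$multiplier < 0))
    stop("amplitudes, FWHM and multipliers must be non-negative",
         call. = FALSE)
  if (noise_sd < 0 || spike_rate < 0)
    stop("noise_sd and spike_rate must be non-negative", call. = FALSE)
  structure(list(class_label = class_label,
                 peaks = as.data.frame(peaks),
                 fluorescence_scale = fluorescence_scale,
                 baseline_coeffs = as.numeric(baseline_coeffs),
                 noise_sd = noise_sd, spike_rate = spike_rate),
            class = "class_template")
}

#' Default spectral templates for the six senescence classes
#'
#' One template per class. Peak centers follow the assignment table of
#' common leaf biomolecules (carotenoids, celluloses, chlorophyll-a,
#' lignin, pectins, xylan, alpha-amyrin); class multipliers encode the
#' qualitative between-class trends (see [class_template()]); fluorescence
#' scales reproduce the printed per-class intensity maxima.
#'
#' @return named list of six `class_template` objects
#' @export
default_templates <- function() {
  base <- peak_template_base()
  mult <- class_multiplier_table()
  out <- lapply(senescence_classes(), function(cl) {
    pk <- base
    pk$multiplier <- mult[, cl]
    class_template(cl, pk, fluorescence_defaults(cl))
  })
  names(out) <- senescence_classes()
  out
}

# peak-height-normalised Lorentzian profile
lorentz_profile <- function(nu, center, fwhm) {
  g <- fwhm / 2
  1 / (1 + ((nu - center) / g)^2)
}

#' Closed-form noiseless spectrum of a template
#'
#' Evaluates the deterministic part of the generator: the Lorentzian peak
#' sum times class multipliers plus the relative baseline, rescaled so that
#' its maximum equals `scale` (the fluorescence draw). Used by tests as the
#' synthetic ground truth.
#'
#' @param template a `class_template`
#' @param grid wavenumber grid (cm^-1)
#' @param scale target spectrum maximum (a.u.); default the template's
#'   (first-component) fluorescence mean
#' @param include_baseline include the smooth background (default TRUE)
#' @return numeric vector of intensities on `grid`
#' @export
template_spectrum <- function(template, grid,
                              scale = template$fluorescence_scale$mean[1L],
                              include_baseline = TRUE) {
  pk <- template$peaks
  shape <- rep(0, length(grid))
  for (i in seq_len(nrow(pk)))
    shape <- shape + pk$amplitude[i] * pk$multiplier[i] *
      lorentz_profile(grid, pk$center[i], pk$fwhm[i])
  u <- (grid - 690) / 965
  base <- drop(outer(u, seq_along(template$baseline_coeffs) - 1, `^`) %*%
                 template$baseline_coeffs)
  clean <- if (include_baseline) shape + base else shape
  ref <- max(shape + base)  # normalisation constant includes the baseline
  clean / ref * scale
}

#' Simulation configuration
#'
#' @param n_per_class spectra per senescence class (default 100)
#' @param acquisitions_per_map spectra per map (default 10);
#'   `n_per_class` must be divisible by it
#' @param grid numeric `c(start, stop, step)` in cm^-1
#'   (default `c(690, 1655, 1)`)
#' @param seed integer RNG seed
#' @param class_templates list of `class_template`s
#'   (default [default_templates()])
#' @return object of class `simulation_config`
#' @export
simulation_config <- function(n_per_class = 100, acquisitions_per_map = 10,
                              grid = c(690, 1655, 1), seed = 1,
                              class_templates = default_templates()) {
  if (n_per_class < 1 || acquisitions_per_map < 1)
    stop("counts must be positive", call. = FALSE)
  if (n_per_class %% acquisitions_per_map != 0)
    stop("n_per_class must be divisible by acquisitions_per_map",
         call. = FALSE)
  if (length(grid) != 3 || grid[3] <= 0 || grid[1] >= grid[2])
    stop("grid must be c(start, stop, step) with step > 0 and start < stop",
         call. = FALSE)
  structure(list(n_per_class = n_per_class,
                 acquisitions_per_map = acquisitions_per_map,
                 grid = as.numeric(grid), seed = as.integer(seed),
                 class_templates = class_templates),
            class = "simulation_config")
}

draw_fluorescence <- function(fs) {
  k <- length(fs$mean)
  j <- if (k == 1L) 1L else
    sample.int(k, 1L, prob = fs$weight / sum(fs$weight))
  s <- stats::rnorm(1L, fs$mean[j], fs$sd[j])
  max(s, 0.02 * fs$mean[j])  # physical floor: intensities stay positive
}

#' Simulate a class-labelled spectral dataset
#'
#' Each spectrum is the Lorentzian peak sum times class multipliers times a
#' sampled fluorescence scale, plus the smooth baseline, Gaussian noise and
#' Poisson-count cosmic-ray spikes (single-grid-point deltas of 5-20x the
#' local signal). Deterministic for a fixed seed. Map and sample identifiers
#' are assigned in blocks of `acquisitions_per_map`.
#'
#' @param config a [simulation_config()]
#' @return a `raman_dataset`
#' @export
simulate_dataset <- function(config) {
  if (!inherits(config, "simulation_config"))
    config <- do.call(simulation_config, config)
  g <- config$grid
  grid <- seq(g[1], g[2], by = g[3])
  p <- length(grid)
  with_seed_maybe(config$seed, {
    rows <- list()
    meta <- list()
    for (tmpl in config$class_templates) {
      cl <- tmpl$class_label
      clean_unit <- template_spectrum(tmpl, grid, scale = 1)
      for (i in seq_len(config$n_per_class)) {
        s <- draw_fluorescence(tmpl$fluorescence_scale)
        y <- clean_unit * s
        if (tmpl$noise_sd > 0)
          y <- y + stats::rnorm(p, 0, tmpl$noise_sd)
        n_spk <- if (tmpl$spike_rate > 0)
          stats::rpois(1L, tmpl$spike_rate) else 0L
        if (n_spk > 0L) {
          at <- sample.int(p, n_spk)
          y[at] <- y[at] + stats::runif(n_spk, 5, 20) * abs(y[at])
        }
        rows[[length(rows) + 1L]] <- y
        meta[[length(meta) + 1L]] <- data.frame(
          sample_id = sprintf("%s-%03d", cl, i),
          map_id = sprintf("%s-map%02d", cl,
                           ceiling(i / config$acquisitions_per_map)),
          class = cl, stringsAsFactors = FALSE)
      }
    }
    spectral_dataset(grid, do.call(rbind, rows), do.call(rbind, meta))
  })
}

# senescence stage coordinate used by the absorbance model: the four whole
# leaf classes sit at integer stages 0..3; the visually green subclasses
# sit between HOL and MinSOL
class_stage_index <- function(classes) {
  idx <- c("HOL" = 0, "MinSOL-H" = 1 / 3, "ModSOL-H" = 2 / 3,
           "MinSOL" = 1, "ModSOL" = 2, "SOL" = 3)
  unknown <- setdiff(classes, names(idx))
  if (length(unknown))
    stop("unknown class label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  unname(idx[classes])
}

#' Simulate 600 nm absorbance readings per senescence class
#'
#' Mean absorbance follows a negative exponential in the senescence stage
#' index, A(t) = A0 * exp(-b t), with A0 = 1.67 a.u. at HOL and b chosen so
#' the SOL (stage 3) mean is 0.298 a.u.; replicate noise is Gaussian with
#' SD proportional to the mean (default 2.5 %, matching the printed
#' HOL/SOL dispersions).
#'
#' @param classes class labels (possibly repeated)
#' @param n_replicates readings per listed class (default 3)
#' @param sd_frac noise SD as a fraction of the class mean (0 = exact curve)
#' @param seed RNG seed
#' @return data.frame with columns `class`, `replicate`, `a600`
#' @export
simulate_absorbance <- function(classes = senescence_classes(),
                                n_replicates = 3, sd_frac = 0.025,
                                seed = NULL) {
  t <- class_stage_index(classes)
  b <- log(1.67 / 0.298) / 3
  mu <- 1.67 * exp(-b * t)
  with_seed_maybe(seed, {
    out <- do.call(rbind, lapply(seq_along(classes), function(i) {
      a <- stats::rnorm(n_replicates, mu[i], sd_frac * mu[i])
      data.frame(class = classes[i], replicate = seq_len(n_replicates),
                 a600 = a, stringsAsFactors = FALSE)
    }))
    out
  })
}

rgb_class_means <- function(class_label) {
  switch(class_label,
    "HOL"      = c(62, 125, 48),   # green dominant
    "MinSOL-H" = c(66, 128, 50),
    "ModSOL-H" = c(64, 126, 49),
    "MinSOL"   = c(63, 126, 48),   # visually close to HOL
    "ModSOL"   = c(165, 172, 78),  # all channels raised: yellowing
    "SOL"      = c(175, 105, 78),  # red > green: browning
    stop("unknown class label: ", class_label, call. = FALSE))
}

#' Simulate an RGB image patch for a senescence class
#'
#' Per-pixel channel values are drawn around class-specific means
#' (green-dominant for healthy-looking tissue, all channels raised for
#' yellowing ModSOL, red above green for browned SOL), rounded and clipped
#' to \[0, 255\].
#'
#' @param class_label one of [senescence_classes()]
#' @param size integer `c(height, width)` in pixels (default `c(16, 16)`)
#' @param noise_sd per-channel Gaussian SD (default 12; 0 = uniform patch)
#' @param seed RNG seed
#' @return integer array `height x width x 3` of class `rgb_patch`
#' @export
simulate_rgb_patch <- function(class_label, size = c(16, 16), noise_sd = 12,
                               seed = NULL) {
  mu <- rgb_class_means(class_label)
  size <- as.integer(size)
  if (length(size) != 2L || any(size < 1L))
    stop("size must be at least 1 x 1", call. = FALSE)
  with_seed_maybe(seed, {
    px <- array(0L, dim = c(size[1], size[2], 3))
    for (ch in 1:3) {
      v <- stats::rnorm(size[1] * size[2], mu[ch], noise_sd)
      px[, , ch] <- matrix(as.integer(pmin(pmax(round(v), 0), 255)),
                           size[1], size[2])
    }
    structure(px, class = "rgb_patch", class_label = class_label)
  })
}
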