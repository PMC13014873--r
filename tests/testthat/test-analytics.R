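test_that("peak intensities follow the nearest-grid-point rule", {
  s <- spectrum(1000:1010, c(1, 2, 3, 7, 5, 4, 3, 2, 1, 0.5, 0.2))
  expect_identical(peak_intensity(s, 1003), 7)
  # off-grid lookups resolve to the nearest point
  expect_identical(peak_intensity(s, 1003.4), 7)
  expect_identical(peak_intensity(s, 1003.6), 5)
  # equidistant ties resolve toward the lower wavenumber
  s2 <- spectrum(c(1000, 1002), c(11, 22))
  expect_identical(peak_intensity(s2, 1001), 11)
  # windowed lookup is the brute-force window maximum
  w <- 690:710
  y <- stats::runif(21)
  s3 <- spectrum(w, y)
  for (target in c(695, 700, 705))
    for (win in 1:4)
      expect_equal(peak_intensity(s3, target, window = win),
                   max(y[abs(w - target) <= win]))
  expect_error(peak_intensity(s, 900), "outside grid span")
})

test_that("peak ratios behave and order HOL-like vs SOL-like spectra", {
  s <- spectrum(c(700, 701, 702), c(2, 4, 1))
  expect_equal(peak_ratio(s, 700, 701), 0.5)
  expect_equal(peak_ratio(s, 701, 701), 1.0)
  expect_error(peak_ratio(spectrum(c(1, 2), c(1, 0)), 1, 2),
               "zero denominator.*2")
  grid <- seq(690, 1655, by = 1)
  tmpl <- default_templates()
  hol <- spectrum(grid, template_spectrum(tmpl$HOL, grid,
                                          include_baseline = FALSE))
  sol <- spectrum(grid, template_spectrum(tmpl$SOL, grid,
                                          include_baseline = FALSE))
  # carbohydrate/lignin ratio grows with senescence
  expect_gt(peak_ratio(sol, 898, 1606), peak_ratio(hol, 898, 1606))
})

test_that("crystallinity has the Eq.-style symmetry, limits and scaling", {
  make <- function(i1462, i1481) {
    w <- seq(1450, 1490, by = 1)
    y <- rep(0, length(w))
    y[w == 1462] <- i1462
    y[w == 1481] <- i1481
    spectrum(w, y)
  }
  expect_equal(crystallinity(make(5, 5)), 0.5)
  expect_equal(crystallinity(make(0, 3)), 1.0)
  expect_equal(crystallinity(make(60.9, 89.1)), 0.594)
  expect_error(crystallinity(make(0, 0)), "zero denominator")
  # monotone increasing in I1481 at fixed I1462, bounded in [0, 1]
  vals <- vapply(seq(0, 50, by = 5),
                 function(a) crystallinity(make(20, a)), numeric(1))
  expect_false(is.unsorted(vals))
  expect_true(all(vals >= 0 & vals <= 1))
  # invariant under global intensity scaling
  expect_equal(crystallinity(make(12, 30)), crystallinity(make(120, 300)))
})

test_that("Simpson areas are exact on cubics and accurate on sin", {
  x <- seq(0, 2, length.out = 5)
  expect_equal(simpson_area(spectrum(x, x^2)), 8 / 3)
  expect_equal(simpson_area(spectrum(x, x^3)), 4)
  # constant c over width w integrates to c * w
  expect_equal(simpson_area(spectrum(seq(0, 10, 1), rep(3, 11))), 30)
  xs <- seq(0, pi, length.out = 101)
  expect_lt(abs(simpson_area(spectrum(xs, sin(xs))) - 2), 1e-6)
  # even point count: trapezoid on the final interval
  x4 <- c(0, 1, 2, 3)
  y4 <- c(0, 1, 4, 9)
  expect_equal(simpson_area(spectrum(x4, y4)), 8 / 3 + (4 + 9) / 2)
  expect_error(simpson_area(spectrum(c(0, 1), c(1, 1))), "at least 3")
})

test_that("Simpson agrees with the trapezoid rule on smooth templates", {
  grid <- seq(690, 1655, by = 1)
  trapezoid <- function(x, y)
    sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  for (cl in c("HOL", "SOL")) {
    y <- template_spectrum(default_templates()[[cl]], grid)
    a_simp <- simpson_area(spectrum(grid, y))
    a_trap <- trapezoid(grid, y)
    expect_lt(abs(a_simp - a_trap) / a_trap, 0.02)
  }
})

test_that("relative region areas are normalised fractions", {
  w <- seq(690, 1655, by = 1)
  s <- spectrum(w, 2 + 0.001 * (w - 690))   # linear: additivity is exact
  full <- region_spec("full", 690, 1655)
  expect_equal(relative_region_area(s, full), 1.0)
  left <- region_spec("left", 690, 1100)
  right <- region_spec("right", 1100, 1655)
  expect_lt(abs(relative_region_area(s, left) +
                  relative_region_area(s, right) - 1), 1e-9)
  # the cellulose region fraction is larger for SOL-like spectra
  tmpl <- default_templates()
  hol <- spectrum(w, template_spectrum(tmpl$HOL, w))
  sol <- spectrum(w, template_spectrum(tmpl$SOL, w))
  cellulose <- region_spec("860-970", 860, 970)
  expect_gt(relative_region_area(sol, cellulose),
            relative_region_area(hol, cellulose))
  expect_error(region_spec("bad", 1000, 900), "lo must be")
  expect_error(region_spec("bad", 600, 900), "within")
})

test_that("ratios, crystallinity and relative areas are scale invariant", {
  ds <- simulate_dataset(simulation_config(n_per_class = 2,
                                           acquisitions_per_map = 2,
                                           seed = 9))
  s <- get_spectrum(ds, 1)
  s10 <- spectrum(s$wavenumber, 10 * s$intensity)
  expect_equal(peak_ratio(s10, 898, 1606), peak_ratio(s, 898, 1606))
  expect_equal(crystallinity(s10), crystallinity(s))
  rg <- region_spec("r", 860, 970)
  expect_equal(relative_region_area(s10, rg), relative_region_area(s, rg))
})

test_that("trend fits recover linear and exponential truth", {
  x <- 0:9
  lin <- fit_trend(x, 3 + 2 * x, "linear")
  expect_equal(unname(lin$parameters["slope"]), 2)
  expect_equal(lin$r_squared, 1)
  ex <- fit_trend(x, 2 * exp(0.5 * x), "exponential")
  expect_equal(unname(ex$parameters["A"]), 2, tolerance = 1e-6)
  expect_equal(unname(ex$parameters["b"]), 0.5, tolerance = 1e-6)
  expect_equal(ex$r_squared, 1, tolerance = 1e-9)
  expect_error(fit_trend(rep(1, 5), 1:5, "linear"), "degenerate")
  expect_error(fit_trend(1:5, c(-1, 2, 3, 4, 5), "exponential"),
               "positive")
  expect_error(fit_trend(1:2, 1:2), "at least 3")
})

test_that("noisy exponential rate is recovered within 10 %", {
  # simulation study: n = 100, 5 % multiplicative noise, many seeds
  x <- seq(0, 3, length.out = 100)
  errs <- vapply(1:100, function(seed) {
    withr::with_seed(seed, {
      y <- 2 * exp(0.8 * x) * (1 + stats::rnorm(100, 0, 0.05))
      fit <- fit_trend(x, y, "exponential")
      abs(unname(fit$parameters["b"]) - 0.8) / 0.8
    })
  }, numeric(1))
  expect_lt(stats::median(errs), 0.05)
  expect_gt(mean(errs < 0.10), 0.95)
})

test_that("rgb channel means average pixels with optional masking", {
  img <- array(0, dim = c(2, 2, 3))
  img[, , 1] <- 10; img[, , 2] <- 200; img[, , 3] <- 30
  expect_equal(unname(rgb_channel_means(img)), c(10, 200, 30))
  half <- array(0, dim = c(2, 1, 3))
  half[1, , ] <- 0; half[2, , ] <- 255
  expect_equal(unname(rgb_channel_means(half)), rep(127.5, 3))
  mask <- matrix(c(TRUE, FALSE), 2, 1)
  expect_equal(unname(rgb_channel_means(half, mask)), c(0, 0, 0))
  expect_error(rgb_channel_means(half, matrix(FALSE, 2, 1)), "empty mask")
  expect_error(rgb_channel_means(array(0, c(2, 2, 2))), "h x w x 3")
})

test_that("instrument closed forms are dimensionally right", {
  expect_equal(spot_size(830, 0.4), 2.53)
  expect_equal(spot_size(1000, 0.61), 2.00)
  expect_equal(total_integration_time(5, 10), 50)
  expect_error(spot_size(830, 1.5), "numerical_aperture")
  expect_error(spot_size(-1, 0.4), "positive")
})

test_that("analytics_table is tidy and keyed by sample and class", {
  ds <- simulate_dataset(simulation_config(n_per_class = 4,
                                           acquisitions_per_map = 4,
                                           seed = 4))
  tab <- analytics_table(ds)
  expect_equal(nrow(tab), n_spectra(ds))
  expect_true(all(c("sample_id", "class", "crystallinity",
                    "relarea_860-970", "ratio_898_1606") %in% names(tab)))
  rel <- tab[, grep("relarea", names(tab))]
  expect_true(all(rel >= 0 & rel <= 1))
})
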