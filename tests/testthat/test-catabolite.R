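make_linelist <- function(wn, act, name = "test-cat", stage = "early") {
  catabolite_linelist(name, stage,
                      data.frame(mode = seq_along(wn),
                                 wavenumber_cm1 = wn,
                                 activity_A4_AMU = act))
}

test_that("line-list JSON round trips and rejects bad input", {
  ll <- make_linelist(c(1700, 900, 1200), c(50, 120, 80))
  expect_equal(ll$lines$wavenumber_cm1, c(900, 1200, 1700)) # sorted
  f <- withr::local_tempfile(fileext = ".json")
  write_linelist(ll, f)
  back <- parse_linelist(f)
  expect_equal(back$name, ll$name)
  expect_equal(back$stage, ll$stage)
  expect_equal(back$lines, ll$lines)
  bad <- withr::local_tempfile(fileext = ".json")
  writeLines("{not json", bad)
  expect_error(parse_linelist(bad), "malformed JSON")
  nofield <- withr::local_tempfile(fileext = ".json")
  writeLines('{"name": "x", "lines": []}', nofield)
  expect_error(parse_linelist(nofield), "missing field 'stage'")
  expect_error(make_linelist(c(-5, 100), c(1, 2)), "positive")
  expect_error(make_linelist(c(800, 900), c(-1, 2)), "non-negative")
  expect_error(catabolite_linelist("x", "someday",
                                   data.frame(mode = 1,
                                              wavenumber_cm1 = 800,
                                              activity_A4_AMU = 1)),
               "stage must be one of")
})

test_that("the packaged synthetic example line list parses", {
  f <- system.file("extdata", "linelist_chlorophyll_b_synthetic.json",
                   package = "ramansen")
  ll <- parse_linelist(f)
  expect_s3_class(ll, "catabolite_linelist")
  expect_equal(ll$stage, "early")
  filtered <- filter_top_peaks(ll)
  # the 1711.8 line is retained at parse but truncated away by filtering
  expect_true(1711.8 %in% ll$lines$wavenumber_cm1)
  expect_false(1711.8 %in% filtered$wavenumber_cm1)
})

test_that("filter_top_peaks applies range, top-k then activity floor", {
  ll <- make_linelist(seq(700, 1300, by = 100),
                      c(100, 90, 80, 70, 60, 50, 40))
  out <- filter_top_peaks(ll)
  expect_equal(out$activity_A4_AMU, c(100, 90, 80, 70, 60))
  # k larger than available lines keeps them all
  ll3 <- make_linelist(c(700, 800, 900), c(35, 45, 55))
  expect_equal(nrow(filter_top_peaks(ll3)), 3L)
  # the floor drops rows already selected into the top five
  llw <- make_linelist(700 + (0:5) * 50, c(100, 29, 29, 29, 29, 29))
  expect_equal(nrow(filter_top_peaks(llw)), 1L)
  expect_equal(filter_top_peaks(llw)$activity_A4_AMU, 100)
  # empty results are allowed
  expect_equal(nrow(filter_top_peaks(make_linelist(2000, 500))), 0L)
})

test_that("filtering matches a brute-force oracle on random lists", {
  withr::with_seed(7, {
    for (rep in 1:50) {
      n <- sample(1:12, 1)
      wn <- stats::runif(n, 600, 1800)
      act <- stats::runif(n, 0, 120)
      ll <- make_linelist(wn, act)
      got <- filter_top_peaks(ll)
      # oracle: in-range -> sort by activity -> top 5 -> >= 30
      keep <- wn >= 690 & wn <= 1655
      oracle <- sort(act[keep], decreasing = TRUE)
      oracle <- oracle[seq_len(min(5, length(oracle)))]
      oracle <- oracle[oracle >= 30]
      expect_equal(got$activity_A4_AMU, oracle)
      expect_lte(nrow(got), 5L)
      if (nrow(got)) expect_gte(min(got$activity_A4_AMU), 30)
    }
  })
})

test_that("the packaged filtered-peak table reproduces the stage tallies", {
  t3 <- load_filtered_peak_table()
  counts <- stage_counts(t3)
  expect_equal(unname(counts["early"]), 29L)
  expect_equal(unname(counts["late"]), 9L)
  expect_true(all(t3$wavenumber_cm1 >= 690 & t3$wavenumber_cm1 <= 1655))
  # duplicate wavenumbers across catabolites are allowed (e.g. 1475)
  expect_gte(sum(t3$wavenumber_cm1 == 1475), 2L)
  empty <- t3[0, ]
  expect_equal(unname(stage_counts(empty)),
               c(0L, 0L, 0L, 0L, 0L))
  missing <- t3
  missing$stage[3] <- NA
  expect_error(stage_counts(missing), "stage annotation")
})

test_that("rendered spectra conserve activity and shift with scaling", {
  ll <- make_linelist(1100, 250)
  s <- render_spectrum(ll)
  expect_lt(abs(simpson_area(s) - 250) / 250, 0.01)
  # two equal lines give two equal maxima
  ll2 <- make_linelist(c(1000, 1100), c(80, 80))
  s2 <- render_spectrum(ll2)
  expect_equal(peak_intensity(s2, 1000), peak_intensity(s2, 1100),
               tolerance = 1e-6)
  # frequency scaling moves each apex to scale_factor x centre
  s3 <- render_spectrum(make_linelist(c(1000, 1500), c(90, 90)),
                        scale_factor = 0.96)
  apex <- s3$wavenumber[order(s3$intensity, decreasing = TRUE)[1:4]]
  expect_true(any(abs(apex - 960) <= 1))
  expect_true(any(abs(apex - 1440) <= 1))
  expect_error(render_spectrum(ll, fwhm = 0), "FWHM")
  # conservation over random in-range multi-line lists
  withr::with_seed(19, {
    for (rep in 1:10) {
      n <- sample(2:6, 1)
      ll_r <- make_linelist(stats::runif(n, 900, 1400),
                            stats::runif(n, 30, 300))
      total <- sum(ll_r$lines$activity_A4_AMU)
      expect_lt(abs(simpson_area(render_spectrum(ll_r)) - total) / total,
                0.01)
    }
  })
  # gaussian broadening conserves activity too
  expect_lt(abs(simpson_area(render_spectrum(ll, shape = "gaussian")) -
                  250) / 250, 0.01)
})

test_that("band grouping respects the collision tolerance", {
  t_a <- data.frame(wavenumber_cm1 = c(1490, 1510), catabolite = "A",
                    stage = "late", spatially_unique = c(TRUE, TRUE))
  t_b <- data.frame(wavenumber_cm1 = c(1495, 1510), catabolite = "B",
                    stage = "mid", spatially_unique = c(TRUE, FALSE))
  bands <- unique_bands(list(t_a, t_b), collision_tolerance = 2)
  # 1490 and 1495 stay distinct at tolerance 2; the 1510s merge
  expect_equal(bands$wavenumber_cm1, c(1490, 1495, 1510))
  expect_equal(bands$contributors[3], "A;B")
  expect_equal(bands$n_lines[3], 2L)
  merged <- unique_bands(list(t_a, t_b), collision_tolerance = 10)
  expect_equal(nrow(merged), 2L)   # {1490, 1495} merge, {1510, 1510} merge
  expect_equal(merged$wavenumber_cm1[1], 1492.5)
  expect_error(unique_bands(list()), "at least one")
  # grouping oracle on sorted random draws: bands break exactly at gaps
  # wider than the tolerance
  withr::with_seed(23, {
    wn <- sort(stats::runif(30, 700, 1600))
    tab <- data.frame(wavenumber_cm1 = wn, catabolite = "X",
                      stage = "early", spatially_unique = FALSE)
    got <- unique_bands(list(tab), collision_tolerance = 5)
    expect_equal(nrow(got), 1L + sum(diff(wn) > 5))
  })
})

test_that("the packaged table isolates the reported unique bands", {
  t3 <- load_filtered_peak_table()
  bands <- unique_bands(list(t3))
  uni <- bands[bands$unique, ]
  # the spatially unique vibrations cluster near 1490, 1495, 1510, 1535
  expect_equal(nrow(uni), 4L)
  expect_true(all(abs(uni$wavenumber_cm1 -
                        c(1490, 1495, 1510, 1535)) <= 1))
  # shared-band contributors: both late-stage partners sit at 1510
  at1510 <- uni[round(uni$wavenumber_cm1) == 1510, ]
  expect_match(at1510$contributors, "bc-NChlC")
  expect_match(at1510$contributors, "DChlC-YTPP-2")
})

test_that("band-class matching honours the tolerance semantics", {
  bands <- data.frame(wavenumber_cm1 = c(1490, 1495, 1510, 1535),
                      contributors = "x", stages = "late")
  classes <- list(
    HOL = c(1490.5, 1494, 1509),
    SOL = c(1491, 1496))
  rep_ <- match_to_classes(bands, classes, tolerance = 3)
  expect_true(all(rep_$present_HOL[1:3]))
  expect_false(rep_$present_HOL[4])
  expect_equal(rep_$present_SOL, c(TRUE, TRUE, FALSE, FALSE))
  # tolerance 0 means exact matching only
  exact <- match_to_classes(bands, list(A = c(1490, 1510.1)),
                            tolerance = 0)
  expect_equal(exact$present_A, c(TRUE, FALSE, FALSE, FALSE))
  # a band absent from a window is absent from the report
  none <- match_to_classes(data.frame(wavenumber_cm1 = 1510),
                           list(B = c(1500, 1520)), tolerance = 3)
  expect_false(none$present_B)
  # empty class tables force FALSE and are messaged
  expect_message(
    empty <- match_to_classes(bands, list(C = numeric(0))),
    "no peaks")
  expect_true(all(!empty$present_C))
  # tables built with 1490/1495 everywhere flag both bands everywhere
  everywhere <- lapply(senescence_classes(), function(cl)
    c(1490, 1495, 800))
  names(everywhere) <- senescence_classes()
  all_present <- match_to_classes(bands[1:2, ], everywhere)
  flags <- as.matrix(all_present[, grep("present_", names(all_present))])
  expect_true(all(flags))
})
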