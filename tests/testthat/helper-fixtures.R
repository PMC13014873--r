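# shared fixtures, built in code; the expensive default dataset is
# generated once per test run and cached for reuse across files

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]]))
    assign(key, force(expr), envir = .fixture_cache)
  .fixture_cache[[key]]
}

# the generator's stated world: default templates, 100 spectra per class
default_raw_dataset <- function() {
  cached("raw100",
         simulate_dataset(simulation_config(n_per_class = 100, seed = 1)))
}

default_prep_dataset <- function() {
  cached("prep100", preprocess_dataset(default_raw_dataset()))
}

# a small noiseless spectrum with a handful of well-separated Lorentzians
toy_peaks <- function() {
  data.frame(center = c(800, 1003, 1300, 1525),
             height = c(40, 100, 60, 80),
             fwhm = c(12, 12, 12, 12))
}

toy_clean_spectrum <- function(grid = seq(690, 1655, by = 1),
                               baseline = function(w) 0 * w) {
  pk <- toy_peaks()
  y <- baseline(grid)
  for (i in seq_len(nrow(pk))) {
    g <- pk$fwhm[i] / 2
    y <- y + pk$height[i] / (1 + ((grid - pk$center[i]) / g)^2)
  }
  spectrum(grid, y)
}

# two-class, well-separated gaussian feature clouds for classifier tests
separable_features <- function(n_per_class = 25, p = 8, gap = 8,
                               classes = c("A", "B"), seed = 99) {
  withr::with_seed(seed, {
    x <- NULL
    lab <- character(0)
    for (k in seq_along(classes)) {
      mu <- rep(0, p)
      mu[k] <- gap
      x <- rbind(x, matrix(stats::rnorm(n_per_class * p, 0, 1),
                           n_per_class, p, byrow = TRUE) +
                   matrix(mu, n_per_class, p, byrow = TRUE))
      lab <- c(lab, rep(classes[k], n_per_class))
    }
    colnames(x) <- paste0("f", seq_len(p))
    list(x = x, labels = lab)
  })
}

# adjusted Rand index, written directly from the pair-counting definition
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(v) sum(choose(v, 2))
  n <- sum(tab)
  sum_ij <- comb2(as.vector(tab))
  sum_a <- comb2(rowSums(tab))
  sum_b <- comb2(colSums(tab))
  expected <- sum_a * sum_b / choose(n, 2)
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}
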