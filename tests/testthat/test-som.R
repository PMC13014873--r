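test_that("training is seed-deterministic and covers separated classes", {
  sep <- separable_features(n_per_class = 20, p = 6, gap = 10)
  m1 <- train_som(sep$x, sep$labels, grid = c(4, 4), rlen = 10, seed = 5)
  m2 <- train_som(sep$x, sep$labels, grid = c(4, 4), rlen = 10, seed = 5)
  expect_identical(m1$weights, m2$weights)
  expect_identical(m1$neuron_labels, m2$neuron_labels)
  m3 <- train_som(sep$x, sep$labels, grid = c(4, 4), rlen = 10, seed = 6)
  expect_false(identical(m1$weights, m3$weights))
  # each well-separated class owns at least one neuron
  expect_true(all(c("A", "B") %in% m1$neuron_labels))
})

test_that("a dataset of one duplicated sample labels every neuron", {
  x <- matrix(rep(c(1, 2, 3), 10), 10, 3, byrow = TRUE)
  m <- train_som(x, rep("only", 10), grid = c(3, 3), rlen = 5, seed = 1)
  expect_true(all(m$neuron_labels == "only"))
  expect_error(train_som(x, c(rep("a", 9), NA), grid = c(2, 2)),
               "at least one sample")
})

test_that("evaluation reproduces an overfit model and routes unlabelled", {
  sep <- separable_features(n_per_class = 15, p = 5, gap = 12)
  m <- train_som(sep$x, sep$labels, grid = c(4, 4), rlen = 20, seed = 2)
  ev <- evaluate_som(m, sep$x, sep$labels)
  expect_equal(ev$accuracy, 100)
  expect_equal(sum(ev$confusion), length(sep$labels))
  expect_equal(unname(rowSums(ev$confusion)),
               unname(as.vector(table(sep$labels))))
  # all-one-class test set: that class 100 %, others NA
  only_a <- sep$labels == "A"
  ev_a <- evaluate_som(m, sep$x[only_a, ], sep$labels[only_a])
  expect_equal(unname(ev_a$per_class["A"]), 100)
  expect_true(is.na(ev_a$per_class["B"]))
  # forcing a neuron unlabelled reroutes its samples to labelled ones
  m2 <- m
  m2$neuron_labels[] <- "unassigned"
  m2$neuron_labels[c(1, 16)] <- m$neuron_labels[c(1, 16)]
  ev2 <- evaluate_som(m2, sep$x, sep$labels)
  expect_gt(ev2$n_rerouted, 0)
  expect_equal(sum(ev2$confusion), length(sep$labels))
  expect_error(evaluate_som(m, sep$x[, 1:3], sep$labels),
               "feature length")
})

test_that("accuracy equals an independent count of correct assignments", {
  sep <- separable_features(n_per_class = 12, p = 4, gap = 3, seed = 13)
  m <- train_som(sep$x, sep$labels, grid = c(3, 3), rlen = 10, seed = 3)
  ev <- evaluate_som(m, sep$x, sep$labels)
  # oracle: per-sample nearest-neuron label computed with plain R
  pred <- apply(sep$x, 1, function(v) {
    d <- rowSums(sweep(m$weights, 2, v)^2)
    ord <- order(d)
    lab <- m$neuron_labels[ord]
    lab[lab != "unassigned"][1]
  })
  expect_equal(ev$accuracy, 100 * mean(pred == sep$labels))
})

test_that("six separated classes evaluate above 95 % on an 80/20 split", {
  sep <- separable_features(n_per_class = 25, p = 10, gap = 9,
                            classes = letters[1:6], seed = 21)
  cv <- split_and_cv(sep$x, sep$labels, folds = 0, repeats = 2,
                     seed = 11, grid = c(6, 6), rlen = 15)
  expect_gte(cv$testing["mean"], 95)
  # split arithmetic: 25 per class at 80/20 leaves 5 per class to test,
  # pooled over 2 repeats
  expect_equal(unname(rowSums(cv$confusion)), rep(10L, 6))
})

test_that("cross-validated runs report mean +/- SD and overall accuracy", {
  sep <- separable_features(n_per_class = 20, p = 6, gap = 10,
                            classes = c("A", "B", "C"), seed = 31)
  cv <- split_and_cv(sep$x, sep$labels, folds = 4, repeats = 2, seed = 8,
                     grid = c(4, 4), rlen = 8)
  expect_equal(cv$overall,
               (cv$training["mean"] + cv$testing["mean"]) / 2,
               ignore_attr = TRUE)
  expect_true(all(is.finite(c(cv$training, cv$testing))))
  # degenerate single-class data scores 100 everywhere
  one <- matrix(stats::rnorm(40), 20, 2)
  cv1 <- split_and_cv(one, rep("z", 20), folds = 0, repeats = 2,
                      seed = 1, grid = c(2, 2), rlen = 5)
  expect_equal(unname(cv1$testing["mean"]), 100)
  expect_error(split_and_cv(sep$x, sep$labels, folds = 50, seed = 1),
               "at least")
})

test_that("overall accuracy is the unweighted train/test mean", {
  expect_equal(overall_model_accuracy(95.51, 88.50), 92.005)
})

test_that("somdi recovers a planted class-specific band", {
  # class A uniquely carries a band at feature '907'; all classes share a
  # common band elsewhere
  wn <- c(898, 907, 1003, 1157, 1328, 1525)
  withr::with_seed(17, {
    n <- 30
    make_class <- function(cl) {
      x <- matrix(stats::rnorm(n * length(wn), 0, 0.05), n, length(wn))
      x[, wn == 1003] <- x[, wn == 1003] + 1
      if (cl == "A") x[, wn == 907] <- x[, wn == 907] + 1.2
      if (cl == "B") x[, wn == 1525] <- x[, wn == 1525] + 1.2
      x
    }
    x <- rbind(make_class("A"), make_class("B"), make_class("C"))
    labels <- rep(c("A", "B", "C"), each = n)
  })
  m <- train_som(x, labels, grid = c(4, 4), rlen = 25, seed = 9)
  sd_ <- somdi(m, feature_names = wn)
  expect_equal(sd_$feature_names[sd_$top_features$A[1]], 907)
  expect_equal(sd_$feature_names[sd_$top_features$B[1]], 1525)
  expect_true(all(unlist(sd_$profiles) >= 0))
  expect_true(all(lengths(sd_$profiles) == length(wn)))
})

test_that("somdi vanishes for indistinguishable or single classes", {
  withr::with_seed(5, {
    x <- matrix(stats::rnorm(40 * 4, 0, 0.01), 40, 4) +
      matrix(rep(c(1, 2, 3, 4), 40), 40, 4, byrow = TRUE)
  })
  two_same <- train_som(x, rep(c("p", "q"), 20), grid = c(3, 3),
                        rlen = 10, seed = 2)
  prof <- somdi(two_same)
  expect_lt(max(abs(unlist(prof$profiles))), 0.02)
  single <- train_som(x, rep("solo", 40), grid = c(3, 3), rlen = 10,
                      seed = 2)
  expect_equal(max(abs(unlist(somdi(single)$profiles))), 0)
})

test_that("somdi is invariant to global intensity scaling", {
  sep <- separable_features(n_per_class = 15, p = 6, gap = 6, seed = 23)
  m1 <- train_som(sep$x, sep$labels, grid = c(3, 3), rlen = 10, seed = 4)
  m2 <- train_som(sep$x * 1000, sep$labels, grid = c(3, 3), rlen = 10,
                  seed = 4)
  p1 <- somdi(m1)$profiles
  p2 <- somdi(m2)$profiles
  expect_equal(p1, p2, tolerance = 1e-10)
})

test_that("subset refits drop classes and their planted features", {
  # 20 features; the three non-SOL classes differ along five signal
  # bands so their SOMDI top-5 is saturated by real discriminators,
  # while the 907 band is carried by SOL alone
  wn <- peaks_of_interest()
  signal <- c(744, 1003, 1157, 1328, 1525)
  withr::with_seed(29, {
    n <- 25
    class_profiles <- list(
      HOL = c(1.6, 2.0, 1.8, 1.2, 2.2),
      MinSOL = c(1.0, 1.4, 1.0, 0.8, 1.2),
      ModSOL = c(0.4, 0.9, 0.5, 0.5, 0.4),
      SOL = c(0.2, 0.5, 0.3, 0.4, 0.3))
    x <- NULL
    labels <- character(0)
    for (cl in names(class_profiles)) {
      xi <- matrix(stats::rnorm(n * length(wn), 0, 0.05), n, length(wn))
      xi[, match(signal, wn)] <- xi[, match(signal, wn)] +
        matrix(class_profiles[[cl]], n, 5, byrow = TRUE)
      if (cl == "SOL") xi[, wn == 917] <- xi[, wn == 917] + 2
      x <- rbind(x, xi)
      labels <- c(labels, rep(cl, n))
    }
  })
  refit <- subset_refit(x, labels, exclude = "SOL", feature_names = wn,
                        grid = c(4, 4), rlen = 20, seed = 6)
  expect_equal(sort(refit$model$classes), c("HOL", "MinSOL", "ModSOL"))
  # the SOL-only planted band leaves the subset SOMDI top-5 entirely
  top_wn <- unlist(lapply(refit$somdi$top_features, function(i) wn[i]))
  expect_false(917 %in% top_wn)
  # but it tops SOL's profile in the full-model SOMDI
  full_model <- train_som(x, labels, grid = c(4, 4), rlen = 20, seed = 6)
  full_somdi <- somdi(full_model, feature_names = wn)
  expect_equal(wn[full_somdi$top_features$SOL[1]], 917)
  # excluding nothing reproduces train_som under the same seed
  full <- subset_refit(x, labels, exclude = character(0),
                       grid = c(4, 4), rlen = 10, seed = 3)
  direct <- train_som(x, labels, grid = c(4, 4), rlen = 10, seed = 3)
  expect_identical(full$model$weights, direct$weights)
  expect_error(subset_refit(x, labels,
                            exclude = c("HOL", "MinSOL", "ModSOL")),
               "fewer than 2")
})
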