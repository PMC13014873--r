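# Self-organising-map classification with a discriminant-index (SOMDI)
# readout. Training is classic online Kohonen learning (winner-take-all,
# Gaussian neighbourhood, linearly decaying learning rate and radius) on a
# hexagonal neuron grid; neurons are labelled by the majority class of the
# training samples they win.

hex_coords <- function(rows, cols) {
  coords <- matrix(0, rows * cols, 2)
  k <- 1L
  for (i in seq_len(rows)) for (j in seq_len(cols)) {
    coords[k, ] <- c(j + 0.5 * ((i - 1L) %% 2L), (i - 1L) * sqrt(3) / 2)
    k <- k + 1L
  }
  coords
}

as_feature_matrix <- function(x) {
  if (inherits(x, "raman_dataset")) x$intensities else as.matrix(x)
}

#' Train a self-organising map
#'
#' @param x numeric matrix (samples x features) or a `raman_dataset`
#'   (classification uses baseline-subtracted, non-normalised intensities)
#' @param labels class label per sample (taken from the dataset metadata
#'   when `x` is a `raman_dataset` and `labels` is NULL)
#' @param grid integer `c(rows, cols)` of the hexagonal neuron grid
#' @param rlen presentations of the full sample set (training epochs)
#' @param alpha learning rate `c(initial, final)`, linear decay
#' @param radius neighbourhood radius `c(initial, final)`; default from
#'   half the grid diagonal down to 1
#' @param seed RNG seed (weight initialisation + presentation order)
#' @return object of class `som_model`: neuron `weights`, hexagonal
#'   `coords`, per-neuron majority-class `neuron_labels` (possibly
#'   `"unassigned"`), class levels and hyperparameters
#' @export
train_som <- function(x, labels = NULL, grid = c(8, 8), rlen = 20,
                      alpha = c(0.5, 0.01), radius = NULL, seed = NULL) {
  if (inherits(x, "raman_dataset") && is.null(labels))
    labels <- x$meta$class
  x <- as_feature_matrix(x)
  if (is.null(labels)) stop("labels are required", call. = FALSE)
  labels <- as.character(labels)
  if (length(labels) != nrow(x))
    stop("labels must match the number of samples", call. = FALSE)
  if (any(table(labels) < 1L) || anyNA(labels))
    stop("every class needs at least one sample", call. = FALSE)
  if (!all(is.finite(x))) stop("features must be finite", call. = FALSE)
  rows <- grid[1]; cols <- grid[2]
  n_neurons <- rows * cols
  coords <- hex_coords(rows, cols)
  if (is.null(radius))
    radius <- c(sqrt((rows * sqrt(3) / 2)^2 + cols^2) / 2, 1)
  with_seed_maybe(seed, {
    init_rows <- sample.int(nrow(x), n_neurons, replace = TRUE)
    w0 <- x[init_rows, , drop = FALSE]
    order <- as.integer(replicate(rlen, sample.int(nrow(x))))
    w <- cpp_som_train(x, w0, order, coords, alpha[1], alpha[2],
                       radius[1], radius[2])
    bmu <- cpp_som_bmu(x, w, seq_len(n_neurons))
    classes <- sort(unique(labels))
    neuron_labels <- rep("unassigned", n_neurons)
    for (k in seq_len(n_neurons)) {
      won <- labels[bmu == k]
      if (length(won)) {
        tab <- table(factor(won, levels = classes))
        neuron_labels[k] <- names(tab)[which.max(tab)]
      }
    }
    # neurons that won no sample inherit the label of the nearest
    # labelled neuron in weight space, so the whole map is class-covered
    unmapped <- which(neuron_labels == "unassigned")
    mapped <- which(neuron_labels != "unassigned")
    if (length(unmapped) && length(mapped)) {
      nearest <- cpp_som_bmu(w[unmapped, , drop = FALSE], w, mapped)
      neuron_labels[unmapped] <- neuron_labels[mapped[nearest]]
    }
    structure(list(weights = w, coords = coords, grid = c(rows, cols),
                   neuron_labels = neuron_labels, classes = classes,
                   hyper = list(rlen = rlen, alpha = alpha,
                                radius = radius, seed = seed)),
              class = "som_model")
  })
}

#' @export
print.som_model <- function(x, ...) {
  cat(sprintf("<som_model> %d x %d hexagonal grid, %d features\n",
              x$grid[1], x$grid[2], ncol(x$weights)))
  print(table(factor(x$neuron_labels,
                     levels = c(x$classes, "unassigned"))))
  invisible(x)
}

#' Evaluate a SOM on labelled data
#'
#' Each sample is assigned the label of its best-matching (minimum
#' Euclidean distance) neuron. Samples whose winner is unlabelled are
#' routed to the nearest labelled neuron and counted in `n_rerouted`.
#'
#' @param model a `som_model`
#' @param x test features (matrix or `raman_dataset`)
#' @param labels true labels
#' @return object of class `eval_report`: `confusion` (rows = truth),
#'   `accuracy` (%), `per_class` (%), `n_rerouted`
#' @export
evaluate_som <- function(model, x, labels = NULL) {
  if (inherits(x, "raman_dataset") && is.null(labels))
    labels <- x$meta$class
  x <- as_feature_matrix(x)
  labels <- as.character(labels)
  if (ncol(x) != ncol(model$weights))
    stop("feature length does not match the model", call. = FALSE)
  labelled <- which(model$neuron_labels != "unassigned")
  if (!length(labelled)) stop("model has no labelled neurons",
                              call. = FALSE)
  all_bmu <- cpp_som_bmu(x, model$weights, seq_along(model$neuron_labels))
  rerouted <- model$neuron_labels[all_bmu] == "unassigned"
  pred <- model$neuron_labels[all_bmu]
  if (any(rerouted)) {
    sub <- cpp_som_bmu(x[rerouted, , drop = FALSE], model$weights,
                       labelled)
    pred[rerouted] <- model$neuron_labels[labelled[sub]]
  }
  lev <- sort(unique(c(model$classes, labels)))
  confusion <- table(truth = factor(labels, levels = lev),
                     predicted = factor(pred, levels = lev))
  acc <- 100 * sum(diag(confusion)) / sum(confusion)
  row_tot <- rowSums(confusion)
  per_class <- ifelse(row_tot > 0, 100 * diag(confusion) / row_tot, NA)
  structure(list(confusion = confusion, accuracy = acc,
                 per_class = per_class,
                 n_rerouted = sum(rerouted)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> accuracy %.2f%%\n", x$accuracy))
  print(x$confusion)
  invisible(x)
}

stratified_split <- function(labels, train_fraction) {
  train <- integer(0)
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    n_tr <- round(train_fraction * length(idx))
    train <- c(train, sample(idx, n_tr))
  }
  sort(train)
}

stratified_folds <- function(labels, folds) {
  fold_of <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold_of[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold_of
}

#' Repeated split + cross-validated SOM evaluation
#'
#' Per repeat: a stratified `train_fraction` split; `folds`-fold
#' cross-validation on the training portion (training accuracy is the mean
#' fold accuracy); a final model on the full training portion evaluated on
#' the held-out testing portion. The overall model accuracy is the
#' unweighted mean of the mean training and mean testing accuracies.
#'
#' @param x features (matrix or `raman_dataset`)
#' @param labels class labels
#' @param train_fraction training share of each split (default 0.8)
#' @param folds cross-validation folds on the training portion (default
#'   10; 0 skips cross-validation and reports resubstitution accuracy)
#' @param repeats independent runs (default 10)
#' @param seed RNG seed
#' @param ... passed to [train_som()] (grid, rlen, ...)
#' @return object of class `cv_report` with training/testing accuracy
#'   mean +/- SD over repeats, `overall` accuracy, per-class testing
#'   accuracies (mean over repeats) and the pooled testing confusion matrix
#' @export
split_and_cv <- function(x, labels = NULL, train_fraction = 0.8,
                         folds = 10, repeats = 10, seed = NULL, ...) {
  if (inherits(x, "raman_dataset") && is.null(labels))
    labels <- x$meta$class
  xm <- as_feature_matrix(x)
  labels <- as.character(labels)
  class_sizes <- table(labels)
  if (folds > 0 && any(floor(class_sizes * train_fraction) < folds))
    stop("every class needs at least `folds` training samples",
         call. = FALSE)
  with_seed_maybe(seed, {
    train_acc <- test_acc <- numeric(repeats)
    per_class_acc <- NULL
    confusion <- NULL
    for (r in seq_len(repeats)) {
      tr <- stratified_split(labels, train_fraction)
      te <- setdiff(seq_along(labels), tr)
      if (folds > 0) {
        fold_of <- stratified_folds(labels[tr], folds)
        fold_acc <- numeric(folds)
        for (f in seq_len(folds)) {
          fit_idx <- tr[fold_of != f]
          val_idx <- tr[fold_of == f]
          m <- train_som(xm[fit_idx, , drop = FALSE], labels[fit_idx],
                         seed = NULL, ...)
          fold_acc[f] <- evaluate_som(m, xm[val_idx, , drop = FALSE],
                                      labels[val_idx])$accuracy
        }
        train_acc[r] <- mean(fold_acc)
      }
      final <- train_som(xm[tr, , drop = FALSE], labels[tr], seed = NULL,
                         ...)
      if (folds == 0)
        train_acc[r] <- evaluate_som(final, xm[tr, , drop = FALSE],
                                     labels[tr])$accuracy
      ev <- evaluate_som(final, xm[te, , drop = FALSE], labels[te])
      test_acc[r] <- ev$accuracy
      per_class_acc <- rbind(per_class_acc, ev$per_class)
      confusion <- if (is.null(confusion)) ev$confusion else
        confusion + ev$confusion
    }
    structure(list(
      training = c(mean = mean(train_acc), sd = stats::sd(train_acc)),
      testing = c(mean = mean(test_acc), sd = stats::sd(test_acc)),
      overall = overall_model_accuracy(mean(train_acc), mean(test_acc)),
      per_class_testing = colMeans(per_class_acc, na.rm = TRUE),
      confusion = confusion, repeats = repeats, folds = folds),
      class = "cv_report")
  })
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf(
    "<cv_report> training %.2f +/- %.2f%%, testing %.2f +/- %.2f%%, overall %.2f%%\n",
    x$training["mean"], x$training["sd"], x$testing["mean"],
    x$testing["sd"], x$overall))
  invisible(x)
}

#' Overall model accuracy from training and testing accuracies
#'
#' The unweighted mean of the two accuracies, the convention used to
#' summarise a repeated split-and-validate run (e.g. training 95.51 % and
#' testing 88.50 % give 92.01 %).
#'
#' @param training,testing accuracies in percent
#' @return overall accuracy in percent
#' @export
overall_model_accuracy <- function(training, testing) {
  (training + testing) / 2
}

#' SOM discriminant index (SOMDI) profiles
#'
#' Each labelled neuron's weight vector is scaled to unit Euclidean norm;
#' the SOMDI for class c is the elementwise mean of scaled weights over
#' neurons labelled c minus the elementwise mean over all labelled
#' neurons, with negatives clipped to zero. Features are ranked by
#' descending discriminant weight.
#'
#' @param model a trained, labelled `som_model`
#' @param feature_names optional feature names (e.g. wavenumbers)
#' @param top_k ranked features to report per class (default 5)
#' @return object of class `somdi_profile`: per-class non-negative weight
#'   vectors and top-k feature indices/names
#' @export
somdi <- function(model, feature_names = NULL, top_k = 5) {
  labelled <- model$neuron_labels != "unassigned"
  if (!any(labelled)) stop("model has no labelled neurons", call. = FALSE)
  w <- model$weights[labelled, , drop = FALSE]
  norms <- sqrt(rowSums(w^2))
  norms[norms == 0] <- 1
  w <- w / norms
  lab <- model$neuron_labels[labelled]
  centre <- colMeans(w)
  profiles <- list()
  top <- list()
  for (cl in model$classes) {
    sel <- lab == cl
    if (!any(sel)) {
      profiles[[cl]] <- numeric(0)
      top[[cl]] <- integer(0)
      next
    }
    d <- colMeans(w[sel, , drop = FALSE]) - centre
    d[d < 0] <- 0
    if (!is.null(feature_names)) names(d) <- feature_names
    profiles[[cl]] <- d
    top[[cl]] <- order(d, decreasing = TRUE)[seq_len(min(top_k, length(d)))]
  }
  structure(list(profiles = profiles, top_features = top,
                 feature_names = feature_names),
            class = "somdi_profile")
}

#' Retrain a SOM after excluding classes
#'
#' @param x features (matrix or `raman_dataset`)
#' @param labels class labels
#' @param exclude class labels to drop (may be empty)
#' @param feature_names passed to [somdi()]
#' @param ... passed to [train_som()]
#' @return list with the refit `model` and its `somdi` profile
#' @export
subset_refit <- function(x, labels = NULL, exclude = character(0),
                         feature_names = NULL, ...) {
  if (inherits(x, "raman_dataset") && is.null(labels))
    labels <- x$meta$class
  xm <- as_feature_matrix(x)
  labels <- as.character(labels)
  keep <- !(labels %in% exclude)
  if (length(unique(labels[keep])) < 2L)
    stop("fewer than 2 classes remain after exclusion", call. = FALSE)
  model <- train_som(xm[keep, , drop = FALSE], labels[keep], ...)
  list(model = model, somdi = somdi(model, feature_names = feature_names))
}
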