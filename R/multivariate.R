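# Comparator classifiers on the 20-peak feature table: PLS-DA with
# Q2/R2/VIP, and PCA + k-means on the first two principal components.

#' The 20 peaks-of-interest used as the multivariate feature set
#' @return numeric vector of wavenumbers (cm^-1), canonical order
#' @export
peaks_of_interest <- function() {
  c(700, 744, 854, 898, 917, 1003, 1048, 1147, 1157, 1226, 1288, 1309,
    1328, 1343, 1355, 1451, 1456, 1494, 1525, 1606)
}

#' Extract the 20-peak feature table from a dataset
#'
#' Nearest-grid-point intensities at the peaks-of-interest, in canonical
#' order regardless of input ordering.
#'
#' @param ds a `raman_dataset`
#' @param peaks peak wavenumbers (default [peaks_of_interest()])
#' @return object of class `feature_table`: numeric matrix `x`
#'   (samples x peaks), `class` labels and `wavenumbers`
#' @export
extract_features <- function(ds, peaks = peaks_of_interest()) {
  wn <- ds$wavenumbers
  out_of_span <- peaks < min(wn) | peaks > max(wn)
  if (any(out_of_span))
    stop("peak(s) ", paste(peaks[out_of_span], collapse = ", "),
         " cm^-1 outside the grid span of sample '",
         ds$meta$sample_id[1L], "'", call. = FALSE)
  cols <- vapply(peaks, function(p) nearest_index(wn, p), integer(1))
  x <- ds$intensities[, cols, drop = FALSE]
  colnames(x) <- paste0("wn", peaks)
  structure(list(x = x, class = ds$meta$class, wavenumbers = peaks,
                 sample_id = ds$meta$sample_id),
            class = "feature_table")
}

autoscale <- function(x, center = NULL, scale = NULL) {
  if (is.null(center)) center <- colMeans(x)
  if (is.null(scale)) scale <- apply(x, 2, stats::sd)
  list(x = sweep(sweep(x, 2, center), 2, scale, `/`),
       center = center, scale = scale)
}

one_hot <- function(labels, levels) {
  y <- matrix(0, length(labels), length(levels),
              dimnames = list(NULL, levels))
  y[cbind(seq_along(labels), match(labels, levels))] <- 1
  y
}

# NIPALS PLS2 on preprocessed X (centred/scaled) and centred Y.
# Returns weights W, loadings P, Y-loadings Q, scores T and the explained
# Y sum of squares per component (q_a^2 * t_a' t_a), which drives VIP.
nipals_pls2 <- function(x, y, n_components, tol = 1e-10, max_iter = 500) {
  n <- nrow(x); p <- ncol(x); q <- ncol(y)
  W <- matrix(0, p, n_components)
  P <- matrix(0, p, n_components)
  Q <- matrix(0, q, n_components)
  Tm <- matrix(0, n, n_components)
  ssy <- numeric(n_components)
  for (a in seq_len(n_components)) {
    u <- y[, which.max(apply(y, 2, stats::var))]
    t_old <- rep(Inf, n)
    for (it in seq_len(max_iter)) {
      w <- drop(crossprod(x, u))
      w <- w / sqrt(sum(w^2))
      t <- drop(x %*% w)
      qv <- drop(crossprod(y, t)) / sum(t^2)
      u <- drop(y %*% qv) / sum(qv^2)
      if (sqrt(sum((t - t_old)^2)) < tol * sqrt(sum(t^2))) break
      t_old <- t
    }
    pv <- drop(crossprod(x, t)) / sum(t^2)
    x <- x - tcrossprod(t, pv)
    y <- y - tcrossprod(t, qv)
    W[, a] <- w; P[, a] <- pv; Q[, a] <- qv; Tm[, a] <- t
    ssy[a] <- sum(qv^2) * sum(t^2)
  }
  list(W = W, P = P, Q = Q, scores = Tm, ssy = ssy)
}

pls_coefficients <- function(fit) {
  # B such that Yhat_centred = Xscaled %*% B
  fit$W %*% solve(crossprod(fit$P, fit$W)) %*% t(fit$Q)
}

#' Fit a PLS-DA model
#'
#' NIPALS PLS2 on autoscaled features against one-hot class indicators;
#' predicted class is the argmax of the predicted indicator. R2 is the
#' indicator variance explained on the fit; Q2 = 1 - PRESS/TSS by
#' stratified cross-validation; VIP_j = sqrt(p * sum_a SS_a
#' (w_ja/||w_a||)^2 / sum_a SS_a), so that sum_j VIP_j^2 = p.
#'
#' @param features `feature_table` or numeric matrix
#' @param labels class labels (taken from the feature table if NULL)
#' @param n_components latent components (default 5)
#' @param cv_folds stratified folds for Q2 (default 5)
#' @param seed RNG seed for fold allocation
#' @return object of class `plsda_model` with `vip`, `r2`, `q2`,
#'   `accuracy` (%), `scores`, `weights`, `classes`
#' @export
plsda_fit <- function(features, labels = NULL, n_components = 5,
                      cv_folds = 5, seed = NULL) {
  if (inherits(features, "feature_table")) {
    labels <- labels %||% features$class
    x <- features$x
  } else x <- as.matrix(features)
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2L) stop("need at least 2 classes", call. = FALSE)
  if (nrow(x) <= n_components)
    stop("need more samples than components", call. = FALSE)
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    warning("dropping constant feature(s): ",
            paste(colnames(x)[sds == 0], collapse = ", "), call. = FALSE)
    x <- x[, sds > 0, drop = FALSE]
  }
  sc <- autoscale(x)
  y <- one_hot(labels, classes)
  y_centred <- sweep(y, 2, colMeans(y))
  fit <- nipals_pls2(sc$x, y_centred, n_components)
  B <- pls_coefficients(fit)
  yhat <- sc$x %*% B
  r2 <- 1 - sum((y_centred - yhat)^2) / sum(y_centred^2)
  pred <- classes[max.col(sweep(yhat, 2, colMeans(y), `+`))]
  accuracy <- 100 * mean(pred == labels)
  # VIP
  wnorm <- sweep(fit$W, 2, sqrt(colSums(fit$W^2)), `/`)
  p <- ncol(x)
  vip <- sqrt(p * drop(wnorm^2 %*% fit$ssy) / sum(fit$ssy))
  names(vip) <- colnames(x)
  # cross-validated Q2
  press <- tss <- 0
  with_seed_maybe(seed, {
    fold_of <- stratified_folds(labels, cv_folds)
    for (f in seq_len(cv_folds)) {
      tr <- fold_of != f; te <- !tr
      sc_tr <- autoscale(x[tr, , drop = FALSE])
      y_tr <- one_hot(labels[tr], classes)
      mu_y <- colMeans(y_tr)
      fit_f <- nipals_pls2(sc_tr$x, sweep(y_tr, 2, mu_y),
                           min(n_components, sum(tr) - 1L))
      x_te <- sweep(sweep(x[te, , drop = FALSE], 2, sc_tr$center), 2,
                    sc_tr$scale, `/`)
      yhat_te <- sweep(x_te %*% pls_coefficients(fit_f), 2, mu_y, `+`)
      y_te <- one_hot(labels[te], classes)
      press <- press + sum((y_te - yhat_te)^2)
      tss <- tss + sum(sweep(y_te, 2, mu_y)^2)
    }
  })
  structure(list(classes = classes, n_components = n_components,
                 weights = fit$W, loadings = fit$P, scores = fit$scores,
                 ssy = fit$ssy, coefficients = B, center = sc$center,
                 scale = sc$scale, y_means = colMeans(y), r2 = r2,
                 q2 = 1 - press / tss, accuracy = accuracy, vip = vip),
            class = "plsda_model")
}

#' @export
print.plsda_model <- function(x, ...) {
  cat(sprintf(
    "<plsda_model> %d components, R2 = %.3f, Q2 = %.3f, accuracy = %.1f%%\n",
    x$n_components, x$r2, x$q2, x$accuracy))
  invisible(x)
}

#' Predict classes from a PLS-DA model
#' @param object a `plsda_model`
#' @param newdata feature matrix (same columns as the fit)
#' @param ... unused
#' @export
predict.plsda_model <- function(object, newdata, ...) {
  x <- sweep(sweep(as.matrix(newdata), 2, object$center), 2, object$scale,
             `/`)
  yhat <- sweep(x %*% object$coefficients, 2, object$y_means, `+`)
  object$classes[max.col(yhat)]
}

kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(0, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1L), ]
  d2 <- rowSums(sweep(x, 2, centers[1, ])^2)
  for (j in seq_len(k - 1L) + 1L) {
    probs <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[j, ] <- x[sample.int(n, 1L, prob = probs), ]
    d2 <- pmin(d2, rowSums(sweep(x, 2, centers[j, ])^2))
  }
  centers
}

#' PCA followed by k-means on the first two principal components
#'
#' PCA on autoscaled features; Lloyd's algorithm with k-means++
#' initialisation on (PC1, PC2). The within-cluster sum of squares is
#' recorded at every Lloyd iteration (it is non-increasing).
#'
#' @param features `feature_table` or numeric matrix
#' @param k number of clusters (default 4)
#' @param seed RNG seed
#' @param max_iter Lloyd iteration cap (default 100)
#' @param labels optional class labels for the contingency table
#' @return object of class `pckmeans`: `cluster` assignments, `centers`,
#'   PC `scores`, `objective_trace`, `contingency` (clusters x classes,
#'   when labels are known)
#' @export
pca_kmeans <- function(features, k = 4, seed = NULL, max_iter = 100,
                       labels = NULL) {
  if (inherits(features, "feature_table")) {
    labels <- labels %||% features$class
    x <- features$x
  } else x <- as.matrix(features)
  n <- nrow(x)
  if (k < 1L || k > n) stop("k must be between 1 and n", call. = FALSE)
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  scores <- pc$x[, 1:2, drop = FALSE]
  with_seed_maybe(seed, {
    centers <- kmeanspp_init(scores, k)
    cluster <- integer(n)
    trace <- numeric(0)
    for (it in seq_len(max_iter)) {
      d2 <- sapply(seq_len(k), function(j)
        rowSums(sweep(scores, 2, centers[j, ])^2))
      if (k == 1L) d2 <- matrix(d2, ncol = 1L)
      new_cluster <- max.col(-d2)
      trace <- c(trace, sum(d2[cbind(seq_len(n), new_cluster)]))
      if (identical(new_cluster, cluster)) break
      cluster <- new_cluster
      for (j in seq_len(k)) {
        sel <- cluster == j
        if (any(sel)) centers[j, ] <- colMeans(scores[sel, , drop = FALSE])
      }
    }
    contingency <- if (!is.null(labels) && !all(is.na(labels)))
      table(cluster = cluster, class = labels) else NULL
    structure(list(cluster = cluster, centers = centers, scores = scores,
                   objective_trace = trace, contingency = contingency,
                   sdev = pc$sdev),
              class = "pckmeans")
  })
}

#' @export
print.pckmeans <- function(x, ...) {
  cat(sprintf("<pckmeans> %d clusters, objective %.4g after %d iterations\n",
              nrow(x$centers), utils::tail(x$objective_trace, 1),
              length(x$objective_trace)))
  if (!is.null(x$contingency)) print(x$contingency)
  invisible(x)
}
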