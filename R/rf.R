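# Random-forest classifier: bagged CART ensemble with out-of-bag error,
# per-feature permutation importance and proximity-based outlier scores.

#' Fit a random forest
#'
#' Bagged Gini-split decision trees grown to purity. OOB error comes from
#' out-of-bag majority votes; permutation importance is the mean decrease
#' in OOB accuracy when a feature is permuted among each tree's OOB
#' samples; proximity(i, j) is the fraction of trees placing i and j in
#' the same terminal node; the outlier score of sample i is
#' n / sum_{j in class(i)} proximity(i, j)^2, median/MAD-normalised within
#' its class.
#'
#' @param features `feature_table` or numeric matrix (samples x features)
#' @param labels class labels
#' @param n_trees trees in the ensemble (default 500)
#' @param mtry features tried per split (default 7)
#' @param seed RNG seed
#' @param min_node minimum node size before splitting stops (default 1)
#' @param importance compute permutation importance (default TRUE)
#' @param proximity compute the proximity matrix and outlier scores
#'   (default TRUE)
#' @return object of class `rf_model`: `oob_error` (fraction),
#'   `per_class_error`, `oob_predictions`, `importance`, `proximity`,
#'   `outlier_scores`, `trees`
#' @export
rf_fit <- function(features, labels = NULL, n_trees = 500, mtry = 7,
                   seed = NULL, min_node = 1, importance = TRUE,
                   proximity = TRUE) {
  if (inherits(features, "feature_table")) {
    labels <- labels %||% features$class
    x <- features$x
  } else x <- as.matrix(features)
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2L) stop("need at least 2 classes", call. = FALSE)
  single <- names(which(table(labels) == 1L))
  if (length(single))
    warning("class(es) with a single sample: ",
            paste(single, collapse = ", "),
            "; their proximity outlier scores are undefined",
            call. = FALSE)
  n <- nrow(x); p <- ncol(x); k <- length(classes)
  y0 <- match(labels, classes) - 1L
  mtry <- min(mtry, p)
  with_seed_maybe(seed, {
    votes <- matrix(0L, n, k, dimnames = list(NULL, classes))
    prox <- if (proximity) matrix(0, n, n) else NULL
    ntree_used <- if (proximity) numeric(1) else NULL
    imp_sum <- rep(0, p)
    imp_cnt <- 0L
    trees <- vector("list", n_trees)
    all_rows <- seq_len(n)
    for (b in seq_len(n_trees)) {
      boot <- sample.int(n, n, replace = TRUE)
      tree <- cpp_grow_tree(x, y0, boot, mtry, k, min_node)
      trees[[b]] <- tree
      oob <- setdiff(all_rows, unique(boot))
      if (length(oob)) {
        ap <- cpp_tree_apply(tree, x, oob)
        votes[cbind(oob, ap$class + 1L)] <-
          votes[cbind(oob, ap$class + 1L)] + 1L
        if (importance && length(oob) > 1L) {
          correct0 <- sum(ap$class == y0[oob])
          for (j in seq_len(p)) {
            xp <- x[oob, , drop = FALSE]
            xp[, j] <- xp[, j][sample.int(length(oob))]
            app <- cpp_tree_apply(tree, xp, seq_along(oob))
            imp_sum[j] <- imp_sum[j] +
              (correct0 - sum(app$class == y0[oob])) / length(oob)
          }
          imp_cnt <- imp_cnt + 1L
        }
      }
      if (proximity) {
        apall <- cpp_tree_apply(tree, x, all_rows)
        cpp_prox_update(prox, apall$leaf)
      }
    }
    voted <- rowSums(votes) > 0
    oob_pred <- rep(NA_character_, n)
    oob_pred[voted] <- classes[max.col(votes[voted, , drop = FALSE],
                                       ties.method = "first")]
    oob_error <- mean(oob_pred[voted] != labels[voted])
    per_class_error <- vapply(classes, function(cl) {
      sel <- voted & labels == cl
      if (!any(sel)) return(NA_real_)
      mean(oob_pred[sel] != cl)
    }, numeric(1))
    imp <- if (importance && imp_cnt > 0L) imp_sum / imp_cnt else NULL
    if (!is.null(imp)) names(imp) <- colnames(x)
    outlier <- NULL
    if (proximity) {
      prox <- prox / n_trees
      diag(prox) <- 1
      raw <- vapply(seq_len(n), function(i) {
        same <- which(labels == labels[i] & seq_len(n) != i)
        s <- sum(prox[i, same]^2)
        if (s == 0) return(NA_real_)
        n / s
      }, numeric(1))
      outlier <- raw
      for (cl in classes) {
        sel <- labels == cl
        med <- stats::median(raw[sel], na.rm = TRUE)
        dev <- stats::median(abs(raw[sel] - med), na.rm = TRUE)
        # a clean class can have MAD exactly 0; fall back to the mean
        # absolute deviation, then to 1 for a fully degenerate class
        if (!is.finite(dev) || dev == 0)
          dev <- mean(abs(raw[sel] - med), na.rm = TRUE)
        if (!is.finite(dev) || dev == 0) dev <- 1
        outlier[sel] <- (raw[sel] - med) / dev
      }
    }
    structure(list(classes = classes, n_trees = n_trees, mtry = mtry,
                   oob_error = oob_error,
                   per_class_error = per_class_error,
                   oob_predictions = oob_pred, importance = imp,
                   proximity = prox, outlier_scores = outlier,
                   trees = trees, feature_names = colnames(x),
                   labels = labels),
              class = "rf_model")
  })
}

#' @export
print.rf_model <- function(x, ...) {
  cat(sprintf("<rf_model> %d trees, mtry %d, OOB error %.2f%%\n",
              x$n_trees, x$mtry, 100 * x$oob_error))
  invisible(x)
}

#' Predict classes with a random forest
#' @param object an `rf_model`
#' @param newdata feature matrix (same columns as the fit)
#' @param ... unused
#' @export
predict.rf_model <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  k <- length(object$classes)
  votes <- matrix(0L, nrow(x), k)
  for (tree in object$trees) {
    ap <- cpp_tree_apply(tree, x, seq_len(nrow(x)))
    votes[cbind(seq_len(nrow(x)), ap$class + 1L)] <-
      votes[cbind(seq_len(nrow(x)), ap$class + 1L)] + 1L
  }
  object$classes[max.col(votes, ties.method = "first")]
}

#' Classification accuracy implied by an out-of-bag error
#'
#' `100 - oob_error_percent`, the convention used to report a forest's
#' accuracy from its OOB estimate (e.g. an OOB error of 7.75 % implies
#' 92.25 % accuracy).
#'
#' @param oob_error_percent OOB error in percent
#' @return accuracy in percent
#' @export
rf_accuracy_from_oob <- function(oob_error_percent) {
  100 - oob_error_percent
}
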