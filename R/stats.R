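# Nonparametric group comparisons: tie-corrected Kruskal-Wallis ANOVA,
# Dunn's post-hoc pairwise z tests and significance labelling.

check_groups <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need at least 2 groups", call. = FALSE)
  sizes <- vapply(groups, length, integer(1))
  if (any(sizes < 1L)) {
    j <- which(sizes < 1L)[1L]
    nm <- names(groups)[j] %||% as.character(j)
    stop("group '", nm, "' is empty", call. = FALSE)
  }
  if (is.null(names(groups)))
    names(groups) <- paste0("group", seq_along(groups))
  groups
}

# pooled ranks, per-group rank sums and the tie-correction sums
rank_summaries <- function(groups) {
  values <- unlist(groups, use.names = FALSE)
  g <- rep(names(groups), vapply(groups, length, integer(1)))
  r <- rank(values)  # midranks for ties
  n <- length(values)
  ties <- table(values)
  list(n = n, sizes = vapply(groups, length, integer(1)),
       rank_sums = tapply(r, factor(g, levels = names(groups)), sum),
       tie_sum = sum(ties^3 - ties))
}

#' Kruskal-Wallis rank ANOVA
#'
#' Tie-corrected H statistic with a chi-square p-value on k - 1 degrees of
#' freedom. When every pooled value is identical (complete ties) H = 0 and
#' p = 1.
#'
#' @param groups list of numeric vectors, one per group
#' @return object of class `test_result` with `statistic` (H), `df` and
#'   `p_value`
#' @export
kruskal_wallis <- function(groups) {
  groups <- check_groups(groups)
  rs <- rank_summaries(groups)
  n <- rs$n
  correction <- 1 - rs$tie_sum / (n^3 - n)
  if (correction <= 0) {           # all values identical
    h <- 0; p <- 1
  } else {
    h <- (12 / (n * (n + 1)) * sum(rs$rank_sums^2 / rs$sizes) -
            3 * (n + 1)) / correction
    p <- stats::pchisq(h, df = length(groups) - 1L, lower.tail = FALSE)
  }
  structure(list(method = "Kruskal-Wallis", statistic = h,
                 df = length(groups) - 1L, p_value = p,
                 groups = names(groups)),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, df = %s, p = %.4g\n", x$method,
              x$statistic, x$df %||% NA, x$p_value))
  invisible(x)
}

#' Dunn's post-hoc pairwise tests
#'
#' Pairwise z statistics from mean ranks of the pooled ranking with tie
#' correction, two-sided p-values and the chosen multiplicity adjustment.
#' All k(k-1)/2 pairs are reported. Bonferroni is the default pairing with
#' Dunn's test; `"none"` is selectable for comparison against unadjusted
#' values.
#'
#' @param groups list of numeric vectors, one per group
#' @param adjustment `"bonferroni"`, `"holm"` or `"none"`
#' @return data.frame with columns `group1`, `group2`, `z`, `p_value`,
#'   `adjusted_p`, `label`
#' @export
dunn_posthoc <- function(groups, adjustment = c("bonferroni", "holm",
                                                "none")) {
  adjustment <- match.arg(adjustment)
  groups <- check_groups(groups)
  rs <- rank_summaries(groups)
  n <- rs$n
  mean_ranks <- rs$rank_sums / rs$sizes
  var_term <- n * (n + 1) / 12 - rs$tie_sum / (12 * (n - 1))
  k <- length(groups)
  pairs <- utils::combn(k, 2)
  z <- p <- numeric(ncol(pairs))
  for (m in seq_len(ncol(pairs))) {
    i <- pairs[1, m]; j <- pairs[2, m]
    se <- sqrt(var_term * (1 / rs$sizes[i] + 1 / rs$sizes[j]))
    z[m] <- if (se == 0) 0 else (mean_ranks[i] - mean_ranks[j]) / se
    p[m] <- 2 * stats::pnorm(-abs(z[m]))
  }
  adj <- stats::p.adjust(p, method = adjustment)
  data.frame(group1 = names(groups)[pairs[1, ]],
             group2 = names(groups)[pairs[2, ]],
             z = z, p_value = p, adjusted_p = adj,
             label = significance_labels(adj),
             stringsAsFactors = FALSE)
}

#' Significance labels
#'
#' Maps p-values to `ns` (> 0.05), `*` (< 0.05), `**` (< 0.01) and
#' `***` (< 0.005).
#'
#' @param p numeric vector of p-values in \[0, 1\]
#' @return character vector of labels
#' @export
significance_labels <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  out <- rep("ns", length(p))
  out[p < 0.05] <- "*"
  out[p < 0.01] <- "**"
  out[p < 0.005] <- "***"
  out
}

#' Kruskal-Wallis + Dunn summary over a tidy table
#'
#' @param data data.frame
#' @param value name of the numeric column
#' @param by name of the grouping column
#' @param adjustment passed to [dunn_posthoc()]
#' @return list with `kruskal` (`test_result`), `dunn` (pairwise table)
#'   and `summary` (per-group mean +/- SD)
#' @export
kw_dunn <- function(data, value, by = "class",
                    adjustment = "bonferroni") {
  groups <- split(data[[value]], data[[by]])
  ord <- intersect(senescence_classes(), names(groups))
  if (length(ord) == length(groups)) groups <- groups[ord]
  summ <- data.frame(
    group = names(groups),
    n = vapply(groups, length, integer(1)),
    mean = vapply(groups, mean, numeric(1)),
    sd = vapply(groups, stats::sd, numeric(1)),
    stringsAsFactors = FALSE)
  list(kruskal = kruskal_wallis(groups),
       dunn = dunn_posthoc(groups, adjustment),
       summary = summ)
}
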