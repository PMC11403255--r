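new_rank_test <- function(statistic, p_value, method, n_per_group,
                          tie_corrected) {
  structure(list(statistic = statistic, p_value = p_value,
                 method = method, n_per_group = n_per_group,
                 tie_corrected = tie_corrected),
            class = "rank_test")
}

#' @export
print.rank_test <- function(x, ...) {
  cat(x$method, "\n")
  cat(sprintf("  statistic = %.4g, p = %.4g (n = %s)%s\n",
              x$statistic, x$p_value,
              paste(x$n_per_group, collapse = ", "),
              if (x$tie_corrected) ", tie-corrected" else ""))
  invisible(x)
}

#' Two-sided Mann-Whitney U test
#'
#' U is computed from midranks; the reported statistic is the smaller of
#' the two mirrored U values. The p-value is exact (by the null
#' permutation distribution of U) when the combined sample size is at
#' most 16 and there are no ties, and otherwise uses the normal
#' approximation with tie and continuity corrections.
#'
#' @param x,y numeric samples, each non-empty.
#' @return A `rank_test` with the smaller U, the p-value and the method
#'   branch used.
#' @export
mann_whitney_u <- function(x, y) {
  if (length(x) < 1 || length(y) < 1)
    stop("both samples must be non-empty", call. = FALSE)
  stopifnot(is.numeric(x), is.numeric(y), all(is.finite(c(x, y))))
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  u2 <- n1 * n2 - u1
  ties <- any(duplicated(c(x, y)))
  exact <- (n1 + n2 <= 16) && !ties
  p <- suppressWarnings(
    wilcox.test(x, y, exact = exact, correct = TRUE)$p.value)
  new_rank_test(min(u1, u2), min(p, 1),
                paste0("Mann-Whitney U test (two-sided, ",
                       if (exact) "exact" else
                         "normal approximation with continuity correction",
                       ")"),
                c(n1, n2), tie_corrected = !exact && ties)
}

#' Kruskal-Wallis rank test
#'
#' Tie-corrected H statistic against a chi-square reference with
#' `k - 1` degrees of freedom. When every observation is tied the tie
#' correction degenerates; that case is defined as no evidence against
#' the null (`H = 0`, `p = 1`).
#'
#' @param groups list of >= 2 numeric samples (each non-empty, total
#'   n >= 3).
#' @return A `rank_test` with H and the chi-square p-value.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    stop("at least two groups are required", call. = FALSE)
  n <- lengths(groups)
  if (any(n < 1) || sum(n) < 3)
    stop("each group needs >= 1 observation and >= 3 in total",
         call. = FALSE)
  all_vals <- unlist(groups, use.names = FALSE)
  ties <- any(duplicated(all_vals))
  if (length(unique(all_vals)) == 1)
    return(new_rank_test(0, 1,
                         "Kruskal-Wallis rank sum test (all values tied)",
                         n, tie_corrected = TRUE))
  kt <- kruskal.test(all_vals, factor(rep(seq_along(groups), n)))
  new_rank_test(unname(kt$statistic), kt$p.value,
                "Kruskal-Wallis rank sum test", n, tie_corrected = ties)
}

#' Dunn's post hoc pairwise comparisons
#'
#' Pairwise z statistics from the pooled midranks with tie correction
#' (Dunn 1964), two-sided p-values, and a family-wise adjustment over the
#' comparison family (all pairs).
#'
#' @param groups list of >= 2 numeric samples.
#' @param adjust `"bonferroni"` (the convention of common prism-style
#'   implementations), `"holm"`, or `"none"`.
#' @return Data frame with one row per pair: `group1`, `group2`, `z`,
#'   `p_unadjusted`, `p_adjusted`.
#' @export
dunns_posthoc <- function(groups,
                          adjust = c("bonferroni", "holm", "none")) {
  adjust <- match.arg(adjust)
  if (!is.list(groups) || length(groups) < 2)
    stop("at least two groups are required", call. = FALSE)
  n <- lengths(groups)
  if (any(n < 1)) stop("each group needs >= 1 observation", call. = FALSE)
  labels <- names(groups)
  if (is.null(labels)) labels <- paste0("group", seq_along(groups))
  vals <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), n)
  N <- length(vals)
  r <- rank(vals)
  mean_rank <- tapply(r, g, mean)
  tie_sizes <- table(vals)
  tie_term <- sum(tie_sizes^3 - tie_sizes) / (12 * (N - 1))
  var_base <- N * (N + 1) / 12 - tie_term
  pairs <- utils::combn(seq_along(groups), 2)
  z <- apply(pairs, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    se <- sqrt(var_base * (1 / n[i] + 1 / n[j]))
    if (se == 0) return(0)      # all values tied
    (mean_rank[[i]] - mean_rank[[j]]) / se
  })
  p <- 2 * pnorm(-abs(z))
  p[abs(z) == 0 & var_base <= 0] <- 1
  p_adj <- pmin(p.adjust(p, method = adjust), 1)
  data.frame(group1 = labels[pairs[1, ]], group2 = labels[pairs[2, ]],
             z = z, p_unadjusted = p, p_adjusted = p_adj,
             stringsAsFactors = FALSE)
}

#' Sociability index of the three-chamber test
#'
#' Time in the novel-mouse chamber over the summed novel-mouse and
#' novel-object chamber times; centre-chamber time is excluded by
#' definition. An index of 0.5 means no social preference.
#'
#' @param time_novel_mouse_s,time_novel_object_s chamber times, seconds;
#'   vectorized.
#' @return Numeric vector of indices in `[0, 1]`.
#' @export
sociability_index <- function(time_novel_mouse_s, time_novel_object_s) {
  stopifnot(all(time_novel_mouse_s >= 0), all(time_novel_object_s >= 0))
  tot <- time_novel_mouse_s + time_novel_object_s
  if (any(tot == 0))
    stop("sociability index undefined: both interaction times are zero",
         call. = FALSE)
  time_novel_mouse_s / tot
}

#' Normalized cumulative distribution of a sample
#'
#' The right-continuous empirical cumulative distribution function,
#' rising from 0 to exactly 1 at the sample maximum, as used to compare
#' distributions of e.g. mEPSC amplitudes or spine head diameters.
#'
#' @param sample non-empty numeric vector.
#' @return An object of class `normalized_cdf`: list with sorted unique
#'   `values`, their `cumulative_fraction`, and `fun` (a step function).
#' @export
normalized_cdf <- function(sample) {
  if (length(sample) < 1)
    stop("sample must be non-empty", call. = FALSE)
  stopifnot(is.numeric(sample), all(is.finite(sample)))
  f <- ecdf(sample)
  v <- sort(unique(sample))
  structure(list(values = v, cumulative_fraction = f(v), fun = f),
            class = "normalized_cdf")
}

#' @export
print.normalized_cdf <- function(x, ...) {
  cat("Normalized cumulative distribution over", length(x$values),
      "distinct values in [", min(x$values), ",", max(x$values), "]\n")
  invisible(x)
}

#' @export
plot.normalized_cdf <- function(x, ..., xlab = "value",
                                ylab = "cumulative fraction") {
  plot(x$fun, ..., xlab = xlab, ylab = ylab)
  invisible(x)
}

#' Mean and standard error of the mean
#'
#' @param sample numeric vector; SEM needs `n >= 2`.
#' @return Named vector `c(mean, sem)` with
#'   `sem = sd(sample) / sqrt(n)` (n-1 denominator in the sd).
#' @export
mean_sem <- function(sample) {
  stopifnot(is.numeric(sample), all(is.finite(sample)))
  if (length(sample) < 2)
    stop("SEM undefined for fewer than two observations", call. = FALSE)
  c(mean = mean(sample), sem = sd(sample) / sqrt(length(sample)))
}
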