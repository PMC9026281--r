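# Rank-based cohort statistics: tie-corrected Spearman correlation with exact
# permutation p at small n, Wilcoxon signed-rank with exact sign enumeration,
# and median/IQR summaries. Implemented from first principles; base R's
# cor.test / wilcox.test serve as independent cross-checks in the test suite.

#' Spearman rank correlation with midrank ties
#'
#' Ranks both vectors with midranks for ties and computes `rho` as the
#' Pearson correlation of the rank vectors. The two-sided p-value is exact
#' (full enumeration of all `n!` permutations of one rank vector) for
#' `n <= exact_limit`, otherwise the t approximation with `n - 2` degrees of
#' freedom. Pairs with a missing value in either vector are dropped
#' (pairwise-complete) and the number used is reported.
#'
#' @param x,y numeric vectors of equal length.
#' @param exact_limit largest n for which the permutation null is fully
#'   enumerated; default 8.
#' @return object of class `correlation_result`: list with `rho`, `p_value`,
#'   `n_used`, `method_note` (`"exact"` or `"approximate"`).
#' @examples
#' spearman_corr(c(1, 2, 2, 3), c(1, 2, 3, 4))  # rho 0.9487
#' @export
spearman_corr <- function(x, y, exact_limit = 8) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("insufficient data: need at least 3 complete pairs")
  rx <- rank(x); ry <- rank(y)
  if (stats::var(rx) == 0 || stats::var(ry) == 0)
    stop("undefined correlation: a rank vector is constant")
  rho <- stats::cor(rx, ry)
  if (n <= exact_limit) {
    rxc <- rx - mean(rx); ryc <- ry - mean(ry)
    perms <- all_permutations(n)
    # rho is monotone in the cross-product for fixed margins
    cp_obs <- sum(rxc * ryc)
    cp_perm <- as.vector(matrix(ryc[perms], nrow(perms), n) %*% rxc)
    p_value <- mean(abs(cp_perm) >= abs(cp_obs) - 1e-12)
    note <- "exact"
  } else {
    if (abs(rho) >= 1) {
      p_value <- 0
    } else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      p_value <- 2 * stats::pt(-abs(tstat), df = n - 2)
    }
    note <- "approximate"
  }
  structure(list(rho = rho, p_value = p_value, n_used = n,
                 method_note = note),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Spearman rho %+.3f, p = %.4g (n = %d, %s)\n",
              x$rho, x$p_value, x$n_used, x$method_note))
  invisible(x)
}

# all permutations of 1..n as an n! x n matrix (n <= 9 in practice)
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  for (k in seq_len(n)) {
    rows <- (k - 1L) * nrow(sub) + seq_len(nrow(sub))
    out[rows, 1L] <- k
    rest <- seq_len(n)[-k]
    out[rows, -1L] <- matrix(rest[sub], nrow(sub), n - 1L)
  }
  out
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Drops zero differences, ranks the absolute differences with midranks, and
#' reports `W` as the smaller of the positive- and negative-rank sums. The
#' two-sided p-value is exact -- all `2^n` sign assignments enumerated on the
#' achieved (possibly tied) ranks -- for `n_effective <= exact_limit`,
#' otherwise a normal approximation with tie-corrected variance and
#' continuity correction.
#'
#' @param a,b paired numeric vectors of equal length.
#' @param exact_limit largest effective n for full enumeration; default 12.
#' @return object of class `paired_test_result`: list with `statistic` (W),
#'   `p_value`, `n_effective`, `medians` (of `a` and `b`), `method_note`.
#' @examples
#' wilcoxon_signed_rank(c(2, 4, 6), c(1, 2, 3))  # W = 0, exact p = 0.25
#' @export
wilcoxon_signed_rank <- function(a, b, exact_limit = 12) {
  if (length(a) != length(b)) stop("paired vectors must have equal length")
  keep <- is.finite(a) & is.finite(b)
  d <- a[keep] - b[keep]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stop("degenerate test: all paired differences are zero")
  r <- rank(abs(d))
  w_pos <- sum(r[d > 0])
  w_neg <- sum(r[d < 0])
  if (n <= exact_limit) {
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    w_dist <- as.vector(signs %*% r)
    p_value <- min(1, 2 * min(mean(w_dist <= w_pos + 1e-12),
                              mean(w_dist >= w_pos - 1e-12)))
    note <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (w_pos - mu - sign(w_pos - mu) * 0.5) / sqrt(sigma2)
    p_value <- 2 * stats::pnorm(-abs(z))
    note <- "approximate"
  }
  structure(list(statistic = min(w_pos, w_neg), p_value = p_value,
                 n_effective = n,
                 medians = c(stats::median(a[keep]), stats::median(b[keep])),
                 method_note = note),
            class = "paired_test_result")
}

#' @export
print.paired_test_result <- function(x, ...) {
  cat(sprintf(
    "Wilcoxon signed-rank: W = %g, p = %.4g (n_eff = %d, %s); medians %.1f vs %.1f\n",
    x$statistic, x$p_value, x$n_effective, x$method_note,
    x$medians[1], x$medians[2]))
  invisible(x)
}

#' Median and interquartile range of a cohort variable
#'
#' Median is the middle order statistic (mean of the two middles for even
#' n); the quartiles use linear interpolation between order statistics at
#' positions `1 + (n - 1) p` by default (base R's type 7), with alternative
#' estimators selectable.
#'
#' @param values numeric vector, non-empty after removing `NA`.
#' @param quantile_method `"linear"` (type 7, default), `"exclusive"`
#'   (type 6) or `"median_unbiased"` (type 8).
#' @return named numeric vector `c(median, q1, q3)`.
#' @examples
#' cohort_median_iqr(c(1, 2, 3, 4))["median"]  # 2.5
#' @export
cohort_median_iqr <- function(values,
                              quantile_method = c("linear", "exclusive",
                                                  "median_unbiased")) {
  quantile_method <- match.arg(quantile_method)
  values <- values[is.finite(values)]
  if (length(values) == 0) stop("no finite values supplied")
  type <- c(linear = 7, exclusive = 6, median_unbiased = 8)[[quantile_method]]
  q <- stats::quantile(values, probs = c(0.25, 0.75), type = type,
                       names = FALSE)
  c(median = stats::median(values), q1 = q[1], q3 = q[2])
}

#' Run the full cohort analysis on a per-subject table
#'
#' Emits (a) the whole-skeleton median/IQR; (b) Spearman correlations of the
#' whole-skeleton mean with infiltration percentage, haemoglobin and age,
#' each on pairwise-complete subjects; (c) Wilcoxon signed-rank comparisons
#' of whole-skeleton vs regional means (all subjects) and whole-skeleton vs
#' lesion means (lesion-bearing subjects only). Analyses that cannot run
#' (insufficient data, degenerate differences) are skipped with a logged
#' reason rather than aborting the report.
#'
#' @param table data.frame with columns `subject_id`, `whole_mean`, and
#'   optionally `regional_mean`, `lesion_mean`, `infiltration_pct`,
#'   `haemoglobin`, `age`. Missing values must be `NA`, never silently
#'   absent rows.
#' @return object of class `study_report`: list with `whole_summary`,
#'   `correlations`, `comparisons`, and a character `log` of skips/drops.
#' @export
run_study_statistics <- function(table) {
  stopifnot(is.data.frame(table), "whole_mean" %in% names(table))
  if (anyDuplicated(table$subject_id))
    stop("subject_id values must be unique")
  log <- character()
  note <- function(msg) log <<- c(log, msg)

  whole_summary <- cohort_median_iqr(table$whole_mean)

  correlations <- list()
  for (covar in c("infiltration_pct", "haemoglobin", "age")) {
    if (!covar %in% names(table)) {
      note(sprintf("correlation with %s skipped: column absent", covar))
      next
    }
    n_missing <- sum(!is.finite(table[[covar]]) | !is.finite(table$whole_mean))
    if (n_missing > 0)
      note(sprintf("correlation with %s: %d incomplete pair(s) dropped",
                   covar, n_missing))
    correlations[[covar]] <- tryCatch(
      spearman_corr(table$whole_mean, table[[covar]]),
      error = function(e) {
        note(sprintf("correlation with %s skipped: %s", covar,
                     conditionMessage(e)))
        NULL
      })
  }

  comparisons <- list()
  for (other in c("regional_mean", "lesion_mean")) {
    if (!other %in% names(table)) {
      note(sprintf("comparison with %s skipped: column absent", other))
      next
    }
    n_missing <- sum(!is.finite(table[[other]]) | !is.finite(table$whole_mean))
    if (n_missing > 0)
      note(sprintf("comparison with %s: %d incomplete pair(s) dropped",
                   other, n_missing))
    comparisons[[paste0("whole_vs_", sub("_mean", "", other))]] <- tryCatch(
      wilcoxon_signed_rank(table$whole_mean, table[[other]]),
      error = function(e) {
        note(sprintf("comparison with %s skipped: %s", other,
                     conditionMessage(e)))
        NULL
      })
  }

  structure(list(whole_summary = whole_summary, correlations = correlations,
                 comparisons = comparisons, log = log),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("Whole-skeleton VNCa: median %.1f HU (IQR %.1f, %.1f)\n",
              x$whole_summary["median"], x$whole_summary["q1"],
              x$whole_summary["q3"]))
  for (nm in names(x$correlations)) {
    cat(sprintf("  vs %s: ", nm)); print(x$correlations[[nm]])
  }
  for (nm in names(x$comparisons)) {
    cat(sprintf("  %s: ", nm)); print(x$comparisons[[nm]])
  }
  if (length(x$log)) cat("  notes:", paste(x$log, collapse = "; "), "\n")
  invisible(x)
}
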