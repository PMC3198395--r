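# Descriptive cohort statistics: printed-style proportions, percentage
# reductions, mean +/- SEM, and paired comparisons.

# half-up rounding (R's round() is banker's)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Cohort proportion as a printed percentage
#'
#' 100 * n_positive / n_total, half-up rounded to one decimal (or to an
#' integer on demand), matching the convention of printed cohort
#' percentages such as 59/569 = 10.4 %.
#'
#' @param n_positive,n_total counts.
#' @param digits decimals to keep (1 by default; 0 for integer percent).
#' @return percentage.
#' @export
proportion_pct <- function(n_positive, n_total, digits = 1) {
  if (n_total < 1) stop("n_total must be >= 1")
  if (n_positive < 0 || n_positive > n_total)
    stop("n_positive must lie in [0, n_total]")
  round_half_up(100 * n_positive / n_total, digits)
}

#' Percentage reduction of an amplitude
#'
#' 100 * (|before| - |after|) / |before|; invariant to the overall sign
#' of the two amplitudes, so inward-negative currents can be passed
#' directly.
#'
#' @param before,after amplitudes (e.g. pA).
#' @return percent reduction (negative if |after| > |before|).
#' @export
percent_reduction <- function(before, after) {
  if (before == 0) stop("before must be nonzero")
  100 * (abs(before) - abs(after)) / abs(before)
}

#' Mean and standard error of the mean
#'
#' @param values numeric vector (nonempty).
#' @return list: `mean`, `sem` (sample SD / sqrt(n); NA with a `defined`
#'   flag when n < 2), `n`.
#' @export
mean_sem <- function(values) {
  if (!length(values)) stop("values must be nonempty")
  n <- length(values)
  list(mean = mean(values),
       sem = if (n >= 2L) stats::sd(values) / sqrt(n) else NA_real_,
       n = n, sem_defined = n >= 2L)
}

#' Paired comparison of two conditions
#'
#' Default is the Wilcoxon signed-rank test (exact for n <= 25, no
#' continuity correction), the conventional choice for small paired
#' samples; a paired t-test is available by flag. The test used is
#' recorded in the result. Identical vectors give p = 1 with statistic 0
#' (no non-zero differences to rank).
#'
#' @param before,after paired measurements (equal length, n >= 3).
#' @param method "wilcoxon" (default) or "t".
#' @return list: `p_value`, `statistic`, `method`, `n`.
#' @export
paired_compare <- function(before, after, method = c("wilcoxon", "t")) {
  method <- match.arg(method)
  if (length(before) != length(after))
    stop("before and after must have equal length")
  n <- length(before)
  if (n < 3L) stop("at least 3 pairs required")
  d <- after - before
  if (method == "t") {
    ht <- stats::t.test(after, before, paired = TRUE)
    return(list(p_value = unname(ht$p.value),
                statistic = unname(ht$statistic),
                method = "paired t-test", n = n))
  }
  if (all(d == 0))
    return(list(p_value = 1, statistic = 0,
                method = "Wilcoxon signed-rank (exact)", n = n))
  nz <- d[d != 0]   # zero differences dropped, as is conventional
  if (length(nz) <= 25L) {
    ex <- signed_rank_exact(nz)
    list(p_value = ex$p_value, statistic = ex$statistic,
         method = "Wilcoxon signed-rank (exact)", n = n)
  } else {
    ht <- suppressWarnings(
      stats::wilcox.test(after, before, paired = TRUE, exact = FALSE,
                         correct = TRUE))
    list(p_value = unname(ht$p.value), statistic = unname(ht$statistic),
         method = "Wilcoxon signed-rank (normal approximation)", n = n)
  }
}

# Exact two-sided signed-rank p-value for nonzero differences d,
# supporting tied |d| via midranks: the null distribution of
# V = sum of (mid)ranks of positive differences is built by dynamic
# programming over doubled ranks (so midranks stay integral).
signed_rank_exact <- function(d) {
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  r2 <- as.integer(round(2 * r))
  tot <- sum(r2)
  dist <- numeric(tot + 1L)
  dist[1L] <- 1
  for (ri in r2) {
    shifted <- c(numeric(ri), dist[seq_len(tot + 1L - ri)])
    dist <- (dist + shifted) / 2
  }
  v2 <- as.integer(round(2 * v))
  p_le <- sum(dist[seq_len(v2 + 1L)])
  p_ge <- sum(dist[seq.int(v2 + 1L, tot + 1L)])
  list(p_value = min(1, 2 * min(p_le, p_ge)), statistic = v)
}

#' Cohort summary record
#'
#' @param label text label.
#' @param n_positive,n_total counts (optional; give `values` instead or
#'   as well).
#' @param values numeric measurements for mean +/- SEM (optional).
#' @return list of class `cohort_summary` with `label`, `n_total`,
#'   `n_positive`, `pct`, `mean`, `sem`.
#' @export
cohort_summary <- function(label, n_positive = NA_integer_,
                           n_total = NA_integer_, values = NULL) {
  pct <- if (is.finite(n_positive) && is.finite(n_total))
    proportion_pct(n_positive, n_total) else NA_real_
  ms <- if (!is.null(values)) mean_sem(values)
        else list(mean = NA_real_, sem = NA_real_)
  structure(list(label = label, n_total = n_total,
                 n_positive = n_positive, pct = pct,
                 mean = ms$mean, sem = ms$sem),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("%s: %s/%s (%s%%), mean %s +/- %s SEM\n", x$label,
              format(x$n_positive), format(x$n_total), format(x$pct),
              format(signif(x$mean, 3)), format(signif(x$sem, 3))))
  invisible(x)
}
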