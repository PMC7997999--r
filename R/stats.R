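# Exact two-sided rank-sum p-value by complete enumeration of which ranks
# belong to sample A, using mid-ranks for ties. Feasible for combined n
# up to ~20 (choose(20, 10) = 184756 configurations).
rank_sum_exact <- function(a, b) {
  na <- length(a)
  r <- rank(c(a, b))
  w_obs <- sum(r[seq_len(na)])
  combos <- utils::combn(length(r), na)
  w_null <- colSums(matrix(r[combos], nrow = na))
  eps <- 1e-9
  p_low <- mean(w_null <= w_obs + eps)
  p_high <- mean(w_null >= w_obs - eps)
  min(1, 2 * min(p_low, p_high))
}

# Normal approximation with mid-rank tie correction and continuity
# correction (the convention of the classical large-sample rank-sum test).
rank_sum_normal <- function(a, b) {
  na <- length(a); nb <- length(b); n <- na + nb
  r <- rank(c(a, b))
  w <- sum(r[seq_len(na)]) - na * (na + 1) / 2   # Mann-Whitney U of sample a
  mu <- na * nb / 2
  ties <- table(r)
  sigma2 <- (na * nb / 12) * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(1)
  z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-abs(z)))
}

#' Unpaired two-sided rank-sum (Mann-Whitney/Wilcoxon) test
#'
#' For combined sample sizes up to `exact_max_n` the two-sided p-value is
#' computed by complete enumeration of rank assignments using mid-ranks, so
#' it remains exact in the presence of ties (which pixel-quantized
#' descriptors produce in abundance); larger samples use the normal
#' approximation with tie and continuity corrections. The reported statistic
#' is the Mann-Whitney U of the first sample.
#'
#' @param a,b Numeric samples (non-empty).
#' @param exact_max_n Largest combined size for the exact path (default 20).
#' @return A list: `statistic` (U), `p_value`, `method`.
#' @export
rank_sum_test <- function(a, b, exact_max_n = 20) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) == 0 || length(b) == 0) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  na <- length(a); nb <- length(b)
  r <- rank(c(a, b))
  u <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  if (na + nb <= exact_max_n) {
    list(statistic = u, p_value = rank_sum_exact(a, b),
         method = "exact rank-sum enumeration (mid-ranks)")
  } else {
    list(statistic = u, p_value = rank_sum_normal(a, b),
         method = "normal approximation with tie correction")
  }
}

#' Compare two groups with the tests used for trajectory populations
#'
#' Applies either the unpaired two-sided rank-sum test (the terms
#' Mann-Whitney and Wilcoxon both denote this unpaired test here) via
#' [rank_sum_test()], or Welch's unpaired two-sided t-test via
#' [stats::t.test()].
#'
#' @param a,b Numeric samples.
#' @param test `"mann_whitney"` (default) or `"t_test"`.
#' @param labels Character pair of group labels.
#' @return A list of class `group_comparison`: labels, per-group `n`,
#'   `mean`, `sd`, the `test` name, `statistic` and two-sided `p_value`,
#'   and `direction` (sign of `mean(b) - mean(a)`).
#' @export
compare_groups <- function(a, b, test = c("mann_whitney", "t_test"),
                           labels = c("A", "B")) {
  test <- match.arg(test)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) == 0 || length(b) == 0) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  if (test == "t_test") {
    if (length(a) < 2 || length(b) < 2) {
      stop("t-test requires at least 2 observations per group", call. = FALSE)
    }
    ht <- stats::t.test(a, b, alternative = "two.sided")
    statistic <- unname(ht$statistic)
    p <- ht$p.value
  } else {
    rs <- rank_sum_test(a, b)
    statistic <- rs$statistic
    p <- rs$p_value
  }
  structure(
    list(labels = labels,
         n = c(length(a), length(b)),
         mean = c(mean(a), mean(b)),
         sd = c(stats::sd(a), stats::sd(b)),
         test = test, statistic = statistic, p_value = p,
         direction = sign(mean(b) - mean(a))),
    class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf(
    "%s vs %s (%s): n = %d/%d, mean = %.4g/%.4g, statistic = %.4g, two-sided p = %.3g\n",
    x$labels[1], x$labels[2], x$test, x$n[1], x$n[2], x$mean[1], x$mean[2],
    x$statistic, x$p_value))
  invisible(x)
}
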