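# Exact Wilcoxon signed-rank test for small paired samples.
#
# The statistic W is the smaller of the positive-rank and negative-rank sums
# after discarding zero differences and mid-ranking ties. Significance follows
# the critical-value convention of classic tables: the comparison is
# significant at two-tailed alpha when W <= W_c, where W_c is the largest w
# whose two-tailed exact probability 2 * P(W+ <= w) does not exceed alpha
# (computed by exhaustive enumeration over the 2^N equiprobable sign
# assignments of the ranks). The exact p-value uses the same enumeration on
# the observed, possibly tied, ranks; above `exact_max` pairs a normal
# approximation with tie correction takes over.

# Distribution of the positive-rank sum W+ for given ranks under the null
# (each rank independently positive or negative with probability 1/2).
# Ranks may be half-integers (mid-ranks); internally doubled to integers.
# Returns P(W+ <= w) as a function over the doubled scale.
signed_rank_cdf <- function(ranks) {
  r2 <- as.integer(round(2 * ranks))
  total <- sum(r2)
  # dynamic-programming convolution, equivalent to full 2^N enumeration
  counts <- numeric(total + 1L)  # counts[w+1] = #assignments with sum w
  counts[1L] <- 1
  for (r in r2) {
    shifted <- c(rep(0, r), counts[seq_len(total + 1L - r)])
    counts <- counts + shifted
  }
  cum <- cumsum(counts) / sum(counts)
  function(w) {
    # w on the original (possibly half-integer) scale
    idx <- floor(2 * w + 1e-9) + 1L
    idx <- pmin(pmax(idx, 0L), total + 1L)
    ifelse(idx == 0L, 0, cum[idx])
  }
}

#' Exact critical value for the Wilcoxon signed-rank test
#'
#' The largest statistic w such that the exact two-tailed probability
#' 2 * P(W+ <= w) is at most `alpha`, for untied ranks 1..N. `NA` when no w
#' qualifies (N too small for significance at `alpha`).
#'
#' @param n effective number of pairs (after zero-difference removal).
#' @param alpha two-tailed significance level (default 0.05).
#' @return Integer critical value, or NA.
#' @export
wilcoxon_critical_value <- function(n, alpha = 0.05) {
  stopifnot(n >= 0L)
  if (n == 0L) return(NA_integer_)
  cdf <- signed_rank_cdf(seq_len(n))
  w_max <- n * (n + 1L) / 2L
  ok <- which(2 * cdf(0:w_max) <= alpha + 1e-12)
  if (length(ok) == 0L) NA_integer_ else as.integer(max(ok) - 1L)
}

#' Wilcoxon signed-rank test
#'
#' Paired two-sided test. Differences `a - b` equal to zero are discarded
#' (reducing the effective N); absolute differences are ranked with mid-ranks
#' for ties; W is the smaller of the positive- and negative-rank sums. The
#' test is exact (full sign-assignment enumeration) for N <= `exact_max` and
#' uses a tie-corrected normal approximation above.
#'
#' @param a,b paired numeric vectors of equal length.
#' @param alpha two-tailed significance level (default 0.05).
#' @param exact_max largest N for which the exact distribution is used.
#' @return Object of class `wilcoxon_sr`: list with `W`, `N`, `W_c`,
#'   `significant` and `exact_p`. When all differences are zero, `W` and
#'   `exact_p` are NA and the result is not significant.
#' @export
wilcoxon_signed_rank <- function(a, b, alpha = 0.05, exact_max = 25L) {
  stopifnot(length(a) == length(b), length(a) >= 1L)
  d <- as.numeric(a) - as.numeric(b)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    return(structure(list(W = NA_real_, N = 0L, W_c = NA_integer_,
                          significant = FALSE, exact_p = NA_real_),
                     class = "wilcoxon_sr"))
  }
  r <- rank(abs(d))
  w_plus <- sum(r[d > 0])
  w_minus <- sum(r[d < 0])
  W <- min(w_plus, w_minus)
  W_c <- wilcoxon_critical_value(n, alpha)
  if (n <= exact_max) {
    cdf <- signed_rank_cdf(r)
    p <- min(1, 2 * cdf(W))
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(ties^3 - ties) / 48
    z <- (W - mu) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(z))
  }
  structure(list(W = W, N = n, W_c = W_c,
                 significant = !is.na(W_c) && W <= W_c,
                 exact_p = p),
            class = "wilcoxon_sr")
}

#' @export
print.wilcoxon_sr <- function(x, ...) {
  cat("Wilcoxon signed-rank test\n")
  cat(sprintf("  W = %s, N = %d, W_c(0.05 two-tailed) = %s\n",
              format(x$W), x$N, format(x$W_c)))
  cat(sprintf("  exact p = %s; %ssignificant\n", format(x$exact_p),
              if (isTRUE(x$significant)) "" else "not "))
  invisible(x)
}
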