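#' Per-group case and control frequencies
#'
#' @param n_h,n_s Group control and case counts.
#' @param N_h,N_s Cohort totals (both positive).
#' @return List with `p_h = n_h / N_h` and `p_s = n_s / N_s`.
#' @export
gv_frequencies <- function(n_h, n_s, N_h, N_s) {
  if (any(N_h <= 0) || any(N_s <= 0))
    stop("cohort totals must be positive")
  if (any(n_h < 0) || any(n_s < 0) || any(n_h > N_h) || any(n_s > N_s))
    stop("group counts must lie in [0, cohort total]")
  list(p_h = n_h / N_h, p_s = n_s / N_s)
}

#' Odds ratio of a genetic-vector group
#'
#' The count form \eqn{OR = n_s (N_h - n_h) / (n_h (N_s - n_s))}, identical
#' to the frequency form \eqn{[p_s/(1-p_s)] / [p_h/(1-p_h)]}. Groups with
#' `n_h == 0` or `n_s == 0` ("zero GVs") have no finite odds ratio and
#' return `NA`; see [classify_zero()].
#'
#' @param n_h,n_s Group control and case counts (vectorized).
#' @param N_h,N_s Cohort totals.
#' @return Numeric odds ratio(s); `NA` for zero GVs, `Inf` when
#'   `n_s == N_s` with `n_h < N_h`.
#' @export
odds_ratio <- function(n_h, n_s, N_h, N_s) {
  gv_frequencies(n_h, n_s, N_h, N_s)  # validates bounds
  out <- n_s * (N_h - n_h) / (n_h * (N_s - n_s))
  out[n_h == 0 | n_s == 0] <- NA_real_
  out
}

#' Classify zero genetic-vector groups
#'
#' A group populated only by controls is "solely healthy"; only by cases,
#' "solely sick". Both kinds are excluded from odds-ratio screening and
#' analysed separately via [zero_gv_matrices()].
#'
#' @param n_h,n_s Group control and case counts (vectorized).
#' @return Character vector: `"none"`, `"solely_healthy"` or `"solely_sick"`.
#' @export
classify_zero <- function(n_h, n_s) {
  if (any(n_h < 0) || any(n_s < 0) || any(n_h + n_s < 1))
    stop("each group needs nonnegative counts and at least one individual")
  ifelse(n_h == 0, "solely_sick",
         ifelse(n_s == 0, "solely_healthy", "none"))
}

#' Exact distribution of the randomized odds ratio
#'
#' For a group of fixed size `n_t` drawn from a cohort of `N_h` controls and
#' `N_s` cases, the number of cases `k` in the group follows the
#' hypergeometric law of Fisher's exact test,
#' \deqn{p(k) = \binom{N_s}{k} \binom{N_h}{n_t - k} / \binom{N_h+N_s}{n_t},}
#' and each `k` maps to the odds ratio
#' \deqn{OR(k) = k (N_h - n_t + k) / ((n_t - k)(N_s - k)),}
#' which is 0 at the all-control edge and infinite at the all-case edge.
#' This discrete distribution is the exact null of the group's observed
#' odds ratio and is the basis for the threshold and tail-probability
#' criteria.
#'
#' @param N_h,N_s Cohort control and case totals.
#' @param n_t Group size, `1 <= n_t <= N_h + N_s`.
#' @return An object of class `or_dist` with elements `n_k` (admissible case
#'   counts), `or` (strictly increasing odds ratios, possibly `Inf` at the
#'   upper edge), `p` (probabilities summing to 1) and the parameters.
#' @export
or_distribution <- function(N_h, N_s, n_t) {
  if (length(N_h) != 1L || length(N_s) != 1L || length(n_t) != 1L)
    stop("parameters must be scalars")
  if (N_h < 0 || N_s < 0 || N_h + N_s < 1)
    stop("cohort totals must be nonnegative with at least one individual")
  if (n_t < 1 || n_t > N_h + N_s)
    stop("'n_t' must satisfy 1 <= n_t <= N_h + N_s")
  k <- max(0, n_t - N_h):min(n_t, N_s)
  p <- stats::dhyper(k, m = N_s, n = N_h, k = n_t)
  num <- k * (N_h - n_t + k)
  den <- (n_t - k) * (N_s - k)
  or <- ifelse(den == 0, Inf, num / den)
  structure(list(n_k = k, or = or, p = p,
                 N_h = as.integer(N_h), N_s = as.integer(N_s),
                 n_t = as.integer(n_t)),
            class = "or_dist")
}

#' @export
print.or_dist <- function(x, ...) {
  cat(sprintf(
    "Randomized-OR distribution: N_h = %d, N_s = %d, n_t = %d (%d support points)\n",
    x$N_h, x$N_s, x$n_t, length(x$n_k)))
  if (x$n_t >= 2)
    cat(sprintf("  mean OR = %.4f, P(OR = Inf) = %.3g\n",
                mean_or(x), sum(x$p[!is.finite(x$or)])))
  invisible(x)
}

#' Mean and variance of the randomized odds ratio
#'
#' Moments are taken as the literal sum over `k = 1 .. n_t - 1` with raw
#' hypergeometric weights: the `k = 0` term would contribute zero and the
#' all-case endpoint, whose odds ratio is infinite, is excluded so the
#' moments stay finite. The weights are not renormalized after the
#' exclusion.
#'
#' @param dist An `or_dist` with `n_t >= 2`.
#' @return The mean (resp. variance) of the randomized odds ratio.
#' @export
mean_or <- function(dist) {
  or_moment(dist, 1L)
}

#' @rdname mean_or
#' @export
var_or <- function(dist) {
  or_moment(dist, 2L) - or_moment(dist, 1L)^2
}

or_moment <- function(dist, order) {
  stopifnot(inherits(dist, "or_dist"))
  if (dist$n_t < 2)
    stop("moments require n_t >= 2 (at least one interior support point)")
  use <- dist$n_k >= 1L & dist$n_k <= dist$n_t - 1L
  sum(dist$or[use]^order * dist$p[use])
}

#' Odds-ratio fluctuation thresholds at a given accuracy
#'
#' Finds the narrowest interval of support odds ratios outside which the
#' randomized odds ratio falls with probability at most `alpha` per tail:
#' the upper threshold is the smallest support value `u` with
#' \eqn{\sum_{OR > u} p(OR) \le \alpha} (ties accepted), and the lower
#' threshold mirrors it on the lower tail. Because the support is discrete
#' the achieved tail masses are at most, and generally below, `alpha`; the
#' infinite-OR endpoint is excluded from the upper tail so the threshold is
#' finite, and its mass is reported separately.
#'
#' @param dist An `or_dist`.
#' @param alpha Tail accuracy in (0, 1); conventionally 0.05.
#' @return An object of class `or_thresholds`: `or_lower_tr`, `or_upper_tr`,
#'   `alpha`, achieved tail masses, the excluded infinite-endpoint mass
#'   `p_inf`, and degeneracy flags set when only the empty tail meets
#'   `alpha` (thresholds then sit at the support extremes with achieved
#'   mass 0).
#' @export
or_thresholds <- function(dist, alpha = 0.05) {
  stopifnot(inherits(dist, "or_dist"))
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("'alpha' must be a single number in (0, 1)")
  fin <- is.finite(dist$or)
  or <- dist$or[fin]
  p <- dist$p[fin]
  p_inf <- sum(dist$p[!fin])
  # upper: tail mass strictly above each candidate, in increasing order
  up_tail <- rev(cumsum(rev(p))) - p        # P(OR > or_i) among finite support
  i_up <- which(up_tail <= alpha)[1L]       # smallest u works first
  lo_tail <- cumsum(p) - p                  # P(OR < or_i)
  i_lo <- max(which(lo_tail <= alpha))      # largest v
  structure(list(
    or_lower_tr = or[i_lo], or_upper_tr = or[i_up], alpha = alpha,
    achieved_alpha_lower = lo_tail[i_lo], achieved_alpha_upper = up_tail[i_up],
    p_inf = p_inf,
    degenerate_upper = i_up == length(or) && up_tail[i_up] == 0 &&
      (length(or) < 2L || up_tail[length(or) - 1L] > alpha),
    degenerate_lower = i_lo == 1L && lo_tail[1L] == 0 &&
      (length(or) < 2L || lo_tail[2L] > alpha)),
    class = "or_thresholds")
}

#' @export
print.or_thresholds <- function(x, ...) {
  cat(sprintf(
    "OR thresholds at alpha = %g: lower %.4g (tail %.4g), upper %.4g (tail %.4g)\n",
    x$alpha, x$or_lower_tr, x$achieved_alpha_lower,
    x$or_upper_tr, x$achieved_alpha_upper))
  if (x$degenerate_upper || x$degenerate_lower)
    cat("  note: support too coarse for a nonempty tail at this alpha\n")
  invisible(x)
}

#' Tail probability of the randomized odds ratio beyond an observed value
#'
#' The exact confidence measure for an observed group odds ratio: the
#' probability that the randomized odds ratio strictly exceeds (`side =
#' "upper"`) or falls strictly below (`side = "lower"`) the observed value.
#' The infinite-OR endpoint is excluded from the upper sum unless
#' `include_inf = TRUE`; its mass is available as `sum(dist$p[!is.finite(dist$or)])`.
#'
#' @param dist An `or_dist`.
#' @param or_exp Observed (finite) odds ratio.
#' @param side `"upper"` or `"lower"`.
#' @param include_inf Count the all-case endpoint in the upper tail.
#' @return A probability.
#' @export
tail_prob <- function(dist, or_exp, side = c("upper", "lower"),
                      include_inf = FALSE) {
  stopifnot(inherits(dist, "or_dist"))
  if (!is.finite(or_exp)) stop("'or_exp' must be finite")
  side <- match.arg(side)
  if (side == "upper") {
    use <- dist$or > or_exp & (include_inf | is.finite(dist$or))
  } else {
    use <- dist$or < or_exp
  }
  sum(dist$p[use])
}

#' Per-group exact statistics for a genetic-vector table
#'
#' Computes, for every group: frequencies, observed odds ratio, zero-GV
#' status, and — from the group's randomized-OR distribution at the given
#' cohort totals — the mean randomized OR, the lower/upper `alpha`
#' fluctuation thresholds, and the exact tail probabilities beyond the
#' observed odds ratio. Zero GVs get `NA` odds ratios and tails; groups of
#' size 1 additionally get `NA` moments.
#'
#' @param table A `gv_table`.
#' @param alpha Tail accuracy for the thresholds.
#' @param N_h,N_s Cohort totals to condition on; default the table's own.
#'   Pass the post-filter totals of a common, zero-free subset when
#'   screening that subset.
#' @return A data.frame with one row per group: `gv`, `n_h`, `n_s`, `p_h`,
#'   `p_s`, `or`, `zero`, `mean_rand_or`, `or_lower_tr`, `or_upper_tr`,
#'   `p_upper`, `p_lower`.
#' @export
gv_stats <- function(table, alpha = 0.05, N_h = table$N_h, N_s = table$N_s) {
  stopifnot(inherits(table, "gv_table"))
  n_h <- table$n_h; n_s <- table$n_s
  fr <- gv_frequencies(n_h, n_s, N_h, N_s)
  or <- odds_ratio(n_h, n_s, N_h, N_s)
  n_t <- n_h + n_s
  res <- data.frame(gv = rownames(table$states), n_h = n_h, n_s = n_s,
                    p_h = fr$p_h, p_s = fr$p_s, or = or,
                    zero = classify_zero(n_h, n_s),
                    mean_rand_or = NA_real_, or_lower_tr = NA_real_,
                    or_upper_tr = NA_real_, p_upper = NA_real_,
                    p_lower = NA_real_, stringsAsFactors = FALSE)
  # distributions depend on n_t only; compute once per distinct size
  for (nt in unique(n_t)) {
    d <- or_distribution(N_h, N_s, nt)
    thr <- or_thresholds(d, alpha)
    rows <- which(n_t == nt)
    if (nt >= 2) res$mean_rand_or[rows] <- mean_or(d)
    res$or_lower_tr[rows] <- thr$or_lower_tr
    res$or_upper_tr[rows] <- thr$or_upper_tr
    for (i in rows) {
      if (is.na(or[i]) || !is.finite(or[i])) next
      res$p_upper[i] <- tail_prob(d, or[i], "upper")
      res$p_lower[i] <- tail_prob(d, or[i], "lower")
    }
  }
  res
}
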