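#' Weighted pool-adjacent-violators monotonization
#'
#' Computes the nondecreasing sequence closest to `p` in weighted least
#' squares, which for binomial proportions weighted by their trial counts
#' is also the maximum-likelihood monotone fit. Adjacent violators are
#' pooled into blocks whose fitted value is the weighted mean of the
#' pooled observations, so the weighted mean is preserved within each
#' block and the output stays in `[0, 1]` whenever the input does.
#'
#' @param p Numeric vector of proportions in `[0, 1]`.
#' @param w Positive weights of the same length (typically per-`d` trial
#'   counts); defaults to equal weights.
#' @return Monotone nondecreasing numeric vector of the same length.
#' @examples
#' pav_monotonize(c(0.2, 0.6, 0.4))          # -> 0.2, 0.5, 0.5
#' pav_monotonize(c(1, 0), w = c(1, 3))      # -> 0.25, 0.25
#' @export
pav_monotonize <- function(p, w = rep(1, length(p))) {
  n <- length(p)
  if (length(w) != n)
    stop("`p` and `w` must have the same length")
  if (any(!is.finite(w)) || any(w <= 0))
    stop("weights must be positive and finite")
  if (any(!is.finite(p)) || any(p < -1e-12) || any(p > 1 + 1e-12))
    stop("`p` must lie in [0, 1]")
  if (n <= 1L) return(as.numeric(p))

  # stack of blocks: value, weight, size
  val <- numeric(n); wt <- numeric(n); sz <- integer(n)
  top <- 0L
  for (i in seq_len(n)) {
    top <- top + 1L
    val[top] <- p[i]; wt[top] <- w[i]; sz[top] <- 1L
    while (top > 1L && val[top - 1L] > val[top]) {
      val[top - 1L] <- (wt[top - 1L] * val[top - 1L] + wt[top] * val[top]) /
        (wt[top - 1L] + wt[top])
      wt[top - 1L] <- wt[top - 1L] + wt[top]
      sz[top - 1L] <- sz[top - 1L] + sz[top]
      top <- top - 1L
    }
  }
  rep(val[seq_len(top)], times = sz[seq_len(top)])
}

#' Modified Spearman-Karber mean of a monotone psychometric function
#'
#' Treats the increments of a monotone nondecreasing function as a
#' discrete probability distribution over the `d` axis and returns its
#' mean. The observed grid is augmented with anchor points at which the
#' function is fixed to exactly 0 (below the grid) and 1 (above it), so
#' with augmented grid `a_0 < d_1 < ... < d_k < a_1` and proportions
#' `0, p_1, ..., p_k, 1` the estimate is
#' `sum_i (p_{i+1} - p_i) (d_i + d_{i+1}) / 2`.
#'
#' @param d_values Increasing numeric grid in ms.
#' @param p Monotone nondecreasing proportions on that grid (monotonize
#'   first with [pav_monotonize()]; non-monotone input is an error).
#' @param anchors Length-2 numeric vector `(a_lo, a_hi)` with
#'   `a_lo < min(d_values)` and `a_hi > max(d_values)`.
#' @return The Spearman-Karber mean in ms.
#' @examples
#' d <- seq(-50, 50, 10)
#' sk_mean(d, as.numeric(d >= 20), anchors = c(-60, 60))  # jump midpoint 15
#' @export
sk_mean <- function(d_values, p, anchors) {
  d_values <- as.numeric(d_values)
  if (any(diff(d_values) <= 0))
    stop("`d_values` must be strictly increasing")
  if (length(p) != length(d_values))
    stop("`p` must align with `d_values`")
  if (any(diff(p) < -1e-9))
    stop("`p` is not monotone nondecreasing; monotonize first")
  if (length(anchors) != 2L || anchors[1] >= min(d_values) ||
      anchors[2] <= max(d_values))
    stop("`anchors` must satisfy anchors[1] < min(d) and anchors[2] > max(d)")
  dd <- c(anchors[1], d_values, anchors[2])
  pp <- c(0, pmin(pmax(p, 0), 1), 1)
  sum(diff(pp) * (utils::head(dd, -1L) + utils::tail(dd, -1L)) / 2)
}

#' Nonparametric central-threshold estimate
#'
#' Estimates the central threshold of the ternary-response task without
#' distributional assumptions: the right and left psychometric functions
#' are monotonized separately by weighted pool-adjacent-violators (weights
#' = per-`d` trial totals), the Spearman-Karber mean of each is computed
#' with anchored endpoints, and the threshold is half the difference of
#' the two means. The midpoint of the means estimates the point of
#' subjective simultaneity. Because the latency difference contributes
#' equally to both function locations, the half-distance is free of
#' peripheral latencies and reflects the central comparator alone.
#'
#' @param counts A `condition_counts` object.
#' @param anchors Length-2 vector of `d` values where the functions are
#'   fixed to 0 and 1; defaults to one grid step beyond the extremes.
#' @return An object of class `sk_estimate`: list with `condition`,
#'   `mean_R`, `mean_L`, `threshold = (mean_R - mean_L) / 2`,
#'   `midpoint = (mean_R + mean_L) / 2`, and `anchors`.
#' @examples
#' obs <- observer_spec(mu = 30, c_su = 50, seed = 11)
#' cc <- simulate_counts(obs, seq(-200, 200, 25), n_per_d = 400)
#' sk_threshold(cc, anchors = c(-225, 225))
#' @export
sk_threshold <- function(counts, anchors = NULL) {
  stopifnot(inherits(counts, "condition_counts"))
  if (is.null(anchors)) anchors <- default_anchors(counts$d_values)
  ef <- empirical_functions(counts)
  pR <- pav_monotonize(ef$F_R, ef$n)
  pL <- pav_monotonize(ef$F_L, ef$n)
  if (any(pR > pL + 1e-9))
    warning("monotonized F_R exceeds F_L at some d; ",
            "threshold may be distorted at this sample size")
  mean_R <- sk_mean(ef$d, pR, anchors)
  mean_L <- sk_mean(ef$d, pL, anchors)
  structure(
    list(condition = counts$condition,
         mean_R = mean_R, mean_L = mean_L,
         threshold = (mean_R - mean_L) / 2,
         midpoint = (mean_R + mean_L) / 2,
         anchors = anchors),
    class = "sk_estimate")
}

#' @export
print.sk_estimate <- function(x, ...) {
  cat(sprintf("Spearman-Karber estimate (%s)\n", x$condition))
  cat(sprintf("  E(F_R) = %.1f ms, E(F_L) = %.1f ms\n", x$mean_R, x$mean_L))
  cat(sprintf("  central threshold = %.1f ms, midpoint (PSS) = %.1f ms\n",
              x$threshold, x$midpoint))
  cat(sprintf("  anchors [%g, %g] ms\n", x$anchors[1], x$anchors[2]))
  invisible(x)
}
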