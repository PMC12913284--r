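# Build a threshold-estimator closure operating on a 3 x k count matrix
# (rows xy, si, yx). The parametric extractors warm-start every refit at
# the full-data fit, with a single optimizer run per resample.
make_estimator <- function(counts, estimator, anchors, restarts, seed) {
  k <- length(counts$d_values)
  d <- counts$d_values
  if (estimator == "sk") {
    function(m) {
      n <- colSums(m)
      pR <- pav_monotonize(m[1L, ] / n, n)
      pL <- pav_monotonize((m[1L, ] + m[2L, ]) / n, n)
      (sk_mean(d, pR, anchors) - sk_mean(d, pL, anchors)) / 2
    }
  } else {
    fit0 <- fit_two_threshold(counts, restarts = restarts, seed = seed,
                              anchors = anchors)
    init <- unname(coef(fit0)[c("mu", "sigma", "c_su", "c_o", "gamma")])
    field <- if (estimator == "ttm_c_su") "c_su" else "c_o"
    f <- function(m) {
      cc <- condition_counts(counts$condition, d, m[1L, ], m[2L, ], m[3L, ])
      fit <- fit_two_threshold(cc, restarts = 1L, anchors = anchors,
                               init = init)
      fit[[field]]
    }
    attr(f, "full_fit") <- fit0
    f
  }
}

# Multinomial resampling within each d cell, holding per-cell n fixed.
# Returns a function(b) giving the b-th resampled 3 x k count matrix;
# all B draws are generated up front for speed.
make_resampler <- function(counts, B) {
  k <- length(counts$d_values)
  n <- counts$n_xy + counts$n_si + counts$n_yx
  draws <- vector("list", k)
  for (i in seq_len(k)) {
    p <- c(counts$n_xy[i], counts$n_si[i], counts$n_yx[i]) / n[i]
    draws[[i]] <- stats::rmultinom(B, n[i], p)
  }
  function(b) vapply(draws, function(m) m[, b], numeric(3L))
}

observed_matrix <- function(counts) {
  rbind(counts$n_xy, counts$n_si, counts$n_yx)
}

#' Percentile-bootstrap confidence interval for a central threshold
#'
#' Resamples trials within every `d` cell (multinomial draws with the
#' observed cell proportions and the observed cell size), re-estimates
#' the threshold on each of `B` resamples, and returns the 2.5% and 97.5%
#' order statistics of the bootstrap distribution as the 95% confidence
#' interval. Deterministic given `seed`.
#'
#' @param counts A `condition_counts` object.
#' @param estimator `"sk"` (nonparametric Spearman-Karber threshold),
#'   `"ttm_c_su"` or `"ttm_c_o"` (successiveness / order threshold of the
#'   refitted two-threshold model).
#' @param B Number of bootstrap samples (default 1000).
#' @param seed Integer seed.
#' @param anchors Spearman-Karber anchors; default one grid step beyond
#'   the grid.
#' @param level Confidence level (default 0.95).
#' @param restarts Optimizer restarts for the initial parametric fit;
#'   bootstrap refits warm-start at that fit.
#' @param retry_cap Resamples on which the estimator fails are redrawn up
#'   to this many times each; the total retry count is reported.
#' @return An object of class `bootstrap_result`: `point`, `ci_lo`,
#'   `ci_hi`, `B`, `seed`, `estimator`, `level`, `n_retries`, and the
#'   bootstrap `draws`.
#' @examples
#' obs <- observer_spec(c_su = 50, seed = 5)
#' cc <- simulate_counts(obs, seq(-200, 200, 25), n_per_d = 200)
#' bootstrap_threshold(cc, "sk", B = 200, seed = 1, anchors = c(-225, 225))
#' @export
bootstrap_threshold <- function(counts, estimator = c("sk", "ttm_c_su", "ttm_c_o"),
                                B = 1000L, seed = 1L, anchors = NULL,
                                level = 0.95, restarts = 20L,
                                retry_cap = 10L) {
  estimator <- match.arg(estimator)
  stopifnot(inherits(counts, "condition_counts"))
  if (is.null(anchors)) anchors <- default_anchors(counts$d_values)

  old <- get_rng_state(); on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)

  est <- make_estimator(counts, estimator, anchors, restarts, seed)
  point <- est(observed_matrix(counts))
  resample <- make_resampler(counts, B)

  draws <- numeric(B)
  n_retries <- 0L
  k <- length(counts$d_values)
  n_cell <- counts$n_xy + counts$n_si + counts$n_yx
  p_cell <- lapply(seq_len(k), function(i)
    c(counts$n_xy[i], counts$n_si[i], counts$n_yx[i]) / n_cell[i])
  for (b in seq_len(B)) {
    m <- resample(b)
    val <- tryCatch(est(m), error = function(e) NULL)
    tries <- 0L
    while (is.null(val) && tries < retry_cap) {
      tries <- tries + 1L
      m <- vapply(seq_len(k), function(i)
        stats::rmultinom(1L, n_cell[i], p_cell[[i]])[, 1L], numeric(3L))
      val <- tryCatch(est(m), error = function(e) NULL)
    }
    n_retries <- n_retries + tries
    if (is.null(val))
      stop("estimator failed on a bootstrap resample after ", retry_cap,
           " redraws")
    draws[b] <- val
  }

  ci <- percentile_ci(draws, level)
  structure(
    list(point = point, ci_lo = ci[1], ci_hi = ci[2], B = as.integer(B),
         seed = as.integer(seed), estimator = estimator, level = level,
         condition = counts$condition, n_retries = n_retries,
         draws = draws),
    class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("Bootstrap threshold (%s, %s): %.1f ms, %g%% CI [%.1f, %.1f]\n",
              x$condition, x$estimator, x$point, 100 * x$level,
              x$ci_lo, x$ci_hi))
  cat(sprintf("  B = %d, seed = %d\n", x$B, x$seed))
  invisible(x)
}

#' Bootstrap test of threshold invariance between two conditions
#'
#' Bootstraps the difference between the central-threshold estimates of
#' two conditions, resampling both conditions independently on every
#' iteration, and declares threshold invariance violated exactly when the
#' percentile CI of the difference excludes zero.
#'
#' @inheritParams bootstrap_threshold
#' @param counts_a,counts_b `condition_counts` for the two conditions.
#' @return An object of class `invariance_result`: condition labels, the
#'   estimator, a `bootstrap_result` for the difference (`a - b`), and
#'   the `violated` flag.
#' @export
invariance_test <- function(counts_a, counts_b,
                            estimator = c("sk", "ttm_c_su", "ttm_c_o"),
                            B = 1000L, seed = 1L, anchors = NULL,
                            level = 0.95, restarts = 20L,
                            retry_cap = 10L) {
  estimator <- match.arg(estimator)
  stopifnot(inherits(counts_a, "condition_counts"),
            inherits(counts_b, "condition_counts"))
  if (is.null(anchors))
    anchors <- default_anchors(c(counts_a$d_values, counts_b$d_values))

  old <- get_rng_state(); on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)

  est_a <- make_estimator(counts_a, estimator, anchors, restarts, seed)
  est_b <- make_estimator(counts_b, estimator, anchors, restarts, seed)
  point <- est_a(observed_matrix(counts_a)) - est_b(observed_matrix(counts_b))
  res_a <- make_resampler(counts_a, B)
  res_b <- make_resampler(counts_b, B)

  draws <- numeric(B)
  for (b in seq_len(B)) {
    va <- est_a(res_a(b))
    vb <- est_b(res_b(b))
    draws[b] <- va - vb
  }
  ci <- percentile_ci(draws, level)

  diff <- structure(
    list(point = point, ci_lo = ci[1], ci_hi = ci[2], B = as.integer(B),
         seed = as.integer(seed), estimator = estimator, level = level,
         condition = paste(counts_a$condition, "-", counts_b$condition),
         n_retries = 0L, draws = draws),
    class = "bootstrap_result")

  structure(
    list(condition_a = counts_a$condition, condition_b = counts_b$condition,
         estimator = estimator, diff = diff,
         violated = ci[1] > 0 || ci[2] < 0),
    class = "invariance_result")
}

#' @export
print.invariance_result <- function(x, ...) {
  cat(sprintf("Threshold invariance: %s vs %s (%s)\n",
              x$condition_a, x$condition_b, x$estimator))
  cat(sprintf("  difference %.1f ms, %g%% CI [%.1f, %.1f]\n",
              x$diff$point, 100 * x$diff$level, x$diff$ci_lo, x$diff$ci_hi))
  cat(sprintf("  invariance violated: %s\n", x$violated))
  invisible(x)
}

#' Threshold practice curve across session levels
#'
#' Partitions the sessions into consecutive practice levels (e.g. 20
#' sessions with `sessions_per_level = 5` give 4 levels), and estimates
#' the threshold with a bootstrap CI per level and condition.
#'
#' @param trials Cleaned trial data frame with a `session` column.
#' @param sessions_per_level Number of consecutive sessions per level.
#' @inheritParams bootstrap_threshold
#' @return A data frame with one row per level and condition: `level`,
#'   `sessions`, `condition`, `point`, `ci_lo`, `ci_hi`.
#' @export
practice_curve <- function(trials, sessions_per_level = 5L,
                           estimator = c("sk", "ttm_c_su", "ttm_c_o"),
                           B = 1000L, seed = 1L, anchors = NULL,
                           restarts = 20L) {
  estimator <- match.arg(estimator)
  trials <- validate_trials(trials)
  sessions <- sort(unique(trials$session))
  level_of <- ceiling(seq_along(sessions) / sessions_per_level)
  levels_map <- stats::setNames(level_of, sessions)
  d_values <- sort(unique(trials$d))
  if (is.null(anchors)) anchors <- default_anchors(d_values)

  rows <- list()
  for (lev in unique(level_of)) {
    in_level <- trials$session %in% sessions[level_of == lev]
    sub <- trials[in_level, , drop = FALSE]
    empty <- empty_cells_on_grid(sub, d_values)
    if (nrow(empty) > 0L)
      stop("practice level ", lev, " has empty cell(s): ",
           paste(sprintf("%s/d=%g", empty$condition, empty$d),
                 collapse = ", "))
    counts <- tabulate_counts(sub, d_values = d_values)
    for (cond in names(counts)) {
      bt <- bootstrap_threshold(counts[[cond]], estimator, B = B,
                                seed = seed + lev, anchors = anchors,
                                restarts = restarts)
      rows[[length(rows) + 1L]] <- data.frame(
        level = lev,
        sessions = paste(range(sessions[level_of == lev]), collapse = "-"),
        condition = cond, point = bt$point,
        ci_lo = bt$ci_lo, ci_hi = bt$ci_hi)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

empty_cells_on_grid <- function(trials, d_values) {
  tab <- table(factor(trials$condition),
               factor(trials$d, levels = d_values))
  idx <- which(tab == 0L, arr.ind = TRUE)
  data.frame(condition = rownames(tab)[idx[, 1L]],
             d = as.numeric(colnames(tab)[idx[, 2L]]))
}

#' Paired t test and within-subject effect size
#'
#' Two-sided paired t test of per-subject threshold estimates between two
#' conditions, with the within-subject effect size
#' `d_z = mean(a - b) / sd(a - b)` (sample SD, `n - 1` denominator).
#' If the differences have zero variance, `t` is reported as `0`
#' (zero mean) or signed infinity (nonzero mean).
#'
#' @param values_a,values_b Per-subject values (ms), equal length `n >= 2`.
#' @return An object of class `group_stats`: `n`, `mean_a`, `mean_b`,
#'   `t`, `df = n - 1`, two-sided `p`, and `d_z`.
#' @examples
#' paired_t_dz(c(143, 123, 111, 62, 59), c(14, 23, 37, 21, 28))
#' @export
paired_t_dz <- function(values_a, values_b) {
  if (length(values_a) != length(values_b))
    stop("`values_a` and `values_b` must have equal length")
  n <- length(values_a)
  if (n < 2L) stop("need at least 2 paired observations")
  diffs <- values_a - values_b
  sdd <- stats::sd(diffs)
  m <- mean(diffs)
  if (sdd == 0) {
    t_stat <- if (m == 0) 0 else sign(m) * Inf
    p <- if (m == 0) 1 else 0
    d_z <- t_stat / sqrt(n)
  } else {
    tt <- stats::t.test(values_a, values_b, paired = TRUE)
    t_stat <- unname(tt$statistic)
    p <- tt$p.value
    d_z <- m / sdd
  }
  structure(
    list(n = n, mean_a = mean(values_a), mean_b = mean(values_b),
         t = t_stat, df = n - 1L, p = p, d_z = d_z),
    class = "group_stats")
}

#' @export
print.group_stats <- function(x, ...) {
  cat(sprintf("Paired comparison, n = %d\n", x$n))
  cat(sprintf("  means: %.1f vs %.1f ms\n", x$mean_a, x$mean_b))
  cat(sprintf("  t(%d) = %.2f, p = %.3f, d_z = %.2f\n",
              x$df, x$t, x$p, x$d_z))
  invisible(x)
}
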