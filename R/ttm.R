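#' Response probabilities of the two-threshold observer model
#'
#' Closed-form trinomial response probabilities at stimulus-onset
#' difference `d` for an observer whose central arrival-time difference is
#' `DA = DL + d` with `DL ~ Normal(mu, sigma^2)`. Writing
#' `z(c) = pnorm((c - mu - d) / sigma)`,
#' \deqn{p_{si} = z(c_{su}) - z(-c_{su})}
#' \deqn{p_{xy} = 1 - z(c_o) + \gamma\,[(z(c_o) - z(c_{su})) + (z(-c_{su}) - z(-c_o))]}
#' and `p_yx = 1 - p_xy - p_si`. The three probabilities are nonnegative
#' and sum to one at every `d`.
#'
#' @param observer An [observer_spec()], or any list with elements `mu`,
#'   `sigma`, `c_su`, `c_o`, `gamma`.
#' @param d Numeric vector of stimulus-onset differences in ms.
#' @return A matrix with one row per `d` and columns `p_xy`, `p_si`,
#'   `p_yx`.
#' @examples
#' obs <- observer_spec(mu = 20, sigma = 60, c_su = 40, c_o = 120, gamma = 0.4)
#' ttm_probabilities(obs, d = c(-100, 0, 100))
#' @export
ttm_probabilities <- function(observer, d) {
  mu <- observer$mu; sigma <- observer$sigma
  c_su <- observer$c_su; c_o <- observer$c_o; gamma <- observer$gamma
  if (sigma <= 0) stop("`sigma` must be > 0")
  if (c_su < 0) stop("`c_su` must be >= 0")
  if (c_o < c_su) stop("`c_o` must be >= c_su")
  if (gamma < 0 || gamma > 1) stop("`gamma` must lie in [0, 1]")

  z <- function(cc) stats::pnorm((cc - mu - d) / sigma)
  p_si <- z(c_su) - z(-c_su)
  p_guess <- (z(c_o) - z(c_su)) + (z(-c_su) - z(-c_o))
  p_xy <- (1 - z(c_o)) + gamma * p_guess
  p_yx <- 1 - p_xy - p_si
  out <- cbind(p_xy = p_xy, p_si = p_si, p_yx = pmax(p_yx, 0))
  rownames(out) <- NULL
  out
}

# Negative multinomial log-likelihood of counts under the model, with a
# probability floor to keep boundary parameter values finite.
ttm_negloglik <- function(theta, d, n_xy, n_si, n_yx, eps = 1e-9) {
  pars <- list(mu = theta[1], sigma = exp(theta[2]),
               c_su = theta[3], c_o = theta[3] + theta[4],
               gamma = stats::plogis(theta[5]))
  p <- ttm_probabilities(pars, d)
  p <- pmax(p, eps)
  -sum(n_xy * log(p[, "p_xy"]) + n_si * log(p[, "p_si"]) +
         n_yx * log(p[, "p_yx"]))
}

# Multi-start initial values: data-driven base start plus Latin-hypercube
# jitter around it. Internal parameterization:
# theta = (mu, log sigma, c_su, delta = c_o - c_su, logit gamma).
ttm_starts <- function(counts, restarts, anchors) {
  ef <- empirical_functions(counts)
  sk <- tryCatch(sk_threshold(counts, anchors = anchors),
                 error = function(e) NULL)
  mu0 <- if (!is.null(sk)) -sk$midpoint else 0
  c0 <- if (!is.null(sk)) max(sk$threshold, 5) else diff(range(ef$d)) / 8
  # crude scale from the 25-75% span of the monotonized right function
  pR <- pav_monotonize(ef$F_R, ef$n)
  q25 <- suppressWarnings(min(ef$d[pR >= 0.25], na.rm = TRUE))
  q75 <- suppressWarnings(min(ef$d[pR >= 0.75], na.rm = TRUE))
  s0 <- (q75 - q25) / 1.349
  if (!is.finite(s0) || s0 <= 0) s0 <- diff(range(ef$d)) / 6

  base <- c(mu0, log(s0), c0, 0, 0)
  starts <- list(base, c(mu0, log(s0), c0 * 0.6, c0 * 0.8, 0))
  n_extra <- max(restarts - length(starts), 0L)
  if (n_extra > 0) {
    u <- lhs::randomLHS(n_extra, 5L)
    span <- diff(range(ef$d))
    for (i in seq_len(n_extra)) {
      starts[[length(starts) + 1L]] <- c(
        mu0 + (u[i, 1] - 0.5) * span / 2,
        log(s0) + (u[i, 2] - 0.5) * 2,
        c0 * (0.25 + 1.5 * u[i, 3]),
        c0 * 1.5 * u[i, 4],
        stats::qlogis(0.1 + 0.8 * u[i, 5]))
    }
  }
  starts[seq_len(max(restarts, 1L))]
}

#' Fit the two-threshold observer model by maximum likelihood
#'
#' Maximizes the trinomial log-likelihood of per-`d` response counts over
#' `(mu, sigma, c_su, c_o, gamma)`. The ordering constraint `c_o >= c_su
#' >= 0` is enforced by optimizing `c_su` and `delta = c_o - c_su` on
#' `[0, Inf)`; `sigma` is optimized on the log scale and `gamma` on the
#' log-odds scale. Because the likelihood can be multimodal when the guess
#' region is flat, the optimizer is restarted from a data-driven base
#' start (location from the Spearman-Karber midpoint, scale from the
#' quartile span of the monotonized right function) plus Latin-hypercube
#' jitter, and the best restart is returned.
#'
#' @param counts A `condition_counts` object (see [tabulate_counts()]).
#' @param restarts Number of optimizer starts (default 20).
#' @param seed Integer seed for the Latin-hypercube jitter; `NULL` leaves
#'   the RNG state alone.
#' @param anchors Anchors passed to the Spearman-Karber initializer.
#' @param reltol Relative log-likelihood convergence tolerance.
#' @param init Optional numeric vector `(mu, sigma, c_su, c_o, gamma)`
#'   used as the only data-independent start (used by the bootstrap to
#'   warm-start refits).
#' @return An object of class `ttm_fit`: a list with the fitted `mu`,
#'   `sigma`, `c_su`, `c_o`, `gamma`, the maximized `loglik`, `converged`
#'   flag, `n_restarts_used`, and a `predict` closure giving fitted
#'   response probabilities on any `d` grid.
#' @examples
#' obs <- observer_spec(mu = 10, sigma = 50, c_su = 40, c_o = 90, seed = 7)
#' cc <- simulate_counts(obs, d_values = seq(-200, 200, 25), n_per_d = 300)
#' fit <- fit_two_threshold(cc, restarts = 5, seed = 1)
#' fit
#' @export
fit_two_threshold <- function(counts, restarts = 20L, seed = NULL,
                              anchors = NULL, reltol = 1e-6, init = NULL) {
  stopifnot(inherits(counts, "condition_counts"))
  keep <- with(counts, n_xy + n_si + n_yx > 0)
  d <- counts$d_values[keep]
  if (length(d) < 5L)
    stop("need at least 5 distinct d values with nonzero totals, got ",
         length(d))
  n_xy <- counts$n_xy[keep]; n_si <- counts$n_si[keep]; n_yx <- counts$n_yx[keep]
  if (is.null(anchors))
    anchors <- default_anchors(counts$d_values)
  if (!is.null(seed)) {
    old <- get_rng_state(); on.exit(restore_rng_state(old), add = TRUE)
    set.seed(seed)
  }

  if (is.null(init)) {
    starts <- ttm_starts(counts, restarts, anchors)
  } else {
    stopifnot(length(init) == 5L)
    gam <- min(max(init[5], 1e-6), 1 - 1e-6)
    starts <- list(c(init[1], log(init[2]), init[3],
                     max(init[4] - init[3], 0), stats::qlogis(gam)))
    if (restarts > 1L)
      starts <- c(starts, ttm_starts(counts, restarts - 1L, anchors))
  }

  nll <- function(theta) ttm_negloglik(theta, d, n_xy, n_si, n_yx)
  best <- NULL
  n_used <- 0L
  for (th0 in starts) {
    n_used <- n_used + 1L
    res <- tryCatch(
      stats::optim(th0, nll, method = "L-BFGS-B",
                   lower = c(-Inf, -Inf, 0, 0, -20),
                   upper = c(Inf, Inf, Inf, Inf, 20),
                   control = list(maxit = 500L, factr = reltol / 1e-15)),
      error = function(e) NULL)
    if (is.null(res)) next
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best))
    stop("two-threshold fit failed from every start")

  th <- best$par
  structure(
    list(mu = th[1], sigma = exp(th[2]), c_su = th[3],
         c_o = th[3] + th[4], gamma = stats::plogis(th[5]),
         loglik = -best$value,
         converged = best$convergence == 0,
         n_restarts_used = n_used,
         condition = counts$condition,
         d_values = counts$d_values,
         predict = local({
           pars <- list(mu = th[1], sigma = exp(th[2]), c_su = th[3],
                        c_o = th[3] + th[4], gamma = stats::plogis(th[5]))
           function(d) ttm_probabilities(pars, d)
         })),
    class = "ttm_fit")
}

#' @export
print.ttm_fit <- function(x, ...) {
  cat("Two-threshold model fit",
      if (!is.null(x$condition)) paste0("(", x$condition, ")"), "\n")
  cat(sprintf("  mu = %.1f ms, sigma = %.1f ms\n", x$mu, x$sigma))
  cat(sprintf("  c_su = %.1f ms, c_o = %.1f ms, gamma = %.3f\n",
              x$c_su, x$c_o, x$gamma))
  cat(sprintf("  log-likelihood %.2f; converged: %s (%d start%s)\n",
              x$loglik, x$converged, x$n_restarts_used,
              if (x$n_restarts_used == 1L) "" else "s"))
  invisible(x)
}

#' @export
coef.ttm_fit <- function(object, ...) {
  c(mu = object$mu, sigma = object$sigma, c_su = object$c_su,
    c_o = object$c_o, gamma = object$gamma)
}

#' @export
logLik.ttm_fit <- function(object, ...) {
  structure(object$loglik, df = 5L, class = "logLik")
}
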