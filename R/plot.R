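#' Diagnostic plot of the empirical psychometric functions
#'
#' Plots the observed right and left psychometric functions of one
#' condition against the stimulus-onset difference, optionally overlaying
#' the predicted functions of a fitted two-threshold model.
#'
#' @param counts A `condition_counts` object.
#' @param fit Optional `ttm_fit` whose predictions are drawn as curves.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the empirical function data frame.
#' @export
plot_psychometric <- function(counts, fit = NULL, ...) {
  ef <- empirical_functions(counts)
  graphics::plot(ef$d, ef$F_R, ylim = c(0, 1), pch = 16,
                 xlab = "stimulus-onset difference d (ms)",
                 ylab = "response proportion",
                 main = counts$condition, ...)
  graphics::points(ef$d, ef$F_L, pch = 1)
  if (!is.null(fit)) {
    grid <- seq(min(ef$d), max(ef$d), length.out = 201L)
    p <- fit$predict(grid)
    graphics::lines(grid, p[, "p_xy"], lty = 1)
    graphics::lines(grid, p[, "p_xy"] + p[, "p_si"], lty = 2)
  }
  graphics::legend("topleft", bty = "n", pch = c(16, 1),
                   legend = c(expression(F[R] == P(xy ~ "|" ~ d)),
                              expression(F[L] == P(xy ~ "|" ~ d) + P(si ~ "|" ~ d))))
  invisible(ef)
}
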