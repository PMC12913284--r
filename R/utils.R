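# Small internal helpers shared across modules.

# Default Spearman-Karber anchors: one grid step beyond the extremes.
default_anchors <- function(d_values) {
  step <- mean(diff(sort(unique(d_values))))
  c(min(d_values) - step, max(d_values) + step)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

# Order-statistic (type 1) percentile interval.
percentile_ci <- function(x, level = 0.95) {
  alpha <- (1 - level) / 2
  unname(stats::quantile(x, c(alpha, 1 - alpha), type = 1, names = FALSE))
}

is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)
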