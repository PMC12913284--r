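# Independent oracles and small fixture builders shared across tests.

# Brute-force weighted isotonic regression: enumerate every partition of
# 1..n into consecutive blocks, fit each block at its weighted mean, keep
# partitions with nondecreasing block means, minimize weighted SSE. The
# global optimum is attained by one such partition, so this is exact.
brute_force_isotonic <- function(p, w) {
  n <- length(p)
  best <- NULL
  best_sse <- Inf
  # each of the 2^(n-1) cut patterns defines a consecutive partition
  for (mask in 0:(2^(n - 1L) - 1L)) {
    cuts <- which(bitwAnd(mask, 2^(0:(n - 2L))) > 0)
    bounds <- c(0L, cuts, n)
    fitted <- numeric(n)
    means <- numeric(length(bounds) - 1L)
    for (j in seq_len(length(bounds) - 1L)) {
      idx <- (bounds[j] + 1L):bounds[j + 1L]
      means[j] <- sum(w[idx] * p[idx]) / sum(w[idx])
      fitted[idx] <- means[j]
    }
    if (any(diff(means) < -1e-12)) next
    sse <- sum(w * (p - fitted)^2)
    if (sse < best_sse - 1e-12) {
      best_sse <- sse
      best <- fitted
    }
  }
  best
}

# Monte-Carlo oracle for the two-threshold decision rule: raw draws of
# the latency difference pushed through the verbal rule, no shared code
# with ttm_probabilities().
mc_decision_rule <- function(observer, d, n_draws, seed) {
  set.seed(seed)
  DA <- rnorm(n_draws, observer$mu, observer$sigma) + d
  resp <- character(n_draws)
  si <- abs(DA) < observer$c_su
  detect <- abs(DA) >= observer$c_o
  resp[si] <- "si"
  resp[detect & DA >= 0] <- "xy"
  resp[detect & DA < 0] <- "yx"
  guess <- !si & !detect
  g <- runif(sum(guess)) < observer$gamma
  resp[guess] <- ifelse(g, "xy", "yx")
  c(p_xy = mean(resp == "xy"), p_si = mean(resp == "si"),
    p_yx = mean(resp == "yx"))
}

# Deterministic counts exactly proportional to model probabilities
# (rounded), for saturated-likelihood style checks.
exact_counts <- function(observer, d_values, n_per_d) {
  p <- ttm_probabilities(observer, d_values)
  n_xy <- round(p[, "p_xy"] * n_per_d)
  n_si <- round(p[, "p_si"] * n_per_d)
  n_yx <- n_per_d - n_xy - n_si
  condition_counts("exact", d_values, n_xy, n_si, pmax(n_yx, 0))
}

# Small trial fixture with hand-chosen artefacts for cleaning tests;
# every argument is recycled to n rows.
make_trials <- function(n = 100, d = 0, rt = 600, session = 1L, block = 3L,
                        condition = "a", response = "si",
                        corrected = FALSE, lapse = FALSE) {
  df <- data.frame(subject = "S",
                   session = rep_len(session, n),
                   block = rep_len(block, n),
                   condition = rep_len(condition, n),
                   d = rep_len(d, n),
                   response = rep_len(response, n),
                   rt = rep_len(rt, n),
                   corrected = rep_len(corrected, n),
                   lapse = rep_len(lapse, n),
                   stringsAsFactors = FALSE)
  rownames(df) <- NULL
  df
}

exp1_grid <- seq(-200, 200, by = 50 / 3)
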