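#' Specify a synthetic two-threshold observer
#'
#' The observer follows the independent-channels architecture: on each trial
#' the peripheral latency difference `DL ~ Normal(mu, sigma^2)` adds to the
#' stimulus-onset difference `d` to give the central arrival-time difference
#' `DA = DL + d`, which the central comparator judges against two
#' thresholds. If `|DA| < c_su` the stimuli feel simultaneous (`si`); if
#' `|DA| >= c_o` their order is perceived veridically from the sign of
#' `DA`; in between (`c_su <= |DA| < c_o`) successiveness is detected but
#' order must be guessed, with probability `gamma` of guessing `xy`.
#' Setting `c_su = c_o = C` recovers the classical single-threshold
#' observer.
#'
#' Contamination emulates realistic response artefacts: premature
#' responses (RT < 150 ms), delayed responses (RT > 5,000 ms), attentional
#' lapses (double-clicks), and finger errors that the observer corrects
#' (the final response stays valid). Default rates are the mean rates
#' reported for trained observers in this task (0.2%, 0.1%, 0.2%, 1.0%).
#'
#' @param mu Mean of the peripheral latency difference `DL` in ms.
#' @param sigma SD of `DL` in ms; must be positive. Default 40 ms, a
#'   realistic value for trained observers with steep psychometric
#'   functions.
#' @param c_su Successiveness threshold in ms, `>= 0`.
#' @param c_o Order threshold in ms, `>= c_su`. Defaults to `c_su`
#'   (single-threshold observer).
#' @param gamma Probability of responding `xy` when order is guessed.
#' @param contamination Named list of per-trial rates in `[0, 1)`:
#'   `premature`, `delayed`, `lapse`, `finger_error`.
#' @param seed Integer seed stored with the spec and used by
#'   [simulate_observer()].
#'
#' @return An object of class `observer_spec`.
#' @export
observer_spec <- function(mu = 0, sigma = 40, c_su = 50, c_o = c_su,
                          gamma = 0.5,
                          contamination = list(premature = 0.002,
                                               delayed = 0.001,
                                               lapse = 0.002,
                                               finger_error = 0.010),
                          seed = 1L) {
  if (!is.numeric(sigma) || sigma <= 0)
    stop("`sigma` must be > 0")
  if (!is.numeric(c_su) || c_su < 0)
    stop("`c_su` must be >= 0")
  if (!is.numeric(c_o) || c_o < c_su)
    stop("`c_o` must be >= c_su")
  if (gamma < 0 || gamma > 1)
    stop("`gamma` must lie in [0, 1]")
  default_rates <- list(premature = 0.002, delayed = 0.001,
                        lapse = 0.002, finger_error = 0.010)
  contamination <- utils::modifyList(default_rates, as.list(contamination))
  unknown <- setdiff(names(contamination), names(default_rates))
  if (length(unknown))
    stop("unknown contamination rate(s): ", paste(unknown, collapse = ", "))
  rates <- unlist(contamination[names(default_rates)])
  if (any(rates < 0 | rates >= 1))
    stop("contamination rates must lie in [0, 1)")

  structure(
    list(mu = as.numeric(mu), sigma = as.numeric(sigma),
         c_su = as.numeric(c_su), c_o = as.numeric(c_o),
         gamma = as.numeric(gamma),
         contamination = as.list(rates),
         seed = as.integer(seed)),
    class = "observer_spec")
}

#' @export
print.observer_spec <- function(x, ...) {
  cat("Two-threshold observer\n")
  cat(sprintf("  DL ~ Normal(mu = %g, sigma = %g) ms\n", x$mu, x$sigma))
  cat(sprintf("  c_su = %g ms, c_o = %g ms, gamma = %g\n",
              x$c_su, x$c_o, x$gamma))
  cat(sprintf("  contamination: premature %.3f, delayed %.3f, lapse %.3f, finger error %.3f\n",
              x$contamination$premature, x$contamination$delayed,
              x$contamination$lapse, x$contamination$finger_error))
  invisible(x)
}
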