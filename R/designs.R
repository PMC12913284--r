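#' Specify an experimental design for the ternary-response task
#'
#' A design fixes the grid of stimulus-onset differences, the number of
#' trials per grid value and condition, and the session/block layout used
#' to schedule them. Two built-in layouts, [exp1_design()] and
#' [exp2_design()], reproduce the canonical intramodal-vs-intermodal and
#' strong-vs-weak audio-visual designs.
#'
#' @param d_values Strictly increasing numeric vector of stimulus-onset
#'   differences in ms (`d = t_y - t_x`).
#' @param trials_per_d Number of trials per `d` value and condition.
#' @param conditions Character vector of condition labels.
#' @param sessions Number of sessions.
#' @param blocks_per_session Number of blocks per session.
#' @param condition_assignment How conditions are scheduled:
#'   `"alternate_blocks"` alternates conditions across blocks (each block is
#'   pure), `"within_block"` interleaves all conditions within every block.
#' @param anchors Length-2 numeric vector: the `d` values at which the
#'   psychometric functions are assumed to reach 0 and 1, used as
#'   Spearman-Karber anchors downstream.
#' @param practice Practice-trial rule applied by [clean_trials()]: a list
#'   with elements `session` and `blocks`, or `NULL` for none.
#'
#' @return An object of class `design_spec`.
#' @seealso [observer_spec()], [simulate_observer()]
#' @export
design_spec <- function(d_values, trials_per_d, conditions,
                        sessions = 1L, blocks_per_session = 1L,
                        condition_assignment = c("alternate_blocks", "within_block"),
                        anchors = NULL, practice = NULL) {
  condition_assignment <- match.arg(condition_assignment)
  d_values <- as.numeric(d_values)
  if (length(d_values) < 2L || any(diff(d_values) <= 0))
    stop("`d_values` must be strictly increasing with at least two values")
  if (trials_per_d < 1L)
    stop("`trials_per_d` must be a positive integer")
  conditions <- as.character(conditions)
  if (length(conditions) < 1L || anyDuplicated(conditions))
    stop("`conditions` must be distinct labels")
  if (sessions < 1L || blocks_per_session < 1L)
    stop("`sessions` and `blocks_per_session` must be positive integers")
  if (is.null(anchors))
    anchors <- c(min(d_values) - mean(diff(d_values)),
                 max(d_values) + mean(diff(d_values)))
  anchors <- as.numeric(anchors)
  if (length(anchors) != 2L || anchors[1] >= min(d_values) || anchors[2] <= max(d_values))
    stop("`anchors` must bracket the d grid: anchors[1] < min(d) and anchors[2] > max(d)")

  total_blocks <- sessions * blocks_per_session
  if (condition_assignment == "alternate_blocks") {
    if (total_blocks %% length(conditions) != 0)
      stop("total number of blocks must be divisible by the number of conditions")
    blocks_per_cond <- total_blocks / length(conditions)
  } else {
    blocks_per_cond <- total_blocks
  }
  if (trials_per_d %% blocks_per_cond != 0)
    stop("`trials_per_d` (", trials_per_d, ") must divide evenly over the ",
         blocks_per_cond, " blocks available per condition")

  structure(
    list(d_values = d_values,
         trials_per_d = as.integer(trials_per_d),
         conditions = conditions,
         sessions = as.integer(sessions),
         blocks_per_session = as.integer(blocks_per_session),
         condition_assignment = condition_assignment,
         anchors = anchors,
         practice = practice),
    class = "design_spec")
}

#' Built-in design: intramodal vs. intermodal stimulation
#'
#' 25 stimulus-onset differences from -200 to +200 ms in steps of 16.6 ms
#' (50/3 ms exactly), 400 trials per `d` and condition, scheduled as 20
#' sessions of 20 blocks with conditions alternating between blocks
#' (20,000 trials in total). Anchors at +/-225 ms; the first two blocks of
#' session 1 are practice.
#'
#' @param trials_per_d Trials per `d` value and condition (default 400).
#' @param sessions Number of sessions (default 20).
#' @return A `design_spec`.
#' @export
exp1_design <- function(trials_per_d = 400L, sessions = 20L) {
  design_spec(
    d_values = seq(-200, 200, by = 50 / 3),
    trials_per_d = trials_per_d,
    conditions = c("intramodal", "intermodal"),
    sessions = sessions,
    blocks_per_session = 20L,
    condition_assignment = "alternate_blocks",
    anchors = c(-225, 225),
    practice = list(session = 1L, blocks = 1:2))
}

#' Built-in design: strong vs. weak intermodal stimulation
#'
#' 15 stimulus-onset differences from -350 to +350 ms in steps of 50 ms,
#' 180 trials per `d` and condition, scheduled as 5 sessions of 18 blocks
#' with both intensity conditions interleaved within each block (5,400
#' trials in total). Anchors at +/-400 ms; the first block of session 1 is
#' practice.
#'
#' @param trials_per_d Trials per `d` value and condition (default 180).
#' @param sessions Number of sessions (default 5).
#' @return A `design_spec`.
#' @export
exp2_design <- function(trials_per_d = 180L, sessions = 5L) {
  design_spec(
    d_values = seq(-350, 350, by = 50),
    trials_per_d = trials_per_d,
    conditions = c("strong", "weak"),
    sessions = sessions,
    blocks_per_session = 18L,
    condition_assignment = "within_block",
    anchors = c(-400, 400),
    practice = list(session = 1L, blocks = 1L))
}

#' @export
print.design_spec <- function(x, ...) {
  cat("Ternary-response design\n")
  cat(sprintf("  d grid: %d values in [%g, %g] ms\n",
              length(x$d_values), min(x$d_values), max(x$d_values)))
  cat(sprintf("  %d trials per d per condition; conditions: %s (%s)\n",
              x$trials_per_d, paste(x$conditions, collapse = ", "),
              x$condition_assignment))
  cat(sprintf("  %d sessions x %d blocks; anchors [%g, %g] ms\n",
              x$sessions, x$blocks_per_session, x$anchors[1], x$anchors[2]))
  invisible(x)
}
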