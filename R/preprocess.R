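#' Apply trial-exclusion and correction rules
#'
#' Removes practice trials, block-level exclusions, premature responses
#' (RT strictly below `rt_min`), delayed responses (RT strictly above
#' `rt_max`), and attentional lapses (double-clicks). Trials whose
#' response was corrected after a finger error are retained, since their
#' final response is valid. Exclusion categories are disjoint, applied in
#' the order practice, block exclusion, premature, delayed, lapse, so the
#' reported counts are additive:
#' `n_retained = n_input - n_practice - n_block_excluded - n_premature -
#' n_delayed - n_lapse`.
#'
#' @param trials Trial data frame (see [simulate_observer()] /
#'   [read_trials()]).
#' @param rt_min,rt_max RT window bounds in ms; exclusion is strict
#'   (`rt < rt_min`, `rt > rt_max`). Defaults 150 and 5,000 ms.
#' @param practice Practice rule: a list with elements `session` and
#'   `blocks` (trials in those blocks of that session are dropped), or
#'   `NULL` for none.
#' @param exclude_blocks Optional data frame with columns `session` and
#'   `block` naming blocks to drop wholesale (e.g. technical failures);
#'   matched across all conditions.
#' @return A list with elements `trials` (retained trials) and `report`
#'   (a `cleaning_report` with counts and proportions per category).
#' @examples
#' des <- exp1_design(trials_per_d = 20, sessions = 1)
#' trials <- simulate_observer(des, observer_spec(seed = 3))
#' cleaned <- clean_trials(trials, practice = des$practice)
#' cleaned$report
#' @export
clean_trials <- function(trials, rt_min = 150, rt_max = 5000,
                         practice = NULL, exclude_blocks = NULL) {
  trials <- validate_trials(trials)
  n_input <- nrow(trials)

  is_practice <- rep(FALSE, n_input)
  if (!is.null(practice))
    is_practice <- trials$session %in% practice$session &
      trials$block %in% practice$blocks

  is_block_excl <- rep(FALSE, n_input)
  if (!is.null(exclude_blocks)) {
    key <- paste(trials$session, trials$block)
    is_block_excl <- key %in% paste(exclude_blocks$session,
                                    exclude_blocks$block)
  }
  is_block_excl <- is_block_excl & !is_practice

  avail <- !is_practice & !is_block_excl
  is_premature <- avail & trials$rt < rt_min
  is_delayed <- avail & !is_premature & trials$rt > rt_max
  is_lapse <- avail & !is_premature & !is_delayed & trials$lapse

  keep <- avail & !is_premature & !is_delayed & !is_lapse
  retained <- trials[keep, , drop = FALSE]
  rownames(retained) <- NULL

  if (nrow(retained) == 0L)
    stop("no trials retained after cleaning")
  empty <- empty_cells(retained)
  if (nrow(empty) > 0L)
    stop("cleaning left zero trials in cell(s): ",
         paste(sprintf("%s/d=%g", empty$condition, empty$d), collapse = ", "))

  n_eval <- sum(avail)
  report <- structure(
    list(n_input = n_input,
         n_practice = sum(is_practice),
         n_block_excluded = sum(is_block_excl),
         n_premature = sum(is_premature),
         n_delayed = sum(is_delayed),
         n_lapse = sum(is_lapse),
         n_corrected = sum(retained$corrected),
         n_retained = nrow(retained),
         proportions = c(
           premature = sum(is_premature) / n_eval,
           delayed = sum(is_delayed) / n_eval,
           lapse = sum(is_lapse) / n_eval,
           corrected = sum(retained$corrected) / n_eval)),
    class = "cleaning_report")

  list(trials = retained, report = report)
}

empty_cells <- function(trials) {
  tab <- table(trials$condition, trials$d)
  idx <- which(tab == 0L, arr.ind = TRUE)
  data.frame(condition = rownames(tab)[idx[, 1L]],
             d = as.numeric(colnames(tab)[idx[, 2L]]))
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat("Trial cleaning report\n")
  cat(sprintf("  input: %d trials; retained: %d\n", x$n_input, x$n_retained))
  cat(sprintf("  practice %d, block-excluded %d\n",
              x$n_practice, x$n_block_excluded))
  cat(sprintf("  premature %d (%.2f%%), delayed %d (%.2f%%), lapse %d (%.2f%%)\n",
              x$n_premature, 100 * x$proportions["premature"],
              x$n_delayed, 100 * x$proportions["delayed"],
              x$n_lapse, 100 * x$proportions["lapse"]))
  cat(sprintf("  corrected (retained) %d (%.2f%%)\n",
              x$n_corrected, 100 * x$proportions["corrected"]))
  invisible(x)
}

#' Per-condition trinomial response counts
#'
#' `condition_counts()` constructs the container holding, for one
#' condition, the counts of `xy`, `si` and `yx` responses at every value
#' of the `d` grid — the empirical basis of the two psychometric
#' functions. `tabulate_counts()` builds one per condition from cleaned
#' trials.
#'
#' @param condition Condition label.
#' @param d_values Increasing numeric grid in ms.
#' @param n_xy,n_si,n_yx Nonnegative count vectors aligned to `d_values`.
#' @return A `condition_counts` object.
#' @export
condition_counts <- function(condition, d_values, n_xy, n_si, n_yx) {
  d_values <- as.numeric(d_values)
  if (any(diff(d_values) <= 0))
    stop("`d_values` must be strictly increasing")
  k <- length(d_values)
  if (length(n_xy) != k || length(n_si) != k || length(n_yx) != k)
    stop("count vectors must align with `d_values`")
  if (any(c(n_xy, n_si, n_yx) < 0))
    stop("counts must be nonnegative")
  structure(
    list(condition = as.character(condition), d_values = d_values,
         n_xy = as.numeric(n_xy), n_si = as.numeric(n_si),
         n_yx = as.numeric(n_yx)),
    class = "condition_counts")
}

#' @rdname condition_counts
#' @param trials Cleaned trial data frame.
#' @param d_values Optional declared grid; trials at `d` values outside it
#'   raise an error. Defaults to the distinct `d` values present.
#' @return `tabulate_counts()` returns a named list of `condition_counts`,
#'   one per condition.
#' @export
tabulate_counts <- function(trials, d_values = NULL) {
  trials <- validate_trials(trials)
  if (is.null(d_values)) {
    d_values <- sort(unique(trials$d))
  } else {
    d_values <- as.numeric(d_values)
    outside <- setdiff(unique(trials$d), d_values)
    if (length(outside))
      stop("trials at d value(s) outside the declared grid: ",
           paste(sort(outside), collapse = ", "))
  }
  conditions <- unique(trials$condition)
  out <- lapply(conditions, function(cond) {
    sub <- trials[trials$condition == cond, , drop = FALSE]
    tab <- table(factor(sub$response, levels = c("xy", "si", "yx")),
                 factor(sub$d, levels = d_values))
    condition_counts(cond, d_values,
                     n_xy = as.numeric(tab["xy", ]),
                     n_si = as.numeric(tab["si", ]),
                     n_yx = as.numeric(tab["yx", ]))
  })
  stats::setNames(out, conditions)
}

#' @export
print.condition_counts <- function(x, ...) {
  cat(sprintf("Response counts, condition '%s': %d d values, %d trials\n",
              x$condition, length(x$d_values),
              sum(x$n_xy + x$n_si + x$n_yx)))
  invisible(x)
}

#' @export
as.data.frame.condition_counts <- function(x, ...) {
  data.frame(condition = x$condition, d = x$d_values,
             n_xy = x$n_xy, n_si = x$n_si, n_yx = x$n_yx)
}

#' Empirical psychometric functions from response counts
#'
#' Computes the right function `F_R(d) = P(xy | d)` and the left function
#' `F_L(d) = P(xy | d) + P(si | d) = 1 - P(yx | d)` from raw counts. By
#' construction `0 <= F_R <= F_L <= 1` at every `d`.
#'
#' @param counts A `condition_counts` object; every `d` cell must contain
#'   at least one trial.
#' @return A data frame with columns `d`, `n`, `F_R`, `F_L`.
#' @export
empirical_functions <- function(counts) {
  stopifnot(inherits(counts, "condition_counts"))
  n <- counts$n_xy + counts$n_si + counts$n_yx
  if (any(n == 0))
    stop("zero-total cell(s) at d = ",
         paste(counts$d_values[n == 0], collapse = ", "))
  data.frame(d = counts$d_values, n = n,
             F_R = counts$n_xy / n,
             F_L = (counts$n_xy + counts$n_si) / n)
}

#' Write per-condition counts to CSV
#'
#' @param counts_list A list of `condition_counts` (or a single one).
#' @param path File path.
#' @export
write_counts <- function(counts_list, path) {
  if (inherits(counts_list, "condition_counts"))
    counts_list <- list(counts_list)
  df <- do.call(rbind, lapply(counts_list, as.data.frame))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("condition", "d", "n_xy", "n_si", "n_yx")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("counts file lacks column(s): ", paste(missing, collapse = ", "))
  out <- lapply(split(df, df$condition), function(sub) {
    sub <- sub[order(sub$d), , drop = FALSE]
    condition_counts(sub$condition[1L], sub$d, sub$n_xy, sub$n_si, sub$n_yx)
  })
  out[unique(df$condition)]
}
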