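#' Configure an end-to-end analysis
#'
#' Bundles the experiment layout and analysis settings consumed by
#' [run_pipeline()]. All randomness in the pipeline flows from `seed`, so
#' identical configs on identical input give identical results.
#'
#' @param design A [design_spec()]; supplies the `d` grid, anchors and
#'   practice rule.
#' @param estimators Character vector of threshold estimators to run:
#'   any of `"sk"`, `"ttm_c_su"`, `"ttm_c_o"`.
#' @param B Bootstrap samples (default 1000).
#' @param seed Integer seed.
#' @param rt_min,rt_max RT exclusion window in ms.
#' @param exclude_blocks Optional data frame of `session`/`block` pairs to
#'   drop (e.g. technical failures).
#' @param compare Length-2 character vector of condition labels for the
#'   invariance test; defaults to the design's first two conditions.
#' @param practice_levels If not `NULL`, sessions per practice level for
#'   [practice_curve()] (nonparametric estimator).
#' @param restarts Optimizer restarts for parametric fits.
#' @param output_dir If not `NULL`, results are written there as
#'   JSON/CSV.
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(design, estimators = c("sk", "ttm_c_su", "ttm_c_o"),
                            B = 1000L, seed = 1L,
                            rt_min = 150, rt_max = 5000,
                            exclude_blocks = NULL, compare = NULL,
                            practice_levels = NULL, restarts = 20L,
                            output_dir = NULL) {
  stopifnot(inherits(design, "design_spec"))
  estimators <- match.arg(estimators, several.ok = TRUE)
  if (is.null(compare) && length(design$conditions) >= 2L)
    compare <- design$conditions[1:2]
  if (!is.null(compare) && !all(compare %in% design$conditions))
    stop("`compare` must name conditions present in the design")
  structure(
    list(design = design, estimators = estimators, B = as.integer(B),
         seed = as.integer(seed), rt_min = rt_min, rt_max = rt_max,
         exclude_blocks = exclude_blocks, compare = compare,
         practice_levels = practice_levels,
         restarts = as.integer(restarts), output_dir = output_dir),
    class = "analysis_config")
}

#' Run the full threshold-invariance analysis on trial data
#'
#' Executes the complete chain on one subject's trial data: cleaning
#' (practice, RT window, lapses, block exclusions), tabulation into
#' per-condition counts, nonparametric and/or parametric threshold
#' estimation, percentile-bootstrap CIs per condition and estimator, the
#' invariance test between the two compared conditions, and optionally a
#' practice curve. If `output_dir` is set in the config, results are
#' written as `results.json` and `counts.csv`.
#'
#' @param config An [analysis_config()].
#' @param trials A trial data frame, or a path to a trial CSV.
#' @return A list with elements `report` (cleaning), `counts`,
#'   `sk` (per-condition `sk_estimate`s), `fits` (per-condition
#'   `ttm_fit`s, if parametric estimators requested), `bootstrap` (nested
#'   list estimator -> condition -> `bootstrap_result`), `invariance`
#'   (estimator -> `invariance_result`), and `practice` (data frame or
#'   `NULL`).
#' @examples
#' des <- exp1_design(trials_per_d = 40, sessions = 2)
#' obs <- list(intramodal = observer_spec(c_su = 25, seed = 2),
#'             intermodal = observer_spec(c_su = 100, seed = 2))
#' trials <- simulate_observer(des, obs)
#' res <- run_pipeline(analysis_config(des, estimators = "sk", B = 200),
#'                     trials)
#' res$invariance$sk
#' @export
run_pipeline <- function(config, trials) {
  stopifnot(inherits(config, "analysis_config"))
  if (is.character(trials)) trials <- read_trials(trials)

  cleaned <- clean_trials(trials, rt_min = config$rt_min,
                          rt_max = config$rt_max,
                          practice = config$design$practice,
                          exclude_blocks = config$exclude_blocks)
  counts <- tabulate_counts(cleaned$trials,
                            d_values = config$design$d_values)
  anchors <- config$design$anchors

  sk <- lapply(counts, sk_threshold, anchors = anchors)

  fits <- NULL
  if (any(config$estimators != "sk"))
    fits <- lapply(counts, fit_two_threshold, restarts = config$restarts,
                   seed = config$seed, anchors = anchors)

  bootstrap <- list()
  invariance <- list()
  for (est in config$estimators) {
    bootstrap[[est]] <- lapply(counts, bootstrap_threshold,
                               estimator = est, B = config$B,
                               seed = config$seed, anchors = anchors,
                               restarts = config$restarts)
    if (!is.null(config$compare)) {
      invariance[[est]] <- invariance_test(
        counts[[config$compare[1]]], counts[[config$compare[2]]],
        estimator = est, B = config$B, seed = config$seed,
        anchors = anchors, restarts = config$restarts)
    }
  }

  practice <- NULL
  if (!is.null(config$practice_levels))
    practice <- practice_curve(cleaned$trials,
                               sessions_per_level = config$practice_levels,
                               estimator = "sk", B = config$B,
                               seed = config$seed, anchors = anchors)

  result <- list(report = cleaned$report, counts = counts, sk = sk,
                 fits = fits, bootstrap = bootstrap,
                 invariance = invariance, practice = practice)

  if (!is.null(config$output_dir))
    write_results(result, config)
  result
}

write_results <- function(result, config) {
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  write_counts(result$counts, file.path(config$output_dir, "counts.csv"))
  serializable <- list(
    seed = config$seed, B = config$B,
    cleaning = unclass(result$report),
    sk = lapply(result$sk, unclass),
    fits = lapply(result$fits, function(f)
      if (is.null(f)) NULL else unclass(f)[c("mu", "sigma", "c_su", "c_o",
                                             "gamma", "loglik", "converged",
                                             "n_restarts_used")]),
    bootstrap = lapply(result$bootstrap, function(per_cond)
      lapply(per_cond, function(b)
        unclass(b)[c("point", "ci_lo", "ci_hi", "B", "seed", "estimator")])),
    invariance = lapply(result$invariance, function(iv)
      list(condition_a = iv$condition_a, condition_b = iv$condition_b,
           estimator = iv$estimator, diff = iv$diff$point,
           ci_lo = iv$diff$ci_lo, ci_hi = iv$diff$ci_hi,
           violated = iv$violated)),
    practice = result$practice)
  jsonlite::write_json(serializable,
                       file.path(config$output_dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       dataframe = "rows")
  invisible(NULL)
}
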