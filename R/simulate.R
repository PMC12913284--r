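#' Simulate trial-level data from a two-threshold observer
#'
#' Generates one complete synthetic run of a ternary-response experiment:
#' for every trial the peripheral latency difference `DL ~ Normal(mu,
#' sigma^2)` is drawn, the central arrival-time difference `DA = DL + d`
#' is judged against the observer's thresholds (`si` if `|DA| < c_su`,
#' veridical order response if `|DA| >= c_o`, otherwise a guess that is
#' `xy` with probability `gamma`), and trials are scheduled into sessions
#' and blocks according to the design. Contamination is applied
#' independently per trial afterwards: premature trials get an RT below
#' 150 ms, delayed trials an RT above 5,000 ms, lapses are flagged as
#' double-clicks, and finger errors are flagged as corrected with the
#' final (valid) response retained.
#'
#' @param design A [design_spec()].
#' @param observer A single [observer_spec()] applied to all conditions,
#'   or a named list of `observer_spec`s, one per condition label.
#' @param subject Subject label stored in the output.
#' @return A data frame of trials with columns `subject`, `session`,
#'   `block`, `condition`, `d`, `response` (factor `xy`/`si`/`yx`), `rt`
#'   (ms), `corrected`, `lapse`.
#' @examples
#' des <- exp1_design(trials_per_d = 20, sessions = 1)
#' obs <- observer_spec(mu = 0, c_su = 50, seed = 1)
#' trials <- simulate_observer(des, obs)
#' head(trials)
#' @export
simulate_observer <- function(design, observer, subject = "S01") {
  stopifnot(inherits(design, "design_spec"))
  observers <- normalize_observers(design, observer)

  old <- get_rng_state(); on.exit(restore_rng_state(old), add = TRUE)
  set.seed(observers[[1L]]$seed)

  total_blocks <- design$sessions * design$blocks_per_session
  n_cond <- length(design$conditions)
  pieces <- vector("list", n_cond)

  for (ci in seq_len(n_cond)) {
    cond <- design$conditions[ci]
    obs <- observers[[cond]]
    if (design$condition_assignment == "alternate_blocks") {
      block_idx <- seq(ci, total_blocks, by = n_cond)
    } else {
      block_idx <- seq_len(total_blocks)
    }
    reps_per_block <- design$trials_per_d / length(block_idx)

    n_d <- length(design$d_values)
    n_trials <- design$trials_per_d * n_d
    d <- rep(design$d_values, each = design$trials_per_d)
    # block assignment: each block receives reps_per_block repeats of each d
    block_seq <- rep(rep(block_idx, each = reps_per_block), times = n_d)

    DA <- stats::rnorm(n_trials, mean = obs$mu, sd = obs$sigma) + d
    response <- ttm_decide(DA, obs)

    rt <- round(pmin(pmax(stats::rlnorm(n_trials, log(600), 0.35), 160), 4900))
    premature <- stats::runif(n_trials) < obs$contamination$premature
    delayed <- !premature & stats::runif(n_trials) < obs$contamination$delayed
    lapse <- stats::runif(n_trials) < obs$contamination$lapse
    corrected <- stats::runif(n_trials) < obs$contamination$finger_error
    rt[premature] <- round(stats::runif(sum(premature), 50, 149))
    rt[delayed] <- round(stats::runif(sum(delayed), 5001, 7000))

    pieces[[ci]] <- data.frame(
      subject = subject,
      session = (block_seq - 1L) %/% design$blocks_per_session + 1L,
      block = (block_seq - 1L) %% design$blocks_per_session + 1L,
      condition = cond,
      d = d,
      response = response,
      rt = rt,
      corrected = corrected,
      lapse = lapse,
      stringsAsFactors = FALSE)
  }

  trials <- do.call(rbind, pieces)
  # randomize presentation order within each (session, block)
  ord <- order(trials$session, trials$block,
               stats::runif(nrow(trials)))
  trials <- trials[ord, , drop = FALSE]
  rownames(trials) <- NULL
  trials$response <- factor(trials$response, levels = c("xy", "si", "yx"))
  trials
}

# Decision rule of the two-threshold observer, vectorized over DA.
# Ties: xy/yx assigned at |DA| >= threshold (weak inequality on the
# detect side), si strictly inside (-c_su, c_su).
ttm_decide <- function(DA, obs) {
  n <- length(DA)
  response <- character(n)
  si <- abs(DA) < obs$c_su
  detect <- abs(DA) >= obs$c_o
  guess <- !si & !detect
  response[si] <- "si"
  response[detect] <- ifelse(DA[detect] >= 0, "xy", "yx")
  if (any(guess))
    response[guess] <- ifelse(stats::runif(sum(guess)) < obs$gamma,
                              "xy", "yx")
  response
}

normalize_observers <- function(design, observer) {
  if (inherits(observer, "observer_spec")) {
    observers <- stats::setNames(
      rep(list(observer), length(design$conditions)), design$conditions)
  } else if (is.list(observer)) {
    if (!all(design$conditions %in% names(observer)))
      stop("`observer` list must be named with every condition label: ",
           paste(design$conditions, collapse = ", "))
    observers <- observer[design$conditions]
    ok <- vapply(observers, inherits, logical(1), "observer_spec")
    if (!all(ok)) stop("all elements of `observer` must be observer_spec objects")
  } else {
    stop("`observer` must be an observer_spec or a named list of them")
  }
  observers
}

#' Simulate per-cell response counts directly from model probabilities
#'
#' Fast path used for estimator validation and bootstrap studies: draws
#' trinomial counts per `d` value straight from [ttm_probabilities()],
#' skipping trial-level scheduling, RTs and contamination.
#'
#' @param observer An [observer_spec()] (contamination is ignored; the
#'   spec's `seed` drives the draws, so results are reproducible).
#' @param d_values Numeric grid of stimulus-onset differences in ms.
#' @param n_per_d Trials per grid value (scalar or vector).
#' @param condition Condition label for the output.
#' @return A `condition_counts` object.
#' @export
simulate_counts <- function(observer, d_values, n_per_d,
                            condition = "sim") {
  old <- get_rng_state(); on.exit(restore_rng_state(old), add = TRUE)
  set.seed(observer$seed)
  n_per_d <- rep_len(as.integer(n_per_d), length(d_values))
  p <- ttm_probabilities(observer, d_values)
  counts <- vapply(seq_along(d_values),
                   function(i) stats::rmultinom(1L, n_per_d[i], p[i, ])[, 1L],
                   numeric(3L))
  condition_counts(condition = condition, d_values = d_values,
                   n_xy = counts[1L, ], n_si = counts[2L, ],
                   n_yx = counts[3L, ])
}

#' Read and write the tidy trial CSV interchange format
#'
#' One row per trial with the fixed header `subject, session, block,
#' condition, d, response, rt, corrected, lapse`. `read_trials()`
#' validates the schema and reports offending row numbers.
#'
#' @param trials A trial data frame as returned by [simulate_observer()].
#' @param path File path.
#' @return `read_trials()` returns the validated trial data frame;
#'   `write_trials()` returns `path` invisibly.
#' @export
write_trials <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  trials <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_trials(trials)
}

validate_trials <- function(trials) {
  required <- c("subject", "session", "block", "condition", "d",
                "response", "rt", "corrected", "lapse")
  missing <- setdiff(required, names(trials))
  if (length(missing))
    stop("trial data lack required column(s): ",
         paste(missing, collapse = ", "))
  if (nrow(trials) == 0L)
    stop("trial data contain no rows")
  bad <- which(!trials$response %in% c("xy", "si", "yx"))
  if (length(bad))
    stop("invalid response value(s) at row(s): ",
         paste(utils::head(bad, 10L), collapse = ", "))
  bad_rt <- which(!is.finite(trials$rt) | trials$rt < 0)
  if (length(bad_rt))
    stop("negative or missing rt at row(s): ",
         paste(utils::head(bad_rt, 10L), collapse = ", "))
  trials$response <- factor(trials$response, levels = c("xy", "si", "yx"))
  trials$corrected <- as.logical(trials$corrected)
  trials$lapse <- as.logical(trials$lapse)
  trials
}

#' Serialize design and observer specifications
#'
#' Writes a `design_spec` or `observer_spec` to JSON or to a flat
#' `key: value` text file, and reads it back.
#'
#' @param x A `design_spec` or `observer_spec`.
#' @param path File path.
#' @param format `"json"` or `"keyvalue"`.
#' @return `read_spec()` returns the reconstructed spec object.
#' @export
write_spec <- function(x, path, format = c("json", "keyvalue")) {
  format <- match.arg(format)
  kind <- if (inherits(x, "design_spec")) "design_spec"
          else if (inherits(x, "observer_spec")) "observer_spec"
          else stop("`x` must be a design_spec or observer_spec")
  fields <- unclass(x)
  if (format == "json") {
    jsonlite::write_json(c(list(.class = kind), fields), path,
                         auto_unbox = TRUE, digits = NA, null = "null")
  } else {
    flat <- c(.class = kind, unlist(fields))
    writeLines(sprintf("%s: %s", names(flat),
                       vapply(flat, format_scalar, character(1))),
               path)
  }
  invisible(path)
}

format_scalar <- function(v) {
  if (is.numeric(v)) format(v, digits = 15) else as.character(v)
}

#' @rdname write_spec
#' @export
read_spec <- function(path, format = c("json", "keyvalue")) {
  format <- match.arg(format)
  if (format == "json") {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    kind <- obj$.class
    obj$.class <- NULL
  } else {
    lines <- readLines(path)
    keys <- sub(":.*$", "", lines)
    vals <- sub("^[^:]*: ?", "", lines)
    kind <- vals[keys == ".class"]
    keep <- keys != ".class"
    obj <- rebuild_keyvalue(keys[keep], vals[keep])
  }
  if (identical(kind, "design_spec")) {
    do.call(design_spec, obj[c("d_values", "trials_per_d", "conditions",
                               "sessions", "blocks_per_session",
                               "condition_assignment", "anchors")])
  } else if (identical(kind, "observer_spec")) {
    obj$contamination <- as.list(obj$contamination)
    do.call(observer_spec, obj[c("mu", "sigma", "c_su", "c_o", "gamma",
                                 "contamination", "seed")])
  } else {
    stop("unrecognized spec file: ", path)
  }
}

rebuild_keyvalue <- function(keys, vals) {
  # unlist() flattens vectors to name1, name2, ... and lists to name.sub
  out <- list()
  for (base in unique(sub("[0-9]+$", "", keys))) {
    idx <- grepl(paste0("^", gsub("\\.", "\\\\.", base), "[0-9]*$"), keys)
    v <- vals[idx]
    num <- suppressWarnings(as.numeric(v))
    out[[base]] <- if (all(!is.na(num))) num else v
  }
  # regroup dotted names (contamination.premature -> contamination$premature)
  dotted <- grep("\\.", names(out), value = TRUE)
  for (nm in dotted) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    out[[parts[1]]][[parts[2]]] <- out[[nm]]
    out[[nm]] <- NULL
  }
  out
}
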