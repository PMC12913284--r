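#' Packaged per-subject threshold tables
#'
#' Returns the published per-subject central-threshold estimates (point
#' estimate and bootstrapped 95% CI limits, ms-rounded) for the two
#' built-in experiment layouts: the intramodal-vs-intermodal study (five
#' subjects, 20 sessions each) and the strong-vs-weak intensity study
#' (ten subjects, five sessions each). Each table has one row per
#' subject, estimator (`nonparametric`, `parametric_c_su`,
#' `parametric_c_o`) and condition (including the within-subject
#' `difference`), and feeds the group-level analyses (see
#' [paired_t_dz()]).
#'
#' @return A list with data frames `exp1` and `exp2`, each with columns
#'   `subject`, `estimator`, `condition`, `estimate`, `ci_lo`, `ci_hi`.
#' @examples
#' tabs <- load_fixture_tables()
#' subset(tabs$exp1, estimator == "nonparametric" & condition == "intermodal")
#' @export
load_fixture_tables <- function() {
  read_one <- function(file) {
    path <- system.file("extdata", file, package = "centhresh",
                        mustWork = TRUE)
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  list(exp1 = read_one("thresholds_exp1.csv"),
       exp2 = read_one("thresholds_exp2.csv"))
}

#' Group statistics for every estimator in a fixture table
#'
#' Convenience wrapper: for each estimator in a per-subject threshold
#' table, runs [paired_t_dz()] on the two condition columns.
#'
#' @param table A data frame as returned by [load_fixture_tables()].
#' @param condition_a,condition_b Condition labels to compare.
#' @return A data frame with one row per estimator: group means, `t`,
#'   `df`, `p`, and `d_z`.
#' @export
group_stats_table <- function(table, condition_a, condition_b) {
  out <- lapply(unique(table$estimator), function(est) {
    sub <- table[table$estimator == est, ]
    a <- sub$estimate[sub$condition == condition_a]
    b <- sub$estimate[sub$condition == condition_b]
    subj_a <- sub$subject[sub$condition == condition_a]
    subj_b <- sub$subject[sub$condition == condition_b]
    stopifnot(identical(subj_a, subj_b))
    gs <- paired_t_dz(a, b)
    data.frame(estimator = est, n = gs$n,
               mean_a = gs$mean_a, mean_b = gs$mean_b,
               t = gs$t, df = gs$df, p = gs$p, d_z = gs$d_z)
  })
  do.call(rbind, out)
}
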