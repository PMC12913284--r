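test_that("clean run passes through untouched", {
  trials <- make_trials(100, d = rep(c(-50, 50), 50),
                        response = rep(c("yx", "xy"), 50))
  out <- clean_trials(trials)
  expect_equal(out$report$n_retained, 100L)
  expect_equal(out$report$n_premature, 0L)
  expect_equal(out$report$n_delayed, 0L)
  expect_equal(out$report$n_lapse, 0L)
  expect_equal(nrow(out$trials), 100L)
})

test_that("injected artefacts are counted exactly and removed", {
  base <- make_trials(94, d = rep(c(-50, 50), 47),
                      response = rep(c("yx", "xy"), 47))
  bad <- rbind(
    make_trials(3, d = 50, response = "xy", rt = 100),     # premature
    make_trials(2, d = -50, response = "yx", rt = 6000),   # delayed
    make_trials(1, d = 50, response = "si", lapse = TRUE)) # lapse
  out <- clean_trials(rbind(base, bad))
  expect_equal(out$report$n_input, 100L)
  expect_equal(out$report$n_premature, 3L)
  expect_equal(out$report$n_delayed, 2L)
  expect_equal(out$report$n_lapse, 1L)
  expect_equal(out$report$n_retained, 94L)
  expect_equal(out$report$n_retained,
               out$report$n_input - out$report$n_practice -
                 out$report$n_block_excluded - out$report$n_premature -
                 out$report$n_delayed - out$report$n_lapse)
})

test_that("RT window boundaries are strict: 150 and 5000 ms are retained", {
  trials <- make_trials(4, d = rep(c(-50, 50), 2),
                        response = rep(c("yx", "xy"), 2),
                        rt = c(150, 5000, 149, 5001))
  out <- clean_trials(trials)
  expect_equal(out$report$n_retained, 2L)
  expect_equal(out$report$n_premature, 1L)
  expect_equal(out$report$n_delayed, 1L)
  expect_true(all(out$trials$rt %in% c(150, 5000)))
})

test_that("practice and block exclusions drop whole blocks; corrected trials stay", {
  trials <- rbind(
    make_trials(10, session = 1, block = 1, d = 0),           # practice
    make_trials(10, session = 1, block = 2, d = 0),           # practice
    make_trials(30, session = 1, block = 3, d = 0, corrected = TRUE),
    make_trials(20, session = 2, block = 1, d = 0))           # excluded block
  out <- clean_trials(trials, practice = list(session = 1, blocks = 1:2),
                      exclude_blocks = data.frame(session = 2, block = 1))
  expect_equal(out$report$n_practice, 20L)
  expect_equal(out$report$n_block_excluded, 20L)
  expect_equal(out$report$n_retained, 30L)
  expect_equal(out$report$n_corrected, 30L)
})

test_that("cleaning is idempotent", {
  des <- design_spec(d_values = seq(-100, 100, 50), trials_per_d = 40,
                     conditions = c("a", "b"), blocks_per_session = 2)
  trials <- simulate_observer(des, observer_spec(c_su = 40, seed = 11))
  once <- clean_trials(trials)
  twice <- clean_trials(once$trials)
  expect_equal(twice$trials, once$trials)
  expect_equal(twice$report$n_retained, once$report$n_retained)
  expect_equal(twice$report$n_premature + twice$report$n_delayed +
                 twice$report$n_lapse, 0L)
})

test_that("tabulation conserves trials and respects the declared grid", {
  trials <- make_trials(20, d = 0,
                        response = c(rep("xy", 10), rep("si", 5), rep("yx", 5)))
  trials$d <- 0
  cc <- tabulate_counts(trials, d_values = c(-50, 0, 50))[["a"]]
  expect_equal(cc$n_xy[cc$d_values == 0], 10)
  expect_equal(cc$n_si[cc$d_values == 0], 5)
  expect_equal(cc$n_yx[cc$d_values == 0], 5)
  expect_equal(sum(cc$n_xy + cc$n_si + cc$n_yx), nrow(trials))
  expect_error(tabulate_counts(trials, d_values = c(-50, 50)), "outside")

  # full simulated run: totals per condition and cell match the design
  des <- exp1_design(trials_per_d = 40, sessions = 2)
  sim <- simulate_observer(des, observer_spec(c_su = 50, seed = 3))
  counts <- tabulate_counts(sim, d_values = des$d_values)
  expect_named(counts, des$conditions)
  totals <- sapply(counts, function(x) sum(x$n_xy + x$n_si + x$n_yx))
  expect_equal(unname(totals), rep(40 * 25, 2))
})

test_that("empirical functions satisfy 0 <= F_R <= F_L <= 1 and match counts", {
  cc <- condition_counts("a", c(-50, 0, 50),
                         n_xy = c(0, 10, 18), n_si = c(2, 5, 2),
                         n_yx = c(18, 5, 0))
  ef <- empirical_functions(cc)
  expect_equal(ef$F_R, c(0, 0.5, 0.9))
  expect_equal(ef$F_L, c(0.1, 0.75, 1))
  expect_true(all(ef$F_R <= ef$F_L))
  expect_equal(ef$F_L - ef$F_R, c(2, 5, 2) / 20)  # = P(si|d)

  all_si <- condition_counts("a", c(-10, 10), n_xy = c(0, 0),
                             n_si = c(5, 5), n_yx = c(0, 0))
  ef2 <- empirical_functions(all_si)
  expect_equal(ef2$F_R, c(0, 0))
  expect_equal(ef2$F_L, c(1, 1))

  zero <- condition_counts("a", c(-10, 10), n_xy = c(1, 0),
                           n_si = c(1, 0), n_yx = c(1, 0))
  expect_error(empirical_functions(zero), "zero-total")
})

test_that("trial CSV and counts CSV round-trip", {
  des <- design_spec(d_values = seq(-100, 100, 50), trials_per_d = 10,
                     conditions = c("a", "b"), blocks_per_session = 2)
  trials <- simulate_observer(des, observer_spec(c_su = 40, seed = 21))
  path <- tempfile(fileext = ".csv")
  write_trials(trials, path)
  back <- read_trials(path)
  expect_equal(back$d, trials$d)
  expect_equal(as.character(back$response), as.character(trials$response))

  counts <- tabulate_counts(trials)
  cpath <- tempfile(fileext = ".csv")
  write_counts(counts, cpath)
  back_counts <- read_counts(cpath)
  expect_equal(back_counts[["a"]]$n_xy, counts[["a"]]$n_xy)
  expect_equal(back_counts[["b"]]$d_values, counts[["b"]]$d_values)
})
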