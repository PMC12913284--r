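test_that("degenerate, perfectly separated data give a zero-width CI", {
  d <- seq(-100, 100, 25)
  n <- 50
  cc <- condition_counts("a", d,
                         n_xy = as.numeric(d > 0) * n,
                         n_si = as.numeric(d == 0) * n,
                         n_yx = as.numeric(d < 0) * n)
  bt <- bootstrap_threshold(cc, "sk", B = 100, seed = 1,
                            anchors = c(-125, 125))
  expect_equal(bt$ci_lo, bt$ci_hi)
  expect_equal(bt$ci_lo, bt$point)
})

test_that("bootstrap is deterministic given the seed", {
  obs <- observer_spec(c_su = 50, seed = 31)
  cc <- simulate_counts(obs, seq(-200, 200, 25), 100)
  b1 <- bootstrap_threshold(cc, "sk", B = 150, seed = 7,
                            anchors = c(-225, 225))
  b2 <- bootstrap_threshold(cc, "sk", B = 150, seed = 7,
                            anchors = c(-225, 225))
  expect_identical(b1$draws, b2$draws)
  expect_identical(c(b1$ci_lo, b1$ci_hi), c(b2$ci_lo, b2$ci_hi))
  b3 <- bootstrap_threshold(cc, "sk", B = 150, seed = 8,
                            anchors = c(-225, 225))
  expect_false(identical(b1$draws, b3$draws))
})

test_that("CI endpoints are order statistics and widen as cells shrink", {
  obs <- observer_spec(c_su = 50, seed = 32)
  widths <- vapply(c(400, 100, 25), function(n) {
    cc <- simulate_counts(obs, seq(-200, 200, 25), n)
    bt <- bootstrap_threshold(cc, "sk", B = 300, seed = 5,
                              anchors = c(-225, 225))
    expect_lte(bt$ci_lo, bt$ci_hi)
    expect_true(bt$ci_lo %in% bt$draws && bt$ci_hi %in% bt$draws)
    bt$ci_hi - bt$ci_lo
  }, numeric(1))
  expect_true(all(diff(widths) > 0))
})

test_that("identical conditions are never declared a violation", {
  obs <- observer_spec(c_su = 50, seed = 33)
  cc <- simulate_counts(obs, seq(-200, 200, 25), 200)
  iv <- invariance_test(cc, cc, "sk", B = 200, seed = 2,
                        anchors = c(-225, 225))
  expect_false(iv$violated)
  expect_true(iv$diff$ci_lo <= 0 && iv$diff$ci_hi >= 0)
})

test_that("a real threshold difference is detected with the expected size", {
  obs_a <- observer_spec(c_su = 100, sigma = 40, seed = 34)
  obs_b <- observer_spec(c_su = 25, sigma = 40, seed = 35)
  cc_a <- simulate_counts(obs_a, exp1_grid, 400)
  cc_b <- simulate_counts(obs_b, exp1_grid, 400)
  iv <- invariance_test(cc_a, cc_b, "sk", B = 500, seed = 3,
                        anchors = c(-225, 225))
  expect_true(iv$violated)
  expect_lt(abs(iv$diff$point - 75), 6)
})

test_that("equal thresholds with different latencies are not flagged", {
  obs_a <- observer_spec(mu = -60, c_su = 50, sigma = 40, seed = 36)
  obs_b <- observer_spec(mu = 60, c_su = 50, sigma = 40, seed = 37)
  cc_a <- simulate_counts(obs_a, exp1_grid, 400)
  cc_b <- simulate_counts(obs_b, exp1_grid, 400)
  iv <- invariance_test(cc_a, cc_b, "sk", B = 500, seed = 4,
                        anchors = c(-225, 225))
  expect_false(iv$violated)
})

test_that("parametric bootstrap extracts the requested threshold", {
  obs <- observer_spec(mu = 0, sigma = 50, c_su = 40, c_o = 100,
                       gamma = 0.5, seed = 38)
  cc <- simulate_counts(obs, seq(-200, 200, 25), 300)
  bt_su <- bootstrap_threshold(cc, "ttm_c_su", B = 60, seed = 6,
                               anchors = c(-225, 225), restarts = 6)
  bt_o <- bootstrap_threshold(cc, "ttm_c_o", B = 60, seed = 6,
                              anchors = c(-225, 225), restarts = 6)
  expect_lt(abs(bt_su$point - 40), 12)
  expect_lt(abs(bt_o$point - 100), 15)
  expect_true(bt_su$ci_lo <= bt_su$point && bt_su$point <= bt_su$ci_hi)
  expect_true(bt_o$ci_lo <= bt_o$point && bt_o$point <= bt_o$ci_hi)
})

test_that("practice curve partitions sessions into consecutive levels", {
  des <- design_spec(d_values = seq(-200, 200, 50), trials_per_d = 40,
                     conditions = c("a", "b"), sessions = 20,
                     blocks_per_session = 2)
  obs <- observer_spec(c_su = 50, sigma = 40, seed = 39)
  trials <- simulate_observer(des, obs)
  pc <- practice_curve(trials, sessions_per_level = 5, estimator = "sk",
                       B = 100, seed = 1, anchors = c(-225, 225))
  expect_equal(sort(unique(pc$level)), 1:4)
  expect_equal(nrow(pc), 4 * 2)
  # stationary observer: level estimates vary within CI widths
  for (cond in c("a", "b")) {
    sub <- pc[pc$condition == cond, ]
    expect_lt(max(sub$point) - min(sub$point),
              2 * max(sub$ci_hi - sub$ci_lo))
  }
})

test_that("one level equals the pooled estimate", {
  des <- design_spec(d_values = seq(-200, 200, 50), trials_per_d = 30,
                     conditions = "a", sessions = 5,
                     blocks_per_session = 1)
  obs <- observer_spec(c_su = 50, seed = 40)
  trials <- simulate_observer(des, obs)
  pc <- practice_curve(trials, sessions_per_level = 5, estimator = "sk",
                       B = 50, seed = 1, anchors = c(-225, 225))
  expect_equal(nrow(pc), 1L)
  pooled <- sk_threshold(tabulate_counts(trials)[["a"]],
                         anchors = c(-225, 225))
  expect_equal(pc$point, pooled$threshold)
})

test_that("paired t and d_z match the closed-form on a hand example", {
  a <- c(10, 20, 36)
  b <- c(6, 12, 20)
  diffs <- a - b          # 4, 8, 16
  m <- mean(diffs); s <- sd(diffs)
  gs <- paired_t_dz(a, b)
  expect_equal(gs$t, m / (s / sqrt(3)))
  expect_equal(gs$d_z, m / s)
  expect_equal(gs$df, 2L)
  expect_equal(gs$p, 2 * pt(-abs(gs$t), df = 2))
})

test_that("paired t handles identical and zero-variance inputs", {
  gs0 <- paired_t_dz(c(5, 7, 9), c(5, 7, 9))
  expect_equal(gs0$t, 0)
  expect_equal(gs0$d_z, 0)
  gs_inf <- paired_t_dz(c(5, 7, 9), c(2, 4, 6))
  expect_true(is.infinite(gs_inf$t) && gs_inf$t > 0)
  expect_error(paired_t_dz(1:3, 1:2), "equal length")
})
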