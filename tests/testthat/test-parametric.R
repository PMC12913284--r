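test_that("response probabilities are a proper trinomial at every d", {
  obs <- observer_spec(mu = -15, sigma = 70, c_su = 35, c_o = 110,
                       gamma = 0.3)
  p <- ttm_probabilities(obs, seq(-400, 400, 25))
  expect_true(all(p >= 0))
  expect_true(all(abs(rowSums(p) - 1) < 1e-12))
})

test_that("probabilities are symmetric when mu = 0, d = 0 and gamma = 1/2", {
  obs <- observer_spec(mu = 0, sigma = 50, c_su = 30, c_o = 90, gamma = 0.5)
  p <- ttm_probabilities(obs, 0)
  expect_equal(unname(p[1, "p_xy"]), unname(p[1, "p_yx"]))
})

test_that("closed form matches a Monte-Carlo run of the verbal decision rule", {
  obs <- observer_spec(mu = 20, sigma = 60, c_su = 40, c_o = 120,
                       gamma = 0.4)
  n_draws <- 2e5
  for (d in c(-150, -30, 0, 60, 180)) {
    mc <- mc_decision_rule(obs, d, n_draws, seed = 1000 + d)
    p <- ttm_probabilities(obs, d)[1, ]
    for (resp in c("p_xy", "p_si", "p_yx")) {
      se <- sqrt(max(p[resp] * (1 - p[resp]), 1e-12) / n_draws)
      expect_lt(abs(mc[resp] - p[resp]), 4 * se + 1e-9)
    }
  }
})

test_that("single-threshold special case collapses the guess region", {
  obs <- observer_spec(mu = 0, sigma = 50, c_su = 60, c_o = 60, gamma = 0.9)
  p1 <- ttm_probabilities(obs, c(-80, 0, 80))
  obs2 <- observer_spec(mu = 0, sigma = 50, c_su = 60, c_o = 60, gamma = 0.1)
  p2 <- ttm_probabilities(obs2, c(-80, 0, 80))
  expect_equal(p1, p2)  # gamma has no effect when c_su = c_o
})

test_that("fit recovers generating parameters on a moderate dataset", {
  obs <- observer_spec(mu = 20, sigma = 60, c_su = 40, c_o = 120,
                       gamma = 0.4, seed = 500)
  cc <- simulate_counts(obs, exp1_grid, n_per_d = 400)
  fit <- fit_two_threshold(cc, restarts = 10, seed = 1,
                           anchors = c(-225, 225))
  expect_true(fit$converged)
  expect_lt(abs(fit$mu - 20), 8)
  expect_lt(abs(fit$c_su - 40), 8)
  expect_lt(abs(fit$c_o - 120), 12)
  expect_lt(abs(fit$gamma - 0.4), 0.1)
  expect_gte(fit$c_o, fit$c_su)
  expect_lte(fit$loglik, 0)
})

test_that("likelihood at the optimum dominates the generating parameters", {
  for (seed in 1:5) {
    obs <- observer_spec(mu = -10, sigma = 50, c_su = 30, c_o = 80,
                         gamma = 0.6, seed = 600 + seed)
    cc <- simulate_counts(obs, seq(-200, 200, 25), n_per_d = 150)
    fit <- fit_two_threshold(cc, restarts = 6, seed = seed,
                             anchors = c(-225, 225))
    # full log-likelihood at the generating parameters
    p_true <- ttm_probabilities(obs, cc$d_values)
    ll_gen <- sum(cc$n_xy * log(pmax(p_true[, 1], 1e-9)) +
                    cc$n_si * log(pmax(p_true[, 2], 1e-9)) +
                    cc$n_yx * log(pmax(p_true[, 3], 1e-9)))
    expect_gte(fit$loglik, ll_gen - 1e-6)
  }
})

test_that("fit is translation-equivariant in d", {
  obs <- observer_spec(mu = 10, sigma = 55, c_su = 45, c_o = 100,
                       gamma = 0.5, seed = 700)
  d <- seq(-200, 200, 25)
  cc <- simulate_counts(obs, d, n_per_d = 400)
  shift <- 60
  cc_shift <- condition_counts("shifted", d + shift, cc$n_xy, cc$n_si,
                               cc$n_yx)
  fit0 <- fit_two_threshold(cc, restarts = 8, seed = 2,
                            anchors = c(-225, 225))
  fit1 <- fit_two_threshold(cc_shift, restarts = 8, seed = 2,
                            anchors = c(-225 + shift, 225 + shift))
  expect_lt(abs((fit1$mu + shift) - fit0$mu), 2)
  expect_lt(abs(fit1$c_su - fit0$c_su), 2)
  expect_lt(abs(fit1$c_o - fit0$c_o), 2)
  expect_lt(abs(fit1$sigma - fit0$sigma), 2)
})

test_that("collapsed generator (c_su = c_o) yields delta near zero and no LR gain", {
  obs <- observer_spec(mu = 0, sigma = 50, c_su = 60, c_o = 60,
                       gamma = 0.5, seed = 800)
  cc <- simulate_counts(obs, exp1_grid, n_per_d = 400)
  fit <- fit_two_threshold(cc, restarts = 10, seed = 3,
                           anchors = c(-225, 225))
  expect_lt(fit$c_o - fit$c_su, 5)

  # single-threshold submodel: profile the likelihood with delta fixed 0
  nll1 <- function(th) centhresh:::ttm_negloglik(c(th[1:3], 0, 0),
                                                 cc$d_values, cc$n_xy,
                                                 cc$n_si, cc$n_yx)
  sub <- stats::optim(c(fit$mu, log(fit$sigma), fit$c_su), nll1,
                      method = "L-BFGS-B", lower = c(-Inf, -Inf, 0))
  lr <- 2 * (fit$loglik - (-sub$value))
  expect_lt(lr, qchisq(0.99, df = 2))  # no significant improvement
})

test_that("counts proportional to the model reach the saturated bound", {
  obs <- observer_spec(mu = 5, sigma = 45, c_su = 30, c_o = 70, gamma = 0.4)
  cc <- exact_counts(obs, seq(-150, 150, 25), n_per_d = 100000)
  fit <- fit_two_threshold(cc, restarts = 8, seed = 4, anchors = c(-175, 175))
  n <- cc$n_xy + cc$n_si + cc$n_yx
  phat <- cbind(cc$n_xy, cc$n_si, cc$n_yx) / n
  sat <- sum(cbind(cc$n_xy, cc$n_si, cc$n_yx) *
               ifelse(phat > 0, log(pmax(phat, 1e-300)), 0))
  expect_lt(sat - fit$loglik, 1)      # within 1 log-lik unit of saturation
  expect_gte(sat + 1e-9, fit$loglik)  # saturated bound is an upper bound
})

test_that("degenerate inputs are rejected", {
  cc <- condition_counts("a", c(-50, 0, 50), n_xy = c(0, 5, 9),
                         n_si = c(1, 3, 1), n_yx = c(9, 2, 0))
  expect_error(fit_two_threshold(cc), "at least 5")
})
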