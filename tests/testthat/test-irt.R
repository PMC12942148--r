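test_that("2PL response probabilities take their closed-form values", {
  expect_equal(prob_2pl(0.3, 1.2, 0.3), 0.5)
  expect_equal(prob_2pl(1, 1, 0), 0.73106, tolerance = 1e-5)
  expect_equal(prob_2pl(0, 2, 1), 0.11920, tolerance = 1e-4)
  expect_error(prob_2pl(0, -1, 0), "positive")
})

test_that("EM calibration recovers the generating item parameters", {
  sim <- simulate_effort_data(effort_config(I = 2000, J = 30, pi = 0, seed = 31))
  fit <- fit_2pl(sim$U)
  expect_true(fit$converged)
  expect_lte(median(abs(fit$b_hat - sim$items$b)), 0.05)
  expect_lte(median(abs(fit$a_hat - sim$items$a)), 0.15)
  # marginal log-likelihood is non-decreasing along the EM path
  expect_true(all(diff(fit$loglik_trace) >= -1e-8))
})

test_that("EM calibration is deterministic and permutation-equivariant", {
  sim <- simulate_effort_data(effort_config(I = 400, J = 10, pi = 0, seed = 32))
  f1 <- fit_2pl(sim$U)
  f2 <- fit_2pl(sim$U)
  expect_identical(f1$a_hat, f2$a_hat)
  expect_identical(f1$b_hat, f2$b_hat)

  perm <- c(4, 1, 10, 2, 9, 3, 8, 5, 7, 6)
  fp <- fit_2pl(sim$U[, perm])
  expect_equal(fp$a_hat, f1$a_hat[perm], tolerance = 1e-6)
  expect_equal(fp$b_hat, f1$b_hat[perm], tolerance = 1e-6)
})

test_that("estimation error shrinks with the calibration sample size", {
  big <- simulate_effort_data(effort_config(I = 2000, J = 15, pi = 0, seed = 33))
  small_cfg <- effort_config(I = 500, J = 15, pi = 0, seed = 33)
  small <- simulate_effort_data(small_cfg)   # same bank (same seed, same J)
  expect_equal(big$items, small$items)
  err <- function(sim) {
    f <- fit_2pl(sim$U)
    median(c(abs(f$a_hat - sim$items$a), abs(f$b_hat - sim$items$b)))
  }
  expect_lt(err(big), err(small))
})

test_that("degenerate and invalid response matrices are handled", {
  sim <- simulate_effort_data(effort_config(I = 300, J = 8, pi = 0, seed = 34))
  U <- sim$U
  U[, 3] <- 1L
  expect_warning(fit <- fit_2pl(U), "constant")
  expect_false(fit$item_converged[3])

  bad <- sim$U; bad[1, 1] <- 2L
  expect_error(fit_2pl(bad), "binary")
})

test_that("ability MLE solves the score equation", {
  # Rasch closed form: logit of the proportion correct
  est <- estimate_theta_mle(c(rep(1, 7), rep(0, 3)), rep(1, 10), rep(0, 10))
  expect_equal(est$theta_hat, log(7 / 3), tolerance = 1e-6)
  expect_equal(est$status, "interior")

  # clamping at perfect / zero scores
  expect_equal(estimate_theta_mle(rep(1, 5), rep(1, 5), rep(0, 5)),
               list(theta_hat = 4, status = "clamped_high"))
  expect_equal(estimate_theta_mle(rep(0, 5), rep(1, 5), rep(0, 5)),
               list(theta_hat = -4, status = "clamped_low"))

  # 2PL instance against the brute-force grid maximizer
  a <- c(1, 1.5, 2); b <- c(-1, 0, 1); u <- c(1, 1, 0)
  est2 <- estimate_theta_mle(u, a, b)
  expect_equal(est2$theta_hat, oracle_theta_grid(u, a, b), tolerance = 1e-5)

  expect_error(estimate_theta_mle(integer(0), numeric(0), numeric(0)), "empty")
})

test_that("interior MLEs leave a vanishing score residual", {
  set.seed(41)
  for (k in 1:50) {
    inst <- random_pf_instance()
    if (is.null(inst)) next
    est <- estimate_theta_mle(inst$u, inst$a, inst$b)
    if (est$status != "interior") next
    resid <- sum(inst$a * (inst$u - prob_2pl(est$theta_hat, inst$a, inst$b)))
    expect_lt(abs(resid), 1e-8)
  }
})

test_that("tidy and glance expose the calibration results", {
  sim <- simulate_effort_data(effort_config(I = 300, J = 6, pi = 0, seed = 35))
  fit <- fit_2pl(sim$U)
  td <- tidy(fit)
  expect_named(td, c("item", "a_hat", "b_hat", "converged"))
  expect_equal(nrow(td), 6)
  gl <- glance(fit)
  expect_equal(gl$n_persons, 300)
  expect_true(gl$loglik < 0)
})
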