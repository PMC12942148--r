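test_that("lz matches hand-evaluated worked examples", {
  # two identical items, theta = 1: P = 0.73106, w = 1
  expect_equal(compute_lz(c(1, 1), 1, c(1, 1), c(0, 0)), 0.8578,
               tolerance = 1e-4)
  expect_equal(compute_lz(c(0, 0), 1, c(1, 1), c(0, 0)), -2.3317,
               tolerance = 1e-4)
  # theta at every difficulty: all weights zero
  deg <- compute_lz(c(1, 0), 0, c(1, 1), c(0, 0))
  expect_true(is.na(deg))
  expect_equal(attr(deg, "degenerate_reason"), "zero_variance")
})

test_that("the Snijders correction components satisfy their defining identities", {
  # symmetric Rasch pair: cJ = 0, corrected weights equal raw weights
  comp <- lzstar_components(0, c(1, 1), c(-1, 1))
  expect_equal(comp$cJ, 0)
  expect_equal(comp$w_star, comp$w)
  expect_equal(comp$r, c(1, 1))
  expect_identical(comp$r0, 0)

  # identical Rasch items: constant weights annihilated -> degenerate
  comp2 <- lzstar_components(0.5, c(1, 1, 1), c(0, 0, 0))
  expect_equal(comp2$degenerate_reason, "zero_variance")

  # defining identity w* + cJ * a - w = 0 on random instances
  set.seed(52)
  for (k in 1:25) {
    inst <- random_pf_instance()
    if (is.null(inst)) next
    th <- estimate_theta_mle(inst$u, inst$a, inst$b)$theta_hat
    cm <- lzstar_components(th, inst$a, inst$b)
    expect_lt(max(abs(cm$w_star + cm$cJ * cm$r - cm$w)), 1e-12)
    expect_lt(max(abs(cm$Pprime - inst$a * cm$P * (1 - cm$P))), 1e-12)
  }
})

test_that("lz* equals the independent oracle on the worked Rasch example", {
  # b = (-1, 1), u = (1, 0): theta-hat = 0 solves the score equation, cJ = 0
  est <- estimate_theta_mle(c(1, 0), c(1, 1), c(-1, 1))
  expect_equal(est$theta_hat, 0, tolerance = 1e-8)
  expect_equal(compute_lz_star(c(1, 0), 0, c(1, 1), c(-1, 1)), 0.8578,
               tolerance = 1e-4)
  # Guttman error, same items
  expect_equal(compute_lz_star(c(0, 1), 0, c(1, 1), c(-1, 1)), -2.3317,
               tolerance = 1e-4)
})

test_that("vectorized statistics agree with direct formula evaluation", {
  set.seed(53)
  n_checked <- 0
  while (n_checked < 200) {
    inst <- random_pf_instance()
    if (is.null(inst)) next
    th <- estimate_theta_mle(inst$u, inst$a, inst$b)
    if (th$status != "interior") next
    expect_equal(compute_lz(inst$u, th$theta_hat, inst$a, inst$b),
                 oracle_lz(inst$u, th$theta_hat, inst$a, inst$b),
                 tolerance = 1e-10)
    expect_equal(compute_lz_star(inst$u, th$theta_hat, inst$a, inst$b),
                 oracle_lzstar(inst$u, th$theta_hat, inst$a, inst$b),
                 tolerance = 1e-10)
    n_checked <- n_checked + 1
  }
})

test_that("lz* is invariant to item ordering", {
  set.seed(54)
  inst <- random_pf_instance(20)
  th <- estimate_theta_mle(inst$u, inst$a, inst$b)$theta_hat
  v0 <- compute_lz_star(inst$u, th, inst$a, inst$b)
  for (k in 1:5) {
    p <- sample(20)
    expect_equal(compute_lz_star(inst$u[p], th, inst$a[p], inst$b[p]), v0,
                 tolerance = 1e-12)
  }
})

test_that("flagging uses a strict threshold", {
  expect_true(flag_noneffortful(-1.7))
  expect_false(flag_noneffortful(0))
  expect_false(flag_noneffortful(-1.645))
  expect_equal(flag_noneffortful(c(-2, NA, 1)), c(TRUE, NA, FALSE))
})

test_that("person_fit returns a consistent per-person table", {
  sim <- simulate_effort_data(effort_config(I = 200, J = 12, seed = 55))
  pf <- person_fit(sim$U, sim$items)
  expect_named(pf, c("person", "theta_hat", "status", "lz", "lz_star",
                     "flagged", "degenerate_reason"))
  ok <- !is.na(pf$lz_star)
  expect_identical(pf$flagged[ok], pf$lz_star[ok] < -1.645)
  expect_true(all(abs(pf$theta_hat) <= 4))
  # same statistics when abilities are supplied precomputed
  th <- estimate_abilities(sim$U, sim$items)
  pf2 <- person_fit(sim$U, sim$items, theta_hat = th)
  expect_equal(pf, pf2)
})
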