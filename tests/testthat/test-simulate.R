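test_that("item parameters respect their generating distributions", {
  set.seed(11)
  items <- draw_item_parameters(50)
  expect_true(all(items$a > 1 & items$a < 2.5))
  expect_true(all(items$alpha > 1.5 & items$alpha < 2.5))
  expect_true(all(items$beta > -0.2 & items$beta < 0.2))

  set.seed(99)
  big <- draw_item_parameters(1e5)
  expect_equal(mean(big$a), 1.75, tolerance = 0.02 / 1.75)

  set.seed(7); bank1 <- draw_item_parameters(15)
  set.seed(7); bank2 <- draw_item_parameters(15)
  expect_identical(bank1, bank2)

  expect_error(draw_item_parameters(0), "positive")
})

test_that("person parameters reproduce the target covariance structure", {
  set.seed(21)
  p <- draw_person_parameters(1e5)
  expect_equal(cor(p$theta, p$tau), 0.25 / sqrt(0.1275), tolerance = 0.03)
  expect_lt(abs(mean(p$theta)), 0.02)
  expect_equal(mean(p$tau), -3.5, tolerance = 0.01)

  set.seed(22)
  ind <- draw_person_parameters(2e4, mu = c(0, 0), Sigma = diag(c(2, 2)))
  expect_lt(abs(cor(ind$theta, ind$tau)), 0.03)

  expect_error(draw_person_parameters(10, Sigma = matrix(c(1, 2, 2, 1), 2, 2)),
               "positive definite")
})

test_that("non-effort assignment hits the prevalence and tercile quotas exactly", {
  cfg <- effort_config(I = 1000, J = 30, pi = 0.4, severity = "high", seed = 3)
  set.seed(3)
  persons <- draw_person_parameters(1000)
  asg <- assign_noneffort(persons, cfg)
  expect_equal(sum(asg$is_noneffortful), 400)

  terc <- cut(rank(persons$tau, ties.method = "first"),
              breaks = c(0, 333, 666, 1000), labels = 1:3)
  counts <- table(terc[asg$is_noneffortful])
  expect_equal(as.integer(counts), c(240, 120, 40))

  # mask contract: effortful rows empty, non-effortful rows sized by severity
  expect_true(all(rowSums(asg$noneffort_mask[!asg$is_noneffortful, ]) == 0))
  ne <- which(asg$is_noneffortful)
  expect_equal(rowSums(asg$noneffort_mask[ne, ]),
               round(asg$pi_i[ne] * 30), ignore_attr = TRUE)
  # high severity at J=30: round(U(0.5, 0.75) * 30) lies in [15, 23]
  expect_true(all(rowSums(asg$noneffort_mask[ne, ]) >= 15))
  expect_true(all(rowSums(asg$noneffort_mask[ne, ]) <= 23))
})

test_that("zero prevalence marks nobody", {
  cfg <- effort_config(I = 200, J = 10, pi = 0, seed = 1)
  set.seed(1)
  asg <- assign_noneffort(draw_person_parameters(200), cfg)
  expect_false(any(asg$is_noneffortful))
  expect_false(any(asg$noneffort_mask))
})

test_that("observation model matches the mixture components", {
  # one person, one item, many replicate cells via a large synthetic layout
  cfg <- effort_config(I = 1e5, J = 1, pi = 0, drt = "low", seed = 5)
  items <- tibble::tibble(item = 1L, a = 1.5, b = 0.2, alpha = 2, beta = 0.1)
  persons <- tibble::tibble(person = seq_len(1e5),
                            theta = rep(0.7, 1e5), tau = rep(-3.5, 1e5))
  # all cells non-effortful
  asg_ne <- list(is_noneffortful = rep(TRUE, 1e5),
                 pi_i = rep(1, 1e5),
                 noneffort_mask = matrix(TRUE, 1e5, 1))
  set.seed(5)
  obs <- generate_observations(items, persons, asg_ne, cfg)
  expect_equal(mean(obs$U), 0.25, tolerance = 0.01 / 0.25)
  expect_equal(mean(log(obs$T_mat)), -1, tolerance = 0.012)
  expect_equal(var(as.numeric(log(obs$T_mat))), 0.25, tolerance = 0.01 / 0.25)

  # all cells effortful: accuracy and log-time moments follow the 2PL/lognormal
  asg_eff <- list(is_noneffortful = rep(FALSE, 1e5),
                  pi_i = rep(NA_real_, 1e5),
                  noneffort_mask = matrix(FALSE, 1e5, 1))
  set.seed(6)
  obs2 <- generate_observations(items, persons, asg_eff, cfg)
  expect_equal(mean(obs2$U), prob_2pl(0.7, 1.5, 0.2), tolerance = 0.02)
  expect_equal(mean(log(obs2$T_mat)), 0.1 - (-3.5), tolerance = 0.01)
  expect_equal(var(as.numeric(log(obs2$T_mat))), 1 / 4, tolerance = 0.05)
})

test_that("simulated datasets are deterministic and well-formed", {
  cfg <- effort_config(I = 500, J = 15, pi = 0.2, seed = 17)
  s1 <- simulate_effort_data(cfg)
  s2 <- simulate_effort_data(cfg)
  expect_identical(s1$U, s2$U)
  expect_identical(s1$T_mat, s2$T_mat)

  expect_equal(dim(s1$U), c(500L, 15L))
  expect_true(all(s1$U %in% 0:1))
  expect_true(all(s1$T_mat > 0))
  expect_equal(sum(s1$persons$is_noneffortful), 100)

  td <- tidy(s1)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("person", "theta", "tau", "is_noneffortful", "pi_i",
                     "prop_correct", "mean_rt"))
})

test_that("datasets round-trip through the CSV writers", {
  sim <- simulate_effort_data(effort_config(I = 40, J = 6, seed = 2))
  dir <- withr::local_tempdir()
  paths <- write_effort_data(sim, dir)
  expect_true(all(file.exists(paths)))
  back <- read_effort_data(paths["responses"], paths["times"])
  expect_equal(unname(back$U), unname(sim$U))
  expect_equal(unname(back$T_mat), unname(sim$T_mat), tolerance = 1e-12)
})
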