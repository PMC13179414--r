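test_that("scenario coefficient vectors have the stated shapes", {
  gA <- scenario_coefficients("A")
  expect_equal(length(gA), 10)
  expect_true(all(abs(gA - gA[1]) < 1e-15))          # equal influence
  expect_equal(sum(gA^2), 1, tolerance = 1e-12)

  gB <- scenario_coefficients("B")
  expect_true(all(diff(gB) < 0))                     # strictly decreasing
  expect_equal(gB[1] / gB[10], 10)                   # delta_1 / delta_10
  expect_equal(sum(gB^2), 1, tolerance = 1e-12)

  gC <- scenario_coefficients("C")
  expect_equal(gC[6:10], rep(0, 5))                  # only X1..X5 matter
  expect_equal(sum(gC^2), 1, tolerance = 1e-12)

  expect_error(scenario_coefficients("D"), "unknown")
})

test_that("empirical-quantile censoring hits the order statistic exactly", {
  set.seed(42)
  n <- 1000
  T1 <- rexp(n) * 100
  T2 <- rexp(n) * 100
  cens <- apply_censoring(T1, T2, q = 0.35)
  expect_equal(sum(pmin(T1, T2) <= cens$t_cens), 350)
  # events are recorded strictly before t_cens: the subject attaining the
  # order statistic is censored, so 349 subjects carry an observed event
  ev <- cens$data$event_death == 1 | cens$data$event_nonfatal == 1
  expect_equal(sum(ev), 349)
})

test_that("censoring keeps the composite outcome internally consistent", {
  d <- simulate_trial(400, scenario = "B", seed = 5)
  expect_silent(validate_trial_data(d))
  expect_true(all(d$time_nonfatal <= d$time_death))
  expect_true(all(d$time_death <= attr(d, "t_cens")))
  # no nonfatal event: nonfatal time equals end of follow-up
  i <- d$event_nonfatal == 0
  expect_equal(d$time_nonfatal[i], d$time_death[i])
})

test_that("nearly no censoring recovers almost all events", {
  set.seed(7)
  T1 <- rexp(500)
  T2 <- rexp(500)
  cens <- apply_censoring(T1, T2, q = 0.999)
  ev <- cens$data$event_death == 1 | cens$data$event_nonfatal == 1
  expect_gte(mean(ev), 0.99)
})

test_that("identical latent times leave every comparison tied", {
  Tc <- rep(10, 20)
  cens <- apply_censoring(Tc, Tc, q = 0.35)
  S <- score_matrix(cens$data)
  expect_true(all(S == 0.5))
})

test_that("simulation is reproducible by seed", {
  d1 <- simulate_trial(100, "A", seed = 77)
  d2 <- simulate_trial(100, "A", seed = 77)
  d3 <- simulate_trial(100, "A", seed = 78)
  expect_identical(d1, d2)
  expect_false(isTRUE(all.equal(d1$time_death, d3$time_death)))
})

test_that("outcome marginals coincide across scenarios", {
  # gamma'X ~ N(0,1) in all scenarios, so the latent first-event time
  # distribution is scenario-free
  dA <- simulate_trial(3000, "A", seed = 100)
  dC <- simulate_trial(3000, "C", seed = 200)
  lA <- attr(dA, "latent")
  lC <- attr(dC, "latent")
  ks <- suppressWarnings(stats::ks.test(pmin(lA$T1, lA$T2),
                                        pmin(lC$T1, lC$T2)))
  expect_gt(ks$p.value, 0.001)
})

test_that("no treatment effect and no covariate effect give nu near 1/2", {
  d <- simulate_trial(5000, gamma = rep(0, 3), treatment_effect = 0,
                      seed = 9)
  r <- win_odds(d)
  expect_lt(abs(r$nu - 0.5), 3 * r$se_nu)
})

test_that("a positive treatment effect yields marginal win odds above 1", {
  d <- simulate_trial(2000, "A", treatment_effect = 0.3, seed = 10)
  r <- win_odds(d)
  expect_gt(r$nu - 0.5, 3 * r$se_nu)
  expect_gt(r$theta, 1)
})

test_that("flipped treatment is independent of outcomes and covariates", {
  set.seed(55)
  cors <- nus <- numeric(40)
  for (r in seq_len(40)) {
    d <- simulate_trial(300, "A")
    d <- flip_treatment(d)
    cors[r] <- cor(d$arm, d$X1)
    nus[r] <- win_statistics(score_matrix(d), d$arm)$nu_direct
  }
  expect_lt(abs(mean(cors)), 0.03)
  expect_lt(abs(mean(nus) - 0.5), 0.01)
})

test_that("permutation flip preserves group sizes", {
  d <- simulate_trial(200, "A", seed = 12)
  f <- flip_treatment(d, method = "permute", seed = 1)
  expect_equal(sum(f$arm), sum(d$arm))
  expect_false(identical(f$arm, d$arm))
})

test_that("the flip-null distribution does not depend on the flip seed", {
  nu1 <- nu2 <- numeric(150)
  for (r in seq_len(150)) {
    d <- simulate_trial(150, "A", seed = 3000 + r)
    f1 <- flip_treatment(d, seed = 10 + r)
    f2 <- flip_treatment(d, seed = 20000 + r)
    nu1[r] <- win_statistics(score_matrix(f1), f1$arm)$nu_direct
    nu2[r] <- win_statistics(score_matrix(f2), f2$arm)$nu_direct
  }
  ks <- suppressWarnings(stats::ks.test(nu1, nu2))
  expect_gt(ks$p.value, 0.001)
})

test_that("the operating-characteristics runner is deterministic and tidy", {
  oc1 <- run_operating_characteristics("A", n = 80, n_reps = 10,
                                       adjust = list("unadjusted", 1),
                                       seed = 5)
  oc2 <- run_operating_characteristics("A", n = 80, n_reps = 10,
                                       adjust = list("unadjusted", 1),
                                       seed = 5)
  expect_equal(as.data.frame(oc1), as.data.frame(oc2))
  expect_equal(nrow(oc1), 2)
  expect_true(all(oc1$rate >= 0 & oc1$rate <= 1))
  rej <- attr(oc1, "rejections")[["A_n80"]]
  expect_equal(dim(rej), c(10, 2))
})
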