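test_that("with no covariates the PIM collapses to logit(nu_direct)", {
  for (seed in c(1, 2)) {
    d <- random_trial(80, seed)
    S <- score_matrix(d)
    pim <- fit_pim(S, d$arm)
    nu <- win_statistics(S, d$arm)$nu_direct
    expect_equal(pim$tau_A, log(nu / (1 - nu)), tolerance = 1e-8)
    expect_equal(standardize_pim(pim), nu, tolerance = 1e-10)
  }
})

test_that("an all-tie score matrix is solved exactly by beta = 0", {
  set.seed(3)
  n <- 30
  S <- matrix(0.5, n, n)
  arm <- rep(c(0, 1), n / 2)
  X <- matrix(rnorm(2 * n), n, 2)
  pim <- fit_pim(S, arm, X)
  expect_equal(pim$tau_A, 0)
  expect_equal(unname(pim$tau_X), c(0, 0))
  expect_true(pim$converged)
})

test_that("Fisher scoring matches glm on the pseudo-observations", {
  d <- random_trial(45, 13)
  S <- score_matrix(d)
  X <- as.matrix(d[, c("X1", "X2", "X3")])
  pim <- fit_pim(S, d$arm, X)
  ref <- suppressWarnings(glm_pim(S, d$arm, X))
  expect_equal(unname(c(pim$tau_A, pim$tau_X)), unname(ref),
               tolerance = 1e-6)
})

test_that("the solver recovers known PIM coefficients", {
  # pairwise responses drawn from a true logit PIM; the estimating
  # equations are unbiased, so estimates land within Monte-Carlo spread
  set.seed(101)
  n <- 300
  arm <- rbinom(n, 1, 0.5)
  X <- matrix(rnorm(2 * n), n, 2)
  tau <- c(0.4, 0.6, -0.5)
  S <- matrix(0.5, n, n)
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      p <- expit_(tau[1] * (arm[j] - arm[i]) + sum(tau[2:3] * (X[j, ] - X[i, ])))
      S[i, j] <- rbinom(1, 1, p)
      S[j, i] <- 1 - S[i, j]
    }
  }
  fit <- fit_pim(S, arm, X)
  expect_lt(max(abs(c(fit$tau_A, fit$tau_X) - tau)), 0.05)
})

test_that("standardization matches the naive pair average", {
  d <- random_trial(40, 14)
  S <- score_matrix(d)
  X <- as.matrix(d[, c("X1", "X2")])
  pim <- fit_pim(S, d$arm, X)
  expect_equal(standardize_pim(pim, X),
               oracle_nu_stand(pim$tau_A, pim$tau_X, X),
               tolerance = 1e-12)
})

test_that("augmentation equals standardization and collapses for flat H", {
  d <- random_trial(50, 15)
  S <- score_matrix(d)
  X <- as.matrix(d[, c("X1", "X2", "X3")])
  pim <- fit_pim(S, d$arm, X)
  nu_direct <- win_statistics(S, d$arm)$nu_direct
  n <- nrow(d)
  aug <- augment_pim(S, d$arm, pim, X)
  expect_equal(aug, standardize_pim(pim, X), tolerance = 1e-8)
  expect_equal(aug, oracle_nu_aug(S, d$arm, pim$tau_A, pim$tau_X, X),
               tolerance = 1e-12)
  # H identically zero and H constant both vanish from the augmentation
  expect_equal(augment_pim(S, d$arm, H = matrix(0, n, n)), nu_direct)
  expect_equal(augment_pim(S, d$arm, H = matrix(0.37, n, n)), nu_direct,
               tolerance = 1e-12)
})

test_that("adjusted result satisfies the scale-transform identities", {
  d <- random_trial(150, 16)
  res <- adjusted_inference(d, covariates = c("X1", "X2"))
  expect_equal(res$ci_theta, res$ci_nu / (1 - res$ci_nu))
  expect_equal(res$se_log_theta, res$se_nu / (res$nu * (1 - res$nu)))
  # at nu = 1/2 the log-theta variance is 16 x the nu variance
  expect_equal((0.5 * (1 - 0.5))^-2, 16)
})

test_that("empty adjustment set reproduces the direct analysis", {
  d <- random_trial(120, 17)
  direct <- win_odds(d)
  adj <- adjusted_inference(d, covariates = character())
  expect_equal(adj$nu, direct$nu, tolerance = 1e-10)
  expect_equal(adj$theta, direct$theta, tolerance = 1e-9)
})

test_that("arm relabeling flips the adjusted estimate symmetrically", {
  d <- random_trial(120, 18)
  r1 <- adjusted_inference(d, covariates = c("X1", "X2"))
  d2 <- d
  d2$arm <- 1 - d$arm
  r2 <- adjusted_inference(d2, covariates = c("X1", "X2"))
  expect_equal(r2$nu, 1 - r1$nu, tolerance = 1e-8)
  expect_equal(abs(r2$z), abs(r1$z), tolerance = 1e-6)
})

test_that("sandwich variance tracks the direct variance without covariates", {
  d <- random_trial(2000, 31)
  S <- score_matrix(d)
  r_direct <- direct_inference(S, d$arm)
  pim <- fit_pim(S, d$arm)
  v <- sandwich_variance(S, d$arm, pim)
  expect_equal(as.numeric(v), r_direct$se_nu^2, tolerance = 0.01)
})

test_that("streaming engine reproduces the dense engine", {
  d <- random_trial(150, 19)
  dense <- adjusted_inference(d, covariates = c("X1", "X2"),
                              engine = "dense")
  stream <- adjusted_inference(d, covariates = c("X1", "X2"),
                               engine = "streaming")
  expect_equal(stream$nu, dense$nu, tolerance = 1e-12)
  expect_equal(stream$se_nu, dense$se_nu, tolerance = 1e-12)
  expect_equal(stream$pim$tau_A, dense$pim$tau_A, tolerance = 1e-10)
})

test_that("bootstrap variance is in the vicinity of the sandwich", {
  d <- random_trial(200, 20)
  sand <- adjusted_inference(d, covariates = "X1")
  boot <- adjusted_inference(d, covariates = "X1", variance = "bootstrap",
                             boot_reps = 200, boot_seed = 99)
  expect_lt(abs(boot$se_nu / sand$se_nu - 1), 0.3)
})

test_that("adjustment for prognostic covariates reduces Monte-Carlo variance", {
  nu_d <- nu_a <- numeric(60)
  for (r in seq_len(60)) {
    d <- random_trial(500, 500 + r)
    S <- score_matrix(d)
    nu_d[r] <- win_statistics(S, d$arm)$nu_direct
    X <- as.matrix(d[, paste0("X", 1:10)])
    pim <- fit_pim(S, d$arm, X)
    nu_a[r] <- standardize_pim(pim, X)
  }
  expect_lt(var(nu_a), var(nu_d))
})

test_that("a pure-noise covariate perturbs the estimate only slightly", {
  diffs <- se_ratio <- numeric(20)
  for (r in seq_len(20)) {
    d <- random_trial(300, 700 + r)
    set.seed(9000 + r)
    d$noise <- rnorm(nrow(d))
    r1 <- adjusted_inference(d, covariates = "X1")
    r2 <- adjusted_inference(d, covariates = c("X1", "noise"))
    diffs[r] <- r2$nu - r1$nu
    se_ratio[r] <- r2$se_nu / r1$se_nu
  }
  expect_lt(mean(abs(diffs)), 0.01)
  expect_lt(abs(mean(se_ratio) - 1), 0.05)
})

test_that("degenerate and ill-posed designs raise clear errors", {
  d <- random_trial(40, 21)
  S <- score_matrix(d)
  # constant covariate has no pairwise information
  Xc <- cbind(const = rep(2, nrow(d)))
  expect_error(fit_pim(S, d$arm, Xc), "constant")
  # collinear covariates
  X2 <- as.matrix(d[, c("X1", "X2")])
  X2 <- cbind(X2, lin = X2[, 1] - 2 * X2[, 2])
  expect_error(fit_pim(S, d$arm, X2), "rank")
  # iteration cap produces a diagnostic error
  X <- as.matrix(d[, "X1", drop = FALSE])
  expect_error(fit_pim(S, d$arm, X, max_iter = 1L), "converge")
})

test_that("separable pairwise responses trigger the separation guard", {
  # death-only outcomes perfectly ordered by a covariate: the pairwise
  # logistic problem is separable and coefficients diverge
  n <- 24
  d <- data.frame(arm = rep(c(0, 1), n / 2),
                  time_death = seq_len(n) + 0.5, event_death = 1,
                  time_nonfatal = seq_len(n) + 0.5, event_nonfatal = 0,
                  X1 = seq_len(n) / n)
  S <- score_matrix(d)
  expect_error(fit_pim(S, d$arm, as.matrix(d[, "X1", drop = FALSE])),
               "separa")
})
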