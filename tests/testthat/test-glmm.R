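tiny_fixture <- function(seed = 42) {
  # 3 providers x 4 patients with marked between-group heterogeneity (so the
  # random-intercept SD is estimated away from the boundary); small enough
  # for dense-grid integration of the marginal likelihood
  set.seed(seed)
  list(y = c(0, 0, 0, 1, 1, 1, 1, 1, 0, 1, 0, 0),
       X = data.frame(x = round(rnorm(12), 2)),
       g = rep(1:3, each = 4))
}

test_that("marginal log-likelihood matches dense-grid integration", {
  fx <- tiny_fixture()
  fit <- fit_random_intercept_logistic(fx$y, fx$X, fx$g, nAGQ = 25)
  expect_true(fit$converged)
  beta <- fit$fixed$estimate
  oracle <- grid_loglik(fx$y, fx$X, fx$g, beta, fit$sigma)
  expect_equal(fit$loglik, oracle, tolerance = 1e-6)
})

test_that("weighted marginal log-likelihood matches the weighted grid oracle", {
  fx <- tiny_fixture()
  w <- c(1, 2, 1, 3, 1, 1, 2, 1, 1, 1, 2, 1)
  fit <- fit_random_intercept_logistic(fx$y, fx$X, fx$g, weights = w, nAGQ = 25)
  oracle <- grid_loglik(fx$y, fx$X, fx$g, fit$fixed$estimate, fit$sigma, w = w)
  expect_equal(fit$loglik, oracle, tolerance = 1e-6)
})

test_that("quadrature refinement is converged at the default order", {
  fx <- tiny_fixture()
  f15 <- fit_random_intercept_logistic(fx$y, fx$X, fx$g, nAGQ = 15)
  f30 <- fit_random_intercept_logistic(fx$y, fx$X, fx$g, nAGQ = 30)
  expect_lt(abs(f15$loglik - f30$loglik), 1e-6)
})

test_that("unit weights reproduce the unweighted fit", {
  fx <- tiny_fixture()
  f0 <- fit_random_intercept_logistic(fx$y, fx$X, fx$g, nAGQ = 15)
  f1 <- fit_random_intercept_logistic(fx$y, fx$X, fx$g,
                                      weights = rep(1, 12), nAGQ = 15)
  expect_equal(f0$fixed$estimate, f1$fixed$estimate, tolerance = 1e-8)
  expect_equal(f0$sigma, f1$sigma, tolerance = 1e-8)
  expect_equal(f0$eb$deviation, f1$eb$deviation, tolerance = 1e-8)
})

test_that("rescaling all weights barely moves point estimates at design sizes", {
  # the random-effect prior does not rescale with frequency weights, so exact
  # invariance cannot hold in a mixed model; at realistic cluster sizes the
  # fixed effects are insensitive to a common weight factor
  set.seed(12)
  coh <- make_test_cohort(K = 4, n_k = 400)
  dat <- add_test_outcomes(coh, alpha0 = c(-0.3, 0, 0, 0.3))
  f1 <- fit_random_intercept_logistic(dat$y, dat["age"], dat$provider,
                                      weights = rep(2, nrow(dat)), nAGQ = 1)
  f2 <- fit_random_intercept_logistic(dat$y, dat["age"], dat$provider,
                                      weights = rep(4, nrow(dat)), nAGQ = 1)
  expect_equal(f1$fixed$estimate, f2$fixed$estimate, tolerance = 1e-2)
})

test_that("with no group effects the fit collapses to ordinary logistic regression", {
  set.seed(8)
  n <- 4000
  x <- rnorm(n)
  g <- rep(1:4, each = n / 4)
  y <- rbinom(n, 1, plogis(-1 + 0.5 * x))
  fit <- fit_random_intercept_logistic(y, data.frame(x = x), g, nAGQ = 1)
  ref <- glm(y ~ x, family = binomial())
  expect_lt(fit$sigma, 0.05)
  expect_equal(fit$fixed$estimate, unname(coef(ref)), tolerance = 1e-3)
})

test_that("empirical-Bayes deviations are shrunk relative to fixed effects", {
  set.seed(15)
  coh <- make_test_cohort(K = 6, n_k = 300)
  dat <- add_test_outcomes(coh, alpha0 = c(-0.5, -0.2, 0, 0, 0.2, 0.5))
  fit <- fit_random_intercept_logistic(dat$y, dat[case_mix_variables()],
                                       dat$provider, nAGQ = 1)
  eb <- empirical_bayes_deviations(fit)
  # fixed-effect (dummy) deviations from the average provider effect
  fe <- glm(stats::reformulate(c("0 + factor(provider)", case_mix_variables()), "y"),
            family = binomial(), data = dat)
  dummies <- coef(fe)[1:6]
  dev_fe <- dummies - mean(dummies)
  expect_true(all(abs(eb$deviation) < abs(dev_fe) + 1e-8))
  expect_gt(stats::cor(eb$deviation, dev_fe), 0.9)
})

test_that("symmetric two-group data yields mirror-image deviations", {
  y <- c(rep(1, 30), rep(0, 70), rep(1, 70), rep(0, 30))
  g <- rep(1:2, each = 100)
  fit <- fit_random_intercept_logistic(y, NULL, g, nAGQ = 25)
  eb <- empirical_bayes_deviations(fit)
  expect_equal(eb$deviation[1], -eb$deviation[2], tolerance = 1e-4)
  expect_lt(abs(fit$fixed$estimate[1]), 1e-4)
})

test_that("the fast PIRLS profile agrees with adaptive quadrature at design sizes", {
  set.seed(33)
  coh <- make_test_cohort(K = 6, n_k = 500)
  dat <- add_test_outcomes(coh, alpha0 = rnorm(6, 0, 0.1942))
  f0 <- fit_random_intercept_logistic(dat$y, dat[case_mix_variables()],
                                      dat$provider, nAGQ = 0)
  f9 <- fit_random_intercept_logistic(dat$y, dat[case_mix_variables()],
                                      dat$provider, nAGQ = 9)
  expect_lt(abs(f0$sigma - f9$sigma), 5e-3)
  expect_lt(max(abs(f0$eb$deviation - f9$eb$deviation)), 5e-3)
})

test_that("failures are flagged and refused downstream", {
  fit <- fit_random_intercept_logistic(c(0, 1), NULL, c(1, 2), nAGQ = 50)
  if (!fit$converged) {
    expect_error(empirical_bayes_deviations(fit),
                 class = "profilesim_fit_error")
  }
  bad <- structure(list(converged = FALSE), class = "ri_fit")
  expect_error(empirical_bayes_deviations(bad), class = "profilesim_fit_error")
  expect_error(fit_random_intercept_logistic(c(0, 1), NULL, c(1, 2),
                                             weights = c(-1, 1)),
               class = "profilesim_schema_error")
})

test_that("tidy and glance expose the fit in broom style", {
  fx <- tiny_fixture()
  fit <- fit_random_intercept_logistic(fx$y, fx$X, fx$g, nAGQ = 15)
  td <- tidy(fit)
  expect_identical(td$term, c("(Intercept)", "x"))
  expect_true(all(c("estimate", "std.error") %in% names(td)))
  rv <- tidy(fit, effects = "ran_vals")
  expect_identical(nrow(rv), 3L)
  gl <- glance(fit)
  expect_identical(gl$n_groups, 3L)
  expect_true(gl$converged)
})
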