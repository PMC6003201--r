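test_that("scenario validation enforces the design constraints", {
  expect_s3_class(scenario_spec(), "scenario_spec")
  expect_error(scenario_spec(p_bar = 0), class = "profilesim_config_error")
  expect_error(scenario_spec(S = 3), class = "profilesim_config_error")
  # odd outlier count cannot split equally over two sides
  expect_error(scenario_spec(K = 10, p_out = 0.3, S = 2),
               class = "profilesim_config_error")
  expect_s3_class(scenario_spec(K = 10, p_out = 0.3, S = 1), "scenario_spec")
})

test_that("provider truth allocation matches the outlier design", {
  spec <- scenario_spec(K = 50, p_out = 0.2, H = 2, S = 2)
  tr <- allocate_provider_truth(spec, seed = 3)
  expect_identical(sum(tr$class != "normal"), 10L)
  expect_identical(sum(tr$class == "low"), 5L)
  expect_identical(sum(tr$class == "high"), 5L)
  # outlier distribution means at H = 2, sigma = 0.1942
  expect_equal(sort(unique(tr$mu)), c(-0.3884, 0, 0.3884), tolerance = 1e-12)
  expect_true(all(tr$n_k == 1000L))

  one_sided <- allocate_provider_truth(scenario_spec(K = 10, S = 1), seed = 4)
  expect_identical(sum(one_sided$class == "high"), 0L)
  expect_identical(sum(one_sided$class == "low"), 2L)
  expect_true(all(one_sided$mu[one_sided$class == "low"] > 0))

  degenerate <- allocate_provider_truth(scenario_spec(K = 10, H = 0), seed = 5)
  expect_true(all(degenerate$mu == 0))
  expect_identical(sum(degenerate$class != "normal"), 2L)
})

test_that("volume allocation follows min(nk) and P(nmin)", {
  spec <- scenario_spec(K = 10, min_nk = 500, p_nmin = 1)
  tr <- allocate_provider_truth(spec, seed = 6)
  expect_identical(sum(tr$n_k == 500L), 5L)
  expect_identical(sum(tr$n_k == 1000L), 5L)
  # with P(nmin) = 1 every outlier is a small provider
  expect_true(all(tr$n_k[tr$class != "normal"] == 500L))

  # infeasible small-slot demand is reallocated within the constraint
  spec2 <- scenario_spec(K = 10, p_out = 0.8, S = 2, min_nk = 500, p_nmin = 1)
  tr2 <- allocate_provider_truth(spec2, seed = 7)
  expect_identical(sum(tr2$n_k == 500L), 5L)
  expect_identical(attr(tr2, "reallocated"), 3L)
})

test_that("log-odds shifts map to the stated odds ratios", {
  expect_equal(mu_to_odds_ratio(0.3884), 1.475, tolerance = 5e-4)
  expect_equal(mu_to_odds_ratio(-0.3884), 0.678, tolerance = 5e-4)
  expect_identical(mu_to_odds_ratio(0), 1)
})

test_that("intercept calibration solves the closed forms", {
  coh <- tibble::as_tibble(c(list(provider = rep(1:2, each = 50)),
                             setNames(as.list(rep(list(rep(0, 100)), 8)),
                                      case_mix_variables())))
  tr <- tibble::tibble(provider = 1:2, alpha0 = c(0, 0))
  expect_equal(calibrate_intercept(coh, tr, target = 0.5), 0, tolerance = 1e-9)
  expect_equal(calibrate_intercept(coh, tr, target = 0.10), log(1 / 9),
               tolerance = 1e-8)
})

test_that("calibration residual is below 1e-6 on realized replicates", {
  spec <- scenario_spec(K = 10)
  d <- simulate_replicate_data(spec, seed = 14)
  off <- plogis(d$gamma00 +
                  drop(as.matrix(d$data[case_mix_variables()]) %*%
                         euroscore_coefficients()) +
                  d$truth$alpha0[d$data$provider])
  expect_lt(abs(mean(off) - spec$p_bar), 1e-6)
  # per-provider realized incidence respects the 1% floor
  inc <- tapply(d$data$y, d$data$provider, mean)
  expect_true(all(inc >= 0.01))
  # overall realized incidence is near the target (3 binomial SEs)
  expect_lt(abs(mean(d$data$y) - 0.10), 3 * sqrt(0.1 * 0.9 / nrow(d$data)))
})

test_that("outcome generation reduces to iid Bernoulli when effects vanish", {
  coh <- make_test_cohort(K = 2, n_k = 500)
  tr <- tibble::tibble(provider = 1:2, alpha0 = c(0, 0))
  beta0 <- setNames(rep(0, 8), case_mix_variables())
  y <- draw_outcomes(coh, tr, beta = beta0, gamma00 = qlogis(0.3), seed = 9,
                     min_incidence = 0)
  set.seed(9)
  oracle <- rbinom(1000, 1L, 0.3)
  expect_identical(as.integer(y), oracle)

  # threshold 0 accepts the first draw
  expect_identical(attr(y, "redraws"), 0L)
})

test_that("unattainable provider incidence raises a classed error", {
  coh <- make_test_cohort(K = 2, n_k = 200)
  tr <- tibble::tibble(provider = 1:2, alpha0 = c(0, 0))
  beta0 <- setNames(rep(0, 8), case_mix_variables())
  expect_error(
    draw_outcomes(coh, tr, beta = beta0, gamma00 = qlogis(1e-5), seed = 1,
                  min_incidence = 0.05, max_redraws = 5),
    class = "profilesim_incidence_error")
})

test_that("random-intercept draws recover sigma across replicates", {
  spec <- scenario_spec(K = 50)
  draws <- unlist(lapply(1:200, function(s) {
    tr <- allocate_provider_truth(spec, seed = s)
    tr$alpha0[tr$class == "normal"] - tr$mu[tr$class == "normal"]
  }))
  expect_gt(length(draws), 5000)
  expect_lt(abs(sd(draws) / 0.1942 - 1), 0.05)
})
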