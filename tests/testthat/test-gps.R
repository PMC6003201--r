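confounded_cohort <- function(K = 4, n = 1200, seed = 5) {
  # provider attendance driven by case-mix so the gPS fit is informative
  set.seed(seed)
  cov <- generate_cohort(case_mix_config(), n)
  m <- draw_assignment_model(K)
  p <- assignment_probabilities(m, cov)
  g <- -log(-log(matrix(runif(n * K), n, K)))
  dplyr::mutate(cov, provider = max.col(log(p) + g), .before = 1)
}

test_that("gPS rows are probabilities over providers", {
  dat <- confounded_cohort()
  gps <- estimate_gps(dat)
  expect_identical(dim(unclass(gps)), c(1200L, 4L))
  expect_true(all(gps > 0))
  expect_equal(rowSums(gps), rep(1, 1200), tolerance = 1e-10)
})

test_that("two-provider gPS equals binary logistic regression", {
  dat <- confounded_cohort(K = 2, n = 800, seed = 6)
  gps <- estimate_gps(dat)
  vars <- case_mix_variables()
  ref <- glm(stats::reformulate(vars, "I(provider == 2)"),
             family = binomial(), data = dat,
             control = stats::glm.control(epsilon = 1e-12))
  expect_equal(unname(gps[, 2]), unname(fitted(ref)), tolerance = 1e-6)
})

test_that("the Newton engine matches nnet::multinom", {
  dat <- confounded_cohort(K = 4, n = 1000, seed = 7)
  g_newton <- estimate_gps(dat)
  g_nnet <- estimate_gps(dat, engine = "multinom")
  ll <- function(g) sum(log(g[cbind(seq_len(nrow(dat)), dat$provider)]))
  # same optimum: Newton attains at least multinom's likelihood, probabilities agree
  expect_gte(ll(g_newton), ll(g_nnet) - 1e-4)
  expect_lt(max(abs(unclass(g_newton) - unclass(g_nnet))), 5e-3)
})

test_that("intercept-only gPS returns the observed provider shares", {
  dat <- confounded_cohort(K = 3, n = 600, seed = 8)
  gps <- estimate_gps(dat, covariates = character(0))
  shares <- as.numeric(table(factor(dat$provider, 1:3))) / 600
  expect_equal(unname(gps[1, ]), shares, tolerance = 1e-12)
  expect_true(all(apply(unclass(gps), 2, function(col) length(unique(col)) == 1)))
})

test_that("inverse-probability weights are reciprocals of the attended gPS", {
  gps <- structure(matrix(c(0.25, 0.5, 0.75, 0.5), 2, 2), reference = 1L)
  expect_equal(ipw_weights(gps, c(1, 2)), c(4, 2))
  uni <- structure(matrix(1 / 4, 3, 4), reference = 1L)
  expect_equal(ipw_weights(uni, c(1, 3, 4)), rep(4, 3))
  zero <- structure(matrix(c(0, 1, 1, 0), 2, 2), reference = 1L)
  expect_error(ipw_weights(zero, c(1, 2)), class = "profilesim_fit_error")
})

test_that("an exactly fitted gPS reproduces the K-fold pseudo-population", {
  # with the intercept-only (exactly fitted) gPS, the summed IPW weights are
  # n_k / share_k per provider, so the pseudo-population totals N * K
  dat <- confounded_cohort(K = 3, n = 600, seed = 9)
  gps <- estimate_gps(dat, covariates = character(0))
  w <- ipw_weights(gps, dat$provider)
  expect_equal(sum(w), 600 * 3, tolerance = 1e-9)
})

test_that("weight trimming caps at the 98th percentile", {
  w <- c(rep(1, 98), 40, 80)
  trimmed <- trim_weights(w)
  cap <- unname(quantile(w, 0.98, type = 7))
  expect_equal(max(trimmed), cap)
  expect_identical(sum(trimmed > cap), 0L)
  expect_identical(trimmed[1:98], w[1:98])
  # the two extreme weights both collapse onto the cap
  expect_equal(trimmed[99:100], c(cap, cap))

  expect_identical(trim_weights(rep(2, 50)), rep(2, 50))
  w2 <- runif(500)
  expect_lte(max(trim_weights(w2)), unname(quantile(w2, 0.98, type = 7)))
})

test_that("marginal mean weights follow the stratification formula", {
  # provider 1 gPS takes 1000 distinct values so quintiles hold 200 each;
  # 25 of the 100 attendees of provider 1 sit in the lowest stratum
  gps1 <- seq(0.0005, 0.9995, length.out = 1000)
  gps <- structure(cbind(gps1, 1 - gps1), reference = 1L)
  attended <- rep(2L, 1000)
  pick <- c(1:25, 201:220, 401:420, 601:620, 801:815)  # 25,20,20,20,15
  attended[pick] <- 1L
  w <- mmws_weights(gps, attended)
  expect_equal(unname(w[1]), 200 * 0.1 / 25)   # = 0.8
  expect_equal(unname(w[201]), 200 * 0.1 / 20) # = 1.0
  expect_equal(unname(w[801]), 200 * 0.1 / 15)
  # weights sum to the provider volume when every stratum has attendees
  expect_equal(sum(w[attended == 1L]), 100)
})

test_that("balanced attendance gives unit marginal mean weights", {
  # attendance proportional to the marginal share within every stratum
  gps1 <- rep(seq(0.1, 0.9, length.out = 5), each = 40)
  gps <- structure(cbind(gps1, 1 - gps1), reference = 1L)
  attended <- rep(rep(c(1L, 2L), c(10, 30)), 5)  # Pr(X=1) = 0.25 in each stratum
  w <- mmws_weights(gps, attended)
  expect_equal(as.numeric(w), rep(1, 200))
})
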