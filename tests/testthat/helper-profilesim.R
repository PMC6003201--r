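# Small cohort with directly assigned providers (bypasses quota filling) for
# cheap method-level fixtures.
make_test_cohort <- function(K = 4, n_k = 150, seed = 1,
                             config = case_mix_config()) {
  set.seed(seed)
  cov <- generate_cohort(config, K * n_k)
  dplyr::mutate(cov, provider = rep(seq_len(K), each = n_k), .before = 1)
}

# Outcomes for a test cohort from the outcome model with given provider
# intercepts (alpha0, length K) and overall intercept.
add_test_outcomes <- function(cohort, alpha0, gamma00 = -2.2,
                              beta = euroscore_coefficients(), seed = 2) {
  set.seed(seed)
  vars <- case_mix_variables()
  eta <- gamma00 + alpha0[cohort$provider] +
    drop(as.matrix(cohort[vars]) %*% beta[vars])
  dplyr::mutate(cohort, y = rbinom(nrow(cohort), 1L, plogis(eta)))
}

# Brute-force marginal log-likelihood of the random-intercept logistic model
# by dense-grid integration over the random effect (independent oracle for
# the GLMM engine). `w` are frequency weights on log-likelihood terms.
grid_loglik <- function(y, X, groups, beta, sigma, w = NULL,
                        half_width = 10, n_grid = 20001) {
  if (is.null(w)) w <- rep(1, length(y))
  eta_fix <- if (is.null(X)) rep(beta[1], length(y)) else
    drop(cbind(1, as.matrix(X)) %*% beta)
  b <- seq(-half_width * max(sigma, 0.05), half_width * max(sigma, 0.05),
           length.out = n_grid)
  db <- b[2] - b[1]
  total <- 0
  for (g in unique(groups)) {
    idx <- groups == g
    # log integrand on the grid: sum_i w_i log f(y_i | b) + log phi(b)
    lp <- outer(eta_fix[idx], b, "+")
    ll_obs <- colSums(w[idx] * (y[idx] * lp - log1p(exp(lp))))
    lg <- ll_obs + stats::dnorm(b, 0, sigma, log = TRUE)
    m <- max(lg)
    total <- total + m + log(sum(exp(lg - m)) * db)
  }
  total
}

# Cache for expensive Monte-Carlo runs shared across test files (computed at
# most once per test_dir invocation).
.sim_cache <- new.env(parent = emptyenv())

cached_run <- function(key, spec_args, reps, methods = profiling_methods(),
                       point, seed = 1) {
  if (!exists(key, envir = .sim_cache)) {
    spec <- do.call(scenario_spec, spec_args)
    assign(key,
           run_scenario(spec, reps = reps, seed = seed, methods = methods,
                        point = point),
           envir = .sim_cache)
  }
  get(key, envir = .sim_cache)
}

# The reduced-scale baseline design (K = 10 providers of 1000 patients,
# p.. = 0.10, P(out) = 0.2, H = 2, S = 2) used by several accuracy checks.
baseline_run <- function(reps = 50) {
  cached_run("baseline_k10", list(K = 10), reps = reps, point = 402L)
}
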