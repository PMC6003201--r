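#' Specify a simulation scenario
#'
#' A scenario fixes the data-generating design: number of providers, target
#' average outcome incidence, fraction and separation of true outliers, the
#' number of outlier sides, and the provider-volume structure.
#'
#' @param K Number of providers (even, so an equal two-sided outlier split is
#'   always possible).
#' @param p_bar Target average incidence of the outcome over the whole sample.
#' @param p_out Fraction of providers that are true outliers.
#' @param H Separation of the outlier random-intercept distributions, in units
#'   of `sigma`.
#' @param S Number of outlier sides: 2 = both directions, 1 = below-average
#'   performance (higher mortality) only.
#' @param min_nk Volume of the smaller providers; half the providers get
#'   `min_nk` patients, the other half 1000.
#' @param p_nmin Probability that an outlier provider is one of the smaller
#'   providers (only relevant when `min_nk < 1000`).
#' @param sigma Standard deviation of the provider random intercepts on the
#'   log-odds scale. The default 0.1942 is the between-provider SD estimated
#'   from a national isolated-CABG registry.
#' @param min_incidence Minimum realized outcome incidence required of every
#'   provider (guards against separation when fitting); default 1%.
#' @return An object of class `scenario_spec`.
#' @examples
#' scenario_spec(K = 10)
#' @export
scenario_spec <- function(K = 50, p_bar = 0.10, p_out = 0.2, H = 2, S = 2,
                          min_nk = 1000, p_nmin = 0.5, sigma = 0.1942,
                          min_incidence = 0.01) {
  ok <- is.numeric(K) && K >= 2 && K == round(K) &&
    p_bar > 0 && p_bar < 1 && p_out > 0 && p_out < 1 &&
    H >= 0 && S %in% c(1, 2) && min_nk >= 1 && min_nk <= 1000 &&
    p_nmin >= 0 && p_nmin <= 1 && sigma >= 0 &&
    min_incidence >= 0 && min_incidence < 1
  if (!ok) {
    rlang::abort("Invalid scenario parameters; see ?scenario_spec.",
                 class = "profilesim_config_error")
  }
  n_out <- round(p_out * K)
  if (n_out < 1) {
    rlang::abort("`p_out * K` rounds to zero true outliers.",
                 class = "profilesim_config_error")
  }
  if (S == 2 && n_out %% 2 != 0) {
    rlang::abort("With S = 2, round(p_out * K) must be even so outliers split equally.",
                 class = "profilesim_config_error")
  }
  structure(list(K = as.integer(K), p_bar = p_bar, p_out = p_out, H = H,
                 S = as.integer(S), min_nk = as.integer(min_nk),
                 p_nmin = p_nmin, sigma = sigma,
                 min_incidence = min_incidence),
            class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf(
    "Scenario: K=%d, p..=%.2f, P(out)=%.2f, H=%g, S=%d, min(nk)=%d, P(nmin)=%.2f, sigma=%.4f\n",
    x$K, x$p_bar, x$p_out, x$H, x$S, x$min_nk, x$p_nmin, x$sigma))
  invisible(x)
}

#' Allocate true provider status, random intercepts and volumes
#'
#' Picks `round(p_out * K)` providers as true outliers (split equally between
#' the below- and above-average sides when `S = 2`, all below-average when
#' `S = 1`), draws each provider's random intercept from `N(mu, sigma^2)` with
#' `mu = +H * sigma` for below-average (higher-mortality) outliers,
#' `-H * sigma` for above-average outliers and 0 otherwise, and assigns half
#' the providers volume `min_nk` and half 1000. Each outlier independently
#' receives a small volume with probability `p_nmin`; if more outliers want
#' small volumes than small slots exist, the excess is reassigned to large
#' slots (recorded in the `reallocated` attribute).
#'
#' @param spec A [scenario_spec()].
#' @param seed Optional integer seed.
#' @return A tibble with one row per provider: `provider`, `class` (factor:
#'   `normal`, `low`, `high`; `low` = below-average performance, i.e. excess
#'   mortality), `mu`, `alpha0`, `n_k`.
#' @export
allocate_provider_truth <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (!is.null(seed)) set.seed(seed)
  K <- spec$K
  n_out <- round(spec$p_out * K)
  outliers <- sort(sample.int(K, n_out))
  cls <- rep("normal", K)
  if (spec$S == 2L) {
    side <- sample(rep(c("low", "high"), each = n_out / 2L))
  } else {
    side <- rep("low", n_out)
  }
  cls[outliers] <- side
  mu <- c(normal = 0, low = spec$H * spec$sigma, high = -spec$H * spec$sigma)[cls]
  alpha0 <- rnorm(K, mu, spec$sigma)

  n_small <- K %/% 2L
  n_k <- rep(1000L, K)
  reallocated <- 0L
  if (spec$min_nk < 1000L && n_small > 0L) {
    wants_small <- outliers[runif(n_out) < spec$p_nmin]
    if (length(wants_small) > n_small) {
      keep <- sample(wants_small, n_small)
      reallocated <- length(wants_small) - n_small
      wants_small <- keep
    }
    pool <- setdiff(seq_len(K), wants_small)
    extra <- sample(pool, n_small - length(wants_small))
    n_k[c(wants_small, extra)] <- spec$min_nk
  }
  out <- tibble::tibble(
    provider = seq_len(K),
    class = factor(cls, levels = c("normal", "low", "high")),
    mu = unname(mu),
    alpha0 = alpha0,
    n_k = n_k)
  attr(out, "reallocated") <- reallocated
  out
}

#' Convert a log-odds shift to an odds ratio
#'
#' @param mu Log-odds shift (e.g. a provider random-intercept mean).
#' @return `exp(mu)`.
#' @examples
#' mu_to_odds_ratio(2 * 0.1942)  # 1.475: a below-average outlier at H = 2
#' @export
mu_to_odds_ratio <- function(mu) {
  stopifnot(is.numeric(mu), all(is.finite(mu)))
  exp(mu)
}

#' Case-mix log-odds coefficients for the outcome model
#'
#' Defaults transcribed from the logistic EuroSCORE mortality model (Roques
#' et al. 2003, Eur Heart J 24:882-883), with age entered as a centered
#' per-year log-odds term. These are stand-ins for the original model's exact
#' coding (which uses age increments above 60 and clinical cut-offs) and can
#' be overridden wherever an outcome model is built.
#'
#' @return Named numeric vector of length 8 (log odds ratios), ordered as
#'   [case_mix_variables()].
#' @export
euroscore_coefficients <- function() {
  c(age = 0.0666354,
    sex = 0.3304052,
    pulmonary_disease = 0.4931341,
    arteriopathy = 0.6558917,
    unstable_angina = 0.5677075,
    lv_dysfunction = 0.4191643,
    recent_mi = 0.5460218,
    emergency = 0.7127953)
}

#' Calibrate the overall intercept to a target incidence
#'
#' Finds the unique `gamma00` such that the mean outcome probability over the
#' realized sample,
#' `mean(plogis(gamma00 + alpha0[provider] + Z %*% beta))`, equals the target.
#' The mean probability is strictly increasing in `gamma00`, so bisection on a
#' wide bracket always converges; the residual is below 1e-6.
#'
#' @param cohort An assigned cohort (from [fill_quotas()]).
#' @param truth Provider truth table (from [allocate_provider_truth()]).
#' @param beta Named case-mix coefficient vector (default
#'   [euroscore_coefficients()]).
#' @param target Target average incidence in (0, 1).
#' @return The calibrated intercept `gamma00` (log-odds scale).
#' @export
calibrate_intercept <- function(cohort, truth, beta = euroscore_coefficients(),
                                target) {
  stopifnot(target > 0, target < 1)
  off <- linear_offset(cohort, truth, beta)
  f <- function(g) mean(plogis(g + off)) - target
  uniroot(f, interval = c(-50, 50), tol = 1e-12)$root
}

# alpha0 + Z beta for each patient, in cohort row order
linear_offset <- function(cohort, truth, beta) {
  vars <- case_mix_variables()
  beta <- beta[vars]
  if (anyNA(beta)) {
    rlang::abort("`beta` must name all 8 case-mix variables.",
                 class = "profilesim_schema_error")
  }
  drop(as.matrix(cohort[vars]) %*% beta) + truth$alpha0[cohort$provider]
}

#' Draw binary outcomes for an assigned cohort
#'
#' Draws each patient's outcome from `Bernoulli(p_ik)` with
#' `logit(p_ik) = gamma00 + alpha0_k + Z beta`. A draw is accepted only if
#' every provider's realized incidence is at least `min_incidence` (this
#' prevents separation in the downstream fits); otherwise the full outcome
#' vector is redrawn, up to `max_redraws` times, after which a classed error
#' (`profilesim_incidence_error`) signals the caller to regenerate the random
#' intercepts.
#'
#' @param cohort An assigned cohort (from [fill_quotas()]).
#' @param truth Provider truth table.
#' @param beta Named case-mix coefficient vector.
#' @param gamma00 Calibrated overall intercept (see [calibrate_intercept()]).
#' @param seed Optional integer seed.
#' @param min_incidence Per-provider minimum realized incidence (default 1%).
#' @param max_redraws Redraw budget before giving up (default 100).
#' @return Integer 0/1 vector of outcomes in cohort row order, with the number
#'   of redraws used in the `redraws` attribute.
#' @export
draw_outcomes <- function(cohort, truth, beta = euroscore_coefficients(),
                          gamma00, seed = NULL, min_incidence = 0.01,
                          max_redraws = 100) {
  if (!is.null(seed)) set.seed(seed)
  p <- plogis(gamma00 + linear_offset(cohort, truth, beta))
  n <- length(p)
  prov <- cohort$provider
  n_k <- tabulate(prov, nbins = max(prov))
  for (attempt in 0:max_redraws) {
    y <- rbinom(n, 1L, p)
    events <- tabulate(prov[y == 1L], nbins = max(prov))
    if (min_incidence <= 0 || all(events / n_k >= min_incidence)) {
      attr(y, "redraws") <- attempt
      return(y)
    }
  }
  rlang::abort(
    paste0("Could not reach a per-provider incidence of ", min_incidence,
           " within ", max_redraws, " redraws."),
    class = "profilesim_incidence_error")
}
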