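#' Risk-adjustment method names
#'
#' The six methods compared by the simulation: two-stage fixed-effects
#' logistic regression (`lr_f`), random-effects logistic regression (`lr_r`),
#' gPS case-mix adjustment (`gps_a`), gPS inverse-probability weighting raw
#' and trimmed (`gps_w`, `gps_wt`), and marginal mean weighting through
#' stratification (`gps_mws`).
#'
#' @return Character vector of method identifiers.
#' @export
profiling_methods <- function() {
  c("lr_f", "lr_r", "gps_a", "gps_w", "gps_wt", "gps_mws")
}

outlier_labels <- function(flagged, direction_up) {
  factor(ifelse(!flagged, "normal", ifelse(direction_up, "low", "high")),
         levels = c("normal", "low", "high"))
}

#' Classify providers with fixed-effects logistic regression
#'
#' Two-stage procedure: a logistic regression on the case-mix variables alone
#' yields the overall intercept; a second model without intercept containing
#' all K provider dummies plus the case-mix variables yields per-provider
#' effects with Wald standard errors. A provider is flagged when its 95% Wald
#' confidence interval excludes the stage-1 intercept (treated as a known
#' constant); `low` means below-average performance (excess mortality).
#'
#' @param data Assigned cohort with `provider`, the 8 case-mix columns and an
#'   outcome column `y` (or pass `outcomes`).
#' @param outcomes Binary outcome vector; defaults to `data$y`.
#' @param conf_level Wald confidence level (default 0.95).
#' @return A tibble (one row per provider): `method`, `provider`, `estimate`
#'   (provider log-odds), `std.error`, `reference` (the stage-1 intercept),
#'   `flagged`, `label`.
#' @export
classify_lrf <- function(data, outcomes = data$y, conf_level = 0.95) {
  vars <- case_mix_variables()
  K <- max(data$provider)
  d <- data.frame(y = outcomes,
                  prov = factor(data$provider, levels = seq_len(K)),
                  data[vars])
  f1 <- glm(stats::reformulate(vars, "y"), family = binomial(), data = d)
  gamma_hat <- unname(coef(f1)[1L])
  f2 <- glm(stats::reformulate(c("0 + prov", vars), "y"),
            family = binomial(), data = d)
  if (!f1$converged || !f2$converged) {
    rlang::abort("Fixed-effects logistic regression did not converge.",
                 class = "profilesim_fit_error")
  }
  est <- coef(f2)[seq_len(K)]
  se <- sqrt(diag(vcov(f2)))[seq_len(K)]
  if (any(!is.finite(est)) || any(!is.finite(se)) || any(se > 100)) {
    rlang::abort("Separation in the fixed-effects provider model.",
                 class = "profilesim_fit_error")
  }
  z <- qnorm(1 - (1 - conf_level) / 2)
  flagged <- (est - z * se > gamma_hat) | (est + z * se < gamma_hat)
  tibble::tibble(method = "lr_f",
                 provider = seq_len(K),
                 estimate = unname(est),
                 std.error = unname(se),
                 reference = gamma_hat,
                 flagged = unname(flagged),
                 label = outlier_labels(flagged, est > gamma_hat))
}

# shared empirical-Bayes two-SD classification rule
classify_from_ri <- function(fit, method, rule_sd = c("model", "empirical")) {
  rule_sd <- match.arg(rule_sd)
  if (!isTRUE(fit$converged)) {
    rlang::abort(paste0("Random-intercept fit failed for method ", method, "."),
                 class = "profilesim_fit_error")
  }
  eb <- fit$eb
  sd_used <- if (rule_sd == "model") fit$sigma else sd(eb$deviation)
  flagged <- abs(eb$deviation) > 2 * sd_used
  tibble::tibble(method = method,
                 provider = as.integer(as.character(eb$provider)),
                 estimate = eb$deviation,
                 std.error = NA_real_,
                 reference = sd_used,
                 flagged = flagged,
                 label = outlier_labels(flagged, eb$deviation > 0)) |>
    dplyr::arrange(.data$provider)
}

#' Classify providers with random-effects logistic regression
#'
#' Fits a random-intercept logistic model with the 8 case-mix variables as
#' fixed effects and flags a provider when its empirical-Bayes deviation from
#' the overall intercept exceeds two observed standard deviations. By default
#' the threshold uses the model-estimated random-intercept SD
#' (`rule_sd = "model"`); `rule_sd = "empirical"` uses the sample SD of the
#' empirical-Bayes deviations instead.
#'
#' @inheritParams classify_lrf
#' @param nAGQ Integration scheme passed to
#'   [fit_random_intercept_logistic()]; the simulation pipeline default is 0.
#' @param rule_sd Which standard deviation the two-SD rule uses.
#' @return A classification tibble (see [classify_lrf()]); `reference` holds
#'   the SD used by the rule.
#' @export
classify_lrr <- function(data, outcomes = data$y, nAGQ = 0,
                         rule_sd = c("model", "empirical")) {
  vars <- case_mix_variables()
  fit <- fit_random_intercept_logistic(outcomes, X = data[vars],
                                       groups = data$provider, nAGQ = nAGQ)
  classify_from_ri(fit, "lr_r", rule_sd)
}

#' Classify providers with gPS case-mix adjustment
#'
#' Fits a random-intercept logistic model with the K - 1 non-reference gPS
#' columns entered linearly as fixed effects (the reference provider's column
#' is dropped because gPS rows sum to one), then applies the same two-SD
#' empirical-Bayes rule as [classify_lrr()].
#'
#' @inheritParams classify_lrr
#' @param gps A gPS matrix from [estimate_gps()].
#' @return A classification tibble.
#' @export
classify_gps_a <- function(data, outcomes = data$y, gps, nAGQ = 0,
                           rule_sd = c("model", "empirical")) {
  ref <- attr(gps, "reference") %||% 1L
  X <- as.data.frame(gps[, -ref, drop = FALSE])
  names(X) <- paste0("gps_", setdiff(seq_len(ncol(gps)), ref))
  fit <- fit_random_intercept_logistic(outcomes, X = X,
                                       groups = data$provider, nAGQ = nAGQ)
  classify_from_ri(fit, "gps_a", rule_sd)
}

#' Classify providers with a weighted providers-only model
#'
#' Fits a weighted random-intercept logistic regression with only the overall
#' intercept and the provider random effects (case-mix enters through the
#' weights), then applies the two-SD empirical-Bayes rule. This is the
#' analysis stage shared by gPS inverse-probability weighting (`gps_w`), its
#' trimmed variant (`gps_wt`) and marginal mean weighting (`gps_mws`).
#'
#' @inheritParams classify_lrr
#' @param weights Non-negative per-patient weights (see [ipw_weights()],
#'   [trim_weights()], [mmws_weights()]).
#' @param method Method label recorded in the result.
#' @return A classification tibble.
#' @export
classify_weighted <- function(data, outcomes = data$y, weights,
                              method = "gps_w", nAGQ = 0,
                              rule_sd = c("model", "empirical")) {
  fit <- fit_random_intercept_logistic(outcomes, X = NULL,
                                       groups = data$provider,
                                       weights = weights, nAGQ = nAGQ)
  classify_from_ri(fit, method, rule_sd)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
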