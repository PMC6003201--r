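#' Draw a provider-assignment model
#'
#' Providers attract patients through a multinomial logit on the eight case-mix
#' variables. Each non-reference provider gets a single coefficient
#' `beta_k ~ Uniform(0, 1)` applied identically to all eight predictors, so
#' providers with larger `beta_k` systematically attract higher-risk patients
#' (confounding by case-mix). Provider 1 is the reference with all parameters
#' zero; intercepts are zero throughout because provider volumes are fixed by
#' quota filling, not by the intercepts.
#'
#' @param K Number of providers (at least 2).
#' @param seed Optional integer seed.
#' @return An object of class `assignment_model` with elements `K`, `alpha`
#'   (all zero), `beta` (length `K`, `beta[1] = 0`) and `reference` (1).
#' @export
draw_assignment_model <- function(K, seed = NULL) {
  if (!is.numeric(K) || length(K) != 1L || K < 2 || K != round(K)) {
    rlang::abort("`K` must be a single integer >= 2.",
                 class = "profilesim_config_error")
  }
  if (!is.null(seed)) set.seed(seed)
  K <- as.integer(K)
  structure(list(K = K,
                 alpha = rep(0, K),
                 beta = c(0, runif(K - 1L)),
                 reference = 1L),
            class = "assignment_model")
}

#' @export
print.assignment_model <- function(x, ...) {
  cat("Provider assignment model: K =", x$K,
      "(reference = provider", paste0(x$reference, ")\n"))
  cat("  beta:", paste(sprintf("%.3f", x$beta), collapse = " "), "\n")
  invisible(x)
}

#' Per-patient provider-attendance probabilities
#'
#' Evaluates the multinomial logit: for patient i,
#' `pi_k = exp(alpha_k + beta_k * sum(Z_i)) / sum_j exp(alpha_j + beta_j * sum(Z_i))`,
#' where the shared coefficient multiplies every one of the eight predictors.
#'
#' @param model An [draw_assignment_model()] object.
#' @param covariates A cohort tibble containing the 8 columns of
#'   [case_mix_variables()].
#' @return A numeric matrix (patients x K); every row sums to 1.
#' @export
assignment_probabilities <- function(model, covariates) {
  stopifnot(inherits(model, "assignment_model"))
  vars <- case_mix_variables()
  if (!all(vars %in% names(covariates))) {
    rlang::abort(
      paste0("`covariates` must contain the 8 predictor columns: ",
             paste(setdiff(vars, names(covariates)), collapse = ", "), " missing."),
      class = "profilesim_schema_error")
  }
  z_sum <- rowSums(as.matrix(covariates[vars]))
  eta <- outer(z_sum, model$beta) +
    matrix(model$alpha, nrow = length(z_sum), ncol = model$K, byrow = TRUE)
  eta <- eta - apply(eta, 1L, max)   # guard overflow: age spans +/- 3 sd
  p <- exp(eta)
  p / rowSums(p)
}

#' Fill fixed per-provider volumes by rejection sampling
#'
#' Repeats until every provider holds exactly its target volume: draw a fresh
#' patient from the case-mix generator, draw one provider from that patient's
#' attendance probabilities, keep the patient if the provider still has room
#' and discard the patient entirely otherwise. This reproduces fixed provider
#' volumes while preserving the confounded assignment mechanism (with mild
#' conditioning as quotas near completion).
#'
#' @param model An [draw_assignment_model()] object.
#' @param config A [case_mix_config()] used to draw candidate patients.
#' @param volumes Integer vector of length `K`; target patients per provider.
#' @param seed Optional integer seed.
#' @param max_draws Safety cap on candidate draws (default 1000 x total N).
#' @return A tibble with columns `patient`, `provider` (integer in `1:K`) and
#'   the 8 case-mix columns, ordered by provider; the realized volume of every
#'   provider equals its target exactly. Target volumes are attached as the
#'   `volumes` attribute.
#' @export
fill_quotas <- function(model, config, volumes, seed = NULL,
                        max_draws = 1000 * sum(volumes)) {
  stopifnot(inherits(model, "assignment_model"), inherits(config, "case_mix_config"))
  if (length(volumes) != model$K || any(volumes < 1) || any(volumes != round(volumes))) {
    rlang::abort("`volumes` must give a positive integer volume for each of the K providers.",
                 class = "profilesim_config_error")
  }
  if (!is.null(seed)) set.seed(seed)
  K <- model$K
  volumes <- as.integer(volumes)
  remaining <- volumes
  kept_cov <- vector("list", 0L)
  kept_prov <- vector("list", 0L)
  drawn <- 0
  while (any(remaining > 0L)) {
    m <- max(1000L, min(as.integer(4 * sum(remaining)), 50000L))
    cand <- generate_cohort(config, m)
    p <- assignment_probabilities(model, cand)
    # Gumbel-max draw of one provider per candidate
    g <- -log(-log(matrix(runif(m * K), m, K)))
    choice <- max.col(log(p) + g)
    drawn <- drawn + m
    # sequential acceptance is equivalent to: per provider, keep the first
    # `remaining[k]` candidates (in draw order) that chose provider k
    keep <- logical(m)
    for (k in which(remaining > 0L)) {
      idx <- which(choice == k)
      keep[utils::head(idx, remaining[k])] <- TRUE
      remaining[k] <- remaining[k] - min(length(idx), remaining[k])
    }
    if (any(keep)) {
      kept_cov[[length(kept_cov) + 1L]] <- cand[keep, , drop = FALSE]
      kept_prov[[length(kept_prov) + 1L]] <- choice[keep]
    }
    if (drawn > max_draws && any(remaining > 0L)) {
      rlang::abort(
        paste0("Quota filling exceeded ", max_draws, " candidate draws; ",
               sum(remaining), " slots unfilled (providers ",
               paste(which(remaining > 0L), collapse = ", "), ")."),
        class = "profilesim_quota_error")
    }
  }
  out <- dplyr::bind_cols(
    tibble::tibble(provider = unlist(kept_prov)),
    dplyr::bind_rows(kept_cov))
  out <- dplyr::arrange(out, .data$provider)
  out <- dplyr::mutate(out, patient = dplyr::row_number(), .before = 1L)
  attr(out, "volumes") <- volumes
  out
}
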