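#' Case-mix predictor names
#'
#' The eight predictors of in-hospital mortality after isolated CABG used
#' throughout the package: centered age plus seven binary risk factors, each
#' kept only if its population prevalence exceeds 5%.
#'
#' @return Character vector of length 8.
#' @export
case_mix_variables <- function() {
  c("age", "sex", "pulmonary_disease", "arteriopathy", "unstable_angina",
    "lv_dysfunction", "recent_mi", "emergency")
}

#' Default prevalences for the binary case-mix variables
#'
#' Stand-in marginal prevalences for a CABG cohort. The empirical registry the
#' design emulates does not publish its joint distribution, so these are
#' plausible synthetic values chosen once; all exceed the 5% inclusion rule.
#'
#' @return Named numeric vector of length 7 (probabilities).
#' @export
cabg_prevalences <- function() {
  c(sex = 0.25,               # female sex
    pulmonary_disease = 0.10, # chronic pulmonary disease
    arteriopathy = 0.10,      # extracardiac arteriopathy
    unstable_angina = 0.15,
    lv_dysfunction = 0.25,    # moderate LV dysfunction (EF 30-50%)
    recent_mi = 0.10,
    emergency = 0.07)
}

#' Configure the synthetic case-mix generator
#'
#' @param age_sd Standard deviation of centered age, in years. Age is drawn
#'   from a normal truncated at +/- 3 standard deviations.
#' @param prevalences Named probabilities for the seven binary variables,
#'   each strictly between 0.05 and 0.95.
#' @param correlation Optional 8 x 8 correlation matrix (rows/columns ordered
#'   as [case_mix_variables()]) for a latent-Gaussian copula. `NULL` (the
#'   default) generates the predictors independently.
#' @return An object of class `case_mix_config`.
#' @examples
#' cfg <- case_mix_config()
#' generate_cohort(cfg, n = 5, seed = 1)
#' @export
case_mix_config <- function(age_sd = 10,
                            prevalences = cabg_prevalences(),
                            correlation = NULL) {
  if (!is.numeric(age_sd) || length(age_sd) != 1L || age_sd <= 0) {
    rlang::abort("`age_sd` must be a single positive number.",
                 class = "profilesim_config_error")
  }
  binaries <- setdiff(case_mix_variables(), "age")
  if (!all(binaries %in% names(prevalences))) {
    rlang::abort(
      paste0("`prevalences` must name all of: ", paste(binaries, collapse = ", ")),
      class = "profilesim_config_error")
  }
  prevalences <- prevalences[binaries]
  if (any(prevalences <= 0.05) || any(prevalences >= 0.95)) {
    rlang::abort(
      "All binary prevalences must lie in (0.05, 0.95); rarer factors are excluded by design.",
      class = "profilesim_config_error")
  }
  if (!is.null(correlation)) {
    p <- length(case_mix_variables())
    if (!is.matrix(correlation) || !all(dim(correlation) == c(p, p)) ||
        !isTRUE(all.equal(correlation, t(correlation), tolerance = 1e-10)) ||
        !isTRUE(all.equal(unname(diag(correlation)), rep(1, p)))) {
      rlang::abort("`correlation` must be a symmetric 8 x 8 matrix with unit diagonal.",
                   class = "profilesim_config_error")
    }
    ev <- eigen(correlation, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8) {
      rlang::abort("`correlation` must be positive semi-definite.",
                   class = "profilesim_config_error")
    }
  }
  structure(list(age_sd = age_sd,
                 prevalences = prevalences,
                 correlation = correlation),
            class = "case_mix_config")
}

#' @export
print.case_mix_config <- function(x, ...) {
  cat("Case-mix configuration (8 predictors)\n")
  cat("  age: centered normal, sd", x$age_sd, "years, truncated at +/-",
      3 * x$age_sd, "\n")
  cat("  binary prevalences:\n")
  for (nm in names(x$prevalences)) {
    cat(sprintf("    %-18s %.3f\n", nm, x$prevalences[[nm]]))
  }
  cat("  correlation:", if (is.null(x$correlation)) "independent" else "latent-Gaussian copula", "\n")
  invisible(x)
}

#' Generate a synthetic patient cohort
#'
#' Draws `n` case-mix profiles: centered age from a truncated normal and seven
#' binary risk factors from Bernoulli margins, optionally coupled through a
#' latent-Gaussian copula.
#'
#' @param config A [case_mix_config()].
#' @param n Number of patients (may be 0).
#' @param seed Optional integer seed; when supplied the result is reproducible.
#' @return A tibble with `n` rows and the 8 columns of [case_mix_variables()].
#'   `age` is numeric (years, centered); the binaries are 0/1 integers.
#' @export
generate_cohort <- function(config, n, seed = NULL) {
  stopifnot(inherits(config, "case_mix_config"))
  if (!is.numeric(n) || length(n) != 1L || n < 0 || n != round(n)) {
    rlang::abort("`n` must be a single non-negative integer.",
                 class = "profilesim_config_error")
  }
  if (!is.null(seed)) set.seed(seed)
  vars <- case_mix_variables()
  prev <- config$prevalences
  if (n == 0) {
    out <- c(list(age = numeric(0)),
             setNames(rep(list(integer(0)), 7L), names(prev)))
    return(tibble::as_tibble(out)[vars])
  }
  if (is.null(config$correlation)) {
    z_age <- rnorm(n)
    u_bin <- matrix(runif(n * 7L), n, 7L)
  } else {
    L <- chol_psd(config$correlation)
    Zl <- matrix(rnorm(n * 8L), n, 8L) %*% L
    z_age <- Zl[, 1L]
    u_bin <- stats::pnorm(Zl[, -1L, drop = FALSE])
  }
  # truncation at 3 sd via the inverse-CDF so the copula structure is kept
  p_hi <- stats::pnorm(3)
  u_age <- stats::pnorm(z_age)
  age <- qnorm((1 - p_hi) + u_age * (2 * p_hi - 1)) * config$age_sd
  # upper-tail threshold so a larger latent value means presence of the
  # risk factor (keeps copula correlations positively oriented)
  bin <- vapply(seq_along(prev),
                function(j) as.integer(u_bin[, j] > 1 - prev[[j]]),
                integer(n))
  bin <- matrix(bin, nrow = n, dimnames = list(NULL, names(prev)))
  tibble::as_tibble(cbind(tibble::tibble(age = age), tibble::as_tibble(bin)))[vars]
}

# Cholesky-like factor tolerant of semi-definite matrices (eigen fallback).
chol_psd <- function(S) {
  out <- tryCatch(chol(S), error = function(e) NULL)
  if (!is.null(out)) return(out)
  e <- eigen(S, symmetric = TRUE)
  t(e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow(S)) %*% t(e$vectors))
}
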