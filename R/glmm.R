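#' Fit a (weighted) random-intercept logistic regression
#'
#' The estimation engine shared by the random-effects classification methods:
#' a logistic mixed model with a provider random intercept, optional fixed
#' effects and optional non-negative per-patient weights. Weights multiply
#' each patient's log-likelihood contribution (frequency-type weighting), the
#' convention used by `lme4::glmer`, which performs the fit.
#'
#' `nAGQ` selects the integration scheme for the random effect: `0` estimates
#' fixed effects inside the penalized least-squares step (fastest), `1` is the
#' Laplace approximation, and larger values use adaptive Gauss-Hermite
#' quadrature with that many nodes. With the provider volumes used in these
#' simulations (>= 500 patients) the three agree to several decimals; the
#' simulation pipeline defaults to `nAGQ = 0` and the test suite verifies the
#' agreement against dense-grid integration.
#'
#' @param y Binary 0/1 outcome vector.
#' @param X Optional fixed-effect design: a data frame or matrix of numeric
#'   covariates (no intercept column; one is always included), or `NULL` for a
#'   providers-only model.
#' @param groups Provider labels (coercible to factor), same length as `y`.
#' @param weights Optional non-negative per-patient weights.
#' @param nAGQ Integration scheme (see Details); default 1 (Laplace).
#' @return An object of class `ri_fit`: a list with `fixed` (tibble of
#'   estimates and standard errors), `sigma` (random-intercept SD estimate),
#'   `eb` (tibble of empirical-Bayes provider deviations), `loglik`,
#'   `converged`, `messages`, `nAGQ`, `n`, and the underlying `glmer` fit.
#' @examples
#' set.seed(1)
#' g <- rep(1:4, each = 50)
#' y <- rbinom(200, 1, plogis(-1 + c(-0.3, 0.1, 0, 0.4)[g]))
#' fit <- fit_random_intercept_logistic(y, groups = g)
#' glance(fit)
#' @export
fit_random_intercept_logistic <- function(y, X = NULL, groups, weights = NULL,
                                          nAGQ = 1) {
  if (length(y) != length(groups)) {
    rlang::abort("`y` and `groups` must have the same length.",
                 class = "profilesim_schema_error")
  }
  dat <- data.frame(.y = as.numeric(y), .g = factor(groups))
  if (!is.null(X)) {
    X <- as.data.frame(X)
    if (nrow(X) != length(y)) {
      rlang::abort("`X` must have one row per observation.",
                   class = "profilesim_schema_error")
    }
    names(X) <- make.names(names(X), unique = TRUE)
    dat <- cbind(dat, X)
    rhs <- paste(c(names(X), "(1 | .g)"), collapse = " + ")
  } else {
    rhs <- "(1 | .g)"
  }
  if (!is.null(weights)) {
    if (any(weights < 0) || length(weights) != length(y)) {
      rlang::abort("`weights` must be non-negative, one per observation.",
                   class = "profilesim_schema_error")
    }
    wsum <- tapply(weights, dat$.g, sum)
    if (any(wsum <= 0)) {
      rlang::abort("Each provider needs a positive total weight.",
                   class = "profilesim_schema_error")
    }
    dat$.w <- weights
  }
  form <- stats::as.formula(paste(".y ~", rhs))
  msgs <- character(0)
  fit <- withCallingHandlers(
    tryCatch(
      lme4::glmer(form, data = dat, family = binomial(),
                  weights = if (is.null(weights)) NULL else dat$.w,
                  nAGQ = nAGQ),
      error = function(e) e),
    warning = function(w) {
      m <- conditionMessage(w)
      if (!grepl("non-integer #successes", m)) msgs <<- c(msgs, m)
      invokeRestart("muffleWarning")
    },
    message = function(m) {
      msgs <<- c(msgs, trimws(conditionMessage(m)))
      invokeRestart("muffleMessage")
    })
  if (inherits(fit, "error")) {
    return(structure(list(fit = NULL, fixed = NULL, sigma = NA_real_,
                          eb = NULL, loglik = NA_real_, converged = FALSE,
                          messages = conditionMessage(fit), nAGQ = nAGQ,
                          n = length(y)),
                     class = "ri_fit"))
  }
  sig <- sqrt(unname(unlist(lme4::VarCorr(fit))))
  fe <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(vcov(fit))))
  re <- lme4::ranef(fit)$.g
  eb <- tibble::tibble(provider = rownames(re), deviation = re[, 1L])
  converged <- is.finite(sig) && all(is.finite(fe)) &&
    is.finite(as.numeric(logLik(fit)))
  structure(list(
    fit = fit,
    fixed = tibble::tibble(term = names(fe), estimate = unname(fe),
                           std.error = unname(se)),
    sigma = sig,
    eb = eb,
    loglik = as.numeric(logLik(fit)),
    converged = converged,
    messages = msgs,
    nAGQ = nAGQ,
    n = length(y)),
    class = "ri_fit")
}

#' @export
print.ri_fit <- function(x, ...) {
  cat("Random-intercept logistic fit (", nrow(x$eb), " providers, n = ",
      x$n, ")\n", sep = "")
  cat("  sigma-hat:", format(x$sigma, digits = 4),
      " logLik:", format(x$loglik, digits = 8),
      " nAGQ:", x$nAGQ,
      " converged:", x$converged, "\n")
  invisible(x)
}

#' Empirical-Bayes provider deviations
#'
#' Posterior-mode random intercepts: each provider's deviation from the fitted
#' overall intercept, shrunk toward zero by the mixed model.
#'
#' @param fit An [fit_random_intercept_logistic()] result.
#' @return A tibble with columns `provider` and `deviation` (log-odds scale).
#' @export
empirical_bayes_deviations <- function(fit) {
  stopifnot(inherits(fit, "ri_fit"))
  if (!isTRUE(fit$converged)) {
    rlang::abort("Cannot extract empirical-Bayes deviations from an unconverged fit.",
                 class = "profilesim_fit_error")
  }
  fit$eb
}

#' @export
tidy.ri_fit <- function(x, effects = c("fixed", "ran_vals"), ...) {
  effects <- match.arg(effects)
  if (!isTRUE(x$converged)) {
    rlang::abort("Cannot tidy an unconverged fit.", class = "profilesim_fit_error")
  }
  if (effects == "fixed") {
    dplyr::mutate(x$fixed, effect = "fixed", .before = 1L)
  } else {
    dplyr::mutate(x$eb, effect = "ran_vals", .before = 1L)
  }
}

#' @export
glance.ri_fit <- function(x, ...) {
  tibble::tibble(sigma = x$sigma,
                 logLik = x$loglik,
                 nobs = x$n,
                 n_groups = if (is.null(x$eb)) NA_integer_ else nrow(x$eb),
                 nAGQ = x$nAGQ,
                 converged = x$converged)
}
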