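#' Estimate generalized propensity scores
#'
#' Fits a multinomial logistic regression of the attended provider on the
#' eight case-mix variables and returns each patient's fitted probability of
#' attending every provider. Covariates are standardized internally for
#' numerical stability; fitted probabilities are unaffected.
#'
#' The default engine is a Newton-Raphson maximum-likelihood solver with
#' analytic Hessian (written for this package because the simulation fits the
#' model hundreds of times per scenario; it typically converges in under ten
#' iterations). `engine = "multinom"` fits the identical model with
#' `nnet::multinom`; the two agree to the optimizer tolerance and the test
#' suite cross-checks them.
#'
#' @param cohort An assigned cohort tibble with a `provider` column and the
#'   case-mix columns.
#' @param covariates Predictor columns to include (default all 8 of
#'   [case_mix_variables()]; an empty vector fits the intercept-only model,
#'   whose fitted rows are the observed provider shares).
#' @param engine `"newton"` (default) or `"multinom"`.
#' @param maxit Maximum optimizer iterations.
#' @param tol Relative log-likelihood convergence tolerance (Newton engine).
#' @return A numeric matrix (patients x K) of class `gps_matrix`; rows sum to
#'   1 and the reference category (provider 1) index is attached as the
#'   `reference` attribute.
#' @export
estimate_gps <- function(cohort, covariates = case_mix_variables(),
                         engine = c("newton", "multinom"),
                         maxit = 200, tol = 1e-10) {
  engine <- match.arg(engine)
  stopifnot(all(c("provider", covariates) %in% names(cohort)))
  K <- max(cohort$provider)
  if (K < 2) {
    rlang::abort("gPS estimation needs at least 2 providers.",
                 class = "profilesim_config_error")
  }
  n <- nrow(cohort)
  if (length(covariates) == 0L) {
    shares <- tabulate(cohort$provider, nbins = K) / n
    p <- matrix(shares, n, K, byrow = TRUE)
  } else {
    Z <- as.matrix(cohort[covariates])
    sds <- apply(Z, 2L, sd)
    sds[sds == 0] <- 1
    Zs <- scale(Z, center = TRUE, scale = sds)
    if (engine == "newton") {
      p <- multinom_newton(cbind(1, Zs), cohort$provider, K,
                           maxit = maxit, tol = tol)
    } else {
      dat <- data.frame(.prov = factor(cohort$provider, levels = seq_len(K)),
                        Zs)
      fit <- nnet::multinom(.prov ~ ., data = dat, trace = FALSE,
                            maxit = max(maxit, 500), MaxNWts = 5000)
      if (fit$convergence != 0) {
        rlang::abort("Multinomial gPS model did not converge.",
                     class = "profilesim_fit_error")
      }
      p <- fitted(fit)
      if (K == 2L && is.null(dim(p))) p <- cbind(1 - p, p)
      p <- unname(as.matrix(p))
    }
  }
  colnames(p) <- seq_len(K)
  structure(p, reference = 1L, class = c("gps_matrix", class(p)))
}

# Newton-Raphson ML for the multinomial logit (class 1 = reference).
# X includes an intercept column; returns the N x K fitted probabilities.
# The full Hessian is assembled with two BLAS products: with
# M = [X * P_1, ..., X * P_{K-1}], H = blockdiag(X' diag(P_j) X) - M'M.
multinom_newton <- function(X, y, K, maxit = 200, tol = 1e-10) {
  N <- nrow(X); p <- ncol(X); Km <- K - 1L
  Y <- matrix(0, N, Km)
  for (k in 2:K) Y[y == k, k - 1L] <- 1
  B <- matrix(0, p, Km)
  probs <- function(B) {
    eta <- X %*% B
    m <- pmax(eta[cbind(seq_len(N), max.col(eta, ties.method = "first"))], 0)
    E <- exp(eta - m)
    denom <- exp(-m) + rowSums(E)
    list(P = E / denom, ll = sum(eta * Y) - sum(m + log(denom)))
  }
  cur <- probs(B)
  for (it in seq_len(maxit)) {
    P <- cur$P
    G <- crossprod(X, Y - P)
    M <- X[, rep(seq_len(p), Km)] * P[, rep(seq_len(Km), each = p)]
    H <- -crossprod(M)
    XtPX <- crossprod(X, M)          # p x (p*Km): X' diag(P_j) X blocks
    for (j in seq_len(Km)) {
      idx <- (j - 1L) * p + seq_len(p)
      H[idx, idx] <- H[idx, idx] + XtPX[, idx]
    }
    step <- tryCatch(solve(H + diag(1e-10, p * Km), as.vector(G)),
                     error = function(e) NULL)
    if (is.null(step)) {
      rlang::abort("Multinomial gPS model: singular Hessian.",
                   class = "profilesim_fit_error")
    }
    fac <- 1
    repeat {
      cand <- probs(B + matrix(fac * step, p, Km))
      if (cand$ll >= cur$ll || fac < 1e-6) break
      fac <- fac / 2
    }
    done <- abs(cand$ll - cur$ll) < tol * (abs(cur$ll) + 1)
    B <- B + matrix(fac * step, p, Km)
    cur <- cand
    if (done) {
      return(unname(cbind(1 - rowSums(cur$P), cur$P)))
    }
  }
  rlang::abort("Multinomial gPS model did not converge.",
               class = "profilesim_fit_error")
}

#' Inverse-probability-of-attendance weights
#'
#' Each patient's weight is the reciprocal of the gPS of the provider actually
#' attended, creating a pseudo-population in which case-mix is balanced across
#' providers.
#'
#' @param gps A gPS matrix from [estimate_gps()].
#' @param attended Integer provider labels, one per patient.
#' @return Numeric weight vector.
#' @export
ipw_weights <- function(gps, attended) {
  stopifnot(nrow(gps) == length(attended))
  p <- gps[cbind(seq_along(attended), attended)]
  if (any(p <= 0)) {
    rlang::abort("Zero fitted attendance probability for an attended provider (positivity violation).",
                 class = "profilesim_fit_error")
  }
  1 / p
}

#' Trim extreme weights to an upper percentile
#'
#' Weights above the `1 - trim_fraction` sample quantile (linear-interpolation
#' quantile, type 7) are capped at that quantile; all other weights are
#' unchanged.
#'
#' @param weights Non-negative weight vector.
#' @param trim_fraction Fraction of the upper tail to cap (default 0.02, i.e.
#'   the 98th percentile).
#' @return Trimmed weight vector.
#' @examples
#' trim_weights(c(rep(1, 98), 50, 100))
#' @export
trim_weights <- function(weights, trim_fraction = 0.02) {
  stopifnot(all(weights >= 0), trim_fraction >= 0, trim_fraction < 1)
  cap <- unname(quantile(weights, 1 - trim_fraction, type = 7))
  pmin(weights, cap)
}

#' Marginal mean weights through stratification
#'
#' For each provider `k`, all patients are binned into `n_strata` quantile
#' strata of their gPS for `k` (quintiles by default). A patient who attended
#' `k` and falls in stratum `s` receives
#' `MMW = n_s * Pr(X = k) / n_{X = k, s}`,
#' where `n_s` is the stratum size over the whole sample, `Pr(X = k)` is the
#' observed share attending `k` and `n_{X = k, s}` counts attendees of `k` in
#' the stratum. Ties that collapse strata reduce the effective stratum count
#' (recorded in the `effective_strata` attribute).
#'
#' @param gps A gPS matrix from [estimate_gps()].
#' @param attended Integer provider labels, one per patient.
#' @param n_strata Number of quantile strata (default 5).
#' @return Numeric weight vector with attribute `effective_strata` (per
#'   provider).
#' @export
mmws_weights <- function(gps, attended, n_strata = 5) {
  stopifnot(nrow(gps) == length(attended), n_strata >= 2)
  n <- length(attended)
  K <- ncol(gps)
  w <- numeric(n)
  eff <- integer(K)
  for (k in seq_len(K)) {
    br <- unique(quantile(gps[, k], probs = seq(0, 1, length.out = n_strata + 1),
                          type = 7))
    if (length(br) < 2L) br <- c(-Inf, Inf)
    stratum <- cut(gps[, k], breaks = br, include.lowest = TRUE, labels = FALSE)
    eff[k] <- length(br) - 1L
    att <- attended == k
    pr_k <- mean(att)
    n_s <- tabulate(stratum, nbins = eff[k])
    n_ks <- tabulate(stratum[att], nbins = eff[k])
    w[att] <- n_s[stratum[att]] * pr_k / n_ks[stratum[att]]
  }
  attr(w, "effective_strata") <- eff
  w
}
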