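#' The one-at-a-time scenario grid
#'
#' Seven scenarios, each sweeping a single design parameter while the others
#' stay at their baseline values (K = 50, p.. = 0.10, P(out) = 0.2, H = 2,
#' S = 2, min(nk) = 1000, P(nmin) = 0.5): the number of providers, the average
#' mortality incidence, the true-outlier fraction, the outlier separation, the
#' number of outlier sides, the minimum provider volume, and the probability
#' that outliers are small providers.
#'
#' @return A tibble with one row per design point: `scenario`, `point`, `K`,
#'   `p_bar`, `p_out`, `H`, `S`, `min_nk`, `p_nmin`.
#' @export
scenario_grid <- function() {
  base <- list(K = 50, p_bar = 0.10, p_out = 0.2, H = 2, S = 2,
               min_nk = 1000, p_nmin = 0.5)
  sweeps <- list(
    list(scenario = 1L, K = c(10, 20, 30, 40, 50)),
    list(scenario = 2L, p_bar = c(0.03, 0.10, 0.20)),
    list(scenario = 3L, p_out = c(0.08, 0.20, 0.40)),
    list(scenario = 4L, H = c(1, 2, 3, 4)),
    list(scenario = 5L, S = c(1, 2)),
    list(scenario = 6L, min_nk = c(500, 1000)),
    list(scenario = 7L, p_nmin = c(0.5, 1)))
  purrr::map_dfr(sweeps, function(sw) {
    par <- setdiff(names(sw), "scenario")
    vals <- sw[[par]]
    purrr::map_dfr(seq_along(vals), function(i) {
      row <- base
      row[[par]] <- vals[i]
      tibble::as_tibble(c(list(scenario = sw$scenario, point = i), row))
    })
  })
}

#' Deterministic replicate seeds
#'
#' Maps (master seed, design point, replicate index) to a seed below 2^31
#' through an affine map modulo a prime, injective in (point, replicate) for a
#' fixed master seed (for `replicate < 1e6` and `point < 2147`). Seeding is
#' index-based, so replicates can be executed in any order.
#'
#' @param master Master integer seed.
#' @param point Design-point index (>= 0).
#' @param replicate Replicate index (>= 1).
#' @return An integer seed.
#' @export
derive_seed <- function(master, point, replicate) {
  p <- 2147483629
  ((master %% p) * 48271 + point * 1e6 + replicate) %% p + 1
}

# scenario_spec from a grid row (tibble with the design columns)
spec_from_row <- function(row, sigma = 0.1942, min_incidence = 0.01) {
  scenario_spec(K = row$K, p_bar = row$p_bar, p_out = row$p_out, H = row$H,
                S = row$S, min_nk = row$min_nk, p_nmin = row$p_nmin,
                sigma = sigma, min_incidence = min_incidence)
}

#' Generate one complete replicate dataset
#'
#' One full data-generation pass: draw an assignment model (fresh uniform
#' confounding coefficients), allocate provider truth and volumes, fill the
#' volume quotas, calibrate the overall intercept to the target incidence on
#' the realized sample, and draw outcomes. If the per-provider minimum
#' incidence cannot be met within the outcome redraw budget, the provider
#' random intercepts are redrawn (classes and volumes kept) and the intercept
#' recalibrated, up to `max_truth_attempts` times.
#'
#' @param spec A [scenario_spec()].
#' @param seed Integer seed (all randomness in the replicate derives from it).
#' @param config Case-mix configuration.
#' @param beta Outcome-model case-mix coefficients.
#' @param max_truth_attempts Random-intercept redraw budget (default 20).
#' @return A list: `data` (cohort tibble with outcome column `y`), `truth`,
#'   `model`, `gamma00`, `truth_redraws`.
#' @export
simulate_replicate_data <- function(spec, seed, config = case_mix_config(),
                                    beta = euroscore_coefficients(),
                                    max_truth_attempts = 20) {
  stopifnot(inherits(spec, "scenario_spec"))
  set.seed(seed)
  model <- draw_assignment_model(spec$K)
  truth <- allocate_provider_truth(spec)
  cohort <- fill_quotas(model, config, truth$n_k)
  for (attempt in seq_len(max_truth_attempts)) {
    gamma00 <- calibrate_intercept(cohort, truth, beta, spec$p_bar)
    y <- tryCatch(
      draw_outcomes(cohort, truth, beta, gamma00,
                    min_incidence = spec$min_incidence),
      profilesim_incidence_error = function(e) NULL)
    if (!is.null(y)) {
      data <- dplyr::mutate(cohort, y = as.integer(y))
      return(list(data = data, truth = truth, model = model,
                  gamma00 = gamma00, truth_redraws = attempt - 1L))
    }
    truth$alpha0 <- rnorm(spec$K, truth$mu, spec$sigma)
  }
  rlang::abort("Replicate generation failed: minimum provider incidence unreachable.",
               class = "profilesim_incidence_error")
}

#' Run one Monte-Carlo replicate
#'
#' Generates a replicate dataset with [simulate_replicate_data()] and applies
#' the requested risk-adjustment methods to the identical data. Method-level
#' fit failures are recorded (the method's confusion counts are `NA`) while
#' the remaining methods proceed.
#'
#' @inheritParams simulate_replicate_data
#' @param methods Subset of [profiling_methods()] to apply.
#' @param nAGQ Integration scheme for the random-intercept fits (default 0;
#'   see [fit_random_intercept_logistic()]).
#' @param rule_sd Standard deviation used by the two-SD empirical-Bayes rule.
#' @param keep_data Keep the generated dataset in the result (default FALSE).
#' @return An object of class `replicate_result`: a list with `counts` (tibble:
#'   `method`, `failed`, `tp`, `fp`, `tn`, `fn`), `classifications` (per
#'   provider and method), `truth`, `gamma00`, `seed`, and optionally `data`.
#' @export
run_replicate <- function(spec, seed, config = case_mix_config(),
                          beta = euroscore_coefficients(),
                          methods = profiling_methods(), nAGQ = 0,
                          rule_sd = c("model", "empirical"),
                          keep_data = FALSE, max_truth_attempts = 20) {
  rule_sd <- match.arg(rule_sd)
  methods <- match.arg(methods, profiling_methods(), several.ok = TRUE)
  rep_data <- simulate_replicate_data(spec, seed, config, beta,
                                      max_truth_attempts)
  data <- rep_data$data
  truth <- rep_data$truth

  needs_gps <- any(methods %in% c("gps_a", "gps_w", "gps_wt", "gps_mws"))
  gps <- NULL
  gps_error <- NULL
  if (needs_gps) {
    gps <- tryCatch(estimate_gps(data),
                    profilesim_fit_error = function(e) {
                      gps_error <<- conditionMessage(e); NULL
                    })
  }
  w_ipw <- if (!is.null(gps) && any(methods %in% c("gps_w", "gps_wt")))
    tryCatch(ipw_weights(gps, data$provider),
             profilesim_fit_error = function(e) NULL)
  w_mmw <- if (!is.null(gps) && "gps_mws" %in% methods)
    mmws_weights(gps, data$provider)

  classify_one <- function(m) {
    switch(m,
      lr_f = classify_lrf(data),
      lr_r = classify_lrr(data, nAGQ = nAGQ, rule_sd = rule_sd),
      gps_a = {
        if (is.null(gps)) rlang::abort(gps_error %||% "gPS estimation failed.",
                                       class = "profilesim_fit_error")
        classify_gps_a(data, gps = gps, nAGQ = nAGQ, rule_sd = rule_sd)
      },
      gps_w = ,
      gps_wt = {
        if (is.null(w_ipw)) rlang::abort("IPW weights unavailable.",
                                         class = "profilesim_fit_error")
        w <- if (m == "gps_wt") trim_weights(w_ipw) else w_ipw
        classify_weighted(data, weights = w, method = m, nAGQ = nAGQ,
                          rule_sd = rule_sd)
      },
      gps_mws = {
        if (is.null(w_mmw)) rlang::abort("MMW weights unavailable.",
                                         class = "profilesim_fit_error")
        classify_weighted(data, weights = w_mmw, method = "gps_mws",
                          nAGQ = nAGQ, rule_sd = rule_sd)
      })
  }

  results <- purrr::map(setNames(methods, methods), function(m) {
    tryCatch(classify_one(m), profilesim_fit_error = function(e) NULL)
  })
  counts <- purrr::map_dfr(methods, function(m) {
    res <- results[[m]]
    if (is.null(res)) {
      tibble::tibble(method = m, failed = TRUE, tp = NA_integer_,
                     fp = NA_integer_, tn = NA_integer_, fn = NA_integer_)
    } else {
      dplyr::mutate(confusion(truth$class, res$label),
                    method = m, failed = FALSE, .before = 1L)
    }
  })
  out <- list(counts = counts,
              classifications = dplyr::bind_rows(purrr::compact(results)),
              truth = truth,
              gamma00 = rep_data$gamma00,
              seed = seed)
  if (keep_data) out$data <- data
  structure(out, class = "replicate_result")
}

#' @export
print.replicate_result <- function(x, ...) {
  cat("Replicate (seed ", x$seed, "): ", sum(x$truth$class != "normal"),
      " true outliers among ", nrow(x$truth), " providers\n", sep = "")
  print(x$counts)
  invisible(x)
}

#' Run a scenario design point over many replicates
#'
#' Replicate seeds derive deterministically from the master seed and replicate
#' index ([derive_seed()]), so results are reproducible and independent of
#' execution order. Replicates whose data generation fails outright are
#' recorded as failed for every method.
#'
#' @inheritParams run_replicate
#' @param reps Number of Monte-Carlo replicates.
#' @param seed Master seed.
#' @param point Design-point index used in seed derivation (default 1).
#' @param out_dir Optional directory; when given, per-replicate counts and the
#'   summary are written as CSV files.
#' @return A list with `replicates` (per-replicate counts tibble, including a
#'   `replicate` column) and `summary` (a [summarize_performance()] tibble).
#' @export
run_scenario <- function(spec, reps = 100, seed = 1,
                         config = case_mix_config(),
                         beta = euroscore_coefficients(),
                         methods = profiling_methods(), nAGQ = 0,
                         rule_sd = c("model", "empirical"),
                         point = 1L, out_dir = NULL, max_truth_attempts = 20) {
  stopifnot(reps >= 1)
  rule_sd <- match.arg(rule_sd)
  replicates <- purrr::map_dfr(seq_len(reps), function(r) {
    s <- derive_seed(seed, point, r)
    res <- tryCatch(
      run_replicate(spec, s, config, beta, methods, nAGQ, rule_sd,
                    max_truth_attempts = max_truth_attempts),
      profilesim_incidence_error = function(e) NULL,
      profilesim_quota_error = function(e) NULL)
    counts <- if (is.null(res)) {
      tibble::tibble(method = methods, failed = TRUE, tp = NA_integer_,
                     fp = NA_integer_, tn = NA_integer_, fn = NA_integer_)
    } else {
      res$counts
    }
    dplyr::mutate(counts, replicate = r, .before = 1L)
  })
  summary <- summarize_performance(replicates)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(replicates, file.path(out_dir, "replicates.csv"),
                     row.names = FALSE)
    utils::write.csv(summary, file.path(out_dir, "summary.csv"),
                     row.names = FALSE)
  }
  list(replicates = replicates, summary = summary)
}

#' Run a sweep of design points
#'
#' Applies [run_scenario()] to each row of a design grid (e.g. a filtered
#' [scenario_grid()]) and returns tidy per-design-point summaries.
#'
#' @param grid A tibble of design points with the columns of
#'   [scenario_grid()].
#' @inheritParams run_scenario
#' @param sigma Random-intercept SD passed to every [scenario_spec()].
#' @return A list with `replicates` and `summary`, each carrying the design
#'   columns of `grid`.
#' @export
run_grid <- function(grid, reps = 100, seed = 1, config = case_mix_config(),
                     beta = euroscore_coefficients(),
                     methods = profiling_methods(), nAGQ = 0,
                     rule_sd = c("model", "empirical"), sigma = 0.1942,
                     out_dir = NULL) {
  rule_sd <- match.arg(rule_sd)
  runs <- purrr::map(seq_len(nrow(grid)), function(i) {
    row <- grid[i, ]
    spec <- spec_from_row(row, sigma = sigma)
    res <- run_scenario(spec, reps = reps, seed = seed, config = config,
                        beta = beta, methods = methods, nAGQ = nAGQ,
                        rule_sd = rule_sd,
                        point = if ("point" %in% names(row))
                          (row$scenario %||% 0) * 100 + row$point else i)
    list(replicates = dplyr::bind_cols(row[rep(1L, nrow(res$replicates)), ],
                                       res$replicates),
         summary = dplyr::bind_cols(row[rep(1L, nrow(res$summary)), ],
                                    res$summary))
  })
  out <- list(replicates = purrr::map_dfr(runs, "replicates"),
              summary = purrr::map_dfr(runs, "summary"))
  class(out$summary) <- c("performance_summary", class(out$summary))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(out$replicates, file.path(out_dir, "replicates.csv"),
                     row.names = FALSE)
    utils::write.csv(out$summary, file.path(out_dir, "summary.csv"),
                     row.names = FALSE)
  }
  out
}
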