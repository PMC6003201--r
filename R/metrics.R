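#' Provider-level confusion counts
#'
#' Compares observed outlier labels with true status on the outlier/normal
#' dichotomy: a flagged provider counts as a true positive whenever the
#' provider is truly outlying, regardless of the flagged direction.
#'
#' @param truth True labels (`normal`/`low`/`high`), one per provider.
#' @param observed Observed labels, same length and encoding.
#' @return A one-row tibble with columns `tp`, `fp`, `tn`, `fn`.
#' @examples
#' confusion(c("low", "high", "normal", "normal"),
#'           c("low", "normal", "high", "normal"))
#' @export
confusion <- function(truth, observed) {
  if (length(truth) != length(observed)) {
    rlang::abort("`truth` and `observed` must have the same length.",
                 class = "profilesim_schema_error")
  }
  t_out <- as.character(truth) != "normal"
  o_out <- as.character(observed) != "normal"
  tibble::tibble(tp = sum(t_out & o_out),
                 fp = sum(!t_out & o_out),
                 tn = sum(!t_out & !o_out),
                 fn = sum(t_out & !o_out))
}

#' Classification-accuracy measures from confusion counts
#'
#' Standard ratios; a measure whose denominator is zero (e.g. PPV when no
#' provider was flagged) is reported as `NA`, never as zero.
#'
#' @param counts A tibble with columns `tp`, `fp`, `tn`, `fn` (one or more
#'   rows).
#' @return `counts` with columns `sensitivity`, `specificity`, `ppv`, `npv`
#'   appended.
#' @export
performance <- function(counts) {
  ratio <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  dplyr::mutate(counts,
                sensitivity = ratio(.data$tp, .data$tp + .data$fn),
                specificity = ratio(.data$tn, .data$tn + .data$fp),
                ppv = ratio(.data$tp, .data$tp + .data$fp),
                npv = ratio(.data$tn, .data$tn + .data$fn))
}

#' Summarise replicate results into performance measures
#'
#' Averages per-replicate sensitivity, specificity, PPV and NPV over the
#' replicates where each measure is defined, attaches 90th-percentile
#' intervals (5th and 95th linear-interpolation sample percentiles of the
#' per-replicate values), and computes eagerness: the proportion of usable
#' replicates in which at least one provider was flagged.
#'
#' @param replicates A tibble of per-replicate, per-method results as produced
#'   by [run_scenario()]: columns `method`, `failed`, `tp`, `fp`, `tn`, `fn`,
#'   plus any grouping columns named in `by`.
#' @param by Extra grouping columns (e.g. a swept design parameter); results
#'   are always grouped by `method`.
#' @return A tibble of class `performance_summary`, long over `measure`
#'   (`sensitivity`, `specificity`, `ppv`, `npv`, `eagerness`) with columns
#'   `mean`, `lo90`, `hi90`, `n_defined`, `n_failed`.
#' @export
summarize_performance <- function(replicates, by = character(0)) {
  grp <- c(by, "method")
  usable <- dplyr::filter(replicates, !.data$failed)
  if (nrow(usable) == 0) {
    rlang::abort("No usable replicates to summarise.",
                 class = "profilesim_config_error")
  }
  meas <- performance(usable)
  long <- tidyr::pivot_longer(
    meas, cols = c("sensitivity", "specificity", "ppv", "npv"),
    names_to = "measure", values_to = "value")
  core <- long |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(grp, "measure")))) |>
    dplyr::summarise(
      mean = mean(.data$value, na.rm = TRUE),
      lo90 = if (any(!is.na(.data$value)))
        unname(quantile(.data$value, 0.05, na.rm = TRUE, type = 7)) else NA_real_,
      hi90 = if (any(!is.na(.data$value)))
        unname(quantile(.data$value, 0.95, na.rm = TRUE, type = 7)) else NA_real_,
      n_defined = sum(!is.na(.data$value)),
      .groups = "drop")
  eager <- meas |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(measure = "eagerness",
                     mean = mean(.data$tp + .data$fp >= 1),
                     lo90 = NA_real_, hi90 = NA_real_,
                     n_defined = dplyr::n(), .groups = "drop")
  failed <- replicates |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(n_failed = sum(.data$failed), .groups = "drop")
  out <- dplyr::bind_rows(core, eager) |>
    dplyr::left_join(failed, by = grp) |>
    dplyr::arrange(dplyr::across(dplyr::all_of(c(grp, "measure"))))
  class(out) <- c("performance_summary", class(out))
  out
}
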