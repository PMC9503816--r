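# End-to-end drivers tying windows, stages and the duration model together.

#' Run Stages 1 and 2 across a set of candidate wear-duration windows
#'
#' Partitions the observations into every window of `specs`, summarizes each
#' window per subject and feature, and runs difference testing (Stage 1) and
#' ICC analysis (Stage 2) of every non-baseline window against the baseline
#' window, plus the per-domain reliability summary.
#'
#' @param obs Feature-observation tibble.
#' @param specs Named list of [duration_spec()]s containing exactly one
#'   baseline (default [default_duration_specs()]).
#' @param config Configuration list (see [default_config()]).
#' @param seed Seed for `random_contiguous` windows.
#' @return List of class `wear_reliability_analysis`: `summaries` (named
#'   list of summary tibbles), `stage1`, `stage2` (row-bound result
#'   tibbles), `reliability` (per-domain percentage summary) and
#'   `baseline_label`.
#' @export
analyze_wear_durations <- function(obs, specs = default_duration_specs(),
                                   config = default_config(), seed = NULL) {
  is_base <- vapply(specs, `[[`, logical(1), "baseline")
  if (sum(is_base) != 1) {
    abort("specs must contain exactly one baseline window",
          class = "weartime_input_error")
  }
  obs <- add_day_index(obs, config$tz_offset_hours)
  summaries <- lapply(specs, function(sp) {
    summarize_windows(
      partition_windows(obs, sp, seed = seed,
                        tz_offset_hours = config$tz_offset_hours),
      min_obs = config$min_obs
    )
  })
  base_label <- names(specs)[is_base]
  bsum <- summaries[[base_label]]
  others <- names(specs)[!is_base]
  s1 <- dplyr::bind_rows(lapply(others, function(l) {
    stage1_difference(summaries[[l]], bsum, alpha = config$alpha)
  }))
  s2 <- dplyr::bind_rows(lapply(others, function(l) {
    stage2_icc(summaries[[l]], bsum, threshold = config$icc_threshold)
  }))
  structure(
    list(summaries = summaries, stage1 = s1, stage2 = s2,
         reliability = summarize_reliability(s1, s2),
         baseline_label = base_label),
    class = "wear_reliability_analysis"
  )
}

#' @export
print.wear_reliability_analysis <- function(x, ...) {
  cat(sprintf(
    "Wear-duration reliability analysis (baseline: %s)\n%d window(s), %d Stage-1 and %d Stage-2 cells\n",
    x$baseline_label, length(x$summaries), nrow(x$stage1), nrow(x$stage2)
  ))
  print(as.data.frame(x$reliability), row.names = FALSE)
  invisible(x)
}

#' Estimate days required per feature, with regression covariates
#'
#' Runs Stages 1 and 2 for first-days windows of 1..`max(candidate_days)`
#' days against the first-week baseline, determines each feature's minimum
#' qualifying duration, attaches the observation-count and log-CV
#' covariates from the first two days, and (when enough features qualify)
#' fits the wear-duration regression.
#'
#' @param obs Feature-observation tibble spanning at least the baseline
#'   week.
#' @param candidate_days Candidate durations (default 1:7).
#' @param baseline_days Baseline window length (default 7).
#' @param config Configuration list.
#' @param fit_regression Fit the days-required regression when at least six
#'   features qualify (default TRUE).
#' @return List of class `days_required_analysis`: `days_required` tibble,
#'   `covariates`, `estimates` (join of the two), `regression` (a
#'   `wear_duration_fit` or NULL), `stage1`, `stage2`.
#' @export
estimate_days_required <- function(obs, candidate_days = 1:7,
                                   baseline_days = 7,
                                   config = default_config(),
                                   fit_regression = TRUE) {
  obs <- add_day_index(obs, config$tz_offset_hours)
  bsum <- summarize_windows(
    partition_windows(obs, duration_spec("baseline", baseline_days,
                                         baseline = TRUE)),
    min_obs = config$min_obs
  )
  s1 <- list(); s2 <- list()
  for (d in sort(candidate_days)) {
    ws <- summarize_windows(
      partition_windows(obs, duration_spec(as.character(d), d)),
      min_obs = config$min_obs
    )
    s1[[length(s1) + 1]] <- stage1_difference(ws, bsum, alpha = config$alpha)
    s2[[length(s2) + 1]] <- stage2_icc(ws, bsum,
                                       threshold = config$icc_threshold)
  }
  s1 <- dplyr::bind_rows(s1); s2 <- dplyr::bind_rows(s2)
  dr <- days_required(s1, s2, candidate_days = candidate_days)
  cov <- feature_covariates(obs, tz_offset_hours = config$tz_offset_hours)
  estimates <- dplyr::inner_join(dr, cov, by = "feature_name")
  regression <- NULL
  if (fit_regression) {
    eligible <- estimates[estimates$reached, ]
    if (nrow(eligible) >= 6) {
      regression <- fit_duration_regression(eligible)
    } else {
      inform(sprintf(
        "regression skipped: only %d feature(s) reached days_required",
        nrow(eligible)))
    }
  }
  n_unreached <- sum(!dr$reached)
  if (n_unreached > 0) {
    inform(sprintf("%d feature(s) did not reach days_required within %d days",
                   n_unreached, max(candidate_days)))
  }
  structure(
    list(days_required = dr, covariates = cov, estimates = estimates,
         regression = regression, stage1 = s1, stage2 = s2),
    class = "days_required_analysis"
  )
}

#' @export
print.days_required_analysis <- function(x, ...) {
  cat("Days-required analysis\n")
  print(as.data.frame(x$days_required[, c("feature_name", "days_required",
                                          "reached")]),
        row.names = FALSE)
  if (!is.null(x$regression)) print(x$regression)
  invisible(x)
}
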