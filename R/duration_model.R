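# Days-required determination, the wear-duration regression, and the
# bootstrap power analysis.

#' Minimum days of wear satisfying Stages 1 and 2
#'
#' For each feature, the smallest candidate duration (in days) at which the
#' median, 95th percentile and CV summaries simultaneously show no
#' significant difference from baseline (Stage 1) and a strong ICC
#' (Stage 2). Candidate days with missing or non-evaluable stage results are
#' skipped with a warning; features that never qualify are reported as not
#' reached.
#'
#' @param stage1,stage2 Row-bound stage result tibbles covering the
#'   candidate durations, with `duration_label` equal to the candidate day
#'   (coercible to integer).
#' @param candidate_days Integer vector of candidate durations (default
#'   1:7; the baseline week bounds the search).
#' @return Tibble: `feature_name`, `days_required` (NA when not reached),
#'   `reached`, `n_days_skipped`; the per-candidate pass record is attached
#'   as the `criteria` attribute.
#' @export
days_required <- function(stage1, stage2, candidate_days = 1:7) {
  s1 <- stage1; s1$day <- suppressWarnings(as.integer(s1$duration_label))
  s2 <- stage2; s2$day <- suppressWarnings(as.integer(s2$duration_label))
  feats <- sort(unique(c(s1$feature_name, s2$feature_name)))
  criteria <- list()
  rows <- lapply(feats, function(f) {
    skipped <- 0L
    required <- NA_integer_
    for (d in sort(candidate_days)) {
      a <- s1[s1$feature_name == f & s1$day == d, ]
      b <- s2[s2$feature_name == f & s2$day == d, ]
      have_all <- nrow(a) == 3 && nrow(b) == 3 &&
        all(a$evaluable) && all(b$evaluable)
      if (!have_all) {
        skipped <- skipped + 1L
        next
      }
      pass <- all(!a$significant) && all(b$strong)
      criteria[[length(criteria) + 1]] <<- tibble::tibble(
        feature_name = f, day = d, no_difference = all(!a$significant),
        strong_icc = all(b$strong), pass = pass
      )
      if (pass) { required <- d; break }
    }
    if (skipped > 0) {
      warn(sprintf("days_required('%s'): %d candidate day(s) skipped (missing or non-evaluable stage results)",
                   f, skipped), class = "weartime_skip_warning")
    }
    tibble::tibble(feature_name = f, days_required = required,
                   reached = !is.na(required), n_days_skipped = skipped)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "criteria") <- dplyr::bind_rows(criteria)
  out
}

#' Observation-count and variability covariates for the regression
#'
#' From the first `n_days` days of monitoring (default 2): `count` is the
#' mean over subjects of the per-subject observations per day, and `cv` the
#' mean over subjects of the per-subject coefficient of variation pooled
#' across those days. `log_cv` is the natural log. Features whose CV cannot
#' be computed for any subject are excluded with a warning.
#'
#' @param obs Feature-observation tibble.
#' @param n_days Covariate window in days (default 2).
#' @param tz_offset_hours Day-boundary offset (see [partition_windows()]).
#' @return Tibble: `feature_name`, `count`, `cv`, `log_cv`.
#' @export
feature_covariates <- function(obs, n_days = 2, tz_offset_hours = 0) {
  obs <- add_day_index(obs, tz_offset_hours)
  if (max(obs$day_index) < n_days) {
    abort(sprintf("feature_covariates needs at least %d days of data", n_days),
          class = "weartime_input_error")
  }
  subjects <- sort(unique(obs$subject_id))
  win <- obs[obs$day_index <= n_days, , drop = FALSE]
  by_feat <- split(win[, c("subject_id", "value")], win$feature_name)
  out <- dplyr::bind_rows(lapply(names(by_feat), function(f) {
    d <- by_feat[[f]]
    vals <- split(d$value[!is.na(d$value)], d$subject_id[!is.na(d$value)])
    n_i <- vapply(subjects, function(s) {
      v <- vals[[s]]; if (is.null(v)) 0L else length(v)
    }, integer(1))
    cv_i <- vapply(subjects, function(s) {
      v <- vals[[s]]
      if (is.null(v) || length(v) < 2) return(NA_real_)
      m <- mean(v); s_ <- sd(v)
      if (abs(m) < 1e-8 * s_) NA_real_ else s_ / abs(m)
    }, numeric(1))
    tibble::tibble(
      feature_name = f,
      count = mean(n_i) / n_days,
      cv = if (all(is.na(cv_i))) NA_real_ else mean(cv_i, na.rm = TRUE)
    )
  }))
  bad <- is.na(out$cv) | out$cv <= 0
  if (any(bad)) {
    warn(sprintf("excluding %d feature(s) without a valid CV from covariates",
                 sum(bad)), class = "weartime_skip_warning")
    out <- out[!bad, , drop = FALSE]
  }
  out$log_cv <- log(out$cv)
  out
}

#' Wear-duration regression
#'
#' Ordinary least squares of days required on log CV, observation count and
#' their interaction: `days_required ~ 1 + log_cv + count + log_cv:count`.
#'
#' @param estimates Tibble with columns `days_required`, `log_cv`, `count`
#'   (one row per feature whose days-required was reached); at least
#'   `min_features` complete rows.
#' @param min_features Minimum observations for the fit (default 6).
#' @return List of class `wear_duration_fit`: `coefficients` tibble (term,
#'   estimate, std_error, p_value), `r_squared`, `adj_r_squared`, `n`,
#'   `sigma`, and the underlying `lm` fit.
#' @export
fit_duration_regression <- function(estimates, min_features = 6) {
  d <- estimates[complete.cases(
    estimates[, c("days_required", "log_cv", "count")]), ]
  if (nrow(d) < min_features) {
    abort(sprintf("need at least %d features with days_required reached (have %d)",
                  min_features, nrow(d)),
          class = "weartime_input_error")
  }
  X <- cbind(1, d$log_cv, d$count, d$log_cv * d$count)
  colnames(X) <- c("intercept", "log_cv", "count", "interaction")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    abort(paste0("design matrix is rank deficient; collinear column(s): ",
                 paste(dropped, collapse = ", ")),
          class = "weartime_rank_error")
  }
  fit <- lm(days_required ~ log_cv * count, data = d)
  sm <- summary(fit)
  tss <- sum((d$days_required - mean(d$days_required))^2)
  if (!is.finite(sm$r.squared) ||
      tss < 1e-12 * (1 + mean(d$days_required)^2)) {
    sm$r.squared <- 0                                  # constant response
    sm$adj.r.squared <- 0
  }
  coefs <- tibble::tibble(
    term = c("intercept", "log_cv", "count", "interaction"),
    estimate = unname(sm$coefficients[, 1]),
    std_error = unname(sm$coefficients[, 2]),
    p_value = unname(sm$coefficients[, 4])
  )
  structure(
    list(coefficients = coefs, r_squared = sm$r.squared,
         adj_r_squared = sm$adj.r.squared, n = nrow(d),
         sigma = sm$sigma, fit = fit),
    class = "wear_duration_fit"
  )
}

#' @export
print.wear_duration_fit <- function(x, ...) {
  cat("Wear-duration regression: days_required ~ 1 + log_cv + count + interaction\n")
  print(as.data.frame(x$coefficients), row.names = FALSE, digits = 4)
  cat(sprintf("R-squared: %.3f; adjusted R-squared: %.3f; n = %d\n",
              x$r_squared, x$adj_r_squared, x$n))
  invisible(x)
}

#' Export a regression report
#'
#' @param fit A `wear_duration_fit`.
#' @param path Output path; `.json` writes JSON, anything else a CSV of the
#'   coefficient table with the fit statistics appended as a comment header.
#' @return `path`, invisibly.
#' @export
write_regression_report <- function(fit, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(
      list(coefficients = fit$coefficients, r_squared = fit$r_squared,
           adj_r_squared = fit$adj_r_squared, n = fit$n),
      path, auto_unbox = TRUE, digits = NA
    )
  } else {
    readr::write_csv(fit$coefficients, path)
  }
  invisible(path)
}

#' Bootstrap power analysis of a duration-pair ICC
#'
#' Resamples subjects with replacement `B` times (default 1000) and
#' recomputes the ICC(C,k) between the two durations per replicate,
#' reporting the bootstrap distribution summary and the proportion of
#' replicates with a strong ICC. Degenerate replicates (zero between-subject
#' variance) are dropped and counted. Fully reproducible under a fixed seed.
#'
#' @param window_summaries,baseline_summaries Summary tibbles from
#'   [summarize_windows()] for the two durations.
#' @param feature One feature name.
#' @param statistic One of `"median"`, `"p95"`, `"cv"`.
#' @param B Number of bootstrap replicates (default 1000).
#' @param seed Integer seed.
#' @param threshold Strong-ICC threshold (default 0.7).
#' @return Object of class `bootstrap_power`: `feature`, `statistic`,
#'   `duration_pair`, `B`, `seed`, `n_subjects`, `icc_point`, `icc_mean`,
#'   `icc_ci` (2.5/97.5 percentiles), `proportion_strong`, `n_dropped`, and
#'   the replicate vector `icc`.
#' @export
bootstrap_power <- function(window_summaries, baseline_summaries, feature,
                            statistic = "median", B = 1000, seed = 1,
                            threshold = 0.7) {
  w <- window_summaries[window_summaries$feature_name == feature, ]
  b <- baseline_summaries[baseline_summaries$feature_name == feature, ]
  joined <- dplyr::inner_join(w, b, by = c("subject_id", "feature_name"),
                              suffix = c("_w", "_b"))
  xw <- joined[[paste0(statistic, "_w")]]
  xb <- joined[[paste0(statistic, "_b")]]
  ok <- !is.na(xw) & !is.na(xb)
  mat <- cbind(xw[ok], xb[ok])
  n <- nrow(mat)
  if (n < 5) {
    abort("bootstrap_power needs at least 5 complete subject pairs",
          class = "weartime_input_error")
  }
  point <- icc_consistency(mat)$icc
  reps <- withr::with_seed(seed, vapply(seq_len(B), function(i) {
    idx <- sample.int(n, n, replace = TRUE)
    m <- mat[idx, , drop = FALSE]
    if (var(m[, 1]) == 0 || var(m[, 2]) == 0) return(NA_real_)
    icc_consistency(m)$icc
  }, numeric(1)))
  dropped <- sum(is.na(reps))
  good <- reps[!is.na(reps)]
  structure(
    list(
      feature = feature, statistic = statistic,
      duration_pair = c(
        if (nrow(w) > 0) w$duration_label[1] else NA_character_,
        if (nrow(b) > 0) b$duration_label[1] else NA_character_
      ),
      B = B, seed = seed, n_subjects = n,
      icc_point = point,
      icc_mean = mean(good),
      icc_ci = quantile(good, c(0.025, 0.975), names = FALSE),
      proportion_strong = mean(good >= threshold),
      n_dropped = dropped,
      icc = reps
    ),
    class = "bootstrap_power"
  )
}

#' @export
print.bootstrap_power <- function(x, ...) {
  cat(sprintf(
    "Bootstrap ICC power analysis: %s (%s), %s vs %s\n  B = %d (seed %d, %d dropped), point ICC %.3f\n  mean %.3f, 95%% CI [%.3f, %.3f], P(ICC >= 0.7) = %.3f\n",
    x$feature, x$statistic, x$duration_pair[1], x$duration_pair[2],
    x$B, x$seed, x$n_dropped, x$icc_point, x$icc_mean,
    x$icc_ci[1], x$icc_ci[2], x$proportion_strong
  ))
  invisible(x)
}
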