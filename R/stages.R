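# The three-stage wear-duration reliability analysis:
#   Stage 1 - rank-sum difference testing of window summaries vs baseline
#   Stage 2 - two-way consistency intraclass correlation ICC(C,k)
#   Stage 3 - stability of Spearman correlations with patient-reported
#             measures across wear durations

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact distribution when the combined sample size is at most
#' `exact_max_n` and there are no ties; normal approximation with
#' tie/continuity correction otherwise.
#'
#' @param x,y Numeric samples.
#' @param exact_max_n Largest combined sample size for which the exact
#'   distribution is used (default 20).
#' @return List with `p_value` and `statistic` (the Mann-Whitney count for
#'   `x`).
#' @export
rank_sum_test <- function(x, y, exact_max_n = 20) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y)) <= exact_max_n && !ties
  ht <- suppressWarnings(wilcox.test(x, y, alternative = "two.sided",
                                     exact = exact, correct = TRUE))
  list(p_value = unname(ht$p.value), statistic = unname(ht$statistic))
}

#' Stage 1: difference testing of window summaries against baseline
#'
#' For each feature and summary statistic (median, 95th percentile, CV),
#' compares the across-subject vector of window summaries with the baseline
#' vector by a two-sided Wilcoxon rank-sum test. Cells with fewer than
#' `min_subjects` non-missing values on either side are flagged not
#' evaluable. Subjects are treated as unpaired groups, matching the
#' framework's stated test; no multiple-testing correction is applied (the
#' number of tests performed is recorded so users can apply their own).
#'
#' @param window_summaries,baseline_summaries Summary tibbles from
#'   [summarize_windows()].
#' @param alpha Significance threshold (default 0.05).
#' @param min_subjects Minimum non-missing subjects per side (default 3).
#' @return Tibble: `feature_name`, `statistic`, `duration_label`,
#'   `n_window`, `n_baseline`, `p_value`, `significant`, `evaluable`, with a
#'   `n_tests` attribute.
#' @export
stage1_difference <- function(window_summaries, baseline_summaries,
                              alpha = 0.05, min_subjects = 3) {
  label <- if (nrow(window_summaries) > 0)
    window_summaries$duration_label[1] else NA_character_
  feats <- sort(unique(window_summaries$feature_name))
  stats_ <- c("median", "p95", "cv")
  wi <- split(seq_len(nrow(window_summaries)), window_summaries$feature_name)
  bi <- split(seq_len(nrow(baseline_summaries)), baseline_summaries$feature_name)
  ncell <- length(feats) * length(stats_)
  feature_name <- statistic <- character(ncell)
  n_window <- n_baseline <- integer(ncell)
  p_value <- numeric(ncell)
  k <- 0L
  for (f in feats) {
    for (s in stats_) {
      k <- k + 1L
      xv <- window_summaries[[s]][wi[[f]]]
      yv <- if (is.null(bi[[f]])) numeric(0) else baseline_summaries[[s]][bi[[f]]]
      xv <- xv[!is.na(xv)]; yv <- yv[!is.na(yv)]
      feature_name[k] <- f; statistic[k] <- s
      n_window[k] <- length(xv); n_baseline[k] <- length(yv)
      p_value[k] <- if (length(xv) >= min_subjects &&
                        length(yv) >= min_subjects)
        rank_sum_test(xv, yv)$p_value else NA_real_
    }
  }
  evaluable <- !is.na(p_value)
  res <- tibble::tibble(
    feature_name = feature_name, statistic = statistic,
    duration_label = label, n_window = n_window, n_baseline = n_baseline,
    p_value = p_value,
    significant = ifelse(evaluable, p_value < alpha, NA),
    evaluable = evaluable
  )
  attr(res, "n_tests") <- sum(evaluable)
  res
}

pivot_statistics <- function(summaries) {
  tidyr::pivot_longer(
    summaries[, c("subject_id", "feature_name", "median", "p95", "cv")],
    cols = c("median", "p95", "cv"),
    names_to = "statistic", values_to = "value"
  )
}

#' Intraclass correlation ICC(C,k): two-way consistency, average measures
#'
#' Computed from the two-way mixed-model mean squares as
#' `(MSR - MSE) / MSR`, where `MSR` is the between-subject (row) mean square
#' and `MSE` the residual mean square after removing row and column effects.
#' The consistency definition ignores fixed offsets between columns, so a
#' constant shift of one column leaves the ICC at 1.
#'
#' @param values An `n x k` numeric matrix (subjects by measurements); rows
#'   containing missing values are dropped.
#' @return List with `icc` (NA, flagged, when the between-subject variance
#'   is zero), `n`, `k`, `msr`, `msc`, `mse`.
#' @export
icc_consistency <- function(values) {
  values <- as.matrix(values)
  values <- values[complete.cases(values), , drop = FALSE]
  n <- nrow(values); k <- ncol(values)
  if (n < 2 || k < 2) {
    abort("icc_consistency needs at least 2 complete rows and 2 columns",
          class = "weartime_input_error")
  }
  grand <- mean(values)
  row_means <- rowMeans(values)
  col_means <- colMeans(values)
  ssr <- k * sum((row_means - grand)^2)
  ssc <- n * sum((col_means - grand)^2)
  sst <- sum((values - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  icc <- if (msr <= 0 || msr < 1e-14 * max(sst, 1)) NA_real_
         else (msr - mse) / msr
  list(icc = icc, n = n, k = k, msr = msr, msc = msc, mse = mse)
}

#' Stage 2: ICC(C,k) of window summaries against baseline
#'
#' For each feature and summary statistic, computes the two-way consistency
#' average-measures ICC between the per-subject window and baseline
#' summaries (k = 2 measurements). Subjects missing either side are dropped
#' pairwise; cells with fewer than `min_pairs` complete pairs are flagged
#' not evaluable. An ICC of `threshold` (default 0.70) or higher is
#' classified as strong.
#'
#' @inheritParams stage1_difference
#' @param threshold Strength threshold on the ICC (default 0.7).
#' @param min_pairs Minimum complete subject pairs (default 5).
#' @return Tibble: `feature_name`, `statistic`, `duration_label`, `icc`,
#'   `strong`, `n_subjects`, `evaluable`.
#' @export
stage2_icc <- function(window_summaries, baseline_summaries, threshold = 0.7,
                       min_pairs = 5) {
  label <- if (nrow(window_summaries) > 0)
    window_summaries$duration_label[1] else NA_character_
  feats <- sort(unique(window_summaries$feature_name))
  stats_ <- c("median", "p95", "cv")
  wi <- split(seq_len(nrow(window_summaries)), window_summaries$feature_name)
  bi <- split(seq_len(nrow(baseline_summaries)), baseline_summaries$feature_name)
  ncell <- length(feats) * length(stats_)
  feature_name <- statistic <- character(ncell)
  icc <- numeric(ncell)
  n_subjects <- integer(ncell)
  k <- 0L
  for (f in feats) {
    iw <- wi[[f]]
    ib <- bi[[f]]
    m <- if (is.null(ib)) rep(NA_integer_, length(iw))
         else match(window_summaries$subject_id[iw],
                    baseline_summaries$subject_id[ib])
    for (s in stats_) {
      k <- k + 1L
      feature_name[k] <- f; statistic[k] <- s
      x <- window_summaries[[s]][iw]
      y <- if (is.null(ib)) rep(NA_real_, length(x))
           else baseline_summaries[[s]][ib][m]
      ok <- !is.na(x) & !is.na(y)
      n_subjects[k] <- sum(ok)
      icc[k] <- if (sum(ok) < min_pairs) NA_real_
                else icc_consistency(cbind(x[ok], y[ok]))$icc
    }
  }
  tibble::tibble(
    feature_name = feature_name, statistic = statistic,
    duration_label = label, icc = icc,
    strong = ifelse(is.na(icc), NA, icc >= threshold),
    n_subjects = n_subjects,
    evaluable = !is.na(icc)
  )
}

#' Spearman correlation with p-value
#'
#' Wrapper over [stats::cor.test()] (exact where R computes it for small
#' tie-free samples, approximation otherwise). Returns missing values for
#' constant input.
#'
#' @param x,y Numeric vectors.
#' @return List with `rho` and `p_value`.
#' @export
spearman_correlation <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3 || sd(x) == 0 || sd(y) == 0) {
    return(list(rho = NA_real_, p_value = NA_real_))
  }
  ht <- suppressWarnings(cor.test(x, y, method = "spearman"))
  list(rho = unname(ht$estimate), p_value = unname(ht$p.value))
}

#' Stage 3: correlation with patient-reported measures across wear durations
#'
#' For each feature, summary statistic and wear duration (1..`max_days`
#' days), computes the Spearman correlation between the across-subject
#' summaries and a patient-reported measure (ABC biweekly median or MFIS
#' end-of-period score). A feature-statistic pair is stable when a
#' significant correlation emerges at some duration `d` and stays
#' significant with similar strength (|rho(d') - rho(d)| <= `epsilon`) for
#' every later duration; the emergence day is the smallest such `d`.
#'
#' @param summaries Long summary tibble covering durations 1..`max_days`
#'   with a numeric `duration_days` column (one [summarize_windows()] result
#'   per duration, row-bound).
#' @param prm_scores Tibble with `subject_id` and `score` for one PRM.
#' @param prm Label recorded on the output (`"ABC"` or `"MFIS"`).
#' @param alpha Significance threshold (default 0.05).
#' @param epsilon Stability tolerance on the correlation strength (default
#'   0.10).
#' @param min_subjects Minimum subjects with both feature summary and PRM
#'   (default 10).
#' @param max_days Longest duration considered (default 14).
#' @return List with `by_duration` (tibble of `rho`/`p_value` per feature,
#'   statistic and duration) and `emergence` (tibble with `emergence_day`
#'   and `stable` per feature and statistic).
#' @export
stage3_prm_correlation <- function(summaries, prm_scores, prm = "ABC",
                                   alpha = 0.05, epsilon = 0.10,
                                   min_subjects = 10, max_days = 14) {
  long <- dplyr::inner_join(
    pivot_long_with_duration(summaries),
    prm_scores, by = "subject_id"
  )
  by_duration <- long %>%
    dplyr::group_by(.data$feature_name, .data$statistic,
                    .data$duration_days) %>%
    dplyr::group_modify(function(d, key) {
      ok <- !is.na(d$value) & !is.na(d$score)
      if (sum(ok) < min_subjects) {
        return(tibble::tibble(rho = NA_real_, p_value = NA_real_,
                              n = sum(ok), evaluable = FALSE))
      }
      ct <- spearman_correlation(d$value[ok], d$score[ok])
      tibble::tibble(rho = ct$rho, p_value = ct$p_value, n = sum(ok),
                     evaluable = !is.na(ct$rho))
    }) %>%
    dplyr::ungroup() %>%
    dplyr::mutate(prm = prm, significant = .data$p_value < alpha)

  emergence <- by_duration %>%
    dplyr::group_by(.data$feature_name, .data$statistic) %>%
    dplyr::group_modify(function(d, key) {
      d <- d[order(d$duration_days), ]
      day <- emergence_day(d$duration_days, d$rho, d$significant,
                           epsilon, max_days)
      tibble::tibble(prm = prm, emergence_day = day, stable = !is.na(day))
    }) %>%
    dplyr::ungroup()

  list(by_duration = by_duration, emergence = emergence)
}

pivot_long_with_duration <- function(summaries) {
  tidyr::pivot_longer(
    summaries[, c("subject_id", "feature_name", "duration_days",
                  "median", "p95", "cv")],
    cols = c("median", "p95", "cv"),
    names_to = "statistic", values_to = "value"
  )
}

# Smallest duration d at which a significant correlation appears and, for
# every later duration up to max_days, stays significant with
# |rho(d') - rho(d)| <= epsilon. NA when no such duration exists.
emergence_day <- function(days, rho, significant, epsilon, max_days) {
  keep <- days <= max_days & !is.na(significant)
  days <- days[keep]; rho <- rho[keep]; significant <- significant[keep]
  for (i in seq_along(days)) {
    if (!significant[i]) next
    later <- seq_along(days) >= i
    if (all(significant[later]) &&
        all(abs(rho[later] - rho[i]) <= epsilon)) {
      return(days[i])
    }
  }
  NA_integer_
}

#' Matrix export of Stage 3 correlations for heat maps
#'
#' @param by_duration The `by_duration` tibble from
#'   [stage3_prm_correlation()].
#' @param statistic Which summary statistic to export.
#' @return List with `rho` (feature x duration matrix) and `significant`
#'   (logical mask of the same shape).
#' @export
correlation_heatmap_matrix <- function(by_duration, statistic = "median") {
  d <- by_duration[by_duration$statistic == statistic, ]
  feats <- sort(unique(d$feature_name))
  days <- sort(unique(d$duration_days))
  rho <- matrix(NA_real_, length(feats), length(days),
                dimnames = list(feats, days))
  sig <- matrix(NA, length(feats), length(days),
                dimnames = list(feats, days))
  idx <- cbind(match(d$feature_name, feats), match(d$duration_days, days))
  rho[idx] <- d$rho
  sig[idx] <- d$significant
  list(rho = rho, significant = sig)
}

#' Summarize Stage 1 and Stage 2 outcomes per domain
#'
#' Reports, per window and domain, the percentage of features with a strong
#' ICC and the percentage without a significant difference for each summary
#' statistic, rounded to the nearest integer. Denominators are the full
#' domain feature counts (10 gait, 13 sway); gated gait features (entropy
#' ratio and Lyapunov measures) are excluded from the gait denominator and
#' reported under the `gait_gated` domain. Cells that were not evaluable
#' count against the percentage.
#'
#' @param stage1,stage2 Result tibbles from [stage1_difference()] and
#'   [stage2_icc()] (several windows may be row-bound).
#' @return Tibble: `duration_label`, `domain`, `statistic`,
#'   `pct_strong_icc`, `pct_no_diff`, `n_features`.
#' @export
summarize_reliability <- function(stage1, stage2) {
  vocab <- feature_vocabulary()
  add_domain <- function(d) {
    d$domain <- vocab$domain[match(d$feature_name, vocab$feature_name)]
    d
  }
  s1 <- add_domain(stage1); s2 <- add_domain(stage2)
  denom <- c(gait = sum(vocab$domain == "gait"),
             gait_gated = sum(vocab$domain == "gait_gated"),
             sway = sum(vocab$domain == "sway"))
  merged <- dplyr::full_join(
    s1[, c("feature_name", "statistic", "duration_label", "domain",
           "significant", "evaluable")],
    s2[, c("feature_name", "statistic", "duration_label", "domain", "strong")],
    by = c("feature_name", "statistic", "duration_label", "domain")
  )
  merged %>%
    dplyr::group_by(.data$duration_label, .data$domain, .data$statistic) %>%
    dplyr::summarise(
      pct_strong_icc = round(100 * sum(.data$strong %in% TRUE) /
                               denom[[.data$domain[1]]]),
      pct_no_diff = round(100 * sum(.data$significant %in% FALSE) /
                            denom[[.data$domain[1]]]),
      n_features = dplyr::n(),
      .groups = "drop"
    )
}
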