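# Candidate wear-duration windows and per-subject summary triplets
# (median, 95th percentile, coefficient of variation).

#' Define a candidate wear-duration window
#'
#' @param label Window label (e.g. `"2d"`, `"baseline_week"`).
#' @param length_days Window length in whole days (>= 1); ignored for the
#'   weekday/weekend anchors.
#' @param anchor One of `"first_days"` (calendar days 1..length of each
#'   subject's monitoring), `"random_contiguous"` (a uniformly chosen
#'   contiguous block, seeded), `"weekdays"` (all Mon-Fri observations
#'   pooled) or `"weekends"` (Sat-Sun pooled).
#' @param baseline Flag marking the run's reference window; exactly one spec
#'   per run should set it.
#' @return Object of class `duration_spec`.
#' @export
duration_spec <- function(label, length_days = 1L,
                          anchor = c("first_days", "random_contiguous",
                                     "weekdays", "weekends"),
                          baseline = FALSE) {
  anchor <- match.arg(anchor)
  if (anchor %in% c("first_days", "random_contiguous") && length_days < 1) {
    abort("length_days must be >= 1", class = "weartime_input_error")
  }
  structure(list(label = label, length_days = as.integer(length_days),
                 anchor = anchor, baseline = baseline),
            class = "duration_spec")
}

#' @export
print.duration_spec <- function(x, ...) {
  cat(sprintf("<duration_spec> %s: %s%s%s\n", x$label, x$anchor,
              if (x$anchor %in% c("first_days", "random_contiguous"))
                sprintf(" (%d days)", x$length_days) else "",
              if (x$baseline) " [baseline]" else ""))
  invisible(x)
}

#' The study's default window set
#'
#' One-week baseline plus 1, 2 and 3 days and 2-6 weeks, all anchored at the
#' start of each subject's monitoring so that shorter windows nest inside
#' the baseline week, plus pooled weekday and weekend windows.
#'
#' @return Named list of `duration_spec` objects.
#' @export
default_duration_specs <- function() {
  specs <- list(
    duration_spec("1d", 1), duration_spec("2d", 2), duration_spec("3d", 3),
    duration_spec("1w", 7, baseline = TRUE),
    duration_spec("2w", 14), duration_spec("3w", 21),
    duration_spec("4w", 28), duration_spec("5w", 35),
    duration_spec("6w", 42),
    duration_spec("weekday", anchor = "weekdays"),
    duration_spec("weekend", anchor = "weekends")
  )
  setNames(specs, vapply(specs, `[[`, character(1), "label"))
}

# Calendar day index per subject: 1 = first monitored day, boundaries at
# subject-local midnight via the configured time-zone offset. A precomputed
# `day_index` column (with its `.date` companion) is reused untouched.
add_day_index <- function(obs, tz_offset_hours = 0) {
  if (all(c("day_index", ".date") %in% names(obs))) return(obs)
  date <- as.Date(obs$bout_start + tz_offset_hours * 3600, tz = "UTC")
  obs$.date <- date
  day0 <- vapply(split(as.integer(date), obs$subject_id), min, integer(1))
  obs$day_index <- as.integer(date) - day0[obs$subject_id] + 1L
  obs
}

#' Partition feature observations into a candidate wear-duration window
#'
#' Subjects whose monitoring span is shorter than the window are excluded
#' and logged (mirroring per-window cohort attrition). Partial wear days
#' count as monitoring days whenever they contain at least one observation.
#'
#' @param obs Feature-observation tibble.
#' @param spec A [duration_spec()].
#' @param seed Integer seed, required for the `random_contiguous` anchor.
#' @param tz_offset_hours Offset applied before assigning observations to
#'   calendar days (day boundaries at subject-local midnight).
#' @return The subset of `obs` falling in the window, with columns
#'   `day_index` and `duration_label` added and an `excluded_subjects`
#'   attribute naming subjects without sufficient span.
#' @export
partition_windows <- function(obs, spec, seed = NULL, tz_offset_hours = 0) {
  stopifnot(inherits(spec, "duration_spec"))
  obs <- add_day_index(obs, tz_offset_hours)
  span <- obs %>%
    dplyr::group_by(.data$subject_id) %>%
    dplyr::summarise(span = max(.data$day_index), .groups = "drop")
  if (spec$anchor %in% c("first_days", "random_contiguous")) {
    short <- span$subject_id[span$span < spec$length_days]
    if (length(short) > 0) {
      inform(sprintf("window '%s': excluding %d subject(s) with span < %d days",
                     spec$label, length(short), spec$length_days))
    }
    obs <- obs[!obs$subject_id %in% short, , drop = FALSE]
  } else {
    short <- character()
  }
  out <- switch(
    spec$anchor,
    first_days = obs[obs$day_index <= spec$length_days, , drop = FALSE],
    random_contiguous = {
      if (is.null(seed)) {
        abort("random_contiguous windows need a seed",
              class = "weartime_input_error")
      }
      subjects <- sort(unique(obs$subject_id))
      spans <- span$span[match(subjects, span$subject_id)]
      starts <- withr::with_seed(seed, vapply(spans, function(s) {
        if (s <= spec$length_days) 1L
        else sample.int(s - spec$length_days + 1L, 1)
      }, integer(1)))
      start_of <- setNames(starts, subjects)
      s0 <- start_of[obs$subject_id]
      obs[obs$day_index >= s0 & obs$day_index < s0 + spec$length_days, ,
          drop = FALSE]
    },
    weekdays = obs[format(obs$.date, "%u") %in% c("1", "2", "3", "4", "5"), ,
                   drop = FALSE],
    weekends = obs[format(obs$.date, "%u") %in% c("6", "7"), , drop = FALSE]
  )
  out$.date <- NULL
  out$duration_label <- spec$label
  attr(out, "excluded_subjects") <- short
  out
}

#' Per-subject summary triplets for a window
#'
#' For each subject and feature, the median, interpolated 95th percentile
#' and coefficient of variation (sample SD over absolute mean) of all
#' observations in the window. Summaries are missing when fewer than
#' `min_obs` observations are available, and the CV is additionally missing
#' when the mean is indistinguishable from zero relative to the SD.
#'
#' @param obs Windowed observations from [partition_windows()] (or any
#'   feature-observation tibble).
#' @param duration_label Label recorded on the output; defaults to the
#'   `duration_label` column of `obs` when present.
#' @param min_obs Minimum observations per subject-feature cell (default 3).
#' @return Tibble: `subject_id`, `feature_name`, `duration_label`, `n_obs`,
#'   `median`, `p95`, `cv`.
#' @export
summarize_windows <- function(obs, duration_label = NULL, min_obs = 3) {
  if (is.null(duration_label)) {
    duration_label <- if ("duration_label" %in% names(obs) && nrow(obs) > 0)
      obs$duration_label[1] else NA_character_
  }
  key <- paste(obs$subject_id, obs$feature_name, sep = "\r")
  ord <- order(obs$subject_id, obs$feature_name)
  uk <- unique(key[ord])
  first <- match(uk, key)
  groups <- split(obs$value, factor(key, levels = uk))
  stats <- vapply(groups, function(v) {
    v <- v[!is.na(v)]
    n <- length(v)
    med <- if (n >= min_obs) median.default(v) else NA_real_
    p95 <- if (n >= min_obs)
      unname(quantile(v, 0.95, names = FALSE, type = 7)) else NA_real_
    cv <- if (n >= max(min_obs, 2)) {
      m <- mean(v); s <- sd(v)
      if (abs(m) < 1e-8 * s) NA_real_ else s / abs(m)
    } else NA_real_
    c(n, med, p95, cv)
  }, numeric(4))
  tibble::tibble(
    subject_id = obs$subject_id[first],
    feature_name = obs$feature_name[first],
    duration_label = duration_label,
    n_obs = as.integer(unname(stats[1, ])),
    median = unname(stats[2, ]),
    p95 = unname(stats[3, ]),
    cv = unname(stats[4, ])
  )
}
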