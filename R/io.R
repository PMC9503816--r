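#' Read a bout-level feature observation table
#'
#' Feature tables are UTF-8 CSV with a header row and columns `subject_id`,
#' `bout_start` (ISO-8601, stored as UTC), `feature_name`, `value`,
#' `bout_duration` (seconds). Feature names are checked against
#' [feature_vocabulary()] and bout-duration gates are enforced (sway features
#' need bouts of at least 30 s, entropy-ratio features more than 30 s,
#' Lyapunov features more than 60 s). Missing values are encoded as empty
#' fields, never sentinel numbers.
#'
#' @param path Path to a CSV file.
#' @return A tibble of feature observations with parsed UTC timestamps.
#' @seealso [write_feature_table()], [read_prm_table()]
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path), class = "weartime_io_error")
  }
  required <- c("subject_id", "bout_start", "feature_name", "value",
                "bout_duration")
  header <- names(suppressMessages(
    readr::read_csv(path, n_max = 0, show_col_types = FALSE)
  ))
  missing <- setdiff(required, header)
  if (length(missing) > 0) {
    abort(paste0("Feature table is missing required column(s): ",
                 paste(missing, collapse = ", ")),
          class = "weartime_schema_error")
  }
  obs <- suppressWarnings(suppressMessages(readr::read_csv(
    path,
    col_types = readr::cols(
      subject_id = readr::col_character(),
      bout_start = readr::col_datetime(),
      feature_name = readr::col_character(),
      value = readr::col_double(),
      bout_duration = readr::col_double()
    )
  )))
  prob <- readr::problems(obs)
  if (nrow(prob) > 0) {
    abort(sprintf("Unparseable value in %s at line %d, column '%s': got '%s'",
                  path, prob$row[1] + 1L, header[prob$col[1]],
                  prob$actual[1]),
          class = "weartime_parse_error")
  }
  attr(obs$bout_start, "tzone") <- "UTC"
  validate_feature_observations(obs)
  obs[required]
}

#' Write a feature observation table
#'
#' Timestamps are written as ISO-8601 UTC with millisecond precision so that
#' read/write round-trips are lossless.
#'
#' @param obs Tibble of feature observations (see [read_feature_table()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(obs, path) {
  validate_feature_observations(obs)
  out <- obs
  out$bout_start <- format(obs$bout_start, "%Y-%m-%dT%H:%M:%OS3Z", tz = "UTC")
  readr::write_csv(out, path)
  invisible(path)
}

prm_ranges <- list(
  ABC  = c(0, 100),
  MFIS = c(0, 84),
  MSWS = c(12, 60),
  PDDS = c(0, 8)
)

#' Read a patient-reported measure (PRM) table
#'
#' PRM tables are CSV with columns `subject_id`, `instrument` (one of ABC,
#' MFIS, MSWS, PDDS), `administration_time` (ISO-8601 UTC) and `score`.
#' Scores are range-checked per instrument (ABC 0-100, MFIS 0-84, MSWS 12-60,
#' PDDS 0-8). Duplicate administrations of the same instrument to the same
#' subject at the same time are deduplicated with a warning, keeping the last
#' row in file order.
#'
#' @param path Path to a CSV file.
#' @return A tibble of PRM records.
#' @export
read_prm_table <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path), class = "weartime_io_error")
  }
  required <- c("subject_id", "instrument", "administration_time", "score")
  header <- names(suppressMessages(
    readr::read_csv(path, n_max = 0, show_col_types = FALSE)
  ))
  missing <- setdiff(required, header)
  if (length(missing) > 0) {
    abort(paste0("PRM table is missing required column(s): ",
                 paste(missing, collapse = ", ")),
          class = "weartime_schema_error")
  }
  prm <- suppressWarnings(suppressMessages(readr::read_csv(
    path,
    col_types = readr::cols(
      subject_id = readr::col_character(),
      instrument = readr::col_character(),
      administration_time = readr::col_datetime(),
      score = readr::col_double()
    )
  )))
  prob <- readr::problems(prm)
  if (nrow(prob) > 0) {
    abort(sprintf("Unparseable value in %s at line %d: got '%s'",
                  path, prob$row[1] + 1L, prob$actual[1]),
          class = "weartime_parse_error")
  }
  attr(prm$administration_time, "tzone") <- "UTC"
  validate_prm_records(prm[required])
}

validate_prm_records <- function(prm) {
  bad_inst <- setdiff(unique(prm$instrument), names(prm_ranges))
  if (length(bad_inst) > 0) {
    abort(paste0("Unknown instrument(s): ", paste(bad_inst, collapse = ", ")),
          class = "weartime_vocab_error")
  }
  for (inst in unique(prm$instrument)) {
    rng <- prm_ranges[[inst]]
    sc <- prm$score[prm$instrument == inst]
    out <- !is.na(sc) & (sc < rng[1] | sc > rng[2])
    if (any(out)) {
      abort(sprintf("%s score out of range [%g, %g]: %g", inst, rng[1],
                    rng[2], sc[which(out)[1]]),
            class = "weartime_range_error")
    }
  }
  key <- paste(prm$subject_id, prm$instrument, prm$administration_time)
  if (anyDuplicated(key)) {
    warn(sprintf(
      "%d duplicate (subject, instrument, time) PRM record(s); keeping last",
      sum(duplicated(key))
    ), class = "weartime_dedup_warning")
    prm <- prm[!duplicated(key, fromLast = TRUE), ]
  }
  prm
}

#' Write a PRM table
#'
#' @param prm Tibble of PRM records (see [read_prm_table()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_prm_table <- function(prm, path) {
  out <- prm
  out$administration_time <-
    format(prm$administration_time, "%Y-%m-%dT%H:%M:%OS3Z", tz = "UTC")
  readr::write_csv(out, path)
  invisible(path)
}

#' Biweekly median of daily ABC scores
#'
#' The Activity-Specific Balance Confidence scale is administered daily during
#' wear weeks; its subject-level summary for Stage 3 is the median over a
#' two-week window.
#'
#' @param prm Tibble of PRM records.
#' @param window_days Window length in days (default 14).
#' @param window_start Optional POSIXct start of the window; defaults to each
#'   subject's first ABC administration.
#' @return Tibble with `subject_id` and `abc` (the windowed median). Subjects
#'   with no ABC record in the window are omitted with a message; they are
#'   excluded from Stage 3.
#' @export
abc_biweekly_median <- function(prm, window_days = 14, window_start = NULL) {
  abc <- prm[prm$instrument == "ABC" & !is.na(prm$score), ]
  if (nrow(abc) == 0) {
    inform("No ABC records; all subjects flagged missing for Stage 3")
    return(tibble::tibble(subject_id = character(), abc = double()))
  }
  abc %>%
    dplyr::group_by(.data$subject_id) %>%
    dplyr::group_modify(function(d, key) {
      start <- if (is.null(window_start)) min(d$administration_time)
               else window_start
      keep <- d$administration_time >= start &
        d$administration_time < start + window_days * 86400
      if (!any(keep)) return(tibble::tibble(abc = double()))
      tibble::tibble(abc = median(d$score[keep]))
    }) %>%
    dplyr::ungroup()
}

#' End-of-window MFIS score
#'
#' The Modified Fatigue Impact Scale is sampled at the end of each two-week
#' cycle; the Stage 3 summary is the last administration inside the window.
#'
#' @inheritParams abc_biweekly_median
#' @return Tibble with `subject_id` and `mfis`.
#' @export
mfis_period_score <- function(prm, window_days = 14, window_start = NULL) {
  mfis <- prm[prm$instrument == "MFIS" & !is.na(prm$score), ]
  if (nrow(mfis) == 0) {
    return(tibble::tibble(subject_id = character(), mfis = double()))
  }
  mfis %>%
    dplyr::group_by(.data$subject_id) %>%
    dplyr::group_modify(function(d, key) {
      start <- if (is.null(window_start)) min(d$administration_time) -
        (window_days - 1) * 86400 else window_start
      keep <- d$administration_time >= start &
        d$administration_time <= start + window_days * 86400
      if (!any(keep)) return(tibble::tibble(mfis = double()))
      tibble::tibble(mfis = d$score[keep][which.max(d$administration_time[keep])])
    }) %>%
    dplyr::ungroup()
}

#' Default run configuration
#'
#' Central defaults for the analysis: day boundaries are taken at
#' subject-local midnight via `tz_offset_hours`; windows with fewer than
#' `min_obs` observations yield missing summaries; Stage 1 uses `alpha`;
#' Stage 2 uses `icc_threshold`; Stage 3 stability uses `epsilon_stability`;
#' partial wear days count as monitoring days when they contain at least one
#' observation (`partial_days = "count"`).
#'
#' @return Named list of configuration values.
#' @export
default_config <- function() {
  list(
    tz_offset_hours = 0,
    min_obs = 3,
    alpha = 0.05,
    icc_threshold = 0.7,
    epsilon_stability = 0.10,
    baseline_days = 7,
    stage3_max_days = 14,
    valid_stride_range_s = c(0.4, 2.5),
    partial_days = "count",
    sampen_m = 2,
    sampen_r_frac = 0.2,
    lyap_emb_dim = 5,
    welch_segment_s = 10,
    welch_overlap = 0.5
  )
}

#' Read a run configuration file
#'
#' YAML or JSON; unknown keys are rejected, missing keys fall back to
#' [default_config()].
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return Named list of configuration values.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path), class = "weartime_io_error")
  }
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  defaults <- default_config()
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown) > 0) {
    abort(paste0("Unknown config key(s): ", paste(unknown, collapse = ", ")),
          class = "weartime_schema_error")
  }
  utils::modifyList(defaults, cfg)
}

#' Write raw accelerometer bouts as delimited tables
#'
#' Two CSVs: a long samples table (`subject_id`, `bout_id`, `activity`,
#' `start_time`, `sampling_rate`, `sample_index`, `vertical`, `ap`, `ml`)
#' and, when any bout carries stride events, an events table (`bout_id`,
#' `foot`, `event`, `time`).
#'
#' @param bouts List of `accel_bout` objects.
#' @param samples_path Output CSV for samples.
#' @param events_path Output CSV for stride events (required when any bout
#'   has them).
#' @return `samples_path`, invisibly.
#' @export
write_bout_tables <- function(bouts, samples_path, events_path = NULL) {
  samples <- dplyr::bind_rows(lapply(seq_along(bouts), function(i) {
    b <- bouts[[i]]
    tibble::tibble(
      subject_id = b$subject_id, bout_id = i, activity = b$activity,
      start_time = format(b$start_time, "%Y-%m-%dT%H:%M:%OS3Z", tz = "UTC"),
      sampling_rate = b$sampling_rate,
      sample_index = seq_len(nrow(b$samples)),
      vertical = b$samples[, "vertical"],
      ap = b$samples[, "ap"], ml = b$samples[, "ml"]
    )
  }))
  readr::write_csv(samples, samples_path)
  events <- dplyr::bind_rows(lapply(seq_along(bouts), function(i) {
    ev <- bouts[[i]]$stride_events
    if (is.null(ev)) NULL else dplyr::mutate(ev, bout_id = i, .before = 1)
  }))
  if (nrow(events) > 0) {
    if (is.null(events_path)) {
      abort("bouts carry stride events; supply events_path",
            class = "weartime_io_error")
    }
    readr::write_csv(events, events_path)
  }
  invisible(samples_path)
}

#' Read raw accelerometer bouts from delimited tables
#'
#' @param samples_path Samples CSV from [write_bout_tables()].
#' @param events_path Optional stride-events CSV.
#' @return List of `accel_bout` objects ordered by `bout_id`.
#' @export
read_bout_tables <- function(samples_path, events_path = NULL) {
  samples <- readr::read_csv(samples_path, show_col_types = FALSE)
  required <- c("subject_id", "bout_id", "activity", "start_time",
                "sampling_rate", "sample_index", "vertical", "ap", "ml")
  missing <- setdiff(required, names(samples))
  if (length(missing) > 0) {
    abort(paste0("Bout table is missing required column(s): ",
                 paste(missing, collapse = ", ")),
          class = "weartime_schema_error")
  }
  events <- if (!is.null(events_path) && file.exists(events_path)) {
    readr::read_csv(events_path, show_col_types = FALSE)
  } else NULL
  lapply(split(samples, samples$bout_id), function(d) {
    d <- d[order(d$sample_index), ]
    ev <- if (!is.null(events)) {
      e <- events[events$bout_id == d$bout_id[1], c("foot", "event", "time")]
      if (nrow(e) > 0) e[order(e$time), ] else NULL
    } else NULL
    accel_bout(
      subject_id = d$subject_id[1], activity = d$activity[1],
      start_time = as.POSIXct(d$start_time[1],
                              format = "%Y-%m-%dT%H:%M:%OSZ", tz = "UTC"),
      samples = cbind(vertical = d$vertical, ap = d$ap, ml = d$ml),
      sampling_rate = d$sampling_rate[1],
      stride_events = ev
    )
  })
}
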