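#' Construct a tri-axial accelerometer bout
#'
#' A bout is a contiguous classified activity period (walking or standing)
#' from one sensor. Samples are tri-axial acceleration in g after orientation
#' correction, with axes labelled vertical, anterior-posterior (AP) and
#' medial-lateral (ML). Walking bouts may carry stride-event annotations
#' (foot contact / foot off times in seconds from bout start); standing bouts
#' must not.
#'
#' @param subject_id Subject identifier.
#' @param activity `"walking"` or `"standing"`.
#' @param start_time POSIXct bout start (UTC).
#' @param samples Numeric matrix with columns `vertical`, `ap`, `ml` (g).
#' @param sampling_rate Sampling rate in Hz (default 31.25).
#' @param stride_events Optional tibble with columns `foot` (`"left"`/
#'   `"right"`), `event` (`"foot_contact"`/`"foot_off"`), `time` (s from bout
#'   start), strictly increasing in time.
#' @return An object of class `accel_bout`.
#' @export
accel_bout <- function(subject_id, activity, start_time, samples,
                       sampling_rate = 31.25, stride_events = NULL) {
  activity <- match.arg(activity, c("walking", "standing"))
  samples <- as.matrix(samples)
  if (ncol(samples) != 3) {
    abort("`samples` must have 3 columns (vertical, ap, ml)",
          class = "weartime_bout_error")
  }
  colnames(samples) <- c("vertical", "ap", "ml")
  if (!is.null(stride_events)) {
    if (activity == "standing") {
      abort("standing bouts must not carry stride events",
            class = "weartime_bout_error")
    }
    stride_events <- tibble::as_tibble(stride_events)
    if (is.unsorted(stride_events$time, strictly = FALSE)) {
      abort("stride event times must be non-decreasing",
            class = "weartime_bout_error")
    }
    per_foot <- split(stride_events$time, stride_events$foot)
    if (any(vapply(per_foot, function(t) is.unsorted(t, strictly = TRUE),
                   logical(1)))) {
      abort("stride event times must be strictly increasing within a foot",
            class = "weartime_bout_error")
    }
  }
  structure(
    list(
      subject_id = subject_id,
      activity = activity,
      start_time = start_time,
      sampling_rate = sampling_rate,
      samples = samples,
      stride_events = stride_events
    ),
    class = "accel_bout"
  )
}

#' @export
print.accel_bout <- function(x, ...) {
  cat(sprintf(
    "<accel_bout> %s %s, %.1f s at %.4g Hz (%d samples)%s\n",
    x$subject_id, x$activity, bout_duration(x), x$sampling_rate,
    nrow(x$samples),
    if (!is.null(x$stride_events))
      sprintf(", %d stride events", nrow(x$stride_events)) else ""
  ))
  invisible(x)
}

#' Duration of a bout in seconds
#' @param bout An `accel_bout`.
#' @return Duration in seconds.
#' @export
bout_duration <- function(bout) {
  nrow(bout$samples) / bout$sampling_rate
}

#' Build a stride set from stride-event annotations
#'
#' Pairs successive foot contacts of the same foot into strides and attaches
#' the intervening foot-off, yielding per-stride stance, swing and stride
#' durations. Strides whose duration falls outside `valid_range_s` are
#' flagged invalid and excluded from bout means (free-living event detectors
#' occasionally emit spurious events; the default validity band 0.4-2.5 s
#' brackets physiological stride times).
#'
#' @param stride_events Tibble with columns `foot`, `event`, `time` (s).
#' @param valid_range_s Length-2 numeric; strides with durations outside this
#'   band are marked invalid.
#' @return Tibble with one row per stride: `foot`, `start_contact`,
#'   `foot_off`, `next_contact`, `stride`, `stance`, `swing`, `valid`.
#' @export
stride_set <- function(stride_events,
                       valid_range_s = default_config()$valid_stride_range_s) {
  stride_events <- tibble::as_tibble(stride_events)
  out <- lapply(split(stride_events, stride_events$foot), function(ev) {
    ev <- ev[order(ev$time), ]
    contacts <- ev$time[ev$event == "foot_contact"]
    offs <- ev$time[ev$event == "foot_off"]
    if (length(contacts) < 2) return(NULL)
    rows <- lapply(seq_len(length(contacts) - 1), function(i) {
      c0 <- contacts[i]; c1 <- contacts[i + 1]
      off <- offs[offs > c0 & offs < c1]
      if (length(off) != 1) return(NULL)
      tibble::tibble(foot = ev$foot[1], start_contact = c0, foot_off = off,
                     next_contact = c1)
    })
    dplyr::bind_rows(rows)
  })
  strides <- dplyr::bind_rows(out)
  if (nrow(strides) == 0) {
    return(tibble::tibble(
      foot = character(), start_contact = double(), foot_off = double(),
      next_contact = double(), stride = double(), stance = double(),
      swing = double(), valid = logical()
    ))
  }
  strides <- strides[order(strides$start_contact), ]
  strides$stride <- strides$next_contact - strides$start_contact
  strides$stance <- strides$foot_off - strides$start_contact
  strides$swing <- strides$next_contact - strides$foot_off
  strides$valid <- strides$stride >= valid_range_s[1] &
    strides$stride <= valid_range_s[2]
  strides
}
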