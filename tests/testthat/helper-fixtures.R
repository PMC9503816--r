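# Programmatic fixtures shared across test files.

# Feature-observation rows placed at noon of the given monitoring day.
make_obs <- function(subject, day, value, feature = "stride_duration",
                     start_date = as.Date("2021-06-07"), bout_duration = 20) {
  tibble::tibble(
    subject_id = subject,
    bout_start = as.POSIXct(start_date, tz = "UTC") +
      (day - 1) * 86400 + 12 * 3600,
    feature_name = feature,
    value = value,
    bout_duration = bout_duration
  )
}

# Summary-triplet tibble from a vector of per-subject medians.
make_summaries <- function(med, feature = "stride_duration", label = "w",
                           p95 = med, cv = abs(med) * 0.1 + 0.01,
                           subjects = sprintf("S%02d", seq_along(med))) {
  tibble::tibble(
    subject_id = subjects, feature_name = feature, duration_label = label,
    n_obs = 10L, median = med, p95 = p95, cv = cv
  )
}

# Standing bout with prescribed sample matrix shortcuts.
make_standing_bout <- function(samples, fs = 31.25, subject = "S01") {
  accel_bout(subject, "standing",
             as.POSIXct("2021-06-07 09:00:00", tz = "UTC"), samples, fs)
}

# A planar low-pass Gaussian process, the kind of signal the sway metrics
# see after projection.
make_planar_noise <- function(n, fs = 31.25, amp = 0.01, k = 8) {
  smooth <- function() {
    x <- rnorm(n + 2 * k)
    as.numeric(stats::filter(x, rep(1 / k, k), sides = 2))[(k + 1):(k + n)] *
      sqrt(k) * amp
  }
  planar <- cbind(ap = smooth(), ml = smooth())
  planar <- sweep(planar, 2, colMeans(planar))
  attr(planar, "sampling_rate") <- fs
  planar
}

# Alternating left/right stride events: strict stride period and stance
# fraction, starting with a right contact at t = 0.
make_stride_events <- function(n_strides = 10, stride = 1.0, stance = 0.6) {
  ev <- list()
  for (foot in c("right", "left")) {
    off0 <- if (foot == "right") 0 else stride / 2
    contacts <- off0 + stride * (0:n_strides)
    ev[[foot]] <- rbind(
      data.frame(foot = foot, event = "foot_contact", time = contacts),
      data.frame(foot = foot, event = "foot_off",
                 time = contacts + stance * stride)
    )
  }
  ev <- dplyr::bind_rows(ev)
  tibble::as_tibble(ev[order(ev$time), ])
}
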