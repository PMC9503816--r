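# Postural sway: horizontal-plane projection, the 13 stabilogram metrics,
# and the percentile-threshold bout filter.

#' Project a standing bout onto the horizontal plane
#'
#' Estimates the gravity direction from the bout-mean acceleration vector,
#' rotates the samples by the minimal rotation aligning that direction with
#' the vertical axis (so static tilt is absorbed into the gravity estimate),
#' and returns the mean-removed AP/ML components.
#'
#' @param bout A standing `accel_bout` of at least `min_duration_s` seconds.
#' @param min_duration_s Minimum bout duration (default 30 s, the gate under
#'   which sway metrics are not computed).
#' @return Numeric matrix with columns `ap` and `ml` (g), mean-removed, with
#'   attribute `sampling_rate`.
#' @details Bouts whose mean acceleration magnitude falls outside
#'   \[0.5, 1.5\] g are rejected with an error of class
#'   `weartime_bout_rejected`: such bouts are not quiet standing (sensor off
#'   body, or sustained motion).
#' @export
horizontal_projection <- function(bout, min_duration_s = 30) {
  if (bout$activity != "standing") {
    abort("horizontal_projection expects a standing bout",
          class = "weartime_bout_error")
  }
  if (bout_duration(bout) < min_duration_s) {
    abort(sprintf("standing bout shorter than %g s", min_duration_s),
          class = "weartime_gate_error")
  }
  g <- colMeans(bout$samples)
  gmag <- sqrt(sum(g^2))
  if (gmag < 0.5 || gmag > 1.5) {
    abort(sprintf(
      "mean acceleration magnitude %.3f g outside [0.5, 1.5]; not quiet standing",
      gmag
    ), class = "weartime_bout_rejected")
  }
  # rotate so the gravity estimate becomes the vertical axis
  # axes ordered (vertical, ap, ml) -> use (x, y, z) = (ap, ml, vertical)
  xyz <- bout$samples[, c("ap", "ml", "vertical"), drop = FALSE]
  u <- g[c("ap", "ml", "vertical")] / gmag
  R <- rotation_to_ez(u)
  rotated <- xyz %*% t(R)
  planar <- rotated[, 1:2, drop = FALSE]
  planar <- sweep(planar, 2, colMeans(planar))
  colnames(planar) <- c("ap", "ml")
  attr(planar, "sampling_rate") <- bout$sampling_rate
  planar
}

# Minimal (Rodrigues) rotation taking unit vector u to e_z = (0, 0, 1).
rotation_to_ez <- function(u) {
  ez <- c(0, 0, 1)
  v <- c(u[2] * ez[3] - u[3] * ez[2],
         u[3] * ez[1] - u[1] * ez[3],
         u[1] * ez[2] - u[2] * ez[1])  # u x ez
  s <- sqrt(sum(v^2))
  c_ <- sum(u * ez)
  if (s < 1e-12) {
    if (c_ > 0) return(diag(3))
    # antiparallel: rotate pi about the x axis
    return(diag(c(1, -1, -1)))
  }
  vx <- matrix(c(0, -v[3], v[2],
                 v[3], 0, -v[1],
                 -v[2], v[1], 0), 3, 3, byrow = TRUE)
  diag(3) + vx + vx %*% vx * ((1 - c_) / s^2)
}

#' Compute the 13 postural-sway metrics for one standing bout
#'
#' Time-domain metrics are computed from the mean-removed planar (AP, ML)
#' acceleration: `distance` (mean planar magnitude), `rms`, `range` (maximum
#' resultant excursion), `path_per_s` (summed successive-sample planar
#' displacement divided by bout duration), `jerk` (mean magnitude of the
#' first difference times the sampling rate), `mean_velocity` (mean of the
#' per-axis mean absolute derivatives), and `sway_area_per_s` (the swept
#' area: total area enclosed between successive planar position vectors,
#' divided by bout duration, so that stationary signals of different
#' lengths score alike).
#' Frequency-domain metrics come from the summed per-axis Welch power
#' spectrum via [spectral_summary()]: `power`, `f50`, `f95`,
#' `centroidal_frequency`, `frequency_dispersion`; `mean_period` is the
#' reciprocal of the centroidal frequency.
#'
#' @param planar Matrix with columns `ap`, `ml` from
#'   [horizontal_projection()], or any mean-removed two-column planar signal.
#' @param sampling_rate Hz; taken from the `sampling_rate` attribute of
#'   `planar` when missing.
#' @param bout_duration Bout duration in seconds; defaults to
#'   `nrow(planar) / sampling_rate`.
#' @return Named list of the 13 sway metrics.
#' @export
compute_sway_metrics <- function(planar, sampling_rate = NULL,
                                 bout_duration = NULL) {
  if (is.null(sampling_rate)) sampling_rate <- attr(planar, "sampling_rate")
  if (is.null(sampling_rate)) {
    abort("sampling_rate missing", class = "weartime_signal_error")
  }
  n <- nrow(planar)
  if (is.null(n) || n < 2) {
    abort("compute_sway_metrics needs at least 2 samples",
          class = "weartime_signal_error")
  }
  if (is.null(bout_duration)) bout_duration <- n / sampling_rate
  ap <- planar[, 1]; ml <- planar[, 2]
  mag <- sqrt(ap^2 + ml^2)
  dap <- diff(ap); dml <- diff(ml)
  step <- sqrt(dap^2 + dml^2)

  # swept area: triangles between successive planar vectors from the centroid
  area <- 0.5 * sum(abs(ap[-n] * ml[-1] - ap[-1] * ml[-n]))

  pa <- welch_psd(ap, sampling_rate)
  pm <- welch_psd(ml, sampling_rate)
  spec <- spectral_summary(pa$freq, pa$psd + pm$psd)

  list(
    sway_area_per_s = area / bout_duration,
    centroidal_frequency = spec$centroidal_frequency,
    distance = mean(mag),
    f50 = spec$f50,
    f95 = spec$f95,
    frequency_dispersion = spec$frequency_dispersion,
    jerk = mean(step) * sampling_rate,
    mean_period = if (is.na(spec$centroidal_frequency) ||
                      spec$centroidal_frequency <= 0) NA_real_
                  else 1 / spec$centroidal_frequency,
    mean_velocity = 0.5 * (mean(abs(dap)) + mean(abs(dml))) * sampling_rate,
    path_per_s = sum(step) / bout_duration,
    power = spec$power,
    range = max(mag),
    rms = sqrt(mean(ap^2 + ml^2))
  )
}

#' Sway distance of a standing bout
#'
#' Mean horizontal-plane acceleration deviation; the statistic used by the
#' percentile-based bout filter.
#'
#' @param bout A standing `accel_bout`, or a planar matrix from
#'   [horizontal_projection()].
#' @return Sway distance in g.
#' @export
sway_distance <- function(bout) {
  planar <- if (inherits(bout, "accel_bout")) horizontal_projection(bout)
            else bout
  mean(sqrt(planar[, 1]^2 + planar[, 2]^2))
}

#' Estimate sway-distance filtering thresholds
#'
#' Draws a random sample of standing bouts (10,000 by default; with
#' replacement when fewer are available, without when more) and sets the
#' filter thresholds at the 1.5th and 98.5th percentiles of their sway
#' distances (linear-interpolation quantiles). Bouts below the low threshold
#' are "completely still" (e.g., the wearer was leaning on a support); bouts
#' above the high threshold are erratic.
#'
#' @param bouts List of standing `accel_bout` objects, or a numeric vector of
#'   precomputed sway distances.
#' @param n_sample Number of bouts to sample (default 10000).
#' @param seed Optional integer seed for reproducible sampling.
#' @return Object of class `sway_thresholds`: list with `low`, `high` (g) and
#'   `n_sampled`.
#' @export
estimate_sway_thresholds <- function(bouts, n_sample = 10000, seed = NULL) {
  distances <- if (is.numeric(bouts)) bouts
               else vapply(bouts, sway_distance, numeric(1))
  if (length(distances) == 0) {
    abort("no bouts supplied", class = "weartime_input_error")
  }
  draw <- function() {
    sample(distances, n_sample, replace = length(distances) < n_sample)
  }
  sampled <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  q <- quantile(sampled, c(0.015, 0.985), names = FALSE, type = 7)
  structure(list(low = q[1], high = q[2], n_sampled = n_sample),
            class = "sway_thresholds")
}

#' @export
print.sway_thresholds <- function(x, ...) {
  cat(sprintf("<sway_thresholds> low %.4g g, high %.4g g (n = %d sampled)\n",
              x$low, x$high, x$n_sampled))
  invisible(x)
}

#' Filter standing bouts by sway distance
#'
#' Removes bouts whose sway distance is strictly below the low threshold
#' (reason `too_still`) or strictly above the high threshold (`too_erratic`).
#' Boundary values are retained: the percentile endpoints are data points.
#'
#' @param bouts List of standing `accel_bout` objects, or a numeric vector of
#'   precomputed sway distances.
#' @param thresholds A `sway_thresholds` object.
#' @return List with `retained` (the surviving bouts, or indices when
#'   `bouts` is a distance vector), `rejections` (tibble: `index`,
#'   `distance`, `reason`) and `distances` (all input distances).
#' @export
filter_sway_bouts <- function(bouts, thresholds) {
  stopifnot(inherits(thresholds, "sway_thresholds"))
  distances <- if (is.numeric(bouts)) bouts
               else vapply(bouts, sway_distance, numeric(1))
  too_still <- distances < thresholds$low
  too_erratic <- distances > thresholds$high
  keep <- !(too_still | too_erratic)
  rejections <- tibble::tibble(
    index = which(!keep),
    distance = distances[!keep],
    reason = ifelse(too_still[!keep], "too_still", "too_erratic")
  )
  retained <- if (is.numeric(bouts)) which(keep) else bouts[keep]
  list(retained = retained, rejections = rejections, distances = distances)
}

#' Sway feature observations for a set of standing bouts
#'
#' Applies the sway-distance filter then computes the 13 sway metrics for
#' each retained bout, emitting tidy feature-observation rows.
#'
#' @param bouts List of standing `accel_bout` objects.
#' @param thresholds Optional `sway_thresholds`; when supplied, bouts outside
#'   the thresholds are dropped and logged.
#' @return List with `observations` (feature-observation tibble) and
#'   `rejections` (from the filter, plus bouts rejected by
#'   [horizontal_projection()]).
#' @export
sway_feature_observations <- function(bouts, thresholds = NULL) {
  rows <- list()
  rejections <- list()
  for (i in seq_along(bouts)) {
    bout <- bouts[[i]]
    planar <- tryCatch(horizontal_projection(bout), error = function(e) e)
    if (inherits(planar, "error")) {
      rejections[[length(rejections) + 1]] <- tibble::tibble(
        index = i, distance = NA_real_, reason = "not_quiet_standing")
      next
    }
    d <- sway_distance(planar)
    if (!is.null(thresholds) &&
        (d < thresholds$low || d > thresholds$high)) {
      rejections[[length(rejections) + 1]] <- tibble::tibble(
        index = i, distance = d,
        reason = if (d < thresholds$low) "too_still" else "too_erratic")
      next
    }
    m <- compute_sway_metrics(planar, bout$sampling_rate, bout_duration(bout))
    rows[[length(rows) + 1]] <- tibble::tibble(
      subject_id = bout$subject_id,
      bout_start = bout$start_time,
      feature_name = names(m),
      value = unlist(m, use.names = FALSE),
      bout_duration = bout_duration(bout)
    )
  }
  list(
    observations = dplyr::bind_rows(rows),
    rejections = dplyr::bind_rows(rejections)
  )
}
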