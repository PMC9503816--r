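# Gait features: temporal stride parameters, L1-norm asymmetry indices,
# trunk/thigh stability measures, sample-entropy ratio and largest Lyapunov
# exponents. Stride-event detection is upstream of this module: events arrive
# as annotations, either from a detector or from the synthetic generator.

#' Temporal gait parameters of one walking bout
#'
#' Computes the five temporal measures per stride and averages across the
#' bout: stride, stance and swing duration, duty factor (per-stride
#' stance/stride ratio), and double-support duration (time within each stride
#' during which both feet are in stance, from the intersection of the two
#' feet's stance intervals). Invalid strides are excluded; bouts with fewer
#' than two valid strides are skipped.
#'
#' @param strides A stride tibble from [stride_set()].
#' @param per_foot If `TRUE`, also return per-foot means.
#' @return Named list of pooled bout means (and `left`/`right` sublists when
#'   `per_foot = TRUE`), or `NULL` (with a message) when fewer than two valid
#'   strides are available.
#' @export
temporal_params <- function(strides, per_foot = FALSE) {
  valid <- strides[strides$valid, , drop = FALSE]
  if (nrow(valid) < 2) {
    inform("bout skipped: fewer than 2 valid strides")
    return(NULL)
  }
  # double support: intersect the union of left-stance intervals with the
  # union of right-stance intervals, then allocate overlap to each stride
  stance_iv <- split(valid[, c("start_contact", "foot_off")], valid$foot)
  ds_intervals <- NULL
  if (length(stance_iv) == 2) {
    a <- as.matrix(stance_iv[[1]]); b <- as.matrix(stance_iv[[2]])
    pieces <- list()
    for (i in seq_len(nrow(a))) {
      lo <- pmax(a[i, 1], b[, 1]); hi <- pmin(a[i, 2], b[, 2])
      ok <- hi > lo
      if (any(ok)) pieces[[length(pieces) + 1]] <- cbind(lo[ok], hi[ok])
    }
    if (length(pieces) > 0) ds_intervals <- do.call(rbind, pieces)
  }
  ds_in_window <- function(w0, w1) {
    if (is.null(ds_intervals)) return(0)
    lo <- pmax(ds_intervals[, 1], w0); hi <- pmin(ds_intervals[, 2], w1)
    sum(pmax(hi - lo, 0))
  }
  valid$double_support <- mapply(ds_in_window, valid$start_contact,
                                 valid$next_contact)
  summarise_strides <- function(v) {
    list(
      stride_duration = mean(v$stride),
      stance_duration = mean(v$stance),
      swing_duration = mean(v$swing),
      duty_factor = mean(v$stance / v$stride),
      double_support_duration = mean(v$double_support)
    )
  }
  out <- summarise_strides(valid)
  if (per_foot) {
    for (f in unique(valid$foot)) {
      out[[f]] <- summarise_strides(valid[valid$foot == f, , drop = FALSE])
    }
  }
  out
}

#' L1-norm asymmetry index
#'
#' `|right - left| / (0.5 * (|right| + |left|))`, bounded in \[0, 2\]:
#' 0 at perfect symmetry, 2 when one side is zero. Scale-invariant and
#' symmetric in its arguments. Undefined (returns `NA`) when both sides are
#' zero.
#'
#' @param right,left Scalar (or vectorised) values for each side.
#' @return Asymmetry index in \[0, 2\], `NA` where both inputs are zero.
#' @examples
#' l1_asymmetry(0.6, 0.5)   # 0.1818...
#' l1_asymmetry(2, 0)       # 2
#' @export
l1_asymmetry <- function(right, left) {
  denom <- 0.5 * (abs(right) + abs(left))
  out <- abs(right - left) / denom
  out[denom == 0] <- NA_real_
  out
}

#' Correlation asymmetry between right and left thigh acceleration
#'
#' `0.5 * (1 - corr(right, left))`: 0 for perfectly correlated signals,
#' 1 for sign-flipped signals, 0.5 for uncorrelated signals. Invariant under
#' positive affine transforms of either input. Note the printed transform
#' maps a correlation of zero to 0.5 (and -1 to 1), even though it is
#' sometimes described as mapping zero correlation to one; the formula is
#' authoritative here.
#'
#' @param right,left Equal-length numeric sequences (length >= 2) with
#'   nonzero variance.
#' @return Value in \[0, 1\], or `NA` for degenerate input.
#' @export
correlation_asymmetry <- function(right, left) {
  if (length(right) != length(left) || length(right) < 2) {
    abort("inputs must be equal-length sequences of length >= 2",
          class = "weartime_input_error")
  }
  if (sd(right) == 0 || sd(left) == 0) return(NA_real_)
  0.5 * (1 - cor(right, left))
}

#' Acceleration asymmetry of ensemble-averaged stride curves
#'
#' Each stride's acceleration trace is time-normalized to 101 samples
#' (0-100% of the gait cycle) and ensemble-averaged per leg; the result is
#' the mean over the cycle of the pointwise L1-norm asymmetry between the
#' two mean curves, excluding points where both curves are negligibly small.
#'
#' @param right_strides,left_strides Lists of numeric vectors, one per
#'   stride (each of length >= 2); at least two strides per leg.
#' @param eps Points where both mean curves are below `eps` in magnitude are
#'   excluded from the average.
#' @return Dimensionless asymmetry (>= 0), or `NA` when a leg has fewer than
#'   two strides.
#' @export
acceleration_asymmetry <- function(right_strides, left_strides, eps = 1e-8) {
  if (length(right_strides) < 2 || length(left_strides) < 2) return(NA_real_)
  normalize <- function(x) {
    approx(seq(0, 1, length.out = length(x)), x,
           xout = seq(0, 1, length.out = 101))$y
  }
  rbar <- rowMeans(vapply(right_strides, normalize, numeric(101)))
  lbar <- rowMeans(vapply(left_strides, normalize, numeric(101)))
  keep <- !(abs(rbar) < eps & abs(lbar) < eps)
  if (!any(keep)) return(NA_real_)
  mean(l1_asymmetry(rbar[keep], lbar[keep]))
}

#' RMS of the anterior-posterior acceleration
#'
#' Root mean square of the mean-removed AP channel of a walking bout; a
#' trunk-mounted sensor is conventional but any AP channel is accepted.
#'
#' @param ap Numeric AP acceleration (g), or an `accel_bout` whose `ap`
#'   column is used.
#' @return RMS in g.
#' @export
rms_ap <- function(ap) {
  if (inherits(ap, "accel_bout")) ap <- ap$samples[, "ap"]
  sqrt(mean((ap - mean(ap))^2))
}

#' Frequency dispersion of the medial-lateral acceleration
#'
#' Spectral-moment dispersion of the mean-removed ML channel using the same
#' Welch machinery as the sway metrics; near 0 for a line spectrum.
#'
#' @param ml Numeric ML acceleration (g), or an `accel_bout`.
#' @param sampling_rate Hz (taken from the bout when one is supplied).
#' @return Dispersion in \[0, 1\].
#' @export
frequency_dispersion_ml <- function(ml, sampling_rate = NULL) {
  if (inherits(ml, "accel_bout")) {
    sampling_rate <- ml$sampling_rate
    ml <- ml$samples[, "ml"]
  }
  if (is.null(sampling_rate)) {
    abort("sampling_rate missing", class = "weartime_signal_error")
  }
  p <- welch_psd(ml - mean(ml), sampling_rate)
  spectral_summary(p$freq, p$psd)$frequency_dispersion
}

#' Sample entropy of a signal
#'
#' Richman-Moorman sample entropy with embedding dimension `m` and tolerance
#' `r` (defaults `m = 2`, `r = 0.2` times the signal SD, the community
#' convention for accelerometer signals). Delegates to
#' [pracma::sample_entropy()], which uses the standard template count.
#'
#' @param x Numeric signal.
#' @param m Embedding dimension.
#' @param r Tolerance; defaults to `r_frac * sd(x)`.
#' @param r_frac Fraction of the signal SD used when `r` is missing.
#' @return Sample entropy (nats), `NA` for degenerate (zero-SD) signals.
#' @export
sample_entropy <- function(x, m = 2, r = NULL, r_frac = 0.2) {
  s <- sd(x)
  if (is.na(s) || s == 0) return(NA_real_)
  if (is.null(r)) r <- r_frac * s
  pracma::sample_entropy(x, edim = m, r = r, tau = 1)
}

#' Entropy ratio between trunk and thigh acceleration
#'
#' Ratio of the sample entropy of the trunk resultant to that of the thigh
#' resultant. Regular (more predictable) thigh motion against irregular
#' trunk motion raises the ratio. Only defined for walking bouts longer than
#' 30 s; gate enforcement lives in the bout-level driver.
#'
#' @param trunk,thigh Numeric sequences (resultant acceleration magnitude).
#' @param m,r_frac Sample-entropy parameters (see [sample_entropy()]).
#' @return Dimensionless ratio, `NA` when either signal is degenerate.
#' @export
entropy_ratio <- function(trunk, thigh, m = 2, r_frac = 0.2) {
  se_trunk <- sample_entropy(trunk, m = m, r_frac = r_frac)
  se_thigh <- sample_entropy(thigh, m = m, r_frac = r_frac)
  if (is.na(se_trunk) || is.na(se_thigh) || se_thigh == 0) return(NA_real_)
  se_trunk / se_thigh
}

#' Largest Lyapunov exponent by the Rosenstein divergence method
#'
#' Delay-embeds the signal (embedding dimension 5 by default; delay at the
#' first local minimum of the autocorrelation), finds each point's nearest
#' neighbour outside a Theiler exclusion window, tracks the mean log
#' divergence of neighbour pairs over time, and fits a least-squares slope
#' over the initial divergence window. Only meaningful for walking bouts
#' longer than 60 s; the gate is enforced by the bout-level driver.
#'
#' @param x Numeric signal (one axis of acceleration).
#' @param fs Sampling rate (Hz).
#' @param emb_dim Embedding dimension (default 5).
#' @param delay Embedding delay in samples; default is the first local
#'   minimum of the autocorrelation function.
#' @param fit_window_s Divergence-fit window in seconds (default 0.5,
#'   half a typical stride).
#' @param theiler_s Theiler exclusion window in seconds (default the delay
#'   times the embedding dimension, converted to seconds).
#' @param min_pairs Minimum usable neighbour pairs; fewer returns `NA` with
#'   a message.
#' @return Largest Lyapunov exponent in 1/s, or `NA`.
#' @export
lyapunov_exponent <- function(x, fs, emb_dim = 5, delay = NULL,
                              fit_window_s = 0.5, theiler_s = NULL,
                              min_pairs = 10) {
  n <- length(x)
  if (sd(x) == 0) return(NA_real_)
  if (is.null(delay)) delay <- first_acf_minimum(x)
  if (is.null(theiler_s)) theiler_s <- delay * emb_dim / fs
  theiler <- max(1L, round(theiler_s * fs))
  m <- emb_dim
  N <- n - (m - 1) * delay
  if (N < 4 * theiler || N < 20) {
    inform("lyapunov_exponent: signal too short for embedding")
    return(NA_real_)
  }
  emb <- vapply(seq_len(m), function(k) x[((k - 1) * delay + 1):
                                          ((k - 1) * delay + N)],
                numeric(N))
  kmax <- max(2L, round(fit_window_s * fs))
  horizon <- N - kmax
  if (horizon < min_pairs) {
    inform("lyapunov_exponent: insufficient neighbour pairs")
    return(NA_real_)
  }
  # nearest neighbour outside the Theiler window, among points that can be
  # followed for kmax steps
  nn <- integer(horizon)
  d2 <- function(i, j) {
    di <- emb[i, , drop = FALSE][rep(1, length(j)), , drop = FALSE] -
      emb[j, , drop = FALSE]
    rowSums(di * di)
  }
  cand_all <- seq_len(horizon)
  for (i in seq_len(horizon)) {
    cand <- cand_all[abs(cand_all - i) > theiler]
    if (length(cand) == 0) { nn[i] <- NA_integer_; next }
    dd <- d2(i, cand)
    nn[i] <- cand[which.min(dd)]
  }
  ok <- which(!is.na(nn))
  if (length(ok) < min_pairs) {
    inform("lyapunov_exponent: insufficient neighbour pairs")
    return(NA_real_)
  }
  # mean log divergence over k steps
  mean_log_div <- numeric(kmax + 1)
  for (k in 0:kmax) {
    i <- ok + k; j <- nn[ok] + k
    d <- sqrt(rowSums((emb[i, , drop = FALSE] - emb[j, , drop = FALSE])^2))
    pos <- d > 0
    if (!any(pos)) { mean_log_div[k + 1] <- NA; next }
    mean_log_div[k + 1] <- mean(log(d[pos]))
  }
  t_axis <- (0:kmax) / fs
  use <- !is.na(mean_log_div)
  if (sum(use) < 3) return(NA_real_)
  unname(coef(lm(mean_log_div[use] ~ t_axis[use]))[2])
}

# Embedding delay heuristic, in samples: the first local minimum of the
# autocorrelation function, capped at the 1/e decorrelation lag. On
# broadband signals the first ACF minimum can sit several oscillation
# periods out, which would stretch the embedding window far beyond the
# dynamics' coherence time; the 1/e cap keeps the delay near the standard
# decorrelation scale.
first_acf_minimum <- function(x, max_lag = min(length(x) - 1, 200)) {
  a <- as.numeric(acf(x, lag.max = max_lag, plot = FALSE)$acf)
  first_min <- NA_integer_
  for (k in 2:(length(a) - 1)) {
    if (a[k] < a[k - 1] && a[k] <= a[k + 1]) { first_min <- k - 1L; break }
  }
  if (is.na(first_min)) first_min <- max(1L, which.min(a) - 1L)
  efold <- which(a < exp(-1))
  if (length(efold) > 0) min(first_min, efold[1] - 1L) else first_min
}

#' All gait feature observations for one walking bout
#'
#' Bout-level driver combining the right and left thigh bouts (and an
#' optional trunk bout) with stride-event annotations into tidy
#' feature-observation rows. The 10 summary gait features require at least
#' two valid strides; the entropy-ratio features additionally require a bout
#' longer than 30 s with a trunk signal, and the Lyapunov features a bout
#' longer than 60 s.
#'
#' @param right,left Thigh `accel_bout`s for each leg (walking). `right`
#'   must carry the stride events for both feet, or pass `stride_events`.
#' @param trunk Optional chest/trunk `accel_bout` (same time base).
#' @param stride_events Stride events tibble; defaults to
#'   `right$stride_events`.
#' @param config Configuration list (see [default_config()]).
#' @return Feature-observation tibble (possibly zero rows when the bout is
#'   skipped).
#' @export
compute_gait_features <- function(right, left, trunk = NULL,
                                  stride_events = NULL,
                                  config = default_config()) {
  if (is.null(stride_events)) stride_events <- right$stride_events
  if (is.null(stride_events)) {
    abort("no stride events supplied", class = "weartime_input_error")
  }
  dur <- bout_duration(right)
  fs <- right$sampling_rate
  strides <- stride_set(stride_events, config$valid_stride_range_s)
  tp <- temporal_params(strides, per_foot = TRUE)
  if (is.null(tp)) return(empty_feature_table())

  res <- list(
    stride_duration = tp$stride_duration,
    stance_duration = tp$stance_duration,
    swing_duration = tp$swing_duration,
    duty_factor = tp$duty_factor,
    double_support_duration = tp$double_support_duration
  )
  res$duty_factor_asymmetry <-
    if (!is.null(tp$right) && !is.null(tp$left))
      l1_asymmetry(tp$right$duty_factor, tp$left$duty_factor) else NA_real_

  r_res <- resultant(right); l_res <- resultant(left)
  nshared <- min(length(r_res), length(l_res))
  res$correlation_asymmetry <-
    correlation_asymmetry(r_res[seq_len(nshared)], l_res[seq_len(nshared)])

  seg <- function(sig, foot) {
    v <- strides[strides$valid & strides$foot == foot, , drop = FALSE]
    lapply(seq_len(nrow(v)), function(i) {
      i0 <- max(1, round(v$start_contact[i] * fs) + 1)
      i1 <- min(length(sig), round(v$next_contact[i] * fs))
      if (i1 - i0 < 2) NULL else sig[i0:i1]
    })
  }
  rs <- Filter(Negate(is.null), seg(r_res, "right"))
  ls <- Filter(Negate(is.null), seg(l_res, "left"))
  res$acceleration_asymmetry <- acceleration_asymmetry(rs, ls)

  stab_bout <- if (!is.null(trunk)) trunk else right
  res$rms_ap <- rms_ap(stab_bout)
  res$frequency_dispersion_ml <- frequency_dispersion_ml(stab_bout)

  if (dur > 30 && !is.null(trunk)) {
    t_res <- resultant(trunk)
    res$entropy_ratio <- entropy_ratio(t_res, r_res, m = config$sampen_m,
                                       r_frac = config$sampen_r_frac)
    er_left <- entropy_ratio(t_res, l_res, m = config$sampen_m,
                             r_frac = config$sampen_r_frac)
    res$entropy_ratio_asymmetry <-
      if (is.na(res$entropy_ratio) || is.na(er_left)) NA_real_
      else l1_asymmetry(res$entropy_ratio, er_left)
  }
  if (dur > 60) {
    res$lyapunov_ap <- lyapunov_exponent(stab_bout$samples[, "ap"], fs,
                                         emb_dim = config$lyap_emb_dim)
    res$lyapunov_ml <- lyapunov_exponent(stab_bout$samples[, "ml"], fs,
                                         emb_dim = config$lyap_emb_dim)
  }
  res <- res[!vapply(res, is.na, logical(1))]
  if (length(res) == 0) return(empty_feature_table())
  tibble::tibble(
    subject_id = right$subject_id,
    bout_start = right$start_time,
    feature_name = names(res),
    value = unlist(res, use.names = FALSE),
    bout_duration = dur
  )
}

resultant <- function(bout) {
  sqrt(rowSums(bout$samples^2))
}

empty_feature_table <- function() {
  tibble::tibble(
    subject_id = character(), bout_start = as.POSIXct(character(), tz = "UTC"),
    feature_name = character(), value = double(), bout_duration = double()
  )
}
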