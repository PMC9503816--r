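# Synthetic free-living cohort generator. Emulates a 22-subject, 6-week
# wearable monitoring study: per-feature bout observations with
# between-subject / between-day / within-day variance components, Poisson
# daily bout counts, cohort attrition, and daily ABC / biweekly MFIS
# patient-reported scores linked to a latent impairment trait. Ships with
# closed-form expected-reliability curves used as oracles throughout the
# test suite.

#' Default per-feature generator parameters
#'
#' One row per vocabulary feature. `mu` is the grand mean in feature units;
#' `sigma_subject`, `sigma_day` and `sigma_within` are the between-subject,
#' between-day and within-day SDs; `rate` is the mean daily bout count
#' (bouts/day); `cv_heterogeneity` is the SD of the per-subject log
#' multiplier applied to the within-subject SDs (log-normal dispersion
#' heterogeneity, giving the CV a true between-subject signal);
#' `dur_min`/`dur_max` bound the simulated bout durations so that gated
#' features clear their gates.
#'
#' Components are calibrated so the closed-form reliability curves reproduce
#' the study conditions the framework targets: gait features reliable from
#' about one day of wear (relative noise small, 60 bouts/day), sway features
#' from two to three days (wider distributions, 12 qualifying standing
#' bouts/day), entropy-ratio features gated to about 5 long walking bouts a
#' day, and Lyapunov features slowest of all with about 2 one-minute bouts a
#' day and high within-day variability.
#'
#' @return Tibble of generator parameters, one row per feature.
#' @export
default_feature_params <- function() {
  vocab <- feature_vocabulary()
  mu <- c(
    stride_duration = 1.10, stance_duration = 0.66, swing_duration = 0.44,
    duty_factor = 0.60, double_support_duration = 0.22,
    duty_factor_asymmetry = 0.08, correlation_asymmetry = 0.25,
    acceleration_asymmetry = 0.35, rms_ap = 0.18,
    frequency_dispersion_ml = 0.55,
    entropy_ratio = 1.30, entropy_ratio_asymmetry = 0.25,
    lyapunov_ap = 0.60, lyapunov_ml = 0.50,
    sway_area_per_s = 0.0025, centroidal_frequency = 0.90, distance = 0.012,
    f50 = 0.70, f95 = 2.80, frequency_dispersion = 0.25, jerk = 0.40,
    mean_period = 1.10, mean_velocity = 0.030, path_per_s = 0.030,
    power = 2e-4, range = 0.050, rms = 0.015
  )
  rel <- list(  # relative (subject, day, within) SDs and rate per domain
    gait = list(sd = c(0.10, 0.02, 0.06), rate = 60,
                dur = c(10, 60)),
    gait_gated_entropy = list(sd = c(0.10, 0.05, 0.15), rate = 5,
                              dur = c(35, 90)),
    gait_gated_lyap = list(sd = c(0.06, 0.05, 0.35), rate = 2,
                           dur = c(65, 180)),
    sway = list(sd = c(0.10, 0.07, 0.18), rate = 12,
                dur = c(30, 120))
  )
  pick <- function(f, d) {
    if (d == "gait_gated") {
      if (grepl("^lyapunov", f)) rel$gait_gated_lyap else rel$gait_gated_entropy
    } else rel[[d]]
  }
  rows <- lapply(seq_len(nrow(vocab)), function(i) {
    f <- vocab$feature_name[i]; d <- vocab$domain[i]
    p <- pick(f, d)
    mu_f <- unname(mu[[f]])
    tibble::tibble(
      feature_name = f, domain = d, mu = mu_f,
      sigma_subject = mu_f * p$sd[1],
      sigma_day = mu_f * p$sd[2],
      sigma_within = mu_f * p$sd[3],
      rate = p$rate, cv_heterogeneity = 0.4,
      dur_min = p$dur[1], dur_max = p$dur[2]
    )
  })
  dplyr::bind_rows(rows)
}

#' Synthetic cohort parameters
#'
#' @param n_subjects Cohort size (default 22).
#' @param n_weeks Full monitoring length in weeks (default 6).
#' @param complete_5wk,complete_6wk Number of subjects completing at least
#'   5 and 6 weeks (defaults 21 and 19); the remaining subjects are
#'   truncated at a random point between 2 and 4 weeks. All subjects
#'   complete at least 2 weeks.
#' @param features Per-feature parameter tibble (see
#'   [default_feature_params()]).
#' @param start_date First monitoring day (a Monday by default so weekday/
#'   weekend windows are well populated).
#' @param distribution `"gaussian"` (additive components, closed-form
#'   oracles) or `"lognormal"` (multiplicative components for skewed,
#'   sway-like features; the sigma columns are then log-scale SDs).
#' @param abc_mean,abc_slope,abc_subject_sd,abc_daily_sd Daily ABC link:
#'   `clamp(abc_mean + abc_slope * trait + subject noise + daily noise,
#'   0, 100)`. The latent impairment trait is standard normal, shared by
#'   every feature's subject effect; the negative default slope encodes
#'   lower balance confidence with higher impairment.
#' @param mfis_mean,mfis_slope,mfis_sd End-of-two-week MFIS link, clamped to
#'   0-84.
#' @param kappa Mean retained-bout fraction after sway filtering, entering
#'   the closed-form reliability curves (default 1: the feature-level
#'   generator emits already-filtered streams).
#' @return List of class `cohort_params`.
#' @export
cohort_params <- function(n_subjects = 22, n_weeks = 6, complete_5wk = 21,
                          complete_6wk = 19,
                          features = default_feature_params(),
                          start_date = as.Date("2021-06-07"),
                          distribution = c("gaussian", "lognormal"),
                          abc_mean = 77.6, abc_slope = -20,
                          abc_subject_sd = 8, abc_daily_sd = 4,
                          mfis_mean = 28.3, mfis_slope = 14, mfis_sd = 8,
                          kappa = 1) {
  distribution <- match.arg(distribution)
  stopifnot(complete_6wk <= complete_5wk, complete_5wk <= n_subjects,
            all(features$sigma_subject >= 0), all(features$rate > 0))
  structure(
    list(n_subjects = n_subjects, n_weeks = n_weeks,
         complete_5wk = complete_5wk, complete_6wk = complete_6wk,
         features = features, start_date = start_date,
         distribution = distribution,
         abc_mean = abc_mean, abc_slope = abc_slope,
         abc_subject_sd = abc_subject_sd, abc_daily_sd = abc_daily_sd,
         mfis_mean = mfis_mean, mfis_slope = mfis_slope, mfis_sd = mfis_sd,
         kappa = kappa),
    class = "cohort_params"
  )
}

#' Generate a synthetic free-living cohort
#'
#' Draws, per feature and subject, a daily bout count from
#' `Poisson(rate)` and bout-level values
#' `x = mu + a_i + d_ij + e_ijb` with `a_i = sigma_subject * trait_i`,
#' `d_ij ~ N(0, (m_i sigma_day)^2)` and `e_ijb ~ N(0, (m_i sigma_within)^2)`,
#' where `trait_i ~ N(0, 1)` is the latent impairment trait shared across
#' features and `m_i = exp(cv_heterogeneity * z_i)` a per-subject
#' dispersion multiplier. ABC is administered daily and MFIS at the end of
#' each two-week cycle, both linked to the trait. Output is byte-identical
#' under a fixed seed.
#'
#' @param params A [cohort_params()] object.
#' @param seed Integer seed.
#' @return List of class `synthetic_cohort`: `observations` (feature
#'   table), `prm` (PRM table), `truth` (see [synthetic_truth()]), `params`,
#'   `seed`.
#' @export
generate_cohort <- function(params = cohort_params(), seed = 1) {
  stopifnot(inherits(params, "cohort_params"))
  withr::with_seed(seed, generate_cohort_impl(params, seed))
}

generate_cohort_impl <- function(params, seed) {
  n <- params$n_subjects
  subjects <- sprintf("S%02d", seq_len(n))
  trait <- rnorm(n)

  # attrition: truncate randomly chosen subjects' streams
  weeks <- rep(params$n_weeks, n)
  order_idx <- sample.int(n)
  n_trunc5 <- params$complete_5wk - params$complete_6wk
  n_trunc_early <- n - params$complete_5wk
  if (n_trunc5 > 0) weeks[order_idx[seq_len(n_trunc5)]] <- 5
  if (n_trunc_early > 0) {
    idx <- order_idx[n_trunc5 + seq_len(n_trunc_early)]
    weeks[idx] <- sample(2:4, n_trunc_early, replace = TRUE)
  }
  days <- pmin(weeks, params$n_weeks) * 7

  feats <- params$features
  obs_list <- vector("list", nrow(feats))
  comp_list <- vector("list", nrow(feats))
  for (fi in seq_len(nrow(feats))) {
    fp <- feats[fi, ]
    m_i <- exp(fp$cv_heterogeneity * rnorm(n))
    a_i <- fp$sigma_subject * trait
    # one draw block per feature: subject-days flattened, then bouts
    subj_of_day <- rep.int(seq_len(n), days)
    day_of_day <- sequence(days)
    counts <- rpois(length(subj_of_day), fp$rate)
    d_day <- rnorm(length(subj_of_day), 0, m_i[subj_of_day] * fp$sigma_day)
    tot <- sum(counts)
    if (tot > 0) {
      subj_of <- rep.int(subj_of_day, counts)
      day_of <- rep.int(day_of_day, counts)
      d_ij <- rep.int(d_day, counts)
      e <- rnorm(tot, 0, m_i[subj_of] * fp$sigma_within)
      value <- if (params$distribution == "gaussian") {
        fp$mu + a_i[subj_of] + d_ij + e
      } else {
        fp$mu * exp(fp$sigma_subject * trait[subj_of] + d_ij + e)
      }
      secs <- runif(tot, 8 * 3600, 22 * 3600)
      obs_list[[fi]] <- tibble::tibble(
        subject_id = subjects[subj_of],
        bout_start = as.POSIXct(params$start_date, tz = "UTC") +
          (day_of - 1) * 86400 + secs,
        feature_name = fp$feature_name,
        value = value,
        bout_duration = runif(tot, fp$dur_min, fp$dur_max)
      )
    }
    comp_list[[fi]] <- tibble::tibble(
      feature_name = fp$feature_name, subject_id = subjects,
      dispersion_multiplier = m_i, subject_effect = a_i
    )
  }
  observations <- dplyr::bind_rows(obs_list)
  observations <- observations[order(observations$feature_name,
                                     observations$subject_id,
                                     observations$bout_start), ]

  # patient-reported measures
  abc_subj <- params$abc_mean + params$abc_slope * trait +
    rnorm(n, 0, params$abc_subject_sd)
  prm_rows <- vector("list", n)
  for (i in seq_len(n)) {
    nd <- days[i]
    abc_scores <- pmin(pmax(abc_subj[i] + rnorm(nd, 0, params$abc_daily_sd),
                            0), 100)
    abc <- tibble::tibble(
      subject_id = subjects[i], instrument = "ABC",
      administration_time = as.POSIXct(params$start_date, tz = "UTC") +
        (seq_len(nd) - 1) * 86400 + 20 * 3600,
      score = abc_scores
    )
    mfis_days <- if (nd >= 14) seq(14, nd, by = 14) else integer(0)
    mfis <- if (length(mfis_days) > 0) {
      tibble::tibble(
        subject_id = subjects[i], instrument = "MFIS",
        administration_time = as.POSIXct(params$start_date, tz = "UTC") +
          (mfis_days - 1) * 86400 + 21 * 3600,
        score = pmin(pmax(params$mfis_mean + params$mfis_slope * trait[i] +
                            rnorm(length(mfis_days), 0, params$mfis_sd),
                          0), 84)
      )
    } else NULL
    prm_rows[[i]] <- dplyr::bind_rows(abc, mfis)
  }
  prm <- dplyr::bind_rows(prm_rows)

  truth <- synthetic_truth(params, trait = trait, weeks = weeks,
                           components = dplyr::bind_rows(comp_list))
  structure(
    list(observations = observations, prm = prm, truth = truth,
         params = params, seed = seed),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "<synthetic_cohort> %d subjects, %d features, %d observations (seed %d)\n",
    x$params$n_subjects, nrow(x$params$features), nrow(x$observations),
    x$seed
  ))
  invisible(x)
}

#' Closed-form reliability truth for a synthetic cohort
#'
#' Carries the realized latent traits and per-subject variance components of
#' a generated cohort together with the parameters needed for the
#' closed-form reliability curves (see [expected_reliability()] and
#' [expected_icc()]). Dispersion heterogeneity enters through the log-normal
#' moment `h = exp(2 * cv_heterogeneity^2)`, the mean of the squared
#' per-subject multiplier.
#'
#' @param params A [cohort_params()] object.
#' @param trait Realized latent traits (may be `NULL` before generation).
#' @param weeks Realized per-subject monitoring weeks.
#' @param components Realized per-subject, per-feature effects.
#' @return List of class `synthetic_truth` with a per-feature tibble
#'   `variance` holding `sigma_subject`, `per_day_var` (the day-level
#'   variance of a one-day summary mean) and the generator parameters.
#' @export
synthetic_truth <- function(params, trait = NULL, weeks = NULL,
                            components = NULL) {
  f <- params$features
  h <- exp(2 * f$cv_heterogeneity^2)
  variance <- tibble::tibble(
    feature_name = f$feature_name,
    sigma_subject = f$sigma_subject,
    sigma_day = f$sigma_day,
    sigma_within = f$sigma_within,
    rate = f$rate,
    h = h,
    per_day_var = h * (f$sigma_day^2 + f$sigma_within^2 /
                         (f$rate * params$kappa))
  )
  structure(list(variance = variance, trait = trait, weeks = weeks,
                 components = components),
            class = "synthetic_truth")
}

#' Expected reliability of a d-day summary
#'
#' The closed-form intraclass correlation of a `d`-day summary mean under
#' the generator's hierarchical model:
#' `sigma_a^2 / (sigma_a^2 + (sigma_d^2 + sigma_e^2 / (rate * kappa)) * h / d)`.
#' Monotone non-decreasing in `d`.
#'
#' @param truth A `synthetic_truth` object.
#' @param feature Feature name.
#' @param d Wear duration in days (vectorised).
#' @return Expected reliability in (0, 1).
#' @export
expected_reliability <- function(truth, feature, d) {
  v <- truth$variance[truth$variance$feature_name == feature, ]
  if (nrow(v) != 1) abort(paste0("unknown feature: ", feature))
  sa2 <- v$sigma_subject^2
  sa2 / (sa2 + v$per_day_var / d)
}

#' Expected ICC(C,k) between a d-day window and the baseline window
#'
#' Population value of the two-way consistency average-measures ICC
#' (`k = 2`) between the per-subject `d`-day summary and the
#' `baseline_days` summary, from the generator's variance components:
#' with `V_d = sigma_a^2 + v/d`, `V_b = sigma_a^2 + v/b` and covariance
#' `C = sigma_a^2 + v/max(d, b)` for nested windows (`C = sigma_a^2` for
#' disjoint windows), the average-measures consistency ICC is
#' `2C / ((V_d + V_b)/2 + C)`.
#'
#' @inheritParams expected_reliability
#' @param baseline_days Baseline window length (default 7).
#' @param nested `TRUE` when the shorter window is a subset of the longer
#'   (the default first-days anchoring); `FALSE` for disjoint windows.
#' @param summary `"median"` (the pipeline's central summary) inflates the
#'   bout-level noise term by the median's asymptotic variance ratio
#'   `pi / 2`; `"mean"` uses the raw components.
#' @return Expected ICC(C,2) (vectorised over `d`).
#' @export
expected_icc <- function(truth, feature, d, baseline_days = 7,
                         nested = TRUE, summary = c("median", "mean")) {
  summary <- match.arg(summary)
  v <- truth$variance[truth$variance$feature_name == feature, ]
  if (nrow(v) != 1) abort(paste0("unknown feature: ", feature))
  sa2 <- v$sigma_subject^2
  infl <- if (summary == "median") pi / 2 else 1
  pdv <- v$h * (v$sigma_day^2 + infl * v$sigma_within^2 / v$rate)
  vd <- sa2 + pdv / d
  vb <- sa2 + pdv / baseline_days
  cc <- if (nested) sa2 + pdv / pmax(d, baseline_days) else sa2
  2 * cc / ((vd + vb) / 2 + cc)
}

#' Generate raw accelerometer bouts with stride events
#'
#' Fixture generator for the feature modules. Standing bouts are a gravity
#' vector (optionally tilted) plus low-pass planar Gaussian noise; walking
#' bouts are periodic thigh waveforms with analytically placed foot-contact
#' and foot-off events (configurable stride period and stance fraction) for
#' both legs plus an attenuated trunk channel.
#'
#' @param n_standing,n_walking Number of bouts of each kind.
#' @param standing_duration_s,walking_duration_s Durations in seconds
#'   (recycled); defaults straddle the 30 s and 60 s feature gates.
#' @param stride_s Stride period (s).
#' @param stance_fraction Stance fraction of the stride (duty factor ground
#'   truth).
#' @param noise_amp Planar noise amplitude for standing bouts (g).
#' @param tilt_deg Static tilt of the standing sensor (degrees).
#' @param asymmetry Relative right/left stance-fraction asymmetry for
#'   walking bouts.
#' @param sampling_rate Hz (default 31.25).
#' @param subject_id Subject label on the bouts.
#' @param seed Integer seed.
#' @return List with `standing` (list of `accel_bout`) and `walking` (list
#'   of lists with `right`, `left`, `trunk` bouts; stride events are on the
#'   right bout).
#' @export
generate_raw_bouts <- function(n_standing = 3, n_walking = 3,
                               standing_duration_s = 35,
                               walking_duration_s = c(25, 45, 90),
                               stride_s = 1.0, stance_fraction = 0.6,
                               noise_amp = 0.01, tilt_deg = 0,
                               asymmetry = 0, sampling_rate = 31.25,
                               subject_id = "S01", seed = 1) {
  withr::with_seed(seed, {
    fs <- sampling_rate
    t0 <- as.POSIXct("2021-06-07 09:00:00", tz = "UTC")
    lowpass <- function(n, k = max(3, round(fs / 4))) {
      x <- rnorm(n + 2 * k)
      as.numeric(stats::filter(x, rep(1 / k, k), sides = 2))[
        (k + 1):(k + n)] * sqrt(k)
    }
    standing_duration_s <- rep_len(standing_duration_s, n_standing)
    standing <- lapply(seq_len(n_standing), function(i) {
      ns <- round(standing_duration_s[i] * fs)
      th <- tilt_deg * pi / 180
      g <- c(cos(th), sin(th), 0)  # (vertical, ap, ml)
      samples <- cbind(
        vertical = g[1] + rnorm(ns, 0, noise_amp / 4),
        ap = g[2] + noise_amp * lowpass(ns),
        ml = g[3] + noise_amp * lowpass(ns)
      )
      accel_bout(subject_id, "standing", t0 + (i - 1) * 600, samples, fs)
    })
    walking_duration_s <- rep_len(walking_duration_s, n_walking)
    walking <- lapply(seq_len(n_walking), function(i) {
      dur <- walking_duration_s[i]
      ns <- round(dur * fs)
      tt <- (seq_len(ns) - 1) / fs
      wave <- function(phase) {
        sin(2 * pi * tt / stride_s + phase) +
          0.3 * sin(4 * pi * tt / stride_s + 2 * phase)
      }
      mk <- function(phase, amp) {
        cbind(
          vertical = 1 + 0.2 * amp * wave(phase) + rnorm(ns, 0, 0.005),
          ap = amp * wave(phase) + rnorm(ns, 0, 0.005),
          ml = 0.2 * amp * wave(phase + pi / 3) + rnorm(ns, 0, 0.005)
        )
      }
      sf_right <- stance_fraction
      sf_left <- stance_fraction * (1 + asymmetry)
      events <- list()
      for (foot in c("right", "left")) {
        off0 <- if (foot == "right") 0 else stride_s / 2
        sf <- if (foot == "right") sf_right else sf_left
        contacts <- seq(off0, dur - stride_s, by = stride_s)
        ev <- rbind(
          data.frame(foot = foot, event = "foot_contact", time = contacts),
          data.frame(foot = foot, event = "foot_off",
                     time = contacts + sf * stride_s)
        )
        events[[foot]] <- ev
      }
      events <- dplyr::bind_rows(events)
      events <- events[events$time >= 0 & events$time <= dur, ]
      events <- events[order(events$time), ]
      start <- t0 + 3600 + (i - 1) * 600
      list(
        right = accel_bout(subject_id, "walking", start, mk(0, 0.5), fs,
                           stride_events = tibble::as_tibble(events)),
        left = accel_bout(subject_id, "walking", start, mk(pi, 0.5), fs),
        trunk = accel_bout(subject_id, "walking", start, mk(pi / 6, 0.15), fs)
      )
    })
    list(standing = standing, walking = walking)
  })
}

#' Write the tables of a synthetic cohort to a directory
#'
#' Emits `features.csv`, `prm.csv` and `truth.json` in the cohort I/O
#' formats.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_feature_table(cohort$observations, file.path(dir, "features.csv"))
  write_prm_table(cohort$prm, file.path(dir, "prm.csv"))
  jsonlite::write_json(
    list(variance = cohort$truth$variance,
         trait = cohort$truth$trait,
         weeks = cohort$truth$weeks,
         seed = cohort$seed),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
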