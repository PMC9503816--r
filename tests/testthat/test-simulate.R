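test_that("cohort generation is byte-identical under a fixed seed", {
  p <- cohort_params(features = default_feature_params()[c(1, 20), ],
                     n_weeks = 2)
  a <- generate_cohort(p, seed = 42)
  b <- generate_cohort(p, seed = 42)
  expect_identical(a$observations, b$observations)
  expect_identical(a$prm, b$prm)
  fa <- withr::local_tempfile(fileext = ".csv")
  fb <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(a$observations, fa)
  write_feature_table(b$observations, fb)
  expect_identical(readLines(fa), readLines(fb))
  c_ <- generate_cohort(p, seed = 43)
  expect_false(identical(a$observations$value, c_$observations$value))
})

test_that("the noise-free limit reproduces subject effects exactly", {
  fp <- default_feature_params()[1, ]
  fp$sigma_day <- 0
  fp$sigma_within <- 0
  fp$cv_heterogeneity <- 0
  p <- cohort_params(features = fp, n_weeks = 1, complete_5wk = 22,
                     complete_6wk = 22, abc_subject_sd = 0, abc_daily_sd = 0)
  co <- generate_cohort(p, seed = 5)
  eff <- co$truth$components
  obs <- co$observations
  # every observation equals mu + a_i
  expected <- fp$mu + eff$subject_effect[match(obs$subject_id,
                                               eff$subject_id)]
  expect_equal(obs$value, expected, tolerance = 1e-12)
  # Stage 2 ICC is exactly 1 from a single day
  bsum <- summarize_windows(partition_windows(
    obs, duration_spec("b", 7, baseline = TRUE)))
  w1 <- summarize_windows(partition_windows(obs, duration_spec("1", 1)))
  s2 <- stage2_icc(w1, bsum)
  expect_equal(s2$icc[s2$statistic == "median"], 1)
  # Stage 3 correlation with a noise-free PRM is perfect at day 1
  abc <- abc_biweekly_median(co$prm)
  rho <- spearman_correlation(
    w1$median[match(abc$subject_id, w1$subject_id)], abc$abc)$rho
  expect_equal(abs(rho), 1, tolerance = 0.02)  # PRM clamping can tie ranks
})

test_that("realized variance components match the generator within 10%", {
  fp <- default_feature_params()
  fp <- fp[fp$feature_name == "distance", ]
  fp$cv_heterogeneity <- 0
  p <- cohort_params(n_subjects = 100, features = fp, n_weeks = 4,
                     complete_5wk = 100, complete_6wk = 100)
  est <- sapply(1:5, function(s) {
    co <- generate_cohort(p, seed = 100 + s)
    obs <- co$observations
    obs$day <- as.integer(as.Date(obs$bout_start))
    key <- paste(obs$subject_id, obs$day)
    day_means <- tapply(obs$value, key, mean)
    day_n <- tapply(obs$value, key, length)
    subj_of <- sub(" .*", "", names(day_means))
    # within-day component from pooled within-day variance
    sse <- sum(tapply(obs$value, key, function(v) sum((v - mean(v))^2)))
    sigma_e2 <- sse / (length(obs$value) - length(day_means))
    # between-day from day-mean dispersion less sampling noise
    resid_day <- day_means - tapply(day_means, subj_of, mean)[subj_of]
    n_day <- tapply(rep(1, length(day_means)), subj_of, sum)
    sigma_d2 <- sum(resid_day^2) / (length(day_means) - length(n_day)) -
      sigma_e2 * mean(1 / day_n)
    # between-subject from subject-mean dispersion less day/bout noise
    subj_means <- tapply(obs$value, obs$subject_id, mean)
    per_day_var <- sigma_d2 + sigma_e2 / fp$rate
    sigma_a2 <- var(subj_means) - per_day_var / 28
    c(a = sqrt(sigma_a2), d = sqrt(max(sigma_d2, 0)), e = sqrt(sigma_e2))
  })
  expect_lt(abs(mean(est["a", ]) - fp$sigma_subject),
            0.1 * fp$sigma_subject)
  expect_lt(abs(mean(est["d", ]) - fp$sigma_day), 0.1 * fp$sigma_day)
  expect_lt(abs(mean(est["e", ]) - fp$sigma_within),
            0.1 * fp$sigma_within)
})

test_that("closed-form reliability curves are monotone and bounded", {
  truth <- synthetic_truth(cohort_params())
  for (f in c("stride_duration", "rms", "lyapunov_ap")) {
    r <- expected_reliability(truth, f, 1:14)
    expect_true(all(diff(r) > 0))
    expect_true(all(r > 0 & r < 1))
    icc <- expected_icc(truth, f, 1:7)
    expect_true(all(icc > 0 & icc <= 1))
    expect_true(all(diff(icc) > 0))
  }
  expect_error(expected_reliability(truth, "no_such_feature", 1))
})

test_that("attrition truncates the configured number of subjects", {
  p <- cohort_params(features = default_feature_params()[1, ])
  co <- generate_cohort(p, seed = 9)
  span <- tapply(as.integer(as.Date(co$observations$bout_start)),
                 co$observations$subject_id, function(d) max(d) - min(d) + 1)
  expect_equal(sum(span >= 42 - 1), 19)     # completed 6 weeks
  expect_equal(sum(span >= 35 - 1), 21)     # completed 5 weeks
  expect_true(all(span >= 14 - 1))          # everyone wore at least 2 weeks
})

test_that("PRM streams respect instrument schedules and ranges", {
  p <- cohort_params(features = default_feature_params()[1, ])
  co <- generate_cohort(p, seed = 10)
  abc <- co$prm[co$prm$instrument == "ABC", ]
  mfis <- co$prm[co$prm$instrument == "MFIS", ]
  expect_true(all(abc$score >= 0 & abc$score <= 100))
  expect_true(all(mfis$score >= 0 & mfis$score <= 84))
  # one ABC per monitored day
  n_abc <- table(abc$subject_id)
  expect_true(all(n_abc %in% c(14, 21, 28, 35, 42)))
  # MFIS lands at the end of each two-week cycle
  day_idx <- as.integer(as.Date(mfis$administration_time) -
                          as.Date("2021-06-07")) + 1
  expect_true(all(day_idx %in% c(14, 28, 42)))
  # higher-impairment subjects report lower balance confidence
  tr <- co$truth$trait
  med_abc <- tapply(abc$score, abc$subject_id, median)
  expect_lt(cor(tr, med_abc[sprintf("S%02d", 1:22)]), -0.5)
})

test_that("feature-PRM correlation converges to the latent-link value", {
  fp <- default_feature_params()[1, ]
  fp$cv_heterogeneity <- 0
  fp$rate <- 100
  p <- cohort_params(n_subjects = 400, features = fp, n_weeks = 2,
                     complete_5wk = 400, complete_6wk = 400)
  co <- generate_cohort(p, seed = 11)
  obs <- co$observations
  w <- summarize_windows(partition_windows(obs, duration_spec("14", 14)))
  abc <- abc_biweekly_median(co$prm)
  emp <- spearman_correlation(
    w$median[match(abc$subject_id, w$subject_id)], abc$abc)$rho
  # Monte-Carlo oracle with the same variance components
  withr::local_seed(12)
  n <- 1e6
  t_i <- rnorm(n)
  feat <- fp$sigma_subject * t_i +
    rnorm(n, 0, sqrt(fp$sigma_day^2 / 14 +
                       (pi / 2) * fp$sigma_within^2 / (14 * fp$rate)))
  prm <- pmin(pmax(77.6 - 20 * t_i + rnorm(n, 0, sqrt(8^2 + 4^2 / 14)),
                   0), 100)
  oracle <- cor(rank(feat), rank(prm))
  expect_lt(abs(emp - oracle), 0.05)
})

test_that("raw standing bouts are still when noise-free and sway when not", {
  quiet <- generate_raw_bouts(n_standing = 2, n_walking = 0,
                              noise_amp = 0, seed = 13)
  for (b in quiet$standing) expect_lt(sway_distance(b), 1e-12)
  noisy <- generate_raw_bouts(n_standing = 2, n_walking = 0,
                              noise_amp = 0.01, seed = 13)
  for (b in noisy$standing) expect_gt(sway_distance(b), 1e-5)
  # static tilt is absorbed by the projection, not read as sway
  tilted <- generate_raw_bouts(n_standing = 1, n_walking = 0,
                               noise_amp = 0, tilt_deg = 15, seed = 14)
  expect_lt(sway_distance(tilted$standing[[1]]), 1e-12)
})

test_that("generated stride events encode the configured gait", {
  raw <- generate_raw_bouts(n_walking = 1, n_standing = 0,
                            walking_duration_s = 30, stride_s = 1.1,
                            stance_fraction = 0.63, seed = 15)
  strides <- stride_set(raw$walking[[1]]$right$stride_events)
  tp <- temporal_params(strides)
  expect_equal(tp$stride_duration, 1.1, tolerance = 1e-9)
  expect_equal(tp$duty_factor, 0.63, tolerance = 1e-9)
})
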