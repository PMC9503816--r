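mk_stage_rows <- function(feature, day, sig = FALSE, strong = TRUE) {
  stats_ <- c("median", "p95", "cv")
  list(
    s1 = tibble::tibble(feature_name = feature, statistic = stats_,
                        duration_label = as.character(day),
                        p_value = ifelse(sig, 0.01, 0.5),
                        significant = sig, evaluable = TRUE),
    s2 = tibble::tibble(feature_name = feature, statistic = stats_,
                        duration_label = as.character(day),
                        icc = ifelse(strong, 0.9, 0.5), strong = strong,
                        n_subjects = 22L, evaluable = TRUE)
  )
}

test_that("days required is the first day all six criteria pass", {
  rows <- lapply(1:7, function(d) mk_stage_rows("stride_duration", d))
  s1 <- dplyr::bind_rows(lapply(rows, `[[`, "s1"))
  s2 <- dplyr::bind_rows(lapply(rows, `[[`, "s2"))
  dr <- days_required(s1, s2)
  expect_equal(dr$days_required, 1L)
  expect_true(dr$reached)

  # weak CV ICC on day 1 pushes the answer to day 2
  weak1 <- mk_stage_rows("rms", 1)
  weak1$s2$strong[weak1$s2$statistic == "cv"] <- FALSE
  rest <- lapply(2:7, function(d) mk_stage_rows("rms", d))
  dr2 <- days_required(
    dplyr::bind_rows(weak1$s1, lapply(rest, `[[`, "s1")),
    dplyr::bind_rows(weak1$s2, lapply(rest, `[[`, "s2")))
  expect_equal(dr2$days_required, 2L)

  # never passing
  never <- lapply(1:7, function(d) mk_stage_rows("distance", d,
                                                 strong = FALSE))
  dr3 <- days_required(dplyr::bind_rows(lapply(never, `[[`, "s1")),
                       dplyr::bind_rows(lapply(never, `[[`, "s2")))
  expect_true(is.na(dr3$days_required))
  expect_false(dr3$reached)
})

test_that("candidate days with missing stage results are skipped with a warning", {
  rows <- lapply(2:7, function(d) mk_stage_rows("power", d))
  s1 <- dplyr::bind_rows(lapply(rows, `[[`, "s1"))
  s2 <- dplyr::bind_rows(lapply(rows, `[[`, "s2"))
  expect_warning(dr <- days_required(s1, s2),
                 class = "weartime_skip_warning")
  expect_equal(dr$days_required, 2L)
  expect_equal(dr$n_days_skipped, 1L)
})

test_that("covariates average per-subject daily counts and CVs", {
  obs <- dplyr::bind_rows(
    make_obs("S01", rep(1:2, each = 5), rnorm(10, 10, 1)),
    make_obs("S02", rep(1:2, each = 10), rnorm(20, 10, 1))
  )
  cov <- feature_covariates(obs)
  expect_equal(cov$count, (10 / 2 + 20 / 2) / 2)  # = 7.5

  # per-subject CV exactly 1 gives log CV 0: values (1, b) with sd = mean
  b <- (1 + 1 / sqrt(2)) / (1 - 1 / sqrt(2))
  obs2 <- dplyr::bind_rows(make_obs("S01", 1:2, c(1, b)),
                           make_obs("S02", 1:2, c(1, b)))
  cov2 <- feature_covariates(obs2)
  expect_equal(cov2$cv, 1, tolerance = 1e-12)
  expect_equal(cov2$log_cv, 0, tolerance = 1e-12)

  expect_error(feature_covariates(make_obs("S01", 1, 1:5)),
               class = "weartime_input_error")
})

test_that("the wear-duration regression refits a known model exactly", {
  withr::local_seed(20)
  n <- 27
  d <- tibble::tibble(
    log_cv = log(runif(n, 0.05, 0.8)),
    count = runif(n, 2, 120)
  )
  d$days_required <- 4.41 + 0.86 * d$log_cv - 0.011 * d$count -
    0.0040 * d$log_cv * d$count
  fit <- suppressWarnings(fit_duration_regression(d))
  est <- setNames(fit$coefficients$estimate, fit$coefficients$term)
  expect_equal(est[["intercept"]], 4.41, tolerance = 1e-8)
  expect_equal(est[["log_cv"]], 0.86, tolerance = 1e-8)
  expect_equal(est[["count"]], -0.011, tolerance = 1e-8)
  expect_equal(est[["interaction"]], -0.0040, tolerance = 1e-8)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)

  # constant response: zero slopes, zero R^2
  d2 <- d; d2$days_required <- 3
  fit2 <- suppressWarnings(fit_duration_regression(d2))
  expect_lt(max(abs(fit2$coefficients$estimate[-1])), 1e-10)
  expect_equal(fit2$r_squared, 0)
})

test_that("rank-deficient designs fail naming the collinear column", {
  d <- tibble::tibble(log_cv = log(seq(0.1, 0.6, length.out = 10)),
                      count = 5)
  d$days_required <- 2 + d$log_cv
  expect_error(fit_duration_regression(d), "interaction",
               class = "weartime_rank_error")
  expect_error(fit_duration_regression(d[1:3, ]),
               class = "weartime_input_error")
})

test_that("OLS residuals are orthogonal to every design column", {
  withr::local_seed(21)
  d <- tibble::tibble(log_cv = rnorm(30), count = runif(30, 1, 50))
  d$days_required <- 3 + d$log_cv - 0.05 * d$count + rnorm(30)
  fit <- fit_duration_regression(d)
  X <- cbind(1, d$log_cv, d$count, d$log_cv * d$count)
  expect_lt(max(abs(t(X) %*% residuals(fit$fit))), 1e-8)
})

test_that("coefficient CIs cover the truth at close to nominal rate", {
  withr::local_seed(22)
  n <- 27
  base <- tibble::tibble(log_cv = log(runif(n, 0.05, 0.8)),
                         count = runif(n, 2, 120))
  truth <- c(4.41, 0.86, -0.011, -0.0040)
  mu <- 4.41 + 0.86 * base$log_cv - 0.011 * base$count -
    0.0040 * base$log_cv * base$count
  sigma <- sd(mu) * sqrt(1 / 0.46 - 1)  # noise level giving R^2 near 0.46
  hits <- matrix(FALSE, 50, 4)
  for (r in 1:50) {
    d <- base
    d$days_required <- mu + rnorm(n, 0, sigma)
    ci <- confint(fit_duration_regression(d)$fit)
    hits[r, ] <- truth >= ci[, 1] & truth <= ci[, 2]
  }
  expect_true(all(colMeans(hits) >= 0.86))
})

test_that("bootstrap power analysis is reproducible and consistent", {
  withr::local_seed(23)
  med_b <- rnorm(22, 10, 2)
  med_w <- med_b + rnorm(22, 0, 0.8)
  w <- make_summaries(med_w, label = "2d")
  b <- make_summaries(med_b, label = "baseline")
  r1 <- bootstrap_power(w, b, "stride_duration", "median", B = 500, seed = 7)
  r2 <- bootstrap_power(w, b, "stride_duration", "median", B = 500, seed = 7)
  expect_identical(r1$icc, r2$icc)
  expect_equal(r1$B, 500)
  expect_lte(r1$icc_ci[1], r1$icc_ci[2])
  # bootstrap mean stays near the point estimate
  expect_equal(r1$icc_mean, r1$icc_point, tolerance = 0.05)

  perfect <- bootstrap_power(make_summaries(med_b, label = "2d"), b,
                             "stride_duration", "median", B = 200, seed = 1)
  expect_equal(perfect$proportion_strong, 1)
  expect_error(bootstrap_power(w[1:3, ], b, "stride_duration",
                               B = 10, seed = 1),
               class = "weartime_input_error")
})

test_that("the end-to-end days-required pipeline runs on a synthetic cohort", {
  fp <- default_feature_params()
  sel <- fp[fp$feature_name %in% c("stride_duration", "duty_factor",
                                   "rms", "distance", "range", "jerk",
                                   "power"), ]
  p <- cohort_params(features = sel, n_weeks = 1, complete_5wk = 22,
                     complete_6wk = 22)
  co <- generate_cohort(p, seed = 31)
  an <- suppressWarnings(suppressMessages(
    estimate_days_required(co$observations)))
  expect_equal(nrow(an$days_required), 7)
  expect_true(all(an$days_required$reached))
  expect_true(all(an$days_required$days_required <= 7))
  expect_s3_class(an$regression, "wear_duration_fit")
  expect_equal(an$regression$n, sum(an$days_required$reached))
})
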