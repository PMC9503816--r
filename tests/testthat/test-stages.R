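test_that("rank-sum testing matches enumeration on small groups", {
  r <- rank_sum_test(c(1, 2, 3), c(10, 11, 12))
  expect_equal(r$p_value, 0.1)  # 2/20 orderings, doubled
  expect_equal(r$p_value, oracle_ranksum_p(c(1, 2, 3), c(10, 11, 12)))
  same <- rank_sum_test(c(5, 6, 7, 8), c(5, 6, 7, 8))
  expect_equal(same$p_value, 1)
})

test_that("Stage 1 flags non-evaluable cells and detects shifts", {
  w <- make_summaries(c(1.0, 1.1, 1.2, 1.3, 1.4), label = "1")
  b <- make_summaries(c(1.05, 1.15, 1.22, 1.31, 1.44), label = "baseline")
  s1 <- stage1_difference(w, b)
  expect_equal(nrow(s1), 3)  # median, p95, cv
  expect_true(all(s1$evaluable))
  expect_false(any(s1$significant[s1$statistic == "median"]))

  shifted <- make_summaries(c(10, 11, 12, 13, 14), label = "1")
  s2 <- stage1_difference(shifted, b)
  expect_true(s2$significant[s2$statistic == "median"])

  missing_side <- make_summaries(rep(NA_real_, 5), label = "1",
                                 p95 = rep(NA_real_, 5),
                                 cv = rep(NA_real_, 5))
  s3 <- stage1_difference(missing_side, b)
  expect_false(any(s3$evaluable))
  expect_true(all(is.na(s3$p_value)))
})

test_that("ICC(C,k) has the consistency-model properties", {
  x <- c(1, 2, 3, 4, 5, 7, 9)
  expect_equal(icc_consistency(cbind(x, x))$icc, 1)
  expect_equal(icc_consistency(cbind(x, x + 5))$icc, 1)  # offset-blind
  res <- icc_consistency(cbind(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 6)))
  expect_equal(res$icc, oracle_icc_aov(cbind(c(1, 2, 3, 4, 5),
                                             c(2, 1, 4, 3, 6))),
               tolerance = 1e-12)
  # zero between-subject variance is flagged undefined
  flat <- icc_consistency(cbind(rep(1, 5), rep(1, 5)))
  expect_true(is.na(flat$icc))
  expect_error(icc_consistency(cbind(1, 2)), class = "weartime_input_error")
})

test_that("ICC(C,k) equals the ANOVA oracle on random matrices", {
  withr::local_seed(12)
  for (i in 1:200) {
    mat <- matrix(rnorm(20), 10, 2)
    expect_equal(icc_consistency(mat)$icc, oracle_icc_aov(mat),
                 tolerance = 1e-10)
  }
  # and for k > 2 columns
  for (i in 1:20) {
    mat <- matrix(rnorm(40), 10, 4)
    expect_equal(icc_consistency(mat)$icc, oracle_icc_aov(mat),
                 tolerance = 1e-10)
  }
})

test_that("Stage 2 drops incomplete pairs and applies the strength threshold", {
  med_w <- c(1, 2, 3, 4, 5, NA, 7)
  med_b <- c(1.1, 2.2, 2.9, 4.2, 5.1, 6.0, NA)
  w <- make_summaries(med_w, label = "1")
  b <- make_summaries(med_b, label = "baseline")
  s2 <- stage2_icc(w, b)
  row <- s2[s2$statistic == "median", ]
  expect_equal(row$n_subjects, 5)
  expect_true(row$strong)
  expect_equal(row$icc,
               icc_consistency(cbind(med_w[1:5], med_b[1:5]))$icc)
  # too few pairs
  s3 <- stage2_icc(make_summaries(c(1, 2, 3)), make_summaries(c(1, 2, 3)))
  expect_false(any(s3$evaluable))
})

test_that("Spearman correlation is invariant under monotone transforms", {
  withr::local_seed(13)
  x <- rnorm(15); y <- x + rnorm(15, 0, 0.5)
  base <- spearman_correlation(x, y)
  expect_equal(spearman_correlation(exp(x), y)$rho, base$rho)
  expect_equal(spearman_correlation(x, y^3 + 5 * y)$rho, base$rho)
  expect_equal(spearman_correlation(1:10, 10:1)$rho, -1)
  expect_true(is.na(spearman_correlation(rep(1, 10), rnorm(10))$rho))
})

test_that("Stage 3 finds immediate emergence for a monotone feature-PRM link", {
  withr::local_seed(14)
  score <- seq(30, 90, length.out = 12)
  sums <- dplyr::bind_rows(lapply(1:14, function(d) {
    s <- make_summaries(exp(score / 30), label = as.character(d),
                        subjects = sprintf("S%02d", 1:12))
    s$duration_days <- d
    s
  }))
  prm <- tibble::tibble(subject_id = sprintf("S%02d", 1:12), score = score)
  res <- stage3_prm_correlation(sums, prm, prm = "ABC")
  med <- res$by_duration[res$by_duration$statistic == "median", ]
  expect_true(all(med$rho == 1))
  em <- res$emergence[res$emergence$statistic == "median", ]
  expect_equal(em$emergence_day, 1)
  expect_true(em$stable)
})

test_that("emergence requires sustained significance and stable strength", {
  days <- 1:14
  # significant at day 2 only, then a 0.18 drop out of significance
  rho <- c(0.2, 0.65, rep(0.47, 12))
  sig <- c(FALSE, TRUE, rep(FALSE, 12))
  expect_true(is.na(weartime:::emergence_day(days, rho, sig, 0.10, 14)))
  # significant from day 3 onward with drifting strength below tolerance
  rho2 <- c(0.2, 0.4, seq(0.60, 0.66, length.out = 12))
  sig2 <- c(FALSE, FALSE, rep(TRUE, 12))
  expect_equal(weartime:::emergence_day(days, rho2, sig2, 0.10, 14), 3)
  # a late strength jump beyond the tolerance postpones emergence
  rho3 <- c(rep(0.5, 7), rep(0.75, 7))
  sig3 <- rep(TRUE, 14)
  expect_equal(weartime:::emergence_day(days, rho3, sig3, 0.10, 14), 8)
})

test_that("reliability summaries use fixed domain denominators", {
  gait <- feature_names("gait")
  mk_s1 <- function(sig) tibble::tibble(
    feature_name = gait, statistic = "median", duration_label = "1",
    significant = sig, evaluable = TRUE)
  mk_s2 <- function(strong) tibble::tibble(
    feature_name = gait, statistic = "median", duration_label = "1",
    strong = strong, evaluable = TRUE)
  all_good <- summarize_reliability(mk_s1(rep(FALSE, 10)),
                                    mk_s2(rep(TRUE, 10)))
  expect_equal(all_good$pct_strong_icc, 100)
  expect_equal(all_good$pct_no_diff, 100)
  eight <- summarize_reliability(mk_s1(rep(FALSE, 10)),
                                 mk_s2(c(rep(TRUE, 8), FALSE, FALSE)))
  expect_equal(eight$pct_strong_icc, 80)
  six <- summarize_reliability(mk_s1(rep(FALSE, 10)),
                               mk_s2(c(rep(TRUE, 6), rep(FALSE, 4))))
  expect_equal(six$pct_strong_icc, 60)
  # gated gait features are summarized apart from the core 10
  gated <- feature_names("gait_gated")
  s1 <- dplyr::bind_rows(mk_s1(rep(FALSE, 10)), tibble::tibble(
    feature_name = gated, statistic = "median", duration_label = "1",
    significant = FALSE, evaluable = TRUE))
  s2 <- dplyr::bind_rows(mk_s2(rep(TRUE, 10)), tibble::tibble(
    feature_name = gated, statistic = "median", duration_label = "1",
    strong = c(TRUE, TRUE, FALSE, FALSE), evaluable = TRUE))
  both <- summarize_reliability(s1, s2)
  expect_equal(both$pct_strong_icc[both$domain == "gait"], 100)
  expect_equal(both$pct_strong_icc[both$domain == "gait_gated"], 50)
})

test_that("heat-map export reshapes Stage 3 results", {
  by_dur <- tidyr::expand_grid(feature_name = c("f1", "f2"),
                               statistic = "median", duration_days = 1:3)
  by_dur$rho <- seq(0.1, 0.6, length.out = 6)
  by_dur$significant <- by_dur$rho > 0.3
  m <- correlation_heatmap_matrix(by_dur)
  expect_equal(dim(m$rho), c(2, 3))
  expect_equal(m$rho["f2", "3"], 0.6)
  expect_true(m$significant["f2", "1"] == (by_dur$rho[4] > 0.3))
})
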