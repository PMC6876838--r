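# minimal record builder
make_records <- function(ratio, thickness_by_mouse_day, erythema = 0,
                         desquamation = 0) {
  do.call(rbind, lapply(seq_along(thickness_by_mouse_day), function(m) {
    th <- thickness_by_mouse_day[[m]]
    data.frame(mouse_id = paste0("m", m), group_ratio = ratio,
               day = as.numeric(names(th)),
               thickness_um_1 = th, thickness_um_2 = th, thickness_um_3 = th,
               erythema = erythema, desquamation = desquamation)
  }))
}

test_that("total skin score adds the two scales and rejects off-scale values", {
  expect_identical(total_score(3, 3), 6)
  expect_identical(total_score(0, 0), 0)
  expect_identical(total_score(1.5, 2), 3.5)
  expect_equal(total_score(c(0, 0.5), c(1, 3)), c(1, 3.5))
  expect_error(total_score(1, 0), "erythema")
  expect_error(total_score(0, 2.5), "desquamation")
})

test_that("group time course averages replicates then mice, SEM across mice", {
  recs <- make_records(0.1, list(c("0" = 200, "3" = 210),
                                 c("0" = 300, "3" = 330)))
  gs <- group_timecourse(recs)
  expect_equal(gs$mean_thickness, c(250, 270))
  expect_equal(gs$sem_thickness, c(50, 60))
  expect_equal(gs$n_mice, c(2, 2))
  # identical mice: zero SEM every day
  recs8 <- make_records(0.2, rep(list(c("0" = 220, "5" = 240)), 8))
  gs8 <- group_timecourse(recs8)
  expect_true(all(gs8$sem_thickness == 0))
  expect_warning(group_timecourse(make_records(0.1, list(c("0" = 200)))),
                 "fewer than 2 mice")
})

test_that("replicate averaging enters before the group mean", {
  recs <- make_records(0.1, list(c("0" = 200), c("0" = 200)))
  recs$thickness_um_1 <- c(190, 230)
  recs$thickness_um_2 <- c(200, 200)
  recs$thickness_um_3 <- c(210, 170)
  gs <- group_timecourse(recs)
  expect_equal(gs$mean_thickness, 200)
  expect_equal(gs$sem_thickness, 0)   # both mice average to 200
})

test_that("group SEM scales as SD/sqrt(n) on synthetic draws", {
  set.seed(11)
  th <- stats::rnorm(8, 250, 20)
  recs <- make_records(0.3, lapply(th, function(x) c("0" = x)))
  gs <- group_timecourse(recs)
  expect_equal(gs$sem_thickness, stats::sd(th) / sqrt(8), tolerance = 1e-12)
})

test_that("swelling stats: linear ramp has t50 at half time, flat curve has none", {
  ramp <- data.frame(day = seq(0, 40, by = 4),
                     mean_thickness = 225 + seq(0, 40, by = 4) * 2.5)
  st <- swelling_stats(ramp, baseline = 225)
  expect_equal(st$max_thickness, 325)
  expect_equal(st$day_of_max, 40)
  expect_equal(st$t50, 20)
  flat <- data.frame(day = 0:10, mean_thickness = rep(225, 11))
  st0 <- swelling_stats(flat, baseline = 225)
  expect_equal(st0$max_thickness, 225)
  expect_true(is.na(st0$t50))
})

test_that("t50 never exceeds the day of maximum on generated curves", {
  set.seed(3)
  for (i in 1:20) {
    tpk <- stats::runif(1, 10, 40)
    days <- seq(0, 90, by = 3)
    cv <- data.frame(day = days,
                     mean_thickness = 225 +
                       stats::runif(1, 50, 400) * (days / tpk)^4 *
                       exp(4 * (1 - days / tpk)) +
                       stats::rnorm(length(days), 0, 2))
    st <- swelling_stats(cv, baseline = 225)
    if (!is.na(st$t50)) expect_lte(st$t50, st$day_of_max)
  }
})

test_that("threshold fit is exact on collinear input and converts units", {
  d <- data.frame(ratio = c(0.053, 0.11, 0.17, 0.228, 0.312, 0.491))
  d$max_thickness <- 225 + 840 * (d$ratio - 0.032)
  fit <- fit_threshold(d, control_t0 = 225, ctc = 1800)
  expect_s3_class(fit, "threshold_fit")
  expect_equal(fit$ratio_min, 0.032, tolerance = 1e-12)
  expect_equal(fit$slope, 840, tolerance = 1e-9)
  expect_equal(fit$r, 1, tolerance = 1e-12)
  expect_equal(fit$sigma_min, 57.6, tolerance = 1e-9)
  # FWHM = 2 sqrt(2 ln 2) sigma
  fit60 <- fit_threshold(d, control_t0 = 225, ctc = 60 / 0.032)
  expect_equal(fit60$sigma_min, 60, tolerance = 1e-9)
  expect_equal(fit60$fwhm_min, 141.3, tolerance = 1e-3)
  expect_error(fit_threshold(d[1:2, ], control_t0 = 225), "at least 3")
  dneg <- d; dneg$max_thickness <- rev(d$max_thickness)
  expect_error(fit_threshold(dneg, control_t0 = 225), "no-threshold")
})

test_that("threshold_fit behaves like a model object", {
  d <- data.frame(ratio = c(0.05, 0.1, 0.2, 0.3, 0.5))
  set.seed(5)
  d$max_thickness <- 198 + 840 * d$ratio + stats::rnorm(5, 0, 5)
  fit <- fit_threshold(d, control_t0 = 225, ctc = 1800)
  expect_named(coef(fit),
               c("intercept", "slope", "ratio_min", "sigma_min", "fwhm_min"))
  expect_length(predict(fit), 5)
  expect_equal(predict(fit, data.frame(ratio = 0.2)),
               c("1" = fit$intercept + 0.2 * fit$slope), tolerance = 1e-9)
  expect_equal(sum(residuals(fit)), 0, tolerance = 1e-9)
  expect_output(print(fit), "ratio_min")
})

test_that("threshold recovery is unbiased under the stated noise model", {
  # 6 groups, slope 840.6, threshold 0.032, per-group noise SD 15 um
  ratios <- c(0.053, 0.11, 0.17, 0.228, 0.312, 0.491)
  truth <- 225 + 840.6 * (ratios - 0.032)
  set.seed(9)
  est <- replicate(100, {
    d <- data.frame(ratio = ratios,
                    max_thickness = truth + stats::rnorm(6, 0, 15))
    fit_threshold(d, control_t0 = 225, ctc = 1800)$ratio_min
  })
  expect_lt(abs(mean(est) - 0.032), 0.005)
})

test_that("group comparison: identical groups p = 1, separated groups p < 0.01", {
  a <- make_records(0.1, rep(list(c("0" = 250, "5" = 260)), 8))
  expect_equal(compare_groups(a, a)$p_value, 1)
  set.seed(13)
  gA <- make_records(0.1, lapply(stats::rnorm(8, 250, 10),
                                 function(x) c("0" = x)))
  gB <- make_records(0.5, lapply(stats::rnorm(8, 350, 10),
                                 function(x) c("0" = x)))
  expect_lt(compare_groups(gA, gB)$p_value, 0.01)
  expect_error(compare_groups(a, make_records(0.2, list(c("0" = 200)))),
               "at least 2")
})

test_that("Welch p-value tracks a permutation test on moderate separations", {
  set.seed(17)
  a <- stats::rnorm(8, 250, 15)
  b <- stats::rnorm(8, 262, 15)
  recs_a <- make_records(0.1, lapply(a, function(x) c("0" = x)))
  recs_b <- make_records(0.3, lapply(b, function(x) c("0" = x)))
  p_welch <- compare_groups(recs_a, recs_b)$p_value
  p_perm <- oracle_permutation_p(a, b, n_perm = 1e4)
  expect_lt(abs(p_welch - p_perm), 0.02)
})

test_that("record validation flags malformed input", {
  good <- make_records(0.1, list(c("0" = 200), c("0" = 210)))
  expect_silent(validate_mouse_records(good))
  bad <- good; bad$day <- 95
  expect_error(validate_mouse_records(bad), "\\[0, 90\\]")
  bad2 <- good; bad2$thickness_um_2 <- -5
  expect_error(validate_mouse_records(bad2), "positive")
  expect_error(validate_mouse_records(good[, -1]), "missing columns")
})
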