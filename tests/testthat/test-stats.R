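test_that("dice similarity matches exhaustive pixel counting", {
  a <- matrix(0, 6, 6)
  a[1:2, 1:3] <- 1  # |X| = 6
  b <- matrix(0, 6, 6)
  b[2, 1:3] <- 1
  b[3, 1] <- 1      # |Y| = 4, |X ∩ Y| = 3
  expect_equal(dsc(a, b), 0.6)
  expect_equal(dsc(b, a), 0.6)  # symmetric
  expect_equal(dsc(a, a), 1)
  disj <- matrix(0, 6, 6)
  disj[5:6, 5:6] <- 1
  expect_equal(dsc(a, disj), 0)
  # empty-mask conventions
  z <- matrix(0, 6, 6)
  expect_equal(dsc(z, z), 1)
  expect_equal(dsc(z, a), 0)
  expect_error(dsc(a, matrix(0, 3, 3)), "differ")
  expect_error(dsc(a * 0.5, a), "binary")
})

test_that("dice loss equals one minus DSC on binary masks", {
  set.seed(31)
  for (i in 1:25) {
    x <- random_binary_mask(10, runif(1, 0.1, 0.6))
    y <- random_binary_mask(10, runif(1, 0.1, 0.6))
    expect_lt(abs(dice_loss(x, y) - (1 - dsc(x, y))), 1e-5)
  }
})

test_that("summary t-test reproduces the printed cohort significance bounds", {
  p_of <- function(a, b, variant) {
    ttest_from_summary(a, b, variant)$p_two_sided
  }
  cases <- list(
    list(group_summary(363, 6.12, 1.34), group_summary(232, 6.95, 1.75),
         0.001),  # injured vs intact
    list(group_summary(458, 6.76, 1.51), group_summary(137, 5.41, 1.30),
         0.001),  # male vs female
    list(group_summary(311, 6.33, 1.25), group_summary(52, 4.89, 1.23),
         0.001),  # injured males vs injured females
    list(group_summary(147, 7.66, 1.61), group_summary(85, 5.73, 1.25),
         0.001),  # intact males vs intact females
    list(group_summary(311, 6.33, 1.25), group_summary(147, 7.66, 1.61),
         0.001),  # males injured vs intact
    list(group_summary(52, 4.89, 1.23), group_summary(85, 5.73, 1.25),
         0.005)   # females injured vs intact
  )
  for (cs in cases) {
    expect_lt(p_of(cs[[1]], cs[[2]], "pooled"), cs[[3]])
    expect_lt(p_of(cs[[1]], cs[[2]], "welch"), cs[[3]])
  }
  # identical summaries: no effect
  s <- group_summary(50, 6, 1.2)
  same <- ttest_from_summary(s, s)
  expect_equal(same$t_statistic, 0)
  expect_equal(same$p_two_sided, 1)
})

test_that("raw-value t-test agrees with stats::t.test and the summary path", {
  set.seed(32)
  a <- rnorm(40, 6.1, 1.3)
  b <- rnorm(55, 6.9, 1.7)
  pooled <- ttest_unpaired(a, b, "pooled")
  ref_p <- t.test(a, b, var.equal = TRUE)
  expect_equal(pooled$t_statistic, unname(ref_p$statistic),
               tolerance = 1e-12)
  expect_equal(pooled$p_two_sided, ref_p$p.value, tolerance = 1e-12)
  welch <- ttest_unpaired(a, b, "welch")
  ref_w <- t.test(a, b)
  expect_equal(welch$t_statistic, unname(ref_w$statistic),
               tolerance = 1e-12)
  expect_equal(welch$degrees_of_freedom, unname(ref_w$parameter),
               tolerance = 1e-12)
  # identity with the summary-statistics route
  via_summary <- ttest_from_summary(
    group_summary(length(a), mean(a), sd(a)),
    group_summary(length(b), mean(b), sd(b)), "pooled"
  )
  expect_identical(pooled$t_statistic, via_summary$t_statistic)
  expect_identical(pooled$p_two_sided, via_summary$p_two_sided)
  # a vs a gives t = 0; zero-variance pooled comparison errors
  expect_equal(ttest_unpaired(a, a)$t_statistic, 0)
  expect_error(ttest_unpaired(rep(2, 5), rep(3, 5)), "zero-variance")
})

test_that("|t| grows monotonically with the mean separation", {
  base <- group_summary(60, 6, 1.2)
  tstats <- vapply(c(0.1, 0.3, 0.6, 1.2), function(d) {
    abs(ttest_from_summary(base, group_summary(60, 6 + d, 1.2))$t_statistic)
  }, numeric(1))
  expect_true(all(diff(tstats) > 0))
  set.seed(33)
  a <- rnorm(30)
  b <- rnorm(30)
  t0 <- abs(ttest_unpaired(a, b)$t_statistic)
  t1 <- abs(ttest_unpaired(a, b + 5)$t_statistic)
  expect_gt(t1, t0)
})

test_that("ICC matches an independent reference implementation", {
  # 8 subjects x 3 raters fixture; reference values computed with an
  # independent two-way ANOVA ICC implementation (single measures)
  y <- matrix(c(5.674633, 6.06198, 5.366598,
                6.176571, 5.053287, 5.16094,
                7.773367, 7.796736, 7.499192,
                8.296627, 7.902707, 9.136718,
                4.900594, 5.105552, 5.23096,
                5.774915, 6.547342, 6.494973,
                3.857531, 4.07473, 3.603265,
                7.048353, 7.07014, 7.546791),
              nrow = 8, byrow = TRUE)
  agr <- icc_absolute_agreement(y)
  expect_equal(agr$estimate, 0.9325540728775751, tolerance = 1e-9)
  expect_equal(round(agr$conf_low, 2), 0.79)
  expect_equal(round(agr$conf_high, 2), 0.98)
  expect_equal(agr$label, "good")
  con <- icc_absolute_agreement(y, type = "consistency")
  expect_equal(con$estimate, 0.9242090097449145, tolerance = 1e-9)
})

test_that("ICC honours its definitional properties", {
  set.seed(34)
  base <- rnorm(30, 6, 1.5)
  # all raters identical: perfect reliability
  perfect <- suppressWarnings(icc_absolute_agreement(cbind(base, base, base)))
  expect_equal(perfect$estimate, 1)
  # constant rater offset: absolute agreement < consistency
  off <- cbind(base, base + 2) + matrix(rnorm(60, 0, 0.1), 30)
  expect_lt(icc_absolute_agreement(off)$estimate,
            icc_absolute_agreement(off, type = "consistency")$estimate)
  expect_error(icc_absolute_agreement(cbind(base[1:4], base[1:4])),
               "at least 5")
  expect_error(icc_absolute_agreement(matrix(base, ncol = 1)),
               "at least 2")
  grid <- cbind(base, base + rnorm(30))
  grid[3, 2] <- NA
  expect_error(icc_absolute_agreement(grid), "complete")
  # reliability bands
  expect_equal(notchseg:::icc_label(0.2), "poor")
  expect_equal(notchseg:::icc_label(0.6), "moderate")
  expect_equal(notchseg:::icc_label(0.9), "good")
})

test_that("ICC recovers designed reliability on simulated two-way data", {
  sb <- 1.35
  se <- 0.19
  truth <- sb^2 / (sb^2 + se^2)  # ~0.98
  set.seed(35)
  est <- replicate(200, {
    subj <- rnorm(200, 6.5, sb)
    y <- cbind(subj + rnorm(200, 0, se), subj + rnorm(200, 0, se))
    icc_absolute_agreement(y)$estimate
  })
  expect_lt(abs(mean(est) - truth), 0.01)
})

test_that("pearson correlation matches the covariance formula", {
  set.seed(36)
  x <- rnorm(60)
  expect_equal(pearson(x, x)$r, 1)
  expect_equal(pearson(x, -x)$r, -1)
  expect_equal(pearson(x, -x)$r_squared, 1)
  y <- 0.7 * x + rnorm(60)
  p <- pearson(x, y)
  brute <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(p$r, brute, tolerance = 1e-12)
  expect_equal(p$r_squared, brute^2, tolerance = 1e-12)
  expect_error(pearson(x, rep(1, 60)), "variance")
  expect_error(pearson(x[1:2], x[1:2]), "at least 3")
})

test_that("Bland-Altman limits behave under shifts and perfect agreement", {
  set.seed(37)
  x <- rnorm(50, 6, 1.5)
  same <- bland_altman(x, x)
  expect_equal(same$mean_difference, 0)
  expect_equal(same$loa_low, 0)
  expect_equal(same$loa_high, 0)
  y <- x + rnorm(50, 0, 0.3)
  ba <- bland_altman(x, y)
  ba_shift <- bland_altman(x + 1.5, y)
  expect_equal(ba_shift$mean_difference, ba$mean_difference + 1.5)
  expect_equal(ba_shift$loa_low, ba$loa_low + 1.5)
  expect_equal(ba_shift$loa_high, ba$loa_high + 1.5)
  expect_error(bland_altman(x, y[1:10]), "differ")
  td <- tidy(ba)
  expect_true(td$loa_low <= td$mean_difference &&
                td$mean_difference <= td$loa_high)
})

test_that("cohort comparison reproduces table structure and edge cases", {
  cohort <- generate_cohort(cohort_spec(seed = 5))
  cmp <- cohort_comparison(cohort)
  expect_equal(nrow(cmp$cells), 4)
  expect_equal(sum(cmp$cells$n), nrow(cohort))
  expect_equal(nrow(cmp$marginal), 2)
  expect_equal(nrow(cmp$stratified), 4)
  expect_true(all(cmp$stratified$p < 0.005))
  expect_true(all(cmp$marginal$p < 0.001))
  # all-equal volumes: no differences anywhere
  flat <- cohort
  flat$volume_cm3 <- 6
  cf <- cohort_comparison(flat)
  expect_true(all(cf$marginal$p == 1))
  expect_true(all(cf$stratified$p == 1))
  # a missing stratum marks its comparisons unavailable
  part <- dplyr::filter(cohort, !(group == "intact" & sex == "F"))
  cp <- cohort_comparison(part)
  expect_true(any(is.na(cp$stratified$p)))
  expect_true(all(!is.na(cp$marginal$p)))
})

test_that("agreement report bundles ICC, Pearson and Bland-Altman", {
  set.seed(38)
  manual <- rnorm(60, 6.8, 1.5)
  auto <- manual - 0.3 + rnorm(60, 0, 0.25)
  rep <- agreement_report(manual, auto)
  g <- glance(rep)
  expect_equal(g$r_squared, pearson(manual, auto)$r_squared)
  expect_gt(g$icc, 0.75)
  expect_true(g$loa_low < g$mean_difference &&
                g$mean_difference < g$loa_high)
  pl <- autoplot(rep$bland_altman)
  expect_s3_class(pl, "ggplot")
})
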