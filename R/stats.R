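#' Dice similarity coefficient between two binary masks
#'
#' `2 |X ∩ Y| / (|X| + |Y|)`.  Conventions for empty masks: both empty
#' gives 1 (perfect agreement on absence), exactly one empty gives 0.
#'
#' @param x,y [segmentation_mask()] objects or binary arrays of equal shape.
#' @return DSC in `[0, 1]`.
#' @examples
#' a <- matrix(c(1, 1, 1, 0, 0, 0), 2)
#' dsc(a, a)  # 1
#' @export
dsc <- function(x, y) {
  if (inherits(x, "segmentation_mask")) x <- x$labels
  if (inherits(y, "segmentation_mask")) y <- y$labels
  if (!all(dim2(x) == dim2(y))) stop("mask shapes differ")
  if (!all(x %in% c(0, 1)) || !all(y %in% c(0, 1))) {
    stop("dsc expects binary masks")
  }
  dsc_arrays(x, y)
}

dsc_arrays <- function(x, y) {
  sx <- sum(x)
  sy <- sum(y)
  if (sx == 0 && sy == 0) return(1)
  if (sx == 0 || sy == 0) return(0)
  2 * sum(x * y) / (sx + sy)
}

#' Group summary (n, mean, SD)
#'
#' The printed form of a group in a cohort table; sufficient statistics
#' for an unpaired t-test.
#'
#' @param n Sample size (>= 2).
#' @param mean Group mean.
#' @param sd Group standard deviation (> 0).
#' @param label Optional group label.
#' @return A `group_summary` object.
#' @export
group_summary <- function(n, mean, sd, label = "group") {
  stopifnot(n >= 2, sd > 0)
  structure(list(n = as.integer(n), mean = mean, sd = sd,
                 label = as.character(label)),
            class = "group_summary")
}

#' Unpaired two-sample t-test from summary statistics
#'
#' Computes the two-tailed unpaired t-test directly from printed
#' `(n, mean, SD)` triples — the form in which cohort tables report group
#' volumes.  `variant = "pooled"` is the classical Student test with the
#' pooled variance and `n_a + n_b - 2` degrees of freedom;
#' `variant = "welch"` uses the Welch statistic with Satterthwaite degrees
#' of freedom.
#'
#' @param a,b [group_summary()] objects (or lists with `n`, `mean`, `sd`).
#' @param variant `"pooled"` (default) or `"welch"`.
#' @return A `notch_ttest` object with fields `t_statistic`,
#'   `degrees_of_freedom`, `p_two_sided`, `variant`, `mean_difference`.
#' @examples
#' injured <- group_summary(363, 6.12, 1.34, "injured")
#' intact <- group_summary(232, 6.95, 1.75, "intact")
#' ttest_from_summary(injured, intact)
#' @export
ttest_from_summary <- function(a, b, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  ttest_core(a$n, a$mean, a$sd, b$n, b$mean, b$sd, variant,
             label_a = a$label %||% "a", label_b = b$label %||% "b")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

ttest_core <- function(na, ma, sa, nb, mb, sb, variant,
                       label_a = "a", label_b = "b") {
  if (na < 2 || nb < 2) stop("each group needs at least 2 observations")
  diff <- ma - mb
  if (variant == "pooled") {
    sp2 <- ((na - 1) * sa^2 + (nb - 1) * sb^2) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
  } else {
    va <- sa^2 / na
    vb <- sb^2 / nb
    se <- sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (na - 1) + vb^2 / (nb - 1))
  }
  if (se == 0) {
    if (diff == 0) {
      t <- 0
    } else {
      stop("degenerate zero-variance groups: t-test undefined")
    }
  } else {
    t <- diff / se
  }
  p <- 2 * pt(-abs(t), df)
  structure(
    list(t_statistic = t, degrees_of_freedom = df, p_two_sided = p,
         variant = variant, mean_difference = diff,
         label_a = label_a, label_b = label_b),
    class = "notch_ttest"
  )
}

#' @export
print.notch_ttest <- function(x, ...) {
  cat(sprintf(
    "Unpaired two-tailed t-test (%s): %s vs %s\n  t = %.4g, df = %.4g, p = %.3g, mean difference = %.4g\n",
    x$variant, x$label_a, x$label_b, x$t_statistic, x$degrees_of_freedom,
    x$p_two_sided, x$mean_difference
  ))
  invisible(x)
}

#' @method tidy notch_ttest
#' @export
tidy.notch_ttest <- function(x, ...) {
  tibble::tibble(
    estimate = x$mean_difference, statistic = x$t_statistic,
    p.value = x$p_two_sided, parameter = x$degrees_of_freedom,
    method = paste0("unpaired t-test (", x$variant, ")")
  )
}

#' Unpaired two-sample t-test from raw values
#'
#' Computes each group's `(n, mean, sd)` and delegates to the
#' summary-statistics path, so the two routes agree exactly.
#'
#' @param samples_a,samples_b Numeric vectors (each of length >= 2).
#' @inheritParams ttest_from_summary
#' @return A `notch_ttest` object.
#' @export
ttest_unpaired <- function(samples_a, samples_b,
                           variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  if (length(samples_a) < 2 || length(samples_b) < 2) {
    stop("each group needs at least 2 values")
  }
  ttest_core(length(samples_a), mean(samples_a), sd(samples_a),
             length(samples_b), mean(samples_b), sd(samples_b), variant)
}

#' Intraclass correlation coefficient for a subjects-by-raters grid
#'
#' Single-measurement ICC from the two-way ANOVA decomposition of a
#' complete subjects x raters grid.  `type = "agreement"` (the default)
#' is the two-way random-effects absolute-agreement form — the standard
#' choice for intra-/inter-observer reliability of repeated volume
#' measurements, sensitive to systematic rater offsets;
#' `type = "consistency"` ignores rater offsets.  The 95% confidence
#' interval uses the F-distribution method with Satterthwaite degrees of
#' freedom.  Estimates are labelled by the conventional reliability bands:
#' below 0.4 poor, 0.4-0.75 moderate, above 0.75 good.
#'
#' @param measurements Numeric matrix, one row per subject, one column per
#'   rater (or repeated session); at least 5 subjects and 2 raters, no
#'   missing cells.
#' @param type `"agreement"` or `"consistency"`.
#' @param conf_level Confidence level (default 0.95).
#' @return A `notch_icc` object with the estimate, CI, label and the
#'   mean-square components.
#' @export
icc_absolute_agreement <- function(measurements,
                                   type = c("agreement", "consistency"),
                                   conf_level = 0.95) {
  type <- match.arg(type)
  y <- as.matrix(measurements)
  if (any(!is.finite(y))) stop("ICC requires a complete grid")
  n <- nrow(y)
  k <- ncol(y)
  if (n < 5) stop("need at least 5 subjects")
  if (k < 2) stop("need at least 2 raters")
  grand <- mean(y)
  rmeans <- rowMeans(y)
  cmeans <- colMeans(y)
  ssr <- k * sum((rmeans - grand)^2)
  ssc <- n * sum((cmeans - grand)^2)
  sst <- sum((y - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  alpha <- 1 - conf_level
  if (type == "agreement") {
    est <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
    # Satterthwaite df for the denominator combination
    a <- (k * est) / (n * (1 - est))
    bq <- 1 + (k * est * (n - 1)) / (n * (1 - est))
    v <- (a * msc + bq * mse)^2 /
      ((a * msc)^2 / (k - 1) + (bq * mse)^2 / ((n - 1) * (k - 1)))
    fl <- qf(1 - alpha / 2, n - 1, v)
    fu <- qf(1 - alpha / 2, v, n - 1)
    lower <- n * (msr - fl * mse) /
      (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
    upper <- n * (fu * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * fu * msr)
  } else {
    est <- (msr - mse) / (msr + (k - 1) * mse)
    fobs <- msr / mse
    fl <- qf(1 - alpha / 2, n - 1, (n - 1) * (k - 1))
    fu <- qf(1 - alpha / 2, (n - 1) * (k - 1), n - 1)
    lower <- (fobs / fl - 1) / (fobs / fl + k - 1)
    upper <- (fobs * fu - 1) / (fobs * fu + k - 1)
  }
  est <- min(max(est, -1), 1)
  structure(
    list(estimate = est, conf_low = lower, conf_high = upper,
         conf_level = conf_level, type = type,
         label = icc_label(est), n_subjects = n, n_raters = k,
         ms = c(msr = msr, msc = msc, mse = mse)),
    class = "notch_icc"
  )
}

icc_label <- function(est) {
  if (est < 0.4) "poor" else if (est <= 0.75) "moderate" else "good"
}

#' @export
print.notch_icc <- function(x, ...) {
  cat(sprintf(
    "ICC (two-way random, %s, single measures): %.3f (%.3f, %.3f) [%s]\n",
    x$type, x$estimate, x$conf_low, x$conf_high, x$label
  ))
  invisible(x)
}

#' @method tidy notch_icc
#' @export
tidy.notch_icc <- function(x, ...) {
  tibble::tibble(estimate = x$estimate, conf.low = x$conf_low,
                 conf.high = x$conf_high, conf.level = x$conf_level,
                 type = x$type, label = x$label)
}

#' Pearson correlation with R-squared
#'
#' @param x,y Numeric vectors of equal length >= 3 with nonzero variance.
#' @return A list with `r` and `r_squared`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("lengths differ")
  if (length(x) < 3) stop("need at least 3 pairs")
  if (var(x) == 0 || var(y) == 0) stop("zero variance input")
  r <- cor(x, y)
  list(r = r, r_squared = r^2)
}

#' Bland-Altman limits of agreement
#'
#' For paired measurements, the differences `d_i = x_i - y_i` summarized by
#' their mean and the 95% limits of agreement `mean(d) +/- 1.96 sd(d)`.
#'
#' @param x,y Paired numeric vectors of equal length >= 3.
#' @return A `notch_bland_altman` object with `mean_difference`, `loa_low`,
#'   `loa_high` and the per-pair means/differences for plotting.
#' @examples
#' ba <- bland_altman(rnorm(50, 6, 1.5), rnorm(50, 6, 1.5))
#' tidy(ba)
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y)) stop("lengths differ")
  if (length(x) < 3) stop("need at least 3 pairs")
  d <- x - y
  m <- mean(d)
  s <- sd(d)
  structure(
    list(mean_difference = m, loa_low = m - 1.96 * s, loa_high = m + 1.96 * s,
         means = (x + y) / 2, differences = d),
    class = "notch_bland_altman"
  )
}

#' @export
print.notch_bland_altman <- function(x, ...) {
  cat(sprintf(
    "Bland-Altman: mean difference %.4g, limits of agreement [%.4g, %.4g]\n",
    x$mean_difference, x$loa_low, x$loa_high
  ))
  invisible(x)
}

#' @method tidy notch_bland_altman
#' @export
tidy.notch_bland_altman <- function(x, ...) {
  tibble::tibble(mean_difference = x$mean_difference, loa_low = x$loa_low,
                 loa_high = x$loa_high)
}

#' @method autoplot notch_bland_altman
#' @export
autoplot.notch_bland_altman <- function(object, ...) {
  df <- tibble::tibble(mean = object$means, difference = object$differences)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean, y = .data$difference)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = object$mean_difference,
                        linetype = "solid") +
    ggplot2::geom_hline(yintercept = c(object$loa_low, object$loa_high),
                        linetype = "dashed") +
    ggplot2::labs(x = "Mean of methods (cm³)",
                  y = "Difference (cm³)",
                  title = "Bland–Altman agreement")
}

#' Agreement report between two measurement methods
#'
#' Bundles the three agreement analyses used to validate automatic against
#' manual volumetry: ICC (two-way random, absolute agreement, single
#' measures), Pearson correlation with R^2, and Bland-Altman limits of
#' agreement.
#'
#' @param x,y Paired volume vectors (e.g. manual and automatic, cm^3).
#' @return A `notch_agreement` object.
#' @export
agreement_report <- function(x, y) {
  structure(
    list(icc = icc_absolute_agreement(cbind(x, y)),
         pearson = pearson(x, y),
         bland_altman = bland_altman(x, y)),
    class = "notch_agreement"
  )
}

#' @export
print.notch_agreement <- function(x, ...) {
  print(x$icc)
  cat(sprintf("Pearson r = %.4f (R² = %.4f)\n", x$pearson$r,
              x$pearson$r_squared))
  print(x$bland_altman)
  invisible(x)
}

#' @method glance notch_agreement
#' @export
glance.notch_agreement <- function(x, ...) {
  tibble::tibble(
    icc = x$icc$estimate, icc_low = x$icc$conf_low,
    icc_high = x$icc$conf_high, r = x$pearson$r,
    r_squared = x$pearson$r_squared,
    mean_difference = x$bland_altman$mean_difference,
    loa_low = x$bland_altman$loa_low, loa_high = x$bland_altman$loa_high
  )
}

#' Group comparisons of a cohort volume table
#'
#' Reproduces the structure of case-control cohort tables: marginal
#' comparisons (injured vs intact; male vs female) and the 2x2 stratified
#' comparisons (within each group, male vs female; within each sex,
#' injured vs intact), each cell reported as n / mean / SD with a pooled
#' unpaired two-tailed t-test p-value.  Comparisons whose strata are
#' missing or have fewer than 2 records are marked unavailable (`NA`).
#'
#' @param records A cohort tibble with columns `group`, `sex`,
#'   `volume_cm3` (as from [generate_cohort()]).
#' @param variant t-test variant passed to [ttest_unpaired()].
#' @return A `notch_cohort_comparison` object: tibbles `cells`, `marginal`
#'   and `stratified`.
#' @export
cohort_comparison <- function(records, variant = "pooled") {
  stopifnot(all(c("group", "sex", "volume_cm3") %in% names(records)))
  cells <- dplyr::summarise(
    dplyr::group_by(records, .data$group, .data$sex),
    n = dplyr::n(), mean_cm3 = mean(.data$volume_cm3),
    sd_cm3 = sd(.data$volume_cm3), .groups = "drop"
  )
  cmp <- function(va, vb, label, comparison) {
    if (length(va) < 2 || length(vb) < 2) {
      return(tibble::tibble(
        comparison = comparison, contrast = label,
        n_a = length(va), mean_a = mean(va), sd_a = sd(va),
        n_b = length(vb), mean_b = mean(vb), sd_b = sd(vb),
        t = NA_real_, p = NA_real_
      ))
    }
    tt <- ttest_unpaired(va, vb, variant)
    tibble::tibble(
      comparison = comparison, contrast = label,
      n_a = length(va), mean_a = mean(va), sd_a = sd(va),
      n_b = length(vb), mean_b = mean(vb), sd_b = sd(vb),
      t = tt$t_statistic, p = tt$p_two_sided
    )
  }
  vol <- function(...) {
    records$volume_cm3[interaction_filter(records, ...)]
  }
  marginal <- dplyr::bind_rows(
    cmp(vol(group = "injured"), vol(group = "intact"),
        "injured vs intact", "group"),
    cmp(vol(sex = "M"), vol(sex = "F"), "male vs female", "sex")
  )
  stratified <- dplyr::bind_rows(
    cmp(vol(group = "injured", sex = "M"), vol(group = "injured", sex = "F"),
        "injured: male vs female", "within-group"),
    cmp(vol(group = "intact", sex = "M"), vol(group = "intact", sex = "F"),
        "intact: male vs female", "within-group"),
    cmp(vol(group = "injured", sex = "M"), vol(group = "intact", sex = "M"),
        "males: injured vs intact", "within-sex"),
    cmp(vol(group = "injured", sex = "F"), vol(group = "intact", sex = "F"),
        "females: injured vs intact", "within-sex")
  )
  structure(list(cells = cells, marginal = marginal,
                 stratified = stratified),
            class = "notch_cohort_comparison")
}

interaction_filter <- function(records, group = NULL, sex = NULL) {
  keep <- rep(TRUE, nrow(records))
  if (!is.null(group)) keep <- keep & records$group == group
  if (!is.null(sex)) keep <- keep & records$sex == sex
  keep
}

#' @export
print.notch_cohort_comparison <- function(x, ...) {
  cat("Cohort cells (n, mean ± SD cm³):\n")
  print(x$cells)
  cat("\nMarginal comparisons:\n")
  print(x$marginal[, c("contrast", "t", "p")])
  cat("\nStratified comparisons:\n")
  print(x$stratified[, c("contrast", "t", "p")])
  invisible(x)
}

#' @method tidy notch_cohort_comparison
#' @export
tidy.notch_cohort_comparison <- function(x, ...) {
  dplyr::bind_rows(x$marginal, x$stratified)
}
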