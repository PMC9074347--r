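test_that("analytic notch volume follows the parabolic-segment closed form", {
  # single slice, w = 12 mm, h = 9 mm, pitch 4.4 mm:
  # (2/3) * 1.2 * 0.9 * 0.44 cm^3 = 0.3168 cm^3
  sp <- phantom_spec(size = 64, n_slices = 1, n_notch_slices = 1,
                     notch_width_mm = 12, notch_depth_mm = 9,
                     noise_sd = 0, bias_amplitude = 0)
  expect_equal(sp$analytic_volume_cm3, 0.3168)
  ph <- generate_phantom(sp)
  expect_equal(ph$true_volume_cm3, 0.3168)

  # closed form equals the Riemann sum of per-slice areas for any profile
  w <- c(10, 14, 12)
  h <- c(6, 9, 7)
  sp3 <- phantom_spec(size = 32, n_slices = 5, n_notch_slices = 3,
                      notch_width_mm = w, notch_depth_mm = h)
  expect_equal(sp3$analytic_volume_cm3, sum(2 / 3 * w * h) * 4.4 / 1000)
})

test_that("voxelized mask volume converges to the analytic volume", {
  errs <- vapply(c(64, 128, 256), function(sz) {
    sp <- phantom_spec(size = sz, noise_sd = 0, bias_amplitude = 0)
    ph <- generate_phantom(sp)
    abs(notch_volume(ph$mask)$volume_cm3 - sp$analytic_volume_cm3) /
      sp$analytic_volume_cm3
  }, numeric(1))
  expect_lt(errs[3], 0.02)   # 2% at 256 in-plane
  expect_lt(errs[2], 0.05)   # 5% at 128
  expect_true(all(diff(errs) < 0))  # error shrinks with resolution
})

test_that("phantom generation is deterministic in the seed", {
  sp <- phantom_spec(size = 32, seed = 9)
  a <- generate_phantom(sp)
  b <- generate_phantom(sp)
  expect_identical(a$volume$voxels, b$volume$voxels)
  expect_identical(a$mask$labels, b$mask$labels)
  c <- generate_phantom(phantom_spec(size = 32, seed = 10))
  expect_false(identical(a$volume$voxels, c$volume$voxels))
})

test_that("phantom slices show a notch gap only on notch slices", {
  ph <- generate_phantom(phantom_spec(size = 64, n_slices = 12,
                                      n_notch_slices = 8, noise_sd = 0,
                                      bias_amplitude = 0))
  per_slice <- apply(ph$mask$labels, 1, sum)
  expect_equal(sum(per_slice > 0), 8)
  expect_true(all(diff(which(per_slice > 0)) == 1))  # contiguous
  # the notch region is darker than the surrounding condyle
  z <- which.max(per_slice)
  img <- ph$volume$voxels[z, , ]
  msk <- ph$mask$labels[z, , ]
  expect_lt(mean(img[msk == 1]), mean(img[msk == 0 & img > 0.5]))
})

test_that("invalid phantom specs are rejected", {
  expect_error(phantom_spec(size = 64, notch_width_mm = 120),
               "extends beyond|fit inside")
  expect_error(phantom_spec(n_notch_slices = 20, n_slices = 12))
  expect_error(phantom_spec(notch_width_mm = -2), "strictly positive")
})

test_that("cohort generator matches the stratum distributions", {
  spec <- cohort_spec(seed = 5)
  cohort <- generate_cohort(spec)
  counts <- dplyr::count(cohort, group, sex)
  expect_equal(sum(counts$n), 595)
  inj_m <- cohort$volume_cm3[cohort$group == "injured" & cohort$sex == "M"]
  expect_length(inj_m, 311)
  # sample mean within 3 SE of 6.33 (SD 1.25)
  expect_lt(abs(mean(inj_m) - 6.33), 3 * 1.25 / sqrt(311))
  expect_true(all(cohort$volume_cm3 > 0.5))
})

test_that("cohort generator edge cases: vanishing SD, empty strata, truncation", {
  s0 <- cohort_spec(tibble::tibble(group = "injured", sex = "M", n = 10L,
                                   mean_cm3 = 6, sd_cm3 = 1e-12), seed = 1)
  expect_equal(generate_cohort(s0)$volume_cm3, rep(6, 10), tolerance = 1e-9)
  se <- cohort_spec(tibble::tibble(group = c("injured", "intact"),
                                   sex = c("M", "M"), n = c(0L, 4L),
                                   mean_cm3 = c(6, 7), sd_cm3 = c(1, 1)),
                    seed = 1)
  out <- generate_cohort(se)
  expect_equal(nrow(out), 4)
  expect_true(all(out$group == "intact"))
  st <- cohort_spec(tibble::tibble(group = "injured", sex = "F", n = 200L,
                                   mean_cm3 = 0.8, sd_cm3 = 0.5), seed = 2)
  expect_true(all(generate_cohort(st)$volume_cm3 > 0.5))
})

test_that("stratum moments converge at large n", {
  big <- cohort_spec(tibble::tibble(group = "injured", sex = "M",
                                    n = 10000L, mean_cm3 = 6.33,
                                    sd_cm3 = 1.25), seed = 7)
  v <- generate_cohort(big)$volume_cm3
  expect_lt(abs(mean(v) - 6.33) / 6.33, 0.02)
  expect_lt(abs(sd(v) - 1.25) / 1.25, 0.02)
})

test_that("cohort records scale phantoms to their target volumes", {
  base <- phantom_spec(size = 64)
  records <- tibble::tibble(subject_id = c("a", "b", "c"),
                            volume_cm3 = c(6.0, 4.5, 8.2))
  specs <- cohort_to_phantoms(records, base)
  vols <- vapply(specs, function(s) s$analytic_volume_cm3, numeric(1))
  expect_true(all(abs(vols - records$volume_cm3) / records$volume_cm3 <
                    0.001))
  expect_gte(vols[["a"]], 5.994)
  expect_lte(vols[["a"]], 6.006)

  # in-plane scaling law: scaling w and h by s scales volume by s^2
  s1 <- notchseg:::modify_phantom_scale(base, 1.1)
  s2 <- notchseg:::modify_phantom_scale(s1, 1.1)
  expect_equal(s2$analytic_volume_cm3,
               base$analytic_volume_cm3 * 1.1^4, tolerance = 1e-9)

  # degenerate one-slice phantom matches the closed form after scaling
  one <- phantom_spec(size = 64, n_slices = 1, n_notch_slices = 1,
                      notch_width_mm = 12, notch_depth_mm = 9)
  sone <- cohort_to_phantoms(tibble::tibble(subject_id = "x",
                                            volume_cm3 = 0.5), one)[["x"]]
  expect_equal(sone$analytic_volume_cm3,
               2 / 3 * sone$notch_width_mm * sone$notch_depth_mm * 4.4 / 1000)

  # unreachable volumes error out
  expect_error(cohort_to_phantoms(tibble::tibble(subject_id = "y",
                                                 volume_cm3 = 500), base),
               "unreachable")
})
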