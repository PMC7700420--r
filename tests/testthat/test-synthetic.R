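test_that("band profiles have the Gaussian FWHM geometry", {
  axis <- seq(1000, 1600, by = 0.5)
  b <- band_spec(1300, 40, 2)

  expect_equal(band_profile(b, axis, amplitude = 0), rep(0, length(axis)))

  prof <- band_profile(b, axis)
  expect_equal(max(prof), 2)
  expect_equal(axis[which.max(prof)], 1300)
  # symmetric about the centre on a symmetric grid
  expect_equal(prof, rev(prof))
  # half height exactly at centre +/- FWHM/2
  half <- band_profile(b, c(1300 - 20, 1300 + 20))
  expect_equal(half, c(1, 1), tolerance = 1e-9)

  out <- band_spec(500, 40, 1, name = "stray band")
  expect_error(band_profile(out, axis), "stray band")
})

test_that("noise-free spectra are exact deterministic band sums", {
  axis <- mir_axis()
  bands <- default_mir_bands()
  manual <- Reduce(`+`, lapply(bands, function(b)
    band_profile(b, axis, specfuse:::band_amplitude(b, "colon", "N"))))
  got <- generate_spectrum(bands, "colon", "N", axis)
  expect_equal(got, manual, tolerance = 1e-12)

  # linear baseline enters additively before the scatter factor
  with_base <- generate_spectrum(bands, "colon", "N", axis,
                                 baseline = c(1, 2), scatter = 3)
  u <- (axis - min(axis)) / diff(range(axis))
  expect_equal(with_base, 3 * (manual + 1 + 2 * u), tolerance = 1e-12)
})

test_that("tumour and normal spectra differ only near class-affected bands", {
  axis <- mir_axis()
  bands <- list(
    band_spec(1742, 24, 0.5, class_effect = 0.8),
    band_spec(1550, 30, 0.8),                      # class-neutral
    band_spec(1043, 20, 0.5, class_effect = 1.3))
  d <- generate_spectrum(bands, "colon", "T", axis) -
       generate_spectrum(bands, "colon", "N", axis)
  near <- (abs(axis - 1742) <= 3 * 24) | (abs(axis - 1043) <= 3 * 20)
  expect_true(all(abs(d[!near]) < 1e-6))
  expect_true(any(abs(d[near]) > 0.01))
})

test_that("class separation grows monotonically with the class effect", {
  axis <- mir_axis()
  dist_for <- function(ce) {
    bands <- list(band_spec(1642, 40, 1, class_effect = ce))
    sqrt(sum((generate_spectrum(bands, "colon", "T", axis) -
              generate_spectrum(bands, "colon", "N", axis))^2))
  }
  up <- vapply(c(1.05, 1.1, 1.2, 1.4), dist_for, numeric(1))
  expect_true(all(diff(up) > 0))
  # symmetric in log scale: moving below 1 also increases separation
  down <- vapply(c(0.95, 0.9, 0.8), dist_for, numeric(1))
  expect_true(all(diff(down) > 0))
})

test_that("default cohort matches the three-organ study design", {
  co <- generate_cohort(cohort_config(seed = 4))
  m <- average_replicates(co$mir)
  counts <- table(m$meta$organ, m$meta$class)
  expect_equal(counts["colon", "N"], 27)
  expect_equal(counts["colon", "T"], 25)
  expect_equal(sum(counts["colon", ]), 52)
  expect_equal(counts["stomach", "N"], 32)
  expect_equal(counts["stomach", "T"], 20)
  expect_equal(sum(counts["rectum", ]), 21)
  expect_equal(counts["rectum", "N"], 9)
  expect_equal(counts["rectum", "T"], 12)

  # both modalities share ids, organs and labels
  n <- average_replicates(co$nir)
  expect_identical(m$meta, n$meta)
  expect_equal(ncol(co$mir$intensity), 113)
  expect_equal(ncol(co$nir$intensity), 482)
  # replicates present in the raw blocks
  expect_equal(nrow(co$mir$intensity), 125 * 3)
})

test_that("a minimal one-patient cohort produces matched single rows", {
  cfg <- cohort_config(
    organs = list(colon = list(patients = 1, n_normal = 1, n_tumour = 0)),
    replicate_count = 1, seed = 2)
  co <- generate_cohort(cfg)
  expect_equal(nrow(co$mir$intensity), 1)
  expect_equal(nrow(co$nir$intensity), 1)
  expect_identical(co$mir$meta$position, co$nir$meta$position)
})

test_that("the seed fully determines the cohort and streams are stable", {
  a <- generate_cohort(cohort_config(seed = 11))
  b <- generate_cohort(cohort_config(seed = 11))
  expect_identical(a, b)
  c2 <- generate_cohort(cohort_config(seed = 12))
  expect_false(identical(a$mir$intensity, c2$mir$intensity))

  # enlarging one organ must not reshuffle the draws of another
  small <- tiny_config(seed = 5)
  big <- tiny_config(seed = 5)
  big$organs$rectum$n_tumour <- big$organs$rectum$n_tumour + 4
  co_s <- generate_cohort(small)
  co_b <- generate_cohort(big)
  colon_rows <- co_s$mir$meta$organ == "colon"
  expect_identical(co_s$mir$intensity[colon_rows, ],
                   co_b$mir$intensity[co_b$mir$meta$organ == "colon", ][
                     seq_len(sum(colon_rows)), ])
})

test_that("cohorts round-trip through the CSV + sidecar interface", {
  dir <- withr::local_tempdir()
  co <- generate_cohort(tiny_config(seed = 3))
  write_cohort(co, dir)
  back <- read_cohort(dir)
  expect_equal(back$mir$intensity, co$mir$intensity, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_identical(back$mir$meta$position, co$mir$meta$position)
  expect_equal(back$nir$axis, co$nir$axis, tolerance = 1e-12)
  expect_equal(back$config$seed, 3)
})
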