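test_that("unity-based reference calibration maps raw onto [dark, white]", {
  white <- c(10, 20, 30); dark <- c(1, 2, 3)
  expect_equal(unity_reference_calibration(white, white, dark), c(1, 1, 1))
  expect_equal(unity_reference_calibration(dark, white, dark), c(0, 0, 0))
  expect_equal(unity_reference_calibration((white + dark) / 2, white, dark),
               c(0.5, 0.5, 0.5))
  expect_error(unity_reference_calibration(c(1, 1), c(2, 5), c(2, 1)), "1")
})

test_that("SNV standardises each spectrum with the n-1 denominator", {
  expect_equal(snv(c(1, 2, 3)), c(-1, 0, 1))

  z <- snv(rnorm(50))
  expect_equal(snv(z), z, tolerance = 1e-12)

  x <- rnorm(30)
  expect_equal(snv(3.7 * x + 42), snv(x), tolerance = 1e-12)

  expect_error(snv(rep(2, 10)), "constant")

  set.seed(8)
  m <- snv(matrix(rnorm(200), 10))
  expect_equal(unname(apply(m, 1, mean)), rep(0, 10), tolerance = 1e-10)
  expect_equal(unname(apply(m, 1, sd)), rep(1, 10), tolerance = 1e-10)
})

test_that("Savitzky-Golay filters reproduce polynomial derivatives exactly", {
  t <- seq(0, 12, by = 0.25)
  expect_equal(savgol(3 * t, window = 9, deriv = 1, delta = 0.25),
               rep(3, length(t)), tolerance = 1e-9)
  expect_equal(savgol(5 * t^2, window = 9, deriv = 2, delta = 0.25),
               rep(10, length(t)), tolerance = 1e-8)
  y <- 1 - 2 * t + 0.5 * t^2
  expect_equal(savgol(y, window = 11), y, tolerance = 1e-9)
  # derivative is per physical axis unit: halving the step doubles nothing
  expect_equal(savgol(3 * t, window = 9, deriv = 1, delta = 1),
               rep(3 * 0.25, length(t)), tolerance = 1e-9)

  expect_error(savgol(y, window = 8), "odd")
  expect_error(savgol(y[1:5], window = 9), "shorter")
  expect_error(savgol(y, window = 9, polyorder = 2, deriv = 3), "order")
})

test_that("replicate averaging collapses positions by channel-wise means", {
  ax <- seq(904, by = 8, length.out = 5)
  meta <- data.frame(position = rep(c("a", "b"), each = 2),
                     patient = "p1", organ = "colon",
                     class = rep(c("N", "T"), each = 2),
                     replicate = c(1, 2, 1, 2))
  m <- rbind(rep(0, 5), rep(2, 5), rep(1, 5), rep(5, 5))
  blk <- spectra_block(m, ax, "mir", meta)
  avg <- average_replicates(blk)
  expect_equal(nrow(avg$intensity), 2)
  expect_equal(unname(avg$intensity[1, ]), rep(1, 5))
  expect_equal(unname(avg$intensity[2, ]), rep(3, 5))
  expect_null(avg$meta$replicate)

  set.seed(1)
  m3 <- matrix(rnorm(15), 3)
  blk3 <- spectra_block(m3, ax, "mir",
                        data.frame(position = "a", patient = "p", organ = "colon",
                                   class = "N", replicate = 1:3))
  expect_equal(unname(average_replicates(blk3)$intensity[1, ]),
               unname(colMeans(m3)), tolerance = 1e-12)

  bad <- meta; bad$class <- c("N", "T", "T", "T")   # conflict within 'a'
  blk_bad <- spectra_block(m, ax, "mir", bad)
  expect_error(average_replicates(blk_bad), "conflicting")
})

test_that("min-max scaling is series-wide, idempotent and affine-invariant", {
  m <- rbind(c(-2, 0), c(1, 2))
  s <- minmax_block_scale(m)
  expect_equal(range(s), c(0, 1))
  expect_equal(s[1, 2], 0.5)              # 0 maps to the global midpoint
  expect_equal(minmax_block_scale(s), s, ignore_attr = TRUE)

  # one common coefficient pair: individual rows need not span [0, 1]
  expect_true(min(s[2, ]) > 0)

  set.seed(2)
  r <- matrix(rnorm(40), 5)
  expect_equal(minmax_block_scale(2.5 * r - 7), minmax_block_scale(r),
               ignore_attr = TRUE, tolerance = 1e-12)

  expect_error(minmax_block_scale(matrix(1, 3, 3)), "constant")
})

test_that("chains compose in order and order matters", {
  co <- generate_cohort(tiny_config(seed = 9))
  blk <- average_replicates(co$mir)

  idn <- apply_chain(blk, preprocess_spec("none", minmax = FALSE))
  expect_equal(idn$intensity, blk$intensity, tolerance = 1e-12)

  # composing 2d then snv equals the combined chain
  two_step <- snv(savgol(blk$intensity, window = 9, deriv = 2,
                         delta = mean(diff(blk$axis))))
  combined <- apply_chain(blk, preprocess_spec("2d+snv", minmax = FALSE))
  expect_equal(combined$intensity, two_step, tolerance = 1e-12,
               ignore_attr = TRUE)

  # the reverse order is a genuinely different operator
  reversed <- savgol(snv(blk$intensity), window = 9, deriv = 2,
                     delta = mean(diff(blk$axis)))
  expect_gt(max(abs(reversed - combined$intensity)), 1e-4)

  # min-max runs last when flagged
  with_mm <- apply_chain(blk, preprocess_spec("2d+snv", minmax = TRUE))
  expect_equal(range(with_mm$intensity), c(0, 1))

  expect_error(preprocess_spec("snv+2d"), "unknown chain")
})

test_that("background subtraction removes a fixed reference spectrum", {
  co <- generate_cohort(tiny_config(seed = 10))
  blk <- average_replicates(co$mir)
  bg <- colMeans(blk$intensity)
  out <- subtract_background(blk, bg)
  expect_equal(colMeans(out$intensity), bg * 0, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(subtract_background(blk, bg[-1]), "channel count")
})
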