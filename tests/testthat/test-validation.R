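test_that("confusion statistics follow their definitions exactly", {
  s <- confusion_stats(c(1, 1, 1, 0, 0), c(1, 1, 1, 0, 0))
  expect_equal(c(s$sensitivity, s$specificity, s$accuracy), c(1, 1, 1))

  s2 <- confusion_stats(c(1, 1, 1, 0, 0), rep(0, 5))
  expect_equal(c(s2$sensitivity, s2$specificity, s2$accuracy), c(0, 1, 0.4))

  truth <- c(rep(1, 10), rep(0, 10))
  pred <- c(rep(1, 9), 0, rep(0, 8), 1, 1)   # TP 9 FN 1 TN 8 FP 2
  s3 <- confusion_stats(truth, pred)
  expect_equal(c(s3$tp, s3$fn, s3$tn, s3$fp), c(9, 1, 8, 2))
  expect_equal(c(s3$sensitivity, s3$specificity, s3$accuracy),
               c(0.9, 0.8, 0.85))

  expect_error(confusion_stats(numeric(0), numeric(0)), "empty")
})

test_that("LOO refits once per position and pools held-out predictions", {
  # one channel carries the label exactly: LOO must be perfect
  n <- 16
  meta <- make_meta(n)
  y <- as.numeric(meta$class == "T")
  set.seed(31)
  m <- cbind(y * 2 - 1, matrix(rnorm(n * 10, sd = 0.1), n))
  blk <- spectra_block(m, seq_len(11) + 900, "mir", meta)
  res <- loo_cv(blk, spec = pipeline_spec("mir", mir = preprocess_spec("none"),
                                          ncomp = 2))
  expect_equal(res$stats$accuracy, 1)
  expect_equal(res$n_refits, n)
  expect_equal(length(res$scores), n)

  # pooled stats are exactly the confusion stats of the concatenated folds
  redo <- confusion_stats(res$labels, classify(res$scores, res$threshold))
  expect_identical(res$stats, redo)
})

test_that("LOO score for each fold equals an explicit refit without that row", {
  co <- generate_cohort(tiny_config(seed = 33))
  m <- average_replicates(co$mir); n <- average_replicates(co$nir)
  sp <- pipeline_spec("fused", "1d+snv", "snv", ncomp = 3)
  res <- loo_cv(m, n, sp)
  for (i in c(1, 9, 23)) {
    pos <- names(res$scores)[i]
    keep <- m$meta$position != pos
    fit_i <- fit_pipeline(m[keep], n[keep], sp)
    expect_equal(unname(res$scores[i]),
                 unname(predict(fit_i, m[!keep], n[!keep])),
                 tolerance = 1e-12)
  }
})

test_that("Monte Carlo CV is seeded, sized and redraws one-class folds", {
  co <- generate_cohort(tiny_config(seed = 35))
  m <- average_replicates(co$mir); n <- average_replicates(co$nir)
  sp <- pipeline_spec("fused", "snv", "snv", ncomp = 3)
  a <- monte_carlo_cv(m, n, sp, fraction = 0.2, reps = 12, seed = 42)
  b <- monte_carlo_cv(m, n, sp, fraction = 0.2, reps = 12, seed = 42)
  expect_identical(a$stats, b$stats)
  expect_identical(a$scores, b$scores)
  expect_equal(a$holdout_size, round(0.2 * nrow(m$intensity)))
  expect_equal(length(a$rep_stats), 12)
  expect_equal(length(a$scores), 12 * a$holdout_size)

  c2 <- monte_carlo_cv(m, n, sp, fraction = 0.2, reps = 12, seed = 43)
  expect_false(identical(a$scores, c2$scores))

  # strongly imbalanced classes force one-class holdouts to be redrawn
  nn <- 20
  meta <- make_meta(nn, classes = c(rep("T", 3), rep("N", 17)))
  y <- as.numeric(meta$class == "T")
  set.seed(1)
  blk <- spectra_block(cbind(2 * y - 1, matrix(rnorm(nn * 5, sd = 0.2), nn)),
                       seq_len(6) + 900, "mir", meta)
  r <- monte_carlo_cv(blk, spec = pipeline_spec("mir", mir = preprocess_spec("none"),
                                                ncomp = 2),
                      fraction = 0.1, reps = 30, seed = 7)
  expect_gt(r$redraws, 0)
  expect_equal(r$stats$accuracy, 1)   # perfectly separable
})

test_that("ROC curves are monotone staircases agreeing with pROC", {
  skip_if_not_installed("pROC")
  set.seed(51)
  truth <- rep(c(0, 1), each = 30)
  scores <- rnorm(60) + truth * 1.2
  rc <- roc_curve(truth, scores)
  expect_equal(c(rc$fpr[1], rc$tpr[1]), c(0, 0))
  expect_equal(c(rc$fpr[nrow(rc)], rc$tpr[nrow(rc)]), c(1, 1))
  expect_true(all(diff(rc$fpr) >= 0))
  expect_true(all(diff(rc$tpr) >= 0))

  ref <- pROC::roc(truth, scores, quiet = TRUE, direction = "<")
  ours <- unique(rc[order(rc$fpr, rc$tpr), c("fpr", "tpr")])
  theirs <- unique(data.frame(fpr = 1 - ref$specificities,
                              tpr = ref$sensitivities))
  theirs <- theirs[order(theirs$fpr, theirs$tpr), ]
  expect_equal(unname(as.matrix(ours)), unname(as.matrix(theirs)),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("ROC recognises perfect, reversed and degenerate score sets", {
  truth <- c(1, 1, 1, 0, 0)
  rc <- roc_curve(truth, truth)
  expect_true(any(rc$fpr == 0 & rc$tpr == 1))

  set.seed(53)
  sc <- rnorm(40)
  tr <- rep(c(0, 1), 20)
  staircase_auc <- function(rc)
    sum(diff(rc$fpr) * (rc$tpr[-1] + rc$tpr[-nrow(rc)]) / 2)
  fwd <- roc_curve(tr, sc)
  rev <- roc_curve(tr, -sc)
  # reversing scores reflects the curve through the diagonal: the area
  # under the anti-classifier complements the area under the classifier
  expect_equal(staircase_auc(fwd) + staircase_auc(rev), 1, tolerance = 1e-12)

  expect_error(roc_curve(rep(1, 5), rnorm(5)), "both classes")
})

test_that("model ranking orders by distance to (0,1) with documented ties", {
  truth <- rep(c(0, 1), each = 20)
  set.seed(55)
  perfect <- roc_curve(truth, truth, model_id = "perfect")
  noisy <- roc_curve(truth, truth + rnorm(40, sd = 1.5), model_id = "noisy")
  rk <- rank_models(list(noisy, perfect))
  expect_equal(rk$id[1], "perfect")
  expect_equal(rk$distance[1], 0)

  # exact duplicates: tie resolved by accuracy, then id
  dup1 <- roc_curve(truth, truth, model_id = "b")
  dup2 <- roc_curve(truth, truth, model_id = "a")
  rk2 <- rank_models(list(dup1, dup2), accuracies = c(0.9, 0.8))
  expect_equal(rk2$id, c("b", "a"))
  rk3 <- rank_models(list(dup1, dup2), accuracies = c(0.9, 0.9))
  expect_equal(rk3$id, c("a", "b"))
})
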