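#' Binary classification statistics
#'
#' Exact confusion counts and the derived rates: sensitivity
#' `TP/(TP+FN)` (true-positive rate among tumours), specificity
#' `TN/(TN+FP)` (true-negative rate among normals), accuracy
#' `(TP+TN)/n`.
#'
#' @param truth,pred equal-length 0/1 vectors (1 = tumour).
#' @return An object of class `classification_stats` with fields `tp`,
#'   `fp`, `tn`, `fn`, `sensitivity`, `specificity`, `accuracy`, `n`.
#' @export
confusion_stats <- function(truth, pred) {
  if (!length(truth)) stop("empty input")
  if (length(truth) != length(pred)) stop("length mismatch")
  truth <- class_response(truth); pred <- class_response(pred)
  tp <- sum(truth == 1 & pred == 1); fn <- sum(truth == 1 & pred == 0)
  tn <- sum(truth == 0 & pred == 0); fp <- sum(truth == 0 & pred == 1)
  structure(
    list(tp = tp, fp = fp, tn = tn, fn = fn,
         sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
         accuracy = (tp + tn) / length(truth), n = length(truth)),
    class = "classification_stats"
  )
}

#' @export
print.classification_stats <- function(x, ...) {
  cat(sprintf("Se %.1f%%  Sp %.1f%%  Ac %.1f%%  (TP %d FP %d TN %d FN %d, n = %d)\n",
              100 * x$sensitivity, 100 * x$specificity, 100 * x$accuracy,
              x$tp, x$fp, x$tn, x$fn, x$n))
  invisible(x)
}

#' Pipeline model specification
#'
#' Bundles everything needed to fit one classification model: the modality
#' (single-block MIR or NIR, or low-level fused), the per-block
#' preprocessing chains, the number of latent variables and the decision
#' threshold.
#'
#' @param modality `"fused"`, `"mir"` or `"nir"`.
#' @param mir,nir per-block [preprocess_spec()]s (or chain strings).
#' @param ncomp number of PLS latent variables (clamped per fold to the
#'   feasible maximum `min(n_train - 1, channels)`).
#' @param threshold classification threshold on the continuous score.
#' @return An object of class `pipeline_spec`.
#' @export
pipeline_spec <- function(modality = c("fused", "mir", "nir"),
                          mir = preprocess_spec("2d+snv"),
                          nir = preprocess_spec("2d+snv"),
                          ncomp = 5, threshold = 0.5) {
  modality <- match.arg(modality)
  if (is.character(mir)) mir <- preprocess_spec(mir)
  if (is.character(nir)) nir <- preprocess_spec(nir)
  structure(list(modality = modality, mir = mir, nir = nir,
                 ncomp = ncomp, threshold = threshold),
            class = "pipeline_spec")
}

#' @export
print.pipeline_spec <- function(x, ...) {
  lab <- switch(x$modality,
    fused = paste0(x$mir$chain, " | ", x$nir$chain),
    mir = x$mir$chain, nir = x$nir$chain)
  cat("<pipeline_spec> ", x$modality, " [", lab, "], ", x$ncomp,
      " LV, threshold ", x$threshold, "\n", sep = "")
  invisible(x)
}

## Assemble fold-independent inputs: replicate-averaged, chain-applied
## (per-row operations only) matrices for the modalities the spec uses,
## plus the response and metadata. Min-max scaling is *not* applied here:
## its coefficients are fold statistics and are fitted inside each
## training fold.
assemble_inputs <- function(mir, nir, spec) {
  prep <- function(block) {
    if (!is.null(block$meta$replicate)) block <- average_replicates(block)
    block
  }
  use_mir <- spec$modality %in% c("fused", "mir")
  use_nir <- spec$modality %in% c("fused", "nir")
  if (use_mir && is.null(mir)) stop("modality '", spec$modality,
                                    "' needs an MIR block")
  if (use_nir && is.null(nir)) stop("modality '", spec$modality,
                                    "' needs an NIR block")
  if (spec$modality == "fused") {
    mir <- prep(mir); nir <- prep(nir)
    paired <- pair_positions(mir, nir)
    mir <- paired$mir; nir <- paired$nir
  } else if (use_mir) mir <- prep(mir) else nir <- prep(nir)

  blocks <- list()
  minmax <- logical(0)
  if (use_mir) {
    blocks$mir <- apply_chain_rows(mir, spec$mir)$intensity
    colnames(blocks$mir) <- paste0("mir_", colnames(blocks$mir))
    minmax["mir"] <- spec$mir$minmax
  }
  if (use_nir) {
    blocks$nir <- apply_chain_rows(nir, spec$nir)$intensity
    colnames(blocks$nir) <- paste0("nir_", colnames(blocks$nir))
    minmax["nir"] <- spec$nir$minmax
  }
  ref <- if (use_mir) mir else nir
  list(blocks = blocks, minmax = minmax,
       y = class_response(ref$meta$class), meta = ref$meta)
}

## Fit the fold-dependent part on the training rows: per-block min-max
## coefficients, then PLS-DA on the (optionally fused) training matrix.
fold_fit <- function(inputs, train, ncomp) {
  coefs <- vector("list", length(inputs$blocks))
  names(coefs) <- names(inputs$blocks)
  tr <- list()
  for (nm in names(inputs$blocks)) {
    m <- inputs$blocks[[nm]][train, , drop = FALSE]
    if (inputs$minmax[[nm]]) {
      coefs[[nm]] <- minmax_coefs(m)
      m <- minmax_apply(m, coefs[[nm]])
    }
    tr[[nm]] <- m
  }
  Xtr <- do.call(cbind, tr)
  a <- min(ncomp, nrow(Xtr) - 1L, ncol(Xtr))
  list(model = plsda(Xtr, inputs$y[train], ncomp = a), coefs = coefs)
}

fold_predict <- function(fit, inputs, idx) {
  te <- list()
  for (nm in names(inputs$blocks)) {
    m <- inputs$blocks[[nm]][idx, , drop = FALSE]
    if (inputs$minmax[[nm]]) m <- minmax_apply(m, fit$coefs[[nm]])
    te[[nm]] <- m
  }
  predict(fit$model, do.call(cbind, te))
}

#' Fit the full classification pipeline on a calibration set
#'
#' Applies the preprocessing chains, the series-wide min-max scaling and —
#' for the fused modality — block concatenation, then fits the PLS-DA
#' model on all supplied positions.
#'
#' @param mir,nir [spectra_block()]s (raw replicates are averaged first);
#'   pass `NULL` for the unused block of a single-modality spec.
#' @param spec a [pipeline_spec()].
#' @return An object of class `pipeline_fit`: the `plsda` model, the fitted
#'   min-max coefficients, calibration scores and [confusion_stats()].
#' @export
fit_pipeline <- function(mir, nir = NULL, spec = pipeline_spec()) {
  inputs <- assemble_inputs(mir, nir, spec)
  fit <- fold_fit(inputs, seq_along(inputs$y), spec$ncomp)
  scores <- fold_predict(fit, inputs, seq_along(inputs$y))
  structure(
    list(model = fit$model, coefs = fit$coefs, spec = spec,
         scores = scores, y = inputs$y, meta = inputs$meta,
         stats = confusion_stats(inputs$y, classify(scores, spec$threshold))),
    class = "pipeline_fit"
  )
}

#' @export
print.pipeline_fit <- function(x, ...) {
  print(x$spec)
  cat("calibration: "); print(x$stats)
  invisible(x)
}

#' Predict with a fitted pipeline
#'
#' @param object a [fit_pipeline()] result.
#' @param mir,nir new [spectra_block()]s on the training channel grids.
#' @param ... ignored.
#' @return numeric score vector for the new positions.
#' @export
predict.pipeline_fit <- function(object, mir, nir = NULL, ...) {
  inputs <- assemble_inputs(mir, nir, object$spec)
  fit <- list(model = object$model, coefs = object$coefs)
  fold_predict(fit, inputs, seq_along(inputs$y))
}

cv_result <- function(scheme, scores, labels, meta, threshold, ...) {
  pred <- classify(scores, threshold)
  structure(
    c(list(scheme = scheme, scores = scores, labels = labels, pred = pred,
           meta = meta, threshold = threshold,
           stats = confusion_stats(labels, pred)),
      list(...)),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat("<cv_result> ", x$scheme, " over ", length(x$labels),
      " held-out predictions\n  pooled: ", sep = "")
  print(x$stats)
  invisible(x)
}

#' Leave-one-out cross-validation of the full pipeline
#'
#' Holds out one measurement position at a time; all fold-dependent
#' statistics (block min-max coefficients, PLS centring, the PLS model)
#' are refitted on the remaining positions, and the held-out position is
#' scored with the training-fold coefficients. Deterministic; performs
#' exactly n refits.
#'
#' @inheritParams fit_pipeline
#' @return A `cv_result` with per-position held-out scores and pooled
#'   [confusion_stats()].
#' @export
loo_cv <- function(mir, nir = NULL, spec = pipeline_spec()) {
  inputs <- assemble_inputs(mir, nir, spec)
  n <- length(inputs$y)
  if (min(table(inputs$y)) < 2L)
    stop("leave-one-out needs at least 2 positions per class")
  scores <- numeric(n)
  for (i in seq_len(n)) {
    train <- setdiff(seq_len(n), i)
    fit <- fold_fit(inputs, train, spec$ncomp)
    scores[i] <- fold_predict(fit, inputs, i)
  }
  names(scores) <- inputs$meta$position
  cv_result("loo", scores, inputs$y, inputs$meta, spec$threshold,
            n_refits = n)
}

#' Monte Carlo cross-validation of the full pipeline
#'
#' Each repetition draws a uniform random holdout of `round(fraction * n)`
#' positions without replacement, refits the fold-dependent pipeline on the
#' remainder and scores the holdout. Repetitions whose training fold or
#' holdout contains a single class are redrawn (counted in `redraws`).
#' Fully reproducible from `seed`.
#'
#' @inheritParams fit_pipeline
#' @param fraction holdout fraction of positions, in (0, 1).
#' @param reps number of repetitions.
#' @param seed RNG seed for the holdout draws.
#' @param stratified draw the holdout separately within each class,
#'   preserving the class balance (default `FALSE`: unstratified).
#' @return A `cv_result` with pooled statistics over all held-out
#'   predictions, the per-repetition statistics (`rep_stats`) and their
#'   mean (`mean_stats`).
#' @export
monte_carlo_cv <- function(mir, nir = NULL, spec = pipeline_spec(),
                           fraction = 0.10, reps = 100, seed = 1,
                           stratified = FALSE) {
  if (fraction <= 0 || fraction >= 1) stop("fraction must lie in (0, 1)")
  if (reps < 1) stop("reps must be >= 1")
  inputs <- assemble_inputs(mir, nir, spec)
  n <- length(inputs$y)
  k <- max(1L, round(fraction * n))
  if (k >= n - 1L) stop("holdout of ", k, " leaves too few training rows")

  draw_one <- function() {
    if (stratified) {
      k1 <- max(1L, round(k * mean(inputs$y)))
      k0 <- max(1L, k - k1)
      c(sample(which(inputs$y == 1), k1), sample(which(inputs$y == 0), k0))
    } else sample(n, k)
  }
  all_scores <- all_labels <- list()
  rep_stats <- vector("list", reps)
  redraws <- 0L
  with_seed(seed, {
    for (r in seq_len(reps)) {
      repeat {
        hold <- draw_one()
        ## a single-position holdout cannot contain both classes: in that
        ## degenerate limit the scheme reduces to randomised leave-one-out
        ## subsampling and only the training fold is constrained
        ok <- length(unique(inputs$y[-hold])) == 2L &&
              (k < 2L || length(unique(inputs$y[hold])) == 2L)
        if (ok) break
        redraws <- redraws + 1L
        if (redraws > 1000L * reps)
          stop("could not draw two-class folds; check the class balance")
      }
      fit <- fold_fit(inputs, setdiff(seq_len(n), hold), spec$ncomp)
      sc <- fold_predict(fit, inputs, hold)
      rep_stats[[r]] <- confusion_stats(inputs$y[hold],
                                        classify(sc, spec$threshold))
      all_scores[[r]] <- sc
      all_labels[[r]] <- inputs$y[hold]
    }
  })
  mean_of <- function(f)
    mean(vapply(rep_stats, `[[`, numeric(1), f), na.rm = TRUE)
  cv_result("monte_carlo", unlist(all_scores), unlist(all_labels),
            NULL, spec$threshold,
            rep_stats = rep_stats,
            mean_stats = c(sensitivity = mean_of("sensitivity"),
                           specificity = mean_of("specificity"),
                           accuracy = mean_of("accuracy")),
            seed = seed, fraction = fraction, reps = reps,
            holdout_size = k, redraws = redraws)
}

#' ROC curve by exhaustive threshold sweep
#'
#' Sweeps the decision threshold over `{-Inf}`, every unique score and
#' `{+Inf}` (label 1 iff score > threshold) and records one
#' `(1 - specificity, sensitivity)` point per threshold. The result is a
#' monotone staircase from (0, 0) to (1, 1).
#'
#' @param truth 0/1 labels (both classes required).
#' @param scores continuous classifier scores.
#' @param model_id optional identifier carried into [rank_models()].
#' @return An object of class `roc_curve`: data frame with columns
#'   `threshold`, `fpr`, `tpr`, ordered from (0, 0) to (1, 1).
#' @export
roc_curve <- function(truth, scores, model_id = NULL) {
  truth <- class_response(truth)
  if (length(unique(truth)) < 2L)
    stop("ROC needs both classes present")
  if (length(truth) != length(scores)) stop("length mismatch")
  th <- c(Inf, rev(sort(unique(scores))), -Inf)
  np <- sum(truth == 1); nn <- sum(truth == 0)
  pts <- t(vapply(th, function(t) {
    pred <- scores > t
    c(fpr = sum(pred & truth == 0) / nn, tpr = sum(pred & truth == 1) / np)
  }, numeric(2)))
  out <- data.frame(threshold = th, fpr = pts[, "fpr"], tpr = pts[, "tpr"])
  structure(out, class = c("roc_curve", "data.frame"), model_id = model_id)
}

#' @export
plot.roc_curve <- function(x, add = FALSE, col = "black", ...) {
  if (!add) {
    graphics::plot(x$fpr, x$tpr, type = "s", col = col, xlim = c(0, 1),
                   ylim = c(0, 1), xlab = "1 - specificity",
                   ylab = "sensitivity", ...)
    graphics::abline(0, 1, lty = 3, col = "grey60")
  } else graphics::lines(x$fpr, x$tpr, type = "s", col = col, ...)
  invisible(x)
}

#' Rank models by ROC proximity to the perfect-classification point
#'
#' Orders models by the minimum Euclidean distance of their ROC curve to
#' the point (0, 1) (100% sensitivity and specificity). Ties are broken by
#' pooled accuracy (larger first), then by model id.
#'
#' @param curves list of [roc_curve()]s.
#' @param accuracies optional numeric vector of pooled accuracies used for
#'   tie-breaking.
#' @param ids model identifiers; defaults to the curves' `model_id`
#'   attributes or their position.
#' @return data frame with one row per model — `id`, `distance`, the
#'   threshold attaining it, `accuracy`, `rank` — ordered best first.
#' @export
rank_models <- function(curves, accuracies = NULL, ids = NULL) {
  if (length(curves) < 2L) stop("need at least 2 curves to rank")
  if (is.null(ids))
    ids <- vapply(seq_along(curves), function(i) {
      mid <- attr(curves[[i]], "model_id")
      if (is.null(mid)) as.character(i) else as.character(mid)
    }, character(1))
  if (is.null(accuracies)) accuracies <- rep(NA_real_, length(curves))
  rows <- lapply(seq_along(curves), function(i) {
    cv <- curves[[i]]
    d <- sqrt(cv$fpr^2 + (1 - cv$tpr)^2)
    j <- which.min(d)
    data.frame(id = ids[i], distance = d[j], threshold = cv$threshold[j],
               accuracy = accuracies[i], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  ord <- order(out$distance, -ifelse(is.na(out$accuracy), -Inf, out$accuracy),
               out$id)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
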