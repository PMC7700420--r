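## Extract the numeric feature matrix from any of the package's containers.
feature_matrix <- function(x) {
  if (is.matrix(x)) return(x)
  if (inherits(x, "spectra_block") || inherits(x, "fused_block"))
    return(x$intensity)
  if (is.data.frame(x)) return(as.matrix(x))
  stop("cannot interpret 'x' as a feature matrix")
}

## 0/1 response from class labels ("N" -> 0, "T" -> 1) or numeric input.
class_response <- function(y) {
  if (is.factor(y)) y <- as.character(y)
  if (is.character(y)) {
    if (!all(y %in% c("N", "T")))
      stop("class labels must be 'N' or 'T'")
    y <- as.numeric(y == "T")
  }
  if (!all(y %in% c(0, 1))) stop("y must be coded 0 (normal) / 1 (tumour)")
  as.numeric(y)
}

#' Partial least-squares discriminant analysis (PLS1, NIPALS)
#'
#' Fits a univariate partial least-squares regression of the 0/1 class code
#' on the spectral matrix by the NIPALS algorithm and uses it as a
#' discriminant classifier: 1 codes tumour ("positive"), 0 codes normal.
#' X is column-centred but not variance-scaled (scatter and intensity
#' normalisation belong to the preprocessing chain); y is centred. The
#' weight vector of each component is `X'y` normalised, so the fit is
#' deterministic — no random initialisation.
#'
#' @param x spectral matrix (rows = positions), [spectra_block()] or
#'   [fused_block()].
#' @param y class labels: `"N"`/`"T"`, factor, or 0/1 numeric. Defaults to
#'   the block's metadata when `x` carries one.
#' @param ncomp number of latent variables `A`,
#'   `1 <= A <= min(nrow - 1, ncol)`.
#' @return An object of class `plsda` with components
#'   `ncomp`, `x_center` (column means), `y_center` (mean of y),
#'   `weights` (p x A, unit columns), `loadings` (p x A x-loadings),
#'   `y_loadings` (length A), `scores` (n x A), `coefficients` (regression
#'   vector, length p), `ssy` (y-variance explained per component),
#'   `fitted.values`, `y`, `call`.
#' @seealso [predict.plsda()], [vip()], [classify()]
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(40 * 12), 40)
#' y <- rep(c(0, 1), each = 20)
#' X[, 3] <- X[, 3] + y          # one informative channel
#' fit <- plsda(X, y, ncomp = 2)
#' fit
#' which.max(vip(fit))           # channel 3 stands out
#' @export
plsda <- function(x, y = NULL, ncomp = 5) {
  X <- feature_matrix(x)
  if (is.null(y)) {
    meta <- if (is.list(x) && !is.null(x$meta)) x$meta else
      stop("y is missing and x carries no metadata")
    y <- meta$class
  }
  y <- class_response(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("length(y) != nrow(x)")
  if (length(unique(y)) < 2L)
    stop("y contains a single class; PLS-DA needs both")
  amax <- min(n - 1L, p)
  if (ncomp < 1 || ncomp > amax)
    stop("ncomp must lie in [1, ", amax, "] for this data (got ", ncomp, ")")
  ncomp <- as.integer(ncomp)

  x_center <- colMeans(X)
  Xa <- sweep(X, 2L, x_center)
  y_center <- mean(y)
  ya <- y - y_center

  W <- P <- matrix(0, p, ncomp)
  TT <- matrix(0, n, ncomp)
  q <- ssy <- numeric(ncomp)
  for (a in seq_len(ncomp)) {
    w <- crossprod(Xa, ya)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12 * max(1, sqrt(sum(Xa^2))) || nw == 0)
      stop("no covariance left to extract component ", a,
           "; reduce ncomp")
    w <- w / nw
    t_a <- as.vector(Xa %*% w)
    tt <- sum(t_a^2)
    p_a <- as.vector(crossprod(Xa, t_a)) / tt
    q_a <- sum(ya * t_a) / tt
    Xa <- Xa - tcrossprod(t_a, p_a)
    ya <- ya - q_a * t_a
    W[, a] <- w; P[, a] <- p_a; TT[, a] <- t_a
    q[a] <- q_a
    ssy[a] <- q_a^2 * tt
  }
  ## regression vector on centred X: b = W (P'W)^-1 q
  b <- as.vector(W %*% solve(crossprod(P, W), q))
  names(b) <- colnames(X)
  fitted <- as.vector(sweep(X, 2L, x_center) %*% b) + y_center

  structure(
    list(ncomp = ncomp, x_center = x_center, y_center = y_center,
         weights = W, loadings = P, y_loadings = q, scores = TT,
         coefficients = b, ssy = ssy, fitted.values = fitted, y = y,
         call = match.call()),
    class = "plsda"
  )
}

#' @export
print.plsda <- function(x, ...) {
  cat("PLS-DA (NIPALS PLS1), ", x$ncomp, " latent variable",
      if (x$ncomp > 1) "s", "\n", sep = "")
  cat("  ", length(x$y), " samples (", sum(x$y == 1), " tumour, ",
      sum(x$y == 0), " normal) x ", length(x$coefficients),
      " channels\n", sep = "")
  expl <- x$ssy / sum((x$y - mean(x$y))^2)
  cat("  y-variance explained per LV: ",
      paste(sprintf("%.1f%%", 100 * expl), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
summary.plsda <- function(object, threshold = 0.5, ...) {
  expl <- object$ssy / sum((object$y - mean(object$y))^2)
  stats <- confusion_stats(object$y,
                           classify(object$fitted.values, threshold))
  out <- list(ncomp = object$ncomp, explained = expl,
              cum_explained = cumsum(expl), calibration = stats,
              threshold = threshold)
  class(out) <- "summary.plsda"
  out
}

#' @export
print.summary.plsda <- function(x, ...) {
  cat("PLS-DA with", x$ncomp, "latent variables\n")
  tab <- rbind(`% y-variance` = 100 * x$explained,
               `% cumulative` = 100 * x$cum_explained)
  colnames(tab) <- paste0("LV", seq_len(x$ncomp))
  print(round(tab, 1))
  cat("\nCalibration (threshold ", x$threshold, "):\n", sep = "")
  print(x$calibration)
  invisible(x)
}

#' @export
coef.plsda <- function(object, ...) object$coefficients

#' @export
fitted.plsda <- function(object, ...) object$fitted.values

#' @export
residuals.plsda <- function(object, ...) object$y - object$fitted.values

#' Predict continuous class scores from a fitted PLS-DA model
#'
#' `score = (X_new - training column means) . b + training y mean`. Scores
#' near 1 indicate tumour-like spectra, near 0 normal-like; [classify()]
#' thresholds them.
#'
#' @param object a fitted [plsda()] model.
#' @param newdata matrix, [spectra_block()] or [fused_block()] with the
#'   training channel count.
#' @param ... ignored.
#' @return numeric score vector.
#' @export
predict.plsda <- function(object, newdata, ...) {
  X <- feature_matrix(newdata)
  if (ncol(X) != length(object$coefficients))
    stop("newdata has ", ncol(X), " channels; model was trained on ",
         length(object$coefficients))
  as.vector(sweep(X, 2L, object$x_center) %*% object$coefficients) +
    object$y_center
}

#' Threshold continuous scores into 0/1 class labels
#'
#' Label 1 (tumour) iff the score strictly exceeds the threshold; a score
#' exactly at the threshold is classified 0 (normal) — a deterministic,
#' conservative tie rule.
#'
#' @param scores numeric score vector.
#' @param threshold decision threshold (default 0.5, the midpoint of the
#'   0/1 coding).
#' @return integer vector of 0/1 labels.
#' @export
classify <- function(scores, threshold = 0.5) {
  as.integer(scores > threshold)
}

#' Variable Importance in Projection
#'
#' @param object a fitted model.
#' @param ... passed to methods.
#' @return numeric importance vector.
#' @export
vip <- function(object, ...) UseMethod("vip")

#' @rdname vip
#' @details For a PLS1 model with p channels,
#' `VIP_j = sqrt(p * sum_a(SSY_a * w_ja^2) / sum_a(SSY_a))` with unit-norm
#' weight columns `w_a` and `SSY_a` the y-variance captured by component a.
#' The scores satisfy `sum_j VIP_j^2 = p`, so channels with VIP > 1 carry
#' more than an average share of the discriminative information.
#' @export
vip.plsda <- function(object, ...) {
  p <- nrow(object$weights)
  v <- sqrt(p * as.vector(object$weights^2 %*% object$ssy) / sum(object$ssy))
  names(v) <- names(object$coefficients)
  v
}

#' Score plot of a fitted PLS-DA model
#'
#' Plots the training scores on the first two latent variables (or LV1
#' against the fitted class score when `ncomp == 1`), coloured by class.
#'
#' @param x a fitted [plsda()] model.
#' @param ... further arguments passed to [graphics::plot()].
#' @export
plot.plsda <- function(x, ...) {
  cls <- ifelse(x$y == 1, "T", "N")
  col <- ifelse(x$y == 1, "firebrick", "steelblue")
  if (x$ncomp >= 2) {
    graphics::plot(x$scores[, 1], x$scores[, 2], col = col, pch = 19,
                   xlab = "LV1 score", ylab = "LV2 score", ...)
  } else {
    graphics::plot(x$scores[, 1], x$fitted.values, col = col, pch = 19,
                   xlab = "LV1 score", ylab = "fitted class score", ...)
  }
  graphics::legend("topright", legend = c("normal", "tumour"),
                   col = c("steelblue", "firebrick"), pch = 19, bty = "n")
  invisible(x)
}
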