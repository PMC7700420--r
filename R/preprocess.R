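#' Unity-based reference calibration
#'
#' Converts a raw single-beam spectrum to unitless reflectance against white
#' and dark reference measurements: `(raw - dark) / (white - dark)`,
#' channel by channel.
#'
#' @param raw,white,dark numeric vectors on the same channel grid.
#' @return numeric reflectance vector.
#' @export
unity_reference_calibration <- function(raw, white, dark) {
  if (length(raw) != length(white) || length(raw) != length(dark))
    stop("raw, white and dark must share one channel grid")
  denom <- white - dark
  bad <- which(denom == 0)
  if (length(bad))
    stop("white and dark references coincide at channel(s): ",
         paste(utils::head(bad, 10L), collapse = ", "))
  (raw - dark) / denom
}

#' Standard normal variate transform
#'
#' Standardises each spectrum to mean 0 and (n-1 denominator) standard
#' deviation 1, removing per-spectrum offset and multiplicative scatter.
#' Given a matrix, rows are transformed independently.
#'
#' @param x numeric vector (one spectrum) or matrix (rows are spectra).
#' @return object of the same shape.
#' @export
snv <- function(x) {
  if (is.matrix(x)) return(t(apply(x, 1L, snv)))
  if (length(x) < 2) stop("SNV needs at least 2 channels")
  s <- stats::sd(x)
  if (s == 0) stop("SNV undefined for a constant spectrum")
  (x - mean(x)) / s
}

#' Savitzky-Golay smoothing / differentiation
#'
#' Local least-squares polynomial filter; the derivative is returned per
#' physical axis unit (`delta^deriv` scaling), so magnitudes are comparable
#' across modalities with different channel spacings. Edge windows are fitted
#' with the same polynomial and evaluated at the off-centre points, so the
#' output keeps the input length and a polynomial of degree <= `polyorder`
#' is reproduced exactly everywhere.
#'
#' @param x numeric vector or matrix (rows are spectra).
#' @param window odd window width in channels, > `polyorder`.
#' @param polyorder polynomial degree (default 2).
#' @param deriv derivative order (0 = smoothing).
#' @param delta axis step in physical units (cm^-1 or nm per channel).
#' @return filtered object, same shape as `x`.
#' @export
savgol <- function(x, window, polyorder = 2, deriv = 0, delta = 1) {
  if (window %% 2 == 0)
    stop("Savitzky-Golay window must be odd (got ", window, ")")
  if (window <= polyorder)
    stop("window must exceed the polynomial order")
  if (deriv > polyorder)
    stop("derivative order cannot exceed the polynomial order")
  if (is.matrix(x)) {
    if (ncol(x) < window)
      stop("spectrum length ", ncol(x), " shorter than window ", window)
    return(t(apply(x, 1L, signal::sgolayfilt,
                   p = polyorder, n = window, m = deriv, ts = delta)))
  }
  if (length(x) < window)
    stop("spectrum length ", length(x), " shorter than window ", window)
  signal::sgolayfilt(x, p = polyorder, n = window, m = deriv, ts = delta)
}

#' Average raw replicates within each position
#'
#' Collapses a block of repeated measurements to one spectrum per position
#' by the channel-wise arithmetic mean. Metadata other than the replicate
#' index must be constant within a position.
#'
#' @param block a [spectra_block()] with a `replicate` column.
#' @return a [spectra_block()] with one row per position (replicate column
#'   dropped), positions in order of first appearance.
#' @export
average_replicates <- function(block) {
  stopifnot_block(block)
  if (is.null(block$meta$replicate))
    stop("block has no replicate index")
  pos <- block$meta$position
  upos <- unique(pos)
  keep <- c("position", "patient", "organ", "class")
  out_meta <- NULL
  out <- matrix(NA_real_, length(upos), ncol(block$intensity))
  for (i in seq_along(upos)) {
    rows <- which(pos == upos[i])
    sub <- block$meta[rows, keep, drop = FALSE]
    if (nrow(unique(sub)) != 1L)
      stop("conflicting metadata within position '", upos[i], "'")
    out[i, ] <- colMeans(block$intensity[rows, , drop = FALSE])
    out_meta <- rbind(out_meta, sub[1L, , drop = FALSE])
  }
  rownames(out_meta) <- NULL
  spectra_block(out, block$axis, block$modality, out_meta)
}

#' Series-wide min-max scaling
#'
#' Rescales a whole block of spectra with one common affine map so that the
#' global minimum over all entries becomes 0 and the global maximum becomes
#' 1. Every spectrum in the series is scaled with the same coefficients --
#' individual spectra need not span [0, 1]. This puts independently
#' preprocessed blocks on a common intensity footing before concatenation.
#'
#' @param x a [spectra_block()] or numeric matrix.
#' @return the rescaled object; the fitted `(min, max)` pair is attached as
#'   attribute `"minmax"`.
#' @export
minmax_block_scale <- function(x) {
  m <- if (inherits(x, "spectra_block")) x$intensity else x
  cf <- minmax_coefs(m)
  scaled <- minmax_apply(m, cf)
  if (inherits(x, "spectra_block")) {
    out <- spectra_block(scaled, x$axis, x$modality, x$meta)
    attr(out, "minmax") <- cf
    out
  } else {
    attr(scaled, "minmax") <- cf
    scaled
  }
}

minmax_coefs <- function(m) {
  lo <- min(m); hi <- max(m)
  if (hi == lo) stop("min-max scaling undefined for a constant block")
  c(min = lo, max = hi)
}

minmax_apply <- function(m, coefs) {
  (m - coefs[["min"]]) / (coefs[["max"]] - coefs[["min"]])
}

#' Preprocessing chain specification
#'
#' Parses the short chain vocabulary used throughout reports: `"none"`,
#' `"snv"`, `"1d"`, `"2d"`, `"1d+snv"`, `"2d+snv"` (derivative first, then
#' SNV — chain order is significant). The window defaults to the modality
#' convention at application time: 25 channels for NIR, 9 for MIR (the
#' nearest odd width to the 8-point convention, which cannot be centred).
#'
#' @param chain chain label (see above).
#' @param window odd Savitzky-Golay window width, or `NULL` for the
#'   modality default.
#' @param polyorder Savitzky-Golay polynomial degree.
#' @param minmax apply the series-wide min-max scaling as the final step.
#' @return An object of class `preprocess_spec`.
#' @export
preprocess_spec <- function(chain = "none", window = NULL, polyorder = 2,
                            minmax = TRUE) {
  known <- c("none", "snv", "1d", "2d", "1d+snv", "2d+snv")
  if (!chain %in% known)
    stop("unknown chain '", chain, "'; expected one of: ",
         paste(known, collapse = ", "))
  steps <- switch(chain,
    "none"   = list(),
    "snv"    = list(list(op = "snv")),
    "1d"     = list(list(op = "deriv", order = 1L)),
    "2d"     = list(list(op = "deriv", order = 2L)),
    "1d+snv" = list(list(op = "deriv", order = 1L), list(op = "snv")),
    "2d+snv" = list(list(op = "deriv", order = 2L), list(op = "snv")))
  if (!is.null(window)) {
    if (window %% 2 == 0) stop("window must be odd")
    if (window <= polyorder) stop("window must exceed polyorder")
  }
  structure(list(chain = chain, steps = steps, window = window,
                 polyorder = polyorder, minmax = minmax),
            class = "preprocess_spec")
}

#' @export
print.preprocess_spec <- function(x, ...) {
  cat("<preprocess_spec> ", x$chain,
      if (x$minmax) " + block min-max" else "", "\n", sep = "")
  invisible(x)
}

default_window <- function(modality) if (modality == "nir") 25L else 9L

## Fold-independent part of a chain: per-row operations only (no min-max).
## Safe to precompute once, outside any cross-validation split.
apply_chain_rows <- function(block, spec) {
  stopifnot_block(block)
  m <- block$intensity
  w <- if (is.null(spec$window)) default_window(block$modality) else spec$window
  step <- mean(diff(block$axis))
  for (s in spec$steps) {
    m <- switch(s$op,
      snv = snv(m),
      deriv = savgol(m, window = w, polyorder = spec$polyorder,
                     deriv = s$order, delta = step),
      stop("unknown preprocessing op '", s$op, "'"))
  }
  spectra_block(m, block$axis, block$modality, block$meta)
}

#' Apply a preprocessing chain to a block
#'
#' Applies the chain's operations in order to every spectrum (row), then —
#' when the spec flags it — the series-wide min-max scaling as the final
#' step.
#'
#' @param block a [spectra_block()].
#' @param spec a [preprocess_spec()].
#' @return the preprocessed [spectra_block()].
#' @export
apply_chain <- function(block, spec) {
  stopifnot(inherits(spec, "preprocess_spec"))
  out <- apply_chain_rows(block, spec)
  if (spec$minmax) out <- minmax_block_scale(out)
  out
}

#' Subtract a background spectrum
#'
#' Optional hook for background correction (e.g. a saline reference in
#' contact-probe MIR measurements): subtracts one fixed spectrum from every
#' row before any other preprocessing.
#'
#' @param block a [spectra_block()].
#' @param background numeric vector on the block's channel grid.
#' @return the corrected [spectra_block()].
#' @export
subtract_background <- function(block, background) {
  stopifnot_block(block)
  if (length(background) != ncol(block$intensity))
    stop("background length does not match the block's channel count")
  spectra_block(sweep(block$intensity, 2L, background), block$axis,
                block$modality, block$meta)
}
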