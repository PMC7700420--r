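#' Pair positions measured by both modalities
#'
#' Restricts two blocks to the measurement positions present in both,
#' sorted identically, and verifies that the shared metadata agree.
#'
#' @param mir,nir [spectra_block()]s carrying position ids (one row per
#'   position, i.e. after [average_replicates()]).
#' @return list with the paired blocks `mir` and `nir`.
#' @export
pair_positions <- function(mir, nir) {
  stopifnot_block(mir); stopifnot_block(nir)
  common <- intersect(mir$meta$position, nir$meta$position)
  if (!length(common))
    warning("no positions shared between the two blocks")
  common <- sort(common)
  im <- match(common, mir$meta$position)
  ii <- match(common, nir$meta$position)
  keep <- c("position", "patient", "organ", "class")
  a <- mir$meta[im, keep]; b <- nir$meta[ii, keep]
  rownames(a) <- rownames(b) <- NULL
  if (!identical(a, b)) {
    off <- which(rowSums(a != b) > 0)
    stop("conflicting metadata for shared position(s): ",
         paste(utils::head(common[off], 5L), collapse = ", "))
  }
  list(mir = mir[im], nir = nir[ii])
}

#' Low-level fusion: concatenate two preprocessed blocks
#'
#' Horizontally concatenates a paired MIR and NIR block (MIR columns first)
#' into one feature matrix. Equal contribution of the two instruments is
#' enforced structurally: by default each block must already be min-max
#' scaled so its global range is [0, 1] (within 1e-9). During
#' cross-validation, where held-out rows are scaled with training-fold
#' coefficients and may fall slightly outside [0, 1], the check is relaxed
#' with `check = "none"`.
#'
#' @param mir,nir paired [spectra_block()]s (identical position order).
#' @param check `"unit"` (default) to enforce the [0, 1] global-range
#'   contract, `"none"` to skip it.
#' @param weights optional length-2 multiplicative block weights
#'   (MIR, NIR); default `c(1, 1)` — equal contribution.
#' @return An object of class `fused_block`: fields `intensity`, `boundary`
#'   (number of MIR columns), `axis_mir`, `axis_nir`, `meta`, `provenance`.
#' @export
concatenate_blocks <- function(mir, nir, check = c("unit", "none"),
                               weights = c(1, 1)) {
  check <- match.arg(check)
  stopifnot_block(mir); stopifnot_block(nir)
  if (nrow(mir$intensity) != nrow(nir$intensity) ||
      !identical(mir$meta$position, nir$meta$position))
    stop("blocks are not paired; run pair_positions() first")
  if (check == "unit") {
    for (b in list(MIR = mir, NIR = nir)) {
      rng <- range(b$intensity)
      if (abs(rng[1]) > 1e-9 || abs(rng[2] - 1) > 1e-9)
        stop("block global range is not [0, 1]; apply minmax_block_scale() ",
             "before fusion (got [", format(rng[1]), ", ", format(rng[2]), "])")
    }
  }
  m <- cbind(mir$intensity * weights[1], nir$intensity * weights[2])
  colnames(m) <- c(paste0("mir_", format_axis_names(mir$axis)),
                   paste0("nir_", format_axis_names(nir$axis)))
  structure(
    list(intensity = m, boundary = ncol(mir$intensity),
         axis_mir = mir$axis, axis_nir = nir$axis,
         meta = mir$meta,
         provenance = list(weights = weights)),
    class = "fused_block"
  )
}

#' @export
print.fused_block <- function(x, ...) {
  cat("<fused_block> ", nrow(x$intensity), " positions x ",
      ncol(x$intensity), " channels (MIR 1..", x$boundary, " | NIR ",
      x$boundary + 1L, "..", ncol(x$intensity), ")\n", sep = "")
  invisible(x)
}

#' @export
dim.fused_block <- function(x) dim(x$intensity)

#' Recover the parent blocks of a fused matrix
#'
#' Column-slices a [concatenate_blocks()] result back into its MIR and NIR
#' parents (undoing any block weights).
#'
#' @param fused a `fused_block`.
#' @return list with [spectra_block()]s `mir` and `nir`.
#' @export
split_fused <- function(fused) {
  stopifnot(inherits(fused, "fused_block"))
  w <- fused$provenance$weights
  k <- fused$boundary
  list(
    mir = spectra_block(fused$intensity[, seq_len(k), drop = FALSE] / w[1],
                        fused$axis_mir, "mir", fused$meta),
    nir = spectra_block(fused$intensity[, -seq_len(k), drop = FALSE] / w[2],
                        fused$axis_nir, "nir", fused$meta)
  )
}
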