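#' Spectral block container
#'
#' A `spectra_block` holds an aligned matrix of spectra for one modality
#' (rows are measurement positions or raw replicates, columns are channels)
#' together with the channel axis and per-row metadata.
#'
#' @param intensity numeric matrix, rows x channels.
#' @param axis numeric vector of channel positions (wavenumber in cm^-1 for
#'   MIR, wavelength in nm for NIR), strictly increasing, length `ncol(intensity)`.
#' @param modality `"mir"` or `"nir"`.
#' @param meta data frame with one row per spectrum. Must contain columns
#'   `position`, `patient`, `organ` and `class` (`"N"`/`"T"`); a `replicate`
#'   column marks raw repeated measurements.
#'
#' @return An object of class `spectra_block`.
#' @export
spectra_block <- function(intensity, axis, modality = c("mir", "nir"), meta) {
  modality <- match.arg(modality)
  intensity <- as.matrix(intensity)
  storage.mode(intensity) <- "double"
  axis <- as.numeric(axis)
  if (length(axis) != ncol(intensity))
    stop("axis length (", length(axis), ") != number of channels (",
         ncol(intensity), ")")
  if (length(axis) > 1L && any(diff(axis) <= 0))
    stop("axis must be strictly increasing")
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  if (nrow(meta) != nrow(intensity))
    stop("meta has ", nrow(meta), " rows but intensity has ", nrow(intensity))
  required <- c("position", "patient", "organ", "class")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols))
    stop("meta is missing columns: ", paste(missing_cols, collapse = ", "))
  bad <- !meta$class %in% c("N", "T")
  if (any(bad))
    stop("class labels must be 'N' or 'T'; offending rows: ",
         paste(utils::head(which(bad), 5L), collapse = ", "))
  colnames(intensity) <- format_axis_names(axis)
  structure(
    list(intensity = intensity, axis = axis, modality = modality, meta = meta),
    class = "spectra_block"
  )
}

format_axis_names <- function(axis) {
  sprintf("%g", axis)
}

#' @export
print.spectra_block <- function(x, ...) {
  cat("<spectra_block> ", toupper(x$modality), ": ",
      nrow(x$intensity), " spectra x ", ncol(x$intensity), " channels [",
      format(min(x$axis)), "..", format(max(x$axis)), " ",
      if (x$modality == "mir") "cm^-1" else "nm", "]\n", sep = "")
  tab <- table(x$meta$organ, x$meta$class)
  print(tab)
  invisible(x)
}

#' @export
dim.spectra_block <- function(x) dim(x$intensity)

#' Subset a spectral block by rows
#'
#' @param x a `spectra_block`.
#' @param i row index (integer, logical or position ids are not interpreted --
#'   plain row indexing).
#' @param ... ignored.
#' @return A `spectra_block` with the selected rows.
#' @export
`[.spectra_block` <- function(x, i, ...) {
  spectra_block(x$intensity[i, , drop = FALSE], x$axis, x$modality,
                x$meta[i, , drop = FALSE])
}

#' Default MIR channel grid
#'
#' Fingerprint-region grid, 1800 down to 900 cm^-1 at 8 cm^-1 resolution
#' (113 channels), stored in increasing wavenumber order; the instrument's
#' descending-wavenumber convention is a display concern only.
#'
#' @return numeric vector of 113 wavenumbers (cm^-1).
#' @export
mir_axis <- function() rev(seq(1800, by = -8, length.out = 113L))

#' Default NIR channel grid
#'
#' 900 to 1700 nm at 1.66 nm resolution (482 channels).
#'
#' @return numeric vector of 482 wavelengths (nm).
#' @export
nir_axis <- function() seq(900, by = 1.66, length.out = 482L)

stopifnot_block <- function(x, arg = deparse(substitute(x))) {
  if (!inherits(x, "spectra_block"))
    stop(arg, " must be a spectra_block")
  invisible(x)
}
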