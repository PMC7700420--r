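#' Write a spectral block to CSV
#'
#' One row per spectrum: position id, metadata columns, then one column per
#' channel headed by its axis value.
#'
#' @param block a [spectra_block()].
#' @param path output CSV file.
#' @return `path`, invisibly.
#' @export
write_spectra_csv <- function(block, path) {
  stopifnot_block(block)
  df <- cbind(block$meta, as.data.frame(block$intensity))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a spectral block from CSV
#'
#' Inverse of [write_spectra_csv()]: metadata columns are recognised by
#' name, every remaining column is a channel whose header parses as the
#' axis value.
#'
#' @param path CSV file.
#' @param modality `"mir"` or `"nir"`.
#' @return a [spectra_block()].
#' @export
read_spectra_csv <- function(path, modality) {
  df <- utils::read.csv(path, check.names = FALSE,
                        stringsAsFactors = FALSE)
  meta_cols <- intersect(c("position", "patient", "organ", "class",
                           "replicate"), names(df))
  chan_cols <- setdiff(names(df), meta_cols)
  axis <- as.numeric(chan_cols)
  if (anyNA(axis))
    stop("non-numeric channel headers: ",
         paste(utils::head(chan_cols[is.na(axis)], 5L), collapse = ", "))
  spectra_block(as.matrix(df[chan_cols]), axis, modality,
                df[meta_cols])
}

#' Write a paired cohort to a directory
#'
#' Writes `mir.csv`, `nir.csv` and a `cohort.json` sidecar with the axis
#' units and the generation configuration.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "spectra_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_spectra_csv(cohort$mir, file.path(dir, "mir.csv"))
  write_spectra_csv(cohort$nir, file.path(dir, "nir.csv"))
  sidecar <- list(
    axis_units = list(mir = "cm^-1", nir = "nm"),
    config = unclass(cohort$config)
  )
  jsonlite::write_json(sidecar, file.path(dir, "cohort.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a paired cohort written by [write_cohort()]
#'
#' @param dir directory containing `mir.csv` and `nir.csv`.
#' @return list with [spectra_block()]s `mir` and `nir` (class
#'   `spectra_cohort`; the `config` element holds the sidecar config when
#'   present).
#' @export
read_cohort <- function(dir) {
  cfg <- NULL
  sc <- file.path(dir, "cohort.json")
  if (file.exists(sc)) cfg <- jsonlite::read_json(sc)$config
  structure(
    list(mir = read_spectra_csv(file.path(dir, "mir.csv"), "mir"),
         nir = read_spectra_csv(file.path(dir, "nir.csv"), "nir"),
         config = cfg),
    class = "spectra_cohort"
  )
}
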