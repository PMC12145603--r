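# Spectrum-set container and plain-text IO.

#' Construct a spectrum set
#'
#' A spectrum set holds a common chemical-shift axis, one intensity row per
#' sample, and the sample metadata (donor, arm, day, replicate,
#' compartment). The axis is stored ascending; the conventional descending
#' NMR display is a plotting concern only.
#'
#' @param ppm Strictly monotone numeric axis (ppm), stored ascending.
#' @param intensity Numeric matrix, one row per sample, `length(ppm)` columns.
#' @param meta Data frame of per-sample metadata; must contain `sample_id`.
#' @return An object of class `spectrum_set`.
#' @export
spectrum_set <- function(ppm, intensity, meta) {
  if (is.null(dim(intensity))) intensity <- matrix(intensity, nrow = 1)
  stopifnot(length(ppm) == ncol(intensity),
            nrow(meta) == nrow(intensity),
            "sample_id" %in% names(meta))
  d <- diff(ppm)
  if (!(all(d > 0) || all(d < 0))) stop("ppm axis must be strictly monotone")
  if (all(d < 0)) { ppm <- rev(ppm); intensity <- intensity[, rev(seq_along(ppm)), drop = FALSE] }
  rownames(intensity) <- meta$sample_id
  structure(list(ppm = ppm, intensity = intensity, meta = meta),
            class = "spectrum_set")
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat("<spectrum_set> ", nrow(x$intensity), " spectra x ", length(x$ppm),
      " points, ", sprintf("%.3f..%.3f ppm\n", min(x$ppm), max(x$ppm)),
      sep = "")
  invisible(x)
}

#' @export
`[.spectrum_set` <- function(x, i, ...) {
  spectrum_set(x$ppm, x$intensity[i, , drop = FALSE],
               x$meta[i, , drop = FALSE])
}

#' Number of spectra in a set
#' @param x A `spectrum_set`.
#' @return Integer count.
#' @export
n_spectra <- function(x) nrow(x$intensity)

#' Write a spectrum set as two-column text files plus a sample sheet
#'
#' Each spectrum is written as `<sample_id>.txt` with tab-separated
#' `ppm intensity` columns; the metadata goes to `sample_sheet.csv`.
#'
#' @param x A `spectrum_set`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_spectra <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, paste0(x$meta$sample_id, ".txt"))
  for (i in seq_len(n_spectra(x))) {
    utils::write.table(
      data.frame(ppm = sprintf("%.6f", x$ppm),
                 intensity = sprintf("%.8g", x$intensity[i, ])),
      paths[i], sep = "\t", quote = FALSE, row.names = FALSE)
  }
  sheet <- file.path(dir, "sample_sheet.csv")
  utils::write.csv(x$meta, sheet, row.names = FALSE)
  invisible(c(paths, sheet))
}

#' Read a spectrum set written by [write_spectra()]
#'
#' @param dir Directory containing `sample_sheet.csv` and per-sample
#'   two-column text files.
#' @return A `spectrum_set`.
#' @export
read_spectra <- function(dir) {
  meta <- utils::read.csv(file.path(dir, "sample_sheet.csv"))
  specs <- lapply(meta$sample_id, function(id) {
    utils::read.table(file.path(dir, paste0(id, ".txt")), header = TRUE)
  })
  ppm <- specs[[1]]$ppm
  for (s in specs) {
    if (length(s$ppm) != length(ppm) || max(abs(s$ppm - ppm)) > 1e-9)
      stop("spectra do not share a common axis")
  }
  spectrum_set(ppm, do.call(rbind, lapply(specs, function(s) s$intensity)),
               meta)
}
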