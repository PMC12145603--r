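# Window integration of named metabolite signals and marker ratios.

#' Integrate metabolite windows of a spectrum set
#'
#' Computes the trapezoidal integral of each spectrum over each named ppm
#' window. A window overlapping the set's excluded regions by more than
#' half its width yields an explicit missing value and a flag; partial
#' overlaps are integrated over the retained contiguous runs only.
#'
#' @param x A `spectrum_set` (typically referenced, aligned, excluded and,
#'   for cell extracts, total-area normalized).
#' @param windows Data frame with columns `name`, `lo`, `hi` (ppm), e.g.
#'   [library_windows()].
#' @return An integral table: the sample metadata plus one column per
#'   metabolite. Attributes: `provenance` (the windows with their excluded
#'   overlap fraction and `flagged` status), `total_area` (per-sample
#'   retained intensity sums of `x`).
#' @export
integrate_windows <- function(x, windows) {
  stopifnot(all(c("name", "lo", "hi") %in% names(windows)),
            all(windows$hi > windows$lo))
  excl <- attr(x, "excluded_regions")
  overlap <- vapply(seq_len(nrow(windows)), function(w) {
    if (is.null(excl)) return(0)
    ov <- 0
    for (r in seq_len(nrow(excl)))
      ov <- ov + max(0, min(windows$hi[w], excl[r, 2]) -
                        max(windows$lo[w], excl[r, 1]))
    ov / (windows$hi[w] - windows$lo[w])
  }, numeric(1))
  flagged <- overlap > 0.5

  step <- stats::median(diff(x$ppm))
  vals <- matrix(NA_real_, n_spectra(x), nrow(windows),
                 dimnames = list(x$meta$sample_id, windows$name))
  for (w in seq_len(nrow(windows))) {
    if (flagged[w]) next
    idx <- which(x$ppm >= windows$lo[w] & x$ppm <= windows$hi[w])
    if (length(idx) < 2L) { flagged[w] <- TRUE; next }
    # integrate per contiguous run so exclusion gaps are not bridged
    runs <- split(idx, cumsum(c(1, diff(x$ppm[idx]) > 1.5 * step)))
    for (i in seq_len(n_spectra(x))) {
      vals[i, w] <- sum(vapply(runs, function(r)
        trapz(x$ppm[r], x$intensity[i, r]), numeric(1)))
    }
  }
  prov <- cbind(windows, excluded_overlap = overlap, flagged = flagged)
  out <- cbind(x$meta, as.data.frame(vals, check.names = FALSE))
  rownames(out) <- NULL
  attr(out, "provenance") <- prov
  attr(out, "total_area") <- attr(x, "total_area") %||%
    stats::setNames(rowSums(x$intensity), x$meta$sample_id)
  out
}

#' Per-sample ratio of two metabolite columns
#'
#' Marker ratios such as Cho/PCho, Etn/PEtn and HTau/Tau. Nonpositive
#' denominators yield missing values, never infinities.
#'
#' @param table An integral table (data frame with metabolite columns).
#' @param num,den Numerator and denominator metabolite names.
#' @return Numeric vector of per-sample ratios.
#' @export
compute_ratio <- function(table, num, den) {
  if (!num %in% names(table)) stop("missing column: ", num)
  if (!den %in% names(table)) stop("missing column: ", den)
  d <- table[[den]]
  out <- table[[num]] / d
  out[!is.na(d) & d <= 0] <- NA_real_
  out
}
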