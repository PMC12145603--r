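# Spectral preprocessing: TSP referencing, region exclusion, recursive
# segment-wise alignment, total-area normalization.

#' Default exclusion masks
#'
#' Closed ppm intervals removed before multivariate analysis: water
#' (5.2-4.5) and TSP (0.6-0.0) for all spectra, methanol (3.3-3.4,
#' extraction solvent) and ethanol (1.1-1.2, 3.6-3.7, cleaning solvent) for
#' cell extracts; media spectra additionally exclude beta-GP/glycerol
#' (3.5-3.9, 4.1-4.2, osteogenic supplement and hydrolysis product) and
#' DMSO (2.7-2.8, dexamethasone solvent).
#'
#' @param compartment `"cell"` or `"media"`.
#' @return Two-column matrix of `(lo, hi)` ppm intervals.
#' @export
default_exclusions <- function(compartment = c("cell", "media")) {
  compartment <- match.arg(compartment)
  endo <- rbind(c(4.5, 5.2), c(0.0, 0.6), c(3.3, 3.4), c(1.1, 1.2),
                c(3.6, 3.7))
  m <- if (compartment == "cell") endo else
    rbind(endo, c(3.5, 3.9), c(4.1, 4.2), c(2.7, 2.8))
  colnames(m) <- c("lo", "hi")
  m
}

merge_regions <- function(regions) {
  if (is.null(regions) || nrow(regions) == 0L) return(regions)
  r <- regions[order(regions[, 1]), , drop = FALSE]
  out <- r[1, , drop = FALSE]
  for (i in seq_len(nrow(r))[-1]) {
    if (r[i, 1] <= out[nrow(out), 2]) {
      out[nrow(out), 2] <- max(out[nrow(out), 2], r[i, 2])
    } else out <- rbind(out, r[i, , drop = FALSE])
  }
  out
}

#' Reference spectra to the TSP peak at 0.00 ppm
#'
#' Shifts each spectrum's axis so that the maximum inside the search window
#' sits at 0.00 ppm, then resamples onto the set's common grid (linear
#' interpolation). Intensities are otherwise unchanged.
#'
#' @param x A `spectrum_set`.
#' @param search_window ppm interval searched for the TSP maximum.
#' @return The referenced `spectrum_set` with per-sample shifts in
#'   `attr(, "tsp_shift")`.
#' @export
reference_to_tsp <- function(x, search_window = c(-0.1, 0.1)) {
  idx <- which(x$ppm >= search_window[1] & x$ppm <= search_window[2])
  if (length(idx) < 3L) stop("TSP search window contains too few points")
  shifts <- numeric(n_spectra(x))
  out <- x$intensity
  for (i in seq_len(n_spectra(x))) {
    seg <- x$intensity[i, idx]
    if (max(seg) - min(seg) <= 0)
      stop("flat TSP window: cannot reference spectrum ", x$meta$sample_id[i])
    shifts[i] <- x$ppm[idx[which.max(seg)]]
    if (shifts[i] != 0)
      out[i, ] <- stats::approx(x$ppm - shifts[i], x$intensity[i, ],
                                xout = x$ppm, rule = 2)$y
  }
  res <- spectrum_set(x$ppm, out, x$meta)
  attr(res, "tsp_shift") <- -shifts
  res
}

#' Exclude spectral regions
#'
#' Removes all grid points falling inside any of the closed ppm intervals
#' of the mask; overlapping intervals are merged before application. The
#' excluded regions are recorded so that downstream integration can flag
#' windows that fall inside them.
#'
#' @param x A `spectrum_set`.
#' @param regions Two-column matrix/data frame of `(lo, hi)` ppm intervals,
#'   e.g. [default_exclusions()].
#' @return The reduced `spectrum_set`; excluded intervals (merged) in
#'   `attr(, "excluded_regions")`.
#' @export
exclude_regions <- function(x, regions) {
  regions <- as.matrix(regions)
  prior <- attr(x, "excluded_regions")
  if (is.null(regions) || nrow(regions) == 0L) {
    res <- x
    attr(res, "excluded_regions") <- prior
    return(res)
  }
  regions <- merge_regions(regions)
  drop <- rep(FALSE, length(x$ppm))
  for (i in seq_len(nrow(regions)))
    drop <- drop | (x$ppm >= regions[i, 1] & x$ppm <= regions[i, 2])
  res <- spectrum_set(x$ppm[!drop], x$intensity[, !drop, drop = FALSE],
                      x$meta)
  all_regions <- merge_regions(rbind(prior, regions))
  attr(res, "excluded_regions") <- all_regions
  res
}

#' Normalize each spectrum to unit total area
#'
#' Divides intensities by their sum over the retained (post-exclusion)
#' points, removing cell-number / dilution scale differences. The original
#' totals are kept as `attr(, "total_area")`.
#'
#' @param x A `spectrum_set`.
#' @return The normalized set; retained intensities of every spectrum sum
#'   to 1.
#' @export
normalize_total_area <- function(x) {
  totals <- rowSums(x$intensity)
  if (any(totals <= 0))
    stop("nonpositive total area for: ",
         paste(x$meta$sample_id[totals <= 0], collapse = ", "))
  res <- spectrum_set(x$ppm, x$intensity / totals, x$meta)
  attr(res, "excluded_regions") <- attr(x, "excluded_regions")
  attr(res, "total_area") <- stats::setNames(totals, x$meta$sample_id)
  res
}

#' Recursive segment-wise peak alignment
#'
#' Aligns every spectrum to a reference (default: point-wise median
#' spectrum) by recursive binary segmentation: each segment receives the
#' integer grid shift maximizing its cross-correlation with the reference,
#' bounded by `max_shift`; segments at least `2 * min_segment` points long
#' are split and their halves refined recursively. Ties in the
#' cross-correlation are broken toward zero shift. The per-point shift map
#' is blended linearly across segment seams and applied by linear
#' interpolation, preserving the total integral to well within 0.5%.
#'
#' @param x A `spectrum_set` on a common uniform axis.
#' @param reference Reference intensity vector, or `NULL` for the median
#'   spectrum.
#' @param max_shift Maximum allowed local shift (ppm).
#' @param min_segment Minimum segment length (points).
#' @return The aligned `spectrum_set`, with the per-spectrum top-level
#'   shifts (grid steps) in `attr(, "global_shift")`.
#' @export
align_segments <- function(x, reference = NULL, max_shift = 0.02,
                           min_segment = 64) {
  stopifnot(max_shift > 0)
  np <- length(x$ppm)
  if (min_segment > np)
    stop("min_segment exceeds the spectrum length")
  step <- stats::median(diff(x$ppm))
  max_pts <- max(1L, round(max_shift / step))
  ref <- reference %||% apply(x$intensity, 2, stats::median)
  stopifnot(length(ref) == np)

  out <- x$intensity
  top <- numeric(n_spectra(x))
  for (i in seq_len(n_spectra(x))) {
    al <- align_one(x$intensity[i, ], ref, max_pts, min_segment)
    out[i, ] <- al$y
    top[i] <- al$top_shift
  }
  res <- spectrum_set(x$ppm, out, x$meta)
  attr(res, "excluded_regions") <- attr(x, "excluded_regions")
  attr(res, "global_shift") <- top
  res
}

# integer shift of y against ref maximizing the dot product; ties -> 0
best_shift <- function(y, ref, max_pts) {
  n <- length(y)
  max_pts <- min(max_pts, n - 1L)
  shifts <- -max_pts:max_pts
  score <- vapply(shifts, function(s) {
    if (s >= 0) sum(y[seq_len(n - s)] * ref[(1 + s):n])
    else sum(y[(1 - s):n] * ref[seq_len(n + s)])
  }, numeric(1))
  best <- max(score)
  cand <- shifts[score >= best - 1e-12 * abs(best)]
  cand[which.min(abs(cand))]
}

align_one <- function(y, ref, max_pts, min_segment) {
  n <- length(y)
  shift_map <- numeric(n)
  # a segment is only shifted when the reference carries appreciable
  # signal there; purely flat/noise segments keep their parent's shift,
  # so spurious noise-driven shifts cannot bleed into neighbouring peaks
  noise_est <- stats::mad(diff(ref)) / sqrt(2)
  has_signal <- function(lo, hi) {
    seg <- ref[lo:hi]
    max(seg) - stats::median(seg) > 8 * noise_est
  }
  # each segment refines its parent's accumulated shift `acc`; the segment
  # is compared to the reference after applying acc, so child shifts are
  # corrections, all bounded by max_pts per level
  rec2 <- function(lo, hi, acc) {
    len <- hi - lo + 1L
    s <- 0L
    if (has_signal(lo, hi)) {
      ys <- shift_vector(y, acc)[lo:hi]
      s <- best_shift(ys, ref[lo:hi], max_pts)
    }
    shift_map[lo:hi] <<- acc + s
    if (len >= 2L * min_segment) {
      mid <- lo + len %/% 2L
      rec2(lo, mid - 1L, acc + s)
      rec2(mid, hi, acc + s)
    }
  }
  rec2(1L, n, 0)
  top <- shift_map[1L]
  sm <- smooth_seams(shift_map, blend = 8L)
  idx <- seq_len(n)
  yo <- stats::approx(idx + sm, y[idx], xout = idx, rule = 2,
                      ties = mean)$y
  list(y = yo, top_shift = top)
}

shift_vector <- function(y, s) {
  n <- length(y)
  s <- as.integer(round(s))
  if (s == 0L) return(y)
  if (s > 0) c(rep(y[1L], s), y[seq_len(n - s)])
  else c(y[(1L - s):n], rep(y[n], -s))
}

# linear blending of a piecewise-constant shift map around each
# discontinuity; the blend width adapts to the jump size so the remapped
# axis stays monotone (|slope| stays well below 1)
smooth_seams <- function(sm, blend = 8L) {
  n <- length(sm)
  jumps <- which(diff(sm) != 0)
  for (j in jumps) {
    half <- max(blend, 4L * abs(as.integer(sm[j + 1L] - sm[j])))
    lo <- max(1L, j - half + 1L)
    hi <- min(n, j + half)
    sm[lo:hi] <- seq(sm[lo], sm[hi], length.out = hi - lo + 1L)
  }
  sm
}
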