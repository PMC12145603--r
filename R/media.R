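# Cumulative blank-referenced correction of conditioned-media values
# across repeated media exchanges.

#' Construct a media series
#'
#' Holds, for one variable (spectral data point or signal integral) of one
#' culture, the raw replicate values over the sampling days, the mean
#' fresh-medium (blank) value applicable to each interval, and the total
#' spectral area of each replicate.
#'
#' @param days Strictly increasing sampling-day indices.
#' @param raw Matrix of raw values, `length(days)` rows x replicates
#'   columns; `NA` marks a missing replicate.
#' @param blank_mean Numeric vector, one mean blank value per interval
#'   (the fresh medium applied at the previous exchange); `NA` marks a
#'   missing blank.
#' @param total_area Matrix like `raw`: total spectral area of each
#'   replicate at each day.
#' @return An object of class `media_series`.
#' @export
media_series <- function(days, raw, blank_mean, total_area) {
  raw <- as.matrix(raw)
  total_area <- as.matrix(total_area)
  if (length(total_area) == 1L)
    total_area <- matrix(total_area, nrow(raw), ncol(raw))
  if (length(blank_mean) == 1L) blank_mean <- rep(blank_mean, length(days))
  stopifnot(length(days) == nrow(raw),
            all(dim(raw) == dim(total_area)),
            length(blank_mean) == length(days))
  if (any(diff(days) <= 0)) stop("days must be strictly increasing")
  structure(list(days = days, raw = raw, blank_mean = blank_mean,
                 total_area = total_area),
            class = "media_series")
}

#' Correct a media series for media exchanges and cell-number differences
#'
#' Applies, in day order, the recursion
#' \deqn{S_{i,j}^{corr} = \bar{S}_{i-1}^{corr} + (S_{i,j} - \bar{B}_{i-1}) / TA_{i,j}}
#' with \eqn{\bar{S}_0^{corr} = 0}: each replicate's corrected value is the
#' previous day's mean corrected value plus the area-normalized change of
#' the current medium relative to the fresh medium applied at the last
#' exchange. Positive trajectories indicate net secretion, negative net
#' uptake. Per-day means use the available replicates only; a day with no
#' replicates carries the most recent available mean forward with a
#' warning.
#'
#' @param m A [media_series()].
#' @return A list of class `corrected_series`: `days`, `corrected` (matrix
#'   like `raw`), `day_mean` (per-day means of the corrected replicates).
#' @export
correct_series <- function(m) {
  stopifnot(inherits(m, "media_series"))
  nT <- length(m$days)
  has_value <- !is.na(m$raw)
  if (any(m$total_area[has_value] <= 0, na.rm = TRUE))
    stop("total_area must be positive")
  miss_blank <- is.na(m$blank_mean) & rowSums(has_value) > 0
  if (any(miss_blank))
    stop("missing blank mean for interval ending at day ",
         m$days[which(miss_blank)[1]])
  corrected <- matrix(NA_real_, nT, ncol(m$raw),
                      dimnames = dimnames(m$raw))
  day_mean <- numeric(nT)
  prev_mean <- 0
  for (i in seq_len(nT)) {
    j <- has_value[i, ]
    corrected[i, j] <- prev_mean +
      (m$raw[i, j] - m$blank_mean[i]) / m$total_area[i, j]
    if (any(j)) {
      day_mean[i] <- mean(corrected[i, j])
    } else {
      warning("no replicates at day ", m$days[i],
              "; carrying forward the previous corrected mean")
      day_mean[i] <- prev_mean
    }
    prev_mean <- day_mean[i]
  }
  structure(list(days = m$days, corrected = corrected, day_mean = day_mean),
            class = "corrected_series")
}

#' Correct a table of media integrals
#'
#' Applies [correct_series()] to every metabolite column of a media
#' integral table, independently per (donor, arm) culture, using per-(arm,
#' day) blank means and per-sample total areas.
#'
#' @param media Data frame with columns `donor`, `arm`, `day`, `replicate`
#'   and one column per metabolite (raw integrals).
#' @param blanks Data frame with columns `arm`, `day`, `replicate` and the
#'   same metabolite columns (fresh-medium integrals for the batch applied
#'   at the previous exchange).
#' @param total_area Numeric vector of total spectral areas, one per row
#'   of `media`.
#' @param variables Metabolite column names; defaults to all non-metadata
#'   columns shared by `media` and `blanks`.
#' @return Data frame shaped like `media` with corrected values.
#' @export
correct_media_table <- function(media, blanks, total_area,
                                variables = NULL) {
  meta_cols <- c("sample_id", "donor", "arm", "day", "replicate",
                 "compartment")
  if (is.null(variables))
    variables <- setdiff(intersect(names(media), names(blanks)), meta_cols)
  stopifnot(length(total_area) == nrow(media), all(total_area > 0))
  out <- media
  days <- sort(unique(media$day))
  for (arm in unique(media$arm)) {
    bl <- blanks[blanks$arm == arm, ]
    for (donor in unique(media$donor[media$arm == arm])) {
      sel <- media$arm == arm & media$donor == donor
      reps <- sort(unique(media$replicate[sel]))
      for (v in variables) {
        raw <- matrix(NA_real_, length(days), length(reps),
                      dimnames = list(days, reps))
        ta <- raw
        for (k in which(sel)) {
          i <- match(media$day[k], days)
          j <- match(media$replicate[k], reps)
          raw[i, j] <- media[[v]][k]
          ta[i, j] <- total_area[k]
        }
        bv <- vapply(days, function(d) {
          rows <- bl$day == d
          if (!any(rows)) NA_real_ else mean(bl[[v]][rows])
        }, numeric(1))
        cs <- correct_series(media_series(days, raw, bv, ta))
        for (k in which(sel)) {
          i <- match(media$day[k], days)
          j <- match(media$replicate[k], reps)
          out[[v]][k] <- cs$corrected[i, j]
        }
      }
    }
  }
  out
}
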