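# Internal numerical and RNG helpers.

#' Lorentzian line shape
#'
#' Evaluates a Lorentzian (Cauchy) peak of given total area, centre and full
#' width at half maximum, the canonical line shape of a well-shimmed 1D NMR
#' resonance.
#'
#' @param x Numeric vector of chemical-shift positions (ppm).
#' @param center Peak centre (ppm).
#' @param area Total (analytic) peak area, in intensity x ppm units.
#' @param fwhm Full width at half maximum (ppm); must be > 0.
#' @return Numeric vector of intensities at `x`.
#' @examples
#' pp <- seq(-0.2, 0.2, length.out = 401)
#' y <- lorentzian(pp, 0, area = 1, fwhm = 0.01)
#' @export
lorentzian <- function(x, center, area, fwhm) {
  stopifnot(fwhm > 0)
  hw <- fwhm / 2
  area * hw / (pi * ((x - center)^2 + hw^2))
}

#' Trapezoidal integral
#'
#' @param x Ordinate vector (strictly monotone).
#' @param y Values at `x`.
#' @return Scalar trapezoidal integral.
#' @export
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

# Evaluate code with a temporary RNG state seeded from `seed`, restoring the
# caller's stream afterwards so simulation determinism never leaks.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Derive a stream-specific 31-bit sub-seed from a master seed.
derive_seed <- function(seed, stream) {
  (as.numeric(seed) * 48271 + 7919 * stream) %% 2147483647
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# memoised combn(n, k) index matrices for the exact rank-sum enumeration
.combn_cache <- new.env(parent = emptyenv())
cached_combn <- function(n, k) {
  key <- paste0(n, "_", k)
  got <- .combn_cache[[key]]
  if (is.null(got)) {
    got <- utils::combn(n, k)
    .combn_cache[[key]] <- got
  }
  got
}

# Piecewise-linear interpolation of effect knots, constant beyond the range.
interp_knots <- function(days, values, at) {
  stats::approx(days, values, xout = at, rule = 2)$y
}
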