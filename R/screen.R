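# Univariate screening: exact Wilcoxon rank-sum, percent-variation
# trajectories, donor-independent signature selection, Spearman maps.

#' Exact two-sided Wilcoxon rank-sum p-value
#'
#' For combined group sizes up to 12, the null distribution of the
#' rank-sum statistic (mid-ranks for ties) is enumerated completely over
#' all group assignments; above that a normal approximation with tie
#' correction and continuity correction is used. The two-sided p-value is
#' the null probability of a rank-sum at least as far from its expectation
#' as observed.
#'
#' @param a,b Numeric value vectors (each non-empty).
#' @return Two-sided p-value in (0, 1].
#' @export
wilcoxon_exact <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  na <- length(a); nb <- length(b)
  if (na == 0L || nb == 0L) stop("both groups must be non-empty")
  r <- rank(c(a, b))
  W <- sum(r[seq_len(na)])
  mu <- na * mean(r)
  if (na + nb <= 12L) {
    cmb <- cached_combn(na + nb, na)
    Wnull <- colSums(matrix(r[cmb], nrow = na))
    p <- mean(abs(Wnull - mu) >= abs(W - mu) - 1e-9)
  } else {
    n <- na + nb
    ties <- table(r)
    sigma2 <- na * nb / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) return(1)
    z <- (abs(W - mu) - 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-max(z, 0)))
  }
  p
}

#' Percent variation between two groups
#'
#' `100 * (mean(oi) - mean(ctr)) / mean(ctr)`; the sign encodes the
#' direction of the change. With `denom = "abs"` the denominator is
#' `|mean(ctr)|`, appropriate for signed quantities such as corrected
#' media trajectories where the control itself may be negative (net
#' uptake).
#'
#' @param ctr,oi Numeric vectors (reference and comparison groups).
#' @param denom `"signed"` (default) or `"abs"`.
#' @return Percent variation (scalar).
#' @export
percent_variation <- function(ctr, oi, denom = c("signed", "abs")) {
  denom <- match.arg(denom)
  mc <- mean(ctr, na.rm = TRUE)
  if (mc == 0) return(NA_real_)
  d <- if (denom == "abs") abs(mc) else mc
  100 * (mean(oi, na.rm = TRUE) - mc) / d
}

#' Univariate marker screen
#'
#' Computes, per metabolite, donor and day, the percent variation of the
#' OI arm relative to same-day CTR (`mode = "differentiation"`) or of each
#' day relative to day `ref_day` within one arm (`mode = "proliferation"`),
#' with exact Wilcoxon rank-sum p-values. Per-donor p-values are only
#' reported when both groups have at least 3 replicates (`visual_only`
#' flags smaller groups); a pooled p-value across donors is always
#' computed per (metabolite, day).
#'
#' @param table Integral (or corrected-media) table: data frame with
#'   `donor`, `arm`, `day`, `replicate` and metabolite columns.
#' @param variables Metabolite column names (default: all non-metadata).
#' @param mode `"differentiation"` or `"proliferation"`.
#' @param arm Arm screened in proliferation mode.
#' @param ref_day Reference day in proliferation mode.
#' @param denom Passed to [percent_variation()]; use `"abs"` for corrected
#'   media tables.
#' @return List of class `screen_result`: `per_donor` (metabolite, donor,
#'   day, pct_var, p, n_ref, n_cmp, visual_only), `pooled` (metabolite,
#'   day, pct_var, p), plus the call parameters.
#' @export
screen_markers <- function(table, variables = NULL,
                           mode = c("differentiation", "proliferation"),
                           arm = "CTR", ref_day = NULL,
                           denom = c("signed", "abs")) {
  mode <- match.arg(mode)
  denom <- match.arg(denom)
  meta_cols <- c("sample_id", "donor", "arm", "day", "replicate",
                 "compartment")
  variables <- variables %||% setdiff(names(table), meta_cols)
  if (mode == "proliferation") {
    table <- table[table$arm == arm, ]
    ref_day <- ref_day %||% min(table$day)
  }
  donors <- sort(unique(table$donor))
  days <- sort(unique(table$day))
  if (mode == "proliferation") days <- setdiff(days, ref_day)

  # precompute group row indices once; the per-variable loop then works on
  # plain numeric vectors
  ref_idx <- list(); cmp_idx <- list()
  for (dn in donors) for (d in days) {
    key <- paste(dn, d)
    if (mode == "differentiation") {
      ref_idx[[key]] <- which(table$donor == dn & table$arm == "CTR" &
                                table$day == d)
      cmp_idx[[key]] <- which(table$donor == dn & table$arm == "OI" &
                                table$day == d)
    } else {
      ref_idx[[key]] <- which(table$donor == dn & table$day == ref_day)
      cmp_idx[[key]] <- which(table$donor == dn & table$day == d)
    }
  }

  per <- list(); pooled <- list()
  for (v in variables) {
    vec <- table[[v]]
    for (d in days) {
      ref_all <- numeric(); cmp_all <- numeric()
      for (dn in donors) {
        key <- paste(dn, d)
        x <- vec[ref_idx[[key]]]; y <- vec[cmp_idx[[key]]]
        x <- x[!is.na(x)]; y <- y[!is.na(y)]
        ref_all <- c(ref_all, x); cmp_all <- c(cmp_all, y)
        if (length(x) == 0L || length(y) == 0L) next
        visual <- length(x) < 3L || length(y) < 3L
        per[[length(per) + 1L]] <- data.frame(
          metabolite = v, donor = dn, day = d,
          pct_var = percent_variation(x, y, denom),
          p = if (visual) NA_real_ else wilcoxon_exact(x, y),
          n_ref = length(x), n_cmp = length(y), visual_only = visual)
      }
      if (length(ref_all) && length(cmp_all))
        pooled[[length(pooled) + 1L]] <- data.frame(
          metabolite = v, day = d,
          pct_var = percent_variation(ref_all, cmp_all, denom),
          p = wilcoxon_exact(ref_all, cmp_all),
          n_ref = length(ref_all), n_cmp = length(cmp_all))
    }
  }
  per <- if (length(per)) do.call(rbind, per) else NULL
  pooled <- if (length(pooled)) do.call(rbind, pooled) else NULL
  structure(list(per_donor = per, pooled = pooled, mode = mode,
                 denom = denom, variables = variables, donors = donors),
            class = "screen_result")
}

#' Donor-independent selection rules
#'
#' @param assess_from First day of the sign-consistency assessment window
#'   (the stage at which inter-donor agreement is expected to be
#'   established).
#' @param min_sig_days Minimum number of assessed days with p < `alpha`.
#' @param alpha Significance level.
#' @param magnitude_floor Minimum |percent variation| at the final day in
#'   every donor (operationalizes visual spectral confirmation).
#' @param min_n_per_donor Per-group replicate count below which
#'   significance is assessed on values pooled across donors (exact
#'   Wilcoxon with triplicates cannot reach p < 0.05, so pooling is the
#'   default path for a triplicate design).
#' @return List of class `selection_rules`.
#' @export
selection_rules <- function(assess_from = 14, min_sig_days = 2,
                            alpha = 0.05, magnitude_floor = 20,
                            min_n_per_donor = 5) {
  structure(list(assess_from = assess_from, min_sig_days = min_sig_days,
                 alpha = alpha, magnitude_floor = magnitude_floor,
                 min_n_per_donor = min_n_per_donor),
            class = "selection_rules")
}

#' Select the donor-independent signature
#'
#' A metabolite is selected iff (i) its percent variation has one common
#' sign across every donor at every assessed day (days >=
#' `rules$assess_from`); (ii) it is significant (p < alpha) at at least
#' `min_sig_days` assessed days — per donor when every donor has at least
#' `min_n_per_donor` replicates per group, otherwise on the
#' pooled-across-donors test; and (iii) its |percent variation| at the
#' final assessed day reaches the magnitude floor in every donor.
#'
#' @param screen A `screen_result` from [screen_markers()] covering at
#'   least two donors.
#' @param rules A [selection_rules()].
#' @return Data frame of selected metabolites with direction and final-day
#'   percent variation per donor; the full per-metabolite rule evaluation
#'   is attached as `attr(, "evaluation")`.
#' @export
select_donor_independent <- function(screen, rules = selection_rules()) {
  stopifnot(inherits(screen, "screen_result"))
  per <- screen$per_donor
  if (length(unique(per$donor)) < 2L)
    stop("need at least 2 screened donors")
  days_all <- sort(unique(per$day))
  assess <- days_all[days_all >= rules$assess_from]
  if (length(assess) == 0L)
    stop("no assessed days at or after day ", rules$assess_from)
  final_day <- max(assess)

  # donors must share assessed days
  for (dn in unique(per$donor)) {
    if (!all(assess %in% per$day[per$donor == dn]))
      stop("donor ", dn, " lacks assessed days; no overlapping day grid")
  }

  eval_rows <- NULL
  for (v in unique(per$metabolite)) {
    pv <- per[per$metabolite == v & per$day %in% assess, ]
    signs <- sign(pv$pct_var)
    sign_ok <- nrow(pv) > 0L && all(signs != 0) &&
      length(unique(signs)) == 1L
    use_per_donor <- all(pv$n_ref >= rules$min_n_per_donor &
                           pv$n_cmp >= rules$min_n_per_donor)
    if (use_per_donor) {
      sig_days <- vapply(unique(pv$donor), function(dn) {
        sum(pv$p[pv$donor == dn] < rules$alpha, na.rm = TRUE)
      }, numeric(1))
      sig_ok <- all(sig_days >= rules$min_sig_days)
    } else {
      po <- screen$pooled
      po <- po[po$metabolite == v & po$day %in% assess, ]
      sig_ok <- sum(po$p < rules$alpha, na.rm = TRUE) >= rules$min_sig_days
    }
    fin <- pv[pv$day == final_day, ]
    mag_ok <- nrow(fin) > 0L &&
      all(abs(fin$pct_var) >= rules$magnitude_floor)
    eval_rows <- rbind(eval_rows, data.frame(
      metabolite = v, sign_consistent = sign_ok, significant = sig_ok,
      magnitude_ok = mag_ok, selected = sign_ok && sig_ok && mag_ok,
      direction = if (sign_ok) c("down", "", "up")[unique(signs) + 2] else NA,
      final_pct_var = mean(fin$pct_var)))
  }
  sel <- eval_rows[eval_rows$selected, c("metabolite", "direction",
                                         "final_pct_var")]
  rownames(sel) <- NULL
  attr(sel, "evaluation") <- eval_rows
  attr(sel, "rules") <- rules
  sel
}

# Spearman rho with mid-ranks
spearman_rho <- function(x, y) {
  stats::cor(rank(x), rank(y))
}

# exact permutation p for small n, t-approximation otherwise
spearman_p <- function(x, y, exact_n = 9) {
  n <- length(x)
  rho <- spearman_rho(x, y)
  if (is.na(rho)) return(NA_real_)
  if (n <= exact_n) {
    rx <- rank(x); ry <- rank(y)
    sx <- stats::sd(rx); sy <- stats::sd(ry)
    if (sx == 0 || sy == 0) return(1)
    perms <- permutations_of(n)
    cross <- matrix(ry[perms], nrow(perms), n) %*% rx
    null_rho <- (cross - n * mean(rx) * mean(ry)) / ((n - 1) * sx * sy)
    mean(abs(null_rho) >= abs(rho) - 1e-9)
  } else {
    if (abs(rho) >= 1) return(.Machine$double.xmin)
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tt), df = n - 2)
  }
}

# all permutations of 1..n (n small), rows = permutations
permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  for (i in seq_len(n)) {
    rows <- (i - 1L) * nrow(sub) + seq_len(nrow(sub))
    out[rows, 1] <- i
    rest <- setdiff(seq_len(n), i)
    out[rows, -1] <- matrix(rest[sub], nrow(sub), n - 1L)
  }
  out
}

#' Thresholded Spearman correlation map
#'
#' Computes mid-rank Spearman correlations between every column of `A` and
#' every column of `B` over paired rows, with exact permutation p-values
#' for 9 or fewer pairs and a t-approximation otherwise, and retains only
#' pairs passing both thresholds.
#'
#' @param A,B Numeric matrices/data frames with aligned rows (e.g.
#'   per-(donor, day) group means). With `B = NULL`, correlates the
#'   columns of `A` among themselves (upper triangle).
#' @param rho_min Minimum |rho| retained.
#' @param p_max Maximum p-value retained.
#' @return Data frame of class `correlation_map`: `var_a`, `var_b`, `rho`,
#'   `p`. All computed pairs are attached as `attr(, "all_pairs")`.
#' @export
spearman_map <- function(A, B = NULL, rho_min = 0.7, p_max = 0.001) {
  A <- as.matrix(A)
  self <- is.null(B)
  B <- if (self) A else as.matrix(B)
  stopifnot(nrow(A) == nrow(B))
  pairs <- NULL
  for (i in seq_len(ncol(A))) {
    jj <- if (self) seq_len(ncol(B)) > i else seq_len(ncol(B)) > 0
    for (j in which(jj)) {
      ok <- stats::complete.cases(A[, i], B[, j])
      if (sum(ok) < 3L) next
      rho <- spearman_rho(A[ok, i], B[ok, j])
      p <- spearman_p(A[ok, i], B[ok, j])
      pairs <- rbind(pairs, data.frame(
        var_a = colnames(A)[i] %||% i, var_b = colnames(B)[j] %||% j,
        rho = rho, p = p, n = sum(ok)))
    }
  }
  keep <- if (is.null(pairs)) NULL else
    pairs[!is.na(pairs$rho) & abs(pairs$rho) >= rho_min &
            pairs$p <= p_max, ]
  if (is.null(keep)) keep <- data.frame(var_a = character(),
                                        var_b = character(),
                                        rho = numeric(), p = numeric(),
                                        n = integer())
  rownames(keep) <- NULL
  attr(keep, "all_pairs") <- pairs
  attr(keep, "thresholds") <- c(rho_min = rho_min, p_max = p_max)
  class(keep) <- c("correlation_map", class(keep))
  keep
}
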