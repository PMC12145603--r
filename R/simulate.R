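# Synthetic cohort simulator: ground-truth-annotated cell-extract and
# conditioned-media spectra (or integral tables) for the three-donor
# CTR-vs-OI osteodifferentiation design.

#' Cohort simulation configuration
#'
#' Defines the study design and noise model of the synthetic cohort. The
#' defaults reproduce the reference design: 3 donors, CTR and OI arms,
#' triplicate cell sampling on days 0/1/4/7/14/21 and media sampling on
#' days 1/4/7/11/14/18/21 with media exchanged at each media sampling, and
#' one group (OI, donor 2, day-21 cells) reduced to a single replicate.
#'
#' @param n_donors Number of donors.
#' @param replicates Replicates per group.
#' @param cell_days Cell-extract sampling days.
#' @param media_days Media sampling days (also the media-exchange days).
#' @param arms Study arms; the second is the induced (positive) class.
#' @param ppm_range Simulated axis range (ppm).
#' @param n_points Grid points across `ppm_range`.
#' @param noise_sd Additive Gaussian noise per spectral point (intensity units).
#' @param shift_jitter_sd Per-spectrum global chemical-shift jitter SD (ppm).
#' @param peak_jitter_sd Additional per-multiplet shift jitter SD (ppm).
#' @param rep_cv Replicate-level coefficient of variation of cell metabolite
#'   levels (log-normal, biological + technical).
#' @param media_rep_cv Replicate-level CV of per-interval media
#'   uptake/secretion increments.
#' @param sample_scale_sd Log-SD of the per-sample global intensity scale
#'   (cell-number / dilution differences removed later by total-area
#'   normalization).
#' @param blank_cv Batch-to-batch CV of fresh-medium composition.
#' @param missing_pattern List of `list(arm, donor, day, compartment,
#'   n_available)` entries reducing a group's replicate count.
#' @param seed Integer seed; fully determines the simulated cohort.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_donors = 3, replicates = 3,
                          cell_days = c(0, 1, 4, 7, 14, 21),
                          media_days = c(1, 4, 7, 11, 14, 18, 21),
                          arms = c("CTR", "OI"),
                          ppm_range = c(-0.5, 10), n_points = 8192,
                          noise_sd = 1.0, shift_jitter_sd = 0.003,
                          peak_jitter_sd = 0.001,
                          rep_cv = 0.06, media_rep_cv = 0.07,
                          sample_scale_sd = 0.15, blank_cv = 0.02,
                          missing_pattern = list(
                            list(arm = "OI", donor = 2, day = 21,
                                 compartment = "cell", n_available = 1)),
                          seed = 1) {
  cfg <- list(n_donors = n_donors, replicates = replicates,
              cell_days = sort(cell_days), media_days = sort(media_days),
              arms = arms, ppm_range = ppm_range, n_points = n_points,
              noise_sd = noise_sd, shift_jitter_sd = shift_jitter_sd,
              peak_jitter_sd = peak_jitter_sd,
              rep_cv = rep_cv, media_rep_cv = media_rep_cv,
              sample_scale_sd = sample_scale_sd, blank_cv = blank_cv,
              missing_pattern = missing_pattern, seed = seed)
  if (any(cfg$cell_days < 0 | cfg$cell_days > 21) ||
      any(cfg$media_days <= 0 | cfg$media_days > 21))
    stop("configured days fall outside the simulation horizon (0..21)")
  stopifnot(n_donors >= 1, replicates >= 1, n_points >= 256,
            ppm_range[1] < ppm_range[2])
  structure(cfg, class = "cohort_config")
}

# expand the sampling grid and apply the missing pattern
sample_grid <- function(cfg, compartment) {
  days <- if (compartment == "cell") cfg$cell_days else cfg$media_days
  g <- expand.grid(replicate = seq_len(cfg$replicates), day = days,
                   donor = seq_len(cfg$n_donors), arm = cfg$arms,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g$compartment <- compartment
  keep <- rep(TRUE, nrow(g))
  for (m in cfg$missing_pattern) {
    if (!identical(m$compartment, compartment)) next
    hit <- g$arm == m$arm & g$donor == m$donor & g$day == m$day
    keep[hit & g$replicate > m$n_available] <- FALSE
  }
  g <- g[keep, ]
  g <- g[order(g$arm, g$donor, g$day, g$replicate), ]
  g$sample_id <- sprintf("%s_%s%d_D%02d_r%d", compartment, g$arm, g$donor,
                         g$day, g$replicate)
  rownames(g) <- NULL
  g[, c("sample_id", "donor", "arm", "day", "replicate", "compartment")]
}

#' Simulate a synthetic osteodifferentiation cohort
#'
#' Generates one sample per (donor, arm, day, replicate, compartment) minus
#' any configured missing groups, either as rendered Lorentzian spectra
#' (`output = "spectra"`) or directly as concentration-level integral
#' tables (`output = "integrals"`, the fast path sharing the same
#' concentration model). Media samples are fresh-medium (blank) composition
#' plus the uptake/secretion accumulated since the last media exchange;
#' matching blank spectra are generated per (arm, exchange interval). Every
#' rendered spectrum carries a TSP reference peak at 0.00 ppm and additive
#' Gaussian noise. The same seed yields identical output.
#'
#' @param lib A `metabolite_library`, e.g. [build_default_library()].
#' @param config A [cohort_config()].
#' @param output `"spectra"` or `"integrals"`.
#' @return A list of class `cohort`: `cells`, `media`, `blanks` (spectrum
#'   sets or tables), and `truth` with the planted signature, the
#'   noise-free per-sample concentrations, and (spectral output) the
#'   noise-free window integrals.
#' @export
simulate_cohort <- function(lib, config = cohort_config(),
                            output = c("spectra", "integrals")) {
  output <- match.arg(output)
  stopifnot(inherits(lib, "metabolite_library"),
            inherits(config, "cohort_config"))
  with_seed(config$seed, simulate_cohort_impl(lib, config, output))
}

simulate_cohort_impl <- function(lib, cfg, output) {
  met <- lib$metabolites
  cell_names <- met$name[met$compartment == "cell"]
  media_names <- met$name[met$compartment == "media"]
  cell_base <- stats::setNames(met$baseline[met$compartment == "cell"], cell_names)
  media_base <- stats::setNames(met$baseline[met$compartment == "media"], media_names)

  # donor-specific multiplicative offsets, confounder metabolites only
  offs <- function(names, conf) {
    o <- matrix(1, cfg$n_donors, length(names), dimnames = list(NULL, names))
    for (d in seq_len(cfg$n_donors))
      o[d, conf] <- exp(stats::rnorm(sum(conf), 0, lib$donor_offset_sdlog))
    o
  }
  cell_off <- offs(cell_names, met$confounder[met$compartment == "cell"])
  media_off <- offs(media_names, met$confounder[met$compartment == "media"])

  sdlog <- function(cv) sqrt(log(1 + cv^2))

  # --- cells: expected and realized concentrations ---------------------
  cells_meta <- sample_grid(cfg, "cell")
  true_cell <- matrix(NA_real_, nrow(cells_meta), length(cell_names),
                      dimnames = list(cells_meta$sample_id, cell_names))
  conc_cell <- true_cell
  mult_cache <- list()
  for (i in seq_len(nrow(cells_meta))) {
    s <- cells_meta[i, ]
    key <- paste(s$arm, s$day)
    if (is.null(mult_cache[[key]]))
      mult_cache[[key]] <- vapply(cell_names, function(nm)
        cell_multiplier(lib, nm, s$arm, s$day), numeric(1))
    true_cell[i, ] <- cell_base * cell_off[s$donor, ] * mult_cache[[key]]
    noise <- exp(stats::rnorm(length(cell_names), 0, sdlog(cfg$rep_cv)))
    scale <- exp(stats::rnorm(1, 0, cfg$sample_scale_sd))
    conc_cell[i, ] <- true_cell[i, ] * noise * scale
  }

  # --- media: blanks per (arm, interval), samples = blank + increment --
  media_meta <- sample_grid(cfg, "media")
  prev_day <- stats::setNames(c(0, utils::head(cfg$media_days, -1)),
                              cfg$media_days)
  blanks_meta <- expand.grid(replicate = seq_len(cfg$replicates),
                             day = cfg$media_days, arm = cfg$arms,
                             KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  blanks_meta <- blanks_meta[order(blanks_meta$arm, blanks_meta$day,
                                   blanks_meta$replicate), ]
  blanks_meta$donor <- NA_integer_
  blanks_meta$compartment <- "blank"
  blanks_meta$sample_id <- sprintf("blank_%s_D%02d_r%d", blanks_meta$arm,
                                   blanks_meta$day, blanks_meta$replicate)
  rownames(blanks_meta) <- NULL
  blanks_meta <- blanks_meta[, c("sample_id", "donor", "arm", "day",
                                 "replicate", "compartment")]

  # fresh-medium batch composition for the interval ending at each day
  batch <- array(NA_real_, c(length(cfg$arms), length(cfg$media_days),
                             length(media_names)),
                 dimnames = list(cfg$arms, cfg$media_days, media_names))
  for (a in cfg$arms) for (d in as.character(cfg$media_days))
    batch[a, d, ] <- media_base *
      exp(stats::rnorm(length(media_names), 0, sdlog(cfg$blank_cv)))

  conc_blank <- matrix(NA_real_, nrow(blanks_meta), length(media_names),
                       dimnames = list(blanks_meta$sample_id, media_names))
  for (i in seq_len(nrow(blanks_meta))) {
    b <- blanks_meta[i, ]
    conc_blank[i, ] <- batch[b$arm, as.character(b$day), ] *
      exp(stats::rnorm(length(media_names), 0, sdlog(cfg$blank_cv / 2)))
  }

  true_media <- matrix(NA_real_, nrow(media_meta), length(media_names),
                       dimnames = list(media_meta$sample_id, media_names))
  conc_media <- true_media
  rate_cache <- list()
  conf <- met$confounder[met$compartment == "media"]
  for (i in seq_len(nrow(media_meta))) {
    s <- media_meta[i, ]
    dt <- s$day - prev_day[[as.character(s$day)]]
    key <- paste(s$arm, s$day)
    if (is.null(rate_cache[[key]]))
      rate_cache[[key]] <- vapply(media_names, function(nm)
        media_rate(lib, nm, s$arm, s$day), numeric(1))
    rate <- rate_cache[[key]]
    rate[conf] <- rate[conf] * media_off[s$donor, conf]
    delta <- rate * dt
    true_media[i, ] <- media_base + delta
    jit <- exp(stats::rnorm(length(media_names), 0, sdlog(cfg$media_rep_cv)))
    conc_media[i, ] <- pmax(batch[s$arm, as.character(s$day), ] + delta * jit, 0)
  }

  truth <- list(signature = planted_signature(lib),
                cell_concentrations = cbind(cells_meta,
                                            as.data.frame(true_cell)),
                media_concentrations = cbind(media_meta,
                                             as.data.frame(true_media)))

  if (output == "integrals") {
    out <- list(
      cells = cbind(cells_meta, as.data.frame(conc_cell)),
      media = cbind(media_meta, as.data.frame(conc_media)),
      blanks = cbind(blanks_meta, as.data.frame(conc_blank)),
      truth = truth)
    class(out) <- "cohort"
    attr(out, "output") <- "integrals"
    return(out)
  }

  # --- spectral rendering ----------------------------------------------
  ppm <- seq(cfg$ppm_range[1], cfg$ppm_range[2], length.out = cfg$n_points)
  mults_for <- function(compartment)
    lib$multiplets[lib$multiplets$compartment == compartment, ]
  render_set <- function(meta, conc, compartment, noisy = TRUE) {
    ml <- mults_for(compartment)
    ints <- matrix(0, nrow(meta), length(ppm),
                   dimnames = list(meta$sample_id, NULL))
    for (i in seq_len(nrow(meta))) {
      gshift <- if (noisy) stats::rnorm(1, 0, cfg$shift_jitter_sd) else 0
      pjit <- if (noisy) stats::rnorm(nrow(ml), 0, cfg$peak_jitter_sd) else
        rep(0, nrow(ml))
      y <- render_peaks(ppm, conc[i, ], ml, gshift, pjit)
      y <- y + lorentzian_trunc(ppm, lib$tsp$center + gshift, lib$tsp$area,
                                lib$tsp$width_hz / SPEC_FREQ_MHZ)
      if (noisy && cfg$noise_sd > 0)
        y <- y + stats::rnorm(length(ppm), 0, cfg$noise_sd)
      ints[i, ] <- y
    }
    spectrum_set(ppm, ints, meta)
  }

  cells <- render_set(cells_meta, conc_cell, "cell")
  media <- render_set(media_meta, conc_media, "media")
  blanks <- render_set(blanks_meta, conc_blank, "media")

  # noise-free window integrals of the deterministic concentrations, via
  # the same rendering and quadrature as the measurement path
  truth$cell_integrals <- true_window_integrals(
    ppm, cells_meta, true_cell, mults_for("cell"),
    library_windows(lib, "cell"))
  truth$media_integrals <- true_window_integrals(
    ppm, media_meta, true_media, mults_for("media"),
    library_windows(lib, "media"))

  out <- list(cells = cells, media = media, blanks = blanks, truth = truth)
  class(out) <- "cohort"
  attr(out, "output") <- "spectra"
  out
}

# Render all multiplets of one sample; each Lorentzian is evaluated on a
# +/- 0.3 ppm support around its (jittered) centre - tails beyond hold
# under 0.3% of the area and are identical across samples.
render_peaks <- function(ppm, conc, mults, gshift, pjit) {
  y <- numeric(length(ppm))
  centers <- mults$center + gshift + pjit
  areas <- conc[mults$name] * mults$rel_area
  for (k in seq_len(nrow(mults))) {
    if (areas[k] <= 0) next
    lo <- findInterval(centers[k] - 0.3, ppm) + 1L
    hi <- findInterval(centers[k] + 0.3, ppm)
    if (hi < lo) next
    idx <- lo:hi
    y[idx] <- y[idx] + lorentzian(ppm[idx], centers[k], areas[k],
                                  mults$width_ppm[k])
  }
  y
}

lorentzian_trunc <- function(ppm, center, area, fwhm) {
  y <- numeric(length(ppm))
  lo <- findInterval(center - 0.3, ppm) + 1L
  hi <- findInterval(center + 0.3, ppm)
  if (hi >= lo) {
    idx <- lo:hi
    y[idx] <- lorentzian(ppm[idx], center, area, fwhm)
  }
  y
}

true_window_integrals <- function(ppm, meta, true_conc, mults, windows) {
  key <- paste(meta$arm, meta$donor, meta$day)
  first <- !duplicated(key)
  vals <- matrix(NA_real_, nrow(meta), nrow(windows),
                 dimnames = list(meta$sample_id, windows$name))
  cache <- list()
  for (i in seq_len(nrow(meta))) {
    k <- key[i]
    if (is.null(cache[[k]])) {
      y <- render_peaks(ppm, true_conc[i, ], mults, 0, rep(0, nrow(mults)))
      cache[[k]] <- vapply(seq_len(nrow(windows)), function(w) {
        idx <- which(ppm >= windows$lo[w] & ppm <= windows$hi[w])
        trapz(ppm[idx], y[idx])
      }, numeric(1))
    }
    vals[i, ] <- cache[[k]]
  }
  cbind(meta, as.data.frame(vals, check.names = FALSE))
}

#' @export
print.cohort <- function(x, ...) {
  kind <- attr(x, "output")
  n <- function(el) if (inherits(el, "spectrum_set")) n_spectra(el) else nrow(el)
  cat("<cohort> (", kind, ") cells: ", n(x$cells), ", media: ", n(x$media),
      ", blanks: ", n(x$blanks), "\n", sep = "")
  invisible(x)
}

#' Write a simulated cohort to disk
#'
#' Spectral cohorts are written as per-sample two-column text files with a
#' sample sheet per compartment; integral cohorts as CSV tables. The ground
#' truth (planted signature and noise-free concentrations) is always
#' written as CSV.
#'
#' @param cohort A `cohort` from [simulate_cohort()].
#' @param dir Output directory.
#' @return Invisibly, `dir`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (identical(attr(cohort, "output"), "spectra")) {
    write_spectra(cohort$cells, file.path(dir, "cells"))
    write_spectra(cohort$media, file.path(dir, "media"))
    write_spectra(cohort$blanks, file.path(dir, "blanks"))
  } else {
    utils::write.csv(cohort$cells, file.path(dir, "cells_integrals.csv"),
                     row.names = FALSE)
    utils::write.csv(cohort$media, file.path(dir, "media_integrals.csv"),
                     row.names = FALSE)
    utils::write.csv(cohort$blanks, file.path(dir, "blank_integrals.csv"),
                     row.names = FALSE)
  }
  utils::write.csv(cohort$truth$signature,
                   file.path(dir, "ground_truth_signature.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$truth$cell_concentrations,
                   file.path(dir, "ground_truth_cells.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$truth$media_concentrations,
                   file.path(dir, "ground_truth_media.csv"),
                   row.names = FALSE)
  invisible(dir)
}
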