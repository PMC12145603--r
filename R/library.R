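# Metabolite library: multiplet definitions, integration windows and planted
# time-course effects for the synthetic osteodifferentiation cohort.

SPEC_FREQ_MHZ <- 500.13  # spectrometer frequency used to convert Hz widths to ppm

#' Build the default metabolite library
#'
#' Constructs the library of endometabolites (cell extracts) and
#' exometabolites (conditioned media) used by the cohort simulator. Each
#' metabolite carries Lorentzian multiplet definitions (centre, relative
#' area, width), a baseline level in arbitrary concentration units, an
#' integration window on its least-overlapped multiplet, and planted
#' time-course effects:
#'
#' * a proliferation profile applied to both study arms of the cell
#'   compartment (multiplicative, ramping from day 0 to day 21);
#' * an osteoinduction ratio applied to the OI arm only, ramping linearly
#'   from a per-metabolite onset day to day 21;
#' * for media metabolites, a per-day net uptake (< 0) or secretion (> 0)
#'   rate for the control arm, and an OI rate ratio phased in over the
#'   culture ("clear differences after the first few days").
#'
#' The library names three signature sets: the 9-endometabolite
#' osteodifferentiation signature (Cho, Etn, UDP-GlcNAc, UDP-GalNAc and
#' U3.48 up by more than 80 percent at day 21; ADP, MG, PCho and PCr down),
#' the 14-endometabolite proliferation signature (HTau, MG, GPC, PEtn and
#' Ino up by more than 85 percent; ADP and ATP down by more than 55 percent;
#' plus Asp, Pro, GSH, Ile, Leu, Val and PCho), and the 17-exometabolite
#' osteodifferentiation signature (reduced uptake of Gln, Ile, Leu, Val,
#' 2-HIBA, Pyr and Glc; increased secretion of 3-HBA, Orn, PyroGlu and Lac;
#' decreased secretion of 3-HIBA, aKG and Cit; donor-independent end levels
#' of Ala, Cho and His). Donor-specific log-normal offsets are restricted to
#' known confounder metabolites (glycerol, GPC, formate, Cr, Tau, 2-HIC,
#' Lac and, in media, acetate, Cr and formate).
#'
#' @return An object of class `metabolite_library`.
#' @seealso [planted_signature()], [neutralize_effects()], [simulate_cohort()]
#' @export
build_default_library <- function() {
  wdef <- 1.2 # Hz FWHM for sharp singlets/doublets

  # --- endometabolites -------------------------------------------------
  # columns: name, baseline, confounder, prolif magnitude (% at D21, both
  # arms), osteo magnitude (% at D21, OI vs CTR), osteo onset day
  endo <- rbind(
    data.frame(name = "Cho",        baseline = 0.8, confounder = FALSE, prolif = 0,    osteo = 150,  onset = 4),
    data.frame(name = "PCho",       baseline = 1.0, confounder = FALSE, prolif = 35,   osteo = -45,  onset = 7),
    data.frame(name = "GPC",        baseline = 0.9, confounder = TRUE,  prolif = 95,   osteo = 0,    onset = NA),
    data.frame(name = "Etn",        baseline = 0.6, confounder = FALSE, prolif = 0,    osteo = 110,  onset = 4),
    data.frame(name = "PEtn",       baseline = 0.8, confounder = FALSE, prolif = 90,   osteo = 0,    onset = NA),
    data.frame(name = "UDP-GlcNAc", baseline = 0.5, confounder = FALSE, prolif = 0,    osteo = 160,  onset = 4),
    data.frame(name = "UDP-GalNAc", baseline = 0.4, confounder = FALSE, prolif = 0,    osteo = 120,  onset = 4),
    data.frame(name = "U3.48",      baseline = 0.5, confounder = FALSE, prolif = 0,    osteo = 100,  onset = 4),
    data.frame(name = "ADP",        baseline = 0.6, confounder = FALSE, prolif = -60,  osteo = -50,  onset = 7),
    data.frame(name = "ATP",        baseline = 0.7, confounder = FALSE, prolif = -60,  osteo = 0,    onset = NA),
    data.frame(name = "PCr",        baseline = 0.9, confounder = FALSE, prolif = 0,    osteo = -55,  onset = 1),
    data.frame(name = "Cr",         baseline = 0.8, confounder = TRUE,  prolif = 0,    osteo = 0,    onset = NA),
    data.frame(name = "MG",         baseline = 0.7, confounder = FALSE, prolif = 100,  osteo = -60,  onset = 4),
    data.frame(name = "HTau",       baseline = 0.9, confounder = FALSE, prolif = 120,  osteo = 0,    onset = NA),
    data.frame(name = "Tau",        baseline = 1.2, confounder = TRUE,  prolif = 0,    osteo = 0,    onset = NA),
    data.frame(name = "Ino",        baseline = 0.6, confounder = FALSE, prolif = 110,  osteo = 0,    onset = NA),
    data.frame(name = "GSH",        baseline = 0.8, confounder = FALSE, prolif = 40,   osteo = 0,    onset = NA),
    data.frame(name = "Asp",        baseline = 0.7, confounder = FALSE, prolif = -30,  osteo = 0,    onset = NA),
    data.frame(name = "Pro",        baseline = 0.6, confounder = FALSE, prolif = -30,  osteo = 0,    onset = NA),
    data.frame(name = "Ile",        baseline = 0.5, confounder = FALSE, prolif = -25,  osteo = 0,    onset = NA),
    data.frame(name = "Leu",        baseline = 0.6, confounder = FALSE, prolif = -25,  osteo = 0,    onset = NA),
    data.frame(name = "Val",        baseline = 0.5, confounder = FALSE, prolif = -25,  osteo = 0,    onset = NA),
    data.frame(name = "glycerol",   baseline = 1.5, confounder = TRUE,  prolif = 0,    osteo = 0,    onset = NA),
    data.frame(name = "formate",    baseline = 0.3, confounder = TRUE,  prolif = 0,    osteo = 0,    onset = NA),
    data.frame(name = "2-HIC",      baseline = 0.4, confounder = TRUE,  prolif = 0,    osteo = 0,    onset = NA),
    data.frame(name = "Lac",        baseline = 2.5, confounder = TRUE,  prolif = 0,    osteo = 0,    onset = NA),
    data.frame(name = "Glc",        baseline = 4.0, confounder = FALSE, prolif = 0,    osteo = 0,    onset = NA),
    data.frame(name = "m-Ino",      baseline = 1.2, confounder = FALSE, prolif = 0,    osteo = 0,    onset = NA),
    data.frame(name = "acetate",    baseline = 0.8, confounder = FALSE, prolif = 0,    osteo = 0,    onset = NA),
    data.frame(name = "Gly",        baseline = 1.0, confounder = FALSE, prolif = 0,    osteo = 0,    onset = NA),
    data.frame(name = "Glu",        baseline = 1.5, confounder = FALSE, prolif = 0,    osteo = 0,    onset = NA),
    data.frame(name = "AMP",        baseline = 0.4, confounder = FALSE, prolif = 0,    osteo = 0,    onset = NA),
    data.frame(name = "Ado",        baseline = 0.3, confounder = FALSE, prolif = 0,    osteo = 0,    onset = NA),
    data.frame(name = "acetone",    baseline = 0.3, confounder = FALSE, prolif = 0,    osteo = 0,    onset = NA)
  )
  endo$compartment <- "cell"

  # multiplets: (name, center ppm, relative area, width Hz); the starred
  # multiplet of each metabolite (its integration window) is the first row
  emul <- function(name, centers, rel, width = wdef) {
    data.frame(name = name, center = centers, rel_area = rel / sum(rel),
               width_hz = width)
  }
  endo_mult <- rbind(
    emul("Cho", 3.195, 1), emul("PCho", 3.220, 1), emul("GPC", 3.245, 1),
    emul("Etn", c(3.145, 3.825), c(0.5, 0.5)),
    emul("PEtn", 3.980, 1),
    emul("UDP-GlcNAc", 5.510, 1, 1.8), emul("UDP-GalNAc", 5.545, 1, 1.8),
    emul("U3.48", 3.480, 1),
    emul("ADP", 8.535, 1), emul("ATP", 8.510, 1),
    emul("PCr", 3.050, 1),
    emul("Cr", c(3.027, 3.925), c(0.43, 0.57)),
    emul("MG", 2.835, 1),
    emul("HTau", c(2.650, 3.355), c(0.5, 0.5)),  # second multiplet falls in the methanol exclusion
    emul("Tau", 3.425, 1), emul("Ino", 6.100, 1), emul("GSH", 2.945, 1),
    emul("Asp", 2.785, 1),
    emul("Pro", c(4.130, 2.010), c(0.3, 0.7)),
    emul("Ile", 1.005, 1), emul("Leu", 0.965, 1), emul("Val", 1.040, 1),
    emul("glycerol", 3.555, 1), emul("formate", 8.440, 1),
    emul("2-HIC", 0.920, 1),
    emul("Lac", c(1.325, 4.115), c(0.75, 0.25)),
    emul("Glc", c(5.230, 3.755), c(0.25, 0.75)),
    emul("m-Ino", 4.060, 1), emul("acetate", 1.920, 1),
    emul("Gly", 3.525, 1), emul("Glu", 2.340, 1),
    emul("AMP", 8.600, 1), emul("Ado", 8.345, 1), emul("acetone", 2.220, 1)
  )
  endo_mult$compartment <- "cell"

  # --- exometabolites --------------------------------------------------
  # rate: net concentration change per day in the control arm (negative =
  # uptake, positive = secretion); oi_ratio: OI rate multiplier at full
  # phase-in (a negative ratio flips uptake into secretion)
  exo <- rbind(
    data.frame(name = "Gln",     baseline = 6.0,  confounder = FALSE, rate = -0.30,  oi_ratio = 0.55),
    data.frame(name = "Ile",     baseline = 2.0,  confounder = FALSE, rate = -0.10,  oi_ratio = 0.55),
    data.frame(name = "Leu",     baseline = 2.5,  confounder = FALSE, rate = -0.12,  oi_ratio = 0.55),
    data.frame(name = "Val",     baseline = 2.0,  confounder = FALSE, rate = -0.10,  oi_ratio = 0.55),
    data.frame(name = "2-HIBA",  baseline = 0.8,  confounder = FALSE, rate = -0.05,  oi_ratio = 0.50),
    data.frame(name = "Pyr",     baseline = 1.5,  confounder = FALSE, rate = -0.10,  oi_ratio = 0.55),
    data.frame(name = "Glc",     baseline = 30.0, confounder = FALSE, rate = -1.20,  oi_ratio = 0.60),
    data.frame(name = "3-HBA",   baseline = 0.5,  confounder = FALSE, rate =  0.06,  oi_ratio = 1.90),
    data.frame(name = "Orn",     baseline = 0.4,  confounder = FALSE, rate =  0.04,  oi_ratio = 2.50),
    data.frame(name = "PyroGlu", baseline = 1.0,  confounder = FALSE, rate = -0.05,  oi_ratio = -1.50),
    data.frame(name = "Lac",     baseline = 2.0,  confounder = FALSE, rate =  0.40,  oi_ratio = 1.50),
    data.frame(name = "3-HIBA",  baseline = 0.3,  confounder = FALSE, rate =  0.05,  oi_ratio = 0.50),
    data.frame(name = "aKG",     baseline = 0.4,  confounder = FALSE, rate =  0.05,  oi_ratio = 0.50),
    data.frame(name = "Cit",     baseline = 0.5,  confounder = FALSE, rate =  0.06,  oi_ratio = 0.45),
    data.frame(name = "Ala",     baseline = 1.5,  confounder = FALSE, rate = -0.08,  oi_ratio = 0.55),
    data.frame(name = "Cho",     baseline = 0.3,  confounder = FALSE, rate = -0.015, oi_ratio = 0.55),
    data.frame(name = "His",     baseline = 0.8,  confounder = FALSE, rate = -0.04,  oi_ratio = 0.55),
    data.frame(name = "acetate", baseline = 1.0,  confounder = TRUE,  rate = -0.05,  oi_ratio = 1),
    data.frame(name = "Cr",      baseline = 0.5,  confounder = TRUE,  rate = -0.03,  oi_ratio = 1),
    data.frame(name = "cystine", baseline = 0.6,  confounder = FALSE, rate = -0.04,  oi_ratio = 1),
    data.frame(name = "Ser",     baseline = 1.2,  confounder = FALSE, rate = -0.06,  oi_ratio = 1),
    data.frame(name = "Thr",     baseline = 1.2,  confounder = FALSE, rate = -0.06,  oi_ratio = 1),
    data.frame(name = "Asp",     baseline = 0.6,  confounder = FALSE, rate = -0.03,  oi_ratio = 1),
    data.frame(name = "formate", baseline = 0.2,  confounder = TRUE,  rate =  0.02,  oi_ratio = 1),
    data.frame(name = "m-Ino",   baseline = 1.0,  confounder = FALSE, rate = -0.04,  oi_ratio = 1),
    data.frame(name = "Phe",     baseline = 0.9,  confounder = FALSE, rate = -0.04,  oi_ratio = 1),
    data.frame(name = "Tyr",     baseline = 0.7,  confounder = FALSE, rate = -0.03,  oi_ratio = 1),
    data.frame(name = "3M2OV",   baseline = 0.3,  confounder = FALSE, rate =  0.03,  oi_ratio = 1)
  )
  exo$compartment <- "media"

  exo_mult <- rbind(
    emul("Gln", 2.450, 1), emul("Ile", 1.005, 1), emul("Leu", 0.965, 1),
    emul("Val", 1.040, 1), emul("2-HIBA", 1.360, 1), emul("Pyr", 2.370, 1),
    emul("Glc", c(5.230, 3.755), c(0.25, 0.75)),  # second multiplet in the beta-GP/glycerol exclusion
    emul("3-HBA", 1.240, 1), emul("Orn", 3.060, 1), emul("PyroGlu", 2.510, 1),
    emul("Lac", c(1.325, 4.115), c(0.75, 0.25)),  # second multiplet in the media 4.1-4.2 exclusion
    emul("3-HIBA", 1.072, 1), emul("aKG", 3.000, 1), emul("Cit", 2.660, 1),
    emul("Ala", 1.475, 1), emul("Cho", 3.195, 1), emul("His", 7.065, 1),
    emul("acetate", 1.920, 1), emul("Cr", 3.027, 1), emul("cystine", 3.425, 1),
    emul("Ser", 3.945, 1), emul("Thr", 4.250, 1), emul("Asp", 2.820, 1),
    emul("formate", 8.440, 1), emul("m-Ino", 4.060, 1), emul("Phe", 7.370, 1),
    emul("Tyr", 6.890, 1), emul("3M2OV", 0.890, 1)
  )
  exo_mult$compartment <- "media"

  metabolites <- rbind(
    endo[, c("name", "compartment", "baseline", "confounder")],
    exo[, c("name", "compartment", "baseline", "confounder")]
  )
  multiplets <- rbind(endo_mult, exo_mult)
  multiplets$width_ppm <- multiplets$width_hz / SPEC_FREQ_MHZ

  # integration window on the first (starred) multiplet of each metabolite
  starred <- multiplets[!duplicated(multiplets[, c("name", "compartment")]), ]
  windows <- data.frame(
    name = starred$name, compartment = starred$compartment,
    lo = starred$center - 0.010, hi = starred$center + 0.010
  )

  lib <- structure(list(
    metabolites = metabolites,
    multiplets = multiplets,
    windows = windows,
    cell_effects = endo[, c("name", "prolif", "osteo", "onset")],
    # proliferation ramp (fraction of the day-21 magnitude at each sampled day)
    prolif_ramp = list(days = c(0, 1, 4, 7, 14, 21),
                       frac = c(0, 0.08, 0.25, 0.45, 0.8, 1)),
    media_rates = exo[, c("name", "rate", "oi_ratio")],
    # phase-in of the OI media-rate ratio over the culture
    media_ramp = list(days = c(1, 4, 7, 11, 14, 18, 21),
                      frac = c(0, 0.3, 0.7, 0.9, 1, 1, 1)),
    donor_offset_sdlog = 0.35,
    tsp = list(center = 0, area = 2.0, width_hz = wdef),
    signatures = list(
      endo_osteo = data.frame(
        metabolite = c("Cho", "Etn", "UDP-GlcNAc", "UDP-GalNAc", "U3.48",
                       "ADP", "MG", "PCho", "PCr"),
        direction = c(rep("up", 5), rep("down", 4))
      ),
      endo_prolif = data.frame(
        metabolite = c("HTau", "MG", "GPC", "PEtn", "Ino", "ADP", "ATP",
                       "Asp", "Pro", "GSH", "Ile", "Leu", "Val", "PCho"),
        direction = c(rep("up", 5), rep("down", 4), "up",
                      rep("down", 3), "up")
      ),
      exo_osteo = data.frame(
        metabolite = c("Gln", "Ile", "Leu", "Val", "2-HIBA", "Pyr", "Glc",
                       "3-HBA", "Orn", "PyroGlu", "Lac",
                       "3-HIBA", "aKG", "Cit", "Ala", "Cho", "His"),
        role = c(rep("reduced uptake", 7), rep("increased secretion", 4),
                 rep("decreased secretion", 3), rep("DI end level", 3))
      )
    )
  ), class = "metabolite_library")
  validate_library(lib)
  lib
}

validate_library <- function(lib) {
  sums <- tapply(lib$multiplets$rel_area,
                 paste(lib$multiplets$name, lib$multiplets$compartment),
                 sum)
  stopifnot(all(abs(sums - 1) < 1e-9),
            all(lib$multiplets$width_hz > 0),
            all(lib$metabolites$baseline >= 0))
  invisible(lib)
}

#' @export
print.metabolite_library <- function(x, ...) {
  n <- table(x$metabolites$compartment)
  cat("<metabolite_library> ", n[["cell"]], " endometabolites, ",
      n[["media"]], " exometabolites\n", sep = "")
  sig <- planted_signature(x)
  cat("planted OI-vs-CTR signature: ", nrow(sig), " metabolites (",
      sum(sig$compartment == "cell"), " endo, ",
      sum(sig$compartment == "media"), " exo)\n", sep = "")
  invisible(x)
}

#' Strip all planted differential effects from a library
#'
#' Sets every arm/compartment effect profile to unity: proliferation and
#' osteoinduction magnitudes become zero and OI media rates equal control
#' rates. The resulting library generates null cohorts in which CTR and OI
#' arms share identical expected dynamics.
#'
#' @param lib A `metabolite_library`.
#' @return The neutralized library.
#' @export
neutralize_effects <- function(lib) {
  lib$cell_effects$prolif <- 0
  lib$cell_effects$osteo <- 0
  lib$media_rates$oi_ratio <- 1
  lib
}

#' Planted OI-vs-CTR signature of a library
#'
#' Returns the ground-truth set of metabolites whose expected dynamics
#' differ between the OI and CTR arms, with direction (sign of the expected
#' percent variation as computed by [screen_markers()]), onset day and
#' day-21 magnitude.
#'
#' @param lib A `metabolite_library`.
#' @return Data frame with columns `metabolite`, `compartment`, `direction`,
#'   `onset_day`, `magnitude_pct`.
#' @export
planted_signature <- function(lib) {
  ce <- lib$cell_effects
  cell <- ce[ce$osteo != 0, ]
  out_cell <- if (nrow(cell)) data.frame(
    metabolite = cell$name, compartment = "cell",
    direction = ifelse(cell$osteo > 0, "up", "down"),
    onset_day = cell$onset, magnitude_pct = cell$osteo
  ) else NULL

  mr <- lib$media_rates
  med <- mr[mr$oi_ratio != 1, ]
  out_med <- if (nrow(med)) {
    # expected cumulative %-variation at day 21 of the corrected trajectory,
    # relative to |CTR|: weighted mean of the ramp times (ratio - 1)
    rmp <- lib$media_ramp
    dt <- diff(c(0, rmp$days))
    fbar <- sum(rmp$frac * dt) / sum(dt)
    mag <- 100 * fbar * (med$oi_ratio - 1) * ifelse(med$rate >= 0, 1, -1)
    onset <- vapply(seq_len(nrow(med)), function(i)
      rmp$days[which(rmp$frac > 0)[1]], numeric(1))
    data.frame(metabolite = med$name, compartment = "media",
               direction = ifelse(mag > 0, "up", "down"),
               onset_day = onset, magnitude_pct = mag)
  } else NULL
  out <- rbind(out_cell, out_med)
  if (is.null(out)) out <- data.frame(metabolite = character(),
                                      compartment = character(),
                                      direction = character(),
                                      onset_day = numeric(),
                                      magnitude_pct = numeric())
  rownames(out) <- NULL
  out
}

#' Expected cell-compartment multiplier of a metabolite at given days
#'
#' Evaluates the planted multiplicative time course of an endometabolite:
#' the proliferation profile (both arms) times, for the OI arm, the
#' osteoinduction ratio ramping from its onset day.
#'
#' @param lib A `metabolite_library`.
#' @param name Metabolite name.
#' @param arm `"CTR"` or `"OI"`.
#' @param day Numeric vector of days.
#' @return Multiplier relative to the day-0 baseline.
#' @export
cell_multiplier <- function(lib, name, arm, day) {
  ce <- lib$cell_effects[lib$cell_effects$name == name, ]
  if (nrow(ce) != 1L) stop("unknown endometabolite: ", name)
  g <- interp_knots(lib$prolif_ramp$days, lib$prolif_ramp$frac, day)
  m <- 1 + g * ce$prolif / 100
  if (arm == "OI" && ce$osteo != 0) {
    h <- pmax(0, (day - ce$onset) / (21 - ce$onset))
    m <- m * (1 + h * ce$osteo / 100)
  }
  m
}

#' Expected media uptake/secretion rate at a given day
#'
#' @param lib A `metabolite_library`.
#' @param name Exometabolite name.
#' @param arm `"CTR"` or `"OI"`.
#' @param day Numeric vector of days (interval end days).
#' @return Net concentration change per day (negative = uptake).
#' @export
media_rate <- function(lib, name, arm, day) {
  mr <- lib$media_rates[lib$media_rates$name == name, ]
  if (nrow(mr) != 1L) stop("unknown exometabolite: ", name)
  r <- rep(mr$rate, length(day))
  if (arm == "OI") {
    f <- interp_knots(lib$media_ramp$days, lib$media_ramp$frac, day)
    r <- mr$rate * (1 + f * (mr$oi_ratio - 1))
  }
  r
}

#' Default integration windows of a library
#'
#' @param lib A `metabolite_library`.
#' @param compartment `"cell"` or `"media"`.
#' @return Data frame with columns `name`, `lo`, `hi` (ppm).
#' @export
library_windows <- function(lib, compartment = c("cell", "media")) {
  compartment <- match.arg(compartment)
  w <- lib$windows[lib$windows$compartment == compartment, ]
  rownames(w) <- NULL
  w[, c("name", "lo", "hi")]
}
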