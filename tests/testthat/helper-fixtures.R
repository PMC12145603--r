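# Shared fixtures, all generated in code.

# a small spectral design: one donor, two arms, two cell days, two media
# days -- full resolution so line shapes stay resolved
small_spec_config <- function(...) {
  cohort_config(n_donors = 1, replicates = 2, cell_days = c(0, 21),
                media_days = c(1, 4), missing_pattern = list(), seed = 7,
                ...)
}

# configuration with every stochastic element switched off
noiseless <- function(cfg) {
  cfg$noise_sd <- 0; cfg$shift_jitter_sd <- 0; cfg$peak_jitter_sd <- 0
  cfg$rep_cv <- 0; cfg$media_rep_cv <- 0; cfg$sample_scale_sd <- 0
  cfg$blank_cv <- 0
  cfg
}

# one or more Lorentzian peaks on a uniform grid, as a spectrum_set
peak_set <- function(centers, areas, n = 1, fwhm = 0.005,
                     ppm = seq(-0.5, 10, length.out = 8192),
                     shifts = rep(0, n), noise_sd = 0, seed = 1) {
  set.seed(seed)
  ints <- t(vapply(seq_len(n), function(i) {
    y <- numeric(length(ppm))
    for (k in seq_along(centers))
      y <- y + lorentzian(ppm, centers[k] + shifts[i], areas[k], fwhm)
    y + stats::rnorm(length(ppm), 0, noise_sd)
  }, numeric(length(ppm))))
  spectrum_set(ppm, ints,
               data.frame(sample_id = paste0("s", seq_len(n)),
                          donor = 1, arm = "CTR", day = 0,
                          replicate = seq_len(n), compartment = "cell"))
}

# shared default-cohort tables for the acceptance suite (built once)
.acceptance_cache <- new.env(parent = emptyenv())
acceptance_tables <- function(seed = 1) {
  key <- paste0("s", seed)
  got <- .acceptance_cache[[key]]
  if (is.null(got)) {
    lib <- build_default_library()
    cohort <- simulate_cohort(lib, cohort_config(seed = seed))
    got <- c(cohort_tables(cohort, lib), list(lib = lib))
    .acceptance_cache[[key]] <- got
  }
  got
}
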