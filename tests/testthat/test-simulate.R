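test_that("the same seed reproduces the cohort exactly, on disk too", {
  lib <- build_default_library()
  cfg <- small_spec_config()
  a <- simulate_cohort(lib, cfg)
  b <- simulate_cohort(lib, cfg)
  expect_identical(a, b)
  d1 <- file.path(tempdir(), "coh_a"); d2 <- file.path(tempdir(), "coh_b")
  write_cohort(a, d1); write_cohort(b, d2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_identical(f1, list.files(d2, recursive = TRUE))
  h1 <- unname(tools::md5sum(file.path(d1, f1)))
  h2 <- unname(tools::md5sum(file.path(d2, f1)))
  expect_identical(h1, h2)
  unlink(c(d1, d2), recursive = TRUE)
  # different seeds differ
  cfg2 <- cfg; cfg2$seed <- 8
  expect_false(identical(simulate_cohort(lib, cfg2), a))
})

test_that("integral output mode is deterministic and carries the same design", {
  lib <- build_default_library()
  cfg <- cohort_config(seed = 3)
  a <- simulate_cohort(lib, cfg, output = "integrals")
  b <- simulate_cohort(lib, cfg, output = "integrals")
  expect_identical(a, b)
  expect_identical(nrow(a$cells), 106L)  # 108 minus 2 missing replicates
  expect_identical(nrow(a$media), 126L)
  expect_identical(nrow(a$blanks), 42L)
})

test_that("the configured missing pattern reduces exactly the stated group", {
  lib <- build_default_library()
  co <- simulate_cohort(lib, cohort_config(seed = 2),
                       output = "integrals")
  m <- co$cells
  hit <- m$arm == "OI" & m$donor == 2 & m$day == 21
  expect_identical(sum(hit), 1L)
  # all other cell groups keep full triplicates
  others <- table(paste(m$arm, m$donor, m$day)[!hit])
  expect_true(all(others == 3))
})

test_that("days outside the horizon are rejected", {
  expect_error(cohort_config(cell_days = c(0, 25)), "horizon")
  expect_error(cohort_config(media_days = c(0, 4)), "horizon")
})

test_that("with all noise off, rendered window areas equal the true integrals", {
  lib <- build_default_library()
  cfg <- noiseless(small_spec_config())
  co <- simulate_cohort(lib, cfg)
  tab <- integrate_windows(co$cells, library_windows(lib, "cell"))
  truth <- co$truth$cell_integrals
  vars <- library_windows(lib, "cell")$name
  for (v in vars) {
    expect_equal(tab[[v]], truth[[v]], tolerance = 1e-9,
                 info = v)
  }
})

test_that("an inert media metabolite leaves no blank-minus-conditioned footprint", {
  lib <- build_default_library()
  lib$media_rates[lib$media_rates$name == "Thr", c("rate", "oi_ratio")] <-
    c(0, 1)
  cfg <- noiseless(small_spec_config())
  co <- simulate_cohort(lib, cfg)
  w <- library_windows(lib, "media")
  med <- integrate_windows(co$media, w)
  bl <- integrate_windows(co$blanks, w)
  for (d in unique(med$day)) {
    diff <- mean(med$Thr[med$day == d]) - mean(bl$Thr[bl$day == d])
    # zero up to far-tail crosstalk from neighbouring resonances
    expect_lt(abs(diff) / mean(bl$Thr[bl$day == d]), 1e-4)
  }
  # an uptaken metabolite does leave a deficit
  expect_lt(mean(med$Gln) - mean(bl$Gln), -1e-3)
})

test_that("planted effects have their sign at every day past onset (noise-free)", {
  lib <- build_default_library()
  cfg <- noiseless(cohort_config(seed = 5))
  co <- simulate_cohort(lib, cfg, output = "integrals")
  tabs <- cohort_tables(co, lib)
  sig <- co$truth$signature
  for (i in seq_len(nrow(sig))) {
    m <- sig$metabolite[i]
    tab <- if (sig$compartment[i] == "cell") tabs$cells else tabs$media
    dn <- if (sig$compartment[i] == "cell") "signed" else "abs"
    days <- sort(unique(tab$day))
    days <- days[days > sig$onset_day[i]]
    for (d in days) {
      pv <- percent_variation(tab[[m]][tab$arm == "CTR" & tab$day == d],
                              tab[[m]][tab$arm == "OI" & tab$day == d],
                              denom = dn)
      expect_identical(sign(pv),
                       if (sig$direction[i] == "up") 1 else -1,
                       info = paste(m, "day", d))
    }
  }
})

test_that("every rendered spectrum carries the TSP reference peak", {
  lib <- build_default_library()
  co <- simulate_cohort(lib, small_spec_config())
  for (set in list(co$cells, co$media, co$blanks)) {
    w <- which(set$ppm > -0.05 & set$ppm < 0.05)
    for (i in seq_len(n_spectra(set))) {
      peak <- set$ppm[w][which.max(set$intensity[i, w])]
      expect_lt(abs(peak), 0.012)  # within the shift jitter
    }
  }
})

test_that("spectrum sets round-trip through the two-column text format", {
  lib <- build_default_library()
  co <- simulate_cohort(lib, small_spec_config())
  d <- file.path(tempdir(), "spectra_rt")
  write_spectra(co$cells, d)
  back <- read_spectra(d)
  expect_equal(back$ppm, co$cells$ppm, tolerance = 1e-6)
  expect_equal(back$intensity, co$cells$intensity, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_identical(back$meta$sample_id, co$cells$meta$sample_id)
  unlink(d, recursive = TRUE)
})
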