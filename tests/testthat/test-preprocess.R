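test_that("a TSP peak already on zero gives (near) zero shift", {
  ppm <- seq(-0.5, 10, by = 0.00125)  # grid contains 0 exactly
  s <- peak_set(centers = c(0, 3), areas = c(2, 1), ppm = ppm)
  out <- reference_to_tsp(s)
  expect_equal(attr(out, "tsp_shift"), 0)
  expect_equal(out$intensity, s$intensity)
})

test_that("a planted reference offset is recovered within one grid step", {
  ppm <- seq(-0.5, 10, by = 0.00125)
  s <- peak_set(centers = c(0.013, 3.013), areas = c(2, 1), ppm = ppm)
  out <- reference_to_tsp(s)
  step <- 0.00125
  expect_lt(abs(attr(out, "tsp_shift") - (-0.013)), step + 1e-12)
  # the TSP maximum now sits at 0.00
  w <- which(out$ppm > -0.1 & out$ppm < 0.1)
  expect_lt(abs(out$ppm[w][which.max(out$intensity[1, w])]), step + 1e-12)
})

test_that("a flat reference window raises an error", {
  ppm <- seq(-0.5, 10, by = 0.01)
  s <- spectrum_set(ppm, matrix(0, 1, length(ppm)),
                    data.frame(sample_id = "s1"))
  expect_error(reference_to_tsp(s), "flat")
})

test_that("an empty mask leaves the spectrum unchanged", {
  s <- peak_set(centers = 3, areas = 1)
  out <- exclude_regions(s, matrix(numeric(), 0, 2))
  expect_equal(out$ppm, s$ppm)
  expect_equal(out$intensity, s$intensity)
})

test_that("overlapping regions are removed as their union", {
  ppm <- seq(0, 4, by = 0.01)
  s <- spectrum_set(ppm, matrix(1, 1, length(ppm)),
                    data.frame(sample_id = "s1"))
  out <- exclude_regions(s, rbind(c(1, 2), c(1.5, 3)))
  expect_identical(sum(s$ppm >= 1 & s$ppm <= 3),
                   length(s$ppm) - length(out$ppm))
  expect_false(any(out$ppm >= 1 & out$ppm <= 3))
  expect_equal(attr(out, "excluded_regions"), rbind(c(1, 3)),
               ignore_attr = TRUE)
})

test_that("the default masks remove the water region entirely", {
  s <- peak_set(centers = c(3, 4.8), areas = c(1, 5))
  out <- exclude_regions(s, default_exclusions("cell"))
  expect_identical(sum(out$ppm >= 4.5 & out$ppm <= 5.2), 0L)
  # media mask removes additional solvent/supplement regions
  outm <- exclude_regions(s, default_exclusions("media"))
  expect_identical(sum(outm$ppm >= 3.5 & outm$ppm <= 3.9), 0L)
  expect_lt(length(outm$ppm), length(out$ppm))
})

test_that("normalization forces unit sums, scale invariance and proportions", {
  s <- peak_set(centers = c(2, 6), areas = c(3, 1), fwhm = 0.003)
  n1 <- normalize_total_area(s)
  expect_equal(sum(n1$intensity), 1, tolerance = 1e-9)
  s2 <- spectrum_set(s$ppm, s$intensity * 7.3, s$meta)
  expect_equal(normalize_total_area(s2)$intensity, n1$intensity)
  # two peaks of area ratio 3:1 hold 75% / 25% of the normalized sum
  lo <- sum(n1$intensity[1, n1$ppm < 4])
  hi <- sum(n1$intensity[1, n1$ppm >= 4])
  expect_equal(lo, 0.75, tolerance = 0.01)
  expect_equal(hi, 0.25, tolerance = 0.01)
  s0 <- spectrum_set(s$ppm, matrix(0, 1, length(s$ppm)),
                     data.frame(sample_id = "z"))
  expect_error(normalize_total_area(s0), "total area")
})

test_that("normalization uses retained points only after exclusion", {
  # a huge solvent signal strictly inside the excluded region must not
  # affect scaling
  base <- peak_set(centers = c(2, 6), areas = c(3, 1), fwhm = 0.003)
  with_water <- base
  wet <- with_water$ppm >= 4.6 & with_water$ppm <= 5.1
  with_water$intensity[, wet] <- with_water$intensity[, wet] + 50
  mask <- default_exclusions("cell")
  n1 <- normalize_total_area(exclude_regions(base, mask))
  n2 <- normalize_total_area(exclude_regions(with_water, mask))
  expect_equal(n1$intensity, n2$intensity)
})

test_that("aligning a spectrum to itself applies no shift", {
  s <- peak_set(centers = c(1.5, 3, 7), areas = c(1, 2, 1), n = 2)
  out <- align_segments(s, reference = s$intensity[1, ])
  expect_equal(attr(out, "global_shift"), c(0, 0))
  expect_equal(out$intensity, s$intensity)
})

test_that("a planted jitter is recovered within one grid step", {
  ppm <- seq(-0.5, 10, length.out = 8192)
  step <- ppm[2] - ppm[1]
  s <- peak_set(centers = 3, areas = 1, n = 2, ppm = ppm,
                shifts = c(0, 0.01))
  out <- align_segments(s, reference = s$intensity[1, ],
                        max_shift = 0.03)
  peak_at <- function(y) ppm[which.max(y)]
  expect_lt(abs(peak_at(out$intensity[2, ]) - peak_at(s$intensity[1, ])),
            step + 1e-12)
})

test_that("alignment reduces deviation and preserves the integral", {
  set.seed(51)
  ppm <- seq(-0.5, 10, length.out = 8192)
  centers <- c(1.2, 2.5, 3.8, 6.1, 8.4)
  n <- 6
  shifts <- runif(n, -0.01, 0.01)
  s <- peak_set(centers = centers, areas = rep(1, 5), n = n, ppm = ppm,
                shifts = shifts)
  ref <- peak_set(centers = centers, areas = rep(1, 5),
                  ppm = ppm)$intensity[1, ]
  out <- align_segments(s, reference = ref, max_shift = 0.02)
  mse <- function(m) mean((sweep(m, 2, ref))^2)
  expect_lt(mse(out$intensity), 0.5 * mse(s$intensity))
  before <- rowSums(s$intensity)
  after <- rowSums(out$intensity)
  expect_true(all(abs(after - before) / before < 0.005))
  # idempotence: realigning moves nothing by more than a grid step
  again <- align_segments(out, reference = ref, max_shift = 0.02)
  expect_true(all(abs(attr(again, "global_shift")) <= 1))
})

test_that("min_segment larger than the spectrum is rejected", {
  s <- peak_set(centers = 3, areas = 1)
  expect_error(align_segments(s, min_segment = length(s$ppm) + 1),
               "min_segment")
})
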