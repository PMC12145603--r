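test_that("exact rank-sum p-values match closed enumeration cases", {
  expect_equal(wilcoxon_exact(c(1, 2, 3), c(4, 5, 6)), 2 / 20)
  expect_equal(wilcoxon_exact(1:5, 6:10), 2 / 252)
  expect_equal(wilcoxon_exact(c(2, 2, 2), c(2, 2, 2)), 1)
})

test_that("exact rank-sum matches an independent enumeration oracle up to 6+6", {
  # oracle: enumerate group assignments as bit masks, recompute rank sums
  # from scratch
  oracle <- function(a, b) {
    n <- length(a) + length(b)
    r <- rank(c(a, b))
    mu <- length(a) * mean(r)
    W <- sum(r[seq_along(a)])
    hits <- 0; total <- 0
    for (bits in 0:(2^n - 1)) {
      sel <- which(bitwAnd(bits, 2^(0:(n - 1))) > 0)
      if (length(sel) != length(a)) next
      total <- total + 1
      if (abs(sum(r[sel]) - mu) >= abs(W - mu) - 1e-9) hits <- hits + 1
    }
    hits / total
  }
  set.seed(10)
  for (na in 2:6) for (nb in c(3, 6)) {
    a <- round(rnorm(na), 1)  # rounding induces occasional ties
    b <- round(rnorm(nb, 0.5), 1)
    expect_equal(wilcoxon_exact(a, b), oracle(a, b),
                 info = paste("sizes", na, nb))
  }
})

test_that("untied exact p-values agree with wilcox.test", {
  set.seed(11)
  for (i in 1:5) {
    a <- rnorm(4); b <- rnorm(5, 1)
    expect_equal(wilcoxon_exact(a, b),
                 stats::wilcox.test(a, b, exact = TRUE)$p.value)
  }
})

test_that("triplicate groups cannot reach p < 0.05 with the exact test", {
  # the strongest possible 3-vs-3 separation
  expect_equal(wilcoxon_exact(c(1, 2, 3), c(10, 11, 12)), 0.1)
})

test_that("percent variation follows its definition", {
  expect_equal(percent_variation(c(2, 2), c(2, 2)), 0)
  expect_equal(percent_variation(c(2, 2), c(5, 5)), 150)
  expect_equal(percent_variation(c(-2, -2), c(-1, -1), denom = "abs"), 50)
  expect_true(is.na(percent_variation(c(0, 0), c(1, 1))))
})

test_that("Spearman rho matches the hand-computed 5-point example", {
  map <- spearman_map(matrix(1:5), matrix(c(3, 1, 2, 5, 4)),
                      rho_min = 0, p_max = 1)
  all_pairs <- attr(map, "all_pairs")
  expect_equal(all_pairs$rho, 0.6)  # 1 - 6*8/(5*24)
})

test_that("Spearman rho is invariant to monotone transforms", {
  x <- c(0.3, 1.2, 2.4, 3.1, 4.8, 6.0)
  map <- spearman_map(matrix(x), matrix(exp(x)), rho_min = 0, p_max = 1)
  expect_equal(attr(map, "all_pairs")$rho, 1)
})

test_that("exact permutation p agrees with the t-approximation regime qualitatively", {
  set.seed(12)
  x <- rnorm(8); y <- x + rnorm(8, 0, 2)
  p_exact <- osteosig:::spearman_p(x, y)
  p_approx <- osteosig:::spearman_p(x, y, exact_n = 0)
  expect_lt(abs(p_exact - p_approx), 0.1)
})

test_that("correlation-map thresholds separate the two published regimes", {
  set.seed(13)
  n <- 30
  x <- rnorm(n)
  y <- x + rnorm(n, 0, 1)
  rho <- cor(rank(x), rank(y))
  expect_true(rho > 0.7 && rho < 0.8)  # construction: rho = 0.76
  lenient <- spearman_map(matrix(x), matrix(y), rho_min = 0.7,
                          p_max = 0.001)
  strict <- spearman_map(matrix(x), matrix(y), rho_min = 0.8,
                         p_max = 0.001)
  expect_identical(nrow(lenient), 1L)
  expect_identical(nrow(strict), 0L)
})

# small integral table with controllable per-metabolite effects
make_screen_table <- function(effects, days = c(14, 21), donors = 1:3,
                              reps = 3, noise = 0.02, seed = 99) {
  set.seed(seed)
  grid <- expand.grid(replicate = seq_len(reps), day = days,
                      donor = donors, arm = c("CTR", "OI"),
                      stringsAsFactors = FALSE)
  for (m in names(effects)) {
    eff <- effects[[m]]  # function(donor, day) -> OI/CTR ratio
    mult <- mapply(function(a, dn, d)
      if (a == "OI") eff(dn, d) else 1, grid$arm, grid$donor, grid$day)
    grid[[m]] <- exp(rnorm(nrow(grid), 0, noise)) * mult
  }
  grid
}

test_that("selection requires a common sign in every donor", {
  tab <- make_screen_table(list(
    good = function(dn, d) 2,
    flipped = function(dn, d) if (dn == 3) 0.5 else 2))
  sel <- select_donor_independent(screen_markers(tab))
  expect_identical(sel$metabolite, "good")
  ev <- attr(sel, "evaluation")
  expect_false(ev$sign_consistent[ev$metabolite == "flipped"])
})

test_that("selection enforces the magnitude floor and significance", {
  tab <- make_screen_table(list(
    strong = function(dn, d) 1.6,
    weak = function(dn, d) 1.08))  # consistent but under the 20% floor
  sel <- select_donor_independent(screen_markers(tab))
  expect_identical(sel$metabolite, "strong")
  ev <- attr(sel, "evaluation")
  expect_false(ev$magnitude_ok[ev$metabolite == "weak"])
})

test_that("groups below triplicates carry no p-value, only the visual flag", {
  tab <- make_screen_table(list(m = function(dn, d) 2))
  tab <- tab[!(tab$arm == "OI" & tab$donor == 2 & tab$day == 21 &
                 tab$replicate > 1), ]
  scr <- screen_markers(tab)
  pd <- scr$per_donor
  row <- pd[pd$donor == 2 & pd$day == 21, ]
  expect_true(row$visual_only)
  expect_true(is.na(row$p))
  expect_identical(row$n_cmp, 1L)
  # all other groups still tested
  expect_true(all(!is.na(pd$p[!pd$visual_only])))
})

test_that("proliferation mode compares each day to the reference day within an arm", {
  set.seed(15)
  grid <- expand.grid(replicate = 1:3, day = c(0, 14, 21), donor = 1:3,
                      arm = c("CTR", "OI"), stringsAsFactors = FALSE)
  grid$m <- ifelse(grid$day > 0, 2, 1) * exp(rnorm(nrow(grid), 0, 0.02))
  scr <- screen_markers(grid, mode = "proliferation", arm = "CTR")
  expect_setequal(unique(scr$per_donor$day), c(14, 21))
  expect_true(all(abs(scr$per_donor$pct_var - 100) < 15))
})

test_that("selection errors without overlapping donor day grids", {
  tab <- make_screen_table(list(m = function(dn, d) 2))
  tab <- tab[!(tab$donor == 2 & tab$day == 21), ]
  scr <- screen_markers(tab)
  expect_error(select_donor_independent(scr), "donor 2")
})
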