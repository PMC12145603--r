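test_that("scaling modes satisfy their invariants and round-trip", {
  set.seed(21)
  X <- matrix(rnorm(60, 5, 2), 10, 6,
              dimnames = list(NULL, paste0("v", 1:6)))
  sc <- scale_columns(X, "uv")
  expect_true(all(abs(colMeans(sc$X)) < 1e-9))
  expect_true(all(abs(apply(sc$X, 2, sd) - 1) < 1e-9))
  expect_equal(unscale_columns(sc$X, sc), X, ignore_attr = TRUE)
  ctr <- scale_columns(X, "center")
  expect_equal(unscale_columns(ctr$X, ctr), X, ignore_attr = TRUE)
  # zero-variance columns dropped with a warning under uv
  X2 <- cbind(X, const = 3)
  expect_warning(sc2 <- scale_columns(X2, "uv"), "zero-variance")
  expect_false("const" %in% colnames(sc2$X))
})

test_that("PCA reconstructs, orders and orients components deterministically", {
  set.seed(22)
  X <- matrix(rnorm(50), 10, 5)
  p <- fit_pca(X, n_components = 5, mode = "center")
  recon <- p$scores %*% t(p$loadings)
  expect_lt(max(abs(recon - scale_columns(X, "center")$X)), 1e-8)
  G <- crossprod(p$scores)
  expect_lt(max(abs(G - diag(diag(G)))), 1e-6)
  expect_true(all(diff(p$explained_variance) <= 1e-12))
  for (a in 1:5) {
    j <- which.max(abs(p$loadings[, a]))
    expect_gte(p$loadings[j, a], 0)
  }
})

test_that("PCA separates planted clusters along PC1", {
  set.seed(23)
  X <- rbind(matrix(rnorm(50, 0), 10, 5), matrix(rnorm(50, 3), 10, 5))
  p <- fit_pca(X, 2, mode = "center")
  s1 <- p$scores[1:10, 1]; s2 <- p$scores[11:20, 1]
  # 1-D silhouette on PC1 scores, two known clusters
  sil <- function(x, own, other) {
    a <- vapply(seq_along(x), function(i) mean(abs(x[i] - own[-i])),
                numeric(1))
    b <- vapply(x, function(v) mean(abs(v - other)), numeric(1))
    mean((b - a) / pmax(a, b))
  }
  expect_gt(sil(s1, s1, s2), 0)
  expect_gt(sil(s2, s2, s1), 0)
})

test_that("the first PLS weight and scores match the analytic example", {
  X <- rbind(c(1, 0), c(-1, 0), c(0, 0))
  y <- c("OI", "CTR", "CTR")  # dummy coding 1, 0, 0
  fit <- fit_plsda(X, y, n_components = 1, mode = "center",
                   positive = "OI")
  # X'u is proportional to (1, 0) for the centred dummy response
  expect_equal(abs(as.numeric(fit$W)), c(1, 0))
  expect_equal(as.numeric(fit$scores) / fit$scores[1], c(1, -1, 0))
})

test_that("PLS scores are mutually orthogonal", {
  set.seed(24)
  X <- matrix(rnorm(80), 16, 5)
  y <- rep(c("A", "B"), each = 8)
  fit <- fit_plsda(X, y, n_components = 3)
  G <- crossprod(fit$scores)
  expect_lt(max(abs(G - diag(diag(G)))), 1e-6)
})

test_that("a single informative variable gets VIP sqrt(p), the rest zero", {
  y <- rep(c(0, 1), each = 4)
  X <- cbind(info = as.numeric(y), matrix(0, 8, 3))
  fit <- fit_plsda(X, y, n_components = 1, mode = "center")
  expect_equal(unname(fit$vip), c(2, 0, 0, 0))  # sqrt(4)
})

test_that("mean squared VIP equals one for any fitted model", {
  set.seed(25)
  for (i in 1:3) {
    X <- matrix(rnorm(9 * 5), 9, 5)
    y <- rep(c("A", "B"), length.out = 9)
    fit <- fit_plsda(X, y, n_components = 2)
    expect_equal(mean(fit$vip^2), 1, tolerance = 1e-9)
  }
})

test_that("VIP agrees with a brute-force evaluation of the formula", {
  set.seed(26)
  X <- matrix(rnorm(24), 6, 4)
  y <- c("A", "B", "A", "B", "B", "A")
  fit <- fit_plsda(X, y, n_components = 2)
  # independent evaluation from the stored weights and SSY
  W <- fit$W; ssy <- fit$explained_y_variance
  p <- nrow(W)
  brute <- vapply(seq_len(p), function(k) {
    sqrt(p * sum(ssy * (W[k, ]^2 / colSums(W^2))) / sum(ssy))
  }, numeric(1))
  expect_equal(unname(fit$vip), brute)
})

test_that("variables with zero weight in all components get VIP zero", {
  y <- rep(c(0, 1), each = 5)
  set.seed(27)
  X <- cbind(matrix(rnorm(20), 10, 2) + as.numeric(y), zero = 0)
  fit <- fit_plsda(X, y, n_components = 2, mode = "center")
  expect_equal(unname(fit$vip["zero"]), 0)
})

test_that("the first NIPALS component equals the dominant eigendirection", {
  set.seed(28)
  X <- scale(matrix(rnorm(40), 8, 5), scale = FALSE)
  y <- rep(c(0, 1), each = 4)
  fit <- fit_plsda(X, y, n_components = 1, mode = "center")
  u <- y - mean(y)
  M <- crossprod(X, u) %*% crossprod(u, X)  # X'y y'X
  e1 <- eigen(M, symmetric = TRUE)$vectors[, 1]
  w1 <- as.numeric(fit$W)
  expect_lt(min(sum((w1 - e1)^2), sum((w1 + e1)^2)), 1e-16)
})

test_that("back-transformed weights are weights times the column SD", {
  set.seed(29)
  X <- matrix(rnorm(40, 0, c(1, 5)), 8, 5)
  y <- rep(c("A", "B"), each = 4)
  fit <- fit_plsda(X, y, n_components = 2, mode = "uv")
  expect_equal(fit$back_weights, fit$W * fit$scaling$sds[fit$scaling$kept])
})

test_that("single-class labels are rejected", {
  expect_error(fit_plsda(matrix(rnorm(10), 5, 2), rep("A", 5), 1),
               "single class")
})

test_that("prediction classifies separable data and ties go to class 0", {
  set.seed(30)
  X <- rbind(matrix(rnorm(20, 0, 0.1), 10, 2),
             matrix(rnorm(20, 3, 0.1), 10, 2))
  y <- rep(c("CTR", "OI"), each = 10)
  fit <- fit_plsda(X, y, n_components = 1)
  pr <- predict(fit, X)
  expect_identical(pr$class, y)
  fit$coefficients[] <- 0  # force every score to the 0.5 tie point
  fit$y_mean <- 0.5
  pr0 <- predict(fit, X)
  expect_true(all(pr0$class == "CTR"))
})

test_that("NIPALS agrees with an independent PLS implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(31)
  X <- matrix(rnorm(60), 12, 5, dimnames = list(NULL, paste0("v", 1:5)))
  y01 <- rep(c(0, 1), each = 6)
  fit <- fit_plsda(X, y01, n_components = 2, mode = "uv")
  ref <- mixOmics::pls(X, y01, ncomp = 2, scale = TRUE,
                       mode = "regression")
  for (a in 1:2) {
    w <- fit$W[, a]; wr <- ref$loadings$X[, a]
    expect_lt(min(sum((w - wr)^2), sum((w + wr)^2)), 1e-8)
  }
})

test_that("model export round-trips through a JSON-compatible list", {
  set.seed(32)
  X <- matrix(rnorm(40), 8, 5, dimnames = list(NULL, paste0("v", 1:5)))
  y <- rep(c("CTR", "OI"), each = 4)
  fit <- fit_plsda(X, y, n_components = 2)
  lst <- plsda_to_list(fit)
  json <- jsonlite::toJSON(lst, auto_unbox = TRUE, digits = NA)
  back <- jsonlite::fromJSON(json)
  expect_equal(back$vip, unname(as.numeric(fit$vip)))
  expect_equal(back$scaling$means, unname(fit$scaling$means))
})
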