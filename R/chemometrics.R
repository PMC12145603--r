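# PCA and PLS-DA (NIPALS) with unit-variance / mean-centred scaling,
# VIP scores and back-transformed loading weights.

#' Column scaling for multivariate modelling
#'
#' Mean-centres each column and, in `"uv"` (unit-variance, autoscaling)
#' mode, divides by the column standard deviation. Zero-variance columns
#' are dropped with a warning in `"uv"` mode.
#'
#' @param X Numeric matrix (samples x variables).
#' @param mode `"uv"` or `"center"`.
#' @param means,sds Optional fixed scaling parameters (e.g. from a training
#'   set); computed from `X` when `NULL`.
#' @return List with `X` (scaled), `means`, `sds`, `mode`, `kept` (column
#'   indices retained).
#' @export
scale_columns <- function(X, mode = c("uv", "center"),
                          means = NULL, sds = NULL) {
  mode <- match.arg(mode)
  X <- as.matrix(X)
  means <- means %||% colMeans(X)
  sds <- sds %||% apply(X, 2, stats::sd)
  kept <- seq_len(ncol(X))
  if (mode == "uv") {
    zero <- sds < 1e-12
    if (any(zero)) {
      warning("dropping zero-variance column(s): ",
              paste(colnames(X)[zero], collapse = ", "))
      kept <- which(!zero)
    }
    Xs <- sweep(sweep(X[, kept, drop = FALSE], 2, means[kept]),
                2, sds[kept], "/")
  } else {
    Xs <- sweep(X, 2, means)
  }
  list(X = Xs, means = means, sds = sds, mode = mode, kept = kept)
}

# apply a fitted scaling to new samples (full original column set)
apply_scaling <- function(newX, sc) {
  newX <- as.matrix(newX)
  if (sc$mode == "uv") {
    sweep(sweep(newX[, sc$kept, drop = FALSE], 2, sc$means[sc$kept]),
          2, sc$sds[sc$kept], "/")
  } else {
    sweep(newX, 2, sc$means)
  }
}

#' Invert column scaling
#'
#' @param Xs Scaled matrix.
#' @param sc Scaling object from [scale_columns()].
#' @return Matrix on the original scale.
#' @export
unscale_columns <- function(Xs, sc) {
  if (sc$mode == "uv")
    sweep(sweep(Xs, 2, sc$sds[sc$kept], "*"), 2, sc$means[sc$kept], "+")
  else sweep(Xs, 2, sc$means, "+")
}

#' Principal component analysis
#'
#' Thin SVD-based PCA of a scaled matrix with a deterministic sign
#' convention: within each component the largest-magnitude loading element
#' is made positive.
#'
#' @param X Numeric matrix (samples x variables).
#' @param n_components Number of components.
#' @param mode Scaling mode passed to [scale_columns()].
#' @return List of class `pca_model`: `scores`, `loadings`,
#'   `explained_variance` (fractions), `scaling`.
#' @export
fit_pca <- function(X, n_components = 2, mode = c("uv", "center")) {
  mode <- match.arg(mode)
  sc <- scale_columns(X, mode)
  if (n_components > min(dim(sc$X)))
    stop("n_components exceeds the matrix rank bound")
  sv <- svd(sc$X, nu = n_components, nv = n_components)
  load <- sv$v
  scores <- sv$u %*% diag(sv$d[seq_len(n_components)], n_components)
  for (a in seq_len(n_components)) {
    j <- which.max(abs(load[, a]))
    if (load[j, a] < 0) { load[, a] <- -load[, a]; scores[, a] <- -scores[, a] }
  }
  dimnames(load) <- list(colnames(sc$X), paste0("PC", seq_len(n_components)))
  dimnames(scores) <- list(rownames(X), paste0("PC", seq_len(n_components)))
  ev <- sv$d^2 / sum(svd(sc$X, nu = 0, nv = 0)$d^2)
  structure(list(scores = scores, loadings = load,
                 explained_variance = ev[seq_len(n_components)],
                 scaling = sc),
            class = "pca_model")
}

#' Fit a two-class PLS-DA model by NIPALS
#'
#' The class labels are dummy-coded 0/1 (the `positive` level is 1) and
#' mean-centred; X is scaled per `mode`. Components are extracted by NIPALS
#' with X- and y-deflation. Samples are classified by their predicted
#' continuous response against a 0.5 cutoff on the 0/1 scale (exact ties
#' assigned to class 0). Loading weights back-transformed to the original
#' variable scale (weight times column standard deviation) are stored for
#' interpretation, alongside VIP scores.
#'
#' @param X Numeric matrix (samples x variables).
#' @param y Two-level factor/character/0-1 vector of class labels.
#' @param n_components Number of latent variables.
#' @param mode Scaling mode.
#' @param positive Label coded 1; default: second sorted unique level.
#' @return List of class `plsda_model` with weights `W`, X-loadings `P`,
#'   y-loadings `q`, scores `T`, coefficients, VIP, back-transformed
#'   weights, per-component explained y-variance, and the scaling.
#' @export
fit_plsda <- function(X, y, n_components = 2, mode = c("uv", "center"),
                      positive = NULL) {
  mode <- match.arg(mode)
  X <- as.matrix(X)
  lv <- sort(unique(as.character(y)))
  if (length(lv) == 1L) stop("y contains a single class")
  if (length(lv) != 2L) stop("PLS-DA here is strictly two-class")
  positive <- positive %||% lv[2]
  y01 <- as.numeric(as.character(y) == positive)
  sc <- scale_columns(X, mode)
  Xw <- sc$X
  ybar <- mean(y01)
  u <- y01 - ybar
  n_components <- min(n_components, min(dim(Xw)))

  p <- ncol(Xw)
  W <- matrix(0, p, n_components)
  P <- matrix(0, p, n_components)
  Tm <- matrix(0, nrow(Xw), n_components)
  q <- numeric(n_components)
  ssy <- numeric(n_components)
  yres <- u
  for (a in seq_len(n_components)) {
    w <- crossprod(Xw, yres)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) { n_components <- a - 1L; break }
    w <- w / nw
    tt <- Xw %*% w
    tt2 <- sum(tt^2)
    pl <- crossprod(Xw, tt) / tt2
    qq <- sum(yres * tt) / tt2
    W[, a] <- w; P[, a] <- pl; Tm[, a] <- tt; q[a] <- qq
    ssy[a] <- qq^2 * tt2
    Xw <- Xw - tcrossprod(tt, pl)
    yres <- yres - qq * tt
  }
  if (n_components == 0L) stop("no usable PLS component (X'y vanished)")
  keep <- seq_len(n_components)
  W <- W[, keep, drop = FALSE]; P <- P[, keep, drop = FALSE]
  Tm <- Tm[, keep, drop = FALSE]; q <- q[keep]; ssy <- ssy[keep]

  B <- W %*% solve(crossprod(P, W), q)
  sdv <- if (sc$mode == "uv") sc$sds[sc$kept] else sc$sds
  model <- structure(list(
    W = W, P = P, q = q, scores = Tm, coefficients = B,
    y_mean = ybar, levels = lv, positive = positive,
    explained_y_variance = ssy / sum((y01 - ybar)^2),
    back_weights = W * sdv,
    scaling = sc, n_components = n_components
  ), class = "plsda_model")
  model$vip <- vip(model)
  model
}

#' Variable importance in projection
#'
#' Standard VIP: \eqn{VIP_k = \sqrt{p \sum_a SSY_a (w_{ak}/\|w_a\|)^2 /
#' \sum_a SSY_a}} where \eqn{SSY_a} is the y-variance explained by
#' component a. The mean squared VIP over variables equals 1 by
#' construction.
#'
#' @param model A fitted `plsda_model`.
#' @return Named numeric vector of VIP scores.
#' @export
vip <- function(model) {
  stopifnot(inherits(model, "plsda_model"))
  W <- model$W
  ssy <- model$explained_y_variance
  p <- nrow(W)
  wn2 <- sweep(W^2, 2, colSums(W^2), "/")
  v <- sqrt(p * as.numeric(wn2 %*% ssy) / sum(ssy))
  stats::setNames(v, colnames(model$scaling$X))
}

#' Predict from a PLS-DA model
#'
#' @param object A `plsda_model`.
#' @param newdata Matrix of new samples (original variable scale).
#' @param ... Unused.
#' @return Data frame with the continuous `score` (0/1 dummy scale) and
#'   the assigned `class` (score > 0.5 is the positive class; exact ties
#'   go to the negative class).
#' @export
predict.plsda_model <- function(object, newdata, ...) {
  sc <- object$scaling
  Xs <- apply_scaling(newdata, sc)
  score <- as.numeric(Xs %*% object$coefficients) + object$y_mean
  neg <- setdiff(object$levels, object$positive)
  data.frame(score = score,
             class = ifelse(score > 0.5, object$positive, neg),
             row.names = rownames(newdata))
}

#' Export a PLS-DA model as a JSON-compatible list
#'
#' @param model A `plsda_model`.
#' @return Plain list of numeric vectors/matrices suitable for
#'   `jsonlite::toJSON()`.
#' @export
plsda_to_list <- function(model) {
  list(weights = unname(model$W), x_loadings = unname(model$P),
       y_loadings = model$q, coefficients = as.numeric(model$coefficients),
       y_mean = model$y_mean, levels = model$levels,
       positive = model$positive, vip = as.numeric(model$vip),
       back_weights = unname(model$back_weights),
       variables = colnames(model$scaling$X),
       scaling = list(mode = model$scaling$mode,
                      means = as.numeric(model$scaling$means),
                      sds = as.numeric(model$scaling$sds)))
}
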