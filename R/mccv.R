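# Monte Carlo cross-validation of PLS-DA: Q2, sensitivity, specificity and
# classification rate over repeated random stratified block partitions.

#' MCCV configuration
#'
#' @param n_blocks Blocks per random stratified partition; one block is
#'   held out per iteration (test fraction about `1/n_blocks`).
#' @param n_iterations Number of Monte Carlo iterations.
#' @param seed Integer seed; fully determines the MCCV result.
#' @param mode Scaling mode (`"uv"` or `"center"`), fit on training data
#'   only within each iteration.
#' @param lv_range Candidate numbers of latent variables; the count is
#'   chosen inside each training split by maximum inner cross-validated Q2.
#' @param inner_folds Folds of the inner component-selection CV.
#' @return An object of class `mccv_config`.
#' @export
mccv_config <- function(n_blocks = 7, n_iterations = 500, seed = 1,
                        mode = c("uv", "center"), lv_range = 1:3,
                        inner_folds = 5) {
  mode <- match.arg(mode)
  stopifnot(n_blocks >= 2, n_iterations >= 1, all(lv_range >= 1))
  structure(list(n_blocks = n_blocks, n_iterations = n_iterations,
                 seed = seed, mode = mode, lv_range = sort(lv_range),
                 inner_folds = inner_folds),
            class = "mccv_config")
}

#' Confusion-matrix metrics
#'
#' @param truth,predicted Equal-length label vectors.
#' @param positive The positive-class label.
#' @return Named vector: `sens` = TP/(TP+FN), `spec` = TN/(TN+FP),
#'   `cr` = (TP+TN)/n (classification rate / accuracy).
#' @export
confusion_metrics <- function(truth, predicted, positive) {
  if (length(truth) == 0L) stop("empty input")
  if (length(truth) != length(predicted)) stop("length mismatch")
  tp <- sum(truth == positive & predicted == positive)
  fn <- sum(truth == positive & predicted != positive)
  tn <- sum(truth != positive & predicted != positive)
  fp <- sum(truth != positive & predicted == positive)
  c(sens = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    spec = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    cr = (tp + tn) / length(truth))
}

#' Predictive power Q2
#'
#' `1 - PRESS/TSS` where TSS is taken about the training-set mean of the
#' 0/1 class coding; predicting the training mean for every sample gives
#' exactly 0.
#'
#' @param y_true 0/1 responses of the held-out samples.
#' @param y_pred Predicted continuous responses.
#' @param y_train_mean Mean of the training responses.
#' @return Scalar Q2 (at most 1; can be negative).
#' @export
q2_score <- function(y_true, y_pred, y_train_mean) {
  press <- sum((y_true - y_pred)^2)
  tss <- sum((y_true - y_train_mean)^2)
  if (tss == 0) return(NA_real_)
  1 - press / tss
}

# stratified assignment of samples to n_blocks blocks (random, balanced
# within class)
stratified_blocks <- function(y, n_blocks) {
  blocks <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    blocks[idx] <- sample(rep_len(sample(n_blocks), length(idx)))
  }
  blocks
}

# fit on train, return continuous predictions for test at each candidate
# LV count (matrix: length(test) x length(lv_range))
pls_predict_lvs <- function(Xtr, ytr, Xte, lv_range, mode) {
  fit <- fit_plsda(Xtr, ytr, n_components = max(lv_range), mode = mode,
                   positive = "1")
  sc <- fit$scaling
  Xs <- apply_scaling(Xte, sc)
  out <- matrix(NA_real_, nrow(Xs), length(lv_range))
  for (k in seq_along(lv_range)) {
    a <- min(lv_range[k], fit$n_components)
    Wa <- fit$W[, 1:a, drop = FALSE]
    Pa <- fit$P[, 1:a, drop = FALSE]
    Ba <- Wa %*% solve(crossprod(Pa, Wa), fit$q[1:a])
    out[, k] <- as.numeric(Xs %*% Ba) + fit$y_mean
  }
  out
}

#' Single MCCV split: train, select components, predict held-out samples
#'
#' Internal workhorse of [run_mccv()], exposed for testability: all scaling
#' parameters and the latent-variable count are determined from the
#' training samples only.
#'
#' @param X Matrix (samples x variables).
#' @param y01 0/1 numeric class labels.
#' @param test_idx Indices of the held-out block.
#' @param cfg An [mccv_config()].
#' @return List with `pred` (continuous), `class` (0/1), `q2`, `lv`
#'   (selected component count), `train_mean`.
#' @export
mccv_split <- function(X, y01, test_idx, cfg) {
  tr <- setdiff(seq_len(nrow(X)), test_idx)
  ytr <- y01[tr]
  if (length(unique(ytr)) < 2L) stop("training split lost a class")
  Xtr <- X[tr, , drop = FALSE]

  lv <- cfg$lv_range[1]
  if (length(cfg$lv_range) > 1L) {
    folds <- stratified_blocks(ytr, min(cfg$inner_folds, length(tr) - 1L))
    press <- numeric(length(cfg$lv_range))
    ok <- TRUE
    for (f in unique(folds)) {
      it <- which(folds == f)
      if (length(unique(ytr[-it])) < 2L) { ok <- FALSE; break }
      pr <- pls_predict_lvs(Xtr[-it, , drop = FALSE], ytr[-it],
                            Xtr[it, , drop = FALSE], cfg$lv_range, cfg$mode)
      press <- press + colSums((ytr[it] - pr)^2)
    }
    if (ok) lv <- cfg$lv_range[which.min(press)]
  }

  pred <- pls_predict_lvs(Xtr, ytr, X[test_idx, , drop = FALSE], lv,
                          cfg$mode)[, 1]
  list(pred = pred, class = as.numeric(pred > 0.5), q2 = q2_score(
    y01[test_idx], pred, mean(ytr)), lv = lv, train_mean = mean(ytr))
}

#' Monte Carlo cross-validation of a PLS-DA classifier
#'
#' Per iteration: a random stratified partition into `n_blocks` blocks is
#' drawn, one block held out, scaling and latent-variable count determined
#' on the remaining blocks, a PLS-DA model fit, and the held-out samples
#' predicted. Q2 is pooled per iteration (TSS about the training-set class
#' mean) and averaged; sensitivity, specificity and classification rate
#' are reported both as iteration means and pooled over all held-out
#' predictions.
#'
#' @param X Matrix (samples x variables).
#' @param y Two-level class labels.
#' @param cfg An [mccv_config()].
#' @param positive Label treated as the positive class (coded 1); default
#'   the second sorted level.
#' @return List of class `mccv_result`: `iterations` (per-iteration Q2,
#'   sens, spec, cr, lv), `summary` (means and SDs), `pooled` (confusion
#'   counts and pooled metrics incl. pooled Q2).
#' @export
run_mccv <- function(X, y, cfg = mccv_config(), positive = NULL) {
  X <- as.matrix(X)
  lv <- sort(unique(as.character(y)))
  stopifnot(length(lv) == 2L)
  positive <- positive %||% lv[2]
  y01 <- as.numeric(as.character(y) == positive)
  if (min(table(y01)) < 2L) stop("need at least 2 samples per class")

  with_seed(cfg$seed, {
    iters <- data.frame(q2 = numeric(cfg$n_iterations), sens = NA_real_,
                        spec = NA_real_, cr = NA_real_, lv = NA_integer_)
    counts <- c(tp = 0, fn = 0, tn = 0, fp = 0)
    press_tot <- 0; tss_tot <- 0
    for (it in seq_len(cfg$n_iterations)) {
      for (try in 1:100) {
        blocks <- stratified_blocks(y01, cfg$n_blocks)
        hold <- sample(cfg$n_blocks, 1)
        test_idx <- which(blocks == hold)
        if (length(test_idx) > 0L &&
            length(unique(y01[-test_idx])) == 2L) break
        if (try == 100) stop("could not build a two-class training split")
      }
      sp <- mccv_split(X, y01, test_idx, cfg)
      m <- confusion_metrics(y01[test_idx], sp$class, 1)
      iters$q2[it] <- sp$q2
      iters$sens[it] <- m["sens"]; iters$spec[it] <- m["spec"]
      iters$cr[it] <- m["cr"]; iters$lv[it] <- sp$lv
      counts["tp"] <- counts["tp"] + sum(y01[test_idx] == 1 & sp$class == 1)
      counts["fn"] <- counts["fn"] + sum(y01[test_idx] == 1 & sp$class == 0)
      counts["tn"] <- counts["tn"] + sum(y01[test_idx] == 0 & sp$class == 0)
      counts["fp"] <- counts["fp"] + sum(y01[test_idx] == 0 & sp$class == 1)
      press_tot <- press_tot + sum((y01[test_idx] - sp$pred)^2)
      tss_tot <- tss_tot + sum((y01[test_idx] - sp$train_mean)^2)
    }
    pooled <- c(
      sens = unname(counts["tp"] / (counts["tp"] + counts["fn"])),
      spec = unname(counts["tn"] / (counts["tn"] + counts["fp"])),
      cr = unname((counts["tp"] + counts["tn"]) / sum(counts)),
      q2 = 1 - press_tot / tss_tot)
    structure(list(
      iterations = iters,
      summary = data.frame(
        metric = c("q2", "sens", "spec", "cr"),
        mean = c(mean(iters$q2, na.rm = TRUE), mean(iters$sens, na.rm = TRUE),
                 mean(iters$spec, na.rm = TRUE), mean(iters$cr, na.rm = TRUE)),
        sd = c(stats::sd(iters$q2, na.rm = TRUE),
               stats::sd(iters$sens, na.rm = TRUE),
               stats::sd(iters$spec, na.rm = TRUE),
               stats::sd(iters$cr, na.rm = TRUE))),
      pooled = pooled, counts = counts, config = cfg,
      positive = positive, n = nrow(X)),
      class = "mccv_result")
  })
}

#' @export
print.mccv_result <- function(x, ...) {
  cat("<mccv_result> ", x$config$n_iterations, " iterations x ",
      x$config$n_blocks, " blocks, n = ", x$n, "\n", sep = "")
  p <- x$pooled
  cat(sprintf("pooled: sens %.3f  spec %.3f  CR %.3f  Q2 %.3f\n",
              p["sens"], p["spec"], p["cr"], p["q2"]))
  invisible(x)
}

#' MCCV model series excluding progressively earlier timepoints
#'
#' Re-runs [run_mccv()] on the subsets of samples with `day >= cutoff` for
#' each cutoff, mirroring model series built on progressively later
#' culture stages.
#'
#' @param X Matrix (samples x variables).
#' @param meta Data frame with `day` and the class column.
#' @param day_cutoffs Increasing day cutoffs.
#' @param cfg An [mccv_config()]; each model derives its own seed from it.
#' @param class_col Name of the label column in `meta`.
#' @param positive Positive-class label.
#' @return Named list of `mccv_result`, one per cutoff, with a `summary`
#'   data frame attribute (cutoff, n, pooled metrics).
#' @export
progressive_timepoint_models <- function(X, meta, day_cutoffs,
                                         cfg = mccv_config(),
                                         class_col = "arm",
                                         positive = NULL) {
  stopifnot(nrow(meta) == nrow(X))
  if (any(day_cutoffs > max(meta$day)))
    stop("cutoff beyond the last sampled day")
  out <- list()
  summ <- NULL
  for (k in seq_along(day_cutoffs)) {
    cut <- day_cutoffs[k]
    sel <- meta$day >= cut
    ysub <- meta[[class_col]][sel]
    if (min(table(ysub)) < 2L)
      stop("fewer than 2 samples per class at cutoff ", cut)
    cfg_k <- cfg
    cfg_k$seed <- derive_seed(cfg$seed, k)
    res <- run_mccv(as.matrix(X)[sel, , drop = FALSE], ysub, cfg_k,
                    positive = positive)
    out[[paste0("D", cut)]] <- res
    summ <- rbind(summ, data.frame(
      cutoff = cut, n = sum(sel), sens = res$pooled["sens"],
      spec = res$pooled["spec"], cr = res$pooled["cr"],
      q2 = res$pooled["q2"], row.names = NULL))
  }
  attr(out, "summary") <- summ
  out
}
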