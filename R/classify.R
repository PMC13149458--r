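# PD-vs-HC classification harness. Features are the 4005 upper-triangle
# edge weights (SVM, SVM64 = PCA to 64 components first) or the connectome
# itself (GNNs). Evaluation is stratified k-fold cross-validation with
# accuracy, precision, recall, AUC and F1 per fold; PD is the positive
# class throughout.

CLASSIFIER_MODELS <- c("GAT", "GCN", "SVM", "SVM64")

#' Stratified k-fold assignment
#'
#' Partitions subjects into k validation folds, stratified by group so
#' that every fold's class ratio is within one subject of the cohort
#' ratio. Deterministic given the seed.
#'
#' @param manifest a [cohort_manifest()].
#' @param k number of folds (>= 2; each class must have >= k members).
#' @param seed integer seed.
#' @return integer vector of fold ids (1..k) named by subject_id, in
#'   manifest order.
#' @export
make_folds <- function(manifest, k = 5, seed = 1L) {
  stopifnot(k >= 2)
  tab <- table(manifest$group)
  if (any(tab < k)) {
    stop("every class needs at least k = ", k, " members; got ",
         paste(sprintf("%s=%d", names(tab), tab), collapse = ", "))
  }
  set.seed(seed)
  fold <- integer(nrow(manifest))
  for (g in names(tab)) {
    idx <- which(manifest$group == g)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  names(fold) <- manifest$subject_id
  fold
}

# Rank-based AUC of scores for the positive class (ties get half credit).
auc_score <- function(scores, is_pos) {
  n1 <- sum(is_pos); n0 <- sum(!is_pos)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[is_pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Confusion metrics with PD as positive class; empty denominators give 0
# (no positive predictions => zero precision, matching how near-degenerate
# classifiers are usually reported).
confusion_metrics <- function(truth_pos, pred_pos) {
  tp <- sum(truth_pos & pred_pos); fp <- sum(!truth_pos & pred_pos)
  fn <- sum(truth_pos & !pred_pos)
  acc <- mean(truth_pos == pred_pos)
  prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
  rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  c(accuracy = acc, precision = prec, recall = rec, f1 = f1)
}

# Standardize columns by training statistics (sd 0 -> left centered only).
fit_scaler <- function(Xtr) {
  mu <- colMeans(Xtr)
  sdv <- apply(Xtr, 2, stats::sd)
  sdv[sdv == 0] <- 1
  list(mu = mu, sd = sdv)
}
apply_scaler <- function(X, sc) sweep(sweep(X, 2, sc$mu), 2, sc$sd, "/")

#' Linear SVM (optionally PCA-64) cross-validated classification
#'
#' Per fold: features are standardized with training-fold statistics only;
#' with `use_pca64` a PCA is fitted on the training fold and the first
#' min(64, rank) components kept; a linear-kernel SVM is fitted and
#' evaluated on the held-out fold. AUC uses the SVM decision values,
#' oriented so larger means more PD-like.
#'
#' @param x a [cohort()] or [simulate_cohort()] result.
#' @param metric,filtering connectome slice to classify.
#' @param folds fold assignment from [make_folds()].
#' @param use_pca64 reduce to 64 principal components first (the SVM64
#'   model).
#' @param cost SVM regularization parameter C (default 1).
#' @return data.frame of per-fold rows: filtering, metric, model, fold,
#'   accuracy, precision, recall, auc, f1.
#' @export
train_eval_svm <- function(x, metric, filtering, folds, use_pca64 = FALSE,
                           cost = 1) {
  if (inherits(x, "sim_cohort")) x <- x$cohort
  stopifnot(inherits(x, "cohort"))
  X <- cohort_edge_matrix(x, metric, filtering)
  y <- factor(x$manifest$group, levels = c("HC", "PD"))
  stopifnot(identical(names(folds), x$manifest$subject_id))
  rows <- vector("list", max(folds))
  for (k in sort(unique(folds))) {
    tr <- folds != k; va <- !tr
    if (length(unique(y[tr])) < 2) stop("single-class training fold")
    sc <- fit_scaler(X[tr, , drop = FALSE])
    Xtr <- apply_scaler(X[tr, , drop = FALSE], sc)
    Xva <- apply_scaler(X[va, , drop = FALSE], sc)
    n_comp <- NA_integer_
    if (use_pca64) {
      pca <- stats::prcomp(Xtr, center = FALSE, scale. = FALSE, rank. = 64)
      n_comp <- ncol(pca$rotation)
      Xtr <- Xtr %*% pca$rotation
      Xva <- Xva %*% pca$rotation
    }
    fit <- e1071::svm(Xtr, y[tr], kernel = "linear", cost = cost,
                      scale = FALSE)
    pred <- stats::predict(fit, Xva, decision.values = TRUE)
    dv <- drop(attr(pred, "decision.values"))
    # decision values are oriented toward the first class named in the
    # column label; flip so larger = more PD-like
    if (grepl("^HC", colnames(attr(pred, "decision.values"))[1])) dv <- -dv
    cm <- confusion_metrics(y[va] == "PD", pred == "PD")
    rows[[k]] <- data.frame(
      filtering = filtering, metric = metric,
      model = if (use_pca64) "SVM64" else "SVM", fold = k,
      accuracy = cm["accuracy"], precision = cm["precision"],
      recall = cm["recall"], auc = auc_score(dv, y[va] == "PD"),
      f1 = cm["f1"], n_components = n_comp,
      stringsAsFactors = FALSE, row.names = NULL
    )
  }
  do.call(rbind, rows)
}

#' Summary grid of classification results
#'
#' Aggregates per-fold rows into the mean +- sd reporting grid: one block
#' per (filtering, metric), one row per model, with the best value per
#' performance column flagged within each block.
#'
#' @param rows row-bound per-fold results from [train_eval_svm()] /
#'   [train_eval_gnn()].
#' @return data.frame with columns filtering, metric, model, then
#'   `<metric>_mean`, `<metric>_sd` for each performance measure, a
#'   formatted `"mean ± sd"` string column per measure, and
#'   `best_<measure>` flags.
#' @export
report_table <- function(rows) {
  meas <- c("accuracy", "precision", "recall", "auc", "f1")
  keys <- unique(rows[, c("filtering", "metric", "model")])
  out <- vector("list", nrow(keys))
  for (k in seq_len(nrow(keys))) {
    sub <- rows[rows$filtering == keys$filtering[k] &
                  rows$metric == keys$metric[k] &
                  rows$model == keys$model[k], ]
    rec <- data.frame(filtering = keys$filtering[k], metric = keys$metric[k],
                      model = keys$model[k], stringsAsFactors = FALSE)
    for (m in meas) {
      rec[[paste0(m, "_mean")]] <- mean(sub[[m]])
      rec[[paste0(m, "_sd")]] <- stats::sd(sub[[m]])
      rec[[paste0(m, "_fmt")]] <- sprintf("%.2f ± %.2f", mean(sub[[m]]),
                                          stats::sd(sub[[m]]))
    }
    out[[k]] <- rec
  }
  out <- do.call(rbind, out)
  for (m in meas) {
    out[[paste0("best_", m)]] <- FALSE
    for (blk in split(seq_len(nrow(out)),
                      paste(out$filtering, out$metric))) {
      vals <- out[[paste0(m, "_mean")]][blk]
      out[[paste0("best_", m)]][blk] <- vals == max(vals)
    }
  }
  rownames(out) <- NULL
  out
}
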