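# Message-passing graph neural networks for connectome classification,
# implemented from scratch (dense linear algebra, manual backpropagation,
# Adam). Two variants:
#   GCN  "node concat"            message(i,j) = MLP(x_i || x_j)
#   GAT  "node concat, attention" message(i,j) = MLP(x_i || (a_ij x_j))
# with a_ij a learned single-head attention coefficient normalized over
# each node's neighborhood (softmax of a LeakyReLU-scored pair function).
# Node features are the connection profiles (each node's row of the
# weight matrix); messages are mean-aggregated over neighbors, node
# features mean-pooled into a graph embedding, and a linear head gives the
# PD logit. Training uses class-weighted binary cross-entropy.

#' One round of message passing
#'
#' Reference implementation of the message-passing update used by the
#' connectome classifiers, exposed for inspection and testing. For every
#' ordered neighbor pair (i, j) with `adjacency[i, j] > 0` the message is
#' `mlp(concat(x_i, a_ij * x_j))`; node i's new features aggregate its
#' incoming messages. With all `a_ij = 1` the attention variant reduces
#' exactly to plain node-concat.
#'
#' @param node_features n x d matrix, row i = features of node i.
#' @param adjacency symmetric n x n weight matrix; nonzero = neighbor.
#' @param mlp function mapping an (n_pairs x 2d) matrix of concatenated
#'   pair features to messages; `NULL` means identity (messages are the
#'   raw concatenations, handy for hand-checked examples).
#' @param variant `"node_concat"` or `"node_concat_attention"`.
#' @param attention for the attention variant: an n x n matrix of
#'   coefficients a_ij, or a scalar applied to every pair; `NULL` means 1
#'   (the stated reduction to node-concat).
#' @param aggregation `"mean"` (default) or `"sum"` over neighbors.
#' @return matrix of updated node features (n x d_message); nodes with no
#'   neighbors get zero rows.
#' @export
message_pass <- function(node_features, adjacency,
                         mlp = NULL,
                         variant = c("node_concat", "node_concat_attention"),
                         attention = NULL,
                         aggregation = c("mean", "sum")) {
  variant <- match.arg(variant)
  aggregation <- match.arg(aggregation)
  X <- as.matrix(node_features)
  n <- nrow(X)
  if (!is.matrix(adjacency) || any(dim(adjacency) != n)) {
    stop("adjacency must be an n x n matrix matching node_features rows")
  }
  pr <- which(adjacency > 0 & row(adjacency) != col(adjacency),
              arr.ind = TRUE)
  pr <- pr[order(pr[, 1], pr[, 2]), , drop = FALSE]
  src <- pr[, 1]; dst <- pr[, 2]
  a <- if (variant == "node_concat") {
    rep(1, length(src))
  } else if (is.null(attention)) {
    rep(1, length(src))
  } else if (length(attention) == 1) {
    rep(attention, length(src))
  } else {
    attention[cbind(src, dst)]
  }
  pair_feat <- cbind(X[src, , drop = FALSE], a * X[dst, , drop = FALSE])
  msg <- if (is.null(mlp)) pair_feat else mlp(pair_feat)
  msg <- as.matrix(msg)
  out <- matrix(0, n, ncol(msg))
  if (length(src)) {
    rs <- rowsum(msg, src)
    rows <- as.integer(rownames(rs))
    deg <- tabulate(src, n)[rows]
    out[rows, ] <- if (aggregation == "mean") rs / deg else rs
  }
  out
}

#' GNN training configuration
#'
#' @param variant `"GCN"` (node concat) or `"GAT"` (node concat with
#'   attention).
#' @param hidden hidden width of each message-passing layer.
#' @param n_layers number of message-passing layers.
#' @param epochs training epochs.
#' @param lr Adam learning rate.
#' @param batch_size minibatch size (graphs).
#' @param seed seed for initialization and batch order.
#' @return list of class `"gnn_config"`.
#' @export
gnn_config <- function(variant = c("GCN", "GAT"), hidden = 8, n_layers = 2,
                       epochs = 30, lr = 5e-3, batch_size = 16, seed = 1L) {
  variant <- match.arg(variant)
  structure(list(variant = variant, hidden = as.integer(hidden),
                 n_layers = as.integer(n_layers),
                 epochs = as.integer(epochs), lr = lr,
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "gnn_config")
}

# Parameter initialization (He-style for the ReLU message MLPs).
gnn_init <- function(d_in, cfg) {
  params <- list(layers = vector("list", cfg$n_layers))
  d <- d_in
  for (l in seq_len(cfg$n_layers)) {
    h <- cfg$hidden
    sdv <- sqrt(2 / (2 * d))
    layer <- list(W1 = matrix(rnorm(d * h, 0, sdv), d, h),
                  W2 = matrix(rnorm(d * h, 0, sdv), d, h),
                  b = numeric(h))
    if (cfg$variant == "GAT") {
      layer$u1 <- rnorm(d, 0, sdv)
      layer$u2 <- rnorm(d, 0, sdv)
    }
    params$layers[[l]] <- layer
    d <- h
  }
  params$w_out <- rnorm(d, 0, sqrt(1 / d))
  params$b_out <- 0
  params
}

# Pair index structure of one graph (ordered neighbor pairs, grouped by
# source node so neighborhood reductions are rowsum calls).
graph_pairs <- function(adjacency) {
  n <- nrow(adjacency)
  pr <- which(adjacency > 0 & row(adjacency) != col(adjacency),
              arr.ind = TRUE)
  pr <- pr[order(pr[, 1], pr[, 2]), , drop = FALSE]
  deg <- tabulate(pr[, 1], n)
  list(src = pr[, 1], dst = pr[, 2], deg = deg, n = n)
}

# group-wise softmax over source-node neighborhoods
softmax_by_src <- function(e, src, n) {
  e <- pmin(pmax(e, -30), 30)
  ex <- exp(e)
  gs <- rowsum(ex, src)
  denom <- numeric(n); denom[as.integer(rownames(gs))] <- gs
  ex / denom[src]
}

# Forward pass through all message-passing layers + readout.
# attention_override: NULL (learned/unit per variant) or a scalar forced
# onto every a_ij (used to check that GAT with a_ij = 1 equals GCN).
# Returns list(logit, caches) when keep_cache, else list(logit).
gnn_forward <- function(params, X, gp, variant, attention_override = NULL,
                        keep_cache = FALSE) {
  src <- gp$src; dst <- gp$dst
  caches <- if (keep_cache) vector("list", length(params$layers)) else NULL
  for (l in seq_along(params$layers)) {
    ly <- params$layers[[l]]
    P1 <- X[src, , drop = FALSE]
    P2 <- X[dst, , drop = FALSE]
    if (!is.null(attention_override)) {
      a <- rep(attention_override, length(src)); epre <- NULL
    } else if (variant == "GAT") {
      epre <- drop(P1 %*% ly$u1 + P2 %*% ly$u2)
      e <- ifelse(epre > 0, epre, 0.2 * epre)  # LeakyReLU score
      a <- softmax_by_src(e, src, gp$n)
    } else {
      a <- rep(1, length(src)); epre <- NULL
    }
    P2s <- a * P2
    Z <- P1 %*% ly$W1 + P2s %*% ly$W2 +
      matrix(ly$b, length(src), length(ly$b), byrow = TRUE)
    M <- pmax(Z, 0)
    Xn <- matrix(0, gp$n, ncol(M))
    rs <- rowsum(M, src)
    rows <- as.integer(rownames(rs))
    Xn[rows, ] <- rs / gp$deg[rows]
    if (keep_cache) {
      caches[[l]] <- list(X = X, P1 = P1, P2 = P2, P2s = P2s, a = a,
                          epre = epre, mask = Z > 0)
    }
    X <- Xn
  }
  g <- colMeans(X)
  logit <- sum(g * params$w_out) + params$b_out
  list(logit = logit, g = g, X_final = X, caches = caches)
}

# Backward pass: gradient of the loss wrt all parameters given
# dlogit = dL/dlogit. Mirrors gnn_forward exactly.
gnn_backward <- function(params, fw, gp, variant, dlogit) {
  src <- gp$src; dst <- gp$dst; n <- gp$n
  grads <- list(layers = vector("list", length(params$layers)))
  grads$w_out <- dlogit * fw$g
  grads$b_out <- dlogit
  dX <- matrix(dlogit * params$w_out / n, n, length(params$w_out),
               byrow = TRUE)
  for (l in rev(seq_along(params$layers))) {
    ly <- params$layers[[l]]
    ca <- fw$caches[[l]]
    dM <- dX[src, , drop = FALSE] / gp$deg[src]
    dZ <- dM * ca$mask
    g <- list(W1 = crossprod(ca$P1, dZ),
              W2 = crossprod(ca$P2s, dZ),
              b = colSums(dZ))
    dP1 <- dZ %*% t(ly$W1)
    dP2s <- dZ %*% t(ly$W2)
    dXin <- matrix(0, n, ncol(ca$X))
    rs <- rowsum(dP1, src)
    dXin[as.integer(rownames(rs)), ] <-
      dXin[as.integer(rownames(rs)), , drop = FALSE] + rs
    dP2 <- ca$a * dP2s
    rs <- rowsum(dP2, dst)
    dXin[as.integer(rownames(rs)), ] <-
      dXin[as.integer(rownames(rs)), , drop = FALSE] + rs
    if (variant == "GAT" && !is.null(ca$epre)) {
      da <- rowSums(dP2s * ca$P2)
      gsum <- rowsum(ca$a * da, src)
      gs <- numeric(n); gs[as.integer(rownames(gsum))] <- gsum
      de <- ca$a * (da - gs[src])
      depre <- de * ifelse(ca$epre > 0, 1, 0.2)
      g$u1 <- drop(crossprod(ca$P1, depre))
      g$u2 <- drop(crossprod(ca$P2, depre))
      s1 <- rowsum(depre, src)
      dXin[as.integer(rownames(s1)), ] <-
        dXin[as.integer(rownames(s1)), , drop = FALSE] +
        drop(s1) %o% ly$u1
      s2 <- rowsum(depre, dst)
      dXin[as.integer(rownames(s2)), ] <-
        dXin[as.integer(rownames(s2)), , drop = FALSE] +
        drop(s2) %o% ly$u2
    }
    grads$layers[[l]] <- g
    dX <- dXin
  }
  grads
}

# flatten/unflatten parameter lists for the Adam update
gnn_flatten <- function(p) {
  unlist(lapply(p$layers, function(l) unlist(l)), use.names = FALSE) |>
    c(p$w_out, p$b_out)
}
gnn_unflatten <- function(v, template) {
  out <- template; i <- 1L
  for (l in seq_along(template$layers)) {
    for (nm in names(template$layers[[l]])) {
      len <- length(template$layers[[l]][[nm]])
      slot <- template$layers[[l]][[nm]]
      slot[] <- v[i:(i + len - 1L)]
      out$layers[[l]][[nm]] <- slot
      i <- i + len
    }
  }
  len <- length(template$w_out)
  out$w_out <- v[i:(i + len - 1L)]; i <- i + len
  out$b_out <- v[i]
  out
}

# Train on a list of graphs. Xs: list of feature matrices, gps: list of
# graph_pairs structures, y: 0/1 labels (1 = PD).
gnn_train <- function(Xs, gps, y, cfg) {
  set.seed(cfg$seed)
  params <- gnn_init(ncol(Xs[[1]]), cfg)
  n_pos <- sum(y == 1); n_neg <- sum(y == 0)
  w_pos <- length(y) / (2 * n_pos); w_neg <- length(y) / (2 * n_neg)
  theta <- gnn_flatten(params)
  m <- v <- numeric(length(theta))
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8; step <- 0L
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(length(y))
    for (start in seq(1, length(ord), by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1L, length(ord))]
      gsum <- NULL
      for (i in idx) {
        fw <- gnn_forward(params, Xs[[i]], gps[[i]], cfg$variant,
                          keep_cache = TRUE)
        p <- 1 / (1 + exp(-fw$logit))
        w <- if (y[i] == 1) w_pos else w_neg
        if (!is.finite(p)) stop("non-finite loss during GNN training")
        dlogit <- w * (p - y[i])
        gr <- gnn_backward(params, fw, gps[[i]], cfg$variant, dlogit)
        gv <- gnn_flatten(gr)
        gsum <- if (is.null(gsum)) gv else gsum + gv
      }
      gsum <- gsum / length(idx)
      step <- step + 1L
      m <- beta1 * m + (1 - beta1) * gsum
      v <- beta2 * v + (1 - beta2) * gsum^2
      mh <- m / (1 - beta1^step); vh <- v / (1 - beta2^step)
      theta <- theta - cfg$lr * mh / (sqrt(vh) + eps)
      params <- gnn_unflatten(theta, params)
    }
  }
  params
}

gnn_predict <- function(params, Xs, gps, variant) {
  vapply(seq_along(Xs), function(i) {
    1 / (1 + exp(-gnn_forward(params, Xs[[i]], gps[[i]], variant)$logit))
  }, numeric(1))
}

#' Cross-validated GNN classification of a cohort
#'
#' Per fold: node features (connection profiles) are standardized
#' entrywise with training-fold statistics, a message-passing network of
#' `cfg$n_layers` layers is trained with class-weighted binary
#' cross-entropy and Adam, and the held-out fold is scored. Deterministic
#' given the config seed.
#'
#' @param x a [cohort()] or [simulate_cohort()] result.
#' @param metric,filtering connectome slice to classify.
#' @param folds fold assignment from [make_folds()].
#' @param cfg a [gnn_config()].
#' @return data.frame of per-fold rows as in [train_eval_svm()], with
#'   `model` `"GCN"` or `"GAT"`.
#' @export
train_eval_gnn <- function(x, metric, filtering, folds,
                           cfg = gnn_config()) {
  if (inherits(x, "sim_cohort")) x <- x$cohort
  stopifnot(inherits(x, "cohort"), inherits(cfg, "gnn_config"))
  subj <- x$manifest$subject_id
  stopifnot(identical(names(folds), subj))
  W <- lapply(subj, function(s)
    cohort_connectome(x, s, metric, filtering)$weights)
  gps <- lapply(W, graph_pairs)
  y <- as.integer(x$manifest$group == "PD")
  n <- length(subj)
  rows <- vector("list", max(folds))
  for (k in sort(unique(folds))) {
    tr <- which(folds != k); va <- which(folds == k)
    # features centered per entry and scaled by the average entry sd,
    # both fitted on the training graphs only; a global scale (rather
    # than entrywise z-scoring) preserves the relative variance of
    # informative entries
    arr <- simplify2array(W[tr])
    mu <- apply(arr, c(1, 2), mean)
    sdv <- apply(arr, c(1, 2), stats::sd)
    scl <- mean(sdv[sdv > 0]); if (!is.finite(scl) || scl == 0) scl <- 1
    Xs <- lapply(W, function(m) (m - mu) / scl)
    cfg_k <- cfg; cfg_k$seed <- cfg$seed + k
    params <- gnn_train(Xs[tr], gps[tr], y[tr], cfg_k)
    p <- gnn_predict(params, Xs[va], gps[va], cfg$variant)
    cm <- confusion_metrics(y[va] == 1, p >= 0.5)
    rows[[k]] <- data.frame(
      filtering = filtering, metric = metric, model = cfg$variant,
      fold = k, accuracy = cm["accuracy"], precision = cm["precision"],
      recall = cm["recall"], auc = auc_score(p, y[va] == 1),
      f1 = cm["f1"], n_components = NA_integer_,
      stringsAsFactors = FALSE, row.names = NULL
    )
  }
  do.call(rbind, rows)
}
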