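test_that("stratified folds keep class ratios and are deterministic", {
  cfg <- simulation_config(seed = 2, metrics = "SC", labels = paste0("R", 1:4))
  man <- simulate_cohort(cfg)$cohort$manifest  # 67 HC / 166 PD
  f <- make_folds(man, k = 5, seed = 9)
  expect_equal(sort(unique(f)), 1:5)
  expect_equal(length(f), 233)
  for (k in 1:5) {
    n_pd <- sum(man$group[f == k] == "PD")
    n_hc <- sum(man$group[f == k] == "HC")
    expect_lte(abs(n_pd - 166 / 5), 1)
    expect_lte(abs(n_hc - 67 / 5), 1)
  }
  expect_identical(f, make_folds(man, k = 5, seed = 9))
  expect_false(identical(f, make_folds(man, k = 5, seed = 10)))

  toy <- cohort_manifest(sprintf("t%d", 1:8), rep(c("PD", "HC"), 4),
                         rep("F", 8), rep(60, 8))
  f2 <- make_folds(toy, k = 2, seed = 1)
  expect_equal(as.integer(table(f2)), c(4L, 4L))
  expect_error(make_folds(toy, k = 5, seed = 1), "at least k")
})

test_that("standardization and PCA are fitted on training data only", {
  set.seed(14)
  Xtr <- matrix(rnorm(50 * 30), 50, 30)
  Xva <- matrix(rnorm(10 * 30), 10, 30)
  sc <- filtconn:::fit_scaler(Xtr)
  pca <- prcomp(filtconn:::apply_scaler(Xtr, sc), center = FALSE, rank. = 5)
  # corrupting validation features cannot change the fitted transforms
  Xva_bad <- Xva * 1e6 + 100
  sc2 <- filtconn:::fit_scaler(Xtr)
  pca2 <- prcomp(filtconn:::apply_scaler(Xtr, sc2), center = FALSE, rank. = 5)
  expect_identical(sc, sc2)
  expect_identical(pca$rotation, pca2$rotation)
  # and corrupted validation rows transform through the same mapping
  expect_equal(filtconn:::apply_scaler(Xva, sc),
               filtconn:::apply_scaler(Xva, sc2))
})

test_that("PCA-64 keeps exactly 64 components when the rank allows", {
  labs <- paste0("R", 1:20)  # 190 edge features
  cfg <- simulation_config(n_hc = 50, n_pd = 50, labels = labs,
                           metrics = "SC", seed = 12)
  sim <- simulate_cohort(cfg)
  folds <- make_folds(sim$cohort$manifest, k = 5, seed = 4)
  rows <- train_eval_svm(sim, "SC", "unfiltered", folds, use_pca64 = TRUE)
  expect_true(all(rows$n_components == 64))
  expect_equal(rows$model, rep("SVM64", 5))
})

test_that("label-permuted cohorts classify at chance level", {
  labs <- paste0("R", 1:12)
  cfg <- simulation_config(n_hc = 40, n_pd = 40, labels = labs,
                           metrics = "SC", seed = 19)
  sim <- simulate_cohort(cfg)
  man <- sim$cohort$manifest
  set.seed(5)
  man$group <- sample(man$group)
  co <- cohort(man, sim$cohort$connectomes, sim$cohort$labels)
  folds <- make_folds(man, k = 5, seed = 2)
  rows <- train_eval_svm(co, "SC", "unfiltered", folds)
  expect_gte(mean(rows$auc), 0.3)
  expect_lte(mean(rows$auc), 0.7)
})

test_that("classification power rises with the planted effect size", {
  labs <- paste0("R", 1:12)
  aucs <- vapply(c(0, 1, 2), function(d) {
    effects <- if (d > 0) {
      list(effect_spec("edge_set", rbind(c(1, 2), c(1, 3), c(2, 3)),
                       cohens_d = d, metric = "FA"))
    } else list()
    cfg <- simulation_config(n_hc = 40, n_pd = 40, labels = labs,
                             metrics = "FA", effects = effects, seed = 77)
    sim <- simulate_cohort(cfg)
    folds <- make_folds(sim$cohort$manifest, k = 4, seed = 3)
    mean(train_eval_svm(sim, "FA", "unfiltered", folds)$auc)
  }, numeric(1))
  expect_true(all(diff(aucs) > 0))
  expect_lt(aucs[1], 0.65)
  expect_gt(aucs[3], 0.8)
})

test_that("report table aggregates folds into the mean±sd grid", {
  rows <- expand.grid(filtering = c("unfiltered", "filtered"),
                      metric = c("SC", "FA"), model = c("SVM", "GCN"),
                      fold = 1:5, stringsAsFactors = FALSE)
  set.seed(1)
  for (m in c("accuracy", "precision", "recall", "auc", "f1")) {
    rows[[m]] <- runif(nrow(rows))
  }
  tab <- report_table(rows)
  expect_equal(nrow(tab), 8)  # 2 filterings x 2 metrics x 2 models
  one <- rows[rows$filtering == "unfiltered" & rows$metric == "SC" &
                rows$model == "SVM", ]
  got <- tab[tab$filtering == "unfiltered" & tab$metric == "SC" &
               tab$model == "SVM", ]
  expect_equal(got$auc_mean, mean(one$auc))
  expect_equal(got$auc_sd, sd(one$auc))
  expect_match(got$auc_fmt, "±")
  # identical folds give sd = 0
  rows0 <- rows[rows$model == "SVM" & rows$metric == "SC" &
                  rows$filtering == "unfiltered", ]
  for (m in c("accuracy", "precision", "recall", "auc", "f1")) rows0[[m]] <- 0.7
  expect_equal(report_table(rows0)$auc_sd, 0)
  # exactly one best flag per measure within each block
  blk <- tab[tab$filtering == "unfiltered" & tab$metric == "SC", ]
  expect_equal(sum(blk$best_auc), 1)
})

test_that("message passing matches the hand-computable identity-MLP case", {
  X <- matrix(c(1, 0,
                0, 2,
                3, 1), 3, 2, byrow = TRUE)
  A <- matrix(1, 3, 3); diag(A) <- 0
  out <- message_pass(X, A)  # identity MLP, mean aggregation
  # node 1 aggregates concat(x1, x2) and concat(x1, x3)
  expect_equal(out[1, ], colMeans(rbind(c(1, 0, 0, 2), c(1, 0, 3, 1))))
  expect_equal(out[2, ], colMeans(rbind(c(0, 2, 1, 0), c(0, 2, 3, 1))))
  # zero-feature graph maps to zeros
  expect_true(all(message_pass(X * 0, A) == 0))
  # attention forced to 1 reduces exactly to plain node concat
  expect_equal(message_pass(X, A, variant = "node_concat_attention",
                            attention = 1),
               message_pass(X, A))
  # attention rescales the neighbor part only
  att <- matrix(0.5, 3, 3)
  out_a <- message_pass(X, A, variant = "node_concat_attention",
                        attention = att)
  expect_equal(out_a[, 1:2], out[, 1:2])
  expect_equal(out_a[, 3:4], out[, 3:4] * 0.5)
})

test_that("message passing is permutation-equivariant", {
  set.seed(8)
  for (rep in 1:5) {
    n <- 6
    X <- matrix(rnorm(n * 3), n, 3)
    A <- rand_sym(n, density = 0.7)
    perm <- sample(n)
    out <- message_pass(X, A)
    out_p <- message_pass(X[perm, ], A[perm, perm])
    expect_equal(out_p, out[perm, ], tolerance = 1e-12)
  }
})

test_that("GAT with unit attention reproduces GCN outputs exactly", {
  set.seed(12)
  n <- 7
  X <- matrix(rnorm(n * n), n, n); X <- (X + t(X)) / 2
  A <- rand_sym(n, density = 0.8)
  gp <- filtconn:::graph_pairs(A)
  cfg <- gnn_config(variant = "GAT", hidden = 5, n_layers = 2, seed = 3)
  set.seed(3)
  params <- filtconn:::gnn_init(n, cfg)
  out_gat1 <- filtconn:::gnn_forward(params, X, gp, "GAT",
                                     attention_override = 1)
  out_gcn <- filtconn:::gnn_forward(params, X, gp, "GCN")
  expect_identical(out_gat1$logit, out_gcn$logit)
  expect_identical(out_gat1$X_final, out_gcn$X_final)
  # learned attention generally differs from the unit-attention reduction
  out_gat <- filtconn:::gnn_forward(params, X, gp, "GAT")
  expect_false(identical(out_gat$logit, out_gcn$logit))
})

test_that("GNN backpropagation matches numerical gradients", {
  set.seed(3)
  n <- 5; d <- 4
  X <- matrix(rnorm(n * d), n, d)
  A <- rand_sym(n, density = 0.7)
  gp <- filtconn:::graph_pairs(A)
  for (variant in c("GCN", "GAT")) {
    cfg <- gnn_config(variant = variant, hidden = 3, n_layers = 2, seed = 5)
    set.seed(5)
    params <- filtconn:::gnn_init(d, cfg)
    lossfun <- function(p) {
      fw <- filtconn:::gnn_forward(p, X, gp, variant)
      -log(1 / (1 + exp(-fw$logit)))
    }
    fw <- filtconn:::gnn_forward(params, X, gp, variant, keep_cache = TRUE)
    pr <- 1 / (1 + exp(-fw$logit))
    gr <- filtconn:::gnn_backward(params, fw, gp, variant, pr - 1)
    th <- filtconn:::gnn_flatten(params)
    gv <- filtconn:::gnn_flatten(gr)
    eps <- 1e-6
    idx <- sample(length(th), 25)
    for (i in idx) {
      tp <- th; tp[i] <- tp[i] + eps
      tm <- th; tm[i] <- tm[i] - eps
      num <- (lossfun(filtconn:::gnn_unflatten(tp, params)) -
                lossfun(filtconn:::gnn_unflatten(tm, params))) / (2 * eps)
      expect_equal(gv[i], num, tolerance = 1e-5)
    }
  }
})
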