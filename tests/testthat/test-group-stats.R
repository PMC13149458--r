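# small node-metric table builder: one metric/filtering/measure family
# with explicitly chosen per-node subject values
fake_nodes <- function(V, subj, metric = "SC", filtering = "unfiltered",
                       measure = "strength") {
  n_nodes <- ncol(V)
  do.call(rbind, lapply(seq_along(subj), function(i) {
    data.frame(subject_id = subj[i], metric = metric, filtering = filtering,
               graph_measure = measure, node = seq_len(n_nodes),
               region = paste0("N", seq_len(n_nodes)), value = V[i, ],
               stringsAsFactors = FALSE)
  }))
}

test_that("BY adjustment matches the closed-form arithmetic", {
  p <- c(0.001, 0.02, 0.5)
  # c(3) = 1 + 1/2 + 1/3; adjusted (before clamping): 0.0055, 0.055, 0.9167
  expect_equal(oracle_by(p), p.adjust(p, "BY"), tolerance = 1e-12)
  expect_equal(p.adjust(p, "BY"),
               c(0.001 * 3 * (11 / 6), 0.02 * 3 / 2 * (11 / 6),
                 0.5 * (11 / 6)),
               tolerance = 1e-12)
  set.seed(3)
  for (rep in 1:10) {
    pr <- runif(sample(5:40, 1))
    expect_equal(p.adjust(pr, "BY"), oracle_by(pr), tolerance = 1e-12)
  }
})

test_that("node tests: Welch t + BY + direction + stars + d", {
  set.seed(21)
  subj <- sprintf("s%02d", 1:30)
  man <- cohort_manifest(subj, rep(c("PD", "HC"), each = 15),
                         rep("F", 30), rep(60, 30))
  V <- matrix(rnorm(30 * 10, 50, 5), 30, 10)
  V[1:15, 1] <- V[1:15, 1] + 12   # PD higher on node 1
  V[16:30, 2] <- V[16:30, 2] + 12 # HC higher on node 2
  nt <- node_group_tests(fake_nodes(V, subj), man)
  expect_equal(nrow(nt), 10)
  expect_equal(nt$direction[1], "P")
  expect_equal(nt$direction[2], "H")
  expect_equal(nt$stars[1], "**")
  expect_true(all(nt$p_by >= nt$p_uncorrected))
  expect_equal(nt$p_by, p.adjust(nt$p_uncorrected, "BY"))
  # d and t sign-consistent; independent oracle on a few nodes
  expect_true(all(sign(nt$d) == sign(nt$t)))
  for (j in c(1, 2, 7)) {
    tt <- t.test(V[1:15, j], V[16:30, j])
    expect_equal(nt$t[j], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(nt$p_uncorrected[j], tt$p.value, tolerance = 1e-10)
    sp <- sqrt((14 * var(V[1:15, j]) + 14 * var(V[16:30, j])) / 28)
    expect_equal(nt$d[j], (mean(V[1:15, j]) - mean(V[16:30, j])) / sp,
                 tolerance = 1e-12)
  }
  # identical groups: t = 0, p = 1, no stars
  V2 <- rbind(V[1:15, ], V[1:15, ])
  nt2 <- node_group_tests(fake_nodes(V2, subj), man)
  expect_true(all(nt2$p_uncorrected == 1))
  expect_true(all(nt2$stars == ""))
  # untestable rows flagged as NA
  V3 <- matrix(1, 30, 3)
  nt3 <- node_group_tests(fake_nodes(V3, subj), man)
  expect_true(all(is.na(nt3$p_uncorrected)))
})

test_that("BY-corrected node families control false rejections under the null", {
  set.seed(60)
  subj <- sprintf("s%02d", 1:24)
  man <- cohort_manifest(subj, rep(c("PD", "HC"), each = 12),
                         rep("M", 24), rep(62, 24))
  any_by <- logical(150)
  for (r in 1:150) {
    V <- matrix(rnorm(24 * 20), 24, 20)
    nt <- node_group_tests(fake_nodes(V, subj), man)
    any_by[r] <- any(nt$p_by < 0.05, na.rm = TRUE)
  }
  # family-wise false rejection probability at q = 0.05 stays at or below
  # 0.05 plus binomial noise (upper 95% bound for p = 0.05, n = 150)
  expect_lte(sum(any_by), qbinom(0.975, 150, 0.05))
})

test_that("global tests report d with CI and delta d across filtering", {
  set.seed(7)
  subj <- sprintf("s%02d", 1:40)
  man <- cohort_manifest(subj, rep(c("PD", "HC"), each = 20),
                         rep("F", 40), rep(61, 40))
  g_of <- function(vals, filtering) {
    data.frame(subject_id = subj, metric = "SC", filtering = filtering,
               global_measure = "mean_strength", value = vals,
               stringsAsFactors = FALSE)
  }
  v <- rnorm(40, 100, 10); v[1:20] <- v[1:20] + 8
  globals <- rbind(g_of(v, "unfiltered"), g_of(v, "filtered"))
  res <- global_group_tests(globals, man)
  expect_equal(nrow(res$tests), 2)
  # identical filtered/unfiltered values: delta d exactly zero
  expect_equal(res$effect_sizes$delta_d, 0)
  expect_true(res$effect_sizes$d_unf_ci_low < res$effect_sizes$d_unfiltered)
  expect_true(res$effect_sizes$d_unf_ci_high > res$effect_sizes$d_unfiltered)
  # CI contains the directly recomputed pooled-sd d
  sp <- sqrt((19 * var(v[1:20]) + 19 * var(v[21:40])) / 38)
  d_hand <- (mean(v[1:20]) - mean(v[21:40])) / sp
  expect_equal(res$effect_sizes$d_unfiltered, d_hand, tolerance = 1e-12)
  # undefined values (assortativity-style) are excluded with a message
  g2 <- g_of(v, "unfiltered"); g2$value[3] <- NA
  expect_message(global_group_tests(g2, man), "excluding 1")
})

test_that("node-level effects average out at the whole-brain scale", {
  labs <- paste0("R", 1:16)
  ef <- effect_spec("node_set", 1:2, cohens_d = 1.0, metric = "SC")
  cfg <- simulation_config(n_hc = 40, n_pd = 40, labels = labs,
                           metrics = "SC", effects = list(ef), seed = 33)
  sim <- simulate_cohort(cfg)
  d_node <- empirical_effect_size(sim, "SC", "unfiltered",
                                  statistic = "strength")
  gm <- compute_cohort_metrics(sim$cohort, "SC", "unfiltered")
  res <- global_group_tests(gm$globals, sim$cohort$manifest)
  d_global <- res$tests$d[res$tests$global_measure == "mean_strength"]
  # the global average dilutes the targeted-node effect
  expect_lt(abs(d_global), max(abs(d_node[1:2])))
  expect_gt(max(abs(d_node[1:2])), 0.5)
})

test_that("filtering-impact categories follow the definitions exactly", {
  base <- data.frame(metric = "SC", graph_measure = "strength",
                     node = 1:4, region = paste0("N", 1:4),
                     t = 1, d = 1, direction = "P", stars = "",
                     stringsAsFactors = FALSE)
  un <- base; un$p_uncorrected <- c(0.03, 0.03, 0.20, 0.20)
  fi <- base; fi$p_uncorrected <- c(0.04, 0.20, 0.03, 0.20)
  imp <- filtering_impact(un, fi)
  expect_equal(imp$category,
               c("null_effect", "removal", "emergence", "never_significant"))
  # pure function of the significance patterns: row order is irrelevant
  imp2 <- filtering_impact(un[c(3, 1, 4, 2), ], fi)
  expect_equal(imp2$category[order(imp2$node)],
               imp$category[order(imp$node)])
  # grid mismatch is an alignment error
  expect_error(filtering_impact(un, fi[-2, ]), "grid")
})

test_that("wide significance report uses the direction-star cell grammar", {
  set.seed(5)
  subj <- sprintf("s%02d", 1:30)
  man <- cohort_manifest(subj, rep(c("PD", "HC"), each = 15),
                         rep("F", 30), rep(60, 30))
  V_u <- matrix(rnorm(30 * 6, 10, 1), 30, 6)
  V_u[1:15, 1] <- V_u[1:15, 1] + 4   # P** expected under SC/U
  V_f <- matrix(rnorm(30 * 6, 10, 1), 30, 6)
  nt <- node_group_tests(rbind(fake_nodes(V_u, subj),
                               fake_nodes(V_f, subj,
                                          filtering = "filtered")), man)
  rep_tab <- significance_report(nt, "strength")
  expect_true(all(c("SC_U", "SC_F") %in% names(rep_tab)))
  expect_equal(rep_tab$SC_U[rep_tab$region == "N1"], "P**")
  expect_true(all(rep_tab$SC_U %in%
                    c("-", "P*", "P**", "H*", "H**")))
  # row order follows each node's best p
  first_p <- min(nt$p_uncorrected[nt$node == 1], na.rm = TRUE)
  expect_equal(rep_tab$region[1], "N1")
  expect_lt(first_p, 0.01)
  # empty input gives an empty table with headers
  empty <- significance_report(nt[0, ], "strength")
  expect_equal(nrow(empty), 0)
  expect_equal(names(empty)[1], "region")
})
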