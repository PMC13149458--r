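small_labs <- paste0("R", 1:15)

test_that("generated cohorts satisfy all connectome invariants", {
  cfg <- simulation_config(n_hc = 4, n_pd = 5, labels = small_labs,
                           metrics = c("SC", "FA", "AD", "RD", "MD"),
                           seed = 17)
  sim <- simulate_cohort(cfg)
  expect_equal(nrow(sim$cohort$manifest), 9)
  expect_length(sim$cohort$connectomes, 9 * 5 * 2)
  for (key in names(sim$cohort$connectomes)) {
    w <- sim$cohort$connectomes[[key]]$weights
    expect_true(all(w >= 0))
    expect_equal(w, t(w))
    expect_equal(unname(diag(w)), rep(0, 15))
  }
  ut <- function(m) m[upper.tri(m)]
  for (s in sim$cohort$manifest$subject_id) {
    sc_u <- cohort_connectome(sim$cohort, s, "SC", "unfiltered")$weights
    sc_f <- cohort_connectome(sim$cohort, s, "SC", "filtered")$weights
    on <- ut(sc_u) > 0  # sampled (connected) region pairs
    # dense but not complete topology
    expect_gt(mean(on), 0.7)
    expect_lt(mean(on), 1)
    fa <- ut(cohort_connectome(sim$cohort, s, "FA", "unfiltered")$weights)
    expect_true(all(fa[on] > 0 & fa[on] < 1))
    expect_true(all(fa[!on] == 0))
    m <- sim$trace[[s]]
    expect_true(all(ut(m) >= 0 & ut(m) <= 1))
    # filtered SC is exactly multiplier x unfiltered SC
    expect_equal(ut(sc_f), ut(m) * ut(sc_u), tolerance = 1e-12)
    # MD close to the tensor coupling (AD + 2 RD) / 3 on sampled edges
    ad <- ut(cohort_connectome(sim$cohort, s, "AD", "unfiltered")$weights)
    rd <- ut(cohort_connectome(sim$cohort, s, "RD", "unfiltered")$weights)
    md <- ut(cohort_connectome(sim$cohort, s, "MD", "unfiltered")$weights)
    expect_true(all(abs(log(md[on]) - log((ad[on] + 2 * rd[on]) / 3)) < 0.05))
    # mean-metric filtering stays within the metric's valid range
    fa_f <- ut(cohort_connectome(sim$cohort, s, "FA", "filtered")$weights)
    expect_true(all(fa_f[on] > 0 & fa_f[on] < 1))
    expect_true(all(fa_f[!on] == 0))
  }
})

test_that("the same seed reproduces the cohort exactly", {
  cfg <- simulation_config(n_hc = 3, n_pd = 3, labels = small_labs,
                           metrics = c("SC", "FA"), seed = 99)
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  expect_identical(s1$cohort$manifest, s2$cohort$manifest)
  expect_identical(lapply(s1$cohort$connectomes, `[[`, "weights"),
                   lapply(s2$cohort$connectomes, `[[`, "weights"))
  expect_identical(s1$trace, s2$trace)
  s3 <- simulate_cohort(simulation_config(n_hc = 3, n_pd = 3,
                                          labels = small_labs,
                                          metrics = c("SC", "FA"), seed = 100))
  expect_false(identical(s1$trace, s3$trace))
})

test_that("default manifest mirrors the study demographics", {
  cfg <- simulation_config(seed = 1, metrics = "SC",
                           labels = paste0("R", 1:5))
  expect_equal(cfg$n_hc, 67)
  expect_equal(cfg$n_pd, 166)
  sim <- simulate_cohort(cfg)
  man <- sim$cohort$manifest
  expect_equal(sum(man$group == "HC"), 67)
  expect_equal(sum(man$group == "PD"), 166)
  expect_true(mean(man$sex[man$group == "PD"] == "F") > 0.2)
  expect_true(all(man$age > 20 & man$age < 110))
})

test_that("planted edge effects are recovered at the requested Cohen's d", {
  for (d in c(0.5, 1.5)) {
    ef <- effect_spec("edge_set", cbind(1, 2), cohens_d = d, metric = "SC")
    cfg <- simulation_config(n_hc = 100, n_pd = 100, labels = small_labs,
                             metrics = "SC", effects = list(ef),
                             seed = 40 + round(10 * d))
    sim <- simulate_cohort(cfg)
    emp <- empirical_effect_size(sim, "SC", "unfiltered")
    expect_lt(abs(emp[1, 2] - d), 0.25)
    # untargeted (sampled) edges stay near zero
    off <- upper_triangle_vector(emp)[-1]
    expect_lt(mean(abs(off), na.rm = TRUE), 0.2)
  }
})

test_that("infeasible effect sizes are rejected before sampling", {
  # raw-scale d is bounded for a log-normal weight family; d = 5 on SC
  # cannot be realized by a location shift
  ef <- effect_spec("edge_set", cbind(1, 2), cohens_d = 5, metric = "SC")
  cfg <- simulation_config(n_hc = 10, n_pd = 10, labels = small_labs,
                           metrics = "SC", effects = list(ef), seed = 1)
  expect_error(simulate_cohort(cfg), "infeasible")
})

test_that("empirical effect size matches a brute-force computation", {
  labs <- paste0("N", 1:6)
  set.seed(13)
  V <- matrix(rlnorm(20 * 15), 20, 15)
  grp <- rep(c("PD", "HC"), each = 10)
  co <- cohort_from_values(V, grp, labs)
  d <- empirical_effect_size(co, "SC", "unfiltered")
  ep <- edge_pairs(6)
  for (e in c(1, 7, 15)) {
    x1 <- V[grp == "PD", e]; x2 <- V[grp == "HC", e]
    sp <- sqrt((9 * var(x1) + 9 * var(x2)) / 18)
    expect_equal(unname(d[ep[e, 1], ep[e, 2]]), (mean(x1) - mean(x2)) / sp,
                 tolerance = 1e-12)
  }
  # identical groups: d = 0; zero variance: undefined (NA)
  V2 <- rbind(V[1:10, ], V[1:10, ])
  d2 <- empirical_effect_size(cohort_from_values(V2, grp, labs),
                              "SC", "unfiltered")
  expect_true(all(d2[upper.tri(d2)] == 0))
  V3 <- matrix(1, 20, 15)
  d3 <- empirical_effect_size(cohort_from_values(V3, grp, labs),
                              "SC", "unfiltered")
  expect_true(all(is.na(d3[upper.tri(d3)])))
})

test_that("multiplier histograms compare groups via the KS statistic", {
  cfg <- simulation_config(n_hc = 12, n_pd = 12, labels = small_labs,
                           metrics = "SC", seed = 6)
  sim <- simulate_cohort(cfg)
  h <- sift2_weight_histograms(sim, n_subjects = 20, seed = 2)
  # same filtering law in both groups: distributions nearly coincide
  expect_lt(h$ks_statistic, 0.05)
  expect_equal(sum(h$histogram$count[h$histogram$group == "HC"]),
               10 * choose(15, 2))

  # requesting more subjects than available errors informatively
  expect_error(sift2_weight_histograms(sim, n_subjects = 40), "available")

  # degenerate all-ones multipliers give a single bin and KS = 0
  fake <- sim
  fake$trace <- lapply(sim$trace, function(m) { m[] <- 1; diag(m) <- 0; m })
  h1 <- sift2_weight_histograms(fake, n_subjects = 10, seed = 2)
  expect_equal(h1$ks_statistic, 0)
  nz <- h1$histogram[h1$histogram$count > 0, ]
  expect_true(all(nz$bin_high == 1))

  # constructed group separation increases the statistic
  fake2 <- sim
  man <- sim$cohort$manifest
  for (s in man$subject_id) {
    mu <- if (man$group[man$subject_id == s] == "PD") 0.9 else 0.5
    m <- sim$trace[[s]]
    m[] <- mu; diag(m) <- 0
    fake2$trace[[s]] <- m
  }
  h2 <- sift2_weight_histograms(fake2, n_subjects = 20, seed = 2)
  expect_gt(h2$ks_statistic, h$ks_statistic)
})

test_that("cohort round-trips through the directory layout", {
  cfg <- simulation_config(n_hc = 2, n_pd = 2, labels = paste0("R", 1:8),
                           metrics = c("SC", "FA"), seed = 23)
  sim <- simulate_cohort(cfg)
  dir <- file.path(tempdir(), "cohort_io_test")
  write_cohort(sim, dir)
  back <- read_cohort(dir, metrics = c("SC", "FA"))
  expect_equal(back$manifest$subject_id, sim$cohort$manifest$subject_id)
  for (key in names(sim$cohort$connectomes)) {
    expect_identical(back$connectomes[[key]]$weights,
                     sim$cohort$connectomes[[key]]$weights)
  }
  unlink(dir, recursive = TRUE)
})
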