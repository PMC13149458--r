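# Synthetic two-group connectome cohorts. The generator stands in for the
# tractography pipeline: it emulates dense weighted undirected connectomes
# for all five connectivity metrics, paired filtered/unfiltered versions
# linked by SIFT2-like per-edge multipliers in [0, 1], and group effects of
# configurable Cohen's d planted on chosen edges or nodes.
#
# Baseline edge-weight families (per-edge means fixed at the cohort level,
# per-subject noise on top):
#   SC       log-normal with a latent distance-decay mean structure, so
#            hubs and weak edges exist; one multiplicative global scaling
#            factor per subject emulates streamline-count variability
#   FA       logit-normal (bounded in (0,1))
#   AD, RD   log-normal; MD = (AD + 2 RD) / 3 up to a small multiplicative
#            noise, mimicking the tensor-derived coupling
# Filtering: per-edge multiplier m ~ Beta with mean decreasing in a latent
# edge implausibility score (long edges are less plausible); filtered
# SC = m * unfiltered SC; mean-metric weights are shrunk toward the edge
# population mean in proportion to (1 - m).

#' Specify a planted group effect
#'
#' Describes one group difference to plant in a simulated cohort: which
#' edges (or all edges incident to which nodes) of which connectivity
#' metric differ between PD and HC, by how much (Cohen's d on the analyzed
#' raw-weight scale; positive means PD > HC), and how the effect interacts
#' with filtering:
#'
#' * `"both"` — the effect is present in filtered and unfiltered
#'   connectomes (planted multiplicatively, which per-edge multipliers
#'   preserve);
#' * `"unfiltered_only"` — the effect is carried by implausible edges:
#'   it is planted additively and the targeted edges get small, highly
#'   variable multipliers, so filtering attenuates it (the "removal"
#'   scenario);
#' * `"masked_until_filtered"` — the effect is superimposed with heavy
#'   spurious-streamline noise that the multipliers exactly down-weight,
#'   so filtering reveals it (the "emergence" scenario).
#'
#' The two filtering-interaction stages model streamline-count mechanics
#' and therefore require `metric = "SC"`.
#'
#' @param target `"edge_set"`, `"node_set"`, or `"none"`.
#' @param members for `edge_set`, a 2-column matrix/cbind of node index
#'   pairs (i < j); for `node_set`, a vector of node indices.
#' @param cohens_d standardized mean difference on the raw weight scale.
#' @param metric metric carrying the effect.
#' @param stage `"both"`, `"unfiltered_only"`, or `"masked_until_filtered"`.
#' @return list of class `"effect_spec"`.
#' @export
effect_spec <- function(target = c("edge_set", "node_set", "none"),
                        members = NULL, cohens_d = 0, metric = "SC",
                        stage = c("both", "unfiltered_only",
                                  "masked_until_filtered")) {
  target <- match.arg(target)
  stage <- match.arg(stage)
  metric <- match.arg(metric, CONN_METRICS)
  stopifnot(is.finite(cohens_d))
  if (target != "none") {
    if (is.null(members) || length(members) == 0) {
      stop("members must be non-empty unless target = 'none'")
    }
    if (target == "edge_set") {
      members <- matrix(as.integer(members), ncol = 2)
      if (any(members[, 1] >= members[, 2])) {
        stop("edge members must be strictly-upper-triangle pairs (i < j)")
      }
    } else {
      members <- as.integer(members)
    }
  }
  if (stage != "both" && metric != "SC") {
    stop("filtering-interaction stages model streamline-count mechanics; ",
         "use metric = 'SC'")
  }
  structure(list(target = target, members = members, cohens_d = cohens_d,
                 metric = metric, stage = stage),
            class = "effect_spec")
}

#' Simulation configuration
#'
#' Defaults mirror the study cohort the generator emulates: 67 HC
#' (24 F / 43 M) and 166 PD (61 F / 105 M), with ages drawn normal per
#' group and sex (HC F 58.8 +- 8.6, HC M 61.8 +- 12.0, PD F 60.1 +- 9.0,
#' PD M 61.7 +- 9.7 years).
#'
#' @param n_hc,n_pd group sizes (each >= 2).
#' @param labels region labels (node order); default [aal90_labels()].
#' @param metrics which connectivity metrics to generate.
#' @param prop_f proportion of female subjects per group,
#'   `c(HC = ..., PD = ...)`.
#' @param age_mean,age_sd age means/sds as `c(HC_F, HC_M, PD_F, PD_M)`.
#' @param baseline named list of baseline edge-weight parameters; see
#'   defaults in the function signature. `sc_mu0`/`sc_alpha` set the
#'   distance-decay log-mean of SC, `*_tau` the fixed per-edge spread,
#'   `*_sigma` the per-subject noise sd on the transformed (log/logit)
#'   scale; `fa_mu` is the FA population mean.
#' @param filtering named list: `eta0`, `eta1` (logistic mean of the
#'   multiplier vs. edge implausibility), `kappa` (Beta concentration),
#'   `gamma` (shrinkage of mean-metric weights toward the edge mean),
#'   `spur_meanlog`, `spur_sdlog` (spurious-noise law for emergence
#'   edges), `removal_mean`, `removal_kappa` (multiplier law for removal
#'   edges).
#' @param subject_scale_sd sd of the per-subject global log-scale factor
#'   applied to SC (default 0.1, i.e. ~10% streamline-count variability).
#' @param effects list of [effect_spec()] objects.
#' @param seed master integer seed; per-subject sub-seeds are derived from
#'   it, so cohorts are reproducible and byte-identical across runs.
#' @return list of class `"simulation_config"`.
#' @export
simulation_config <- function(n_hc = 67, n_pd = 166,
                              labels = aal90_labels(),
                              metrics = CONN_METRICS,
                              prop_f = c(HC = 24 / 67, PD = 61 / 166),
                              age_mean = c(58.79, 61.81, 60.12, 61.68),
                              age_sd = c(8.56, 11.97, 8.99, 9.69),
                              baseline = list(),
                              filtering = list(),
                              subject_scale_sd = 0.1,
                              effects = list(),
                              seed = 1L) {
  stopifnot(n_hc >= 2, n_pd >= 2)
  validate_labels(labels)
  metrics <- match.arg(metrics, CONN_METRICS, several.ok = TRUE)
  base_def <- list(
    sc_mu0 = 4, sc_alpha = 3, sc_tau = 1.0, sc_sigma = 0.6,
    fa_mu = 0.45, fa_tau = 0.30, fa_sigma = 0.15,
    ad_mu = 1.7, ad_tau = 0.08, ad_sigma = 0.05,
    rd_mu = 0.5, rd_tau = 0.12, rd_sigma = 0.06,
    md_sigma = 0.01,
    # cohort-level edge presence: probability plogis(pres0 - pres1 * z)
    # of a region pair being connected at all (z = edge implausibility);
    # defaults give ~85-90% density - dense but not complete, so
    # betweenness and assortativity stay informative
    pres0 = 4, pres1 = 4
  )
  filt_def <- list(
    eta0 = 1.2, eta1 = 2.0, kappa = 30, gamma = 0.5,
    spur_meanlog = 1.0, spur_sdlog = 1.5,
    removal_mean = 0.05, removal_kappa = 2
  )
  baseline <- utils::modifyList(base_def, baseline)
  filtering <- utils::modifyList(filt_def, filtering)
  if (baseline$fa_mu <= 0 || baseline$fa_mu >= 1) {
    stop("FA baseline mean must lie in (0, 1)")
  }
  if (any(c(baseline$sc_sigma, baseline$ad_mu, baseline$rd_mu) <= 0)) {
    stop("SC/diffusivity baselines must be positive")
  }
  for (ef in effects) {
    if (!inherits(ef, "effect_spec")) stop("effects must be effect_spec objects")
    if (!ef$metric %in% metrics) {
      stop("effect targets metric ", ef$metric, " which is not generated")
    }
    if (ef$target == "edge_set" && any(ef$members > length(labels))) {
      stop("effect edge members exceed the number of regions")
    }
    if (ef$target == "node_set" && any(ef$members > length(labels))) {
      stop("effect node members exceed the number of regions")
    }
  }
  structure(list(n_hc = n_hc, n_pd = n_pd, labels = labels,
                 metrics = metrics, prop_f = prop_f,
                 age_mean = age_mean, age_sd = age_sd,
                 baseline = baseline, filtering = filtering,
                 subject_scale_sd = subject_scale_sd,
                 effects = effects, seed = as.integer(seed)),
            class = "simulation_config")
}

# Raw-scale population Cohen's d of a transformed-scale location shift
# delta, for values link^{-1}(mu + delta * is_pd + sigma * eps),
# eps ~ N(0,1). Pooled-sd convention with group sizes (n_pd, n_hc).
# Gauss quadrature over eps.
raw_scale_d <- function(delta, mu, sigma, link, n_pd, n_hc) {
  z <- seq(-8, 8, length.out = 321)
  wq <- stats::dnorm(z); wq <- wq / sum(wq)
  inv <- switch(link, log = exp, logit = stats::plogis)
  x_hc <- inv(mu + sigma * z)
  x_pd <- inv(mu + delta + sigma * z)
  m_hc <- sum(wq * x_hc); v_hc <- sum(wq * (x_hc - m_hc)^2)
  m_pd <- sum(wq * x_pd); v_pd <- sum(wq * (x_pd - m_pd)^2)
  sp <- sqrt(((n_pd - 1) * v_pd + (n_hc - 1) * v_hc) / (n_pd + n_hc - 2))
  (m_pd - m_hc) / sp
}

# Solve for the transformed-scale shift that yields population raw-scale
# Cohen's d equal to `d`. Errors when the request is infeasible for the
# weight family (raw-scale d is bounded for skewed laws).
solve_shift <- function(d, mu, sigma, link, n_pd, n_hc) {
  if (d == 0) return(0)
  f <- function(delta) raw_scale_d(delta, mu, sigma, link, n_pd, n_hc) - d
  lim <- 50 * sigma
  lo <- if (d > 0) 0 else -lim
  hi <- if (d > 0) lim else 0
  if (f(lo) * f(hi) > 0) {
    stop(sprintf(
      "infeasible config: cohens_d = %.3g is not achievable for a %s-scale weight family (sigma = %.3g)",
      d, link, sigma))
  }
  stats::uniroot(f, c(lo, hi), tol = 1e-8)$root
}

# Resolve effect specs into per-edge plans for one metric.
# Returns list(delta = transformed-scale shift per edge, add = raw additive
# shift per edge (computed later from baseline sd), removal = logical,
# spur = logical), with `add_d` holding the requested d for additive edges.
plan_effects <- function(cfg, metric, n_edges, ep) {
  plan <- list(delta_d = numeric(n_edges), add_d = numeric(n_edges),
               removal = logical(n_edges), spur = logical(n_edges))
  eidx_of <- function(ef) {
    if (ef$target == "edge_set") {
      which(paste(ep[, 1], ep[, 2]) %in%
              paste(ef$members[, 1], ef$members[, 2]))
    } else {
      which(ep[, 1] %in% ef$members | ep[, 2] %in% ef$members)
    }
  }
  for (ef in cfg$effects) {
    if (ef$metric != metric || ef$target == "none") next
    idx <- eidx_of(ef)
    if (ef$stage == "both" || ef$stage == "masked_until_filtered") {
      plan$delta_d[idx] <- plan$delta_d[idx] + ef$cohens_d
      if (ef$stage == "masked_until_filtered") plan$spur[idx] <- TRUE
    } else {  # unfiltered_only
      plan$add_d[idx] <- plan$add_d[idx] + ef$cohens_d
      plan$removal[idx] <- TRUE
    }
  }
  plan
}

#' Simulate a two-group cohort of paired filtered/unfiltered connectomes
#'
#' Deterministic given `cfg$seed`. Produces, for every subject and
#' requested metric, an unfiltered and a filtered connectome, plus the
#' per-subject matrix of SIFT2-like multipliers that links them (the
#' filtering ground truth). Planted effects realize the requested raw-scale
#' Cohen's d in the population (the transformed-scale shift is solved
#' numerically per edge), so the empirical d of a generated sample matches
#' the request up to Monte-Carlo error.
#'
#' @param cfg a [simulation_config()].
#' @return list of class `"sim_cohort"`: `cohort` (a [cohort()]), `trace`
#'   (named list of per-subject multiplier matrices), `config`.
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  n_reg <- length(cfg$labels)
  ep <- edge_pairs(n_reg)
  n_edges <- nrow(ep)
  bl <- cfg$baseline; fl <- cfg$filtering
  n <- cfg$n_hc + cfg$n_pd

  set.seed(cfg$seed)
  # --- manifest ------------------------------------------------------
  grp <- c(rep("HC", cfg$n_hc), rep("PD", cfg$n_pd))
  sex <- c(ifelse(runif(cfg$n_hc) < cfg$prop_f["HC"], "F", "M"),
           ifelse(runif(cfg$n_pd) < cfg$prop_f["PD"], "F", "M"))
  cell <- ifelse(grp == "HC", ifelse(sex == "F", 1, 2),
                 ifelse(sex == "F", 3, 4))
  age <- pmax(30, rnorm(n, cfg$age_mean[cell], cfg$age_sd[cell]))
  manifest <- cohort_manifest(sprintf("sub-%03d", seq_len(n)), grp, sex, age)
  is_pd <- grp == "PD"

  # --- cohort-level latents -----------------------------------------
  coords <- matrix(runif(3 * n_reg), n_reg, 3)
  dist_e <- sqrt(rowSums((coords[ep[, 1], ] - coords[ep[, 2], ])^2))
  z_impl <- (dist_e - min(dist_e)) / max(dist_e - min(dist_e))  # implausibility
  mu_m <- stats::plogis(fl$eta0 - fl$eta1 * z_impl)             # multiplier mean
  # cohort-level topology: not every region pair is connected by
  # streamlines; long (implausible) edges are dropped more often
  present <- runif(n_edges) < stats::plogis(bl$pres0 - bl$pres1 * z_impl)

  edge_mu <- list(
    SC = bl$sc_mu0 - bl$sc_alpha * dist_e + rnorm(n_edges, 0, bl$sc_tau),
    FA = stats::qlogis(bl$fa_mu) + rnorm(n_edges, 0, bl$fa_tau),
    AD = log(bl$ad_mu) + rnorm(n_edges, 0, bl$ad_tau),
    RD = log(bl$rd_mu) + rnorm(n_edges, 0, bl$rd_tau)
  )
  # MD inherits most of its log-scale variance from AD and RD through the
  # (AD + 2 RD)/3 coupling; delta-method weights from the baseline means.
  w_ad <- bl$ad_mu / (bl$ad_mu + 2 * bl$rd_mu)
  md_sigma_tot <- sqrt((w_ad * bl$ad_sigma)^2 +
                       ((1 - w_ad) * bl$rd_sigma)^2 + bl$md_sigma^2)
  sigma_of <- c(SC = sqrt(bl$sc_sigma^2 + cfg$subject_scale_sd^2),
                FA = bl$fa_sigma, AD = bl$ad_sigma, RD = bl$rd_sigma,
                MD = md_sigma_tot)
  link_of <- c(SC = "log", FA = "logit", AD = "log", RD = "log", MD = "log")

  # --- resolve effects: per-edge shifts (feasibility before sampling) -
  plans <- list()
  for (metric in cfg$metrics) {
    plan <- plan_effects(cfg, metric, n_edges, ep)
    # targeted edges always exist in the cohort topology
    present[plan$delta_d != 0 | plan$add_d != 0 |
              plan$removal | plan$spur] <- TRUE
    plan$delta <- numeric(n_edges)
    idx <- which(plan$delta_d != 0)
    for (e in idx) {
      mu_e <- if (metric == "MD") {
        log((exp(edge_mu$AD[e]) + 2 * exp(edge_mu$RD[e])) / 3)
      } else edge_mu[[metric]][e]
      plan$delta[e] <- solve_shift(plan$delta_d[e], mu_e, sigma_of[metric],
                                   link_of[metric], cfg$n_pd, cfg$n_hc)
    }
    # additive (removal-stage) shifts: d * population raw sd of the edge
    plan$add <- numeric(n_edges)
    idx <- which(plan$add_d != 0)
    for (e in idx) {
      s_raw <- exp(edge_mu$SC[e]) * exp(sigma_of["SC"]^2 / 2) *
        sqrt(exp(sigma_of["SC"]^2) - 1)
      plan$add[e] <- plan$add_d[e] * s_raw
    }
    plans[[metric]] <- plan
  }

  sub_seeds <- sample.int(.Machine$integer.max - 1L, n)

  # --- per-subject generation ---------------------------------------
  connectomes <- vector("list", 0)
  trace <- vector("list", n)
  names(trace) <- manifest$subject_id
  sc_plan <- plans[["SC"]]
  for (s in seq_len(n)) {
    set.seed(sub_seeds[s])
    g_s <- rnorm(1, 0, cfg$subject_scale_sd)  # SC global log-scale

    # multipliers (shared by all metrics of the subject)
    a <- mu_m * fl$kappa; b <- (1 - mu_m) * fl$kappa
    if (!is.null(sc_plan) && any(sc_plan$removal)) {
      a[sc_plan$removal] <- fl$removal_mean * fl$removal_kappa
      b[sc_plan$removal] <- (1 - fl$removal_mean) * fl$removal_kappa
    }
    m <- rbeta(n_edges, a, b)
    spur <- NULL
    if (!is.null(sc_plan) && any(sc_plan$spur)) {
      spur <- rep(1, n_edges)
      k <- sum(sc_plan$spur)
      spur[sc_plan$spur] <- 1 + rlnorm(k, fl$spur_meanlog, fl$spur_sdlog)
      m[sc_plan$spur] <- m[sc_plan$spur] / spur[sc_plan$spur]
    }
    mmat <- matrix_from_upper(m, n_reg)
    dimnames(mmat) <- list(cfg$labels, cfg$labels)
    trace[[s]] <- mmat

    vals <- list()
    for (metric in cfg$metrics) {
      if (metric == "MD") next  # derived below
      plan <- plans[[metric]]
      mu_e <- edge_mu[[metric]] + if (is_pd[s]) plan$delta else 0
      eps <- rnorm(n_edges, 0, switch(metric, SC = bl$sc_sigma,
                                      FA = bl$fa_sigma, AD = bl$ad_sigma,
                                      RD = bl$rd_sigma))
      v <- switch(link_of[metric], log = exp, logit = stats::plogis)(
        mu_e + eps + if (metric == "SC") g_s else 0)
      if (metric == "SC") {
        if (any(plan$add != 0) && is_pd[s]) {
          v <- pmax(v + plan$add, 1e-9)
        }
        if (!is.null(spur)) v <- v * spur
      }
      vals[[metric]] <- v
    }
    if ("MD" %in% cfg$metrics) {
      plan <- plans[["MD"]]
      base_md <- (vals[["AD"]] %||% exp(edge_mu$AD + rnorm(n_edges, 0, bl$ad_sigma))) +
        2 * (vals[["RD"]] %||% exp(edge_mu$RD + rnorm(n_edges, 0, bl$rd_sigma)))
      mu_shift <- if (is_pd[s]) plan$delta else 0
      vals[["MD"]] <- base_md / 3 * exp(mu_shift + rnorm(n_edges, 0, bl$md_sigma))
    }

    for (metric in cfg$metrics) {
      v_unf <- vals[[metric]]
      v_unf[!present] <- 0  # unconnected region pairs carry no weight
      if (metric == "SC") {
        v_fil <- m * v_unf
      } else {
        pop_mean <- switch(link_of[metric], log = exp, logit = stats::plogis)(
          if (metric == "MD") {
            log((exp(edge_mu$AD) + 2 * exp(edge_mu$RD)) / 3)
          } else edge_mu[[metric]])
        shrink <- fl$gamma * (1 - m)
        v_fil <- (1 - shrink) * v_unf + shrink * pop_mean
        v_fil[!present] <- 0
      }
      for (state in FILTER_STATES) {
        v <- if (state == "unfiltered") v_unf else v_fil
        wmat <- matrix_from_upper(v, n_reg)
        connectomes[[length(connectomes) + 1L]] <-
          connectome(wmat, metric = metric, filtering = state,
                     subject_id = manifest$subject_id[s], labels = cfg$labels)
      }
    }
  }

  structure(list(cohort = cohort(manifest, connectomes, cfg$labels),
                 trace = trace, config = cfg),
            class = "sim_cohort")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.sim_cohort <- function(x, ...) {
  cat("<sim_cohort> seed", x$config$seed, "|",
      length(x$config$effects), "planted effect(s)\n")
  print(x$cohort)
  invisible(x)
}

#' Empirical Cohen's d per edge or node statistic
#'
#' Standardized mean difference (PD minus HC, pooled sd) of each edge
#' weight, or of a node-level graph measure, computed from a cohort.
#' Elements with zero pooled variance are returned as `NA` (undefined d).
#'
#' @param x a [cohort()] or [simulate_cohort()] result.
#' @param metric,filtering which connectome slice to use.
#' @param statistic `"edge"` for per-edge d (returns a symmetric matrix),
#'   or one of `"strength"`, `"betweenness"`, `"clustering"` for per-node d
#'   (returns a vector).
#' @return symmetric matrix or per-node vector of d values.
#' @export
empirical_effect_size <- function(x, metric, filtering,
                                  statistic = c("edge", "strength",
                                                "betweenness", "clustering")) {
  if (inherits(x, "sim_cohort")) x <- x$cohort
  stopifnot(inherits(x, "cohort"))
  statistic <- match.arg(statistic)
  grp <- x$manifest$group
  if (!all(c("PD", "HC") %in% grp)) stop("both groups must be present")
  if (statistic == "edge") {
    V <- cohort_edge_matrix(x, metric, filtering)
  } else {
    nm <- compute_cohort_metrics(x, metric, filtering)$nodes
    nm <- nm[nm$graph_measure == statistic, ]
    V <- do.call(rbind, lapply(split(nm$value, nm$subject_id), identity))
    V <- V[x$manifest$subject_id, , drop = FALSE]
  }
  d <- cohens_d_vec(V[grp == "PD", , drop = FALSE],
                    V[grp == "HC", , drop = FALSE])
  if (statistic == "edge") {
    out <- matrix_from_upper(ifelse(is.na(d), 0, d), length(x$labels))
    out[matrix_from_upper(as.numeric(is.na(d)), length(x$labels)) > 0] <- NA
    dimnames(out) <- list(x$labels, x$labels)
    out
  } else {
    names(d) <- x$labels
    d
  }
}

# Cohen's d with pooled sd, columnwise; zero pooled variance -> NA.
cohens_d_vec <- function(x_pd, x_hc) {
  n1 <- nrow(x_pd); n2 <- nrow(x_hc)
  m1 <- colMeans(x_pd); m2 <- colMeans(x_hc)
  v1 <- apply(x_pd, 2, var); v2 <- apply(x_hc, 2, var)
  sp <- sqrt(((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2))
  d <- (m1 - m2) / sp
  d[sp == 0] <- NA_real_
  d
}

#' SIFT2-like multiplier histograms by group
#'
#' Draws `n_subjects` subjects (half per group) at random, pools their
#' per-edge filtering multipliers, and compares the per-group histograms
#' with a two-sample Kolmogorov-Smirnov statistic — answering whether
#' filtering affects one group more than the other.
#'
#' @param sim a [simulate_cohort()] result (or a list with `trace` and the
#'   manifest available as `cohort$manifest`).
#' @param n_subjects total number of subjects to draw (even; half PD,
#'   half HC).
#' @param seed seed for the subject draw.
#' @param breaks histogram breaks on [0, 1].
#' @return list: `histogram` (data.frame group, bin_low, bin_high, count,
#'   density), `ks_statistic`, `ks_p`, `subjects`.
#' @export
sift2_weight_histograms <- function(sim, n_subjects = 20, seed = 1L,
                                    breaks = seq(0, 1, by = 0.05)) {
  manifest <- sim$cohort$manifest
  trace <- sim$trace
  per_grp <- ceiling(n_subjects / 2)
  ids <- split(manifest$subject_id, manifest$group)
  for (g in c("HC", "PD")) {
    if (length(ids[[g]]) < per_grp) {
      stop(sprintf("requested %d %s subjects but only %d available",
                   per_grp, g, length(ids[[g]])))
    }
  }
  set.seed(seed)
  pick <- lapply(ids[c("HC", "PD")], sample, size = per_grp)
  vals <- lapply(pick, function(ss)
    unlist(lapply(ss, function(s) upper_triangle_vector(trace[[s]])),
           use.names = FALSE))
  hist_df <- do.call(rbind, lapply(names(vals), function(g) {
    h <- graphics::hist(vals[[g]], breaks = breaks, plot = FALSE)
    data.frame(group = g, bin_low = head(breaks, -1), bin_high = breaks[-1],
               count = h$counts, density = h$density,
               stringsAsFactors = FALSE)
  }))
  if (stats::sd(vals$HC) == 0 && stats::sd(vals$PD) == 0 &&
      identical(unique(vals$HC), unique(vals$PD))) {
    ks <- list(statistic = 0, p.value = 1)  # degenerate identical masses
  } else {
    ks <- suppressWarnings(stats::ks.test(vals$HC, vals$PD))
  }
  list(histogram = hist_df,
       ks_statistic = unname(ks$statistic), ks_p = unname(ks$p.value),
       subjects = pick)
}

#' Write a simulated cohort to a directory
#'
#' Layout: `manifest.csv`, `labels.txt`, one connectome per file named
#' `<subject>_<metric>_<filtering>.csv`, and multiplier matrices under
#' `filtering_trace/<subject>.csv`.
#'
#' @param sim a [simulate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_manifest(sim$cohort$manifest, file.path(dir, "manifest.csv"))
  writeLines(sim$cohort$labels, file.path(dir, "labels.txt"))
  for (cm in sim$cohort$connectomes) {
    write_connectome(cm, file.path(dir, sprintf("%s_%s_%s.csv",
                                                cm$subject_id, cm$metric,
                                                cm$filtering)))
  }
  tdir <- file.path(dir, "filtering_trace")
  dir.create(tdir, showWarnings = FALSE)
  for (s in names(sim$trace)) {
    m <- sim$trace[[s]]
    fake <- connectome(m, metric = "SC", filtering = "unfiltered",
                       subject_id = s, labels = rownames(m))
    write_connectome(fake, file.path(tdir, paste0(s, ".csv")))
  }
  invisible(dir)
}

#' Read a cohort from a directory written by [write_cohort()]
#'
#' @param dir cohort directory.
#' @param metrics,filterings which slices to read.
#' @return a [cohort()].
#' @export
read_cohort <- function(dir, metrics = CONN_METRICS,
                        filterings = FILTER_STATES) {
  manifest <- read_manifest(file.path(dir, "manifest.csv"))
  labels <- read_labels(file.path(dir, "labels.txt"))
  conns <- list()
  for (s in manifest$subject_id) {
    for (metric in metrics) {
      for (state in filterings) {
        path <- file.path(dir, sprintf("%s_%s_%s.csv", s, metric, state))
        if (!file.exists(path)) stop("missing connectome file: ", path)
        conns[[length(conns) + 1L]] <-
          read_connectome(path, metric = metric, filtering = state,
                          subject_id = s, labels = labels)
      }
    }
  }
  cohort(manifest, conns, labels)
}
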