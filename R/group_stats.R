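# Node-level and whole-brain group comparisons. Per node and measure:
# two-sided Welch t test, Benjamini-Yekutieli adjustment across the nodes
# of one (metric, filtering, measure) family, direction letter (P = PD
# mean higher, H = HC mean higher), pre-correction significance stars, and
# Cohen's d. Whole-brain: the same test on node-averaged measures and
# assortativity, with d confidence intervals and the change in d under
# filtering. The filtering-impact taxonomy classifies each node cell as
# null effect / removal / emergence from its pre-correction significance
# in the two filtering states.

stars_of <- function(p) {
  ifelse(is.na(p), "", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

# Welch two-sided test + pooled-sd Cohen's d for a subjects x elements
# value matrix split by group. Returns a data.frame of per-element stats.
welch_two_sided <- function(V, is_pd) {
  x1 <- V[is_pd, , drop = FALSE]; x2 <- V[!is_pd, , drop = FALSE]
  res <- welch_t_vec(x1, x2)
  p <- 2 * pt(abs(res$t), df = res$df, lower.tail = FALSE)
  p[res$zero_var & res$t == 0] <- NA  # untestable: no variance, no difference
  tt <- res$t
  tt[res$zero_var & res$t == 0] <- NA
  d <- cohens_d_vec(x1, x2)
  data.frame(t = tt, p_uncorrected = p, d = d,
             direction = ifelse(colMeans(x1) > colMeans(x2), "P",
                                ifelse(colMeans(x1) < colMeans(x2), "H", NA)),
             stringsAsFactors = FALSE)
}

#' Node-level group comparisons with BY correction
#'
#' Runs a two-sided Welch t test per node for every (metric, filtering,
#' graph measure) family in a node-metric table, adjusts p-values with the
#' Benjamini-Yekutieli procedure across the nodes of each family (valid
#' under arbitrary dependence), and reports the direction of the
#' difference, pre-correction significance stars (`**` p < 0.01, `*`
#' p < 0.05, as used in the figures), and Cohen's d with pooled sd.
#'
#' @param nodes the `nodes` data.frame from [compute_cohort_metrics()]
#'   (possibly row-bound over metrics/filterings).
#' @param manifest the [cohort_manifest()] defining the groups.
#' @return data.frame with one row per (metric, filtering, graph_measure,
#'   node): `t`, `p_uncorrected`, `p_by`, `direction` (P/H), `stars`, `d`.
#' @export
node_group_tests <- function(nodes, manifest) {
  is_pd <- manifest$group == "PD"
  if (sum(is_pd) < 2 || sum(!is_pd) < 2) stop("need >= 2 subjects per group")
  fams <- unique(nodes[, c("metric", "filtering", "graph_measure")])
  out <- vector("list", nrow(fams))
  for (k in seq_len(nrow(fams))) {
    f <- fams[k, ]
    sub <- nodes[nodes$metric == f$metric & nodes$filtering == f$filtering &
                   nodes$graph_measure == f$graph_measure, ]
    regions <- unique(sub[order(sub$node), c("node", "region")])
    V <- matrix(NA_real_, nrow(manifest), nrow(regions))
    for (i in seq_len(nrow(manifest))) {
      si <- sub[sub$subject_id == manifest$subject_id[i], ]
      V[i, ] <- si$value[order(si$node)]
    }
    st <- welch_two_sided(V, is_pd)
    st$p_by <- stats::p.adjust(st$p_uncorrected, method = "BY")
    st$stars <- stars_of(st$p_uncorrected)
    out[[k]] <- cbind(
      data.frame(metric = f$metric, filtering = f$filtering,
                 graph_measure = f$graph_measure,
                 node = regions$node, region = regions$region,
                 stringsAsFactors = FALSE),
      st[, c("t", "p_uncorrected", "p_by", "direction", "stars", "d")]
    )
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# Normal-approximation standard error of Cohen's d.
se_cohens_d <- function(d, n1, n2) {
  sqrt((n1 + n2) / (n1 * n2) + d^2 / (2 * (n1 + n2)))
}

#' Whole-brain group comparisons with effect-size summary
#'
#' Two-sided Welch t tests on the node-averaged graph measures and
#' assortativity, plus Cohen's d with a normal-approximation 95% CI and
#' the change in d under filtering (delta d = d_filtered - d_unfiltered).
#' Subjects with undefined assortativity are excluded from that measure
#' with a message.
#'
#' @param globals the `globals` data.frame from [compute_cohort_metrics()]
#'   (row-bound over metrics and both filterings for delta d).
#' @param manifest the [cohort_manifest()].
#' @return list: `tests` (per metric/filtering/measure row with t, p, d,
#'   CI) and `effect_sizes` (per metric/measure: d_unfiltered, d_filtered,
#'   delta_d and CIs).
#' @export
global_group_tests <- function(globals, manifest) {
  is_pd_all <- manifest$group == "PD"
  fams <- unique(globals[, c("metric", "filtering", "global_measure")])
  rows <- vector("list", nrow(fams))
  for (k in seq_len(nrow(fams))) {
    f <- fams[k, ]
    sub <- globals[globals$metric == f$metric &
                     globals$filtering == f$filtering &
                     globals$global_measure == f$global_measure, ]
    v <- sub$value[match(manifest$subject_id, sub$subject_id)]
    keep <- !is.na(v)
    if (any(!keep)) {
      message(sprintf("%s/%s/%s: excluding %d subject(s) with undefined value",
                      f$metric, f$filtering, f$global_measure, sum(!keep)))
    }
    st <- welch_two_sided(matrix(v[keep], ncol = 1), is_pd_all[keep])
    n1 <- sum(is_pd_all[keep]); n2 <- sum(!is_pd_all[keep])
    se <- se_cohens_d(st$d, n1, n2)
    rows[[k]] <- data.frame(
      metric = f$metric, filtering = f$filtering,
      global_measure = f$global_measure,
      t = st$t, p_uncorrected = st$p_uncorrected, d = st$d,
      d_ci_low = st$d - qnorm(0.975) * se,
      d_ci_high = st$d + qnorm(0.975) * se,
      n_used = n1 + n2, stringsAsFactors = FALSE
    )
  }
  tests <- do.call(rbind, rows)
  rownames(tests) <- NULL

  pairs <- unique(tests[, c("metric", "global_measure")])
  es <- vector("list", nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    f <- pairs[k, ]
    tu <- tests[tests$metric == f$metric &
                  tests$global_measure == f$global_measure &
                  tests$filtering == "unfiltered", ]
    tf <- tests[tests$metric == f$metric &
                  tests$global_measure == f$global_measure &
                  tests$filtering == "filtered", ]
    if (nrow(tu) == 0 || nrow(tf) == 0) next
    es[[k]] <- data.frame(
      metric = f$metric, global_measure = f$global_measure,
      d_unfiltered = tu$d, d_filtered = tf$d,
      delta_d = tf$d - tu$d,
      d_unf_ci_low = tu$d_ci_low, d_unf_ci_high = tu$d_ci_high,
      d_fil_ci_low = tf$d_ci_low, d_fil_ci_high = tf$d_ci_high,
      stringsAsFactors = FALSE
    )
  }
  effect_sizes <- do.call(rbind, es)
  rownames(effect_sizes) <- NULL
  list(tests = tests, effect_sizes = effect_sizes)
}

#' Filtering-impact taxonomy
#'
#' Classifies every (metric, graph measure, node) cell by its
#' pre-correction significance at `alpha` in the two filtering states:
#' significant in both — `null_effect` (filtering changes nothing);
#' significant only unfiltered — `removal`; only filtered — `emergence`;
#' neither — `never_significant`.
#'
#' @param unfiltered,filtered [node_group_tests()] tables restricted to
#'   one filtering state each; they must cover the same (metric, measure,
#'   node) grid.
#' @param alpha pre-correction significance level (default 0.05).
#' @return data.frame: metric, graph_measure, node, region, category,
#'   direction_unfiltered, direction_filtered.
#' @export
filtering_impact <- function(unfiltered, filtered, alpha = 0.05) {
  key <- function(df) paste(df$metric, df$graph_measure, df$node, sep = "|")
  ku <- key(unfiltered); kf <- key(filtered)
  miss <- c(setdiff(ku, kf), setdiff(kf, ku))
  if (length(miss)) {
    stop("tables do not cover the same grid; unmatched cells: ",
         paste(head(miss, 5), collapse = ", "),
         if (length(miss) > 5) sprintf(" (+%d more)", length(miss) - 5) else "")
  }
  filtered <- filtered[match(ku, kf), ]
  sig_u <- !is.na(unfiltered$p_uncorrected) & unfiltered$p_uncorrected < alpha
  sig_f <- !is.na(filtered$p_uncorrected) & filtered$p_uncorrected < alpha
  data.frame(
    metric = unfiltered$metric, graph_measure = unfiltered$graph_measure,
    node = unfiltered$node, region = unfiltered$region,
    category = ifelse(sig_u & sig_f, "null_effect",
                      ifelse(sig_u, "removal",
                             ifelse(sig_f, "emergence", "never_significant"))),
    direction_unfiltered = unfiltered$direction,
    direction_filtered = filtered$direction,
    stringsAsFactors = FALSE
  )
}

#' Wide significance report for one graph measure
#'
#' Formats node comparisons the way the study's summary tables do: one row
#' per node, one column per (metric, filtering) combination, each cell a
#' direction letter plus pre-correction stars (`"P**"`, `"H*"`) or `"-"`.
#' Rows are ordered by each node's smallest p-value; by default only nodes
#' with at least one starred cell are kept.
#'
#' @param tests a [node_group_tests()] table (both filterings bound).
#' @param graph_measure which measure to report.
#' @param only_significant drop nodes with no starred cell (default TRUE).
#' @return data.frame: `region` plus one `"<metric>_<U|F>"` column per
#'   metric and filtering state present.
#' @export
significance_report <- function(tests, graph_measure = "strength",
                                only_significant = TRUE) {
  sub <- tests[tests$graph_measure == graph_measure, ]
  metrics <- intersect(CONN_METRICS, unique(sub$metric))
  states <- intersect(FILTER_STATES, unique(sub$filtering))
  cols <- as.vector(t(outer(metrics, states, paste, sep = "|")))
  regions <- unique(sub[order(sub$node), c("node", "region")])
  out <- data.frame(region = regions$region, stringsAsFactors = FALSE)
  best_p <- rep(Inf, nrow(regions))
  for (cl in cols) {
    parts <- strsplit(cl, "|", fixed = TRUE)[[1]]
    cell <- sub[sub$metric == parts[1] & sub$filtering == parts[2], ]
    cell <- cell[match(regions$node, cell$node), ]
    txt <- ifelse(is.na(cell$stars) | cell$stars == "", "-",
                  paste0(cell$direction, cell$stars))
    cname <- paste0(parts[1], "_", if (parts[2] == "unfiltered") "U" else "F")
    out[[cname]] <- txt
    best_p <- pmin(best_p, ifelse(is.na(cell$p_uncorrected), Inf,
                                  cell$p_uncorrected))
  }
  if (only_significant) {
    keep <- apply(out[, -1, drop = FALSE], 1, function(r) any(r != "-"))
    out <- out[keep, , drop = FALSE]
    best_p <- best_p[keep]
  }
  out <- out[order(best_p), , drop = FALSE]
  rownames(out) <- NULL
  out
}
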