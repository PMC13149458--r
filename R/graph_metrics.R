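# Weighted graph measures per subject. Node level: strength, betweenness
# centrality (shortest paths on lengths 1/w), Onnela clustering
# coefficient. Whole-brain level: node averages plus strength
# assortativity. No thresholding is applied anywhere: connectomes are
# analyzed as the dense weighted undirected graphs they are.

GRAPH_NODE_MEASURES <- c("strength", "betweenness", "clustering")
GRAPH_GLOBAL_MEASURES <- c("mean_strength", "mean_betweenness",
                           "mean_clustering", "assortativity")

as_weight_matrix <- function(x) {
  if (inherits(x, "connectome")) x$weights else x
}

#' Node strength
#'
#' Sum of edge weights between a node and its neighbors,
#' `s_i = sum_j w_ij`.
#'
#' @param x a [connectome()] or symmetric weight matrix.
#' @return named numeric vector, one value per node.
#' @export
node_strength <- function(x) {
  rowSums(as_weight_matrix(x))
}

#' Betweenness centrality (weighted, normalized)
#'
#' Fraction of all-pairs shortest paths that pass through each node, with
#' fractional credit when several shortest paths tie. Path lengths use the
#' standard connectivity convention l_ij = 1/w_ij, so strong edges are
#' short. Values are normalized by (N-1)(N-2)/2, the maximum for an
#' undirected graph, and lie in [0, 1]; disconnected pairs contribute
#' nothing and isolated nodes get 0.
#'
#' @inheritParams node_strength
#' @param normalized divide by (N-1)(N-2)/2 (default TRUE).
#' @return named numeric vector per node.
#' @export
betweenness_centrality <- function(x, normalized = TRUE) {
  w <- as_weight_matrix(x)
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  if (igraph::ecount(g) == 0) {
    out <- numeric(nrow(w)); names(out) <- rownames(w); return(out)
  }
  # vertices keep the adjacency-matrix order, isolated nodes included
  b <- as.numeric(igraph::betweenness(g, directed = FALSE,
                                      weights = 1 / igraph::E(g)$weight))
  if (normalized) {
    n <- nrow(w)
    b <- if (n > 2) b / ((n - 1) * (n - 2) / 2) else b * 0
  }
  names(b) <- rownames(w)
  b
}

#' Clustering coefficient (Onnela weighted form)
#'
#' Weighted local clustering after Onnela: with weights rescaled by the
#' graph maximum, `c_i = (1/(k_i (k_i - 1))) * sum_{j,h} (w~_ij w~_jh
#' w~_hi)^(1/3)`, where k_i is the number of neighbors with nonzero
#' weight. Nodes with fewer than two neighbors get 0. The rescaling makes
#' the measure invariant to a global rescaling of the weights.
#'
#' @inheritParams node_strength
#' @return named numeric vector per node, values in [0, 1].
#' @export
clustering_coefficient <- function(x) {
  w <- as_weight_matrix(x)
  mx <- max(w)
  out <- numeric(nrow(w)); names(out) <- rownames(w)
  if (mx == 0) return(out)
  cw <- (w / mx)^(1 / 3)
  num <- diag(cw %*% cw %*% cw)
  k <- rowSums(w > 0)
  ok <- k >= 2
  out[ok] <- num[ok] / (k[ok] * (k[ok] - 1))
  out
}

#' Strength assortativity
#'
#' Pearson correlation between the strengths of connected nodes: every
#' undirected edge contributes both orientations (s_i, s_j) and (s_j, s_i)
#' to the correlation. Returns `NA` when the endpoint strengths have zero
#' variance (e.g. regular graphs), in which case the value is excluded
#' from downstream group tests.
#'
#' @inheritParams node_strength
#' @return scalar in [-1, 1], or `NA` if undefined.
#' @export
assortativity_strength <- function(x) {
  w <- as_weight_matrix(x)
  s <- rowSums(w)
  ep <- which(upper_triangle_vector(w) > 0)
  if (length(ep) < 2) return(NA_real_)
  pairs <- edge_pairs(nrow(w))[ep, , drop = FALSE]
  si <- c(s[pairs[, 1]], s[pairs[, 2]])
  sj <- c(s[pairs[, 2]], s[pairs[, 1]])
  if (sd(si) == 0 || sd(sj) == 0) return(NA_real_)
  stats::cor(si, sj)
}

#' Per-subject node- and whole-brain-level graph metrics for a cohort
#'
#' Computes strength, betweenness centrality and Onnela clustering for
#' every node and subject, plus whole-brain values: the node averages of
#' each measure and the strength assortativity.
#'
#' @param x a [cohort()].
#' @param metric connectivity metric.
#' @param filtering filtering state.
#' @return list with two data.frames: `nodes` (subject_id, metric,
#'   filtering, graph_measure, node, region, value) and `globals`
#'   (subject_id, metric, filtering, global_measure, value).
#' @export
compute_cohort_metrics <- function(x, metric, filtering) {
  stopifnot(inherits(x, "cohort"))
  subj <- x$manifest$subject_id
  n <- length(x$labels)
  node_rows <- vector("list", length(subj))
  glob_rows <- vector("list", length(subj))
  for (k in seq_along(subj)) {
    cm <- cohort_connectome(x, subj[k], metric, filtering)
    st <- node_strength(cm)
    bt <- betweenness_centrality(cm)
    cl <- clustering_coefficient(cm)
    node_rows[[k]] <- data.frame(
      subject_id = subj[k], metric = metric, filtering = filtering,
      graph_measure = rep(GRAPH_NODE_MEASURES, each = n),
      node = rep(seq_len(n), 3L), region = rep(x$labels, 3L),
      value = c(st, bt, cl), stringsAsFactors = FALSE, row.names = NULL
    )
    glob_rows[[k]] <- data.frame(
      subject_id = subj[k], metric = metric, filtering = filtering,
      global_measure = GRAPH_GLOBAL_MEASURES,
      value = c(mean(st), mean(bt), mean(cl), assortativity_strength(cm)),
      stringsAsFactors = FALSE, row.names = NULL
    )
  }
  list(nodes = do.call(rbind, node_rows),
       globals = do.call(rbind, glob_rows))
}
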