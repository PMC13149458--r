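# Edge-level group inference: mass-univariate Welch t statistics and
# threshold-free network-based statistics (TFNBS) with permutation
# family-wise error control. Both directed hypotheses are tested:
#   t1: PD > HC,  t2: HC > PD.

HYPOTHESES <- c("t1_PD_gt_HC", "t2_HC_gt_PD")

# Welch two-sample t statistics for many variables at once.
# x1: n1 x m matrix (group 1 = PD), x2: n2 x m (group 2 = HC).
# Returns list(t, df) of length-m vectors; t > 0 means PD mean > HC mean.
# Variables with zero variance in both groups get t = 0 (equal means) or
# +-Inf (unequal means) and are flagged in `zero_var`.
welch_t_vec <- function(x1, x2) {
  n1 <- nrow(x1); n2 <- nrow(x2)
  if (n1 < 2 || n2 < 2) stop("need at least 2 subjects per group")
  m1 <- colMeans(x1); m2 <- colMeans(x2)
  v1 <- colSums(x1 * x1) / n1 - m1^2; v1 <- v1 * n1 / (n1 - 1)
  v2 <- colSums(x2 * x2) / n2 - m2^2; v2 <- v2 * n2 / (n2 - 1)
  v1 <- pmax(v1, 0); v2 <- pmax(v2, 0)
  se2 <- v1 / n1 + v2 / n2
  zero_var <- se2 == 0
  tt <- (m1 - m2) / sqrt(se2)
  tt[zero_var & (m1 == m2)] <- 0
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  df[zero_var] <- n1 + n2 - 2
  list(t = tt, df = df, zero_var = zero_var)
}

#' Edge-wise Welch t statistics for a cohort slice
#'
#' Computes a two-sample Welch t statistic per upper-triangle edge
#' (positive t means the PD mean exceeds the HC mean) and one-sided
#' p-values for both directed hypotheses, t1: PD > HC and t2: HC > PD.
#'
#' @param x a [cohort()].
#' @param metric connectivity metric (`"SC"`, `"FA"`, `"AD"`, `"RD"`, `"MD"`).
#' @param filtering `"unfiltered"` or `"filtered"`.
#' @return list with symmetric matrices `t`, `df`, `p_t1_PD_gt_HC`,
#'   `p_t2_HC_gt_PD`, and logical matrix `zero_variance` flagging edges with
#'   no variance in either group.
#' @export
edge_t_statistics <- function(x, metric, filtering) {
  stopifnot(inherits(x, "cohort"))
  grp <- x$manifest$group
  if (!all(c("PD", "HC") %in% grp)) stop("both groups (PD, HC) must be present")
  Xe <- cohort_edge_matrix(x, metric, filtering)
  res <- welch_t_vec(Xe[grp == "PD", , drop = FALSE],
                     Xe[grp == "HC", , drop = FALSE])
  n <- length(x$labels)
  p1 <- pt(res$t, df = res$df, lower.tail = FALSE)  # PD > HC
  p2 <- pt(res$t, df = res$df, lower.tail = TRUE)   # HC > PD
  sym <- function(v) {
    m <- matrix_from_upper(v, n)
    dimnames(m) <- list(x$labels, x$labels)
    m
  }
  list(t = sym(res$t), df = sym(res$df),
       p_t1_PD_gt_HC = sym(p1), p_t2_HC_gt_PD = sym(p2),
       zero_variance = sym(as.numeric(res$zero_var)) > 0)
}

#' TFNBS configuration
#'
#' Tuning parameters of the threshold-free network-based statistic: the
#' extent exponent `E`, the height exponent `H`, the number of threshold
#' levels, an optional fixed threshold range on the t scale (default:
#' data-driven, evenly spaced over (0, max observed t]), and the
#' permutation budget.
#'
#' @param E extent exponent (> 0); default 0.5.
#' @param H height exponent (> 0); default 3.
#' @param n_steps number of threshold levels (>= 1); default 100.
#' @param threshold_range optional `c(h_min, h_max)` with `h_min >= 0`;
#'   `NULL` means data-driven `(0, max t]` per hypothesis.
#' @param n_permutations permutation count for FWE control; default 5000.
#' @param seed integer seed for the permutation draw.
#' @return list of class `"tfnbs_config"`.
#' @export
tfnbs_config <- function(E = 0.5, H = 3, n_steps = 100,
                         threshold_range = NULL, n_permutations = 5000,
                         seed = 1L) {
  stopifnot(E > 0 || H >= 0, n_steps >= 1, n_permutations >= 1)
  if (!is.null(threshold_range)) {
    stopifnot(length(threshold_range) == 2, threshold_range[1] >= 0,
              threshold_range[2] > threshold_range[1])
  }
  structure(list(E = E, H = H, n_steps = as.integer(n_steps),
                 threshold_range = threshold_range,
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed)),
            class = "tfnbs_config")
}

# Threshold ladder for one hypothesis: n_steps levels evenly spaced over
# (h_min, h_max], with dh the spacing. Returns list(h, dh) or NULL when no
# suprathreshold t exists.
tfnbs_ladder <- function(cfg, t_max) {
  rng <- cfg$threshold_range
  if (is.null(rng)) rng <- c(0, t_max)
  if (!is.finite(rng[2]) || rng[2] <= rng[1]) return(NULL)
  dh <- (rng[2] - rng[1]) / cfg$n_steps
  list(h = rng[1] + dh * seq_len(cfg$n_steps), dh = dh)
}

#' TFNBS scores for a t-statistic matrix
#'
#' For each threshold h in the ladder, edges with t > h are binarized, the
#' connected components of the resulting graph are found, and every
#' suprathreshold edge accumulates extent^E * h^H * dh, where extent is the
#' number of edges in its component. Hypothesis t2 scores the negated t
#' matrix.
#'
#' @param tmat symmetric t-statistic matrix (positive = PD > HC).
#' @param cfg a [tfnbs_config()].
#' @param hypothesis `"t1_PD_gt_HC"` or `"t2_HC_gt_PD"`.
#' @return symmetric nonnegative score matrix.
#' @export
tfnbs_scores <- function(tmat, cfg, hypothesis = "t1_PD_gt_HC") {
  hypothesis <- match.arg(hypothesis, HYPOTHESES)
  stopifnot(inherits(cfg, "tfnbs_config"), is.matrix(tmat))
  n <- nrow(tmat)
  tv <- upper_triangle_vector(tmat)
  if (hypothesis == "t2_HC_gt_PD") tv <- -tv
  ep <- edge_pairs(n)
  sc <- tfnbs_score_vec(tv, ep, n, cfg)
  out <- matrix_from_upper(sc, n)
  dimnames(out) <- dimnames(tmat)
  out
}

# Score one upper-triangle t vector. Data-driven configs use the
# relative-ladder mode of the C++ scorer (n_steps levels over (0, max t],
# exact at the knife edge t == max t); fixed ranges use the explicit
# ladder.
tfnbs_score_vec <- function(tv, ep, n_nodes, cfg) {
  if (is.null(cfg$threshold_range)) {
    tmax <- max(tv)
    if (!is.finite(tmax) || tmax <= 0) return(numeric(length(tv)))
    tfnbs_score_cpp(tv, ep[, 1] - 1L, ep[, 2] - 1L, n_nodes, numeric(0),
                    cfg$E, cfg$H, 0, tmax, cfg$n_steps)
  } else {
    lad <- tfnbs_ladder(cfg, NA)
    tfnbs_score_cpp(tv, ep[, 1] - 1L, ep[, 2] - 1L, n_nodes, lad$h,
                    cfg$E, cfg$H, lad$dh)
  }
}

# All distinct group assignments for exhaustive permutation testing:
# returns a B x n 0/1 matrix of "PD" membership including the observed one.
exhaustive_assignments <- function(n, n1) {
  combs <- utils::combn(n, n1)
  out <- matrix(0L, ncol(combs), n)
  for (b in seq_len(ncol(combs))) out[b, combs[, b]] <- 1L
  out
}

# Welch t for a batch of permutations via indicator-matrix products.
# P: B x n 0/1 matrix (group-1 membership), Xe: n x m data. Returns B x m.
perm_welch_t <- function(P, Xe) {
  n <- nrow(Xe)
  n1 <- rowSums(P); n2 <- n - n1
  S <- P %*% Xe
  Q <- P %*% (Xe * Xe)
  Stot <- matrix(colSums(Xe), nrow(P), ncol(Xe), byrow = TRUE)
  Qtot <- matrix(colSums(Xe * Xe), nrow(P), ncol(Xe), byrow = TRUE)
  m1 <- S / n1; m2 <- (Stot - S) / n2
  v1 <- pmax((Q - n1 * m1^2) / (n1 - 1), 0)
  v2 <- pmax((Qtot - Q - n2 * m2^2) / (n2 - 1), 0)
  se2 <- v1 / n1 + v2 / n2
  tt <- (m1 - m2) / sqrt(se2)
  tt[se2 == 0 & m1 == m2] <- 0
  tt
}

#' TFNBS with permutation family-wise error control
#'
#' Runs the full edge-level inference for one (metric, filtering) slice of
#' a cohort: observed Welch t statistics, TFNBS scores for both directed
#' hypotheses, uncorrected one-sided p-values, and FWE-corrected p-values
#' from the permutation distribution of the maximum TFNBS score. Group
#' labels are permuted; the same permutations are shared by the two
#' hypotheses. When the number of distinct group assignments does not
#' exceed `n_permutations`, the test switches to exhaustive enumeration and
#' the p-values are exact.
#'
#' @inheritParams edge_t_statistics
#' @param cfg a [tfnbs_config()].
#' @return object of class `"edge_inference"`: list with `t` (matrix),
#'   per-hypothesis elements `score`, `p_uncorrected`, `p_fwe` (matrices),
#'   plus `config`, `n_permutations_used`, `exhaustive`.
#' @export
tfnbs_fwe <- function(x, metric, filtering, cfg = tfnbs_config()) {
  stopifnot(inherits(x, "cohort"), inherits(cfg, "tfnbs_config"))
  grp <- x$manifest$group
  if (!all(c("PD", "HC") %in% grp)) stop("both groups (PD, HC) must be present")
  Xe <- cohort_edge_matrix(x, metric, filtering)
  n <- nrow(Xe); n1 <- sum(grp == "PD")
  nlab <- length(x$labels)
  ep <- edge_pairs(nlab)

  obs <- welch_t_vec(Xe[grp == "PD", , drop = FALSE],
                     Xe[grp == "HC", , drop = FALSE])
  # observed t recomputed through the same batch routine as the
  # permutations, so exact ties (the observed labeling inside the null
  # set) survive floating-point arithmetic
  obs_tv <- perm_welch_t(matrix(as.integer(grp == "PD"), 1), Xe)[1, ]
  p_unc <- list(
    t1_PD_gt_HC = pt(obs$t, df = obs$df, lower.tail = FALSE),
    t2_HC_gt_PD = pt(obs$t, df = obs$df, lower.tail = TRUE)
  )

  n_distinct <- choose(n, n1)
  exhaustive <- is.finite(n_distinct) && n_distinct <= cfg$n_permutations
  if (exhaustive) {
    message(sprintf(
      "exhaustive enumeration: %d distinct assignments <= %d requested permutations",
      n_distinct, cfg$n_permutations))
    P <- exhaustive_assignments(n, n1)
  } else {
    set.seed(cfg$seed)
    P <- t(vapply(seq_len(cfg$n_permutations), function(b) {
      z <- integer(n); z[sample.int(n, n1)] <- 1L; z
    }, integer(n)))
  }
  Tperm <- perm_welch_t(P, Xe)

  result <- list(metric = metric, filtering = filtering, labels = x$labels,
                 t = NULL, config = cfg,
                 n_permutations_used = nrow(P), exhaustive = exhaustive)
  tmat <- matrix_from_upper(obs$t, nlab)
  dimnames(tmat) <- list(x$labels, x$labels)
  result$t <- tmat

  for (hyp in HYPOTHESES) {
    sign_ <- if (hyp == "t1_PD_gt_HC") 1 else -1
    tv <- sign_ * obs_tv
    relative <- is.null(cfg$threshold_range)
    sc <- tfnbs_score_vec(tv, ep, nlab, cfg)
    # Each permuted map is scored by the same function as the observed one:
    # with a data-driven ladder this means every map gets its own
    # (0, max t] ladder, which keeps observed and null scores exchangeable.
    lad <- if (relative) NULL else tfnbs_ladder(cfg, NA)
    null_max <- tfnbs_max_scores_cpp(
      sign_ * Tperm, ep[, 1] - 1L, ep[, 2] - 1L, nlab,
      if (is.null(lad)) numeric(0) else lad$h, cfg$E, cfg$H,
      if (is.null(lad)) 0 else lad$dh, relative, cfg$n_steps)
    if (exhaustive) {
      p_fwe <- vapply(sc, function(s) mean(null_max >= s), numeric(1))
    } else {
      B <- length(null_max)
      p_fwe <- vapply(sc, function(s) (1 + sum(null_max >= s)) / (1 + B),
                      numeric(1))
    }
    sym <- function(v) {
      m <- matrix_from_upper(v, nlab)
      dimnames(m) <- list(x$labels, x$labels)
      m
    }
    result[[hyp]] <- list(score = sym(sc),
                          p_uncorrected = sym(p_unc[[hyp]]),
                          p_fwe = sym(p_fwe),
                          null_max_scores = null_max)
  }
  class(result) <- "edge_inference"
  result
}

#' @export
print.edge_inference <- function(x, ...) {
  cat(sprintf("<edge_inference> metric %s | %s | %d permutations%s\n",
              x$metric, x$filtering, x$n_permutations_used,
              if (x$exhaustive) " (exhaustive)" else ""))
  for (hyp in HYPOTHESES) {
    pf <- upper_triangle_vector(x[[hyp]]$p_fwe)
    cat(sprintf("  %s: min FWE p = %.4g, %d edges FWE-significant at 0.05\n",
                hyp, min(pf), sum(pf <= 0.05)))
  }
  invisible(x)
}

#' Most significant connections, Table-2 style
#'
#' The k most significant region pairs for one hypothesis, sorted by
#' uncorrected p (ties broken by larger |t| first), with uncorrected and
#' FWE-corrected p-values and the t statistic.
#'
#' @param result an [tfnbs_fwe()] result.
#' @param k number of connections to report (clamped to the edge count
#'   with a warning).
#' @param hypothesis which directed hypothesis to report.
#' @return data.frame with columns `connection`, `p_uncorrected`, `p_fwe`,
#'   `t`.
#' @export
top_connections_table <- function(result, k = 10,
                                  hypothesis = "t1_PD_gt_HC") {
  stopifnot(inherits(result, "edge_inference"))
  hypothesis <- match.arg(hypothesis, HYPOTHESES)
  n <- length(result$labels)
  ep <- edge_pairs(n)
  p <- upper_triangle_vector(result[[hypothesis]]$p_uncorrected)
  pf <- upper_triangle_vector(result[[hypothesis]]$p_fwe)
  tv <- upper_triangle_vector(result$t)
  if (k > length(p)) {
    warning("k exceeds the number of edges; clamped to ", length(p))
    k <- length(p)
  }
  ord <- order(p, -abs(tv))
  top <- ord[seq_len(k)]
  data.frame(
    connection = paste(result$labels[ep[top, 1]],
                       result$labels[ep[top, 2]], sep = "↔"),
    p_uncorrected = p[top], p_fwe = pf[top], t = tv[top],
    stringsAsFactors = FALSE
  )
}
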