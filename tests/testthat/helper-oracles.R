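# Independent brute-force oracles used to validate the package's graph
# measures and statistics. These deliberately use naive algorithms (path
# enumeration, triple loops, exhaustive permutation) and share no code
# with the implementations they check.

# random symmetric nonnegative weight matrix with zero diagonal
rand_sym <- function(n, density = 0.5, rng = c(0.2, 3)) {
  w <- matrix(0, n, n)
  ut <- upper.tri(w)
  k <- sum(ut)
  vals <- ifelse(runif(k) < density, runif(k, rng[1], rng[2]), 0)
  w[ut] <- vals
  w + t(w)
}

oracle_strength <- function(w) {
  n <- nrow(w)
  s <- numeric(n)
  for (i in seq_len(n)) for (j in seq_len(n)) s[i] <- s[i] + w[i, j]
  s
}

# all-pairs simple-path enumeration betweenness (lengths 1/w), normalized
oracle_betweenness <- function(w) {
  n <- nrow(w)
  len <- ifelse(w > 0, 1 / w, Inf)
  bc <- numeric(n)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    paths <- list()
    rec <- function(cur, visited, dist) {
      if (cur == t) {
        paths[[length(paths) + 1]] <<- list(v = visited, d = dist)
        return(invisible())
      }
      for (nx in which(w[cur, ] > 0)) {
        if (!(nx %in% visited)) rec(nx, c(visited, nx), dist + len[cur, nx])
      }
    }
    rec(s, s, 0)
    if (!length(paths)) next
    ds <- vapply(paths, function(p) p$d, numeric(1))
    mind <- min(ds)
    sel <- which(ds <= mind * (1 + 1e-12))
    for (p in sel) {
      inter <- setdiff(paths[[p]]$v, c(s, t))
      bc[inter] <- bc[inter] + 1 / length(sel)
    }
  }
  if (n > 2) bc / ((n - 1) * (n - 2) / 2) else bc * 0
}

# Onnela clustering by direct triple summation
oracle_clustering <- function(w) {
  n <- nrow(w)
  mx <- max(w)
  out <- numeric(n)
  if (mx == 0) return(out)
  wh <- (w / mx)^(1 / 3)
  for (i in seq_len(n)) {
    k <- sum(w[i, ] > 0)
    if (k < 2) next
    acc <- 0
    for (j in seq_len(n)) for (h in seq_len(n)) {
      acc <- acc + wh[i, j] * wh[j, h] * wh[h, i]
    }
    out[i] <- acc / (k * (k - 1))
  }
  out
}

oracle_assortativity <- function(w) {
  n <- nrow(w)
  s <- rowSums(w)
  a <- c(); b <- c()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (w[i, j] > 0) {
      a <- c(a, s[i], s[j]); b <- c(b, s[j], s[i])
    }
  }
  if (length(a) < 4 || sd(a) == 0 || sd(b) == 0) return(NA_real_)
  cor(a, b)
}

# per-edge extent^E surface for one suprathreshold adjacency, by hand
# BFS component labeling (no union-find, no igraph)
oracle_extent_surface <- function(adj, E) {
  n <- nrow(adj)
  out <- matrix(0, n, n)
  comp <- rep(0L, n); cid <- 0L
  for (v in seq_len(n)) {
    if (comp[v] == 0L && any(adj[v, ])) {
      cid <- cid + 1L
      queue <- v; comp[v] <- cid
      while (length(queue)) {
        cur <- queue[1]; queue <- queue[-1]
        for (nx in which(adj[cur, ])) {
          if (comp[nx] == 0L) { comp[nx] <- cid; queue <- c(queue, nx) }
        }
      }
    }
  }
  for (cc in seq_len(cid)) {
    nodes <- which(comp == cc)
    sub <- adj[nodes, nodes, drop = FALSE]
    extent <- sum(sub) / 2
    if (extent == 0) next
    for (i in nodes) for (j in nodes) {
      if (adj[i, j]) out[i, j] <- extent^E
    }
  }
  out
}

# TFNBS scores with an explicit threshold ladder
oracle_tfnbs <- function(tmat, thresholds, E, H, dh) {
  n <- nrow(tmat)
  score <- matrix(0, n, n)
  for (h in thresholds) {
    adj <- tmat > h
    diag(adj) <- FALSE
    score <- score + oracle_extent_surface(adj, E) * h^H * dh
  }
  score
}

# TFNBS scores with the data-driven relative ladder: n_steps levels over
# (0, max t], suprathreshold test cross-multiplied (t * n_steps >
# tmax * k) so the knife edge t == tmax is exact
oracle_tfnbs_rel <- function(tmat, n_steps, E, H) {
  n <- nrow(tmat)
  tmax <- max(tmat[upper.tri(tmat)])
  if (tmax <= 0) return(matrix(0, n, n))
  score <- matrix(0, n, n)
  for (k in seq_len(n_steps)) {
    adj <- (tmat * n_steps) > (tmax * k)
    diag(adj) <- FALSE
    h <- tmax * (k) / n_steps
    score <- score + oracle_extent_surface(adj, E) * h^H * (tmax / n_steps)
  }
  score
}

# exhaustive-permutation FWE p-values for a subjects x edges matrix,
# using stats::t.test per edge and the oracle score function
oracle_exhaustive_fwe <- function(X, n1, n_nodes, n_steps, E, H) {
  n <- nrow(X)
  combs <- combn(n, n1)
  t_of <- function(idx) {
    vapply(seq_len(ncol(X)), function(e) {
      unname(stats::t.test(X[idx, e], X[-idx, e])$statistic)
    }, numeric(1))
  }
  tmat_of <- function(tv) {   # row-major upper-triangle edge order
    m <- matrix(0, n_nodes, n_nodes); k <- 1L
    for (i in seq_len(n_nodes - 1)) for (j in (i + 1):n_nodes) {
      m[i, j] <- m[j, i] <- tv[k]; k <- k + 1L
    }
    m
  }
  ut_of <- function(m) {
    out <- numeric(n_nodes * (n_nodes - 1) / 2); k <- 1L
    for (i in seq_len(n_nodes - 1)) for (j in (i + 1):n_nodes) {
      out[k] <- m[i, j]; k <- k + 1L
    }
    out
  }
  obs_t <- t_of(seq_len(n1))
  obs_score <- oracle_tfnbs_rel(tmat_of(obs_t), n_steps, E, H)
  max_scores <- apply(combs, 2, function(idx) {
    sc <- oracle_tfnbs_rel(tmat_of(t_of(idx)), n_steps, E, H)
    max(sc)
  })
  obs_ut <- ut_of(obs_score)
  p <- vapply(obs_ut, function(s) mean(max_scores >= s), numeric(1))
  list(p_fwe = p, obs_score = obs_ut, max_scores = max_scores)
}

# closed-form Benjamini-Yekutieli adjustment
oracle_by <- function(p) {
  m <- length(p)
  cm <- sum(1 / seq_len(m))
  ord <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (i in rev(seq_len(m))) {
    val <- min(prev, cm * m / i * p[ord[i]], 1)
    adj[ord[i]] <- val
    prev <- val
  }
  adj
}

# small cohort of explicitly supplied edge-value matrices (one metric)
cohort_from_values <- function(V, groups, labels,
                               metric = "SC", filtering = "unfiltered") {
  n <- nrow(V)
  man <- cohort_manifest(sprintf("s%02d", seq_len(n)), groups,
                         rep("F", n), rep(60, n))
  conns <- lapply(seq_len(n), function(i) {
    connectome(matrix_from_upper(V[i, ], length(labels)), metric = metric,
               filtering = filtering, subject_id = sprintf("s%02d", i),
               labels = labels)
  })
  cohort(man, conns, labels)
}
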