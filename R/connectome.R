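#' @useDynLib filtconn, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats pt qnorm rbeta rbinom rlnorm rnorm runif sd var
#' @importFrom utils head read.table write.table
NULL

# Canonical connectivity metrics and filtering states.
CONN_METRICS <- c("SC", "FA", "AD", "RD", "MD")
FILTER_STATES <- c("unfiltered", "filtered")

#' Construct a connectome
#'
#' A connectome is a square, symmetric, nonnegative weight matrix over a
#' fixed set of brain regions, tagged with the subject it belongs to, the
#' connectivity metric its edge weights carry, and whether the tractogram it
#' came from was filtered. Edge weights are streamline counts (SC, possibly
#' SIFT2-weighted, hence non-integer) or per-edge means of diffusion-tensor
#' scalars (FA in (0,1); AD/RD/MD in consistent diffusivity units).
#'
#' The diagonal (self-connections) must be zero; a nonzero diagonal is
#' zeroed with a warning since self-edges are meaningless in this analysis.
#'
#' @param weights square numeric matrix, symmetric with nonnegative entries.
#' @param metric one of `"SC"`, `"FA"`, `"AD"`, `"RD"`, `"MD"`.
#' @param filtering `"unfiltered"` or `"filtered"`.
#' @param subject_id subject identifier string.
#' @param labels region labels defining node order; default [aal90_labels()].
#' @return An object of class `"connectome"`: a list with elements
#'   `weights` (matrix with region dimnames), `metric`, `filtering`,
#'   `subject_id`.
#' @export
connectome <- function(weights, metric, filtering, subject_id = "subject",
                       labels = aal90_labels()) {
  metric <- match.arg(metric, CONN_METRICS)
  filtering <- match.arg(filtering, FILTER_STATES)
  validate_labels(labels)
  if (!is.matrix(weights) || !is.numeric(weights)) {
    stop("weights must be a numeric matrix")
  }
  n <- length(labels)
  if (nrow(weights) != n || ncol(weights) != n) {
    stop(sprintf("weights must be %d x %d to match the %d region labels; got %d x %d",
                 n, n, n, nrow(weights), ncol(weights)))
  }
  bad <- which(!is.finite(weights))
  if (length(bad)) {
    rc <- arrayInd(bad[1], dim(weights))
    stop(sprintf("non-finite weight at row %d, column %d", rc[1], rc[2]))
  }
  if (any(weights < 0)) {
    rc <- arrayInd(which(weights < 0)[1], dim(weights))
    stop(sprintf("negative weight at row %d, column %d", rc[1], rc[2]))
  }
  if (max(abs(weights - t(weights))) > 1e-8 * max(1, max(abs(weights)))) {
    stop("weights must be symmetric (w_ij == w_ji)")
  }
  weights <- (weights + t(weights)) / 2  # remove numeric asymmetry
  if (any(diag(weights) != 0)) {
    warning("nonzero diagonal entries zeroed (self-connections are ignored)")
    diag(weights) <- 0
  }
  if (metric == "FA" && any(weights > 1)) {
    stop("FA edge weights must lie in [0, 1]")
  }
  dimnames(weights) <- list(labels, labels)
  structure(
    list(weights = weights, metric = metric, filtering = filtering,
         subject_id = as.character(subject_id)),
    class = "connectome"
  )
}

#' @export
print.connectome <- function(x, ...) {
  nz <- sum(x$weights[upper.tri(x$weights)] > 0)
  n <- nrow(x$weights)
  cat(sprintf("<connectome> subject %s | metric %s | %s | %d regions | %d/%d nonzero edges\n",
              x$subject_id, x$metric, x$filtering, n, nz, n * (n - 1) / 2))
  invisible(x)
}

#' Read a connectome from a delimited text matrix file
#'
#' Accepts comma- or whitespace-delimited square numeric matrices, with an
#' optional header row of region names (as written by [write_connectome()]
#' or by MRtrix-style connectome exports). Upper-triangular-only files, a
#' common dialect for undirected graphs, are mirrored to full symmetric
#' form. A nonzero diagonal is zeroed with a warning.
#'
#' @param path path of the matrix file.
#' @param labels region labels the matrix must conform to.
#' @inheritParams connectome
#' @return A validated [connectome()].
#' @export
read_connectome <- function(path, metric, filtering, subject_id = "subject",
                            labels = aal90_labels()) {
  validate_labels(labels)
  first <- readLines(path, n = 1L, warn = FALSE)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  has_header <- {
    fields <- strsplit(trimws(first), if (sep == ",") "," else "[[:space:]]+")[[1]]
    suppressWarnings(any(is.na(as.numeric(fields))))
  }
  df <- read.table(path, sep = sep, header = has_header,
                   check.names = FALSE, comment.char = "")
  m <- as.matrix(df)
  storage.mode(m) <- "double"
  n <- length(labels)
  if (nrow(m) != n || ncol(m) != n) {
    stop(sprintf("expected a %d x %d matrix, got %d x %d in %s",
                 n, n, nrow(m), ncol(m), path))
  }
  nab <- which(is.na(m))
  if (length(nab)) {
    rc <- arrayInd(nab[1], dim(m))
    stop(sprintf("missing/NaN entry at row %d, column %d in %s", rc[1], rc[2], path))
  }
  lower <- m[lower.tri(m)]
  upper <- t(m)[lower.tri(m)]
  if (all(lower == 0) && any(upper != 0)) {
    m[lower.tri(m)] <- t(m)[lower.tri(m)]  # mirror triangular dialect
  }
  connectome(m, metric = metric, filtering = filtering,
             subject_id = subject_id, labels = labels)
}

#' Write a connectome as a comma-delimited matrix with a header row
#'
#' Values are printed with 17 significant digits so that
#' `read_connectome(write_connectome(x))` round-trips weights exactly.
#'
#' @param x a [connectome()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_connectome <- function(x, path) {
  stopifnot(inherits(x, "connectome"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(colnames(x$weights), collapse = ","), con)
  body <- apply(x$weights, 1L, function(row)
    paste(sprintf("%.17g", row), collapse = ","))
  writeLines(body, con)
  invisible(path)
}

#' Strictly-upper-triangle pairs in row-major order
#'
#' The canonical edge order used by [upper_triangle_vector()] and all
#' edge-level statistics: (1,2), (1,3), ..., (1,n), (2,3), ...
#'
#' @param n number of nodes.
#' @return integer matrix with columns `i`, `j` (1-based, i < j), one row
#'   per edge, n(n-1)/2 rows.
#' @export
edge_pairs <- function(n) {
  i <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  j <- unlist(lapply(seq_len(n - 1L), function(k) (k + 1L):n), use.names = FALSE)
  cbind(i = i, j = j)
}

#' Vectorize the strictly-upper triangle of a connectome
#'
#' Returns the n(n-1)/2 upper-triangle weights (4005 for 90 regions) in the
#' fixed row-major order of [edge_pairs()], identical for every subject on a
#' shared atlas. This is the feature vector used by the SVM classifiers.
#'
#' @param x a [connectome()] or a symmetric numeric matrix.
#' @return numeric vector of length n(n-1)/2.
#' @export
upper_triangle_vector <- function(x) {
  m <- if (inherits(x, "connectome")) x$weights else x
  t(m)[lower.tri(m)]  # row-major upper triangle
}

#' Rebuild a symmetric matrix from an upper-triangle vector
#'
#' Inverse of [upper_triangle_vector()] (zero diagonal).
#'
#' @param v upper-triangle vector in row-major order.
#' @param n number of nodes.
#' @return n x n symmetric matrix.
#' @export
matrix_from_upper <- function(v, n) {
  stopifnot(length(v) == n * (n - 1) / 2)
  m <- matrix(0, n, n)
  mt <- t(m)
  mt[lower.tri(mt)] <- v
  m <- t(mt)
  m + t(m)
}

#' Connection profile of a node
#'
#' The node's full row of the weight matrix (self-entry zero), used as the
#' node's input feature vector for the graph neural networks.
#'
#' @param x a [connectome()].
#' @param node region index (1-based) or region name.
#' @return numeric vector of length n (number of regions).
#' @export
connection_profile <- function(x, node) {
  stopifnot(inherits(x, "connectome"))
  n <- nrow(x$weights)
  if (is.character(node)) {
    node <- match(node, rownames(x$weights))
  }
  if (is.na(node) || node < 1 || node > n) {
    stop("node must be a region index in 1..", n, " or a known region name")
  }
  x$weights[node, ]
}

#' Construct a cohort manifest
#'
#' @param subject_id unique subject identifiers.
#' @param group `"PD"` or `"HC"` per subject.
#' @param sex `"F"` or `"M"` per subject.
#' @param age age in years per subject.
#' @return data.frame with class `"cohort_manifest"`.
#' @export
cohort_manifest <- function(subject_id, group, sex, age) {
  group <- as.character(group); sex <- as.character(sex)
  if (anyDuplicated(subject_id)) stop("subject_id must be unique")
  if (!all(group %in% c("PD", "HC"))) stop("group must be 'PD' or 'HC'")
  if (!all(sex %in% c("F", "M"))) stop("sex must be 'F' or 'M'")
  stopifnot(is.numeric(age), all(is.finite(age)), all(age > 0))
  structure(
    data.frame(subject_id = as.character(subject_id), group = group,
               sex = sex, age = age, stringsAsFactors = FALSE),
    class = c("cohort_manifest", "data.frame")
  )
}

#' Read a cohort manifest CSV (columns subject_id, group, sex, age)
#' @param path CSV file path.
#' @return a [cohort_manifest()].
#' @export
read_manifest <- function(path) {
  df <- read.table(path, sep = ",", header = TRUE, stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "sex", "age")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("manifest is missing columns: ", paste(miss, collapse = ", "))
  cohort_manifest(df$subject_id, df$group, df$sex, df$age)
}

#' Write a cohort manifest CSV
#' @param manifest a [cohort_manifest()].
#' @param path output path.
#' @export
write_manifest <- function(manifest, path) {
  write.table(manifest, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Assemble a cohort
#'
#' A cohort binds a manifest to the connectomes of its subjects across
#' connectivity metrics and filtering states, all sharing one region atlas.
#'
#' @param manifest a [cohort_manifest()].
#' @param connectomes list of [connectome()] objects.
#' @param labels shared region labels.
#' @return object of class `"cohort"`: list(manifest, connectomes, labels)
#'   with connectomes keyed `"<subject>|<metric>|<filtering>"`.
#' @export
cohort <- function(manifest, connectomes, labels = aal90_labels()) {
  stopifnot(inherits(manifest, "cohort_manifest"))
  validate_labels(labels)
  keys <- vapply(connectomes, function(x) {
    stopifnot(inherits(x, "connectome"))
    if (!identical(rownames(x$weights), labels)) {
      stop("connectome for subject ", x$subject_id,
           " does not share the cohort's region labels")
    }
    if (!x$subject_id %in% manifest$subject_id) {
      stop("connectome subject ", x$subject_id, " is not in the manifest")
    }
    paste(x$subject_id, x$metric, x$filtering, sep = "|")
  }, character(1))
  if (anyDuplicated(keys)) stop("duplicate (subject, metric, filtering) connectome")
  names(connectomes) <- keys
  structure(list(manifest = manifest, connectomes = connectomes, labels = labels),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  tab <- table(x$manifest$group)
  cat(sprintf("<cohort> %d subjects (%s) | %d regions | %d connectomes\n",
              nrow(x$manifest),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
              length(x$labels), length(x$connectomes)))
  invisible(x)
}

#' Fetch one connectome from a cohort
#' @param x a [cohort()].
#' @param subject_id,metric,filtering key of the connectome.
#' @return the [connectome()].
#' @export
cohort_connectome <- function(x, subject_id, metric, filtering) {
  key <- paste(subject_id, metric, filtering, sep = "|")
  out <- x$connectomes[[key]]
  if (is.null(out)) stop("no connectome for key ", key)
  out
}

# Subjects x edges matrix of upper-triangle weights for one (metric,
# filtering) slice, rows in manifest order. Backbone of all edge-level and
# classification stages.
cohort_edge_matrix <- function(x, metric, filtering) {
  stopifnot(inherits(x, "cohort"))
  rows <- lapply(x$manifest$subject_id, function(s)
    upper_triangle_vector(cohort_connectome(x, s, metric, filtering)))
  out <- do.call(rbind, rows)
  rownames(out) <- x$manifest$subject_id
  out
}
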