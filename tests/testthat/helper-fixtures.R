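# Shared fixtures and independent oracles used across the suite.

# minimal phenotype table with arbitrary feature values
toy_cohort <- function(values, groups = NULL) {
  n <- nrow(values)
  tibble::tibble(
    subject_id = sprintf("s%02d", seq_len(n)),
    group = groups %||% rep("TDC", n),
    adhd_index = values[, 1], inattentive = values[, 2],
    hyper_impulsive = values[, 3], fsiq = values[, 4],
    viq = values[, 5], piq = values[, 6],
    age = rep(10, n)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# hand-built mapper_graph for flare-rule tests (bypasses the cover stage)
fake_mapper_graph <- function(nodes_subjects, edges, f) {
  nodes <- tibble::tibble(
    node_id = names(nodes_subjects),
    interval = seq_along(nodes_subjects),
    cluster = 1L,
    subjects = unname(nodes_subjects),
    size = lengths(nodes_subjects)
  )
  subjects <- sort(unique(unlist(nodes_subjects)))
  structure(
    list(
      nodes = nodes,
      edges = tibble::tibble(
        from = edges$from %||% character(),
        to = edges$to %||% character(),
        weight = rep(1L, length(edges$from %||% character()))
      ),
      subjects = subjects,
      f = f[subjects],
      cover = cover_config()
    ),
    class = "mapper_graph"
  )
}

# symmetric adjacency with zero diagonal from an edge list (1-based indices)
adjacency_from_edges <- function(n, edges, weights = 1) {
  A <- matrix(0, n, n)
  weights <- rep_len(weights, nrow(edges))
  for (k in seq_len(nrow(edges))) {
    i <- edges[k, 1]; j <- edges[k, 2]
    A[i, j] <- weights[k]; A[j, i] <- weights[k]
  }
  dimnames(A) <- list(paste0("v", 1:n), paste0("v", 1:n))
  A
}

# all set partitions of n elements as restricted-growth strings
all_partitions <- function(n) {
  out <- list()
  recurse <- function(prefix, maxlab) {
    if (length(prefix) == n) {
      out[[length(out) + 1]] <<- prefix
      return(invisible())
    }
    for (lab in seq_len(maxlab + 1)) {
      recurse(c(prefix, lab), max(maxlab, lab))
    }
  }
  recurse(integer(0), 0L)
  out
}

# independent double-sum evaluation of Newman's Q
modularity_oracle <- function(A, assignment) {
  s <- rowSums(A)
  two_m <- sum(s)
  q <- 0
  n <- nrow(A)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (assignment[i] == assignment[j]) {
        q <- q + A[i, j] - s[i] * s[j] / two_m
      }
    }
  }
  q / two_m
}

# exhaustive modularity maximum by partition enumeration (n <= 8)
exhaustive_best_q <- function(A) {
  parts <- all_partitions(nrow(A))
  max(vapply(parts, function(p) modularity_oracle(A, p), numeric(1)))
}

# dense PageRank power iteration, written independently of the package
pagerank_oracle <- function(A, alpha = 0.85, iters = 5000) {
  n <- nrow(A)
  s <- rowSums(A)
  P <- matrix(1 / n, n, n)
  nz <- s > 0
  P[nz, ] <- A[nz, , drop = FALSE] / s[nz]
  G <- alpha * P + (1 - alpha) / n
  v <- rep(1 / n, n)
  for (i in seq_len(iters)) v <- as.numeric(v %*% G)
  v / sum(v)
}

# brute-force Benjamini-Hochberg by literal definition
bh_oracle <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  sorted <- p[ord]
  passing <- which(sorted <= seq_len(m) / m * q)
  reject <- logical(m)
  if (length(passing) > 0) reject[ord[seq_len(max(passing))]] <- TRUE
  reject
}

# random small phenotype matrix for distance oracles
random_feature_matrix <- function(n, p, seed) {
  set.seed(seed)
  matrix(rnorm(n * p), n, p)
}
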