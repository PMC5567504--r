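#' Node centralities on positive-weight undirected graphs
#'
#' `strength_centrality()` is the weighted degree, the row sum of the
#' adjacency matrix. `betweenness_centrality()` counts shortest paths
#' through a node with edge length `1/weight` (stronger connections are
#' shorter), fractional over ties, unnormalized by default.
#' `pagerank()` is the stationary distribution of the damped random walk
#' with damping `alpha` (default 0.85), computed by power iteration;
#' dangling (isolated) nodes redistribute uniformly and the result sums to 1.
#'
#' @param A Symmetric non-negative adjacency matrix with zero diagonal,
#'   e.g. from [positive_graph()].
#' @param normalized Scale betweenness by `2 / ((n-1)(n-2))` (default FALSE,
#'   raw path counts).
#' @param alpha PageRank damping factor in (0, 1).
#' @param tol Power-iteration convergence tolerance on the L1 change.
#' @param max_iter Iteration cap; exceeding it is an error reporting the
#'   residual.
#'
#' @return Named numeric vector, one value per node.
#' @name centralities
NULL

check_adjacency <- function(A) {
  if (!is.matrix(A) || nrow(A) != ncol(A)) abort("`A` must be a square matrix.")
  if (any(A < 0)) abort("`A` must be non-negative; apply positive_graph() first.")
  if (any(diag(A) != 0)) abort("`A` must have a zero diagonal (no self-loops).")
  if (max(abs(A - t(A))) > 1e-12) abort("`A` must be symmetric.")
  if (is.null(colnames(A))) {
    dimnames(A) <- list(sprintf("ROI_%03d", seq_len(ncol(A))),
                        sprintf("ROI_%03d", seq_len(ncol(A))))
  }
  A
}

#' @rdname centralities
#' @export
strength_centrality <- function(A) {
  A <- check_adjacency(A)
  rowSums(A)
}

#' @rdname centralities
#' @export
betweenness_centrality <- function(A, normalized = FALSE) {
  A <- check_adjacency(A)
  ig <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                            weighted = TRUE)
  w <- igraph::E(ig)$weight
  b <- igraph::betweenness(ig, weights = 1 / w, normalized = normalized)
  setNames(as.numeric(b), colnames(A))
}

#' @rdname centralities
#' @export
pagerank <- function(A, alpha = 0.85, tol = 1e-12, max_iter = 1000L) {
  A <- check_adjacency(A)
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must lie strictly in (0, 1).")
  n <- nrow(A)
  s <- rowSums(A)
  dangling <- s == 0
  P <- A
  P[!dangling, ] <- A[!dangling, , drop = FALSE] / s[!dangling]
  pr <- rep(1 / n, n)
  for (it in seq_len(max_iter)) {
    new <- alpha * (as.numeric(pr %*% P) + sum(pr[dangling]) / n) +
      (1 - alpha) / n
    delta <- sum(abs(new - pr))
    pr <- new
    if (delta < tol) {
      return(setNames(pr / sum(pr), colnames(A)))
    }
  }
  abort(paste0("PageRank power iteration did not converge within ", max_iter,
               " iterations (residual ", signif(delta, 3), ")."))
}

#' Tidy per-subject centrality table
#'
#' Applies one centrality measure to every subject's positive-weight graph
#' (the positive part of the subject's signed correlation matrix) and
#' returns a long table ready for group statistics.
#'
#' @param networks Named list of per-subject signed connectivity matrices
#'   (names = subject ids), e.g. outputs of [correlation_network()].
#' @param measure `"strength"`, `"betweenness"` or `"pagerank"`.
#' @param ... Passed to the underlying centrality function (e.g. `alpha`).
#'
#' @return Tibble with columns `subject_id`, `roi`, `value`.
#' @export
centrality_table <- function(networks,
                             measure = c("strength", "betweenness", "pagerank"),
                             ...) {
  measure <- match.arg(measure)
  if (is.null(names(networks))) {
    names(networks) <- sprintf("sub-%03d", seq_along(networks))
  }
  fun <- switch(measure,
    strength = strength_centrality,
    betweenness = betweenness_centrality,
    pagerank = pagerank
  )
  purrr::imap_dfr(networks, function(R, id) {
    v <- fun(positive_graph(R), ...)
    tibble(subject_id = id, roi = names(v), value = unname(v))
  })
}
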