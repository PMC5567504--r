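#' Fit reference (control-group) normalization parameters
#'
#' Computes per-feature means and population standard deviations (divide by
#' the number of reference subjects, not N - 1) over a designated reference
#' subset — typically the typically-developing controls — so that every
#' subject can be expressed in control-referenced z-scores.
#'
#' @param data Data frame with one row per subject.
#' @param reference_ids Character vector of subject ids defining the
#'   reference subset (at least 2; each feature must have nonzero spread
#'   within it).
#' @param features Feature columns to normalize (default: the six clinical
#'   features).
#' @param id_col Name of the subject-id column.
#'
#' @return An object of class `ref_norm` holding `means`, `sds`,
#'   `reference_ids` and `features`.
#' @export
#' @examples
#' cohort <- gen_clinical_cohort(cohort_presets(), seed = 1)
#' ref <- cohort$subject_id[cohort$group == "TDC"]
#' fit_reference_normalization(cohort, ref)
fit_reference_normalization <- function(data, reference_ids,
                                        features = clinical_features(),
                                        id_col = "subject_id") {
  missing_ids <- setdiff(reference_ids, data[[id_col]])
  if (length(missing_ids) > 0) {
    abort(paste0("Reference ids not in `data`: ", toString(head(missing_ids, 5))))
  }
  if (length(reference_ids) < 2) {
    abort("Need at least 2 reference subjects (SD of one point is zero).")
  }
  missing_feat <- setdiff(features, names(data))
  if (length(missing_feat) > 0) {
    abort(paste0("Features missing from `data`: ", toString(missing_feat)))
  }
  ref <- as.matrix(data[data[[id_col]] %in% reference_ids, features, drop = FALSE])
  if (anyNA(ref)) abort("Reference rows contain missing feature values.")
  n <- nrow(ref)
  mu <- colMeans(ref)
  # population SD: the reference cohort is the distribution, not a sample
  sigma <- sqrt(colMeans(sweep(ref, 2, mu)^2))
  zero <- sigma <= 0
  if (any(zero)) {
    abort(paste0(
      "Zero spread in reference feature(s): ", toString(features[zero]),
      "; normalization is undefined."
    ))
  }
  structure(
    list(means = mu, sds = sigma, reference_ids = reference_ids,
         features = features),
    class = "ref_norm"
  )
}

#' @export
print.ref_norm <- function(x, ...) {
  cat("<ref_norm>", length(x$reference_ids), "reference subjects\n")
  print(tibble(feature = x$features, mean = unname(x$means), sd = unname(x$sds)))
  invisible(x)
}

#' Clinical feature columns
#'
#' The canonical six-feature set driving the subject-distance computation:
#' ADHD index, inattentive and hyperactive/impulsive symptom scores, and
#' full-scale, verbal and performance IQ.
#'
#' @return Character vector of column names.
#' @export
clinical_features <- function() .clinical_features

#' Apply or invert reference normalization
#'
#' `normalize_features()` converts each feature to a control-referenced
#' z-score, `(x - mu_ref) / sigma_ref`; `denormalize_features()` inverts it.
#' After normalization the reference rows of every feature have mean 0 and
#' population SD 1.
#'
#' @param data Data frame with the fitted feature columns.
#' @param params A `ref_norm` from [fit_reference_normalization()].
#'
#' @return `data` with the feature columns replaced (a tibble).
#' @export
normalize_features <- function(data, params) {
  stopifnot(inherits(params, "ref_norm"))
  missing_feat <- setdiff(params$features, names(data))
  if (length(missing_feat) > 0) {
    abort(paste0("`data` lacks fitted feature(s): ", toString(missing_feat)))
  }
  out <- as_tibble(data)
  for (j in params$features) {
    out[[j]] <- (out[[j]] - params$means[[j]]) / params$sds[[j]]
  }
  out
}

#' @rdname normalize_features
#' @export
denormalize_features <- function(data, params) {
  stopifnot(inherits(params, "ref_norm"))
  out <- as_tibble(data)
  for (j in params$features) {
    out[[j]] <- out[[j]] * params$sds[[j]] + params$means[[j]]
  }
  out
}

#' Pairwise Euclidean subject distances
#'
#' @param data Data frame of (normalized) subject rows.
#' @param features Feature columns entering the distance.
#' @param id_col Subject-id column used for the matrix dimnames.
#'
#' @return Symmetric subjects x subjects matrix with zero diagonal.
#' @export
euclidean_distances <- function(data, features = clinical_features(),
                                id_col = "subject_id") {
  if (nrow(data) < 2) abort("Need at least 2 subjects for a distance matrix.")
  x <- as.matrix(data[, features, drop = FALSE])
  if (anyNA(x)) abort("Feature matrix contains missing values.")
  D <- as.matrix(dist(x, method = "euclidean"))
  dimnames(D) <- list(data[[id_col]], data[[id_col]])
  D
}

#' L-infinity centrality lens
#'
#' The filter value of a subject is its maximal distance to any other
#' subject, so extremes of the lens sit at the periphery of the point cloud
#' — where topology flares end.
#'
#' @param D Symmetric distance matrix.
#' @return Named numeric vector, one value per subject.
#' @export
linf_centrality <- function(D) {
  stopifnot(is.matrix(D), nrow(D) == ncol(D))
  apply(D, 1, max)
}

#' Mapper cover configuration
#'
#' @param n_intervals Number of uniform-width lens intervals (>= 1). The
#'   default 4 keeps interval preimages at roughly 20-40 subjects for
#'   cohorts around 100-150 subjects, which the in-interval gap heuristic
#'   needs to tell genuine cluster separation from sampling noise.
#' @param overlap_frac Fraction of an interval's (final) width shared with
#'   each neighbour, in (0, 1); 0.5 is the conventional Mapper gain.
#' @param cluster_bins Histogram bin count for the single-linkage cutoff
#'   heuristic inside each interval.
#'
#' @return A `cover_config` list.
#' @export
cover_config <- function(n_intervals = 4L, overlap_frac = 0.5,
                         cluster_bins = 5L) {
  if (n_intervals < 1) abort("`n_intervals` must be >= 1.")
  if (overlap_frac <= 0 || overlap_frac >= 1) {
    abort("`overlap_frac` must lie strictly between 0 and 1.")
  }
  if (cluster_bins < 2) abort("`cluster_bins` must be >= 2.")
  structure(
    list(n_intervals = as.integer(n_intervals),
         overlap_frac = overlap_frac,
         cluster_bins = as.integer(cluster_bins)),
    class = "cover_config"
  )
}

# Single-linkage clustering of one cover interval's subjects, cut at the
# first empty bin of a histogram of merge heights (the classic Mapper
# heuristic). The histogram spans [min merge height, subset diameter] with
# the diameter included as a datum, so a split happens only when a genuine
# gap separates the within-cluster merge scale from the subset diameter;
# one cluster when the histogram has no empty bin.
cluster_interval <- function(D_sub, cluster_bins) {
  n <- nrow(D_sub)
  if (n == 1) return(setNames(1L, rownames(D_sub)))
  d <- stats::as.dist(D_sub)
  diam <- max(d)
  if (diam <= 0) return(setNames(rep(1L, n), rownames(D_sub)))
  hc <- hclust(d, method = "single")
  h <- hc$height
  if (min(h) >= diam) return(setNames(rep(1L, n), rownames(D_sub)))
  breaks <- seq(min(h), diam, length.out = cluster_bins + 1)
  counts <- graphics::hist(c(h, diam), breaks = breaks, plot = FALSE)$counts
  gap <- which(counts == 0)
  if (length(gap) == 0) return(setNames(rep(1L, n), rownames(D_sub)))
  cutoff <- (breaks[gap[1]] + breaks[gap[1] + 1]) / 2
  cutree(hc, h = cutoff)
}

#' Build the Mapper nerve graph (patient-patient network)
#'
#' Covers the lens range with `n_intervals` uniform-width intervals, each
#' widened symmetrically so adjacent intervals share `overlap_frac` of their
#' width; clusters every interval's preimage by single linkage on the
#' restricted distance matrix with a first-empty-histogram-bin cutoff; and
#' connects any two clusters that share a subject (the nerve of the cover).
#' The construction is fully deterministic.
#'
#' @param D Symmetric subject distance matrix (dimnames = subject ids).
#' @param f Lens values, one per subject, in the same order as `D`
#'   (e.g. from [linf_centrality()]).
#' @param cover A [cover_config()].
#'
#' @return An object of class `mapper_graph`: tibbles `nodes` (node id,
#'   source interval, cluster index, member subjects, size) and `edges`
#'   (endpoints plus shared-subject weight), the lens `f`, and the cover.
#' @export
#' @examples
#' cohort <- gen_clinical_cohort(cohort_presets(c(60, 30, 30)), seed = 3)
#' norm <- fit_reference_normalization(
#'   cohort, cohort$subject_id[cohort$group == "TDC"]
#' )
#' D <- euclidean_distances(normalize_features(cohort, norm))
#' g <- build_mapper(D, linf_centrality(D), cover_config())
#' g
build_mapper <- function(D, f, cover = cover_config()) {
  stopifnot(inherits(cover, "cover_config"))
  subjects <- rownames(D)
  if (is.null(subjects)) subjects <- as.character(seq_len(nrow(D)))
  if (length(f) != nrow(D)) abort("`f` and `D` must cover the same subjects.")
  if (length(f) == 0) abort("Empty input: no subjects to cover.")
  f <- setNames(as.numeric(f), subjects)

  fmin <- min(f); fmax <- max(f)
  w <- (fmax - fmin) / cover$n_intervals
  # extend each base interval so adjacent (extended) intervals share
  # overlap_frac of their own final width: e = p*w / (2*(1-p))
  half_ext <- cover$overlap_frac * w / (2 * (1 - cover$overlap_frac))

  node_rows <- list()
  for (i in seq_len(cover$n_intervals)) {
    lo <- fmin + (i - 1) * w - half_ext
    hi <- fmin + i * w + half_ext
    if (w == 0) { lo <- fmin; hi <- fmax } # degenerate constant lens
    members <- subjects[f >= lo & f <= hi]
    if (length(members) == 0) next
    cl <- cluster_interval(D[members, members, drop = FALSE], cover$cluster_bins)
    for (c_idx in sort(unique(cl))) {
      node_rows[[length(node_rows) + 1]] <- tibble(
        interval = i, cluster = as.integer(c_idx),
        subjects = list(members[cl == c_idx])
      )
    }
    if (w == 0) break
  }
  nodes <- dplyr::bind_rows(node_rows)
  nodes <- dplyr::mutate(
    nodes,
    node_id = sprintf("n%02d_%d", .data$interval, .data$cluster),
    size = lengths(.data$subjects), .before = 1
  )

  # nerve: an edge wherever two clusters share at least one subject
  edge_rows <- list()
  nn <- nrow(nodes)
  if (nn > 1) {
    for (a in seq_len(nn - 1)) {
      for (b in seq(a + 1, nn)) {
        shared <- length(intersect(nodes$subjects[[a]], nodes$subjects[[b]]))
        if (shared > 0) {
          edge_rows[[length(edge_rows) + 1]] <- tibble(
            from = nodes$node_id[a], to = nodes$node_id[b], weight = shared
          )
        }
      }
    }
  }
  edges <- if (length(edge_rows) > 0) {
    dplyr::bind_rows(edge_rows)
  } else {
    tibble(from = character(), to = character(), weight = integer())
  }

  structure(
    list(nodes = nodes, edges = edges, subjects = subjects, f = f,
         cover = cover),
    class = "mapper_graph"
  )
}

#' @export
print.mapper_graph <- function(x, ...) {
  cat("<mapper_graph>", nrow(x$nodes), "nodes,", nrow(x$edges), "edges over",
      length(x$subjects), "subjects\n")
  cat("  cover:", x$cover$n_intervals, "intervals, overlap",
      x$cover$overlap_frac, "\n")
  invisible(x)
}

# igraph view of a mapper graph (internal; isolated nodes preserved)
mapper_igraph <- function(graph) {
  igraph::graph_from_data_frame(
    graph$edges, directed = FALSE,
    vertices = data.frame(name = graph$nodes$node_id)
  )
}

#' Average a per-subject variable over each Mapper node
#'
#' Attribute mapping: each node of the patient-patient network is coloured
#' by the arithmetic mean of its member subjects' values, revealing how a
#' clinical or neuroimaging variable varies across the topology.
#'
#' @param graph A `mapper_graph`.
#' @param values Named numeric vector (names = subject ids) covering every
#'   subject in the graph.
#'
#' @return Named numeric vector of per-node means.
#' @export
map_attribute <- function(graph, values) {
  stopifnot(inherits(graph, "mapper_graph"))
  missing_ids <- setdiff(graph$subjects, names(values))
  if (length(missing_ids) > 0) {
    abort(paste0("`values` missing for subject(s): ",
                 toString(head(missing_ids, 5))))
  }
  out <- vapply(graph$nodes$subjects, function(s) mean(values[s]), numeric(1))
  setNames(out, graph$nodes$node_id)
}

#' @describeIn mapper_pipeline Tidy node table of a Mapper graph: one row
#'   per node with interval, cluster, size, member subjects (list-column),
#'   mean lens value and — when group labels were supplied — the node's
#'   majority group.
#' @export
tidy.mapper_graph <- function(x, ...) {
  nodes <- x$nodes
  nodes$mean_lens <- unname(map_attribute(x, x$f))
  if (!is.null(x$groups)) {
    nodes$majority_group <- vapply(
      nodes$subjects, function(s) majority_label(x$groups[s]), character(1)
    )
  }
  dplyr::select(nodes, "node_id", "interval", "cluster", "size",
                "mean_lens", dplyr::any_of("majority_group"), "subjects")
}

#' @describeIn mapper_pipeline One-row summary: subject, node, edge and
#'   flare counts plus the cover parameters.
#' @export
glance.mapper_graph <- function(x, ...) {
  fl <- extract_flares(x)
  tibble(
    n_subjects = length(x$subjects),
    n_nodes = nrow(x$nodes),
    n_edges = nrow(x$edges),
    n_flares = nrow(fl),
    n_intervals = x$cover$n_intervals,
    overlap_frac = x$cover$overlap_frac
  )
}

# majority vote with deterministic alphabetical tie-break
majority_label <- function(labels) {
  tab <- sort(table(labels), decreasing = TRUE)
  winners <- names(tab)[tab == tab[1]]
  sort(winners)[1]
}

#' Run the full topological subtyping pipeline on a phenotype table
#'
#' Chains the whole subject-space analysis: z-score all features against the
#' reference group, compute Euclidean subject distances, the L-infinity
#' centrality lens, and the Mapper nerve graph. Group labels travel with the
#' result so flares can be labelled by majority vote.
#'
#' @param data Phenotype data frame (one row per subject).
#' @param reference_group Group label defining the normalization reference
#'   (default `"TDC"`).
#' @param features Feature columns (default the six clinical features).
#' @param cover A [cover_config()].
#' @param id_col,group_col Subject-id and group-label columns.
#'
#' @return A `mapper_graph` with additional elements `groups` (named vector),
#'   `normalization` (the `ref_norm`) and `distances`.
#' @export
#' @examples
#' cohort <- gen_clinical_cohort(cohort_presets(c(60, 30, 30)), seed = 1)
#' g <- mapper_pipeline(cohort)
#' glance(g)
mapper_pipeline <- function(data, reference_group = "TDC",
                            features = clinical_features(),
                            cover = cover_config(),
                            id_col = "subject_id", group_col = "group") {
  ref_ids <- data[[id_col]][data[[group_col]] == reference_group]
  if (length(ref_ids) == 0) {
    abort(paste0("No subjects with ", group_col, " == '", reference_group, "'."))
  }
  norm <- fit_reference_normalization(data, ref_ids, features, id_col)
  zdata <- normalize_features(data, norm)
  D <- euclidean_distances(zdata, features, id_col)
  f <- linf_centrality(D)
  g <- build_mapper(D, f, cover)
  g$groups <- setNames(as.character(data[[group_col]]), data[[id_col]])
  g$normalization <- norm
  g$distances <- D
  g
}
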