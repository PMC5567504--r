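#' Extract flares (branches) from a Mapper graph
#'
#' Junction nodes are those with degree >= 3. Removing them splits the
#' patient-patient network into flares — the arms along which extreme lens
#' values accumulate and which act as candidate clinical subgroups. A
#' connected component containing no junction is a single flare. Each
#' flare's nodes are ordered from the junction outward (by hop distance to
#' the nearest junction in the intact graph); its member subjects are the
#' union over nodes; when group labels are available the flare is tagged
#' with its majority group.
#'
#' @param graph A `mapper_graph` (e.g. from [mapper_pipeline()]).
#' @param groups Optional named vector of subject group labels; defaults to
#'   the labels carried by the graph, if any.
#'
#' @return A tibble with one row per flare: `flare`, `n_nodes`,
#'   `n_subjects`, `majority_group` (`NA` without labels), and list-columns
#'   `nodes` (junction-outward order) and `subjects`.
#' @export
extract_flares <- function(graph, groups = graph$groups) {
  stopifnot(inherits(graph, "mapper_graph"))
  if (nrow(graph$nodes) == 0) abort("Empty Mapper graph: no nodes.")
  ig <- mapper_igraph(graph)
  deg <- igraph::degree(ig)
  junctions <- names(deg)[deg >= 3]

  pruned <- igraph::delete_vertices(ig, junctions)
  if (igraph::vcount(pruned) == 0) {
    return(tibble(
      flare = integer(), n_nodes = integer(), n_subjects = integer(),
      majority_group = character(), nodes = list(), subjects = list()
    ))
  }
  comp <- igraph::components(pruned)
  membership <- comp$membership

  # hop distance to the nearest junction in the intact graph orders each
  # flare's nodes junction-outward; without junctions fall back to lens order
  if (length(junctions) > 0) {
    dmat <- igraph::distances(ig, v = igraph::V(ig), to = junctions)
    near_junction <- apply(dmat, 1, min)
  } else {
    near_junction <- NULL
  }

  node_subjects <- setNames(graph$nodes$subjects, graph$nodes$node_id)
  node_lens <- map_attribute(graph, graph$f)

  rows <- lapply(seq_len(comp$no), function(k) {
    ids <- names(membership)[membership == k]
    key <- if (is.null(near_junction)) node_lens[ids] else near_junction[ids]
    ids <- ids[order(key, ids)]
    members <- sort(unique(unlist(node_subjects[ids])))
    tibble(
      flare = k,
      n_nodes = length(ids),
      n_subjects = length(members),
      majority_group = if (is.null(groups)) {
        NA_character_
      } else {
        majority_label(groups[members])
      },
      nodes = list(ids),
      subjects = list(members)
    )
  })
  dplyr::bind_rows(rows)
}

#' Select the peripheral subjects of a flare
#'
#' Ranks a flare's member subjects by lens value (L-infinity centrality) and
#' returns the `k` most extreme — the subjects lying farthest out on the
#' branch, used for quantitative subgroup comparisons. Each subject counts
#' once even when it belongs to several nodes; ties are broken by subject id.
#'
#' @param flare A character vector of member subject ids, or one row of the
#'   [extract_flares()] table.
#' @param f Named lens vector covering the members.
#' @param k Number of subjects to select (default 15, the published choice).
#'
#' @return Character vector of subject ids, ordered most-extreme first. If
#'   the flare has fewer than `k` members, all are returned with a warning.
#' @export
select_peripheral <- function(flare, f, k = 15L) {
  if (k < 1) abort("`k` must be >= 1.")
  members <- if (is.data.frame(flare)) flare$subjects[[1]] else as.character(flare)
  members <- unique(members)
  missing_f <- setdiff(members, names(f))
  if (length(missing_f) > 0) {
    abort(paste0("Lens values missing for: ", toString(head(missing_f, 5))))
  }
  ranked <- members[order(-f[members], members)]
  if (length(ranked) < k) {
    warn(paste0("Flare has only ", length(ranked), " members; returning all."))
    return(ranked)
  }
  ranked[seq_len(k)]
}

#' Peripheral-subject selections for every flare
#'
#' Convenience wrapper applying [select_peripheral()] to each row of an
#' [extract_flares()] table with the graph's own lens.
#'
#' @param graph A `mapper_graph` carrying group labels.
#' @param k Subjects per flare (default 15).
#'
#' @return Tibble with columns `flare`, `majority_group`, `subject_id`,
#'   `rank` and `lens`.
#' @export
peripheral_subjects <- function(graph, k = 15L) {
  fl <- extract_flares(graph)
  purrr::pmap_dfr(
    list(fl$flare, fl$majority_group, fl$subjects),
    function(flare, maj, members) {
      sel <- select_peripheral(members, graph$f, k)
      tibble(
        flare = flare, majority_group = maj, subject_id = sel,
        rank = seq_along(sel), lens = unname(graph$f[sel])
      )
    }
  )
}
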