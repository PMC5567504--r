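#' Module-resolved functional connectivity density (FCD)
#'
#' Summarizes a signed connectivity matrix against a module partition:
#' intra-module FCD of module `c` is the mean correlation over unordered ROI
#' pairs inside `c`; inter-module FCD of pair `(c, d)` is the mean over all
#' cross pairs. FCD deliberately uses signed correlations (inter-module
#' densities are often negative), unlike the positive-weight graphs feeding
#' centralities and modularity.
#'
#' @param R Signed ROI x ROI correlation matrix.
#' @param assignment Module labels, one per ROI — a vector (aligned by name
#'   to `R`'s columns when both are named) or a `module_partition`. Module
#'   order in the output follows the order of first appearance.
#'
#' @return One-row tibble with columns `intra_<module>` and
#'   `inter_<module>_<module>`. A module of size 1 has no internal pair and
#'   its intra value is `NA`.
#' @export
#' @examples
#' spec <- modular_series_spec(c(A = 4, B = 3), intra_r = 0.3, inter_r = -0.1,
#'                             n_frames = 200)
#' tc <- gen_modular_timeseries(spec, seed = 1)
#' fcd(correlation_network(tc), attr(tc, "modules"))
fcd <- function(R, assignment) {
  stopifnot(is.matrix(R), nrow(R) == ncol(R))
  if (inherits(assignment, "module_partition")) {
    assignment <- assignment$assignment
  }
  if (length(assignment) != nrow(R)) {
    abort("`assignment` must cover every ROI exactly once.")
  }
  if (!is.null(names(assignment)) && !is.null(colnames(R))) {
    if (!setequal(names(assignment), colnames(R))) {
      abort("`assignment` names do not match the ROI names of `R`.")
    }
    assignment <- assignment[colnames(R)]
  }
  mods <- unique(assignment)
  out <- list()
  for (a in seq_along(mods)) {
    ia <- which(assignment == mods[a])
    out[[paste0("intra_", mods[a])]] <- if (length(ia) < 2) {
      NA_real_
    } else {
      block <- R[ia, ia]
      mean(block[upper.tri(block)])
    }
  }
  if (length(mods) > 1) {
    for (a in seq_len(length(mods) - 1)) {
      for (b in seq(a + 1, length(mods))) {
        ia <- which(assignment == mods[a])
        ib <- which(assignment == mods[b])
        out[[paste0("inter_", mods[a], "_", mods[b])]] <- mean(R[ia, ib])
      }
    }
  }
  as_tibble(out)
}

#' Per-subject FCD table
#'
#' Applies [fcd()] with one fixed reference partition (typically the
#' consensus partition of a chosen group's mean network) to every subject's
#' signed connectivity matrix.
#'
#' @param networks Named list of per-subject signed correlation matrices.
#' @param assignment Reference module assignment (vector or
#'   `module_partition`).
#'
#' @return Tibble with `subject_id` plus one column per intra-/inter-module
#'   measure.
#' @export
fcd_table <- function(networks, assignment) {
  if (is.null(names(networks))) {
    names(networks) <- sprintf("sub-%03d", seq_along(networks))
  }
  purrr::imap_dfr(networks, function(R, id) {
    dplyr::bind_cols(tibble(subject_id = id), fcd(R, assignment))
  })
}
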