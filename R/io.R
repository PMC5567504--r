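#' Read and write the pipeline's plain-text interchange formats
#'
#' Phenotype tables travel as CSV (columns `subject_id`, `group`, the six
#' clinical features, `age`); ROI time courses as TSV with a header row of
#' ROI names; framewise displacement as one value per line; connectivity
#' matrices as CSV with ROI names in the header row and first column.
#'
#' @param data,mat,fd,R Object to write.
#' @param path File path.
#' @return Readers return a tibble ([read_phenotype_csv()]), a frames x ROI
#'   matrix ([read_timecourse_tsv()]), a numeric vector ([read_fd()]) or an
#'   ROI x ROI matrix ([read_connectivity_csv()]); writers return `path`
#'   invisibly.
#' @name pipeline_io
NULL

#' @rdname pipeline_io
#' @export
write_phenotype_csv <- function(data, path) {
  readr::write_csv(data, path)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_phenotype_csv <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    subject_id = readr::col_character(),
    group = readr::col_character(),
    .default = readr::col_double()
  ))
}

#' @rdname pipeline_io
#' @export
write_timecourse_tsv <- function(mat, path) {
  df <- as.data.frame(mat)
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_timecourse_tsv <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_double()))
  as.matrix(df)
}

#' @rdname pipeline_io
#' @export
write_fd <- function(fd, path) {
  writeLines(format(fd, trim = TRUE, scientific = FALSE), path)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_fd <- function(path) {
  as.numeric(readLines(path))
}

#' @rdname pipeline_io
#' @export
write_connectivity_csv <- function(R, path) {
  df <- as.data.frame(R)
  df <- cbind(roi = rownames(R), df)
  readr::write_csv(df, path)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_connectivity_csv <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    roi = readr::col_character(), .default = readr::col_double()
  ))
  m <- as.matrix(df[, -1])
  rownames(m) <- df$roi
  m
}

#' Read one subject's time course and motion series
#'
#' @param tc_path TSV time-course file (header = ROI names).
#' @param fd_path Plain-text FD file, one value per frame.
#' @return A [time_course()].
#' @export
read_subject_timecourse <- function(tc_path, fd_path) {
  time_course(read_timecourse_tsv(tc_path), read_fd(fd_path))
}

#' Export a Mapper graph to GraphML and JSON
#'
#' Node attributes written: `size`, `interval`, `members` (subject ids
#' joined by `";"`), the mean lens value, and any extra per-subject
#' variables supplied via `attributes` (stored as node means). The JSON
#' mirror holds the same nodes and edges as plain arrays.
#'
#' @param graph A `mapper_graph`.
#' @param path Output file path.
#' @param attributes Optional named list of per-subject named vectors to map
#'   onto nodes via [map_attribute()].
#' @return `path`, invisibly.
#' @export
write_mapper_graphml <- function(graph, path, attributes = NULL) {
  stopifnot(inherits(graph, "mapper_graph"))
  ig <- mapper_igraph(graph)
  igraph::V(ig)$size <- graph$nodes$size
  igraph::V(ig)$interval <- graph$nodes$interval
  igraph::V(ig)$members <- vapply(graph$nodes$subjects, paste, character(1),
                                  collapse = ";")
  igraph::V(ig)$mean_lens <- unname(map_attribute(graph, graph$f))
  for (nm in names(attributes)) {
    ig <- igraph::set_vertex_attr(
      ig, nm, value = unname(map_attribute(graph, attributes[[nm]]))
    )
  }
  igraph::write_graph(ig, path, format = "graphml")
  invisible(path)
}

#' @rdname write_mapper_graphml
#' @export
write_mapper_json <- function(graph, path, attributes = NULL) {
  stopifnot(inherits(graph, "mapper_graph"))
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    abort("write_mapper_json() needs the jsonlite package.")
  }
  nodes <- tidy(graph)
  for (nm in names(attributes)) {
    nodes[[nm]] <- unname(map_attribute(graph, attributes[[nm]]))
  }
  payload <- list(
    cover = unclass(graph$cover),
    nodes = nodes,
    edges = graph$edges
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write flare membership and peripheral selections as CSV
#'
#' @param graph A `mapper_graph` with group labels.
#' @param dir Output directory (created if needed).
#' @param k Peripheral subjects per flare.
#' @return Paths of the two files written, invisibly.
#' @export
write_flare_csvs <- function(graph, dir, k = 15L) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fl <- extract_flares(graph)
  members <- tidyr::unnest(
    dplyr::select(fl, "flare", "majority_group", "subjects"),
    "subjects"
  )
  names(members)[names(members) == "subjects"] <- "subject_id"
  p1 <- file.path(dir, "flare_membership.csv")
  readr::write_csv(members, p1)
  p2 <- file.path(dir, "peripheral_subjects.csv")
  readr::write_csv(peripheral_subjects(graph, k), p2)
  invisible(c(p1, p2))
}
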