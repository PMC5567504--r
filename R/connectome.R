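#' Bundle ROI time courses with framewise displacement
#'
#' @param data Frames x ROI numeric matrix (column names = ROI labels).
#' @param fd Per-frame framewise displacement in mm; length must equal the
#'   frame count.
#'
#' @return An object of class `time_course`.
#' @export
time_course <- function(data, fd) {
  data <- as.matrix(data)
  if (length(fd) != nrow(data)) {
    abort(paste0("`fd` length (", length(fd), ") must equal frame count (",
                 nrow(data), ")."))
  }
  if (is.null(colnames(data))) {
    colnames(data) <- sprintf("ROI_%03d", seq_len(ncol(data)))
  }
  structure(list(data = data, fd = as.numeric(fd)), class = "time_course")
}

#' @export
print.time_course <- function(x, ...) {
  cat("<time_course>", nrow(x$data), "frames x", ncol(x$data), "ROIs; max FD",
      signif(max(x$fd), 3), "mm\n")
  invisible(x)
}

#' Scrub high-motion frames
#'
#' Removes exactly the frames whose framewise displacement exceeds the
#' threshold (strictly greater than; frames at exactly the threshold are
#' kept, and no neighbouring frames are deleted). The FD vector is subset
#' alongside the data, so scrubbing is idempotent at a fixed threshold.
#'
#' @param tc A [time_course()].
#' @param threshold Scrub threshold in mm (default 1).
#'
#' @return The scrubbed `time_course`.
#' @export
#' @examples
#' tc <- time_course(matrix(rnorm(30), 10, 3), fd = c(0:8 / 10, 1.5))
#' nrow(scrub(tc)$data)
scrub <- function(tc, threshold = 1) {
  stopifnot(inherits(tc, "time_course"))
  if (threshold <= 0) abort("`threshold` must be > 0.")
  keep <- tc$fd <= threshold
  if (sum(keep) < 2) {
    abort(paste0("Only ", sum(keep), " frame(s) survive scrubbing at ",
                 threshold, " mm; correlations are undefined."))
  }
  time_course(tc$data[keep, , drop = FALSE], tc$fd[keep])
}

#' Pearson functional connectivity matrix
#'
#' @param tc A [time_course()] (scrub first) or a plain frames x ROI matrix.
#'
#' @return Symmetric ROI x ROI correlation matrix with unit diagonal.
#' @export
correlation_network <- function(tc) {
  x <- if (inherits(tc, "time_course")) tc$data else as.matrix(tc)
  if (nrow(x) < 2) abort("Need at least 2 frames for correlations.")
  v <- apply(x, 2, var)
  if (any(v <= 0)) {
    abort(paste0("Zero-variance ROI(s): ",
                 toString(head(colnames(x)[v <= 0], 5)),
                 "; correlation is undefined."))
  }
  R <- cor(x)
  diag(R) <- 1
  R
}

#' Positive-weight adjacency from a connectivity matrix
#'
#' Graph analyses (centralities, modularity) use only positive edge weights:
#' negative off-diagonal correlations are set to zero and the diagonal
#' (self-loops) is removed. Signed correlations remain available for
#' connectivity-density summaries via the original matrix.
#'
#' @param R Symmetric correlation matrix.
#' @return Non-negative adjacency matrix with zero diagonal.
#' @export
positive_graph <- function(R) {
  stopifnot(is.matrix(R), nrow(R) == ncol(R))
  A <- pmax(R, 0)
  diag(A) <- 0
  A
}

#' Group-representative connectivity matrix
#'
#' Elementwise arithmetic mean of per-subject correlation matrices on the
#' raw r scale (set `fisher = TRUE` to average on the Fisher-z scale and
#' back-transform). Averaging precedes any positive-weight thresholding.
#'
#' @param matrices List of ROI x ROI correlation matrices over an identical
#'   ROI set.
#' @param fisher Average in Fisher-z space instead of raw r (default FALSE).
#'
#' @return ROI x ROI matrix.
#' @export
group_mean_network <- function(matrices, fisher = FALSE) {
  stopifnot(is.list(matrices), length(matrices) >= 1)
  ref <- matrices[[1]]
  same <- vapply(matrices, function(m) {
    identical(dim(m), dim(ref)) && identical(colnames(m), colnames(ref))
  }, logical(1))
  if (!all(same)) abort("All matrices must share one ROI set (names and order).")
  if (fisher) {
    z <- Reduce(`+`, lapply(matrices, atanh)) / length(matrices)
    out <- tanh(z)
    diag(out) <- 1
    return(out)
  }
  Reduce(`+`, matrices) / length(matrices)
}

#' Power-style framewise displacement from realignment parameters
#'
#' Optional helper for users holding 6-parameter rigid-body motion estimates
#' rather than precomputed FD: the sum of absolute frame-to-frame changes of
#' the three translations (mm) plus the three rotations (radians) converted
#' to arc length on a `radius`-mm sphere. The first frame has FD 0.
#'
#' @param params Frames x 6 matrix: translations x, y, z (mm) then rotations
#'   pitch, roll, yaw (radians).
#' @param radius Head radius in mm (default 50).
#'
#' @return Numeric FD vector, one value per frame.
#' @export
fd_power <- function(params, radius = 50) {
  params <- as.matrix(params)
  if (ncol(params) != 6) abort("`params` must have 6 columns (3 translations, 3 rotations).")
  d <- abs(diff(params))
  d[, 4:6] <- d[, 4:6] * radius
  c(0, rowSums(d))
}
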