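#' Specify a modular block-correlation time-series generator
#'
#' Describes ROI time courses organised into functional modules: every ROI
#' pair within module `k` has correlation `intra_r[k]`, every pair spanning
#' modules `k` and `l` has the corresponding `inter_r` entry. Frames are
#' i.i.d. multivariate-normal draws from this block correlation matrix —
#' no haemodynamics or temporal autocorrelation are emulated.
#'
#' @param module_sizes Named or unnamed integer vector of ROI counts per
#'   module (names become module labels; unnamed modules are labelled
#'   `M1, M2, ...`).
#' @param intra_r Within-module correlation target(s): scalar or one value
#'   per module, each with absolute value < 1.
#' @param inter_r Between-module correlation target(s): scalar, or one value
#'   per unordered module pair in the order (1,2), (1,3), ..., (2,3), ...,
#'   or a full symmetric k x k matrix.
#' @param n_frames Number of time points (>= 2). Default 232 frames, a
#'   typical preprocessed resting-state run length.
#' @param noise_sd Marginal SD of every ROI series (amplitude scale only;
#'   correlations are untouched).
#'
#' @return An object of class `modular_series_spec`. Construction fails if
#'   the implied block correlation matrix is not positive semi-definite.
#' @seealso [gen_modular_timeseries()], [module_membership()]
#' @export
#' @examples
#' modular_series_spec(c(DMN = 20, VN = 15), intra_r = c(0.34, 0.28),
#'                     inter_r = 0.0, n_frames = 200)
modular_series_spec <- function(module_sizes, intra_r, inter_r,
                                n_frames = 232L, noise_sd = 1) {
  k <- length(module_sizes)
  if (k < 1 || any(module_sizes < 1)) abort("`module_sizes` must be positive counts.")
  if (n_frames < 2) abort("`n_frames` must be >= 2 (one frame defines no correlation).")
  if (noise_sd <= 0) abort("`noise_sd` must be > 0.")
  labels <- names(module_sizes)
  if (is.null(labels)) labels <- paste0("M", seq_len(k))
  intra_r <- rep_len(intra_r, k)
  if (any(abs(intra_r) >= 1)) abort("All `intra_r` must satisfy |r| < 1.")

  n_pairs <- k * (k - 1) / 2
  if (is.matrix(inter_r)) {
    if (!isTRUE(all.equal(inter_r, t(inter_r))) || nrow(inter_r) != k) {
      abort("`inter_r` matrix must be symmetric k x k.")
    }
    inter <- inter_r
  } else {
    vals <- if (length(inter_r) == 1) rep(inter_r, n_pairs) else inter_r
    if (length(vals) != n_pairs) {
      abort(paste0("`inter_r` must be scalar or length ", n_pairs, " (one per module pair)."))
    }
    inter <- matrix(0, k, k)
    inter[lower.tri(inter)] <- NA # fill upper then mirror
    idx <- 1L
    for (a in seq_len(k - 1)) {
      for (b in seq(a + 1, k)) {
        inter[a, b] <- vals[idx]
        inter[b, a] <- vals[idx]
        idx <- idx + 1L
      }
    }
  }
  if (any(abs(inter[upper.tri(inter)]) >= 1)) abort("All `inter_r` must satisfy |r| < 1.")

  # Assemble the full ROI x ROI correlation matrix and validate PSD once.
  assignment <- rep(labels, times = module_sizes)
  p <- length(assignment)
  C <- matrix(0, p, p)
  for (a in seq_len(k)) {
    ia <- which(assignment == labels[a])
    C[ia, ia] <- intra_r[a]
    if (a < k) {
      for (b in seq(a + 1, k)) {
        ib <- which(assignment == labels[b])
        C[ia, ib] <- inter[a, b]
        C[ib, ia] <- inter[a, b]
      }
    }
  }
  diag(C) <- 1
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) {
    worst <- which.min(intra_r)
    abort(paste0(
      "Implied block correlation matrix is not positive semi-definite ",
      "(min eigenvalue ", signif(min(ev), 3), "); revisit the intra/inter ",
      "targets (e.g. module '", labels[worst], "' and its neighbours)."
    ))
  }

  structure(
    list(
      module_sizes = setNames(as.integer(module_sizes), labels),
      labels = labels, intra_r = intra_r, inter_r = inter,
      n_frames = as.integer(n_frames), noise_sd = noise_sd,
      assignment = assignment, correlation = C
    ),
    class = "modular_series_spec"
  )
}

#' @export
print.modular_series_spec <- function(x, ...) {
  cat("<modular_series_spec>", sum(x$module_sizes), "ROIs in",
      length(x$labels), "modules;", x$n_frames, "frames\n")
  invisible(x)
}

#' Simulate ROI time courses with a planted modular correlation structure
#'
#' @param spec A [modular_series_spec()].
#' @param seed Integer seed; identical seed and spec give bit-identical
#'   output. The caller's RNG state is left untouched.
#'
#' @return A numeric matrix, frames in rows and ROIs in columns. Column
#'   names are `<module>_<index>`; the planted module assignment is attached
#'   as attribute `"modules"`.
#' @export
#' @examples
#' spec <- modular_series_spec(c(A = 4, B = 4), intra_r = 0.4, inter_r = 0,
#'                             n_frames = 100)
#' tc <- gen_modular_timeseries(spec, seed = 7)
#' dim(tc)
gen_modular_timeseries <- function(spec, seed) {
  stopifnot(inherits(spec, "modular_series_spec"))
  p <- sum(spec$module_sizes)
  # pivoted Cholesky tolerates the PSD-but-singular case (e.g. intra_r -> 1)
  ch <- suppressWarnings(chol(spec$correlation, pivot = TRUE))
  piv <- attr(ch, "pivot")
  r <- attr(ch, "rank")
  L <- ch[seq_len(r), order(piv), drop = FALSE]
  x <- local_seed(seed, matrix(rnorm(spec$n_frames * r), spec$n_frames, r)) %*% L
  x <- x * spec$noise_sd
  colnames(x) <- unlist(lapply(
    seq_along(spec$labels),
    function(a) sprintf("%s_%02d", spec$labels[a], seq_len(spec$module_sizes[a]))
  ))
  attr(x, "modules") <- setNames(spec$assignment, colnames(x))
  x
}

#' Add motion spikes to a time-course matrix
#'
#' Frames whose framewise displacement (FD) exceeds `threshold` receive
#' additive Gaussian spike noise, emulating residual head-motion artefact
#' that downstream scrubbing should remove. The FD profile is passed through
#' unchanged so the scrub stage can consume it.
#'
#' @param series Frames x ROI matrix.
#' @param fd_profile Numeric vector of per-frame FD values (mm); must match
#'   the frame count.
#' @param threshold FD above which a frame is spiked (default 1 mm, the
#'   scrubbing threshold).
#' @param spike_sd SD of the additive spike noise (default 5).
#' @param seed Optional seed for the spike noise; `NULL` uses the current
#'   RNG stream.
#'
#' @return A list with elements `data` (the spiked matrix) and `fd`
#'   (the FD vector).
#' @export
inject_motion <- function(series, fd_profile, threshold = 1, spike_sd = 5,
                          seed = NULL) {
  if (length(fd_profile) != nrow(series)) {
    abort(paste0(
      "`fd_profile` length (", length(fd_profile),
      ") must equal the frame count (", nrow(series), ")."
    ))
  }
  bad <- which(fd_profile > threshold)
  if (length(bad) > 0) {
    add_spikes <- function() {
      series[bad, ] <- series[bad, ] +
        matrix(rnorm(length(bad) * ncol(series), sd = spike_sd),
               length(bad), ncol(series))
      series
    }
    series <- if (is.null(seed)) add_spikes() else local_seed(seed, add_spikes())
  }
  list(data = series, fd = as.numeric(fd_profile))
}

#' Synthetic five-network module membership table
#'
#' A constructed assignment of 90 ROIs to five canonical resting-state
#' modules — default mode (DMN, 20 ROIs), executive control (ECN, 20),
#' salience (SN, 15), visual (VN, 15) and basal ganglia (BGN, 20) networks.
#' The ROI labels are generic placeholders, not an anatomical atlas lookup:
#' the table exists so simulations and examples share one fixed, documented
#' modular layout.
#'
#' @return A tibble with columns `roi` and `module`.
#' @export
#' @examples
#' dplyr::count(module_membership(), module)
module_membership <- function() {
  path <- system.file("extdata", "module_membership_synthetic.csv",
                      package = "topophen", mustWork = TRUE)
  readr::read_csv(path, col_types = readr::cols(
    roi = readr::col_character(), module = readr::col_character()
  ))
}

#' Module sizes of the synthetic five-network layout
#'
#' Convenience wrapper over [module_membership()] returning the named size
#' vector expected by [modular_series_spec()].
#'
#' @return Named integer vector (DMN, ECN, SN, VN, BGN order).
#' @export
default_module_sizes <- function() {
  mm <- module_membership()
  counts <- table(mm$module)
  order <- c("DMN", "ECN", "SN", "VN", "BGN")
  setNames(as.integer(counts[order]), order)
}
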