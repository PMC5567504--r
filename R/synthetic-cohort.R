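#' Define a clinical group for cohort simulation
#'
#' A group specification is one row of a tidy table: a label, a subject
#' count, and mean/SD pairs for the six clinical features (ADHD index,
#' inattentive score, hyperactive/impulsive score, full-scale IQ, verbal IQ,
#' performance IQ) plus age. The ADHD index is constrained to be the exact
#' sum of the two symptom subscales, so its mean must equal
#' `inattentive_mean + hyper_impulsive_mean` (a small allowance is made for
#' published values rounded to one decimal) and its SD is implied by the
#' subscale SDs and their correlation rather than specified directly.
#'
#' @param label Group name (e.g. `"TDC"`).
#' @param n Number of subjects (>= 1).
#' @param adhd_index_mean,inattentive_mean,hyper_impulsive_mean Symptom means.
#' @param fsiq_mean,viq_mean,piq_mean IQ means.
#' @param inattentive_sd,hyper_impulsive_sd,fsiq_sd,viq_sd,piq_sd
#'   Non-negative SDs for the five independently generated features.
#' @param age_mean,age_sd Age distribution in years.
#'
#' @return A one-row tibble; bind rows of several calls to describe a cohort.
#' @seealso [cohort_presets()] for the published three-group presets,
#'   [gen_clinical_cohort()] to simulate from a specification.
#' @export
#' @examples
#' group_spec("TDC", 15,
#'   adhd_index_mean = 22.4, inattentive_mean = 11.6, hyper_impulsive_mean = 10.8,
#'   fsiq_mean = 123, viq_mean = 125.8, piq_mean = 114.8,
#'   inattentive_sd = 1.9, hyper_impulsive_sd = 2.1,
#'   fsiq_sd = 15, viq_sd = 14.3, piq_sd = 15.1,
#'   age_mean = 12.3, age_sd = 1.6
#' )
group_spec <- function(label, n,
                       adhd_index_mean, inattentive_mean, hyper_impulsive_mean,
                       fsiq_mean, viq_mean, piq_mean,
                       inattentive_sd, hyper_impulsive_sd,
                       fsiq_sd, viq_sd, piq_sd,
                       age_mean, age_sd) {
  if (n < 1) abort("`n` must be >= 1.")
  sds <- c(inattentive_sd, hyper_impulsive_sd, fsiq_sd, viq_sd, piq_sd, age_sd)
  if (any(sds < 0)) abort("All SDs must be >= 0.")
  if (abs(adhd_index_mean - (inattentive_mean + hyper_impulsive_mean)) > 0.15) {
    abort(paste0(
      "`adhd_index_mean` (", adhd_index_mean, ") must equal ",
      "`inattentive_mean + hyper_impulsive_mean` (",
      inattentive_mean + hyper_impulsive_mean,
      "): the ADHD index is generated as the exact subscale sum."
    ))
  }
  tibble(
    label = as.character(label), n = as.integer(n),
    adhd_index_mean = adhd_index_mean,
    inattentive_mean = inattentive_mean,
    hyper_impulsive_mean = hyper_impulsive_mean,
    fsiq_mean = fsiq_mean, viq_mean = viq_mean, piq_mean = piq_mean,
    inattentive_sd = inattentive_sd, hyper_impulsive_sd = hyper_impulsive_sd,
    fsiq_sd = fsiq_sd, viq_sd = viq_sd, piq_sd = piq_sd,
    age_mean = age_mean, age_sd = age_sd
  )
}

#' Published three-group clinical presets
#'
#' Group means and SDs for typically developing controls (TDC) and the mild-
#' and severe-symptom ADHD subgroups (mADHD, sADHD), as published for three
#' 15-subject peripheral selections: ADHD index
#' 22.4/44.1/63.3, inattentive 11.6/26.1/32.1, hyperactive/impulsive
#' 10.8/18.1/31.2, FSIQ 123.0/102.9/104.9, VIQ 125.8/107.9/110.7,
#' PIQ 114.8/96.7/96.8, age 12.3/13.1/11.9.
#'
#' @param n Subject counts, length 3 (TDC, mADHD, sADHD). Defaults to the
#'   published 15 per group; use e.g. `c(60, 30, 30)` for topology-recovery
#'   simulations.
#'
#' @return A three-row group-specification tibble (see [group_spec()]).
#' @export
#' @examples
#' cohort_presets()
#' cohort_presets(n = c(60, 30, 30))
cohort_presets <- function(n = c(15L, 15L, 15L)) {
  stopifnot(length(n) == 3)
  dplyr::bind_rows(
    group_spec("TDC", n[1],
      adhd_index_mean = 22.4, inattentive_mean = 11.6, hyper_impulsive_mean = 10.8,
      fsiq_mean = 123.0, viq_mean = 125.8, piq_mean = 114.8,
      inattentive_sd = 1.9, hyper_impulsive_sd = 2.1,
      fsiq_sd = 15.0, viq_sd = 14.3, piq_sd = 15.1,
      age_mean = 12.3, age_sd = 1.6
    ),
    group_spec("mADHD", n[2],
      adhd_index_mean = 44.1, inattentive_mean = 26.1, hyper_impulsive_mean = 18.1,
      fsiq_mean = 102.9, viq_mean = 107.9, piq_mean = 96.7,
      inattentive_sd = 2.7, hyper_impulsive_sd = 2.5,
      fsiq_sd = 8.0, viq_sd = 10.9, piq_sd = 10.2,
      age_mean = 13.1, age_sd = 1.4
    ),
    group_spec("sADHD", n[3],
      adhd_index_mean = 63.3, inattentive_mean = 32.1, hyper_impulsive_mean = 31.2,
      fsiq_mean = 104.9, viq_mean = 110.7, piq_mean = 96.8,
      inattentive_sd = 2.2, hyper_impulsive_sd = 2.9,
      fsiq_sd = 13.9, viq_sd = 20.1, piq_sd = 12.4,
      age_mean = 11.9, age_sd = 1.6
    )
  )
}

# Run code with a fixed seed without disturbing the caller's RNG stream.
local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}

# Within-group correlation matrix over the five generated features
# (inattentive, hyper_impulsive, fsiq, viq, piq): symptom subscales share
# `symptom_cor`, IQ subscales share `iq_cor`, the two blocks are independent.
feature_cor_matrix <- function(symptom_cor, iq_cor) {
  check_block <- function(r, size, name) {
    block <- matrix(r, size, size)
    diag(block) <- 1
    if (min(eigen(block, symmetric = TRUE, only.values = TRUE)$values) < -1e-10) {
      abort(paste0(
        "Configured correlation ", r, " makes the ", name,
        " block non-positive-semi-definite."
      ))
    }
    block
  }
  sym <- check_block(symptom_cor, 2, "symptom")
  iq <- check_block(iq_cor, 3, "IQ")
  R <- diag(5)
  R[1:2, 1:2] <- sym
  R[3:5, 3:5] <- iq
  R
}

#' Simulate a clinical cohort with known group structure
#'
#' Draws, for each group in `specs`, a multivariate-normal sample of the five
#' free clinical features (inattentive, hyperactive/impulsive, FSIQ, VIQ,
#' PIQ) with the configured within-group correlations, then sets the ADHD
#' index to the exact sum of the two symptom subscales — the arithmetic
#' identity the published group means satisfy. Ages are drawn independently.
#'
#' @param specs Group-specification tibble, e.g. from [cohort_presets()] or
#'   rows of [group_spec()].
#' @param seed Integer seed; identical seed and specs give bit-identical
#'   cohorts. The caller's RNG state is left untouched.
#' @param symptom_cor Correlation between the two symptom subscales
#'   (default 0.5).
#' @param iq_cor Common correlation among the three IQ scores (default 0.6).
#'
#' @return A tibble with one row per subject: `subject_id`, `group`,
#'   the six clinical features, and `age`.
#' @export
#' @examples
#' cohort <- gen_clinical_cohort(cohort_presets(), seed = 1)
#' dplyr::count(cohort, group)
gen_clinical_cohort <- function(specs, seed, symptom_cor = 0.5, iq_cor = 0.6) {
  if (!is.data.frame(specs) || nrow(specs) == 0) {
    abort("`specs` must be a non-empty group-specification data frame.")
  }
  R <- feature_cor_matrix(symptom_cor, iq_cor)
  L <- chol(R)
  local_seed(seed, {
    rows <- purrr::pmap(specs, function(label, n, ...) {
      s <- list(...)
      z <- matrix(rnorm(n * 5), n, 5) %*% L
      means <- c(
        s$inattentive_mean, s$hyper_impulsive_mean,
        s$fsiq_mean, s$viq_mean, s$piq_mean
      )
      sds <- c(
        s$inattentive_sd, s$hyper_impulsive_sd,
        s$fsiq_sd, s$viq_sd, s$piq_sd
      )
      x <- sweep(sweep(z, 2, sds, `*`), 2, means, `+`)
      tibble(
        group = label,
        adhd_index = x[, 1] + x[, 2],
        inattentive = x[, 1],
        hyper_impulsive = x[, 2],
        fsiq = x[, 3], viq = x[, 4], piq = x[, 5],
        age = rnorm(n, s$age_mean, s$age_sd)
      )
    })
    cohort <- dplyr::bind_rows(rows)
    cohort <- dplyr::mutate(
      cohort,
      subject_id = sprintf("sub-%03d", dplyr::row_number()),
      .before = 1
    )
    cohort
  })
}
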