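test_that("cohort generator is deterministic and matches the preset layout", {
  specs <- cohort_presets()
  a <- gen_clinical_cohort(specs, seed = 11)
  b <- gen_clinical_cohort(specs, seed = 11)
  expect_identical(a, b)
  expect_false(identical(a, gen_clinical_cohort(specs, seed = 12)))

  expect_equal(nrow(a), 45)
  expect_setequal(unique(a$group), c("TDC", "mADHD", "sADHD"))
  expect_true(all(clinical_features() %in% names(a)))
  expect_equal(a$adhd_index, a$inattentive + a$hyper_impulsive)
})

test_that("zero-SD groups collapse onto their means with the exact symptom identity", {
  spec <- group_spec("G", 8,
    adhd_index_mean = 30, inattentive_mean = 18, hyper_impulsive_mean = 12,
    fsiq_mean = 100, viq_mean = 105, piq_mean = 95,
    inattentive_sd = 0, hyper_impulsive_sd = 0,
    fsiq_sd = 0, viq_sd = 0, piq_sd = 0,
    age_mean = 10, age_sd = 0
  )
  co <- gen_clinical_cohort(spec, seed = 1)
  expect_equal(co$inattentive, rep(18, 8))
  expect_equal(co$fsiq, rep(100, 8))
  expect_equal(co$adhd_index, co$inattentive + co$hyper_impulsive)
  expect_equal(co$adhd_index, rep(30, 8))
})

test_that("large-sample cohort recovers the specified means and SDs", {
  specs <- cohort_presets(n = rep(2000L, 3))
  co <- gen_clinical_cohort(specs, seed = 42)
  free <- c("inattentive", "hyper_impulsive", "fsiq", "viq", "piq")
  for (g in seq_len(3)) {
    rows <- co[co$group == specs$label[g], ]
    for (feat in free) {
      mu <- specs[[paste0(feat, "_mean")]][g]
      sdv <- specs[[paste0(feat, "_sd")]][g]
      se <- sdv / sqrt(2000)
      expect_lt(abs(mean(rows[[feat]]) - mu), 3 * se)
      # SD of the sample SD ~ sd / sqrt(2(n-1)) for normal data
      expect_lt(abs(sd(rows[[feat]]) - sdv), 3 * sdv / sqrt(2 * 1999))
    }
    # the index mean follows from the identity
    expect_lt(
      abs(mean(rows$adhd_index) - specs$adhd_index_mean[g]),
      3 * sqrt(specs$inattentive_sd[g]^2 + specs$hyper_impulsive_sd[g]^2 +
                 specs$inattentive_sd[g] * specs$hyper_impulsive_sd[g]) / sqrt(2000)
    )
  }
})

test_that("invalid group specs and correlations are rejected", {
  expect_error(
    group_spec("G", 3,
      adhd_index_mean = 50, inattentive_mean = 18, hyper_impulsive_mean = 12,
      fsiq_mean = 100, viq_mean = 105, piq_mean = 95,
      inattentive_sd = 2, hyper_impulsive_sd = 2,
      fsiq_sd = 10, viq_sd = 10, piq_sd = 10,
      age_mean = 10, age_sd = 1
    ),
    "exact subscale sum"
  )
  expect_error(
    gen_clinical_cohort(cohort_presets(), seed = 1, iq_cor = -0.9),
    "IQ block"
  )
  expect_error(
    gen_clinical_cohort(cohort_presets(), seed = 1, symptom_cor = 1.4),
    "symptom"
  )
})

test_that("time-series generator hits its block correlation targets", {
  # independent modules: cross-module mean correlation near 0
  spec0 <- modular_series_spec(c(A = 5, B = 5), intra_r = 0.3, inter_r = 0,
                               n_frames = 5000)
  tc0 <- gen_modular_timeseries(spec0, seed = 5)
  R0 <- cor(tc0)
  cross <- R0[attr(tc0, "modules") == "A", attr(tc0, "modules") == "B"]
  expect_lt(abs(mean(cross)), 2 / sqrt(5000 - 3))

  # single module: within-module mean near the target (Fisher-z SE)
  spec1 <- modular_series_spec(c(M = 8), intra_r = 0.34, inter_r = numeric(0),
                               n_frames = 10000)
  tc1 <- gen_modular_timeseries(spec1, seed = 6)
  R1 <- cor(tc1)
  within <- R1[upper.tri(R1)]
  z_err <- abs(atanh(mean(within)) - atanh(0.34))
  expect_lt(z_err, 2 / sqrt(10000 - 3))

  # determinism
  expect_identical(tc1, gen_modular_timeseries(spec1, seed = 6))
})

test_that("degenerate time-series specs error", {
  expect_error(
    modular_series_spec(c(A = 3), intra_r = 0.3, inter_r = numeric(0),
                        n_frames = 1),
    "n_frames"
  )
  # five mutually repelling modules cannot form a PSD correlation matrix
  expect_error(
    modular_series_spec(c(A = 20, B = 20, C = 15, D = 15, E = 20),
                        intra_r = 0.3, inter_r = -0.2, n_frames = 100),
    "positive semi-definite"
  )
  expect_error(
    modular_series_spec(c(A = 2), intra_r = 1.2, inter_r = numeric(0)),
    "< 1"
  )
})

test_that("motion injection flags the right frames and scrubbing undoes it", {
  spec <- modular_series_spec(c(A = 4, B = 4), intra_r = 0.35, inter_r = -0.05,
                              n_frames = 600)
  clean <- gen_modular_timeseries(spec, seed = 9)

  # all-zero FD profile leaves the series untouched
  quiet <- inject_motion(clean, rep(0, 600))
  expect_identical(quiet$data, clean)
  expect_equal(quiet$fd, rep(0, 600))

  # FD vector is attached verbatim
  small <- clean[1:3, ]
  out <- inject_motion(small, c(0.2, 1.5, 0.3), seed = 2)
  expect_equal(out$fd, c(0.2, 1.5, 0.3))
  expect_identical(out$data[c(1, 3), ], small[c(1, 3), ])
  expect_false(identical(out$data[2, ], small[2, ]))

  expect_error(inject_motion(small, c(0, 0)), "length")

  # scrubbing the spiked frames restores the block correlations
  fd <- rep(0.1, 600)
  fd[seq(10, 600, by = 20)] <- 2
  spiked <- inject_motion(clean, fd, seed = 3)
  scrubbed <- scrub(time_course(spiked$data, spiked$fd), threshold = 1)
  R_clean <- cor(clean[fd <= 1, ])
  R_scrub <- cor(scrubbed$data)
  expect_equal(R_scrub, R_clean, tolerance = 1e-12)
  intra <- R_scrub[1:4, 1:4][upper.tri(diag(4))]
  expect_lt(abs(atanh(mean(intra)) - atanh(0.35)), 2 / sqrt(570 - 3))
})
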