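test_that("reference normalization uses population moments of the reference rows", {
  vals <- matrix(rep(c(1, 2, 3), 6), nrow = 3) # every feature is {1,2,3}
  co <- toy_cohort(vals)
  params <- fit_reference_normalization(co, co$subject_id)
  expect_equal(unname(params$means), rep(2, 6))
  expect_equal(unname(params$sds), rep(sqrt(2 / 3), 6))

  expect_error(fit_reference_normalization(co, co$subject_id[1]), "at least 2")
  co_flat <- co
  co_flat$fsiq <- 5
  expect_error(fit_reference_normalization(co_flat, co_flat$subject_id), "fsiq")
})

test_that("a cohort built to the published FSIQ summary round-trips through normalization", {
  # two reference subjects at 108 and 138: mean 123.0, population SD 15.0
  vals <- matrix(rep(c(108, 138), 6), nrow = 2)
  co <- toy_cohort(vals)
  params <- fit_reference_normalization(co, co$subject_id)
  expect_equal(unname(params$means["fsiq"]), 123.0)
  expect_equal(unname(params$sds["fsiq"]), 15.0)

  z <- normalize_features(co, params)
  # an FSIQ of 108 against the control reference 123 +/- 15 is exactly -1
  expect_equal(z$fsiq[1], -1.0)
  # reference rows are standardized
  expect_equal(mean(z$fsiq), 0)
  expect_equal(sqrt(mean(z$fsiq^2)), 1)

  back <- denormalize_features(z, params)
  expect_equal(back$fsiq, co$fsiq, tolerance = 1e-12)

  # z-scoring is not idempotent unless the reference is already standard
  zz <- normalize_features(z, params)
  expect_false(isTRUE(all.equal(zz$fsiq, z$fsiq)))
})

test_that("normalization round trip holds for random cohorts", {
  set.seed(31)
  for (rep in 1:5) {
    vals <- matrix(rnorm(10 * 6, mean = 50, sd = 8), 10, 6)
    co <- toy_cohort(vals)
    params <- fit_reference_normalization(co, co$subject_id[1:6])
    back <- denormalize_features(normalize_features(co, params), params)
    for (feat in clinical_features()) {
      expect_equal(back[[feat]], co[[feat]], tolerance = 1e-12)
    }
  }
})

test_that("euclidean distances satisfy the direct formula and metric axioms", {
  co <- toy_cohort(rbind(
    c(1, 2, 0, 0, 0, 0),
    c(4, 6, 0, 0, 0, 0)
  ))
  D <- euclidean_distances(co)
  expect_equal(D[1, 2], 5) # 3-4-5 triangle
  expect_equal(D[2, 1], 5)
  expect_equal(diag(D), setNames(c(0, 0), co$subject_id))

  co_same <- toy_cohort(rbind(c(1, 2, 3, 4, 5, 6), c(1, 2, 3, 4, 5, 6)))
  expect_equal(euclidean_distances(co_same)[1, 2], 0)

  # brute-force per-pair oracle on random matrices + metric axioms
  for (seed in 1:5) {
    vals <- random_feature_matrix(5, 6, seed)
    co_r <- toy_cohort(vals)
    D_r <- euclidean_distances(co_r)
    for (a in 1:5) {
      for (b in 1:5) {
        expect_equal(D_r[a, b], sqrt(sum((vals[a, ] - vals[b, ])^2)),
                     tolerance = 1e-12)
      }
    }
    expect_equal(D_r, t(D_r))
    for (a in 1:5) for (b in 1:5) for (c in 1:5) {
      expect_lte(D_r[a, b], D_r[a, c] + D_r[c, b] + 1e-12)
    }
  }
})

test_that("the L-infinity lens is the row maximum of the distance matrix", {
  # collinear points at 0, 1, 3
  co <- toy_cohort(cbind(c(0, 1, 3), matrix(0, 3, 5)))
  D <- euclidean_distances(co)
  expect_equal(unname(linf_centrality(D)), c(3, 2, 3))

  co2 <- toy_cohort(matrix(1, 2, 6))
  expect_equal(unname(linf_centrality(euclidean_distances(co2))), c(0, 0))

  set.seed(77)
  Dr <- as.matrix(dist(matrix(rnorm(40), 8, 5)))
  expect_equal(linf_centrality(Dr), apply(Dr, 1, max))
})

test_that("degenerate and two-cluster covers produce the hand-traced graphs", {
  # all subjects identical: one node holding everyone, no edges
  co <- toy_cohort(matrix(3, 5, 6))
  D <- euclidean_distances(co)
  g <- build_mapper(D, linf_centrality(D), cover_config(n_intervals = 1))
  expect_equal(nrow(g$nodes), 1)
  expect_equal(nrow(g$edges), 0)
  expect_setequal(g$nodes$subjects[[1]], co$subject_id)

  # two tight groups with lens {0, 0.1} and {0.9, 1.0}: 2 nodes, 0 edges
  x <- c(0, 0.1, 0.9, 1.0)
  co2 <- toy_cohort(cbind(x, matrix(0, 4, 5)))
  D2 <- euclidean_distances(co2)
  f2 <- setNames(x, co2$subject_id) # lens chosen by hand for the trace
  g2 <- build_mapper(D2, f2, cover_config(n_intervals = 2, overlap_frac = 0.1))
  expect_equal(nrow(g2$nodes), 2)
  expect_equal(nrow(g2$edges), 0)
  expect_equal(sort(g2$nodes$size), c(2, 2))
})

test_that("every subject is covered and the nerve property holds on generated topologies", {
  for (seed in c(2, 13)) {
    co <- gen_clinical_cohort(cohort_presets(c(20, 10, 10)), seed = seed)
    g <- mapper_pipeline(co)
    expect_setequal(unique(unlist(g$nodes$subjects)), co$subject_id)

    # edge iff subject-set intersection non-empty (pairwise oracle)
    nn <- nrow(g$nodes)
    want <- list()
    for (a in seq_len(nn - 1)) {
      for (b in seq(a + 1, nn)) {
        if (length(intersect(g$nodes$subjects[[a]], g$nodes$subjects[[b]])) > 0) {
          want[[length(want) + 1]] <- paste(g$nodes$node_id[a], g$nodes$node_id[b])
        }
      }
    }
    got <- paste(g$edges$from, g$edges$to)
    expect_setequal(got, unlist(want))
  }
})

test_that("edge count never decreases as the cover overlap grows", {
  co <- gen_clinical_cohort(cohort_presets(c(20, 10, 10)), seed = 4)
  norm <- fit_reference_normalization(co, co$subject_id[co$group == "TDC"])
  D <- euclidean_distances(normalize_features(co, norm))
  f <- linf_centrality(D)
  counts <- vapply(c(0.2, 0.35, 0.5, 0.65, 0.8), function(ov) {
    nrow(build_mapper(D, f, cover_config(4, ov, 5))$edges)
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("attribute mapping averages member subjects per node", {
  co <- gen_clinical_cohort(cohort_presets(c(10, 5, 5)), seed = 8)
  g <- mapper_pipeline(co)

  const <- setNames(rep(7, nrow(co)), co$subject_id)
  expect_equal(unname(map_attribute(g, const)), rep(7, nrow(g$nodes)))

  vals <- setNames(co$fsiq, co$subject_id)
  means <- map_attribute(g, vals)
  for (i in seq_len(nrow(g$nodes))) {
    expect_equal(unname(means[i]), mean(vals[g$nodes$subjects[[i]]]))
  }

  expect_error(map_attribute(g, vals[-1]), "missing")
})

test_that("two-member node mean is the midpoint", {
  g <- fake_mapper_graph(
    list(n1 = c("a", "b")),
    list(from = character(), to = character()),
    f = c(a = 1, b = 2)
  )
  expect_equal(unname(map_attribute(g, c(a = 10, b = 20))), 15)
})
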