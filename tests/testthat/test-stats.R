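test_that("raw one-way ANOVA matches the classical decomposition and lm", {
  d0 <- tibble::tibble(value = rep(c(1, 2, 3), 3),
                       group = rep(c("a", "b", "c"), each = 3))
  r0 <- anova_raw(d0, "value", "group")
  expect_equal(r0$statistic, 0)

  set.seed(101)
  for (rep in 1:5) {
    d <- tibble::tibble(
      value = rnorm(36, mean = rep(c(0, 0.5, 1), each = 12)),
      group = rep(c("a", "b", "c"), each = 12)
    )
    mine <- anova_raw(d, "value", "group")
    oracle <- anova(stats::lm(value ~ group, data = d))
    expect_equal(mine$statistic, oracle$`F value`[1], tolerance = 1e-12)
    expect_equal(mine$p_value, oracle$`Pr(>F)`[1], tolerance = 1e-12)
    expect_equal(c(mine$df1, mine$df2), oracle$Df)
  }

  d_const <- tibble::tibble(value = rep(c(1, 2), each = 3),
                            group = rep(c("a", "b"), each = 3))
  expect_error(anova_raw(d_const, "value", "group"), "within-group variance")
})

test_that("summary-statistics ANOVA equals the raw ANOVA when summaries match exactly", {
  set.seed(102)
  for (rep in 1:5) {
    means <- rnorm(3, 50, 10)
    sds <- runif(3, 2, 6)
    ns <- c(15, 20, 12)
    raw <- purrr::pmap_dfr(
      list(means, sds, ns, c("a", "b", "c")),
      function(m, s, n, g) {
        z <- as.numeric(scale(rnorm(n))) # exact sample mean 0, SD 1
        tibble::tibble(value = m + s * z, group = g)
      }
    )
    summ <- dplyr::summarise(
      dplyr::group_by(raw, group),
      mean = mean(value), sd = sd(value), n = dplyr::n(), .groups = "drop"
    )
    a <- anova_raw(raw, "value", "group")
    b <- anova_from_summary(summ)
    expect_equal(b$statistic, a$statistic, tolerance = 1e-10)
    expect_equal(b$p_value, a$p_value, tolerance = 1e-10)
    expect_equal(c(b$df1, b$df2), c(a$df1, a$df2))
  }

  flat <- tibble::tibble(mean = c(5, 5), sd = c(1, 2), n = c(10, 10))
  expect_equal(anova_from_summary(flat)$statistic, 0)
  expect_error(anova_from_summary(tibble::tibble(mean = 1:2, sd = 1, n = c(1, 5))),
               "n >= 2")
})

test_that("ANCOVA agrees with a nested lm comparison and rejects collinearity", {
  set.seed(103)
  d <- tibble::tibble(
    group = rep(c("a", "b", "c"), each = 10),
    age = rnorm(30, 12, 2)
  )
  d$value <- 0.4 * d$age + rep(c(0, 1, 2), each = 10) + rnorm(30)

  mine <- ancova(d, "value", "group", "age")
  full <- stats::lm(value ~ age + group, data = d)
  red <- stats::lm(value ~ age, data = d)
  oracle <- anova(red, full)
  expect_equal(mine$statistic, oracle$F[2], tolerance = 1e-10)
  expect_equal(mine$p_value, oracle$`Pr(>F)`[2], tolerance = 1e-10)
  expect_equal(c(mine$df1, mine$df2), c(2, 30 - 4))

  d$age2 <- d$age
  expect_error(ancova(d, "value", "group", c("age", "age2")), "collinear")
})

test_that("ANCOVA with a null covariate converges to the plain ANOVA", {
  set.seed(104)
  n <- 3000
  d <- tibble::tibble(
    group = rep(c("a", "b", "c"), each = n / 3),
    age = rnorm(n),
    value = rnorm(n, mean = rep(c(0, 0.2, 0.4), each = n / 3))
  )
  f_anova <- anova_raw(d, "value", "group")$statistic
  f_ancova <- ancova(d, "value", "group", "age")$statistic
  expect_lt(abs(f_anova - f_ancova) / f_anova, 0.02)
})

test_that("pooled t-test matches t.test and flips sign under swap", {
  set.seed(105)
  a <- rnorm(12, 1)
  b <- rnorm(15, 0)
  mine <- two_sample_t(a, b)
  oracle <- stats::t.test(a, b, var.equal = TRUE)
  expect_equal(mine$statistic, unname(oracle$statistic), tolerance = 1e-12)
  expect_equal(mine$p.value, oracle$p.value, tolerance = 1e-12)
  expect_equal(mine$df, 25)

  swapped <- two_sample_t(b, a)
  expect_equal(swapped$statistic, -mine$statistic)
  expect_equal(two_sample_t(a, a)$statistic, 0)
  expect_error(two_sample_t(rep(1, 3), rep(1, 4)), "pooled variance")
})

test_that("Benjamini-Hochberg step-up matches its definition and p.adjust", {
  out <- bh_correct(c(0.01, 0.02, 0.03, 0.04), q = 0.05)
  expect_true(all(out$significant)) # p_(4) = 0.04 <= 0.05

  single <- bh_correct(0.04, q = 0.05)
  expect_true(single$significant)
  expect_false(bh_correct(0.06, q = 0.05)$significant)

  set.seed(106)
  for (rep in 1:20) {
    p <- runif(sample(3:40, 1))^sample(1:3, 1)
    res <- bh_correct(p, q = 0.05)
    expect_equal(res$significant, bh_oracle(p, 0.05))
    expect_equal(res$p.adjusted, stats::p.adjust(p, "BH"), tolerance = 1e-14)
    expect_equal(res$significant, res$p.adjusted <= 0.05)
  }
})

test_that("Bonferroni post-hocs use the pair-count multiplier and true directions", {
  set.seed(107)
  d <- tibble::tibble(
    group = rep(c("a", "b", "c"), each = 20),
    value = rnorm(60, mean = rep(c(0, 3, 6), each = 20))
  )
  ph <- bonferroni_posthoc(d, "value", "group")
  expect_equal(nrow(ph), 3)
  expect_equal(ph$p.bonferroni, pmin(1, ph$p.value * 3))
  expect_true(all(ph$significant))
  expect_equal(ph$direction, c("a<b", "a<c", "b<c"))

  d_same <- tibble::tibble(group = rep(c("a", "b"), each = 10),
                           value = rnorm(20))
  ph2 <- bonferroni_posthoc(d_same, "value", "group")
  expect_false(any(ph2$significant))
})

test_that("compare_groups ties the omnibus, FDR and post-hoc stages together", {
  co <- gen_clinical_cohort(cohort_presets(), seed = 5)
  res <- compare_groups(co, c("fsiq", "adhd_index", "age"), group = "group")
  expect_equal(res$measure, c("fsiq", "adhd_index", "age"))
  expect_equal(res$p.adjusted, bh_correct(res$p.value)$p.adjusted)
  # the huge symptom separation must survive FDR with ordered post-hocs
  idx <- res[res$measure == "adhd_index", ]
  expect_true(idx$significant)
  expect_match(idx$posthoc, "TDC<mADHD")
  expect_match(idx$posthoc, "mADHD<sADHD")

  # ANCOVA route with age as covariate
  resc <- compare_groups(co, c("fsiq", "adhd_index"), group = "group",
                         covariates = "age")
  expect_true(all(resc$method == "ANCOVA"))
  expect_equal(resc$df2, rep(45 - 1 - 3, 2)) # intercept + age + 2 group dummies
})
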