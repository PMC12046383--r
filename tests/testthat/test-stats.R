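test_that("residualization behaves like OLS and names problems", {
  set.seed(1)
  n <- 20
  cov <- data.frame(age = rnorm(n, 65, 8), sex = rep(c("M", "F"), 10),
                    thickness_mm = rnorm(n, 3, 0.2))
  # perfect fit: values = 2 * age -> zero residuals
  r <- residualize(2 * cov$age, cov)
  expect_lt(max(abs(r)), 1e-10)
  # residual mean is zero
  v <- rnorm(n)
  expect_lt(abs(mean(residualize(v, cov))), 1e-12)
  # constant covariates are dropped (message) and act like plain centering
  const_cov <- data.frame(a = rep(1, n), b = rep(3, n))
  expect_message(r2 <- residualize(v, const_cov), "constant")
  expect_equal(r2, v - mean(v), tolerance = 1e-12)
  # collinear covariates are named
  cov2 <- cov
  cov2$age2 <- 2 * cov2$age
  expect_error(residualize(v, cov2), "age2")
  # simulated known coefficients: residualized group difference recovers the
  # generating effect on average (covariates independent of group)
  set.seed(2)
  diffs <- replicate(200, {
    g <- rep(0:1, each = 10)
    age <- rnorm(20, 65, 8)  # independent of g
    y <- 0.5 * age + 0.8 * g + rnorm(20, 0, 0.3)
    r <- residualize(y, data.frame(age = age))
    mean(r[g == 1]) - mean(r[g == 0])
  })
  expect_equal(mean(diffs), 0.8, tolerance = 0.05)
})

test_that("group t-tests honour scope, sign convention, and equivalences", {
  # two groups, constructed profiles; no covariates -> textbook t-test
  set.seed(5)
  subj <- sprintf("s%02d", 1:10)
  cohort <- tibble::tibble(
    subject = subj, group = rep(c("HC", "AbPos"), each = 5),
    age = rnorm(10, 65, 5), sex = "M", pmi_min = 400, ft_days = 40,
    thickness_mm = 3, braak_stage = 0L,
    amyloid_stage = rep(c(0L, 1L), each = 5)
  )
  vals <- c(rnorm(5, 1, 0.1), rnorm(5, 1.5, 0.1))
  profiles <- tibble::tibble(subject = subj, roi = 1L, layer = 1L,
                             metric = "MD", value = vals,
                             n_voxels = NA_integer_)
  tt <- group_ttest(profiles, cohort, metrics = "MD", covariates = NULL)
  ref <- t.test(vals[1:5], vals[6:10], var.equal = TRUE)
  row <- dplyr::filter(tt, scope == "layer")
  expect_equal(row$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(row$p, ref$p.value, tolerance = 1e-12)
  # amyloid-positive higher MD -> negative t under (AbNeg, AbPos) ordering
  expect_lt(row$t, 0)

  # identical groups: t = 0, p = 1
  prof_same <- profiles
  prof_same$value <- rep(c(1, 2, 3, 4, 5), 2)
  tt0 <- group_ttest(prof_same, cohort, metrics = "MD", covariates = NULL)
  expect_equal(dplyr::filter(tt0, scope == "layer")$t, 0)
  expect_equal(dplyr::filter(tt0, scope == "layer")$p, 1)

  # residualize-then-test equals the plain t-test when covariates are
  # orthogonal to values and groups (constant covariates degenerate case)
  tt_cov <- suppressMessages(
    group_ttest(profiles, cohort, metrics = "MD",
                covariates = c("pmi_min", "ft_days"))
  )
  expect_equal(dplyr::filter(tt_cov, scope == "layer")$t, row$t,
               tolerance = 1e-12)
})

test_that("28 ROIs x 6 layers enumerate 168 cell comparisons per metric", {
  set.seed(6)
  subj <- sprintf("s%02d", 1:15)
  cohort <- tibble::tibble(
    subject = subj, group = rep(c("HC", "PART", "AbPos"), c(4, 3, 8)),
    age = rnorm(15, 65, 5), sex = "M", pmi_min = 400, ft_days = 40,
    thickness_mm = rnorm(15, 3, 0.1), braak_stage = 0L,
    amyloid_stage = rep(c(0L, 0L, 1L), c(4, 3, 8))
  )
  profiles <- tidyr::expand_grid(subject = subj, roi = 1:28, layer = 1:6,
                                 metric = c("FA", "MD")) |>
    dplyr::mutate(value = rnorm(dplyr::n(), 1, 0.05),
                  n_voxels = NA_integer_)
  tt <- suppressMessages(group_ttest(profiles, cohort))
  counts <- dplyr::count(tt, metric, scope)
  expect_identical(
    dplyr::filter(counts, scope == "roi_layer")$n, c(168L, 168L))
  expect_identical(dplyr::filter(counts, scope == "layer")$n, c(6L, 6L))
  # q-values respect the BH ordering within each family
  fam <- dplyr::filter(tt, metric == "MD", scope == "roi_layer")
  expect_equal(fam$q, oracle_bh(fam$p), tolerance = 1e-12)
  expect_true(all(fam$q >= fam$p))
})

test_that("BH correction matches the step-up definition", {
  # worked example: all q equal the smallest bound
  expect_equal(fdr_bh(c(0.01, 0.02, 0.03, 0.04))$q, rep(0.04, 4))
  expect_equal(fdr_bh(0.37)$q, 0.37)           # single p: q = p
  expect_true(all(fdr_bh(rep(1, 5))$q == 1))   # all ones stay 1
  expect_error(fdr_bh(c(0.1, NA)), "finite")
  expect_error(fdr_bh(c(0.1, 1.2)), "0, 1|\\[0, 1\\]")

  set.seed(8)
  for (i in 1:20) {
    p <- runif(sample(3:40, 1))
    got <- fdr_bh(p, alpha = 0.05)
    expect_equal(got$q, oracle_bh(p), tolerance = 1e-14)
    # the q < alpha flags reproduce the largest-i rejection rule
    expect_identical(got$significant, oracle_bh_reject(p, 0.05))
  }
})

test_that("the stage mixed model recovers a known Amyloid coefficient", {
  set.seed(10)
  subj <- sprintf("s%02d", 1:15)
  cohort <- tibble::tibble(
    subject = subj, group = rep(c("HC", "PART", "AbPos"), c(4, 3, 8)),
    age = rnorm(15, 65, 8), sex = rep(c("M", "F"), length.out = 15),
    pmi_min = runif(15, 200, 900), ft_days = runif(15, 30, 70),
    thickness_mm = rnorm(15, 3, 0.1),
    braak_stage = c(rep(0L, 4), 1:3, sample(0:3, 8, TRUE)),
    amyloid_stage = c(rep(0L, 7), sample(1:3, 8, TRUE))
  )
  beta_amyloid <- 0.05
  dat <- tidyr::expand_grid(subject = subj, roi = 1:4, layer = 1L,
                            metric = "MD") |>
    dplyr::inner_join(cohort, by = "subject") |>
    dplyr::mutate(value = 1 + beta_amyloid * amyloid_stage +
                    rep(rnorm(15, 0, 0.003), each = 4) +
                    rnorm(dplyr::n(), 0, 0.002),
                  n_voxels = NA_integer_) |>
    dplyr::select(subject, roi, layer, metric, value, n_voxels)
  fit <- fit_stage_lmm(dat, cohort, metric = "MD", scope = "layer")
  co <- dplyr::filter(tidy(fit), term == "amyloid_stage")
  expect_lt(abs(co$estimate - beta_amyloid) / beta_amyloid, 0.1)
  expect_identical(unique(tidy(fit)$model), "lmm_reml")
  expect_gt(co$t, 2)
  gl <- glance(fit)
  expect_identical(gl$n_obs, 60L)
  expect_identical(gl$n_subjects, 15L)

  # per-cell scope has one observation per subject: degrades to OLS, flagged
  fit_cell <- fit_stage_lmm(dat, cohort, metric = "MD", scope = "roi_layer")
  expect_identical(unique(tidy(fit_cell)$model), "ols_fallback")
  expect_identical(nrow(glance(fit_cell)), 4L)

  # a constant stage column is excluded and named
  cohort0 <- dplyr::mutate(cohort, braak_stage = 1L)
  expect_message(
    fit0 <- fit_stage_lmm(dat, cohort0, metric = "MD", scope = "layer"),
    "braak"
  )
  expect_false("braak_stage" %in% tidy(fit0)$term)
})

test_that("matched-pair deltas subtract cell-wise with explicit pairing", {
  prof <- tidyr::expand_grid(subject = c("ad1", "hc1"), roi = 1:2, layer = 1:6,
                             metric = "MD") |>
    dplyr::mutate(value = ifelse(subject == "ad1", 1.1, 1.0),
                  n_voxels = NA_integer_)
  d <- delta_profile(prof, data.frame(case = "ad1", control = "hc1"))
  expect_identical(nrow(d), 12L)
  expect_true(all(abs(d$delta - 0.1) < 1e-12))

  # identical profiles: all deltas zero
  prof0 <- dplyr::mutate(prof, value = 1)
  d0 <- delta_profile(prof0, data.frame(case = "ad1", control = "hc1"))
  expect_true(all(d0$delta == 0))

  # a missing partner cell yields NA and a log message
  prof_miss <- dplyr::filter(prof, !(subject == "hc1" & roi == 2 & layer == 6))
  expect_message(
    dm <- delta_profile(prof_miss, data.frame(case = "ad1", control = "hc1")),
    "missing"
  )
  expect_identical(sum(is.na(dm$delta)), 1L)
  expect_error(delta_profile(prof, data.frame(case = "ad9", control = "hc1")),
               "absent")
})

test_that("Spearman across layers uses exact enumeration at small n", {
  # strictly increasing over 6 layers: rho = 1, exact p = 2/720
  r1 <- spearman_layers(1:6, c(2, 4, 5, 7, 8, 9))
  expect_equal(r1$rho, 1)
  expect_equal(r1$p, 2 / 720, tolerance = 1e-12)
  expect_identical(r1$method, "exact_permutation")
  # reversed: rho = -1, same two-sided p
  r2 <- spearman_layers(1:6, c(9, 8, 7, 5, 4, 2))
  expect_equal(r2$rho, -1)
  expect_equal(r2$p, 2 / 720, tolerance = 1e-12)

  expect_error(spearman_layers(1:2, 1:2), "at least 3")
  expect_error(spearman_layers(1:5, rep(1, 5)), "constant")

  # enumeration agrees with cor.test's exact p for untied data
  set.seed(13)
  for (i in 1:50) {
    x <- sample(100, 6)
    y <- sample(100, 6)
    got <- spearman_layers(x, y)
    ref <- suppressWarnings(cor.test(x, y, method = "spearman", exact = TRUE))
    expect_equal(got$rho, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(got$p, ref$p.value, tolerance = 1e-9)
  }

  # large n falls back to the t approximation
  set.seed(14)
  r3 <- spearman_layers(rnorm(20), rnorm(20))
  expect_identical(r3$method, "t_approximation")
  expect_true(r3$p >= 0 && r3$p <= 1)
})

test_that("injected MD effects propagate into delta profiles", {
  ps <- phantom_spec(voxel_size_mm = 1)
  ph <- make_phantom(ps)
  co <- suppressMessages(
    make_cohort(cohort_spec(seed = 17, cell_sd = 0.01, subject_sd = 0.01),
                ps, dwi_protocol(), phantom = ph)
  )
  hc <- co$cohort$subject[co$cohort$group == "HC"]
  cases <- co$cohort$subject[co$cohort$group == "AbPos"]
  pairs <- data.frame(case = cases, control = rep(hc, length.out = length(cases)))
  d <- delta_profile(dplyr::filter(co$profiles, metric == "MD"), pairs)
  rel <- d |>
    dplyr::inner_join(co$phantom$truth$layer_metrics,
                      by = c("roi", "layer", "metric")) |>
    dplyr::mutate(rel = delta / value) |>
    dplyr::group_by(layer) |>
    dplyr::summarise(rel = mean(rel))
  # injected layers II/III carry ~+10%; the others hover near zero
  expect_true(all(rel$rel[rel$layer %in% 2:3] > 0.06))
  expect_true(all(abs(rel$rel[!rel$layer %in% 2:3]) < 0.04))
})
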