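two_wn <- c(1000, 1004)

test_that("delta, reference sd and effect match hand arithmetic", {
  cases <- make_set(rbind(c(1, 2), c(3, 4)), two_wn, ids = c("a", "b"))
  refs <- make_set(rbind(c(0, 0), c(2, 2)), two_wn, ids = c("x", "y"),
                   roles = "reference")
  fp <- differential_fingerprint(cases, refs)
  expect_equal(fp$delta, c(1, 2))
  expect_equal(fp$ref_sd, c(sqrt(2), sqrt(2)))
  expect_equal(fp$effect, c(1, 2) / sqrt(2), tolerance = 1e-12)
  expect_equal(attr(fp, "n1"), 2)
  expect_equal(attr(fp, "n2"), 2)
})

test_that("identical group compositions give a null fingerprint", {
  set.seed(5)
  m <- matrix(rnorm(20), 2)
  cases <- make_set(m, seq(1000, 1036, 4), ids = c("a", "b"))
  refs <- make_set(m, seq(1000, 1036, 4), ids = c("x", "y"), roles = "reference")
  fp <- differential_fingerprint(cases, refs)
  expect_equal(fp$delta, rep(0, 10))
  expect_equal(fp$effect, rep(0, 10))
  expect_equal(fp$auc, rep(0.5, 10))
})

test_that("pooled t-test agrees with a numeric-integration oracle", {
  cases <- make_set(cbind(c(0, 1, 2), c(5, 6, 7)), two_wn, ids = letters[1:3])
  refs <- make_set(cbind(c(3, 4, 5), c(5, 6, 7)), two_wn, ids = letters[4:6],
                   roles = "reference")
  p <- ttest_pvalues(cases, refs)
  # A = {0,1,2} vs B = {3,4,5}: pooled sd 1, t = -3/sqrt(2/3) = -3.674, df = 4
  t_obs <- 3 / sqrt(2 / 3)
  expect_equal(t_obs, 3.674, tolerance = 1e-3)
  dens <- function(x, df) {
    gamma((df + 1) / 2) / (sqrt(df * pi) * gamma(df / 2)) *
      (1 + x^2 / df)^(-(df + 1) / 2)
  }
  p_oracle <- 2 * stats::integrate(dens, t_obs, Inf, df = 4)$value
  expect_equal(p[1], p_oracle, tolerance = 1e-8)
  expect_equal(p[1], 0.0213, tolerance = 1e-3)
  # equal means -> t = 0, p = 1
  expect_equal(p[2], 1)
})

test_that("t-test p-values are invariant under a common location shift", {
  set.seed(8)
  wn <- seq(1000, 1036, 4)
  a <- matrix(rnorm(30), 3)
  b <- matrix(rnorm(30, 0.5), 3)
  p1 <- ttest_pvalues(make_set(a, wn), make_set(b, wn, ids = c("x", "y", "z")))
  p2 <- ttest_pvalues(make_set(a + 7, wn), make_set(b + 7, wn, ids = c("x", "y", "z")))
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("zero-variance wavenumbers yield NA p-values with a warning", {
  cases <- make_set(rbind(c(1, 1), c(1, 2)), two_wn, ids = c("a", "b"))
  refs <- make_set(rbind(c(2, 0), c(2, 1)), two_wn, ids = c("x", "y"),
                   roles = "reference")
  expect_warning(p <- ttest_pvalues(cases, refs), "zero-variance")
  expect_true(is.na(p[1]))
  expect_false(is.na(p[2]))
})

test_that("U and AUC match the worked example and the degenerate limits", {
  refs <- make_set(cbind(c(1, 2, 3), c(1, 2, 3), c(1, 1, 1)),
                   c(1000, 1004, 1008), ids = c("x", "y", "z"),
                   roles = "reference")
  cases <- make_set(cbind(c(2.5, 3.5, 4), c(10, 11, 12), c(1, 1, 1)),
                    c(1000, 1004, 1008), ids = c("a", "b", "c"))
  mw <- mwu_auc(cases, refs)
  expect_equal(mw$U[1], 8)
  expect_equal(mw$auc[1], 8 / 9)
  expect_equal(mw$auc[2], 1)     # complete separation
  expect_equal(mw$auc[3], 0.5)   # all ties
})

test_that("mwu_auc equals brute-force pair counting on random instances", {
  set.seed(99)
  for (i in 1:200) {
    n1 <- sample(1:10, 1)
    n2 <- sample(1:10, 1)
    vals_case <- if (i %% 2) rnorm(n1) else sample(1:4, n1, replace = TRUE)
    vals_ref <- if (i %% 2) rnorm(n2) else sample(1:4, n2, replace = TRUE)
    cases <- make_set(cbind(vals_case, vals_case), two_wn,
                      ids = sprintf("c%d", 1:n1))
    refs <- make_set(cbind(vals_ref, vals_ref), two_wn,
                     ids = sprintf("r%d", 1:n2), roles = "reference")
    mw <- mwu_auc(cases, refs)
    oracle <- brute_force_auc(vals_case, vals_ref)
    expect_identical(mw$U[1], oracle$U)
    expect_identical(mw$auc[1], oracle$auc)
  }
})

test_that("auc(cases, refs) + auc(refs, cases) = 1", {
  set.seed(17)
  wn <- seq(1000, 1036, 4)
  for (i in 1:20) {
    a <- make_set(matrix(sample(1:5, 40, TRUE), 4), wn, ids = sprintf("a%d", 1:4))
    b <- make_set(matrix(sample(1:5, 30, TRUE), 3), wn, ids = sprintf("b%d", 1:3),
                  roles = "reference")
    expect_equal(mwu_auc(a, b)$auc + mwu_auc(b, a)$auc, rep(1, 10))
  }
})

test_that("statistics respond correctly to a positive rescaling", {
  set.seed(23)
  wn <- seq(1000, 1036, 4)
  a <- matrix(rnorm(40, 1), 4)
  b <- matrix(rnorm(40, 1.3), 4)
  f1 <- differential_fingerprint(make_set(a, wn, ids = sprintf("a%d", 1:4)),
                                 make_set(b, wn, ids = sprintf("b%d", 1:4),
                                          roles = "reference"))
  k <- 3.7
  f2 <- differential_fingerprint(make_set(k * a, wn, ids = sprintf("a%d", 1:4)),
                                 make_set(k * b, wn, ids = sprintf("b%d", 1:4),
                                          roles = "reference"))
  expect_equal(f2$delta, k * f1$delta, tolerance = 1e-9)
  expect_equal(f2$effect, f1$effect, tolerance = 1e-9)
  expect_equal(f2$p, f1$p, tolerance = 1e-9)
  expect_equal(f2$auc, f1$auc)
})

# Build a fingerprint with exactly known effect sizes: references are {0, 2}
# (sd = sqrt(2)) and cases are shifted by effect * sqrt(2) at chosen points.
fp_with_effect <- function(wn, effect) {
  shift <- effect * sqrt(2)
  refs <- make_set(rbind(rep(0, length(wn)), rep(2, length(wn))), wn,
                   ids = c("x", "y"), roles = "reference")
  cases <- make_set(rbind(shift, shift + 2), wn, ids = c("a", "b"))
  suppressWarnings(differential_fingerprint(cases, refs))
}

test_that("significant regions are maximal runs that respect grid gaps", {
  wn <- seq(1400, 1600, 4)
  d <- ifelse(wn >= 1500 & wn <= 1520, 1.2, 0)
  sr <- significant_regions(fp_with_effect(wn, d), d0 = 1)
  expect_equal(nrow(sr), 1)
  expect_equal(sr$wn_start, 1500)
  expect_equal(sr$wn_end, 1520)
  expect_equal(sr$n_points, 6)
  expect_equal(attr(sr, "criterion")$d0, 1)

  # below threshold everywhere -> empty
  expect_equal(nrow(significant_regions(fp_with_effect(wn, d), d0 = 2)), 0)

  # a run may not bridge the excised gap
  wn_gap <- c(seq(1780, 1800, 4), seq(2800, 2820, 4))
  sr_gap <- significant_regions(fp_with_effect(wn_gap, rep(1.5, 12)), d0 = 1)
  expect_equal(nrow(sr_gap), 2)
  expect_equal(sr_gap$wn_start, c(1780, 2800))
  expect_equal(sr_gap$wn_end, c(1800, 2820))
})

test_that("enclosed area integrates |delta| per retained block", {
  wn1 <- seq(1000, 1800, 4)
  fp1 <- fp_with_effect(wn1, rep(1 / sqrt(2), length(wn1)))  # delta = 1
  expect_equal(fp1$delta, rep(1, length(wn1)))
  expect_equal(enclosed_area(fp1), 800)

  # two blocks: delta = 1 on [1000, 1800], 0 on [2800, 3000]
  wn2 <- c(seq(1000, 1800, 4), seq(2800, 3000, 4))
  d2 <- ifelse(wn2 <= 1800, 1 / sqrt(2), 0)
  expect_equal(enclosed_area(fp_with_effect(wn2, d2)), 800)

  expect_equal(area_ratio(fp1, fp1), 1)
  null_fp <- fp_with_effect(wn1, rep(0, length(wn1)))
  expect_equal(enclosed_area(null_fp), 0)
  expect_error(area_ratio(fp1, null_fp), "zero enclosed area")
})

test_that("stage stratification splits cases by metastatic status", {
  cfg <- synthetic_config()
  sim <- simulate_cohort(cfg, seed = 41)
  pp <- preprocess_spectra(sim$spectra)
  cases <- pick_ids(pp, sim$cohort$subject_id[sim$cohort$group == "case"])
  refs_ids <- utils::head(sim$cohort$subject_id[sim$cohort$group == "reference"], 26)
  refs <- pick_ids(pp, refs_ids)
  st <- stage_stratified(cases, refs, sim$cohort)
  expect_equal(st$n_m0, 16)
  expect_equal(st$n_m1, 10)
  expect_equal(st$area_ratio, st$area_m1 / st$area_m0)
  expect_gt(st$area_ratio, 1)  # stage multiplier 2.5 amplifies the M1 contrast

  # unresolvable case ids are refused
  bad <- sim$cohort
  bad$subject_id[bad$subject_id == cases$sample_id[1]] <- "someone_else"
  expect_error(stage_stratified(cases, refs, bad), "not resolvable")
})

test_that("an all-M0 cohort cannot be stratified", {
  cfg <- synthetic_config(frac_m1 = 0, stage_multiplier = 1)
  sim <- simulate_cohort(cfg, seed = 43)
  pp <- preprocess_spectra(sim$spectra)
  cases <- pick_ids(pp, sim$cohort$subject_id[sim$cohort$group == "case"])
  refs <- pick_ids(pp, utils::head(
    sim$cohort$subject_id[sim$cohort$group == "reference"], 26))
  expect_error(stage_stratified(cases, refs, sim$cohort), ">= 2 cases")
})
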