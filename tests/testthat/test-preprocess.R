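# A toy grid whose flatness window [2000, 2300] is well populated.
toy_grid <- seq(1900, 2400, by = 4)

test_that("water coefficient has the closed form -slope(s)/slope(water)", {
  s <- make_set(matrix(0.001 * toy_grid, 1), toy_grid)
  water <- make_set(matrix(0.002 * toy_grid, 1), toy_grid, ids = "w",
                    roles = "water")
  fit <- fit_water_coefficient(s, water)
  expect_equal(fit$coefficient, -0.5, tolerance = 1e-10)

  # brute-force grid-search oracle over c
  wvec <- spectra_matrix(water)[1, ]
  svec <- spectra_matrix(s)[1, ]
  idx <- which(toy_grid >= 2000 & toy_grid <= 2300)
  slope_of <- function(c) {
    y <- (svec + c * wvec)[idx]
    x <- toy_grid[idx]
    abs(sum((x - mean(x)) * y) / sum((x - mean(x))^2))
  }
  cs <- seq(-1, 1, by = 1e-4)
  expect_equal(fit$coefficient, cs[which.min(vapply(cs, slope_of, 0))],
               tolerance = 1e-3)
})

test_that("flat spectra need no correction; flat water is uninformative", {
  flat <- make_set(matrix(0.3, 1, length(toy_grid)), toy_grid)
  sloped_w <- make_set(matrix(0.002 * toy_grid, 1), toy_grid, roles = "water")
  expect_equal(fit_water_coefficient(flat, sloped_w)$coefficient, 0)

  sloped_s <- make_set(matrix(0.001 * toy_grid, 1), toy_grid)
  flat_w <- make_set(matrix(0.5, 1, length(toy_grid)), toy_grid, roles = "water")
  expect_error(fit_water_coefficient(sloped_s, flat_w), "uninformative")
})

test_that("correction with c = 0 is the identity and never worsens flatness", {
  set.seed(3)
  cfg <- synthetic_config()
  s <- simulate_spectrum(cfg, b = 0.2, noise = TRUE)
  water <- make_set(matrix(water_reference_curve(cfg$grid), 1), cfg$grid,
                    ids = "w", roles = "water")
  out0 <- apply_water_correction(s, water, 0)
  expect_equal(spectra_matrix(out0), spectra_matrix(s))

  fit <- fit_water_coefficient(s, water)
  out <- apply_water_correction(s, water, fit)
  expect_lte(abs(correction_log(out)$residual_slope),
             abs(fit$slope_before) + 1e-12)
})

test_that("a constructed contamination clean + b*water is recovered exactly", {
  cfg <- synthetic_config()
  water <- make_set(matrix(water_reference_curve(cfg$grid), 1), cfg$grid,
                    ids = "w", roles = "water")
  for (b in c(-0.4, 0.05, 0.3)) {
    s <- simulate_spectrum(cfg, b = b, noise = FALSE)
    fit <- fit_water_coefficient(s, water)
    expect_equal(fit$coefficient, -b, tolerance = 1e-6)
    out <- apply_water_correction(s, water, fit)
    expect_lt(abs(correction_log(out)$residual_slope), 1e-10)
  }
})

test_that("excision retains exactly the enumerated grid points", {
  grid <- seq(950, 3050, by = 4)
  ss <- make_set(matrix(rnorm(length(grid)), 1), grid)
  out <- excise_regions(ss, keep = list(c(1000, 1800), c(2800, 3000)))
  wn <- wavenumbers(out)
  # independent enumeration oracle
  expected <- grid[(grid >= 1000 & grid <= 1800) | (grid >= 2800 & grid <= 3000)]
  expect_equal(wn, expected)
  expect_length(wn, 250)
  blocks <- imfp:::grid_blocks(wn)
  expect_equal(wn[blocks[[1]][1]], 1002)
  expect_equal(wn[utils::tail(blocks[[1]], 1)], 1798)
  expect_equal(wn[blocks[[2]][1]], 2802)
  expect_equal(wn[utils::tail(blocks[[2]], 1)], 2998)
  # subsetting, never interpolation
  expect_equal(unname(spectra_matrix(out)[1, ]),
               unname(spectra_matrix(ss)[1, match(wn, grid)]))
})

test_that("excision edge cases: full span is identity, empty result errors", {
  grid <- seq(1000, 1100, 4)
  ss <- make_set(matrix(rnorm(2 * length(grid)), 2), grid)
  out <- excise_regions(ss, keep = list(c(1000, 1100)))
  expect_equal(spectra_matrix(out), spectra_matrix(ss))
  expect_error(excise_regions(ss, keep = list(c(2000, 2100))), "every grid point")
})

test_that("L2 normalization satisfies its contract", {
  ss <- make_set(matrix(c(3, 4), 1), c(1000, 1004))
  out <- l2_normalize(ss)
  expect_equal(unname(spectra_matrix(out)[1, ]), c(0.6, 0.8))

  set.seed(7)
  ss2 <- make_set(matrix(rnorm(30), 3), seq(1000, 1036, 4))
  n1 <- l2_normalize(ss2)
  expect_equal(unname(sqrt(rowSums(spectra_matrix(n1)^2))), rep(1, 3),
               tolerance = 1e-12)
  expect_equal(spectra_matrix(l2_normalize(n1)), spectra_matrix(n1))

  zero <- make_set(matrix(0, 1, 2), c(1000, 1004))
  expect_error(l2_normalize(zero), "all-zero")
})

test_that("the chain applies correction, excision, then normalization", {
  cfg <- synthetic_config(seed = 21)
  sim <- simulate_cohort(cfg, seed = 21)
  pp <- preprocess_spectra(sim$spectra)
  expect_false("water" %in% pp$role)
  expect_equal(unname(sqrt(rowSums(spectra_matrix(pp)^2))),
               rep(1, nrow(pp)), tolerance = 1e-12)
  expect_length(wavenumbers(pp), 250)
  expect_equal(nrow(correction_log(pp)), nrow(pp))

  # manual replay of the chain on the same input
  water <- pick_role(sim$spectra, "water")
  nonwater <- pick_ids(sim$spectra,
                       sim$spectra$sample_id[sim$spectra$role != "water"])
  manual <- apply_water_correction(nonwater, water,
                                   fit_water_coefficient(nonwater, water))
  manual <- l2_normalize(excise_regions(manual))
  expect_equal(spectra_matrix(pp), spectra_matrix(manual))
})

test_that("normalizing after vs before excision differ, and 'off' is honored", {
  grid <- seq(950, 3050, by = 4)
  set.seed(9)
  ss <- make_set(matrix(abs(rnorm(length(grid), 0.2, 0.05)), 1), grid)
  after <- l2_normalize(excise_regions(ss))
  before <- excise_regions(l2_normalize(ss))
  expect_gt(max(abs(spectra_matrix(after) - spectra_matrix(before))), 1e-6)

  cfg <- synthetic_config()
  sim <- simulate_cohort(cfg, seed = 22)
  raw <- preprocess_spectra(sim$spectra,
                            params = preprocess_params(normalize = FALSE))
  norms <- sqrt(rowSums(spectra_matrix(raw)^2))
  expect_gt(max(abs(norms - 1)), 0.1)
})

test_that("QC drift statistics behave on constructed inputs", {
  grid <- seq(1000, 1100, 4)
  base <- sin(grid / 30) + 2
  identical_qc <- make_set(rbind(base, base, base), grid,
                           ids = c("q1", "q2", "q3"), roles = "qc")
  rep0 <- qc_drift(identical_qc)
  expect_equal(rep0$per_wavenumber_cv$cv_pct, rep(0, length(grid)))
  expect_equal(rep0$trend_slope, 0)
  expect_equal(rep0$mean_pairwise_rmsd, 0)

  # injected linear drift gamma per acquisition index
  gamma <- 5e-4
  set.seed(31)
  n_qc <- 12
  m <- t(vapply(seq_len(n_qc), function(i) {
    base + gamma * i + rnorm(length(grid), 0, 1e-4)
  }, numeric(length(grid))))
  drifted <- make_set(m, grid, ids = sprintf("q%d", 1:n_qc), roles = "qc")
  rep1 <- qc_drift(drifted)
  expect_lt(abs(rep1$trend_slope - gamma), 2 * rep1$trend_se + 1e-6)

  single <- make_set(matrix(base, 1), grid, roles = "qc")
  expect_error(qc_drift(single), "at least 2")
})
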