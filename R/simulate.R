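#' Configuration for synthetic FTIR plasma cohorts
#'
#' Defines the generative model used by [simulate_cohort()]: a deterministic
#' plasma-like absorbance curve (a sum of Gaussian bands mimicking the
#' dominant carbohydrate, amide II, amide I, ester-carbonyl and CH-stretch
#' features), multiplicative per-subject concentration variation, additive
#' disease effects on selected bands scaled by metastatic status,
#' residual-water baseline artifacts, wavenumber-correlated plus white noise,
#' covariates with case-control imbalance, and pooled-QC spectra interleaved
#' through the acquisition sequence.
#'
#' A simulated spectrum is
#' `A(v) = g * sum_i a_i (1 + delta_i e) G(v; c_i, w_i) + b W(v) + smooth + white`,
#' where `g` is the subject's lognormal concentration factor, `e` is 0 for
#' references, 1 for M0 cases and `stage_multiplier` for M1 cases, `b` is the
#' per-sample residual-water coefficient and `W` the generator's water
#' reference curve.
#'
#' @param n_cases,n_refs,n_candidates Cohort sizes: cases, matched references
#'   (selected downstream by [match_controls()]), and candidate controls.
#' @param grid Wavenumber grid (cm^-1); default 950-3050 at 4 cm^-1 steps.
#' @param bands Tibble with `center`, `width` (Gaussian sd) and `amplitude`.
#' @param effect_bands Tibble with `center` and fractional amplitude shift
#'   `delta` applied to cases; centers must appear in `bands`. `NULL` for a
#'   null (no-signal) cohort.
#' @param stage_multiplier Effect multiplier for metastatic (M1) cases.
#' @param frac_m1 Fraction of cases that are metastatic; the M1 count is
#'   `round(frac_m1 * n_cases)`.
#' @param noise_sd White (independent per wavenumber) noise sd, absorbance.
#' @param smooth_noise_sd Sd (at the absorbance-envelope maximum) of the
#'   wavenumber-correlated compositional noise; its pointwise sd is modulated
#'   by the relative envelope `A(v)/max(A)`, so the silent region carries
#'   white instrument noise only.
#' @param corr_len Correlation length (cm^-1) of the smooth noise (Gaussian
#'   kernel sd); 0 disables the smooth component.
#' @param water_mismatch_range Interval from which each sample's residual
#'   water coefficient `b` is drawn uniformly.
#' @param subject_noise_sd Lognormal sd (sdlog) of the per-subject global
#'   concentration factor `g`.
#' @param covariates Nested list giving mean/sd of `age` and `bmi` for cases
#'   and candidate controls.
#' @param qc_every Interleave one pooled-QC spectrum after every `qc_every`
#'   sample spectra.
#' @param qc_noise_sd White-noise sd of QC spectra.
#' @param qc_trend Instrument drift injected into QC spectra, absorbance per
#'   acquisition index.
#' @param seed Default seed used by [simulate_cohort()] when none is passed.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_cases = 26, n_refs = 26, n_candidates = 67,
                             grid = seq(950, 3050, by = 4),
                             bands = default_bands(),
                             effect_bands = default_effect_bands(),
                             stage_multiplier = 2.5,
                             frac_m1 = 10 / 26,
                             noise_sd = 0.0015,
                             smooth_noise_sd = 0.004,
                             corr_len = 30,
                             water_mismatch_range = c(-0.3, 0.3),
                             subject_noise_sd = 0.05,
                             covariates = list(
                               case = list(age = c(49, 9), bmi = c(29, 6)),
                               candidate = list(age = c(40, 8), bmi = c(26, 5))
                             ),
                             qc_every = 5,
                             qc_noise_sd = 0.001,
                             qc_trend = 0,
                             seed = NULL) {
  validate_grid(grid)
  stopifnot(n_cases >= 2, n_candidates >= 1, n_refs >= 2,
            all(bands$width > 0), all(bands$amplitude >= 0),
            noise_sd >= 0, smooth_noise_sd >= 0, corr_len >= 0,
            subject_noise_sd >= 0, qc_every >= 1,
            frac_m1 >= 0, frac_m1 <= 1)
  if (!is.null(effect_bands) && nrow(effect_bands)) {
    if (!all(effect_bands$center %in% bands$center)) {
      abort("every effect band center must match a band center")
    }
  }
  structure(as.list(environment()), class = "synthetic_config")
}

#' @rdname synthetic_config
#' @export
default_bands <- function() {
  tibble(center = c(1080, 1240, 1400, 1545, 1650, 1740, 2930, 2960),
         width = c(40, 30, 30, 25, 25, 15, 35, 20),
         amplitude = c(0.15, 0.10, 0.12, 0.35, 0.50, 0.08, 0.20, 0.10))
}

#' @rdname synthetic_config
#' @export
default_effect_bands <- function() {
  tibble(center = c(1080, 1545, 1650, 2930),
         delta = c(0.010, 0.012, -0.008, 0.006))
}

# Deterministic plasma-like band sum on the grid.
band_curve <- function(grid, bands) {
  rowSums(vapply(seq_len(nrow(bands)), function(i) {
    bands$amplitude[i] * exp(-(grid - bands$center[i])^2 / (2 * bands$width[i]^2))
  }, numeric(length(grid))))
}

# Additive case effect for e = 1: sum of a_i * delta_i * G_i over effect bands.
effect_curve <- function(cfg) {
  if (is.null(cfg$effect_bands) || !nrow(cfg$effect_bands)) {
    return(numeric(length(cfg$grid)))
  }
  eb <- left_join(cfg$effect_bands, cfg$bands, by = "center")
  rowSums(vapply(seq_len(nrow(eb)), function(i) {
    eb$amplitude[i] * eb$delta[i] *
      exp(-(cfg$grid - eb$center[i])^2 / (2 * eb$width[i]^2))
  }, numeric(length(cfg$grid))))
}

#' The generator's water reference curve
#'
#' A deterministic stand-in for a measured pure-water absorption spectrum: a
#' smooth monotone ramp through the 1900-2400 cm^-1 region (which gives the
#' residual-water artifact its baseline tilt over the 2000-2300 cm^-1
#' flatness window) plus broad bands for the water bending mode near
#' 1640 cm^-1 and the low-wavenumber tail of the OH stretch.
#'
#' @param grid Wavenumber grid (cm^-1).
#' @return Numeric vector of absorbance values on `grid`.
#' @export
water_reference_curve <- function(grid) {
  0.4 * pnorm(grid, mean = 2150, sd = 150) +
    0.8 * exp(-(grid - 1640)^2 / (2 * 80^2)) +
    1.5 * exp(-(grid - 3350)^2 / (2 * 200^2))
}

# Smooth (wavenumber-correlated) compositional noise: white noise convolved
# with a Gaussian kernel of sd corr_len, rescaled to sd smooth_noise_sd per
# point, then modulated by the relative absorbance envelope A(v)/max(A) --
# compositional variation can only appear where molecules absorb, so the
# silent region carries white instrument noise only.
# Returns an n_spectra x n_wavenumber matrix.
smooth_noise <- function(n_spectra, grid, smooth_noise_sd, corr_len, envelope) {
  n <- length(grid)
  if (smooth_noise_sd <= 0 || corr_len <= 0) {
    return(matrix(0, n_spectra, n))
  }
  step <- grid_step(grid)
  half <- ceiling(4 * corr_len / step)
  w <- dnorm(seq(-half, half) * step, 0, corr_len)
  w <- w / sqrt(sum(w^2)) * smooth_noise_sd
  raw <- t(vapply(seq_len(n_spectra), function(i) {
    z <- rnorm(n + 2 * half)
    as.numeric(stats::filter(z, w, sides = 2))[(half + 1):(half + n)]
  }, numeric(n)))
  raw * matrix(envelope, n_spectra, n, byrow = TRUE)
}

# Relative absorbance envelope of the band model, in [0, 1].
noise_envelope <- function(cfg) {
  base <- band_curve(cfg$grid, cfg$bands)
  base / max(base)
}

#' Simulate a single plasma-like spectrum
#'
#' One draw from the generative model of [synthetic_config()], with the latent
#' variables exposed so tests can construct spectra with known ground truth
#' (e.g. a known residual-water coefficient `b`, or zero noise).
#'
#' @param cfg A [synthetic_config()].
#' @param sample_id,role Metadata of the returned spectrum.
#' @param e Effect scale: 0 (reference), 1 (M0 case) or
#'   `cfg$stage_multiplier` (M1 case).
#' @param g Subject concentration factor.
#' @param b Residual-water coefficient.
#' @param noise Draw the white and smooth noise components?
#' @return A one-row `spectrum_set`.
#' @export
simulate_spectrum <- function(cfg, sample_id = "s1", role = "reference",
                              e = 0, g = 1, b = 0, noise = TRUE) {
  stopifnot(inherits(cfg, "synthetic_config"))
  a <- g * (band_curve(cfg$grid, cfg$bands) + e * effect_curve(cfg)) +
    b * water_reference_curve(cfg$grid)
  if (noise) {
    a <- a + as.numeric(smooth_noise(1, cfg$grid, cfg$smooth_noise_sd,
                                     cfg$corr_len, noise_envelope(cfg))) +
      rnorm(length(cfg$grid), 0, cfg$noise_sd)
  }
  m <- matrix(a, nrow = 1)
  df <- bind_cols_quiet(
    tibble(sample_id = sample_id, role = role, acquisition_order = 1L),
    as_tibble(m, .name_repair = "minimal"))
  names(df)[4:ncol(df)] <- format_wavenumber(cfg$grid)
  as_spectrum_set(df)
}

#' Simulate a full FTIR measurement campaign
#'
#' Generates covariates and spectra for `n_cases` breast-cancer-like cases
#' (split into M0/M1 strata by `frac_m1`) and `n_candidates` candidate
#' controls with the configured covariate imbalance, measures them in a
#' random acquisition order with one pooled-QC spectrum interleaved after
#' every `qc_every` sample spectra, and appends the water reference spectrum
#' (role `"water"`, acquisition_order 0).
#'
#' @param cfg A [synthetic_config()].
#' @param seed Integer seed; overrides `cfg$seed`. With a fixed seed the
#'   output is reproducible bit for bit.
#' @return A list with `spectra` (a `spectrum_set`), `cohort` (a cohort
#'   tibble; candidates carry group `"reference"`), and `truth` (per-subject
#'   latent variables `g`, `b`, `e` and the effect configuration).
#' @export
simulate_cohort <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "synthetic_config"))
  if (!is.null(seed)) set.seed(seed)
  n_m1 <- round(cfg$frac_m1 * cfg$n_cases)
  if (n_m1 > 0 && n_m1 < cfg$n_cases && (n_m1 < 2 || cfg$n_cases - n_m1 < 2)) {
    warn("a stage stratum has fewer than 2 cases; stage_stratified() will refuse it")
  }
  case_ids <- sprintf("case_%03d", seq_len(cfg$n_cases))
  cand_ids <- sprintf("ctrl_%03d", seq_len(cfg$n_candidates))
  m1 <- c(rep(TRUE, n_m1), rep(FALSE, cfg$n_cases - n_m1))
  stage <- ifelse(m1, "IV", sample(c("I", "II", "III"), cfg$n_cases, replace = TRUE))
  draw_cov <- function(par, n) pmax(rnorm(n, par[1], par[2]), par[1] / 3)
  cohort <- tibble(
    subject_id = c(case_ids, cand_ids),
    age = c(draw_cov(cfg$covariates$case$age, cfg$n_cases),
            draw_cov(cfg$covariates$candidate$age, cfg$n_candidates)),
    bmi = c(draw_cov(cfg$covariates$case$bmi, cfg$n_cases),
            draw_cov(cfg$covariates$candidate$bmi, cfg$n_candidates)),
    sex = "female",
    group = rep(c("case", "reference"), c(cfg$n_cases, cfg$n_candidates)),
    stage = c(stage, rep("none", cfg$n_candidates))
  )
  cohort$m_status <- ifelse(cohort$group == "case",
                            ifelse(cohort$stage == "IV", "M1", "M0"), "none")

  n_sub <- nrow(cohort)
  e <- ifelse(cohort$group == "case",
              ifelse(cohort$m_status == "M1", cfg$stage_multiplier, 1), 0)
  g <- rlnorm(n_sub, 0, cfg$subject_noise_sd)
  b <- runif(n_sub, cfg$water_mismatch_range[1], cfg$water_mismatch_range[2])

  base <- band_curve(cfg$grid, cfg$bands)
  eff <- effect_curve(cfg)
  wat <- water_reference_curve(cfg$grid)
  a <- outer(g, base) + outer(g * e, eff) + outer(b, wat) +
    smooth_noise(n_sub, cfg$grid, cfg$smooth_noise_sd, cfg$corr_len,
                 noise_envelope(cfg)) +
    matrix(rnorm(n_sub * length(cfg$grid), 0, cfg$noise_sd), n_sub)

  # acquisition: random sample order, QC after every qc_every samples
  ord <- sample(n_sub)
  n_qc <- floor(n_sub / cfg$qc_every)
  total <- n_sub + n_qc
  rows <- vector("list", total)
  acq <- 0L
  qi <- 0L
  out_id <- character(total)
  out_role <- character(total)
  out_acq <- integer(total)
  m_out <- matrix(0, total, length(cfg$grid))
  pos <- 0L
  for (i in seq_len(n_sub)) {
    pos <- pos + 1L
    acq <- acq + 1L
    s <- ord[i]
    out_id[pos] <- cohort$subject_id[s]
    out_role[pos] <- if (cohort$group[s] == "case") "case" else "reference"
    out_acq[pos] <- acq
    m_out[pos, ] <- a[s, ]
    if (i %% cfg$qc_every == 0 && qi < n_qc) {
      pos <- pos + 1L
      acq <- acq + 1L
      qi <- qi + 1L
      out_id[pos] <- sprintf("qc_%03d", qi)
      out_role[pos] <- "qc"
      out_acq[pos] <- acq
      m_out[pos, ] <- base + cfg$qc_trend * acq +
        rnorm(length(cfg$grid), 0, cfg$qc_noise_sd)
    }
  }
  df <- bind_cols_quiet(
    tibble(sample_id = c(out_id, "water_ref"),
           role = c(out_role, "water"),
           acquisition_order = c(out_acq, 0L)),
    as_tibble(rbind(m_out, wat), .name_repair = "minimal"))
  names(df)[4:ncol(df)] <- format_wavenumber(cfg$grid)
  spectra <- as_spectrum_set(df)

  list(spectra = spectra, cohort = cohort,
       truth = list(subjects = tibble(subject_id = cohort$subject_id,
                                      g = g, b = b, e = e),
                    effect_bands = cfg$effect_bands,
                    stage_multiplier = cfg$stage_multiplier,
                    seed = seed))
}

#' Closed-form single-feature AUC of a synthetic configuration
#'
#' Under the generative model with unit concentration factor and no
#' residual-water mismatch, case and reference absorbance at a wavenumber are
#' Gaussian with common sd `sigma(v)` and mean shift `Delta(v)` equal to the
#' effect curve, so the per-wavenumber (M0) AUC is
#' `Phi(Delta(v) / (sigma(v) * sqrt(2)))`. `sigma` combines the white noise
#' sd, the envelope-modulated smooth noise sd and, approximately, the
#' concentration-factor contribution
#' `subject_noise_sd * A(v)`.
#'
#' @param cfg A [synthetic_config()].
#' @return A tibble with `wavenumber`, `delta_mean`, `sigma`, `auc`.
#' @export
theoretical_feature_auc <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  base <- band_curve(cfg$grid, cfg$bands)
  eff <- effect_curve(cfg)
  env <- noise_envelope(cfg)
  sigma <- sqrt(cfg$noise_sd^2 + (cfg$smooth_noise_sd * env)^2 +
                  (cfg$subject_noise_sd * base)^2)
  tibble(wavenumber = cfg$grid, delta_mean = eff, sigma = sigma,
         auc = pnorm(abs(eff) / (sigma * sqrt(2))))
}

#' Calibrate effect amplitudes to a target single-feature AUC
#'
#' Rescales all effect-band `delta`s by one common factor so that the best
#' (maximum over wavenumbers) closed-form single-feature AUC of
#' [theoretical_feature_auc()] equals `target_auc`.
#'
#' @param cfg A [synthetic_config()] with at least one effect band.
#' @param target_auc Desired best single-feature AUC (0.5 < target < 1).
#' @return The modified config.
#' @export
calibrate_effect <- function(cfg, target_auc = 0.8) {
  stopifnot(inherits(cfg, "synthetic_config"),
            target_auc > 0.5, target_auc < 1)
  th <- theoretical_feature_auc(cfg)
  snr <- abs(th$delta_mean) / th$sigma
  if (max(snr) == 0) abort("config has no effect bands to calibrate")
  factor <- qnorm(target_auc) * sqrt(2) / max(snr)
  cfg$effect_bands$delta <- cfg$effect_bands$delta * factor
  cfg
}

#' A single-band benchmark configuration
#'
#' The canonical benchmark cohort for classifier validation: the only signal
#' is one amide-II band contrast, the concentration factor and residual-water
#' mismatch are switched off, and the contrast is calibrated so the best
#' single-feature Gaussian AUC equals `target_auc`. The closed-form value
#' then anchors what the cross-validated classifier should approach.
#'
#' @param target_auc Best single-feature AUC of the benchmark.
#' @param n_cases,n_refs Group sizes (candidates are set to `n_refs` and all
#'   become references).
#' @param ... Further arguments passed to [synthetic_config()].
#' @return A calibrated [synthetic_config()].
#' @export
single_contrast_config <- function(target_auc = 0.8, n_cases = 26,
                                   n_refs = 26, ...) {
  cfg <- synthetic_config(
    n_cases = n_cases, n_refs = n_refs, n_candidates = n_refs,
    effect_bands = tibble(center = 1545, delta = 0.01),
    stage_multiplier = 1, frac_m1 = 0,
    subject_noise_sd = 0, water_mismatch_range = c(0, 0), ...)
  calibrate_effect(cfg, target_auc)
}
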