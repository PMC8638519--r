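#' Per-wavenumber two-sample t-test p-values
#'
#' Two-sided Student t-tests (pooled variance) of case vs reference absorbance
#' at every wavenumber; Welch's unpooled variant is available via
#' `var_equal = FALSE`. Wavenumbers with zero pooled variance get `NA` with a
#' warning.
#'
#' @param cases,refs `spectrum_set`s on an identical grid, each with >= 2
#'   spectra.
#' @param var_equal Pool the variances (classical Student test)?
#' @return Numeric vector of p-values, one per wavenumber.
#' @export
ttest_pvalues <- function(cases, refs, var_equal = TRUE) {
  mats <- check_two_groups(cases, refs)
  a <- mats$a
  b <- mats$b
  n1 <- nrow(a)
  n2 <- nrow(b)
  v1 <- apply(a, 2, var)
  v2 <- apply(b, 2, var)
  dm <- colMeans(a) - colMeans(b)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, length(se))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  p <- rep(NA_real_, length(se))
  ok <- se > 0
  p[ok] <- 2 * pt(-abs(dm[ok] / se[ok]), df[ok])
  p[!ok & dm == 0] <- 1
  if (anyNA(p)) warn("zero-variance wavenumber(s): p-value undefined, set to NA")
  p
}

#' Per-wavenumber Mann-Whitney U and AUC
#'
#' At each wavenumber, `U` counts case-reference pairs in which the case
#' absorbance exceeds the reference (ties count 0.5), and
#' `AUC = U / (n1 * n2)` -- the probability that a randomly chosen case
#' exceeds a randomly chosen reference.
#'
#' @inheritParams ttest_pvalues
#' @return A tibble with `wavenumber`, `U`, `auc`.
#' @export
mwu_auc <- function(cases, refs) {
  mats <- check_two_groups(cases, refs, min_n = 1)
  a <- mats$a
  b <- mats$b
  n1 <- nrow(a)
  n2 <- nrow(b)
  u <- vapply(seq_len(ncol(a)), function(j) {
    r <- rank(c(a[, j], b[, j]))
    sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  }, 0)
  tibble(wavenumber = mats$wn, U = u, auc = u / (n1 * n2))
}

check_two_groups <- function(cases, refs, min_n = 2) {
  stopifnot(is_spectrum_set(cases), is_spectrum_set(refs))
  wn1 <- wavenumbers(cases)
  wn2 <- wavenumbers(refs)
  if (length(wn1) != length(wn2) || any(abs(wn1 - wn2) > 1e-9)) {
    abort("cases and references are not on the same wavenumber grid")
  }
  if (nrow(cases) < min_n || nrow(refs) < min_n) {
    abort(sprintf("each group needs at least %d spectra", min_n))
  }
  list(a = spectra_matrix(cases), b = spectra_matrix(refs), wn = wn1)
}

#' Differential fingerprint between cases and references
#'
#' Computes, per wavenumber: the differential fingerprint
#' `delta = mean(cases) - mean(references)`; the reference-group standard
#' deviation `ref_sd` (n-1); the effect size `effect = delta / ref_sd`
#' (Glass's delta -- the differential fingerprint standardized by the
#' reference group's spread); the two-sided t-test p-value `p` and its
#' Benjamini-Hochberg adjustment `p_bh` (an extension over the raw per-
#' wavenumber p-values, clearly labelled as such); and the Mann-Whitney `U`
#' and per-wavenumber `auc`.
#'
#' Where `delta` and `ref_sd` are both zero the effect is defined as 0; a zero
#' `ref_sd` with nonzero `delta` yields `NA` with a warning.
#'
#' @inheritParams ttest_pvalues
#' @return A tibble of class `differential_fingerprint` with columns
#'   `wavenumber`, `delta`, `ref_sd`, `effect`, `p`, `p_bh`, `U`, `auc`;
#'   attributes `n1`, `n2` record the group sizes.
#' @export
differential_fingerprint <- function(cases, refs, var_equal = TRUE) {
  mats <- check_two_groups(cases, refs)
  delta <- colMeans(mats$a) - colMeans(mats$b)
  ref_sd <- apply(mats$b, 2, sd)
  effect <- rep(NA_real_, length(delta))
  effect[ref_sd > 0] <- delta[ref_sd > 0] / ref_sd[ref_sd > 0]
  effect[ref_sd == 0 & delta == 0] <- 0
  if (anyNA(effect)) {
    warn("reference sd is 0 with nonzero delta at some wavenumbers; effect set to NA")
  }
  p <- ttest_pvalues(cases, refs, var_equal = var_equal)
  mw <- mwu_auc(cases, refs)
  out <- tibble(wavenumber = mats$wn, delta = as.numeric(delta),
                ref_sd = as.numeric(ref_sd), effect = as.numeric(effect),
                p = p, p_bh = stats::p.adjust(p, method = "BH"),
                U = mw$U, auc = mw$auc)
  class(out) <- c("differential_fingerprint", class(tibble()))
  attr(out, "n1") <- nrow(mats$a)
  attr(out, "n2") <- nrow(mats$b)
  out
}

#' Contiguous wavenumber regions with large group differences
#'
#' Finds maximal runs of consecutive retained grid points whose effect size
#' satisfies `|effect| >= d0` and, if `p0` is given, `p <= p0`. Runs never
#' bridge the excised silent region (or any other grid gap).
#'
#' @param fp A [differential_fingerprint()].
#' @param d0 Effect-size threshold (default 1, i.e. one reference standard
#'   deviation).
#' @param p0 Optional p-value threshold.
#' @return A tibble with `wn_start`, `wn_end`, `n_points`, `max_abs_effect`,
#'   `min_p`; the thresholds are recorded in the `"criterion"` attribute.
#' @export
significant_regions <- function(fp, d0 = 1, p0 = NULL) {
  stopifnot(inherits(fp, "differential_fingerprint"))
  hit <- !is.na(fp$effect) & abs(fp$effect) >= d0
  if (!is.null(p0)) hit <- hit & !is.na(fp$p) & fp$p <= p0
  blocks <- grid_blocks(fp$wavenumber)
  out <- purrr::map_dfr(blocks, function(idx) {
    h <- hit[idx]
    if (!any(h)) return(tibble())
    r <- rle(h)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    runs <- which(r$values)
    tibble(wn_start = fp$wavenumber[idx][starts[runs]],
           wn_end = fp$wavenumber[idx][ends[runs]],
           n_points = r$lengths[runs],
           max_abs_effect = map_dbl(runs, function(k) {
             max(abs(fp$effect[idx][starts[k]:ends[k]]))
           }),
           min_p = map_dbl(runs, function(k) {
             suppressWarnings(min(fp$p[idx][starts[k]:ends[k]], na.rm = TRUE))
           }))
  })
  attr(out, "criterion") <- list(d0 = d0, p0 = p0)
  out
}

#' Area enclosed by a differential fingerprint
#'
#' Trapezoidal integral of `|delta|` over the retained wavenumber windows
#' (integrated per contiguous block, then summed), in absorbance * cm^-1.
#' `area_ratio()` compares two fingerprints, e.g. metastatic vs
#' non-metastatic strata.
#'
#' @param fp,fp1,fp2 [differential_fingerprint()] objects.
#' @return `enclosed_area()`: a scalar area; `area_ratio()`:
#'   `enclosed_area(fp1) / enclosed_area(fp2)`.
#' @export
enclosed_area <- function(fp) {
  stopifnot(inherits(fp, "differential_fingerprint"))
  sum(map_dbl(grid_blocks(fp$wavenumber), function(idx) {
    trapz(fp$wavenumber[idx], abs(fp$delta[idx]))
  }))
}

#' @rdname enclosed_area
#' @export
area_ratio <- function(fp1, fp2) {
  a2 <- enclosed_area(fp2)
  if (a2 == 0) abort("denominator fingerprint has zero enclosed area")
  enclosed_area(fp1) / a2
}

#' Stage-stratified differential fingerprints
#'
#' Splits the cases into non-metastatic (M0; stages I-III) and metastatic
#' (M1; stage IV) strata using the cohort's `m_status`, compares each stratum
#' against the same reference spectra, and reports the M1:M0 enclosed-area
#' ratio -- a summary of how much more pronounced the metastatic fingerprint
#' difference is.
#'
#' @param cases `spectrum_set` of case spectra.
#' @param refs `spectrum_set` of reference spectra.
#' @param cohort Cohort tibble resolving every case `sample_id` to an
#'   `m_status` of `"M0"` or `"M1"`; each stratum needs >= 2 cases.
#' @param var_equal Passed to [differential_fingerprint()].
#' @return A list of class `stage_result`: `fp_m0`, `fp_m1`
#'   (differential fingerprints), `n_m0`, `n_m1`, `area_m0`, `area_m1`,
#'   `area_ratio` (M1:M0).
#' @export
stage_stratified <- function(cases, refs, cohort, var_equal = TRUE) {
  stopifnot(is_spectrum_set(cases), is_spectrum_set(refs))
  m <- cohort$m_status[match(cases$sample_id, cohort$subject_id)]
  if (anyNA(m) || !all(m %in% c("M0", "M1"))) {
    bad <- cases$sample_id[is.na(m) | !m %in% c("M0", "M1")]
    abort(paste0("case(s) not resolvable to M0/M1: ", paste(bad, collapse = ", ")))
  }
  pick <- function(status) {
    out <- cases[m == status, ]
    class(out) <- class(cases)
    out
  }
  m0 <- pick("M0")
  m1 <- pick("M1")
  if (nrow(m0) < 2 || nrow(m1) < 2) {
    abort(sprintf("each stage stratum needs >= 2 cases (M0: %d, M1: %d)",
                  nrow(m0), nrow(m1)))
  }
  fp_m0 <- differential_fingerprint(m0, refs, var_equal = var_equal)
  fp_m1 <- differential_fingerprint(m1, refs, var_equal = var_equal)
  structure(list(fp_m0 = fp_m0, fp_m1 = fp_m1,
                 n_m0 = nrow(m0), n_m1 = nrow(m1),
                 area_m0 = enclosed_area(fp_m0), area_m1 = enclosed_area(fp_m1),
                 area_ratio = area_ratio(fp_m1, fp_m0)),
            class = "stage_result")
}

#' @export
print.stage_result <- function(x, ...) {
  cat(sprintf("<stage_result: M0 n=%d, M1 n=%d>\n", x$n_m0, x$n_m1))
  cat(sprintf("  enclosed area  M0: %.4g  M1: %.4g  ratio M1:M0 = %.3f\n",
              x$area_m0, x$area_m1, x$area_ratio))
  invisible(x)
}

#' @export
glance.stage_result <- function(x, ...) {
  tibble(n_m0 = x$n_m0, n_m1 = x$n_m1, area_m0 = x$area_m0,
         area_m1 = x$area_m1, area_ratio = x$area_ratio)
}

#' @export
glance.differential_fingerprint <- function(x, ...) {
  tibble(n1 = attr(x, "n1"), n2 = attr(x, "n2"),
         enclosed_area = enclosed_area(x),
         max_abs_effect = max(abs(x$effect), na.rm = TRUE),
         min_p = suppressWarnings(min(x$p, na.rm = TRUE)),
         max_auc = max(x$auc))
}

#' @export
autoplot.differential_fingerprint <- function(object, d0 = 1, ...) {
  long <- tidyr::pivot_longer(
    select(as_tibble(object), "wavenumber", "delta", "effect", "p", "auc"),
    cols = c("delta", "effect", "p", "auc"),
    names_to = "panel", values_to = "value")
  long$panel <- factor(long$panel, levels = c("delta", "effect", "p", "auc"))
  hline <- tibble(panel = factor(c("effect", "effect", "auc"),
                                 levels = levels(long$panel)),
                  y = c(d0, -d0, 0.5))
  ggplot2::ggplot(long, ggplot2::aes(.data$wavenumber, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(data = hline, ggplot2::aes(yintercept = .data$y),
                        linetype = 2, colour = "grey40") +
    ggplot2::facet_wrap(~panel, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "wavenumber (cm⁻¹)", y = NULL) +
    ggplot2::theme_minimal()
}
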