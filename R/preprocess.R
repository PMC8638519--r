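#' Preprocessing parameters
#'
#' Bundles the spectral preprocessing settings: the flatness window used for
#' water-compensation fitting, the wavenumber windows retained after
#' truncation and silent-region excision, and whether to apply Euclidean (L2)
#' vector normalization.
#'
#' Defaults follow common plasma FTIR practice: the 2000-2300 cm^-1 window
#' (where plasma shows no significant absorption) diagnoses residual-water
#' baseline tilt; the spectra are then truncated to 1000-3000 cm^-1 with the
#' silent region 1800-2800 cm^-1 removed, leaving the fingerprint window
#' 1000-1800 and the CH-stretch window 2800-3000.
#'
#' @param flatness_window Interval (cm^-1) over which the baseline is made flat.
#' @param keep_windows List of intervals (cm^-1) to retain; must be sorted and
#'   non-overlapping.
#' @param normalize Apply L2 vector normalization after excision?
#' @return A list of class `preprocess_params`.
#' @export
preprocess_params <- function(flatness_window = c(2000, 2300),
                              keep_windows = list(c(1000, 1800), c(2800, 3000)),
                              normalize = TRUE) {
  check_window(flatness_window, "flatness_window")
  if (!is.list(keep_windows) || !length(keep_windows)) {
    abort("`keep_windows` must be a non-empty list of intervals")
  }
  for (w in keep_windows) check_window(w, "keep_windows[[i]]")
  starts <- map_dbl(keep_windows, 1)
  ends <- map_dbl(keep_windows, 2)
  if (is.unsorted(starts, strictly = TRUE) || any(head(ends, -1) >= tail(starts, -1))) {
    abort("`keep_windows` must be sorted and non-overlapping")
  }
  structure(list(flatness_window = flatness_window, keep_windows = keep_windows,
                 normalize = isTRUE(normalize)),
            class = "preprocess_params")
}

water_as_vector <- function(water, wn) {
  if (is_spectrum_set(water)) {
    if (nrow(water) != 1) abort("`water` must be a single spectrum")
    if (!isTRUE(all.equal(wavenumbers(water), wn, tolerance = 1e-9))) {
      abort("`water` is not on the same wavenumber grid as the spectra")
    }
    as.numeric(spectra_matrix(water)[1, ])
  } else if (is.numeric(water) && length(water) == length(wn)) {
    as.numeric(water)
  } else {
    abort("`water` must be a one-row spectrum_set or a numeric vector on the same grid")
  }
}

#' Fit per-spectrum water-compensation coefficients
#'
#' Liquid plasma contains less water than the pure-water reference used to
#' reconstruct absorbance, which tilts (and can push negative) the baseline in
#' the 2000-2300 cm^-1 window where plasma itself shows no significant
#' absorption. The compensation adds a multiple `c` of a measured water
#' absorption spectrum to each sample spectrum so that the average slope over
#' that window is minimized. With "average slope" operationalized as the
#' ordinary-least-squares slope of absorbance against wavenumber, the
#' minimizer has the closed form `c = -slope(s) / slope(water)`.
#'
#' @param x A `spectrum_set` (the water spectrum itself, role `"water"`, is
#'   skipped and gets coefficient 0).
#' @param water The water reference: a one-row `spectrum_set` or numeric
#'   vector on the same grid.
#' @param window Flatness window (cm^-1); needs at least 3 grid points.
#' @return A tibble with `sample_id`, `slope_before` (absorbance per cm^-1)
#'   and `coefficient`.
#' @export
fit_water_coefficient <- function(x, water, window = c(2000, 2300)) {
  stopifnot(is_spectrum_set(x))
  check_window(window)
  wn <- wavenumbers(x)
  w <- water_as_vector(water, wn)
  idx <- in_window(wn, window)
  if (length(idx) < 3) abort("flatness window contains fewer than 3 grid points")
  m <- spectra_matrix(x)
  s_slopes <- ols_slope(wn[idx], m[, idx, drop = FALSE])
  w_slope <- ols_slope(wn[idx], w[idx])
  coef <- if (abs(w_slope) < 1e-12) {
    if (any(abs(s_slopes) > 1e-12 & x$role != "water")) {
      abort("water reference uninformative: its slope over the flatness window is ~0")
    }
    rep(0, nrow(m))
  } else {
    -s_slopes / w_slope
  }
  coef[x$role == "water"] <- 0
  tibble(sample_id = x$sample_id, slope_before = as.numeric(s_slopes),
         coefficient = as.numeric(coef))
}

#' Apply water-compensation correction
#'
#' Adds `coefficient * water` to each spectrum and records the residual OLS
#' slope over the flatness window. The correction log is attached as the
#' `"correction"` attribute (see [correction_log()]).
#'
#' @inheritParams fit_water_coefficient
#' @param coefficients A tibble as returned by [fit_water_coefficient()], or a
#'   numeric vector with one coefficient per spectrum.
#' @return The corrected `spectrum_set`.
#' @export
apply_water_correction <- function(x, water, coefficients, window = c(2000, 2300)) {
  stopifnot(is_spectrum_set(x))
  wn <- wavenumbers(x)
  w <- water_as_vector(water, wn)
  if (is.data.frame(coefficients)) {
    ord <- match(x$sample_id, coefficients$sample_id)
    if (anyNA(ord)) abort("`coefficients` is missing some sample_ids")
    coef <- coefficients$coefficient[ord]
  } else {
    stopifnot(length(coefficients) == nrow(x))
    coef <- as.numeric(coefficients)
  }
  m <- spectra_matrix(x) + outer(coef, w)
  out <- set_spectra_matrix(x, m)
  idx <- in_window(wn, window)
  log <- tibble(sample_id = x$sample_id, coefficient = coef,
                residual_slope = as.numeric(ols_slope(wn[idx], m[, idx, drop = FALSE])))
  attr(out, "correction") <- log
  out
}

#' @rdname apply_water_correction
#' @export
correction_log <- function(x) attr(x, "correction")

#' Excise wavenumber regions
#'
#' Restricts spectra to the grid points lying inside any of the `keep`
#' intervals (boundaries inclusive). This is pure column subsetting -- values
#' are never interpolated -- and the resulting grid is non-contiguous when
#' more than one block is retained.
#'
#' @param x A `spectrum_set`.
#' @param keep Sorted, non-overlapping list of intervals (cm^-1).
#' @return A `spectrum_set` on the restricted grid.
#' @export
excise_regions <- function(x, keep = list(c(1000, 1800), c(2800, 3000))) {
  stopifnot(is_spectrum_set(x))
  wn <- wavenumbers(x)
  idx <- sort(unique(unlist(map(keep, ~ in_window(wn, .x)))))
  if (!length(idx)) abort("excision removed every grid point")
  keep_cols <- c(setdiff(names(x), spectral_names(x)), spectral_names(x)[idx])
  out <- x[, keep_cols]
  class(out) <- c("spectrum_set", class(tibble()))
  attr(out, "correction") <- attr(x, "correction")
  out
}

#' Euclidean (L2) vector normalization
#'
#' Scales each spectrum to unit Euclidean norm, removing overall-absorbance
#' (e.g. effective path length or total concentration) variation between
#' measurements.
#'
#' @param x A `spectrum_set`; no spectrum may be all-zero.
#' @return A `spectrum_set` whose rows have unit L2 norm.
#' @export
l2_normalize <- function(x) {
  stopifnot(is_spectrum_set(x))
  m <- spectra_matrix(x)
  nrm <- sqrt(rowSums(m^2))
  if (any(nrm == 0)) {
    abort(paste0("cannot normalize all-zero spectrum: ",
                 paste(x$sample_id[nrm == 0], collapse = ", ")))
  }
  out <- set_spectra_matrix(x, m / nrm)
  attr(out, "correction") <- attr(x, "correction")
  out
}

#' Run the full preprocessing chain
#'
#' Applies, in order: water-compensation correction (fitted per spectrum over
#' the flatness window), truncation/silent-region excision, and (optionally)
#' L2 vector normalization, to every non-water spectrum of the set. QC spectra
#' are processed like sample spectra. The per-sample correction log is
#' attached as the `"correction"` attribute.
#'
#' @param x A `spectrum_set`. If it contains a spectrum with role `"water"`,
#'   that spectrum is used as the water reference (and dropped from the
#'   output) unless `water` is given explicitly.
#' @param water Optional water reference (one-row `spectrum_set` or numeric
#'   vector). `NULL` with no water-role spectrum present skips the water step.
#' @param params A [preprocess_params()] object.
#' @return The preprocessed `spectrum_set` (roles case/reference/qc).
#' @export
preprocess_spectra <- function(x, water = NULL, params = preprocess_params()) {
  stopifnot(is_spectrum_set(x), inherits(params, "preprocess_params"))
  if (is.null(water) && any(x$role == "water")) {
    water <- x[which(x$role == "water")[1], ]
    class(water) <- class(x)
  }
  out <- x |> filter(.data$role != "water")
  class(out) <- c("spectrum_set", class(tibble()))
  if (nrow(out) == 0) abort("no spectra to preprocess")
  if (!is.null(water)) {
    coefs <- fit_water_coefficient(out, water, params$flatness_window)
    out <- apply_water_correction(out, water, coefs, params$flatness_window)
  }
  out <- excise_regions(out, params$keep_windows)
  if (params$normalize) out <- l2_normalize(out)
  attr(out, "params") <- params
  out
}

#' Pooled-QC drift report
#'
#' Summarises repeated measurements of a pooled plasma sample (interleaved
#' throughout a measurement campaign) as instrument-stability diagnostics:
#' the per-wavenumber coefficient of variation, the mean pairwise
#' root-mean-square difference between QC spectra, and the OLS slope of mean
#' absorbance against acquisition index (with its standard error).
#'
#' @param x A `spectrum_set`; only rows with role `"qc"` are used and at least
#'   two are required.
#' @return A list of class `qc_report` with `n_qc`, `per_wavenumber_cv`
#'   (tibble, percent), `mean_pairwise_rmsd`, `trend_slope`, `trend_se`.
#' @export
qc_drift <- function(x) {
  stopifnot(is_spectrum_set(x))
  qc <- x |> filter(.data$role == "qc") |> arrange(.data$acquisition_order)
  if (nrow(qc) < 2) abort("qc_drift needs at least 2 QC spectra")
  m <- as.matrix(qc[, spectral_names(qc)])
  wn <- wavenumbers(qc)
  mu <- colMeans(m)
  sdv <- apply(m, 2, sd)
  cv <- unname(ifelse(abs(mu) > 0, 100 * sdv / abs(mu), NA_real_))
  pairs <- utils::combn(nrow(m), 2)
  rmsd <- mean(apply(pairs, 2, function(p) sqrt(mean((m[p[1], ] - m[p[2], ])^2))))
  idx <- qc$acquisition_order
  means <- rowMeans(m)
  slope <- ols_slope(idx, means)
  resid <- means - mean(means) - slope * (idx - mean(idx))
  se <- if (nrow(m) > 2) {
    sqrt(sum(resid^2) / (nrow(m) - 2) / sum((idx - mean(idx))^2))
  } else {
    NA_real_
  }
  structure(list(n_qc = nrow(qc),
                 per_wavenumber_cv = tibble(wavenumber = wn, cv_pct = cv),
                 mean_pairwise_rmsd = rmsd,
                 trend_slope = slope, trend_se = se),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report: %d QC spectra>\n", x$n_qc))
  cat(sprintf("  median CV: %.3f%%  mean pairwise RMSD: %.3g\n",
              stats::median(x$per_wavenumber_cv$cv_pct, na.rm = TRUE),
              x$mean_pairwise_rmsd))
  cat(sprintf("  trend slope: %.3g absorbance/index (se %.3g)\n",
              x$trend_slope, x$trend_se))
  invisible(x)
}

#' @export
tidy.qc_report <- function(x, ...) x$per_wavenumber_cv

#' @export
glance.qc_report <- function(x, ...) {
  tibble(n_qc = x$n_qc,
         median_cv_pct = stats::median(x$per_wavenumber_cv$cv_pct, na.rm = TRUE),
         mean_pairwise_rmsd = x$mean_pairwise_rmsd,
         trend_slope = x$trend_slope, trend_se = x$trend_se)
}
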