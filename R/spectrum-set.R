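#' Spectrum sets: samples-by-wavenumber absorbance tables
#'
#' A spectrum set is a tibble with one row per measured spectrum and one
#' numeric-named column per wavenumber (cm^-1), plus the metadata columns
#' `sample_id`, `role` (one of `"case"`, `"reference"`, `"qc"`, `"water"`) and
#' `acquisition_order`. All spectra in a set share one wavenumber grid. The
#' grid must be strictly increasing and, within each contiguous block (blocks
#' arise after silent-region excision), uniformly spaced.
#'
#' @param df A data frame with `sample_id` and numeric-named absorbance
#'   columns. Missing `role` / `acquisition_order` columns are filled with
#'   `default_role` and the row order.
#' @param default_role Role assigned where `df` has no `role` column.
#' @return A tibble of class `spectrum_set`.
#' @examples
#' ss <- as_spectrum_set(
#'   data.frame(sample_id = "s1", `1000` = 0.1, `1004` = 0.2, check.names = FALSE)
#' )
#' wavenumbers(ss)
#' @export
as_spectrum_set <- function(df, default_role = "case") {
  df <- as_tibble(df)
  if (!"sample_id" %in% names(df)) {
    abort("a spectrum set needs a `sample_id` column")
  }
  df$sample_id <- as.character(df$sample_id)
  if (!"role" %in% names(df)) df$role <- default_role
  if (!"acquisition_order" %in% names(df)) df$acquisition_order <- seq_len(nrow(df))
  wn <- spectral_names(df)
  if (length(wn) < 2) abort("a spectrum set needs at least two wavenumber columns")
  meta <- setdiff(names(df), wn)
  df <- df[, c(intersect(c("sample_id", "role", "acquisition_order"), meta), wn)]
  validate_spectrum_set(df)
  class(df) <- c("spectrum_set", class(tibble()))
  df
}

#' @rdname as_spectrum_set
#' @param x Object to test.
#' @export
is_spectrum_set <- function(x) inherits(x, "spectrum_set")

# Names of wavenumber (numeric-named) columns, in table order.
spectral_names <- function(df) {
  nm <- names(df)
  nm[!is.na(suppressWarnings(as.numeric(nm)))]
}

#' @rdname as_spectrum_set
#' @export
wavenumbers <- function(df) as.numeric(spectral_names(df))

#' Extract the absorbance matrix of a spectrum set
#'
#' @param df A `spectrum_set` (or any data frame with numeric-named columns).
#' @return A numeric matrix, rows named by `sample_id`, columns by wavenumber.
#' @export
spectra_matrix <- function(df) {
  m <- as.matrix(df[, spectral_names(df), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df$sample_id
  m
}

# Replace the absorbance values of a set, optionally on a new grid.
set_spectra_matrix <- function(df, m, wn = wavenumbers(df)) {
  stopifnot(nrow(m) == nrow(df), ncol(m) == length(wn))
  meta <- df[, setdiff(names(df), spectral_names(df)), drop = FALSE]
  out <- bind_cols_quiet(meta, as_tibble(m, .name_repair = "minimal"))
  names(out)[(ncol(meta) + 1):ncol(out)] <- format_wavenumber(wn)
  class(out) <- c("spectrum_set", class(tibble()))
  out
}

bind_cols_quiet <- function(a, b) {
  out <- c(as.list(a), as.list(b))
  as_tibble(out, .name_repair = "minimal")
}

format_wavenumber <- function(wn) {
  vapply(wn, function(v) format(v, digits = 15, scientific = FALSE, trim = TRUE), "")
}

validate_spectrum_set <- function(df) {
  wn <- wavenumbers(df)
  validate_grid(wn)
  if (anyDuplicated(df$sample_id)) {
    abort(paste0("duplicate sample_id: ",
                 paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", ")))
  }
  bad_role <- setdiff(unique(df$role), c("case", "reference", "qc", "water"))
  if (length(bad_role)) {
    abort(paste0("invalid role(s): ", paste(bad_role, collapse = ", ")))
  }
  m <- spectra_matrix(df)
  if (nrow(m) && !all(is.finite(m))) abort("absorbance values must be finite")
  invisible(df)
}

# A grid is valid when strictly increasing, positive, and uniform within each
# contiguous block (relative tolerance 1e-9 on the step). Gaps from excision
# must be whole multiples of the base step; any other spacing is malformed.
validate_grid <- function(wn) {
  if (length(wn) < 2) abort("grid error: need at least two wavenumbers")
  if (any(wn <= 0)) abort("grid error: wavenumbers must be positive")
  d <- diff(wn)
  if (any(d <= 0)) abort("grid error: wavenumbers must be strictly increasing")
  step <- grid_step(wn)
  k <- d / step
  if (any(abs(k - round(k)) > 1e-6)) {
    abort("grid error: spacing is not uniform (nor a whole multiple of the step)")
  }
  within <- round(k) == 1
  if (any(abs(d[within] - step) > 1e-9 * step)) {
    abort("grid error: spacing not uniform within contiguous blocks")
  }
  invisible(wn)
}

# Nominal step: the smallest spacing (gaps from excision are larger).
grid_step <- function(wn) min(diff(wn))

# TRUE when the grid has no excision gaps.
grid_contiguous <- function(wn) {
  d <- diff(wn)
  all(d <= grid_step(wn) * (1 + 1e-9))
}

# Split grid indices into contiguous blocks (list of index vectors).
grid_blocks <- function(wn) {
  d <- diff(wn)
  step <- grid_step(wn)
  breaks <- which(d > step * (1 + 1e-9))
  starts <- c(1, breaks + 1)
  ends <- c(breaks, length(wn))
  map2(starts, ends, seq)
}

#' @export
print.spectrum_set <- function(x, ...) {
  wn <- wavenumbers(x)
  cat(sprintf("<spectrum_set: %d spectra x %d wavenumbers (%g-%g cm-1%s)>\n",
              nrow(x), length(wn), min(wn), max(wn),
              if (grid_contiguous(wn)) "" else ", non-contiguous"))
  roles <- table(x$role)
  cat("  roles:", paste(sprintf("%s=%d", names(roles), roles), collapse = ", "), "\n")
  NextMethod()
}

#' Read / write wide spectral tables
#'
#' The on-disk format is a wide UTF-8 CSV: one row per spectrum, a `sample_id`
#' column, optional `role` and `acquisition_order` columns, and one column per
#' wavenumber with the wavenumber (cm^-1) as the column name. Values are
#' written with full precision so that a write/read round trip is
#' value-identical.
#'
#' @param path File path of the CSV table.
#' @param role_map Optional named character vector `sample_id -> role`
#'   overriding any role column in the file.
#' @param default_role Role for samples not covered by `role_map` or a role
#'   column.
#' @return `read_spectrum_table()` returns a `spectrum_set`;
#'   `write_spectrum_table()` invisibly returns `path`.
#' @export
read_spectrum_table <- function(path, role_map = NULL, default_role = "case") {
  # base read.csv parses doubles with strtod, which round-trips the 17-digit
  # representation exactly (vroom's fast parser can be one ulp off)
  df <- as_tibble(utils::read.csv(path, check.names = FALSE,
                                  stringsAsFactors = FALSE))
  if (!"sample_id" %in% names(df)) {
    names(df)[1] <- "sample_id"
  }
  if (anyDuplicated(df$sample_id)) {
    abort(paste0("format error: duplicate sample_id in ", path))
  }
  if ("acquisition_order" %in% names(df)) {
    df$acquisition_order <- as.integer(df$acquisition_order)
  }
  ss <- as_spectrum_set(df, default_role = default_role)
  if (!is.null(role_map)) {
    hit <- ss$sample_id %in% names(role_map)
    ss$role[hit] <- unname(role_map[ss$sample_id[hit]])
    validate_spectrum_set(ss)
  }
  ss
}

#' @rdname read_spectrum_table
#' @param x A `spectrum_set`.
#' @export
write_spectrum_table <- function(x, path) {
  stopifnot(is_spectrum_set(x))
  out <- as_tibble(x)
  # 17 significant digits: doubles survive the write/read round trip exactly
  for (nm in spectral_names(out)) {
    out[[nm]] <- sprintf("%.17g", out[[nm]])
  }
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Resample spectra onto a new wavenumber grid
#'
#' Linear interpolation of each spectrum onto `grid`. The new grid must lie
#' within the span of the current one; extrapolation is refused.
#'
#' @param x A `spectrum_set` on a contiguous grid.
#' @param grid Numeric vector of target wavenumbers (strictly increasing).
#' @return A `spectrum_set` on `grid`.
#' @export
align_to_grid <- function(x, grid) {
  stopifnot(is_spectrum_set(x))
  validate_grid(grid)
  wn <- wavenumbers(x)
  if (min(grid) < min(wn) - 1e-9 || max(grid) > max(wn) + 1e-9) {
    abort("range error: target grid extends past the spectrum's wavenumber span")
  }
  m <- spectra_matrix(x)
  out <- t(apply(m, 1, function(a) approx(wn, a, xout = grid)$y))
  if (nrow(m) == 1) out <- matrix(out, nrow = 1)
  set_spectra_matrix(x, out, grid)
}

#' @export
autoplot.spectrum_set <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object),
                              cols = all_of(spectral_names(object)),
                              names_to = "wavenumber", values_to = "absorbance")
  long$wavenumber <- as.numeric(long$wavenumber)
  summ <- long |>
    group_by(.data$role, .data$wavenumber) |>
    summarise(mean = mean(.data$absorbance),
              sd = sd(.data$absorbance), .groups = "drop")
  ggplot2::ggplot(summ, ggplot2::aes(.data$wavenumber, .data$mean,
                                     colour = .data$role, fill = .data$role)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         alpha = 0.25, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "wavenumber (cm⁻¹)", y = "absorbance") +
    ggplot2::theme_minimal()
}
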