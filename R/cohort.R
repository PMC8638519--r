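#' Read a cohort covariate table
#'
#' Reads a subject-level covariate table from CSV (or xlsx, if the readxl
#' package is available). Column names are matched case-insensitively against
#' an alias list (`subject_id`/`id`/`sample_id`, `age`, `bmi`/`body_mass_index`,
#' `sex`/`gender`, `group`/`status`, `stage`, `m_status`/`m`). Group labels are
#' normalized to `"case"` / `"reference"`, tumor stages to Roman numerals
#' I-IV (sub-stages such as "IIA" are collapsed to their main stage), and
#' `m_status` is derived from stage where absent: stage IV cases are M1, other
#' cases M0, references `"none"`.
#'
#' @param path Path to a `.csv` or `.xlsx` file.
#' @return A tibble with columns `subject_id`, `age`, `bmi`, `sex`, `group`,
#'   `stage`, `m_status`.
#' @export
read_cohort <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("xlsx", "xls")) {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      abort("reading xlsx cohort files requires the readxl package")
    }
    df <- readxl::read_excel(path)
  } else {
    df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }
  as_cohort(df)
}

cohort_aliases <- list(
  subject_id = c("subject_id", "id", "sample_id", "subject", "patient_id"),
  age        = c("age", "age_years"),
  bmi        = c("bmi", "body_mass_index"),
  sex        = c("sex", "gender"),
  group      = c("group", "status", "class", "arm"),
  stage      = c("stage", "tumor_stage", "tnm_stage"),
  m_status   = c("m_status", "m", "metastasis", "m_stage")
)

#' Normalize a data frame into a cohort table
#'
#' @param df A data frame of subjects; see [read_cohort()] for the recognized
#'   columns and value dialects.
#' @return A validated cohort tibble.
#' @export
as_cohort <- function(df) {
  df <- as_tibble(df)
  if (nrow(df) == 0) {
    warn("empty cohort table")
    return(tibble(subject_id = character(), age = double(), bmi = double(),
                  sex = character(), group = character(), stage = character(),
                  m_status = character()))
  }
  lowered <- tolower(names(df))
  out <- list()
  for (canon in names(cohort_aliases)) {
    hit <- which(lowered %in% cohort_aliases[[canon]])
    if (length(hit)) out[[canon]] <- df[[hit[1]]]
  }
  missing_req <- setdiff(c("subject_id", "age", "bmi", "group"), names(out))
  if (length(missing_req)) {
    abort(paste0("format error: missing required column(s): ",
                 paste(missing_req, collapse = ", ")))
  }
  out$subject_id <- as.character(out$subject_id)
  for (v in c("age", "bmi")) {
    parsed <- suppressWarnings(as.numeric(out[[v]]))
    bad <- which(is.na(parsed) | parsed <= 0)
    if (length(bad)) {
      abort(sprintf("record error: unparseable or non-positive %s in row(s): %s",
                    v, paste(bad, collapse = ", ")))
    }
    out[[v]] <- parsed
  }
  out$group <- normalize_group(out$group)
  out$sex <- if (is.null(out$sex)) NA_character_ else tolower(as.character(out$sex))
  out$stage <- normalize_stage(if (is.null(out$stage)) rep(NA, nrow(df)) else out$stage)
  out$m_status <- if (is.null(out$m_status)) rep(NA_character_, nrow(df)) else
    toupper(trimws(as.character(out$m_status)))
  tbl <- as_tibble(out)[, c("subject_id", "age", "bmi", "sex", "group",
                            "stage", "m_status")]
  validate_cohort(tbl)
}

normalize_group <- function(g) {
  g <- tolower(trimws(as.character(g)))
  case_vals <- c("case", "cases", "cancer", "bc", "patient", "tumor", "1")
  ref_vals <- c("reference", "references", "control", "controls", "healthy",
                "ref", "0")
  out <- ifelse(g %in% case_vals, "case", ifelse(g %in% ref_vals, "reference", NA))
  if (anyNA(out)) {
    abort(paste0("record error: unrecognized group label(s): ",
                 paste(unique(g[is.na(out)]), collapse = ", ")))
  }
  out
}

normalize_stage <- function(s) {
  s <- toupper(trimws(as.character(s)))
  s[s %in% c("", "NA", "NONE")] <- NA
  s[s %in% c("1", "2", "3", "4")] <- c("I", "II", "III", "IV")[
    match(s[s %in% c("1", "2", "3", "4")], c("1", "2", "3", "4"))]
  m <- regmatches(s, regexpr("^(IV|III|II|I)", s))
  out <- rep(NA_character_, length(s))
  has <- !is.na(s) & grepl("^(IV|III|II|I)", s)
  out[has] <- m
  bad <- !is.na(s) & !has
  if (any(bad)) {
    abort(paste0("record error: unrecognized stage label(s): ",
                 paste(unique(s[bad]), collapse = ", ")))
  }
  out
}

validate_cohort <- function(tbl) {
  if (anyDuplicated(tbl$subject_id)) {
    abort("format error: duplicate subject_id")
  }
  is_case <- tbl$group == "case"
  if (any(is_case & is.na(tbl$stage))) {
    abort(sprintf("record error: case(s) without tumor stage: %s",
                  paste(tbl$subject_id[is_case & is.na(tbl$stage)], collapse = ", ")))
  }
  # stage IV <=> M1 for cases; fill m_status where absent
  derived <- ifelse(is_case, ifelse(tbl$stage == "IV", "M1", "M0"), "none")
  have <- !is.na(tbl$m_status) & tbl$m_status != ""
  clash <- have & is_case & tbl$m_status != derived
  if (any(clash)) {
    abort(sprintf("record error: stage/m_status inconsistent for: %s",
                  paste(tbl$subject_id[clash], collapse = ", ")))
  }
  tbl$m_status <- derived
  tbl$stage[!is_case] <- "none"
  tbl
}

#' Tabulate a categorical variable with percentages
#'
#' Counts each value of `var` and reports its share of the rows as a
#' percentage rounded to `digits` decimals, the convention used in clinical
#' cohort characteristic tables.
#'
#' @param df A data frame (e.g. a cohort table, or one group of it).
#' @param var Column to tabulate (tidy-eval).
#' @param digits Decimal places for the percentage.
#' @return A tibble with `value`, `n`, `pct`.
#' @examples
#' tally_pct(data.frame(g = c("a", "a", "b")), g)
#' @export
tally_pct <- function(df, var, digits = 1) {
  var <- enquo(var)
  df |>
    group_by(value = !!var) |>
    summarise(n = n(), .groups = "drop") |>
    mutate(pct = round(100 * .data$n / sum(.data$n), digits)) |>
    arrange(dplyr::desc(.data$n))
}

#' Summarise a cohort by group
#'
#' @param cohort A cohort tibble.
#' @return One row per group with subject count, percentage of the cohort, and
#'   mean/sd of age and BMI.
#' @export
cohort_summary <- function(cohort) {
  cohort |>
    group_by(.data$group) |>
    summarise(n = n(),
              age_mean = mean(.data$age), age_sd = sd(.data$age),
              bmi_mean = mean(.data$bmi), bmi_sd = sd(.data$bmi),
              .groups = "drop") |>
    mutate(pct = round(100 * .data$n / sum(.data$n), 1))
}
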