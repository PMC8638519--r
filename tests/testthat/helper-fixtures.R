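# Shared fixture builders: everything is generated in code at test time.

# Build a spectrum_set from a matrix of absorbances (rows = spectra).
make_set <- function(m, wn, ids = sprintf("s%d", seq_len(nrow(m))),
                     roles = "case") {
  df <- tibble::as_tibble(m, .name_repair = "minimal")
  names(df) <- as.character(wn)
  df <- dplyr::bind_cols(tibble::tibble(sample_id = ids, role = roles), df)
  as_spectrum_set(df)
}

# Subset a spectrum_set by role, preserving the class.
pick_role <- function(ss, what) {
  out <- ss[ss$role == what, ]
  class(out) <- class(ss)
  out
}

# Subset a spectrum_set by sample_id, preserving the class.
pick_ids <- function(ss, ids) {
  out <- ss[ss$sample_id %in% ids, ]
  class(out) <- class(ss)
  out
}

# A small cohort table with exact covariate values.
make_cohort <- function(ids, age, bmi, group, stage = NULL) {
  tibble::tibble(
    subject_id = ids, age = age, bmi = bmi, sex = "female", group = group,
    stage = if (is.null(stage)) ifelse(group == "case", "II", "none") else stage,
    m_status = ifelse(group == "case",
                      ifelse((if (is.null(stage)) "II" else stage) == "IV", "M1", "M0"),
                      "none"))
}

# Independent oracle: Mann-Whitney U and AUC by explicit pair counting.
brute_force_auc <- function(cases, refs) {
  u <- 0
  for (x in cases) for (y in refs) {
    u <- u + if (x > y) 1 else if (x == y) 0.5 else 0
  }
  list(U = u, auc = u / (length(cases) * length(refs)))
}
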