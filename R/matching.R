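#' Standardize covariates to pooled z-scores
#'
#' Converts the given covariates to z-scores using the pooled mean and
#' standard deviation (n-1 denominator) of all rows supplied, so that cases
#' and candidate controls are standardized on a common scale before distance
#' computations.
#'
#' @param cohort A cohort tibble (typically cases and candidates bound
#'   together).
#' @param covariates Character vector of numeric covariate columns.
#' @return `cohort` with the covariate columns replaced by their z-scores.
#' @export
standardize_covariates <- function(cohort, covariates = c("age", "bmi")) {
  missing_cov <- setdiff(covariates, names(cohort))
  if (length(missing_cov)) {
    abort(paste0("covariate(s) not in table: ", paste(missing_cov, collapse = ", ")))
  }
  for (v in covariates) {
    x <- cohort[[v]]
    if (!is.numeric(x)) abort(sprintf("covariate `%s` is not numeric", v))
    s <- sd(x)
    if (!is.finite(s) || s == 0) {
      abort(sprintf("covariate `%s` has zero variance; cannot standardize", v))
    }
    cohort[[v]] <- (x - mean(x)) / s
  }
  cohort
}

#' Pairwise case-control matching on covariates
#'
#' Selects one control per case from a candidate pool by 1:1 nearest-neighbour
#' matching without replacement in standardized Euclidean covariate space.
#' Cases are processed in a deterministic order -- descending distance from
#' the candidate centroid (hardest-to-match first), ties broken by
#' `subject_id` -- and each takes its nearest unused candidate (ties broken by
#' the lexicographically lower candidate id). `method = "optimal"` instead
#' minimizes the total matched distance via the assignment problem
#' (requires the clue package).
#'
#' @param cases,candidates Cohort tibbles; `candidates` must have at least as
#'   many rows as `cases`.
#' @param covariates Covariates to match on.
#' @param method `"greedy"` (default) or `"optimal"`.
#' @return A list of class `match_result`: `pairs` (tibble with `case_id`,
#'   `control_id`, `distance` in z-score units), `unmatched_candidates`,
#'   `balance_before` and `balance_after` (see [balance_report()]), and the
#'   matched control cohort `controls`.
#' @export
match_controls <- function(cases, candidates, covariates = c("age", "bmi"),
                           method = c("greedy", "optimal")) {
  method <- arg_match(method)
  if (nrow(candidates) < nrow(cases)) {
    abort(sprintf("need at least as many candidates (%d) as cases (%d)",
                  nrow(candidates), nrow(cases)))
  }
  pooled <- bind_rows(mutate(cases, .which = "case"),
                      mutate(candidates, .which = "candidate"))
  z <- standardize_covariates(pooled, covariates)
  cz <- as.matrix(z[z$.which == "case", covariates, drop = FALSE])
  dz <- as.matrix(z[z$.which == "candidate", covariates, drop = FALSE])
  rownames(cz) <- cases$subject_id
  rownames(dz) <- candidates$subject_id

  sel <- switch(method,
    greedy = greedy_assign(cz, dz),
    optimal = optimal_assign(cz, dz)
  )
  dist <- sqrt(rowSums((cz - dz[sel, , drop = FALSE])^2))
  pairs <- tibble(case_id = rownames(cz), control_id = rownames(dz)[sel],
                  distance = as.numeric(dist))
  controls <- candidates[match(pairs$control_id, candidates$subject_id), ]
  controls$group <- "reference"
  structure(list(
    pairs = pairs,
    unmatched_candidates = setdiff(candidates$subject_id, pairs$control_id),
    balance_before = balance_report(cases, candidates, covariates),
    balance_after = balance_report(cases, controls, covariates),
    controls = controls,
    covariates = covariates, method = method
  ), class = "match_result")
}

# Greedy nearest-neighbour without replacement. Case order: descending
# distance to the candidate centroid, ties by id; candidate ties by lower id.
greedy_assign <- function(cz, dz) {
  centroid <- colMeans(dz)
  d_centroid <- sqrt(rowSums((cz - matrix(centroid, nrow(cz), ncol(cz),
                                          byrow = TRUE))^2))
  case_order <- order(-d_centroid, rownames(cz))
  used <- rep(FALSE, nrow(dz))
  sel <- integer(nrow(cz))
  for (i in case_order) {
    d <- sqrt(rowSums((dz - matrix(cz[i, ], nrow(dz), ncol(dz), byrow = TRUE))^2))
    d[used] <- Inf
    best <- min(d)
    tied <- which(d <= best + 1e-12)
    j <- tied[order(rownames(dz)[tied])[1]]
    used[j] <- TRUE
    sel[i] <- j
  }
  sel
}

# Optimal 1:1 assignment minimizing total distance (rectangular LSAP).
optimal_assign <- function(cz, dz) {
  if (!requireNamespace("clue", quietly = TRUE)) {
    abort("method = \"optimal\" requires the clue package")
  }
  dmat <- matrix(0, nrow(cz), nrow(dz))
  for (i in seq_len(nrow(cz))) {
    dmat[i, ] <- sqrt(rowSums((dz - matrix(cz[i, ], nrow(dz), ncol(dz),
                                           byrow = TRUE))^2))
  }
  as.integer(clue::solve_LSAP(dmat))[seq_len(nrow(cz))]
}

#' Covariate balance between two groups
#'
#' Standardized mean difference per covariate,
#' `SMD = (mean_case - mean_control) / sqrt((sd_case^2 + sd_control^2) / 2)`,
#' with n-1 standard deviations. |SMD| below ~0.1-0.25 is conventionally
#' considered acceptable balance.
#'
#' @param cases,controls Cohort tibbles with at least 2 rows each.
#' @param covariates Covariates to assess.
#' @return A tibble with one row per covariate: group means, sds, and `smd`.
#' @export
balance_report <- function(cases, controls, covariates = c("age", "bmi")) {
  if (nrow(cases) < 2 || nrow(controls) < 2) {
    abort("balance_report needs at least 2 subjects per group")
  }
  purrr::map_dfr(covariates, function(v) {
    a <- cases[[v]]
    b <- controls[[v]]
    if (is.null(a) || is.null(b)) abort(sprintf("covariate `%s` not found", v))
    tibble(covariate = v,
           mean_case = mean(a), sd_case = sd(a),
           mean_control = mean(b), sd_control = sd(b),
           smd = (mean(a) - mean(b)) / sqrt((var(a) + var(b)) / 2))
  })
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result: %d pairs (%s matching on %s)>\n",
              nrow(x$pairs), x$method, paste(x$covariates, collapse = ", ")))
  b <- left_join(select(x$balance_before, "covariate", smd_before = "smd"),
                 select(x$balance_after, "covariate", smd_after = "smd"),
                 by = "covariate")
  print(b)
  invisible(x)
}

#' @export
tidy.match_result <- function(x, ...) x$pairs

#' @export
glance.match_result <- function(x, ...) {
  tibble(n_pairs = nrow(x$pairs),
         n_unmatched = length(x$unmatched_candidates),
         mean_distance = mean(x$pairs$distance),
         max_abs_smd_before = max(abs(x$balance_before$smd)),
         max_abs_smd_after = max(abs(x$balance_after$smd)),
         method = x$method)
}

#' @export
autoplot.match_result <- function(object, ...) {
  b <- bind_rows(mutate(object$balance_before, when = "before"),
                 mutate(object$balance_after, when = "after"))
  b$when <- factor(b$when, levels = c("before", "after"))
  ggplot2::ggplot(b, ggplot2::aes(.data$smd, .data$covariate, colour = .data$when)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "standardized mean difference", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}
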