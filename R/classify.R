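#' Build a labelled feature matrix from spectra and cohort
#'
#' Assembles the classification table: one row per case/reference spectrum
#' (QC and water spectra are excluded), columns `subject_id`, `label`
#' (case = 1, reference = 0) and the retained wavenumbers, rows sorted by
#' `subject_id` for determinism.
#'
#' @param x A preprocessed `spectrum_set`.
#' @param cohort Cohort tibble; every case/reference `sample_id` must resolve
#'   to a `subject_id`.
#' @return A tibble of class `feature_matrix`.
#' @export
build_feature_matrix <- function(x, cohort) {
  stopifnot(is_spectrum_set(x))
  keep <- x$role %in% c("case", "reference")
  ss <- x[keep, ]
  idx <- match(ss$sample_id, cohort$subject_id)
  if (anyNA(idx)) {
    abort(paste0("sample(s) not in cohort: ",
                 paste(ss$sample_id[is.na(idx)], collapse = ", ")))
  }
  lab <- ifelse(cohort$group[idx] == "case", 1L, 0L)
  out <- bind_cols_quiet(
    tibble(subject_id = ss$sample_id, label = lab),
    ss[, spectral_names(ss), drop = FALSE]
  )
  out <- arrange(out, .data$subject_id)
  class(out) <- c("feature_matrix", class(tibble()))
  out
}

feature_cols <- function(fm) spectral_names(fm)

#' Linear-SVM classification under repeated stratified k-fold CV
#'
#' For each of `repeats` seeded repetitions, partitions the samples into `k`
#' stratified folds (per-fold class proportions deviate from the global ones
#' by at most one sample), fits a linear support-vector machine
#' (`e1071::svm`, cost `C`, no internal rescaling) on the training folds, and
#' scores the held-out fold with the signed decision value. Each fold yields
#' an ROC curve and its AUC (the probability that a held-out case scores
#' above a held-out reference). The mean ROC is obtained by vertical
#' averaging of all fold ROCs on a fixed false-positive-rate grid
#' (0 to 1, step 0.01).
#'
#' @param fm A [build_feature_matrix()] table; both classes need at least `k`
#'   members.
#' @param k Number of folds.
#' @param repeats Number of CV repetitions.
#' @param cost SVM regularization parameter C.
#' @param seed Integer seed controlling all fold assignments.
#' @return A list of class `cv_result`: `per_split` (tibble with `rep`,
#'   `fold`, `auc`), `mean_auc`, `sd_auc`, `mean_roc` (tibble `fpr`, `tpr`),
#'   and a `settings` record.
#' @export
repeated_cv_svm <- function(fm, k = 10, repeats = 10, cost = 1, seed = 1) {
  stopifnot(inherits(fm, "feature_matrix"))
  y <- fm$label
  n_by_class <- table(factor(y, levels = c(0, 1)))
  if (any(n_by_class < k)) {
    abort(sprintf("each class needs at least k = %d members (have %s)",
                  k, paste(n_by_class, collapse = "/")))
  }
  X <- as.matrix(fm[, feature_cols(fm), drop = FALSE])
  fpr_grid <- seq(0, 1, by = 0.01)
  set.seed(seed)
  per_split <- vector("list", repeats * k)
  tpr_sum <- numeric(length(fpr_grid))
  s <- 0L
  for (r in seq_len(repeats)) {
    fold <- stratified_folds(y, k)
    for (f in seq_len(k)) {
      test <- which(fold == f)
      fit <- e1071::svm(x = X[-test, , drop = FALSE],
                        y = factor(y[-test], levels = c(0, 1)),
                        kernel = "linear", cost = cost, scale = FALSE)
      scores <- svm_scores(fit, X[test, , drop = FALSE])
      auc <- pair_auc(scores[y[test] == 1], scores[y[test] == 0])
      roc <- roc_points(scores, y[test])
      tpr_sum <- tpr_sum + tpr_at(roc, fpr_grid)
      s <- s + 1L
      per_split[[s]] <- tibble(rep = r, fold = f, auc = auc)
    }
  }
  per_split <- bind_rows(per_split)
  structure(list(
    per_split = per_split,
    mean_auc = mean(per_split$auc),
    sd_auc = sd(per_split$auc),
    mean_roc = tibble(fpr = fpr_grid, tpr = tpr_sum / (repeats * k)),
    settings = list(k = k, repeats = repeats, cost = cost, seed = seed,
                    n_case = unname(n_by_class["1"]),
                    n_reference = unname(n_by_class["0"]),
                    n_features = ncol(X))
  ), class = "cv_result")
}

# Stratified fold labels: within each class, shuffle and deal round-robin.
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    fold[sample(idx)] <- rep(seq_len(k), length.out = length(idx))
  }
  fold
}

# Signed decision values oriented so that higher means class "1".
svm_scores <- function(fit, newx) {
  pr <- stats::predict(fit, newx, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  scores <- dv[, 1]
  if (colnames(dv)[1] == "0/1") scores <- -scores
  unname(scores)
}

# AUC by pair counting with midrank tie handling.
pair_auc <- function(pos, neg) {
  if (!length(pos) || !length(neg)) return(NA_real_)
  r <- rank(c(pos, neg))
  u <- sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2
  u / (length(pos) * length(neg))
}

# Empirical ROC staircase, including the (0,0) and (1,1) endpoints; ties in
# score collapse to a single point.
roc_points <- function(scores, labels) {
  ord <- order(scores, decreasing = TRUE)
  sc <- scores[ord]
  lb <- labels[ord]
  tp <- cumsum(lb == 1)
  fp <- cumsum(lb == 0)
  keep <- !duplicated(sc, fromLast = TRUE)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  tibble(fpr = c(0, fp[keep] / n0), tpr = c(0, tp[keep] / n1))
}

# Step-function (right-continuous) TPR at given FPR values.
tpr_at <- function(roc, fpr_grid) {
  vapply(fpr_grid, function(g) max(roc$tpr[roc$fpr <= g + 1e-12]), 0)
}

#' Summarise a cross-validation result
#'
#' @param r A [repeated_cv_svm()] result.
#' @param normalized Optional flag echoed in the summary so that runs on
#'   vector-normalized and non-normalized spectra are distinguishable.
#' @return A one-row tibble: mean and sd of the per-split AUC distribution,
#'   split count, and settings.
#' @export
summarize_cv <- function(r, normalized = NA) {
  stopifnot(inherits(r, "cv_result"))
  tibble(mean_auc = r$mean_auc, sd_auc = r$sd_auc,
         n_splits = nrow(r$per_split),
         k = r$settings$k, repeats = r$settings$repeats,
         cost = r$settings$cost, seed = r$settings$seed,
         normalized = normalized)
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result: %d-fold x %d repeats, linear SVM (C = %g)>\n",
              x$settings$k, x$settings$repeats, x$settings$cost))
  cat(sprintf("  AUC = %.3f +- %.3f over %d splits (n = %d cases / %d references)\n",
              x$mean_auc, x$sd_auc, nrow(x$per_split),
              x$settings$n_case, x$settings$n_reference))
  invisible(x)
}

#' @export
tidy.cv_result <- function(x, ...) x$per_split

#' @export
glance.cv_result <- function(x, ...) summarize_cv(x)

#' @export
autoplot.cv_result <- function(object, ...) {
  ggplot2::ggplot(object$mean_roc, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_abline(intercept = 0, slope = 1, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = sprintf("Mean ROC (AUC = %.2f ± %.2f)",
                                  object$mean_auc, object$sd_auc)) +
    ggplot2::theme_minimal()
}
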