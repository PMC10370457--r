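# Diagnostic transcript panels, cumulative z-score scoring, ROC
# evaluation, and mutual-exclusivity correlation.

#' Panel selection criteria
#'
#' @param expr_floor TPM floor above which a feature counts as expressed
#'   (default 0.5, inclusive).
#' @param min_recurrence Minimum expressed fraction in the positive class
#'   of every positive cohort (default 0.5).
#' @param max_negative Maximum tolerated expressed fraction in each
#'   negative class (default 0.01).
#' @return A named list of class `panel_criteria`.
#' @export
panel_criteria <- function(expr_floor = 0.5, min_recurrence = 0.5,
                           max_negative = 0.01) {
  stopifnot(expr_floor > 0, min_recurrence >= 0, min_recurrence <= 1,
            max_negative >= 0, max_negative <= 1)
  structure(list(expr_floor = expr_floor, min_recurrence = min_recurrence,
                 max_negative = max_negative), class = "panel_criteria")
}

#' Define a diagnostic transcript panel
#'
#' Keeps features whose expressed fraction (TPM at or above the floor) is
#' at least `min_recurrence` in the positive class of every cohort, and at
#' most `max_negative` in every listed negative class. Adding negative
#' classes (e.g. the precursor condition for a stricter sub-panel) can only
#' shrink the panel.
#'
#' @param expr Wide expression tibble (TPM).
#' @param meta Metadata tibble with `sample_id`, `cohort`, `condition`.
#' @param positive_condition Condition label of the positive class.
#' @param negative_conditions Character vector of negative condition
#'   labels.
#' @param criteria A [panel_criteria()] object.
#' @return An object of class `rte_panel`: tibble `feature_id` plus the
#'   per-cohort positive fractions and the max negative fraction, with the
#'   criteria attached.
#' @export
define_panel <- function(expr, meta, positive_condition, negative_conditions,
                         criteria = panel_criteria()) {
  assert_columns(meta, c("sample_id", "cohort", "condition"), "meta")
  m <- expr_matrix(expr)
  pos <- dplyr::filter(meta, .data$condition == positive_condition,
                       .data$sample_id %in% colnames(m))
  if (nrow(pos) == 0) stop_retrotx("no positive samples")
  pos_frac <- pos |>
    dplyr::group_by(.data$cohort) |>
    dplyr::group_map(function(d, key) {
      rowMeans(m[, d$sample_id, drop = FALSE] >= criteria$expr_floor)
    })
  pos_min <- do.call(pmin, pos_frac)
  neg_frac <- vapply(negative_conditions, function(cond) {
    ss <- intersect(meta$sample_id[meta$condition == cond], colnames(m))
    if (length(ss) == 0) stop_retrotx("no samples for negative class %s", cond)
    rowMeans(m[, ss, drop = FALSE] >= criteria$expr_floor)
  }, numeric(nrow(m)))
  neg_max <- if (length(negative_conditions) == 0) rep(0, nrow(m)) else
    apply(cbind(neg_frac), 1, max)
  keep <- pos_min >= criteria$min_recurrence & neg_max <= criteria$max_negative
  if (!any(keep)) rlang::warn("panel is empty under the given criteria")
  out <- tibble::tibble(feature_id = rownames(m)[keep],
                        min_positive_fraction = unname(pos_min[keep]),
                        max_negative_fraction = unname(neg_max[keep]))
  structure(out, class = c("rte_panel", class(out)), criteria = criteria,
            positive_condition = positive_condition,
            negative_conditions = negative_conditions)
}

#' Cumulative z-score of a transcript panel
#'
#' Per panel feature, `z = (value - mean) / sd` with mean and sd computed
#' over all scored samples (or taken from a reference table); the sample
#' score is the sum of z over panel features. Zero-variance features are
#' dropped with a warning before scoring.
#'
#' @param expr Wide expression tibble.
#' @param panel An `rte_panel`, or a character vector of feature ids, or a
#'   tibble with `feature_id` and optional `mean`/`sd` reference columns
#'   (reference-set mode: normalisation parameters fixed externally rather
#'   than re-estimated on the scored samples).
#' @return Tibble `sample_id`, `score`.
#' @export
score_samples <- function(expr, panel) {
  if (is.character(panel)) panel <- tibble::tibble(feature_id = panel)
  assert_columns(panel, "feature_id", "panel")
  m <- expr_matrix(expr)
  miss <- setdiff(panel$feature_id, rownames(m))
  if (length(miss) > 0) stop_retrotx("panel feature(s) absent from matrix: %s",
                                     paste(miss, collapse = ", "))
  sub <- m[panel$feature_id, , drop = FALSE]
  if (all(c("mean", "sd") %in% names(panel)) &&
      !anyNA(panel$mean) && !anyNA(panel$sd)) {
    mu <- panel$mean
    sdev <- panel$sd
  } else {
    mu <- row_means(sub)
    sdev <- sqrt(row_vars(sub))
  }
  keep <- sdev > 0
  if (!any(keep)) stop_retrotx("all panel features have zero variance")
  if (any(!keep)) {
    rlang::warn(sprintf("dropping %d zero-variance panel feature(s)", sum(!keep)))
  }
  z <- (sub[keep, , drop = FALSE] - mu[keep]) / sdev[keep]
  tibble::tibble(sample_id = colnames(m), score = unname(colSums(z)))
}

#' ROC curve, AUC and Youden operating point
#'
#' AUC is computed by the rank statistic with tie correction (the
#' probability that a random positive scores above a random negative, ties
#' counting one half). Sensitivity/specificity are evaluated at every
#' distinct score used as a `>=` threshold; the operating point maximises
#' Youden's J (`sens + spec - 1`), ties broken toward higher specificity.
#'
#' @param scores Numeric vector, or tibble with `score` column from
#'   [score_samples()].
#' @param labels Logical or 0/1 vector: `TRUE`/1 for the positive class.
#' @return Object of class `rte_roc`: list with `curve` (tibble
#'   `threshold`, `sensitivity`, `specificity`), `auc`, and
#'   `operating_point` (one-row tibble).
#' @export
roc_curve <- function(scores, labels) {
  if (is.data.frame(scores)) scores <- scores$score
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) stop_retrotx("scores/labels length mismatch")
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stop_retrotx("both classes must be present")
  r <- rank(scores)
  auc <- (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- sort(unique(scores), decreasing = TRUE)
  sens <- vapply(thr, function(t) sum(scores >= t & labels) / n1, 0)
  spec <- vapply(thr, function(t) sum(scores < t & !labels) / n0, 0)
  curve <- tibble::tibble(threshold = thr, sensitivity = sens, specificity = spec)
  j <- sens + spec - 1
  best <- which(j == max(j))
  best <- best[which.max(spec[best])]
  structure(list(curve = curve, auc = auc,
                 operating_point = curve[best, ],
                 n_positive = n1, n_negative = n0),
            class = "rte_roc")
}

#' @export
print.rte_roc <- function(x, ...) {
  op <- x$operating_point
  cat(sprintf(paste0("<rte_roc> AUC = %.4f (%d pos / %d neg)\n",
                     "  operating point: threshold %.4g, sensitivity %.1f%%, ",
                     "specificity %.1f%%\n"),
              x$auc, x$n_positive, x$n_negative,
              op$threshold, 100 * op$sensitivity, 100 * op$specificity))
  invisible(x)
}

#' Pairwise expression correlation (mutual exclusivity)
#'
#' Spearman correlation matrix of the given features across samples.
#' Mutually exclusive expression shows as negative coefficients. Constant
#' features are excluded with a warning and reported in the
#' `excluded` attribute.
#'
#' @param expr Wide expression tibble.
#' @param feature_ids At least two feature ids present in `expr`.
#' @return Correlation matrix with an `excluded` attribute.
#' @export
mutual_exclusivity <- function(expr, feature_ids) {
  m <- expr_matrix(expr)
  if (ncol(m) < 3) stop_retrotx("need >= 3 samples")
  if (length(feature_ids) < 2) stop_retrotx("need >= 2 features")
  miss <- setdiff(feature_ids, rownames(m))
  if (length(miss) > 0) stop_retrotx("unknown feature(s): %s", paste(miss, collapse = ","))
  sub <- m[feature_ids, , drop = FALSE]
  const <- apply(sub, 1, function(x) stats::sd(x) == 0)
  if (any(const)) {
    rlang::warn(sprintf("excluding %d constant feature(s)", sum(const)))
  }
  sub <- sub[!const, , drop = FALSE]
  if (nrow(sub) < 2) stop_retrotx("fewer than 2 non-constant features")
  cm <- stats::cor(t(sub), method = "spearman")
  attr(cm, "excluded") <- feature_ids[const]
  cm
}
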