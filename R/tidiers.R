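# broom-style tidiers for the package's result objects.

#' @rdname tidiers
#' @param x A retrotx result object.
#' @param ... Unused.
#' @export
tidy.rte_roc <- function(x, ...) x$curve

#' @rdname tidiers
#' @export
glance.rte_roc <- function(x, ...) {
  op <- x$operating_point
  tibble::tibble(auc = x$auc, threshold = op$threshold,
                 sensitivity = op$sensitivity, specificity = op$specificity,
                 n_positive = x$n_positive, n_negative = x$n_negative)
}

#' Tidiers for retrotx results
#'
#' [generics::tidy()] returns the per-observation table of a result
#' (ROC curve points, per-feature selection rows, per-sample distances);
#' [generics::glance()] returns a one-row summary.
#'
#' @name tidiers
#' @rdname tidiers
#' @export
tidy.rte_selection <- function(x, ...) tibble::as_tibble(x)

#' @rdname tidiers
#' @export
glance.rte_selection <- function(x, ...) {
  th <- attr(x, "thresholds")
  tibble::tibble(n_features = nrow(x), n_selected = sum(x$selected),
                 cancer_condition = attr(x, "cancer_condition"),
                 cancer_median_min = th$cancer_median_min, fold = th$fold,
                 healthy_abs_max = th$healthy_abs_max)
}

#' @rdname tidiers
#' @export
tidy.rte_surv_screen <- function(x, ...) tibble::as_tibble(x)

#' @rdname tidiers
#' @export
glance.rte_surv_screen <- function(x, ...) {
  tibble::tibble(n_features = dplyr::n_distinct(x$feature_id),
                 n_cohorts = dplyr::n_distinct(x$cohort),
                 n_estimable = sum(x$estimable))
}

#' @rdname tidiers
#' @export
tidy.rte_be_distance <- function(x, ...) x$distances

#' @rdname tidiers
#' @export
glance.rte_be_distance <- function(x, ...) {
  med <- tapply(x$distances$distance, x$distances$subtype, stats::median)
  tibble::tibble(p = x$p, n_genes = x$n_genes,
                 median_high = unname(med["high"]),
                 median_low = unname(med["low"]))
}

#' @rdname tidiers
#' @export
tidy.rte_pfm <- function(x, ...) {
  m <- unclass(x)
  tibble::as_tibble(m, rownames = "base") |>
    tidyr::pivot_longer(-"base", names_to = "position", values_to = "count") |>
    dplyr::mutate(position = as.integer(sub("^V", "", .data$position)),
                  frequency = .data$count / attr(x, "n_sequences"))
}
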