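# Transcriptome complexity, the cancer-overexpression selection filter,
# differential repeat expression, subfamily enrichment and the
# copy-number bias diagnostic.

#' Per-sample transcriptome complexity
#'
#' Number of features expressed at or above `threshold` TPM in each sample
#' (inclusive boundary), an indirect measure of transcriptome complexity.
#'
#' @param expr Wide expression tibble: `feature_id` plus one numeric column
#'   per sample (TPM).
#' @param threshold Expression floor in TPM (default 0.5).
#' @return Tibble `sample_id`, `n_expressed`.
#' @export
transcriptome_complexity <- function(expr, threshold = 0.5) {
  m <- expr_matrix(expr)
  tibble::tibble(sample_id = colnames(m),
                 n_expressed = unname(colSums(m >= threshold)))
}

#' Selection thresholds for the overexpression filter
#'
#' The numeric cut-offs of the cancer-overexpression filter as explicit
#' configuration: cancer median must exceed `cancer_median_min` TPM; the
#' healthy reference `H` (see [select_overexpressed()]) must satisfy
#' `fold * H <=` the cancer `cancer_percentile`-th percentile and
#' `H < healthy_abs_max` TPM.
#'
#' @param expr_floor Expression floor in TPM used elsewhere (default 0.5).
#' @param cancer_median_min Minimum cancer median TPM (default 0.5, strict).
#' @param fold Required fold separation (default 3).
#' @param healthy_percentile Healthy percentile for the matched tissue
#'   (default 90).
#' @param cancer_percentile Cancer percentile compared against (default 75).
#' @param healthy_abs_max Absolute healthy ceiling in TPM (default 0.5).
#' @return A named list of class `selection_thresholds`.
#' @export
selection_thresholds <- function(expr_floor = 0.5, cancer_median_min = 0.5,
                                 fold = 3, healthy_percentile = 90,
                                 cancer_percentile = 75, healthy_abs_max = 0.5) {
  stopifnot(expr_floor > 0, cancer_median_min > 0, fold > 0,
            healthy_percentile > 0, healthy_percentile < 100,
            cancer_percentile > 0, cancer_percentile < 100,
            healthy_abs_max > 0)
  structure(list(expr_floor = expr_floor, cancer_median_min = cancer_median_min,
                 fold = fold, healthy_percentile = healthy_percentile,
                 cancer_percentile = cancer_percentile,
                 healthy_abs_max = healthy_abs_max),
            class = "selection_thresholds")
}

#' Infer healthy-tissue condition labels from metadata
#'
#' Healthy tissues are metadata conditions with no matched tissue that are
#' not the precursor (`"BE"`) label. Used as the default healthy set by
#' [select_overexpressed()] and as negative classes for panel definition.
#'
#' @param meta Metadata tibble with `condition` and `matched_tissue`.
#' @return Character vector of condition labels.
#' @export
infer_healthy_conditions <- function(meta) {
  unique(meta$condition[is.na(meta$matched_tissue) & meta$condition != "BE"])
}

#' Select cancer-overexpressed features
#'
#' Per feature, computes `mC` (median TPM over the target cancer samples),
#' `q75C` (the cancer percentile from `thresholds`), and the healthy
#' reference `H = max(matched-tissue healthy percentile, max over healthy
#' tissues of that tissue's median)`. A feature is selected iff
#' `mC > cancer_median_min` and `fold * H <= q75C` and
#' `H < healthy_abs_max`. Percentiles use linear interpolation between
#' order statistics (R quantile type 7).
#'
#' @param expr Wide expression tibble (TPM).
#' @param meta Sample metadata tibble with columns `sample_id`,
#'   `condition`, `matched_tissue` (NA for non-cancer rows).
#' @param cancer_condition Condition label of the target cancer.
#' @param thresholds A [selection_thresholds()] object.
#' @param healthy_conditions Healthy tissue labels; by default inferred as
#'   conditions with no matched tissue that are not `"BE"`.
#' @param healthy_rule `"conjunctive"` (default: both healthy conditions
#'   applied to `H = max(...)`) or `"disjunctive"` (either the matched
#'   percentile or the max median may satisfy the fold and ceiling rules).
#' @return An object of class `rte_selection`: the per-feature table with
#'   `feature_id`, `cancer_median`, `cancer_q`, `healthy_ref`, `selected`.
#' @export
select_overexpressed <- function(expr, meta, cancer_condition,
                                 thresholds = selection_thresholds(),
                                 healthy_conditions = NULL,
                                 healthy_rule = c("conjunctive", "disjunctive")) {
  healthy_rule <- match.arg(healthy_rule)
  assert_columns(meta, c("sample_id", "condition", "matched_tissue"), "meta")
  m <- expr_matrix(expr)
  if (nrow(m) == 0) {
    return(structure(tibble::tibble(feature_id = character(),
                                    cancer_median = double(), cancer_q = double(),
                                    healthy_ref = double(), selected = logical()),
                     class = c("rte_selection", "tbl_df", "tbl", "data.frame"),
                     thresholds = thresholds, cancer_condition = cancer_condition))
  }
  healthy_conditions <- healthy_conditions %||% infer_healthy_conditions(meta)
  cancer_samples <- meta$sample_id[meta$condition == cancer_condition]
  if (length(cancer_samples) == 0) stop_retrotx("no samples with condition %s", cancer_condition)
  matched <- unique(stats::na.omit(meta$matched_tissue[meta$condition == cancer_condition]))
  if (length(matched) == 0) {
    stop_retrotx("no matched healthy tissue defined for cancer type %s", cancer_condition)
  }
  matched_samples <- meta$sample_id[meta$condition %in% matched]
  if (length(matched_samples) == 0) {
    stop_retrotx("no samples for matched healthy tissue %s", paste(matched, collapse = ","))
  }
  cancer_samples <- intersect(cancer_samples, colnames(m))
  matched_samples <- intersect(matched_samples, colnames(m))

  mc <- apply(m[, cancer_samples, drop = FALSE], 1, stats::median)
  qc <- apply(m[, cancer_samples, drop = FALSE], 1,
              stats::quantile, probs = thresholds$cancer_percentile / 100,
              names = FALSE)
  h_pct <- apply(m[, matched_samples, drop = FALSE], 1,
                 stats::quantile, probs = thresholds$healthy_percentile / 100,
                 names = FALSE)
  healthy_meds <- vapply(healthy_conditions, function(cond) {
    ss <- intersect(meta$sample_id[meta$condition == cond], colnames(m))
    if (length(ss) == 0) return(rep(NA_real_, nrow(m)))
    apply(m[, ss, drop = FALSE], 1, stats::median)
  }, numeric(nrow(m)))
  max_med <- if (length(healthy_conditions) == 0) rep(0, nrow(m)) else
    apply(cbind(healthy_meds), 1, max, na.rm = TRUE)

  if (healthy_rule == "conjunctive") {
    h <- pmax(h_pct, max_med)
    ok_h <- thresholds$fold * h <= qc & h < thresholds$healthy_abs_max
  } else {
    ok1 <- thresholds$fold * h_pct <= qc & h_pct < thresholds$healthy_abs_max
    ok2 <- thresholds$fold * max_med <= qc & max_med < thresholds$healthy_abs_max
    h <- pmin(h_pct, max_med)
    ok_h <- ok1 | ok2
  }
  out <- tibble::tibble(
    feature_id = rownames(m),
    cancer_median = unname(mc),
    cancer_q = unname(qc),
    healthy_ref = unname(h),
    selected = unname(mc > thresholds$cancer_median_min & ok_h)
  )
  structure(out, class = c("rte_selection", class(out)),
            thresholds = thresholds, cancer_condition = cancer_condition)
}

#' Selected feature ids from a selection table
#'
#' @param selection An `rte_selection` object.
#' @return Character vector of selected feature ids.
#' @export
selected_features <- function(selection) {
  selection$feature_id[selection$selected]
}

#' Differential repeat expression between two groups
#'
#' Fold-change on group means of TPM (pseudocount 0.1 on each mean) and a
#' two-sided Welch t-test on `log2(TPM + 0.1)`, with Benjamini-Hochberg
#' correction over tested features. A feature passes iff its fold-change
#' exceeds `fold_min` in either direction (strict), `p < alpha` and
#' `q < alpha`. Features with zero variance in both groups get `p = 1` and
#' are flagged.
#'
#' @param expr Wide expression tibble (TPM).
#' @param group_a,group_b Character vectors of sample ids.
#' @param fold_min Fold-change threshold (default 6, strict `>`).
#' @param alpha Significance level for both p and q (default 0.05).
#' @return Tibble `feature_id`, `log2_fc`, `fold`, `p`, `q`,
#'   `zero_variance`, `pass`.
#' @export
differential_repeat_expression <- function(expr, group_a, group_b,
                                           fold_min = 6, alpha = 0.05) {
  m <- expr_matrix(expr)
  miss <- setdiff(c(group_a, group_b), colnames(m))
  if (length(miss) > 0) stop_retrotx("unknown sample(s): %s", paste(miss, collapse = ","))
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop_retrotx("need at least 2 samples per group")
  }
  a <- m[, group_a, drop = FALSE]
  b <- m[, group_b, drop = FALSE]
  fold <- unname((row_means(a) + 0.1) / (row_means(b) + 0.1))
  tt <- row_welch(log2p(a), log2p(b))
  q <- bh_adjust(tt$p)
  tibble::tibble(
    feature_id = rownames(m),
    log2_fc = log2(fold),
    fold = fold,
    p = tt$p,
    q = q,
    zero_variance = tt$zero_variance,
    pass = (fold > fold_min | fold < 1 / fold_min) & tt$p < alpha & q < alpha
  )
}

#' Repeat-subfamily enrichment among selected transcripts
#'
#' For each subfamily, a 2x2 table of transcripts overlapping that
#' subfamily versus not, in the selection versus the rest of the
#' background, tested with a two-sided Fisher exact test; the sample odds
#' ratio uses the Haldane 0.5 correction when any cell is zero.
#' Benjamini-Hochberg correction is applied across subfamilies.
#'
#' @param selected Character vector of selected transcript ids (subset of
#'   `background`).
#' @param background Character vector of all transcript ids.
#' @param membership Tibble `transcript_id`, `subfamily` (one row per
#'   overlap; from [rte_group_content()] subfamily sets, unnested).
#' @return Tibble `subfamily`, `a`, `b`, `c`, `d`, `odds_ratio`, `p`, `q`.
#' @export
subfamily_enrichment <- function(selected, background, membership) {
  if (!all(selected %in% background)) {
    stop_retrotx("selected ids must be a subset of the background")
  }
  assert_columns(membership, c("transcript_id", "subfamily"), "membership")
  membership <- dplyr::distinct(membership)
  pre <- unique(membership$subfamily)
  membership <- dplyr::filter(membership, .data$transcript_id %in% background)
  dropped <- setdiff(pre, unique(membership$subfamily))
  if (length(dropped) > 0) {
    rlang::warn(paste0("subfamilies absent from background skipped: ",
                       paste(dropped, collapse = ", ")))
  }
  n_sel <- length(unique(selected))
  n_rest <- length(unique(background)) - n_sel
  res <- membership |>
    dplyr::group_by(.data$subfamily) |>
    dplyr::summarise(
      a = sum(unique(.data$transcript_id) %in% selected),
      c = dplyr::n_distinct(.data$transcript_id) - sum(unique(.data$transcript_id) %in% selected),
      .groups = "drop") |>
    dplyr::mutate(b = n_sel - .data$a, d = n_rest - .data$c)
  if (nrow(res) == 0) {
    rlang::warn("no subfamily present in background; empty enrichment")
    return(tibble::tibble(subfamily = character(), a = integer(), b = integer(),
                          c = integer(), d = integer(), odds_ratio = double(),
                          p = double(), q = double()))
  }
  res <- res |>
    dplyr::mutate(
      p = purrr::pmap_dbl(list(.data$a, .data$b, .data$c, .data$d),
                          function(a, b, c, d) {
                            stats::fisher.test(matrix(c(a, b, c, d), 2,
                                                      byrow = TRUE))$p.value
                          }),
      odds_ratio = purrr::pmap_dbl(list(.data$a, .data$b, .data$c, .data$d),
                                   function(a, b, c, d) {
                                     if (min(a, b, c, d) == 0) {
                                       a <- a + 0.5; b <- b + 0.5
                                       c <- c + 0.5; d <- d + 0.5
                                     }
                                     (a * d) / (b * c)
                                   }),
      q = bh_adjust(.data$p)
    ) |>
    dplyr::select("subfamily", "a", "b", "c", "d", "odds_ratio", "p", "q") |>
    dplyr::arrange(.data$p, .data$subfamily)
  res
}

#' Copy-number bias of subfamily enrichment
#'
#' Spearman rank correlation between a subfamily's genomic copy number and
#' the log of its enrichment odds ratio, quantifying how much apparent
#' enrichment tracks sheer copy number.
#'
#' @param enrichment Tibble from [subfamily_enrichment()].
#' @param copy_number Tibble `subfamily`, `copies`.
#' @return One-row tibble `rho`, `p`, `n`.
#' @export
copy_number_bias <- function(enrichment, copy_number) {
  assert_columns(copy_number, c("subfamily", "copies"), "copy_number")
  d <- dplyr::inner_join(enrichment, copy_number, by = "subfamily") |>
    dplyr::filter(is.finite(log(.data$odds_ratio)), is.finite(.data$copies))
  if (nrow(d) < 3) stop_retrotx("need >= 3 subfamilies with finite odds ratios")
  if (stats::sd(d$copies) == 0 || stats::sd(log(d$odds_ratio)) == 0) {
    stop_retrotx("undefined correlation: constant input vector")
  }
  ct <- suppressWarnings(
    stats::cor.test(d$copies, log(d$odds_ratio), method = "spearman"))
  tibble::tibble(rho = unname(ct$estimate), p = ct$p.value, n = nrow(d))
}
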