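# Gene-level exon- and intron-collapsed quantitation, exon-intron
# correlation, and exon/intron ratio group tests.

#' Collapse interval-level quantification to gene level
#'
#' Sums interval values per gene and layer, separately for the exon-union
#' and intron layers: per gene and sample, `exon_value` is the sum over
#' exon intervals and `intron_value` the sum over intron intervals (zero
#' for genes without intron intervals). Intervals with a missing gene
#' assignment are summed into a reported `unassigned` attribute rather
#' than dropped silently.
#'
#' @param intervals Tibble: `interval_id`, `gene_id`, `layer`
#'   (`"exon"`/`"intron"`), plus one numeric column per sample.
#' @return Long tibble `gene_id`, `sample_id`, `exon_value`,
#'   `intron_value`, with attribute `unassigned` (named numeric per
#'   sample).
#' @export
collapse_gene_counts <- function(intervals) {
  assert_columns(intervals, c("interval_id", "gene_id", "layer"), "intervals")
  bad_layer <- setdiff(unique(intervals$layer), c("exon", "intron"))
  if (length(bad_layer) > 0) stop_retrotx("unknown layer(s): %s",
                                          paste(bad_layer, collapse = ","))
  sample_cols <- setdiff(names(intervals), c("interval_id", "gene_id", "layer"))
  if (length(sample_cols) == 0) stop_retrotx("no sample columns")
  unassigned_rows <- is.na(intervals$gene_id) | intervals$gene_id == ""
  unassigned <- colSums(intervals[unassigned_rows, sample_cols, drop = FALSE])
  long <- intervals[!unassigned_rows, ] |>
    tidyr::pivot_longer(dplyr::all_of(sample_cols), names_to = "sample_id",
                        values_to = "value") |>
    dplyr::group_by(.data$gene_id, .data$sample_id, .data$layer) |>
    dplyr::summarise(value = sum(.data$value), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "layer", values_from = "value",
                       values_fill = 0)
  if (!"exon" %in% names(long)) long$exon <- 0
  if (!"intron" %in% names(long)) long$intron <- 0
  out <- long |>
    dplyr::rename(exon_value = "exon", intron_value = "intron") |>
    dplyr::arrange(.data$gene_id, .data$sample_id)
  attr(out, "unassigned") <- unassigned
  out
}

#' Exon-intron expression correlation within a sample
#'
#' Pearson correlation of `log2(exon_value + 1)` versus
#' `log2(intron_value + 1)` across genes for one sample.
#'
#' @param split Gene-level split tibble from [collapse_gene_counts()].
#' @param sample Sample id.
#' @return One-row tibble `sample_id`, `r`, `p`, `n_genes`.
#' @export
exon_intron_correlation <- function(split, sample) {
  d <- dplyr::filter(split, .data$sample_id == sample)
  if (nrow(d) < 3) stop_retrotx("need >= 3 genes for correlation")
  x <- log2(d$exon_value + 1)
  y <- log2(d$intron_value + 1)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop_retrotx("constant layer: correlation undefined")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  tibble::tibble(sample_id = sample, r = unname(ct$estimate), p = ct$p.value,
                 n_genes = nrow(d))
}

#' Exon/intron ratio test between sample groups
#'
#' Per gene and sample, `ratio = log2((exon_value + 1) / (intron_value +
#' 1))`; ratios are compared between the two groups with a two-sided
#' pooled-variance (Student) t-test. Genes without introns have an
#' undefined ratio and are skipped with a note.
#'
#' @param split Gene-level split tibble from [collapse_gene_counts()].
#' @param group_high,group_low Character vectors of sample ids (e.g. the
#'   top and bottom provirus-expression samples).
#' @param intronless Optional character vector of gene ids known to lack
#'   introns; these are skipped.
#' @return Tibble `gene_id`, `mean_high`, `mean_low`, `statistic`, `p`,
#'   with attribute `skipped` (intronless gene ids).
#' @export
exon_intron_ratio_test <- function(split, group_high, group_low,
                                   intronless = character()) {
  if (length(group_high) == 0 || length(group_low) == 0) {
    stop_retrotx("both groups must be non-empty")
  }
  skipped <- intersect(unique(split$gene_id), intronless)
  if (length(skipped) > 0) {
    rlang::inform(sprintf("skipping %d intronless gene(s)", length(skipped)))
  }
  d <- split |>
    dplyr::filter(!.data$gene_id %in% intronless,
                  .data$sample_id %in% c(group_high, group_low)) |>
    dplyr::mutate(
      ratio = log2((.data$exon_value + 1) / (.data$intron_value + 1)),
      group = ifelse(.data$sample_id %in% group_high, "high", "low"))
  out <- d |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::group_map(function(g, key) {
      hi <- g$ratio[g$group == "high"]
      lo <- g$ratio[g$group == "low"]
      res <- student_t(hi, lo)
      tibble::tibble(gene_id = key$gene_id, mean_high = mean(hi),
                     mean_low = mean(lo), statistic = res$t, p = res$p)
    }) |>
    dplyr::bind_rows()
  attr(out, "skipped") <- skipped
  out
}

# Pooled-variance two-sample t; degenerate zero-variance cases resolved by
# whether the means differ.
student_t <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / (nx + ny - 2)
  if (!is.finite(sp2) || sp2 == 0) {
    if (isTRUE(all.equal(mean(x), mean(y)))) return(list(t = 0, p = 1))
    return(list(t = sign(mean(x) - mean(y)) * Inf, p = 0))
  }
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  list(t = t, p = 2 * stats::pt(-abs(t), nx + ny - 2))
}
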