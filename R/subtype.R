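# HERVH-provirus subtype assignment and downstream association analyses.

#' Subtype configuration
#'
#' @param provirus Feature id of the subtype-defining provirus (e.g. the
#'   HERVH element on Chr Xp22.32).
#' @param cutoff TPM cut-off separating high and low expression
#'   (default 1).
#' @param boundary Which side the boundary value falls on: `"high"`
#'   (default: TPM at or above the cutoff is high) or `"low"`.
#' @return Named list of class `subtype_config`.
#' @export
subtype_config <- function(provirus, cutoff = 1, boundary = c("high", "low")) {
  boundary <- match.arg(boundary)
  stopifnot(cutoff > 0)
  structure(list(provirus = provirus, cutoff = cutoff, boundary = boundary),
            class = "subtype_config")
}

#' Assign provirus-expression subtypes
#'
#' Labels each sample `high` when the provirus feature's TPM is at or
#' above the cut-off (under the default boundary rule), else `low`.
#'
#' @param expr Wide expression tibble.
#' @param config A [subtype_config()].
#' @return Tibble `sample_id`, `provirus_tpm`, `subtype`.
#' @export
assign_subtype <- function(expr, config) {
  m <- expr_matrix(expr)
  if (!config$provirus %in% rownames(m)) {
    stop_retrotx("provirus feature %s not in expression table", config$provirus)
  }
  v <- m[config$provirus, ]
  high <- if (config$boundary == "high") v >= config$cutoff else v > config$cutoff
  tibble::tibble(sample_id = colnames(m), provirus_tpm = unname(v),
                 subtype = unname(ifelse(high, "high", "low")))
}

#' Linear association of features with provirus expression
#'
#' Ordinary least-squares of each feature on the response
#' `log2(provirus TPM + 0.1)`: expression features enter as
#' `log2(TPM + 0.1)`, binary driver alterations as 0/1. Two-sided p from
#' the slope's t statistic; Benjamini-Hochberg correction within the
#' declared family. Constant features are skipped with a note.
#'
#' @param features Wide tibble: `feature_id` plus sample columns (TPM for
#'   expression families, 0/1 for drivers).
#' @param provirus_tpm Named numeric vector of provirus TPM per sample (or
#'   tibble `sample_id`, `provirus_tpm` from [assign_subtype()]).
#' @param family Family label recorded in the output (e.g.
#'   `"transcripts"`, `"exon"`, `"intron"`, `"drivers"`).
#' @param log_features Log-transform the feature values (TRUE for
#'   expression, FALSE for binary drivers).
#' @return Tibble `feature_id`, `family`, `slope`, `p`, `q`, `sign`.
#' @export
linear_association <- function(features, provirus_tpm, family,
                               log_features = TRUE) {
  if (is.data.frame(provirus_tpm)) {
    provirus_tpm <- stats::setNames(provirus_tpm$provirus_tpm,
                                    provirus_tpm$sample_id)
  }
  m <- as.matrix(features[setdiff(names(features), "feature_id")])
  rownames(m) <- features$feature_id
  samples <- intersect(colnames(m), names(provirus_tpm))
  if (length(samples) < 10) stop_retrotx("need >= 10 samples with provirus values")
  x <- m[, samples, drop = FALSE]
  if (log_features) x <- log2p(x)
  y <- log2p(provirus_tpm[samples])
  n <- length(y)
  yc <- y - mean(y)
  syy <- sum(yc^2)
  if (syy == 0) stop_retrotx("provirus expression is constant")
  const <- row_vars(x) == 0
  if (any(const)) {
    rlang::inform(sprintf("skipping %d constant feature(s)", sum(const)))
  }
  x <- x[!const, , drop = FALSE]
  xc <- x - row_means(x)
  slope <- as.vector(xc %*% yc) / syy
  rss <- rowSums((xc - outer(slope, yc))^2)
  se <- sqrt(rss / (n - 2) / syy)
  t <- slope / se
  p <- 2 * stats::pt(-abs(t), n - 2)
  p[se == 0] <- 0  # exact linear dependence
  tibble::tibble(feature_id = rownames(x), family = family, slope = slope,
                 p = p, q = bh_adjust(p), sign = sign(slope))
}

#' Differential expression between subtype groups
#'
#' Welch t-test on `log2(TPM + 0.1)` per gene with Benjamini-Hochberg
#' correction; reports the difference of group means on the log2 scale and
#' a `significant` flag at `q < 0.05`.
#'
#' @param expr Wide expression tibble.
#' @param group_high,group_low Character vectors of sample ids.
#' @param q_max Significance threshold on q (default 0.05).
#' @return Tibble `feature_id`, `log2_diff`, `p`, `q`, `significant`.
#' @export
differential_expression <- function(expr, group_high, group_low, q_max = 0.05) {
  m <- expr_matrix(expr)
  if (length(group_high) < 2 || length(group_low) < 2) {
    stop_retrotx("need >= 2 samples per group")
  }
  tt <- row_welch(log2p(m[, group_high, drop = FALSE]),
                  log2p(m[, group_low, drop = FALSE]))
  q <- bh_adjust(tt$p)
  tibble::tibble(feature_id = rownames(m), log2_diff = tt$diff, p = tt$p,
                 q = q, significant = q < q_max)
}

#' Genes with inverse exon/intron response to provirus expression
#'
#' Candidate genes have a significantly positive intron-layer slope and a
#' significantly negative exon-layer slope against provirus expression
#' (both at `q < q_max`). Candidates are then subjected to
#' [exon_intron_ratio_test()] between the `n_extreme` highest- and
#' lowest-provirus samples.
#'
#' @param exon_assoc,intron_assoc Association tibbles from
#'   [linear_association()] on the exon and intron layers.
#' @param split Gene-level split tibble from [collapse_gene_counts()].
#' @param provirus_tpm Named numeric vector (or tibble from
#'   [assign_subtype()]) of provirus TPM per sample.
#' @param n_extreme Samples per extreme group (default 10), ranked by
#'   provirus TPM with ties broken by sample id.
#' @param q_max Significance threshold for the slope gates (default 0.05).
#' @return Tibble: candidate genes with `slope_exon`, `slope_intron`,
#'   `ratio_p` (empty when no gene passes the sign gates).
#' @export
inverse_splicing_genes <- function(exon_assoc, intron_assoc, split,
                                   provirus_tpm, n_extreme = 10,
                                   q_max = 0.05) {
  if (is.data.frame(provirus_tpm)) {
    provirus_tpm <- stats::setNames(provirus_tpm$provirus_tpm,
                                    provirus_tpm$sample_id)
  }
  cand <- dplyr::inner_join(
    dplyr::filter(exon_assoc, .data$slope < 0, .data$q < q_max) |>
      dplyr::select(gene_id = "feature_id", slope_exon = "slope"),
    dplyr::filter(intron_assoc, .data$slope > 0, .data$q < q_max) |>
      dplyr::select(gene_id = "feature_id", slope_intron = "slope"),
    by = "gene_id")
  if (nrow(cand) == 0) {
    return(tibble::tibble(gene_id = character(), slope_exon = double(),
                          slope_intron = double(), mean_high = double(),
                          mean_low = double(), ratio_p = double()))
  }
  ord <- order(provirus_tpm, names(provirus_tpm))
  ids <- names(provirus_tpm)[ord]
  low <- utils::head(ids, n_extreme)
  high <- utils::tail(ids, n_extreme)
  rt <- exon_intron_ratio_test(
    dplyr::filter(split, .data$gene_id %in% cand$gene_id), high, low)
  dplyr::inner_join(cand, dplyr::select(rt, "gene_id", "mean_high",
                                        "mean_low", ratio_p = "p"),
                    by = "gene_id")
}

#' Transcriptional distance from the precursor-condition centroid
#'
#' Selects the `n_variable_genes` most variable genes on
#' `log2(TPM + 0.1)` across all given samples, z-scores each gene, and
#' measures each cancer sample's Euclidean distance to the centroid of the
#' precursor (BE) samples. Distances are compared between the high and low
#' subtype groups with a two-sided Mann-Whitney test.
#'
#' @param expr Wide expression tibble covering cancer and precursor
#'   samples.
#' @param subtypes Tibble `sample_id`, `subtype` for the cancer samples.
#' @param be_samples Character vector of precursor sample ids.
#' @param n_variable_genes Number of top-variance genes (default 500).
#' @return Object of class `rte_be_distance`: list with `distances`
#'   (tibble `sample_id`, `subtype`, `distance`), `p` (Mann-Whitney), and
#'   `n_genes`.
#' @export
be_distance <- function(expr, subtypes, be_samples, n_variable_genes = 500) {
  if (length(be_samples) == 0) stop_retrotx("BE sample set is empty")
  assert_columns(subtypes, c("sample_id", "subtype"), "subtypes")
  m <- log2p(expr_matrix(expr))
  if (n_variable_genes > nrow(m)) {
    stop_retrotx("n_variable_genes (%d) exceeds available genes (%d)",
                 n_variable_genes, nrow(m))
  }
  use <- c(subtypes$sample_id, be_samples)
  miss <- setdiff(use, colnames(m))
  if (length(miss) > 0) stop_retrotx("unknown sample(s): %s", paste(miss, collapse = ","))
  m <- m[, use, drop = FALSE]
  v <- row_vars(m)
  top <- order(v, decreasing = TRUE)[seq_len(n_variable_genes)]
  z <- m[top, , drop = FALSE]
  sdv <- sqrt(row_vars(z))
  keep <- sdv > 0
  z <- (z[keep, , drop = FALSE] - row_means(z)[keep]) / sdv[keep]
  centroid <- rowMeans(z[, be_samples, drop = FALSE])
  dist <- sqrt(colSums((z[, subtypes$sample_id, drop = FALSE] - centroid)^2))
  distances <- tibble::tibble(sample_id = subtypes$sample_id,
                              subtype = subtypes$subtype,
                              distance = unname(dist))
  hi <- distances$distance[distances$subtype == "high"]
  lo <- distances$distance[distances$subtype == "low"]
  p <- if (length(hi) > 0 && length(lo) > 0) {
    suppressWarnings(stats::wilcox.test(hi, lo)$p.value)
  } else NA_real_
  structure(list(distances = distances, p = p, n_genes = sum(keep)),
            class = "rte_be_distance")
}

#' @export
print.rte_be_distance <- function(x, ...) {
  med <- x$distances |>
    dplyr::group_by(.data$subtype) |>
    dplyr::summarise(median = stats::median(.data$distance), .groups = "drop")
  cat(sprintf("<rte_be_distance> %d genes; Mann-Whitney p = %.3g\n",
              x$n_genes, x$p))
  print(med)
  invisible(x)
}
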