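# Repeat-element model: LTR/internal merging and genic flagging.

#' Default LTR-internal pairing table
#'
#' Repeat annotators report the long terminal repeats (LTRs) and the
#' internal region of an endogenous retrovirus as separate rows. Merging
#' them back into one element needs a pairing between internal models and
#' their LTR models. The default rule is: an internal model is any
#' subfamily ending in `-int`; its base name is the subfamily with that
#' suffix stripped; an LTR row is a partner when its subfamily starts with
#' a prefix listed for that base name in the pairing table. The shipped
#' table covers the HERVH/LTR7 relationship; rows can be added for other
#' proviruses.
#'
#' @return Tibble with columns `internal_base` and `ltr_prefix`.
#' @export
ltr_pairing <- function() {
  tibble::tibble(
    internal_base = c("HERVH", "HERVK", "HERVL"),
    ltr_prefix = c("LTR7", "LTR5", "MLT2A")
  )
}

internal_base_of <- function(subfamily) {
  ifelse(grepl("-int$", subfamily), sub("-int$", "", subfamily), NA_character_)
}

# Which internal base (if any) an LTR subfamily partners with.
ltr_partner_base <- function(subfamily, pairing) {
  out <- rep(NA_character_, length(subfamily))
  for (i in seq_len(nrow(pairing))) {
    hit <- startsWith(subfamily, pairing$ltr_prefix[i]) & is.na(out)
    out[hit] <- pairing$internal_base[i]
  }
  out
}

#' Merge adjacent LTR and internal repeat annotations
#'
#' Consecutive same-chromosome, same-strand rows that belong to the same
#' retroviral element (an internal model and its partnered LTR models per
#' the pairing table) and are separated by at most `gap_tolerance` bases
#' are merged into a single element spanning their union. A merged chain
#' must contain at least one internal row; its subfamily becomes the
#' internal model's base name (e.g. `LTR7Y + HERVH-int + LTR7Y` becomes one
#' `HERVH` element). Unpaired rows pass through unchanged. The operation is
#' idempotent.
#'
#' @param repeats Repeat tibble from [read_repeat_table()], sorted by
#'   chrom/start.
#' @param gap_tolerance Maximum gap in bases between mergeable rows
#'   (default 100).
#' @param pairing Pairing table, see [ltr_pairing()].
#' @return Repeat tibble with merged elements.
#' @export
merge_ltr_internal <- function(repeats, gap_tolerance = 100, pairing = ltr_pairing()) {
  if (gap_tolerance < 0) stop_retrotx("gap_tolerance must be non-negative")
  assert_columns(repeats, c("repeat_id", "chrom", "start", "end", "strand",
                            "subfamily", "family", "rte_class"), "repeats")
  repeats <- dplyr::arrange(repeats, .data$chrom, .data$start, .data$repeat_id)
  base <- internal_base_of(repeats$subfamily)
  is_int <- !is.na(base)
  base[!is_int] <- ltr_partner_base(repeats$subfamily[!is_int], pairing)

  n <- nrow(repeats)
  if (n == 0) return(repeats)
  # chain id: grow a chain while the next row shares chrom/strand/base and
  # is within the gap tolerance of the running end.
  chain <- integer(n)
  chain[1] <- 1L
  run_end <- repeats$end[1]
  for (i in seq_len(n)[-1]) {
    same <- !is.na(base[i]) && !is.na(base[i - 1]) &&
      base[i] == base[i - 1] &&
      repeats$chrom[i] == repeats$chrom[i - 1] &&
      repeats$strand[i] == repeats$strand[i - 1] &&
      (repeats$start[i] - run_end) <= gap_tolerance
    chain[i] <- if (same) chain[i - 1] else chain[i - 1] + 1L
    run_end <- if (same) max(run_end, repeats$end[i]) else repeats$end[i]
  }

  repeats |>
    dplyr::mutate(.chain = chain, .base = base, .int = is_int) |>
    dplyr::group_by(.data$.chain) |>
    dplyr::group_map(function(d, key) {
      if (nrow(d) == 1 || !any(d$.int)) {
        dplyr::select(d, -dplyr::starts_with("."))
      } else {
        ref <- d[which(d$.int)[1], ]
        tibble::tibble(
          repeat_id = d$repeat_id[1],
          chrom = d$chrom[1],
          start = min(d$start),
          end = max(d$end),
          strand = d$strand[1],
          subfamily = d$.base[1],
          family = ref$family,
          rte_class = ref$rte_class,
          merged_n = nrow(d)
        )
      }
    }) |>
    dplyr::bind_rows() |>
    dplyr::arrange(.data$chrom, .data$start, .data$repeat_id)
}

#' Flag genic repeats
#'
#' A repeat is genic when it shares at least one base with any annotated
#' gene body (first exon start to last exon end), strand-agnostically;
#' otherwise it is intergenic. A repeat ending exactly where a gene body
#' starts shares zero bases under the half-open convention and is
#' intergenic.
#'
#' @param repeats Repeat tibble.
#' @param genes Gene tibble from [read_gtf()].
#' @return `repeats` with a logical `genic` column.
#' @export
flag_genic_repeats <- function(repeats, genes) {
  assert_columns(repeats, c("chrom", "start", "end"), "repeats")
  assert_columns(genes, c("chrom", "start", "end"), "genes")
  hit <- GenomicRanges::countOverlaps(
    as_granges0(repeats), as_granges0(genes),
    minoverlap = 1L, ignore.strand = TRUE
  ) > 0
  dplyr::mutate(repeats, genic = hit)
}

#' Bundle the three annotation layers
#'
#' Convenience container holding genes, repeats and contigs checked for
#' internal consistency (unique ids, valid intervals).
#'
#' @param genes,repeats,contigs The three annotation tibbles.
#' @return A list of class `rte_annotation` with elements `genes`,
#'   `repeats`, `contigs`.
#' @export
annotation_bundle <- function(genes, repeats, contigs) {
  for (nm in c("genes", "repeats", "contigs")) {
    d <- get(nm)
    if (any(d$start >= d$end)) stop_retrotx("%s: empty or inverted interval", nm)
  }
  if (anyDuplicated(genes$gene_id)) stop_retrotx("duplicate gene_id")
  if (anyDuplicated(repeats$repeat_id)) stop_retrotx("duplicate repeat_id")
  if (anyDuplicated(contigs$transcript_id)) stop_retrotx("duplicate transcript_id")
  structure(list(genes = genes, repeats = repeats, contigs = contigs),
            class = "rte_annotation")
}

#' @export
print.rte_annotation <- function(x, ...) {
  cat(sprintf("<rte_annotation> %d genes, %d repeats, %d contigs\n",
              nrow(x$genes), nrow(x$repeats), nrow(x$contigs)))
  invisible(x)
}
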