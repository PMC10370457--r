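# Classification of assembled transcript contigs against gene and repeat
# annotations, and terminal-sequence position-frequency matrices.

# Total overlap width (bases) between each contig's blocks and a subject
# interval set, summed per (transcript, subject-key) pair.
overlap_width_by <- function(blocks, subject, key) {
  bg <- as_granges0(blocks)
  sg <- as_granges0(subject)
  ov <- GenomicRanges::findOverlaps(bg, sg, minoverlap = 1L, ignore.strand = TRUE)
  if (length(ov) == 0) {
    return(tibble::tibble(transcript_id = character(), key = character(),
                          width = integer()))
  }
  q <- S4Vectors::queryHits(ov)
  s <- S4Vectors::subjectHits(ov)
  w <- IRanges::width(IRanges::pintersect(IRanges::ranges(bg)[q],
                                          IRanges::ranges(sg)[s]))
  tibble::tibble(transcript_id = blocks$transcript_id[q],
                 key = subject[[key]][s], width = w) |>
    dplyr::group_by(.data$transcript_id, .data$key) |>
    dplyr::summarise(width = sum(.data$width), .groups = "drop")
}

#' Classify contigs by gene/RTE overlap
#'
#' Assigns each contig one of four categories from the 2x2 of two booleans:
#' does any block share at least one base with any gene body, and with any
#' repeat. Categories: `gene_and_rte`, `gene_only`, `rte_only`, `neither`.
#'
#' @param contigs Contig tibble ([read_bed12()]).
#' @param genes Gene tibble ([read_gtf()]).
#' @param repeats Repeat tibble ([read_repeat_table()]).
#' @return Tibble `transcript_id`, `overlaps_gene`, `overlaps_rte`,
#'   `overlap_category`.
#' @export
overlap_category <- function(contigs, genes, repeats) {
  bl <- contig_blocks(contigs)
  bg <- as_granges0(bl)
  g_hit <- GenomicRanges::countOverlaps(bg, as_granges0(genes),
                                        minoverlap = 1L, ignore.strand = TRUE) > 0
  r_hit <- GenomicRanges::countOverlaps(bg, as_granges0(repeats),
                                        minoverlap = 1L, ignore.strand = TRUE) > 0
  bl |>
    dplyr::mutate(g = g_hit, r = r_hit) |>
    dplyr::group_by(.data$transcript_id) |>
    dplyr::summarise(overlaps_gene = any(.data$g), overlaps_rte = any(.data$r),
                     .groups = "drop") |>
    dplyr::mutate(overlap_category = dplyr::case_when(
      .data$overlaps_gene & .data$overlaps_rte ~ "gene_and_rte",
      .data$overlaps_gene ~ "gene_only",
      .data$overlaps_rte ~ "rte_only",
      TRUE ~ "neither"
    ))
}

#' Classify contigs by intron containment
#'
#' `fully_intronic`: every base of every block lies within the intron set
#' of one single gene (blocks may span several introns of that gene).
#' `no_intron_overlap`: zero bases overlap any intron of any gene. All
#' remaining contigs are `other`.
#'
#' @param contigs Contig tibble.
#' @param genes Gene tibble.
#' @return Tibble `transcript_id`, `intron_category`.
#' @export
intron_category <- function(contigs, genes) {
  bl <- contig_blocks(contigs)
  introns <- gene_introns(genes)
  widths <- bl |>
    dplyr::group_by(.data$transcript_id) |>
    dplyr::summarise(total = sum(.data$end - .data$start), .groups = "drop")
  if (nrow(introns) == 0) {
    ov <- tibble::tibble(transcript_id = character(), key = character(),
                         width = integer())
  } else {
    ov <- overlap_width_by(bl, dplyr::rename(introns, key = "gene_id"), "key")
  }
  per_gene <- ov |>
    dplyr::left_join(widths, by = "transcript_id") |>
    dplyr::group_by(.data$transcript_id) |>
    dplyr::summarise(contained = any(.data$width == .data$total), .groups = "drop")
  widths |>
    dplyr::left_join(per_gene, by = "transcript_id") |>
    dplyr::mutate(intron_category = dplyr::case_when(
      isTRUE_v(.data$contained) ~ "fully_intronic",
      is.na(.data$contained) ~ "no_intron_overlap",
      TRUE ~ "other"
    )) |>
    dplyr::select("transcript_id", "intron_category")
}

isTRUE_v <- function(x) !is.na(x) & x

#' RTE content of contigs
#'
#' Repeat classes and subfamilies sharing at least one base with any block
#' of each contig.
#'
#' @param contigs Contig tibble.
#' @param repeats Repeat tibble.
#' @return Tibble `transcript_id`, list-columns `classes_hit` and
#'   `subfamilies_hit` (character vectors, possibly empty).
#' @export
rte_group_content <- function(contigs, repeats) {
  bl <- contig_blocks(contigs)
  bg <- as_granges0(bl)
  rg <- as_granges0(repeats)
  ov <- GenomicRanges::findOverlaps(bg, rg, minoverlap = 1L, ignore.strand = TRUE)
  hits <- tibble::tibble(
    transcript_id = bl$transcript_id[S4Vectors::queryHits(ov)],
    rte_class = repeats$rte_class[S4Vectors::subjectHits(ov)],
    subfamily = repeats$subfamily[S4Vectors::subjectHits(ov)]
  ) |>
    dplyr::group_by(.data$transcript_id) |>
    dplyr::summarise(
      classes_hit = list(sort(unique(.data$rte_class))),
      subfamilies_hit = list(sort(unique(.data$subfamily))),
      .groups = "drop")
  tibble::tibble(transcript_id = unique(contigs$transcript_id)) |>
    dplyr::left_join(hits, by = "transcript_id") |>
    dplyr::mutate(
      classes_hit = purrr::map(.data$classes_hit, ~ .x %||% character()),
      subfamilies_hit = purrr::map(.data$subfamilies_hit, ~ .x %||% character())
    )
}

#' Full per-contig classification table
#'
#' Combines [overlap_category()], [intron_category()] and
#' [rte_group_content()]; the TSV-friendly columns collapse set-valued
#' fields with commas.
#'
#' @inheritParams overlap_category
#' @return One row per contig with all classification columns.
#' @export
classify_contigs <- function(contigs, genes, repeats) {
  overlap_category(contigs, genes, repeats) |>
    dplyr::left_join(intron_category(contigs, genes), by = "transcript_id") |>
    dplyr::left_join(rte_group_content(contigs, repeats), by = "transcript_id") |>
    dplyr::mutate(
      classes = purrr::map_chr(.data$classes_hit, paste, collapse = ","),
      subfamilies = purrr::map_chr(.data$subfamilies_hit, paste, collapse = ",")
    )
}

#' Terminal position-frequency matrix
#'
#' Extracts each contig's spliced sequence (blocks concatenated in genomic
#' order, reverse-complemented for minus-strand contigs), takes the
#' terminal `k` bases at the requested end, and tabulates A/C/G/T counts
#' per position. Ambiguous bases are excluded, so column sums are at most
#' the number of sequences. Contigs shorter than `k` are skipped and
#' counted.
#'
#' @param contigs Contig tibble.
#' @param genome A named [Biostrings::DNAStringSet] (or path to a FASTA
#'   file) with one sequence per chromosome.
#' @param k Number of terminal bases (default 40).
#' @param end Which end: `"five_prime"` or `"three_prime"`.
#' @return An object of class `rte_pfm`: a 4 x `k` integer matrix with
#'   attributes `n_sequences` and `n_skipped`.
#' @export
terminal_pfm <- function(contigs, genome, k = 40, end = c("five_prime", "three_prime")) {
  end <- match.arg(end)
  if (nrow(contigs) == 0) stop_retrotx("no sequences: empty contig list")
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  missing <- setdiff(unique(contigs$chrom), names(genome))
  if (length(missing) > 0) {
    stop_retrotx("chromosome(s) missing from FASTA: %s", paste(missing, collapse = ", "))
  }
  seqs <- purrr::pmap(list(contigs$chrom, contigs$strand, contigs$blocks),
                      function(chrom, strand, b) {
    b <- dplyr::arrange(b, .data$start)
    chr <- paste0(purrr::map2_chr(b$start, b$end, function(st, en) {
      as.character(Biostrings::subseq(genome[[chrom]], start = st + 1L, end = en))
    }), collapse = "")
    s <- Biostrings::DNAString(chr)
    if (identical(strand, "-")) s <- Biostrings::reverseComplement(s)
    s
  })
  lens <- purrr::map_int(seqs, length)
  keep <- lens >= k
  n_skipped <- sum(!keep)
  if (!any(keep)) stop_retrotx("no sequences of length >= %d", k)
  term <- Biostrings::DNAStringSet(purrr::map(seqs[keep], function(s) {
    if (end == "five_prime") Biostrings::subseq(s, 1L, k)
    else Biostrings::subseq(s, length(s) - k + 1L, length(s))
  }))
  cm <- Biostrings::consensusMatrix(term)[c("A", "C", "G", "T"), , drop = FALSE]
  structure(cm, class = c("rte_pfm", class(cm)),
            n_sequences = sum(keep), n_skipped = n_skipped, end = end)
}

#' @export
print.rte_pfm <- function(x, ...) {
  cat(sprintf("<rte_pfm> %s end, %d positions, %d sequences (%d skipped)\n",
              attr(x, "end"), ncol(x), attr(x, "n_sequences"),
              attr(x, "n_skipped")))
  print(unclass(x)[, seq_len(min(10, ncol(x)))])
  invisible(x)
}
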