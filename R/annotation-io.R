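# Readers and writers for gene (GTF), contig (BED12) and repeat (TSV)
# annotations. Internal coordinates are 0-based half-open; GTF and the
# repeat table are 1-based inclusive on disk and converted at the boundary.

#' Read gene models from a GTF file
#'
#' Exon records are grouped by `gene_id`, the per-gene exon structure is the
#' union of exons over all isoforms, and introns are the gaps of that union
#' inside the gene body. Coordinates are converted from the GTF's 1-based
#' inclusive convention to 0-based half-open.
#'
#' @param path Path to a GTF file (ensembl/GENCODE attribute dialect).
#' @return A tibble with one row per gene: `gene_id`, `chrom`, `strand`,
#'   `start`, `end` (gene body, 0-based half-open), and list-columns
#'   `exons` and `introns` of tibbles with `start`/`end`.
#' @export
#' @examples
#' gtf <- tempfile(fileext = ".gtf")
#' writeLines(paste("chr1", "x", "exon", 101, 200, ".", "+", ".",
#'                  'gene_id "g1";', sep = "\t"), gtf)
#' read_gtf(gtf)
read_gtf <- function(path) {
  if (!file.exists(path)) stop_retrotx("GTF file not found: %s", path)
  lines <- readr::read_lines(path)
  body <- which(!startsWith(lines, "#") & nzchar(lines))
  nfield <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  bad <- body[nfield < 9]
  if (length(bad) > 0) {
    stop_retrotx("malformed GTF line %d: expected 9 tab-separated fields", bad[1])
  }
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  if (length(gr) == 0) stop_retrotx("no exon records in %s", path)
  if (any(is.na(gr$gene_id))) stop_retrotx("exon record without gene_id in %s", path)
  ex <- tibble::tibble(
    gene_id = as.character(gr$gene_id),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
  build_genes(ex)
}

# Assemble the per-gene model from a long exon table (0-based half-open).
build_genes <- function(ex) {
  ex |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::group_map(function(d, key) {
      if (length(unique(d$chrom)) > 1) {
        stop_retrotx("gene %s has exons on multiple chromosomes", key$gene_id)
      }
      un <- interval_union(d$start, d$end)
      gene_start <- min(un$start)
      gene_end <- max(un$end)
      tibble::tibble(
        gene_id = key$gene_id,
        chrom = d$chrom[1],
        strand = d$strand[1],
        start = gene_start,
        end = gene_end,
        exons = list(un),
        introns = list(interval_gaps(un))
      )
    }) |>
    dplyr::bind_rows() |>
    dplyr::arrange(.data$chrom, .data$start, .data$gene_id)
}

# Union of possibly-overlapping intervals (0-based half-open).
interval_union <- function(start, end) {
  stopifnot(all(start < end))
  ir <- IRanges::reduce(IRanges::IRanges(start = start + 1L, end = end))
  tibble::tibble(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
}

# Gaps between consecutive disjoint sorted intervals.
interval_gaps <- function(un) {
  if (nrow(un) < 2) return(tibble::tibble(start = integer(), end = integer()))
  tibble::tibble(start = un$end[-nrow(un)], end = un$start[-1])
}

#' Write gene models to a GTF file
#'
#' Emits one `exon` record per exon-union interval, in deterministic order
#' (chrom, start, gene_id). Round-trips with [read_gtf()] bit-exactly on
#' coordinates.
#'
#' @param genes Gene tibble as returned by [read_gtf()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(genes, path) {
  ex <- gene_exons(genes)
  ex <- dplyr::arrange(ex, .data$chrom, .data$start, .data$gene_id)
  lines <- sprintf('%s\tretrotx\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
                   ex$chrom, ex$start + 1L, ex$end, ex$strand, ex$gene_id, ex$gene_id)
  readr::write_lines(lines, path)
  invisible(path)
}

#' Long exon / intron tables for a gene set
#'
#' @param genes Gene tibble from [read_gtf()].
#' @return A tibble with one row per exon-union interval (or intron):
#'   `gene_id`, `chrom`, `strand`, `start`, `end`.
#' @export
gene_exons <- function(genes) {
  assert_columns(genes, c("gene_id", "chrom", "strand", "exons"), "genes")
  tidyr::unnest(
    dplyr::select(genes, "gene_id", "chrom", "strand", "exons"),
    "exons"
  )
}

#' @rdname gene_exons
#' @export
gene_introns <- function(genes) {
  assert_columns(genes, c("gene_id", "chrom", "strand", "introns"), "genes")
  tidyr::unnest(
    dplyr::select(genes, "gene_id", "chrom", "strand", "introns"),
    "introns"
  )
}

#' Derive introns from an exon union
#'
#' Introns are the gaps between consecutive exon-union intervals; a gene with
#' one exon-union interval has none. Exons and introns together tile the gene
#' body exactly.
#'
#' @param exons Tibble with `start`, `end` (0-based half-open), possibly
#'   overlapping (the union is taken first).
#' @return Tibble with `start`, `end` for each intron.
#' @export
derive_introns <- function(exons) {
  interval_gaps(interval_union(exons$start, exons$end))
}

#' Read transcript contigs from a BED12 file
#'
#' @param path Path to a BED12 file (0-based half-open).
#' @return A tibble with one row per contig: `transcript_id`, `chrom`,
#'   `strand`, `start`, `end`, and list-column `blocks` of tibbles with
#'   `start`/`end` (absolute, 0-based half-open, sorted, disjoint).
#' @export
read_bed12 <- function(path) {
  if (!file.exists(path)) stop_retrotx("BED file not found: %s", path)
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "track")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) < 12) stop_retrotx("BED line %d: expected 12 fields, got %d", i, length(f))
    n <- as.integer(f[10])
    sizes <- as.integer(strsplit(f[11], ",")[[1]])
    starts <- as.integer(strsplit(f[12], ",")[[1]])
    if (length(sizes) != n || length(starts) != n) {
      stop_retrotx("BED line %d: blockCount %d does not match block fields", i, n)
    }
    if (any(as.integer(f[2]) + starts + sizes > as.integer(f[3]))) {
      stop_retrotx("BED line %d: block extends past chromEnd", i)
    }
  }
  gr <- rtracklayer::import(path, format = "bed")
  blocks <- gr$blocks  # 1-based, relative to range start
  offs <- GenomicRanges::start(gr) - 1L  # 0-based chromStart
  tibble::tibble(
    transcript_id = as.character(gr$name),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = offs,
    end = GenomicRanges::end(gr),
    blocks = purrr::map2(seq_along(gr), offs, function(i, off) {
      b <- blocks[[i]]
      tibble::tibble(start = off + IRanges::start(b) - 1L,
                     end = off + IRanges::end(b))
    })
  ) |>
    dplyr::arrange(.data$chrom, .data$start, .data$transcript_id)
}

#' Write transcript contigs to a BED12 file
#'
#' @param contigs Contig tibble as returned by [read_bed12()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed12 <- function(contigs, path) {
  contigs <- dplyr::arrange(contigs, .data$chrom, .data$start, .data$transcript_id)
  lines <- purrr::pmap_chr(
    list(contigs$chrom, contigs$start, contigs$end, contigs$transcript_id,
         contigs$strand, contigs$blocks),
    function(chrom, start, end, id, strand, b) {
      b <- dplyr::arrange(b, .data$start)
      paste(chrom, start, end, id, 0L,
            if (strand %in% c("+", "-")) strand else ".",
            start, end, 0L, nrow(b),
            paste0(paste(b$end - b$start, collapse = ","), ","),
            paste0(paste(b$start - start, collapse = ","), ","),
            sep = "\t")
    })
  readr::write_lines(lines, path)
  invisible(path)
}

#' Long block table for a contig set
#'
#' @param contigs Contig tibble from [read_bed12()].
#' @return Tibble with `transcript_id`, `chrom`, `strand`, `start`, `end`
#'   per block.
#' @export
contig_blocks <- function(contigs) {
  assert_columns(contigs, c("transcript_id", "chrom", "strand", "blocks"), "contigs")
  tidyr::unnest(
    dplyr::select(contigs, "transcript_id", "chrom", "strand", "blocks"),
    "blocks"
  )
}

# Fixed family -> RTE class lookup. Class strings on disk are
# "class/family" (e.g. "SINE/Alu"); anything unrecognised maps to Other.
rte_class_of <- function(class_field) {
  cls <- sub("/.*$", "", class_field)
  out <- dplyr::case_when(
    cls == "LINE" ~ "LINE",
    cls == "SINE" ~ "SINE",
    cls == "LTR" ~ "LTR",
    cls == "SVA" | grepl("SVA", class_field, fixed = TRUE) ~ "SVA",
    TRUE ~ "Other"
  )
  unknown <- unique(class_field[out == "Other"])
  if (length(unknown) > 0) {
    rlang::warn(paste0("unknown repeat class string(s) mapped to Other: ",
                       paste(unknown, collapse = ", ")))
  }
  out
}

#' Read a repeat annotation table
#'
#' Reads a RepeatMasker-derived repeat table in a simplified TSV dialect
#' with columns `chrom`, `start`, `end` (1-based inclusive on disk),
#' `strand`, `subfamily`, `class_family` (e.g. `"SINE/Alu"`,
#' `"LTR/ERV1"`). The RTE class is derived from the class component via a
#' fixed lookup; unknown class strings map to `Other` with a warning.
#'
#' @param path Path to the TSV file.
#' @return A tibble with `repeat_id`, `chrom`, `start`, `end` (0-based
#'   half-open), `strand`, `subfamily`, `family`, `rte_class`.
#' @export
read_repeat_table <- function(path) {
  if (!file.exists(path)) stop_retrotx("repeat table not found: %s", path)
  raw <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           chrom = readr::col_character(),
                           start = readr::col_integer(),
                           end = readr::col_integer(),
                           strand = readr::col_character(),
                           subfamily = readr::col_character(),
                           class_family = readr::col_character()
                         ))
  assert_columns(raw, c("chrom", "start", "end", "strand", "subfamily",
                        "class_family"), "repeat table")
  tibble::tibble(
    repeat_id = if ("repeat_id" %in% names(raw)) raw$repeat_id else
      sprintf("rep_%06d", seq_len(nrow(raw))),
    chrom = raw$chrom,
    start = raw$start - 1L,
    end = raw$end,
    strand = raw$strand,
    subfamily = raw$subfamily,
    family = sub("^[^/]*/?", "", raw$class_family),
    rte_class = rte_class_of(raw$class_family)
  ) |>
    dplyr::arrange(.data$chrom, .data$start, .data$repeat_id)
}

#' Write a repeat annotation table
#'
#' Inverse of [read_repeat_table()] (coordinates re-converted to 1-based
#' inclusive; deterministic chrom/start order).
#'
#' @param repeats Repeat tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_repeat_table <- function(repeats, path) {
  repeats <- dplyr::arrange(repeats, .data$chrom, .data$start, .data$repeat_id)
  out <- tibble::tibble(
    repeat_id = repeats$repeat_id,
    chrom = repeats$chrom,
    start = repeats$start + 1L,
    end = repeats$end,
    strand = repeats$strand,
    subfamily = repeats$subfamily,
    class_family = paste0(ifelse(repeats$rte_class == "Other", "Other",
                                 repeats$rte_class), "/", repeats$family)
  )
  readr::write_tsv(out, path)
  invisible(path)
}
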