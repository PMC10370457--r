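# Contig classification: overlap categories, intron containment, RTE
# content, terminal PFMs.

fixture_genes <- function() {
  make_genes(list(
    g1 = tibble::tibble(start = c(1000L, 2000L, 3000L),
                        end = c(1200L, 2200L, 3200L)),
    g2 = tibble::tibble(start = c(10000L, 12000L), end = c(10500L, 12500L))))
}

test_that("overlap categories follow the 2x2 of gene and repeat hits", {
  genes <- fixture_genes()
  reps <- make_repeats(c(1500L, 20000L), c(1600L, 20300L))
  contigs <- dplyr::bind_rows(
    make_contig("in_intron_on_rte", tibble::tibble(start = 1480L, end = 1600L)),
    make_contig("exon_only", tibble::tibble(start = 1050L, end = 1150L)),
    make_contig("standalone", tibble::tibble(start = 20000L, end = 20300L)),
    make_contig("desert", tibble::tibble(start = 50000L, end = 50200L)))
  oc <- overlap_category(contigs, genes, reps)
  got <- stats::setNames(oc$overlap_category, oc$transcript_id)
  expect_equal(got[["in_intron_on_rte"]], "gene_and_rte")
  expect_equal(got[["exon_only"]], "gene_only")
  expect_equal(got[["standalone"]], "rte_only")
  expect_equal(got[["desert"]], "neither")
})

test_that("intron containment distinguishes fully intronic, exonic and straddling", {
  genes <- fixture_genes()
  contigs <- dplyr::bind_rows(
    make_contig("fully_in", tibble::tibble(start = 1300L, end = 1700L)),
    # blocks in two introns of the same gene still count as fully intronic
    make_contig("two_introns", tibble::tibble(start = c(1300L, 2400L),
                                              end = c(1500L, 2600L))),
    make_contig("equals_exon", tibble::tibble(start = 2000L, end = 2200L)),
    make_contig("straddle", tibble::tibble(start = 1100L, end = 1400L)),
    # contained in introns of two different genes -> other
    make_contig("cross_gene", tibble::tibble(start = c(1300L, 11000L),
                                             end = c(1400L, 11100L))))
  ic <- intron_category(contigs, genes)
  got <- stats::setNames(ic$intron_category, ic$transcript_id)
  expect_equal(got[["fully_in"]], "fully_intronic")
  expect_equal(got[["two_introns"]], "fully_intronic")
  expect_equal(got[["equals_exon"]], "no_intron_overlap")
  expect_equal(got[["straddle"]], "other")
  expect_equal(got[["cross_gene"]], "other")
})

test_that("rte content collects classes and subfamilies with >= 1 base overlap", {
  reps <- dplyr::bind_rows(
    make_repeats(1000L, 1300L, subfamily = "AluSx", rte_class = "SINE"),
    make_repeats(5000L, 6500L, subfamily = "L1PA2", family = "L1",
                 rte_class = "LINE"))
  contigs <- dplyr::bind_rows(
    make_contig("both", tibble::tibble(start = c(1200L, 5000L),
                                       end = c(1400L, 5100L))),
    make_contig("none", tibble::tibble(start = 9000L, end = 9100L)))
  rc <- rte_group_content(contigs, reps)
  expect_setequal(rc$classes_hit[[which(rc$transcript_id == "both")]],
                  c("SINE", "LINE"))
  expect_setequal(rc$subfamilies_hit[[which(rc$transcript_id == "both")]],
                  c("AluSx", "L1PA2"))
  expect_length(rc$classes_hit[[which(rc$transcript_id == "none")]], 0)
})

test_that("random contigs match the per-base oracle and categories partition", {
  set.seed(21)
  genes <- fixture_genes()
  starts <- sample.int(25000, 30)
  reps <- make_repeats(starts, starts + sample(50:500, 30, replace = TRUE))
  contigs <- purrr::map_dfr(1:200, function(i) {
    s <- sample.int(26000, 1)
    make_contig(sprintf("c%03d", i),
                tibble::tibble(start = s, end = s + sample(30:800, 1)))
  })
  cl <- classify_contigs(contigs, genes, reps)
  bodies <- dplyr::select(genes, "start", "end")
  introns <- gene_introns(genes)
  for (i in seq_len(nrow(contigs))) {
    b <- contigs$blocks[[i]]
    id <- contigs$transcript_id[i]
    row <- cl[cl$transcript_id == id, ]
    g_ov <- oracle_overlap_bases(b, bodies) > 0
    r_ov <- oracle_overlap_bases(b, reps[, c("start", "end")]) > 0
    expect_equal(row$overlap_category,
                 if (g_ov && r_ov) "gene_and_rte" else if (g_ov) "gene_only"
                 else if (r_ov) "rte_only" else "neither")
    w <- sum(b$end - b$start)
    per_gene <- vapply(unique(introns$gene_id), function(g) {
      oracle_overlap_bases(b, introns[introns$gene_id == g, c("start", "end")])
    }, 0)
    expect_equal(row$intron_category,
                 if (any(per_gene == w)) "fully_intronic"
                 else if (sum(per_gene) == 0) "no_intron_overlap" else "other")
  }
  # totals and exclusivity
  expect_equal(sum(table(cl$overlap_category)), nrow(contigs))
  expect_equal(sum(table(cl$intron_category)), nrow(contigs))
  # fully intronic implies genic
  fi <- cl$overlap_category[cl$intron_category == "fully_intronic"]
  expect_true(all(fi %in% c("gene_and_rte", "gene_only")))
})

test_that("terminal PFM counts identical sequences into single-base columns", {
  genome <- Biostrings::DNAStringSet(c(
    chr1 = paste0(paste(rep("ACGT", 30), collapse = ""),
                  strrep("A", 20), paste(rep("GGCC", 30), collapse = ""))))
  contigs <- dplyr::bind_rows(
    make_contig("t1", tibble::tibble(start = 0L, end = 120L)),
    make_contig("t2", tibble::tibble(start = 0L, end = 120L)))
  pfm <- terminal_pfm(contigs, genome, k = 8, end = "five_prime")
  expect_equal(attr(pfm, "n_sequences"), 2)
  expect_true(all(colSums(unclass(pfm)) == 2))
  expect_equal(unname(unclass(pfm)["A", ]), c(2, 0, 0, 0, 2, 0, 0, 0))
})

test_that("minus-strand extraction reverse-complements (hand-computed 6-mer)", {
  genome <- Biostrings::DNAStringSet(c(chr1 = "TTACGGATCCAA"))
  contigs <- make_contig("m", tibble::tibble(start = 2L, end = 8L),
                         strand = "-")
  # genomic [2,8) = ACGGAT; revcomp = ATCCGT
  pfm <- terminal_pfm(contigs, genome, k = 6, end = "five_prime")
  seq_got <- apply(unclass(pfm), 2, function(col) names(col)[col == 1])
  expect_equal(paste(seq_got, collapse = ""), "ATCCGT")
})

test_that("spliced blocks concatenate before the terminal window is taken", {
  genome <- Biostrings::DNAStringSet(c(chr1 = "AAAACCCCGGGGTTTT"))
  contigs <- make_contig("s", tibble::tibble(start = c(0L, 8L),
                                             end = c(4L, 12L)))
  pfm <- terminal_pfm(contigs, genome, k = 8, end = "three_prime")
  seq_got <- apply(unclass(pfm), 2, function(col) names(col)[col == 1])
  expect_equal(paste(seq_got, collapse = ""), "AAAAGGGG")
})

test_that("PFM errors and skips are reported", {
  genome <- Biostrings::DNAStringSet(c(chr1 = strrep("ACGT", 100)))
  expect_error(terminal_pfm(make_contig("x", tibble::tibble(start = 1L, end = 5L))[0, ],
                            genome), "no sequences")
  short <- make_contig("short", tibble::tibble(start = 0L, end = 10L))
  long <- make_contig("long", tibble::tibble(start = 0L, end = 100L))
  pfm <- terminal_pfm(dplyr::bind_rows(short, long), genome, k = 40)
  expect_equal(attr(pfm, "n_skipped"), 1)
  expect_equal(attr(pfm, "n_sequences"), 1)
  bad <- make_contig("bad", tibble::tibble(start = 0L, end = 50L),
                     chrom = "chrMissing")
  expect_error(terminal_pfm(bad, genome), "missing from FASTA")
})

test_that("simulated poly(A) tails dominate the 3' PFM at the planted rate", {
  sim <- default_sim()
  cls <- sim$truth$contig_classes
  fi <- cls[cls$planted_class == "fully_intronic", ]
  ctg <- dplyr::filter(sim$contigs, .data$transcript_id %in% fi$transcript_id)
  pfm <- terminal_pfm(ctg, sim$genome, k = 40, end = "three_prime")
  polyA <- sim$truth$repeat_polyA
  planted_rate <- mean(polyA$has_polyA[match(fi$host_repeat, polyA$repeat_id)])
  tail_cols <- seq(41 - sim$config$polyA_length, 40)
  a_frac <- mean(unclass(pfm)["A", tail_cols] / attr(pfm, "n_sequences"))
  expect_gte(a_frac, planted_rate)
  # column sums conserve the sequence count (no ambiguous bases simulated)
  expect_true(all(colSums(unclass(pfm)) == attr(pfm, "n_sequences")))
})
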