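# Annotation model: GTF/BED12/repeat-table I/O, intron derivation,
# LTR-internal merging, genic flagging.

write_tmp_gtf <- function(lines) {
  f <- withr::local_tempfile(fileext = ".gtf", .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

gtf_line <- function(chrom, start, end, strand, gene) {
  sprintf('%s\tsrc\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s.t1";',
          chrom, start, end, strand, gene, gene)
}

test_that("GTF exons convert to 0-based half-open and introns are derived", {
  f <- write_tmp_gtf(c(gtf_line("chr1", 101, 200, "+", "g1"),
                       gtf_line("chr1", 301, 400, "+", "g1")))
  g <- read_gtf(f)
  expect_equal(g$exons[[1]], tibble::tibble(start = c(100L, 300L),
                                            end = c(200L, 400L)))
  expect_equal(g$introns[[1]], tibble::tibble(start = 200L, end = 300L))
  expect_equal(g$start, 100L)
  expect_equal(g$end, 400L)
})

test_that("single-exon gene has no introns", {
  f <- write_tmp_gtf(gtf_line("chr1", 51, 150, "-", "g1"))
  g <- read_gtf(f)
  expect_equal(nrow(g$introns[[1]]), 0)
})

test_that("overlapping isoform exons collapse to the per-base union", {
  set.seed(11)
  for (rep in 1:20) {
    ex <- random_intervals(6, max_pos = 2000, max_len = 300)
    f <- write_tmp_gtf(vapply(seq_len(nrow(ex)), function(i) {
      gtf_line("chr1", ex$start[i] + 1L, ex$end[i], "+", "g1")
    }, ""))
    g <- read_gtf(f)
    expect_setequal(bases_of(g$exons[[1]]), bases_of(ex))
    # no duplicate or touching intervals in the union
    un <- g$exons[[1]]
    if (nrow(un) > 1) expect_true(all(un$start[-1] > un$end[-nrow(un)]))
  }
})

test_that("malformed GTF lines are rejected with a line number", {
  f <- write_tmp_gtf(c(gtf_line("chr1", 1, 10, "+", "g1"), "chr1\tbroken"))
  expect_error(read_gtf(f), "line 2")
})

test_that("exon union and introns tile the gene body exactly", {
  set.seed(7)
  for (rep in 1:25) {
    ex <- random_intervals(5, max_pos = 3000, max_len = 250)
    un <- retrotx:::interval_union(ex$start, ex$end)
    intr <- derive_introns(ex)
    body <- seq.int(min(un$start), max(un$end) - 1L)
    expect_setequal(c(bases_of(un), bases_of(intr)), body)
    expect_length(intersect(bases_of(un), bases_of(intr)), 0)
    expect_equal(nrow(intr), nrow(un) - 1)
  }
})

test_that("BED12 blocks reconstruct from block fields", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200\ttx1\t0\t+\t100\t200\t0\t1\t100,\t0,",
               "chr2\t1000\t1200\ttx2\t0\t-\t1000\t1200\t0\t2\t50,50\t0,150"),
             f)
  b <- read_bed12(f)
  expect_equal(b$blocks[[which(b$transcript_id == "tx1")]],
               tibble::tibble(start = 100L, end = 200L))
  expect_equal(b$blocks[[which(b$transcript_id == "tx2")]],
               tibble::tibble(start = c(1000L, 1150L), end = c(1050L, 1200L)))
})

test_that("inconsistent BED12 block fields are rejected", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t100\t200\ttx1\t0\t+\t100\t200\t0\t2\t100,\t0,", f)
  expect_error(read_bed12(f), "blockCount")
  writeLines("chr1\t100\t200\ttx1\t0\t+\t100\t200\t0\t1\t150,\t0,", f)
  expect_error(read_bed12(f), "past chromEnd")
})

test_that("BED12 and GTF round-trips preserve coordinates bit-exactly", {
  set.seed(3)
  contigs <- purrr::map_dfr(1:15, function(i) {
    n_b <- sample(1:4, 1)
    s <- sort(sample.int(5000, n_b)) * 3L
    b <- tibble::tibble(start = s, end = s + sample(20:50, n_b, replace = TRUE))
    make_contig(sprintf("tx%02d", i), b,
                strand = sample(c("+", "-"), 1))
  })
  f <- withr::local_tempfile(fileext = ".bed")
  write_bed12(contigs, f)
  back <- read_bed12(f)
  ord <- match(contigs$transcript_id, back$transcript_id)
  expect_equal(back$blocks[ord], contigs$blocks)
  expect_equal(back$strand[ord], contigs$strand)

  genes <- make_genes(list(a = tibble::tibble(start = c(10L, 400L),
                                              end = c(120L, 600L)),
                           b = tibble::tibble(start = 1000L, end = 1500L)))
  g <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(genes, g)
  back_g <- read_gtf(g)
  expect_equal(back_g$exons[match(genes$gene_id, back_g$gene_id)], genes$exons)
})

test_that("repeat table parses the class/family lookup and coordinates", {
  f <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    chrom = "chr1", start = c(101L, 501L, 901L),
    end = c(200L, 700L, 950L), strand = "+",
    subfamily = c("AluSx", "HERVH-int", "WeirdRep"),
    class_family = c("SINE/Alu", "LTR/ERV1", "Satellite/acro")), f)
  expect_warning(r <- read_repeat_table(f), "WeirdRep|Satellite")
  expect_equal(r$start, c(100L, 500L, 900L))
  expect_equal(r$end, c(200L, 700L, 950L))
  expect_equal(r$rte_class, c("SINE", "LTR", "Other"))
  expect_equal(r$family, c("Alu", "ERV1", "acro"))
})

test_that("LTR + internal + LTR merges into one element named by the internal base", {
  reps <- tibble::tibble(
    repeat_id = c("r1", "r2", "r3", "r4"),
    chrom = "chr1",
    start = c(1000L, 1460L, 6000L, 9000L),
    end = c(1450L, 5990L, 6450L, 9450L),
    strand = "+",
    subfamily = c("LTR7Y", "HERVH-int", "LTR7Y", "LTR7Y"),
    family = "ERV1", rte_class = "LTR")
  m <- merge_ltr_internal(reps, gap_tolerance = 100)
  expect_equal(nrow(m), 2)
  merged <- m[m$subfamily == "HERVH", ]
  expect_equal(merged$start, 1000L)
  expect_equal(merged$end, 6450L)
  expect_equal(merged$rte_class, "LTR")
  # the solo LTR7Y far away passes through unchanged
  expect_true("LTR7Y" %in% m$subfamily)
  expect_error(merge_ltr_internal(reps, gap_tolerance = -1), "non-negative")
})

test_that("rows separated by more than the gap tolerance are not merged", {
  reps <- tibble::tibble(
    repeat_id = c("r1", "r2"), chrom = "chr1",
    start = c(1000L, 2000L), end = c(1450L, 6000L), strand = "+",
    subfamily = c("LTR7Y", "HERVH-int"), family = "ERV1", rte_class = "LTR")
  expect_equal(nrow(merge_ltr_internal(reps, gap_tolerance = 100)), 2)
  expect_equal(nrow(merge_ltr_internal(reps, gap_tolerance = 1000)), 1)
})

test_that("merging enumerates chains correctly on random row sets", {
  # oracle: walk sorted rows, chain while same element family and gap ok
  set.seed(5)
  for (rep in 1:20) {
    n <- 12
    starts <- cumsum(sample(c(50, 150, 400), n, replace = TRUE))
    reps <- tibble::tibble(
      repeat_id = sprintf("r%02d", 1:n), chrom = "chr1",
      start = starts, end = starts + 40L, strand = "+",
      subfamily = sample(c("LTR7Y", "HERVH-int", "AluSx"), n, replace = TRUE),
      family = "x", rte_class = "LTR")
    tol <- 100
    base <- ifelse(reps$subfamily %in% c("LTR7Y", "HERVH-int"), "HERVH", NA)
    chain <- cumsum(c(TRUE, !(base[-1] == base[-n] & !is.na(base[-1]) &
                                !is.na(base[-n]) &
                                (reps$start[-1] - reps$end[-n]) <= tol)))
    expected <- sum(vapply(split(reps$subfamily, chain), function(subs) {
      if (any(subs == "HERVH-int")) 1L else length(subs)
    }, 1L))
    m <- merge_ltr_internal(reps, gap_tolerance = tol)
    expect_equal(nrow(m), expected)
  }
})

test_that("merge_ltr_internal is idempotent", {
  sim <- default_sim()
  once <- merge_ltr_internal(sim$repeats)
  twice <- merge_ltr_internal(once)
  expect_equal(dplyr::select(twice, -dplyr::any_of("merged_n")),
               dplyr::select(once, -dplyr::any_of("merged_n")))
})

test_that("genic flagging matches the per-base oracle and is a partition", {
  genes <- make_genes(list(
    a = tibble::tibble(start = c(100L, 500L), end = c(200L, 700L)),
    b = tibble::tibble(start = 2000L, end = 2500L)))
  # repeat wholly inside an intron is genic; abutting half-open is intergenic
  reps <- make_repeats(c(250L, 50L, 700L), c(350L, 100L, 800L))
  fl <- flag_genic_repeats(reps, genes)
  expect_true(fl$genic[1])    # inside intron [200,500)
  expect_false(fl$genic[2])   # ends exactly at gene-body start 100 (0 shared bases)
  expect_false(fl$genic[3])   # starts exactly at gene-body end 700 (0 shared bases)
})

test_that("genic flags equal brute-force per-base intersection on random input", {
  set.seed(9)
  genes <- make_genes(purrr::map(1:10, function(i) {
    s <- sample.int(40000, 1)
    tibble::tibble(start = c(s, s + 500L), end = c(s + 200L, s + 900L))
  }))
  starts <- sample.int(45000, 150)
  reps <- make_repeats(starts, starts + sample(50:400, 150, replace = TRUE))
  fl <- flag_genic_repeats(reps, genes)
  bodies <- dplyr::select(genes, "start", "end")
  for (i in seq_len(nrow(reps))) {
    expect_identical(
      fl$genic[i],
      oracle_overlap_bases(reps[i, c("start", "end")], bodies) > 0)
  }
  expect_equal(sum(fl$genic) + sum(!fl$genic), nrow(reps))
})

test_that("annotation_bundle validates ids and intervals", {
  sim <- default_sim()
  b <- annotation_bundle(sim$genes, sim$repeats_merged, sim$contigs)
  expect_s3_class(b, "rte_annotation")
  bad <- sim$genes
  bad$gene_id[2] <- bad$gene_id[1]
  expect_error(annotation_bundle(bad, sim$repeats_merged, sim$contigs),
               "duplicate gene_id")
})
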