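# Synthetic-data generator: annotations, genome sequence, expression,
# interval-level quantification, survival and driver data with planted
# ground truth matching the statistical structure the analysis assumes.

#' Simulation configuration
#'
#' Defaults define the study conditions the rest of the package is
#' exercised on: a small two-chromosome genome; genes with multi-exon
#' structure; a repeat catalogue with genic placement fractions and
#' poly(A)-tail probabilities for target-primed classes; a contig plan
#' with known class labels; two cancer cohorts plus healthy tissues and a
#' precursor (BE) group; log-normal baseline TPM with a planted
#' cancer-specific overexpressed set; a bimodal subtype-defining provirus;
#' a latent per-sample splicing-deficiency theta coupled to provirus state
#' that raises intronic and depresses exonic signal of coupled genes;
#' exponential survival with planted hazard ratios acting through
#' top-tertile membership; and subtype-conditional driver-alteration
#' rates.
#'
#' @param seed Master seed; per-component sub-seeds are derived from it so
#'   that, e.g., changing cohort sizes does not perturb the annotation.
#' @param ... Overrides for any default field (unknown names are
#'   rejected).
#' @return Named list of class `sim_config`.
#' @export
sim_config <- function(seed = 1, ...) {
  cfg <- list(
    seed = seed,
    # genome / annotation
    n_chromosomes = 2,
    chrom_length = 400000,
    desert_length = 10000,       # repeat- and gene-free zone per chromosome
    n_genes = 40,
    exons_per_gene = c(2, 6),
    exon_length = c(150, 400),
    intron_length = c(800, 3000),
    intergene_gap = c(2000, 6000),
    repeat_catalogue = tibble::tibble(
      subfamily = c("AluSx", "AluJb", "L1PA2", "L1HS", "L2", "MIR", "SVA_D"),
      class_family = c("SINE/Alu", "SINE/Alu", "LINE/L1", "LINE/L1",
                       "LINE/L2", "SINE/MIR", "SVA/SVA"),
      copies = c(120L, 80L, 30L, 15L, 60L, 80L, 10L),
      genic_fraction = c(0.75, 0.75, 0.6, 0.6, 0.5, 0.5, 0.5),
      polyA_prob = c(0.8, 0.8, 0.7, 0.7, 0, 0, 0.7),
      length = c(300L, 300L, 1500L, 2000L, 600L, 200L, 1200L)
    ),
    polyA_length = 20,
    n_proviruses = 4,            # LTR7Y + HERVH-int + LTR7Y structures
    provirus_internal_length = 4500,
    provirus_ltr_length = 450,
    # contig plan (planted class labels)
    contig_plan = c(fully_intronic = 30, chimeric = 20, rte_only = 8,
                    exonic = 20, neither = 5),
    # cohorts
    cancer_cohorts = c("cohort1", "cohort2"),
    n_cancer_per_cohort = 30,
    healthy_tissues = c("esophagus", "stomach"),
    n_healthy_per_tissue = 25,
    matched_tissue = "esophagus",
    n_be = 20,
    # expression
    baseline_log2_mean = 3,
    baseline_log2_sd_between = 1,
    baseline_log2_sd_within = 1,
    overexpressed_fraction = 0.25,
    silent_log2 = -6,
    delta_log2 = 8,
    overexpressed_log2_sd = 0.8,
    # provirus mixture & splicing deficiency
    provirus_low_mode = 0.1,
    provirus_high_mode = 10,
    provirus_mix_weight = 0.5,
    provirus_log2_sd = 0.35,
    theta_high = 0.6,
    theta_low = 0.05,
    theta_jitter = 0.05,
    rho = 0.9,
    kappa = 0.8,
    # gene-level interval quantification
    n_coupled_genes = 8,
    gene_log2_mean = 5,
    gene_log2_sd_between = 0.8,
    gene_log2_sd_within = 0.5,
    layer_log2_noise = 0.2,
    retention_floor = 0.02,
    uncoupled_retention = 0.08,
    exon_clamp_floor = 0.01,
    # survival
    n_prognostic = 2,
    prognostic_hr = 0.5,
    subtype_hr = 1,
    baseline_hazard = log(2) / 730,
    censoring_fraction = 0.3,
    # drivers
    driver_catalogue = tibble::tibble(
      driver = c("CCND1", "CCNE1", "TP53", "CDKN2A", "SMAD4", "ARID1A",
                 "KRAS", "ERBB2"),
      rate_high = c(0.10, 0.50, 0.65, 0.15, 0.20, 0.20, 0.20, 0.20),
      rate_low = c(0.50, 0.10, 0.65, 0.45, 0.20, 0.20, 0.20, 0.20)
    )
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0) {
    stop_retrotx("unknown config field(s): %s", paste(unknown, collapse = ", "))
  }
  cfg[names(dots)] <- dots
  stopifnot(cfg$rho >= 0, cfg$rho <= 1, cfg$kappa >= 0,
            cfg$overexpressed_fraction >= 0, cfg$overexpressed_fraction <= 1,
            cfg$censoring_fraction >= 0)
  structure(cfg, class = "sim_config")
}

# sample() that never interprets a length-1 vector as 1:n
resample <- function(x, n) x[sample.int(length(x), n)]

#' Simulate annotations, genome sequence and ground truth
#'
#' Places non-overlapping genes, repeats (inside introns per the genic
#' fractions, otherwise in intergenic gaps), LTR-internal-LTR provirus
#' structures, and contigs whose planted class labels agree with
#' [classify_contigs()] on the same annotations. Writes poly(A) tracts
#' into the genome at the tails of target-primed elements at the
#' configured rates.
#'
#' @param config A [sim_config()].
#' @param seed Override of the master seed (default `config$seed`).
#' @return List with `genes`, `repeats` (unmerged rows), `repeats_merged`,
#'   `contigs`, `genome` (DNAStringSet), and `truth` (list; see package
#'   vignette).
#' @export
simulate_annotation <- function(config = sim_config(), seed = config$seed) {
  with_seed(derive_seed(seed, "annotation"), {
    chroms <- tibble::tibble(
      chrom = paste0("chr", seq_len(config$n_chromosomes)),
      length = rep_len(config$chrom_length, config$n_chromosomes))

    # ---- genes ----
    gene_rows <- list()
    gaps <- list()  # intergenic regions usable for repeats
    cursor <- stats::setNames(rep(config$desert_length + 500, nrow(chroms)),
                              chroms$chrom)
    ci <- 1
    for (g in seq_len(config$n_genes)) {
      n_ex <- resample(seq(config$exons_per_gene[1], config$exons_per_gene[2]), 1)
      ex_len <- sample(seq(config$exon_length[1], config$exon_length[2]),
                       n_ex, replace = TRUE)
      in_len <- if (n_ex > 1) {
        sample(seq(config$intron_length[1], config$intron_length[2]),
               n_ex - 1, replace = TRUE)
      } else integer()
      glen <- sum(ex_len) + sum(in_len)
      placed <- FALSE
      for (try in seq_len(nrow(chroms))) {
        chrom <- chroms$chrom[ci]
        if (cursor[chrom] + glen < chroms$length[ci] - 20000) {
          placed <- TRUE; break
        }
        ci <- ci %% nrow(chroms) + 1
      }
      if (!placed) {
        stop_retrotx("chromosomes too small to place %d genes of this size",
                     config$n_genes)
      }
      starts <- cursor[chrom] + c(0, cumsum(ex_len + c(in_len, 0))[-n_ex])
      ex <- tibble::tibble(start = as.integer(starts),
                           end = as.integer(starts + ex_len))
      gene_rows[[g]] <- tibble::tibble(
        gene_id = sprintf("gene%03d", g), chrom = chrom,
        strand = sample(c("+", "-"), 1),
        start = min(ex$start), end = max(ex$end),
        exons = list(ex), introns = list(interval_gaps(ex)))
      gap <- resample(seq(config$intergene_gap[1], config$intergene_gap[2]), 1)
      gaps[[g]] <- tibble::tibble(chrom = chrom,
                                  start = max(ex$end) + 20L,
                                  end = max(ex$end) + gap - 20L)
      cursor[chrom] <- max(ex$end) + gap
      ci <- ci %% nrow(chroms) + 1
    }
    genes <- dplyr::bind_rows(gene_rows) |>
      dplyr::arrange(.data$chrom, .data$start)
    gaps <- dplyr::bind_rows(gaps)
    # chromosome tails (after the last gene) host provirus structures
    tails <- tibble::tibble(chrom = chroms$chrom,
                            start = as.integer(cursor[chroms$chrom] + 1000),
                            end = chroms$length - 1000L)

    # ---- repeats ----
    introns_long <- gene_introns(genes) |>
      dplyr::mutate(width = .data$end - .data$start)
    rep_rows <- list()
    k <- 0
    for (i in seq_len(nrow(config$repeat_catalogue))) {
      cat_row <- config$repeat_catalogue[i, ]
      n_cp <- cat_row$copies
      if (n_cp == 0) next
      len <- cat_row$length
      ok_in <- which(introns_long$width >= len + 20)
      ok_gap <- which((gaps$end - gaps$start) >= len + 40)
      genic <- stats::runif(n_cp) < cat_row$genic_fraction
      if (length(ok_in) == 0) genic[] <- FALSE
      if (any(!genic) && length(ok_gap) == 0) {
        stop_retrotx("no intergenic gap can host a %d bp repeat", len)
      }
      host_in <- introns_long[ok_in[sample.int(length(ok_in), sum(genic),
                                               replace = TRUE)], ]
      host_gap <- gaps[ok_gap[sample.int(length(ok_gap), sum(!genic),
                                         replace = TRUE)], ]
      host <- tibble::tibble(
        chrom = c(host_in$chrom, host_gap$chrom),
        lo = c(host_in$start + 10, host_gap$start + 20),
        hi = c(host_in$end - len - 10, host_gap$end - len - 20),
        host_gene = c(host_in$gene_id, rep(NA_character_, sum(!genic))),
        host_start = c(host_in$start, host_gap$start),
        host_end = c(host_in$end, host_gap$end))
      off <- host$lo + floor(stats::runif(n_cp) * (host$hi - host$lo + 1))
      rep_rows[[i]] <- tibble::tibble(
        repeat_id = sprintf("rep%05d", k + seq_len(n_cp)),
        chrom = host$chrom, start = as.integer(off),
        end = as.integer(off + len),
        strand = sample(c("+", "-"), n_cp, replace = TRUE),
        subfamily = cat_row$subfamily,
        class_family = cat_row$class_family,
        has_polyA = stats::runif(n_cp) < cat_row$polyA_prob,
        host_gene = host$host_gene,
        host_start = as.integer(host$host_start),
        host_end = as.integer(host$host_end))
      k <- k + n_cp
    }
    k <- sum(purrr::map_int(rep_rows, nrow))
    # provirus structures in chromosome tails: LTR7Y + HERVH-int + LTR7Y
    prov_truth <- list()
    for (p in seq_len(config$n_proviruses)) {
      tci <- (p - 1) %% nrow(tails) + 1
      base <- tails$start[tci] + (ceiling(p / nrow(tails)) - 1) * 9000L
      if (base + 2 * config$provirus_ltr_length +
          config$provirus_internal_length > tails$end[tci]) {
        stop_retrotx("chromosome tail too small for provirus %d", p)
      }
      strand <- sample(c("+", "-"), 1)
      L <- config$provirus_ltr_length; M <- config$provirus_internal_length
      seg <- tibble::tibble(
        subfamily = c("LTR7Y", "HERVH-int", "LTR7Y"),
        class_family = "LTR/ERV1",
        start = as.integer(base + c(0, L + 5, L + M + 10)),
        end = as.integer(base + c(L, L + M + 5, 2 * L + M + 10)))
      k <- k + 3L
      rep_rows[[length(rep_rows) + 1]] <- tibble::tibble(
        repeat_id = sprintf("rep%05d", k - 3L + seq_len(3)),
        chrom = tails$chrom[tci], start = seg$start, end = seg$end,
        strand = strand, subfamily = seg$subfamily,
        class_family = seg$class_family, has_polyA = FALSE,
        host_gene = NA_character_,
        host_start = seg$start[1] - 100L, host_end = seg$end[3] + 100L)
      prov_truth[[p]] <- tibble::tibble(
        provirus = sprintf("HERVH_prov%d", p), chrom = tails$chrom[tci],
        start = seg$start[1], end = seg$end[3], strand = strand)
    }
    prov_truth <- dplyr::bind_rows(prov_truth)
    rep_raw <- dplyr::bind_rows(rep_rows) |>
      dplyr::arrange(.data$chrom, .data$start, .data$repeat_id)
    repeats <- tibble::tibble(
      repeat_id = rep_raw$repeat_id, chrom = rep_raw$chrom,
      start = rep_raw$start, end = rep_raw$end, strand = rep_raw$strand,
      subfamily = rep_raw$subfamily,
      family = sub("^[^/]*/", "", rep_raw$class_family),
      rte_class = sub("/.*$", "", rep_raw$class_family))
    repeats_merged <- merge_ltr_internal(repeats) |>
      flag_genic_repeats(genes)

    # ---- contigs with planted class labels ----
    plan <- config$contig_plan
    ctg <- list(); cls <- list()
    n_id <- 0
    add_contig <- function(chrom, strand, blocks, class,
                           host = NA_character_, host_repeat = NA_character_) {
      n_id <<- n_id + 1
      id <- sprintf("ctg_%s_%03d", substr(class, 1, 2), n_id)
      ctg[[n_id]] <<- tibble::tibble(
        transcript_id = id, chrom = chrom, strand = strand,
        start = min(blocks$start), end = max(blocks$end),
        blocks = list(blocks))
      cls[[n_id]] <<- tibble::tibble(transcript_id = id, planted_class = class,
                                     host_gene = host,
                                     host_repeat = host_repeat)
    }
    genic_reps <- dplyr::filter(rep_raw, !is.na(.data$host_gene),
                                !.data$subfamily %in% c("LTR7Y", "HERVH-int"))
    interg_reps <- dplyr::filter(rep_raw, is.na(.data$host_gene),
                                 !.data$subfamily %in% c("LTR7Y", "HERVH-int"))
    # fully intronic: block inside the host intron ending at the repeat tail
    pick <- genic_reps[resample(seq_len(nrow(genic_reps)),
                                min(plan[["fully_intronic"]], nrow(genic_reps))), ]
    for (i in seq_len(nrow(pick))) {
      r <- pick[i, ]
      ext <- sample(0:60, 1)
      b <- if (r$strand == "+") {
        tibble::tibble(start = max(r$host_start, r$start - ext), end = r$end)
      } else {
        tibble::tibble(start = r$start, end = min(r$host_end, r$end + ext))
      }
      add_contig(r$chrom, r$strand, b, "fully_intronic", r$host_gene,
                 r$repeat_id)
    }
    # chimeric: block from inside the upstream exon across the junction to
    # the repeat tail (gene overlap + repeat overlap, partial intron)
    pick <- genic_reps[resample(seq_len(nrow(genic_reps)),
                                min(plan[["chimeric"]], nrow(genic_reps))), ]
    for (i in seq_len(nrow(pick))) {
      r <- pick[i, ]
      gi <- genes[genes$gene_id == r$host_gene, ]
      ex <- gi$exons[[1]]
      up <- ex[ex$end <= r$host_start, ]
      up <- up[nrow(up), ]  # exon immediately left of the host intron
      b <- tibble::tibble(start = max(up$start + 5, up$end - sample(20:80, 1)),
                          end = r$end)
      add_contig(r$chrom, r$strand, b, "chimeric", r$host_gene, r$repeat_id)
    }
    # exonic: block strictly inside one exon (exons are repeat-free)
    ex_all <- gene_exons(genes) |> dplyr::filter(.data$end - .data$start >= 120)
    pick <- ex_all[resample(seq_len(nrow(ex_all)),
                            min(plan[["exonic"]], nrow(ex_all))), ]
    for (i in seq_len(nrow(pick))) {
      e <- pick[i, ]
      len <- resample(60:(e$end - e$start - 10), 1)
      st <- resample(seq(e$start + 5, e$end - len - 5), 1)
      add_contig(e$chrom, e$strand,
                 tibble::tibble(start = st, end = st + len), "exonic",
                 e$gene_id)
    }
    # stand-alone RTE: intergenic repeat span (within host-gap margins)
    pick <- interg_reps[resample(seq_len(nrow(interg_reps)),
                                 min(plan[["rte_only"]], nrow(interg_reps))), ]
    for (i in seq_len(nrow(pick))) {
      r <- pick[i, ]
      add_contig(r$chrom, r$strand,
                 tibble::tibble(start = r$start, end = r$end), "rte_only",
                 host_repeat = r$repeat_id)
    }
    # provirus contigs (stand-alone RTE class, named in truth)
    for (p in seq_len(nrow(prov_truth))) {
      pr <- prov_truth[p, ]
      n_id <- n_id + 1
      id <- pr$provirus
      ctg[[n_id]] <- tibble::tibble(
        transcript_id = id, chrom = pr$chrom, strand = pr$strand,
        start = pr$start, end = pr$end,
        blocks = list(tibble::tibble(start = pr$start, end = pr$end)))
      cls[[n_id]] <- tibble::tibble(transcript_id = id,
                                    planted_class = "rte_only",
                                    host_gene = NA_character_)
    }
    # neither: contigs in the repeat- and gene-free desert
    for (i in seq_len(plan[["neither"]])) {
      chrom <- resample(chroms$chrom, 1)
      len <- sample(200:500, 1)
      st <- resample(seq(200, config$desert_length - len - 200), 1)
      add_contig(chrom, sample(c("+", "-"), 1),
                 tibble::tibble(start = st, end = st + len), "neither")
    }
    contigs <- dplyr::bind_rows(ctg) |>
      dplyr::arrange(.data$chrom, .data$start, .data$transcript_id)
    contig_classes <- dplyr::bind_rows(cls)

    # planted cancer-overexpressed set: a fraction of the non-provirus
    # contigs of the transcribed classes
    eligible <- contig_classes$transcript_id[
      contig_classes$planted_class %in% c("fully_intronic", "chimeric",
                                          "rte_only") &
        !contig_classes$transcript_id %in% prov_truth$provirus]
    n_over <- round(config$overexpressed_fraction * nrow(contig_classes))
    overexpressed <- sort(resample(eligible, min(n_over, length(eligible))))
    # coupled genes: subset of intron-bearing genes
    intron_bearing <- genes$gene_id[purrr::map_int(genes$introns, nrow) > 0]
    coupled <- sort(resample(intron_bearing,
                           min(config$n_coupled_genes, length(intron_bearing))))
    # planted prognostic transcripts among the overexpressed set
    prognostic <- sort(resample(overexpressed,
                              min(config$n_prognostic, length(overexpressed))))
    truth <- list(
      contig_classes = contig_classes,
      overexpressed = overexpressed,
      coupled_genes = coupled,
      uncoupled_genes = setdiff(genes$gene_id, coupled),
      prognostic = tibble::tibble(feature_id = prognostic,
                                  hr = rep(config$prognostic_hr,
                                           length(prognostic))),
      proviruses = prov_truth,
      provirus_id = prov_truth$provirus[1],
      polyA_rate = stats::setNames(config$repeat_catalogue$polyA_prob,
                                   config$repeat_catalogue$subfamily),
      repeat_polyA = rep_raw[, c("repeat_id", "has_polyA")]
    )
    ann <- list(genes = genes, repeats = repeats,
                repeats_merged = repeats_merged, contigs = contigs)
  })
  genome <- with_seed(derive_seed(seed, "sequence"), {
    simulate_genome(ann$repeats, truth$repeat_polyA, config)
  })
  c(ann, list(genome = genome, truth = truth, config = config))
}

# Random genome with poly(A)/poly(T) tracts planted at the tails of
# target-primed repeat copies flagged has_polyA.
simulate_genome <- function(repeats, repeat_polyA, config) {
  chrom_names <- paste0("chr", seq_len(config$n_chromosomes))
  lens <- rep_len(config$chrom_length, config$n_chromosomes)
  seqs <- lapply(seq_along(chrom_names), function(i) {
    sample(c("A", "C", "G", "T"), lens[i], replace = TRUE)
  })
  names(seqs) <- chrom_names
  pa <- config$polyA_length
  reps <- dplyr::inner_join(repeats, repeat_polyA, by = "repeat_id")
  for (i in which(reps$has_polyA)) {
    r <- reps[i, ]
    v <- seqs[[r$chrom]]
    if (r$strand == "+") {
      v[seq(r$end - pa + 1, r$end)] <- "A"   # 1-based positions end-pa+1..end
    } else {
      v[seq(r$start + 1, r$start + pa)] <- "T"
    }
    seqs[[r$chrom]] <- v
  }
  Biostrings::DNAStringSet(vapply(seqs, paste0, "", collapse = ""))
}
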