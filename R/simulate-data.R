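# Expression, interval-quantification, survival and driver simulation on
# top of a simulated annotation, plus whole-dataset write/read.

# Sample sheet implied by the configured cohort sizes.
sim_metadata <- function(config) {
  canc <- purrr::map_dfr(config$cancer_cohorts, function(ch) {
    tibble::tibble(
      sample_id = sprintf("%s_EAC_%03d", ch, seq_len(config$n_cancer_per_cohort)),
      cohort = ch, condition = "EAC", matched_tissue = config$matched_tissue)
  })
  heal <- purrr::map_dfr(config$healthy_tissues, function(ts) {
    tibble::tibble(
      sample_id = sprintf("ref_%s_%03d", ts, seq_len(config$n_healthy_per_tissue)),
      cohort = "reference", condition = ts, matched_tissue = NA_character_)
  })
  be <- tibble::tibble(
    sample_id = sprintf("ref_BE_%03d", seq_len(config$n_be)),
    cohort = "reference", condition = "BE", matched_tissue = NA_character_)
  dplyr::bind_rows(canc, heal, be) |>
    dplyr::mutate(survival_days = NA_real_, event = NA_real_)
}

#' Simulate expression and interval-level quantification
#'
#' Contig TPM is log-normal around per-feature baselines; planted
#' overexpressed contigs are near-silent outside cancer and gain the
#' configured log2 effect in cancer samples. The subtype provirus follows
#' a two-component log-normal mixture (the component defines the planted
#' subtype label). A latent splicing-deficiency theta per cancer sample is
#' tied to the provirus state with correlation `rho`; for coupled genes,
#' intron-interval signal scales with `theta * gene level` and
#' exon-interval signal with `(1 - kappa * theta) * gene level`; healthy
#' and precursor samples have theta = 0.
#'
#' @param ann Result of [simulate_annotation()].
#' @param config A [sim_config()] (default: the one inside `ann`).
#' @param seed Master seed override.
#' @return List: `expr` (wide TPM tibble over contigs), `intervals`
#'   (interval-level quantification tibble), `meta` (sample sheet),
#'   `truth` (the annotation truth extended with `subtype` and `theta`),
#'   `clamped` (count of exon values clamped at the floor).
#' @export
simulate_expression <- function(ann, config = ann$config, seed = config$seed) {
  meta <- sim_metadata(config)
  truth <- ann$truth
  contig_ids <- ann$contigs$transcript_id
  prov_ids <- truth$proviruses$provirus
  main_prov <- truth$provirus_id
  cancer <- meta$sample_id[meta$condition == "EAC"]
  n_s <- nrow(meta)

  with_seed(derive_seed(seed, "expression"), {
    mu_f <- stats::rnorm(length(contig_ids), config$baseline_log2_mean,
                         config$baseline_log2_sd_between)
    names(mu_f) <- contig_ids
    m <- matrix(0, length(contig_ids), n_s,
                dimnames = list(contig_ids, meta$sample_id))
    for (j in seq_len(n_s)) {
      m[, j] <- 2^stats::rnorm(length(contig_ids), mu_f,
                               config$baseline_log2_sd_within)
    }
    # planted overexpressed: near-silent baseline + delta in cancer
    ov <- truth$overexpressed
    if (length(ov) > 0) {
      m[ov, ] <- 2^matrix(stats::rnorm(length(ov) * n_s, config$silent_log2,
                                       config$overexpressed_log2_sd),
                          length(ov), n_s)
      m[ov, cancer] <- 2^matrix(
        stats::rnorm(length(ov) * length(cancer),
                     config$silent_log2 + config$delta_log2,
                     config$overexpressed_log2_sd),
        length(ov), length(cancer))
    }
    # proviruses: silent outside cancer; sporadic low expression in cancer
    # except the subtype-defining provirus, which is bimodal
    if (length(prov_ids) > 0) {
      m[prov_ids, ] <- 2^matrix(stats::rnorm(length(prov_ids) * n_s, -6, 0.5),
                                length(prov_ids), n_s)
      others <- setdiff(prov_ids, main_prov)
      if (length(others) > 0) {
        m[others, cancer] <- 2^matrix(
          stats::rnorm(length(others) * length(cancer), -2, 1.5),
          length(others), length(cancer))
      }
    }
    high <- stats::runif(length(cancer)) < config$provirus_mix_weight
    z <- stats::rnorm(length(cancer))
    mode_log2 <- ifelse(high, log2(config$provirus_high_mode),
                        log2(config$provirus_low_mode))
    m[main_prov, cancer] <- 2^(mode_log2 + config$provirus_log2_sd * z)
    subtype <- tibble::tibble(sample_id = cancer,
                              subtype = ifelse(high, "high", "low"))
  })

  with_seed(derive_seed(seed, "theta"), {
    # theta tied to the provirus state; at rho = 1 it is a monotone
    # function of the provirus draw within each mixture component
    th_mode <- ifelse(high, config$theta_high, config$theta_low)
    th_signal <- th_mode + config$theta_jitter * stats::pnorm(z)
    th_noise <- stats::runif(length(cancer), 0, config$theta_high)
    theta <- stats::setNames(rep(0, n_s), meta$sample_id)
    theta[cancer] <- config$rho * th_signal + (1 - config$rho) * th_noise
    theta <- pmin(theta, 1)

    # interval-level quantification for all genes
    genes <- ann$genes
    mu_g <- stats::rnorm(nrow(genes), config$gene_log2_mean,
                         config$gene_log2_sd_between)
    names(mu_g) <- genes$gene_id
    clamped <- 0L
    rows <- purrr::map(seq_len(nrow(genes)), function(gi) {
      gid <- genes$gene_id[gi]
      ex <- genes$exons[[gi]]; intr <- genes$introns[[gi]]
      coupled <- gid %in% truth$coupled_genes
      G <- 2^stats::rnorm(n_s, mu_g[gid], config$gene_log2_sd_within)
      noise_e <- 2^stats::rnorm(n_s, 0, config$layer_log2_noise)
      noise_i <- 2^stats::rnorm(n_s, 0, config$layer_log2_noise)
      if (coupled) {
        efrac <- 1 - config$kappa * theta[meta$sample_id]
        nclamp <- sum(efrac <= config$exon_clamp_floor)
        if (nclamp > 0) clamped <<- clamped + nclamp
        efrac <- pmax(efrac, config$exon_clamp_floor)
        exon_tot <- efrac * G * noise_e
        intron_tot <- (theta[meta$sample_id] + config$retention_floor) * G * noise_i
      } else {
        exon_tot <- G * noise_e
        intron_tot <- config$uncoupled_retention * G * noise_i
      }
      if (nrow(intr) == 0) intron_tot <- rep(0, n_s)
      ew <- (ex$end - ex$start) / sum(ex$end - ex$start)
      vals <- outer(ew, exon_tot)
      ids <- sprintf("%s_exon%02d", gid, seq_len(nrow(ex)))
      layer <- rep("exon", nrow(ex))
      if (nrow(intr) > 0) {
        iw <- (intr$end - intr$start) / sum(intr$end - intr$start)
        vals <- rbind(vals, outer(iw, intron_tot))
        ids <- c(ids, sprintf("%s_intron%02d", gid, seq_len(nrow(intr))))
        layer <- c(layer, rep("intron", nrow(intr)))
      }
      colnames(vals) <- meta$sample_id
      dplyr::bind_cols(
        tibble::tibble(interval_id = ids, gene_id = gid, layer = layer),
        tibble::as_tibble(vals))
    })
    intervals <- dplyr::bind_rows(rows)
  })

  truth$subtype <- subtype
  truth$theta <- theta
  list(expr = matrix_expr(m), intervals = intervals, meta = meta,
       truth = truth, clamped = clamped)
}

#' Simulate survival data
#'
#' Event times are exponential with hazard
#' `h0 * exp(sum(beta * covariate))`, where each planted prognostic
#' transcript contributes its log hazard ratio through the indicator of
#' top-tertile expression within the sample's cohort, and the subtype
#' contributes `log(subtype_hr)` for high-subtype samples. Censoring is
#' independent uniform, numerically calibrated so the expected censored
#' fraction matches the configuration.
#'
#' @param exprset Result of [simulate_expression()].
#' @param config A [sim_config()].
#' @param seed Master seed override.
#' @return `meta` tibble with `survival_days` and `event` filled for
#'   cancer samples; attribute `censor_horizon` records the calibrated
#'   censoring window.
#' @export
simulate_survival <- function(exprset, config, seed = config$seed) {
  if (config$censoring_fraction >= 1) stop_retrotx("censoring fraction must be < 1")
  meta <- exprset$meta
  truth <- exprset$truth
  m <- expr_matrix(exprset$expr)
  cancer_meta <- dplyr::filter(meta, .data$condition == "EAC")
  with_seed(derive_seed(seed, "survival"), {
    lp <- stats::setNames(rep(0, nrow(cancer_meta)), cancer_meta$sample_id)
    for (f in truth$prognostic$feature_id) {
      beta <- log(truth$prognostic$hr[truth$prognostic$feature_id == f])
      for (ch in unique(cancer_meta$cohort)) {
        ids <- cancer_meta$sample_id[cancer_meta$cohort == ch]
        st <- stratify_tertiles(m[f, ids], ids)
        top <- st$sample_id[st$stratum == "high"]
        lp[top] <- lp[top] + beta
      }
    }
    if (config$subtype_hr != 1) {
      hi <- truth$subtype$sample_id[truth$subtype$subtype == "high"]
      lp[hi] <- lp[hi] + log(config$subtype_hr)
    }
    rate <- config$baseline_hazard * exp(lp)
    t_event <- stats::rexp(length(rate), rate)
    if (config$censoring_fraction == 0) {
      time <- t_event; event <- rep(1, length(rate))
      horizon <- Inf
    } else {
      cens_frac <- function(M) {
        mean((1 - exp(-rate * M)) / (rate * M)) - config$censoring_fraction
      }
      horizon <- stats::uniroot(cens_frac, c(1, 1e7))$root
      t_cens <- stats::runif(length(rate), 0, horizon)
      event <- as.numeric(t_event <= t_cens)
      time <- pmin(t_event, t_cens)
    }
  })
  meta$survival_days[match(cancer_meta$sample_id, meta$sample_id)] <- time
  meta$event[match(cancer_meta$sample_id, meta$sample_id)] <- event
  attr(meta, "censor_horizon") <- horizon
  meta
}

#' Simulate a binary driver-alteration matrix
#'
#' One Bernoulli draw per driver and cancer sample, with
#' subtype-conditional rates from the configured driver catalogue.
#'
#' @param exprset Result of [simulate_expression()].
#' @param config A [sim_config()].
#' @param seed Master seed override.
#' @return Wide tibble: `feature_id` (driver) plus one 0/1 column per
#'   cancer sample.
#' @export
simulate_drivers <- function(exprset, config, seed = config$seed) {
  cat_d <- config$driver_catalogue
  if (any(cat_d$rate_high < 0 | cat_d$rate_high > 1 |
          cat_d$rate_low < 0 | cat_d$rate_low > 1)) {
    stop_retrotx("driver rates must lie in [0, 1]")
  }
  sub <- exprset$truth$subtype
  with_seed(derive_seed(seed, "drivers"), {
    m <- matrix(0L, nrow(cat_d), nrow(sub),
                dimnames = list(cat_d$driver, sub$sample_id))
    for (i in seq_len(nrow(cat_d))) {
      rate <- ifelse(sub$subtype == "high", cat_d$rate_high[i], cat_d$rate_low[i])
      m[i, ] <- stats::rbinom(nrow(sub), 1, rate)
    }
    matrix_expr(m)
  })
}

#' Simulate a complete dataset
#'
#' Runs [simulate_annotation()], [simulate_expression()],
#' [simulate_survival()] and [simulate_drivers()] under one master seed.
#'
#' @param config A [sim_config()].
#' @param seed Master seed (default `config$seed`).
#' @return Object of class `rte_sim`: list with `genes`, `repeats`,
#'   `repeats_merged`, `contigs`, `genome`, `expr`, `intervals`, `meta`,
#'   `drivers`, `truth`, `config`.
#' @export
simulate_dataset <- function(config = sim_config(), seed = config$seed) {
  ann <- simulate_annotation(config, seed)
  ex <- simulate_expression(ann, config, seed)
  meta <- simulate_survival(ex, config, seed)
  drivers <- simulate_drivers(ex, config, seed)
  structure(list(genes = ann$genes, repeats = ann$repeats,
                 repeats_merged = ann$repeats_merged, contigs = ann$contigs,
                 genome = ann$genome, expr = ex$expr,
                 intervals = ex$intervals, meta = meta, drivers = drivers,
                 truth = ex$truth, config = config),
            class = "rte_sim")
}

#' @export
print.rte_sim <- function(x, ...) {
  cat(sprintf(paste0("<rte_sim> %d genes, %d repeat rows, %d contigs, ",
                     "%d samples\n"),
              nrow(x$genes), nrow(x$repeats), nrow(x$contigs),
              nrow(x$meta)))
  invisible(x)
}

#' Write a simulated dataset to plain-text files
#'
#' Writes GTF, BED12, repeat TSV, FASTA, expression TSV, interval
#' quantification TSV, metadata TSV, driver TSV and a JSON truth file,
#' plus a manifest listing every file with its md5 checksum.
#'
#' @param sim An `rte_sim` from [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Manifest tibble (`file`, `md5`), invisibly written to
#'   `manifest.tsv` as well.
#' @export
write_dataset <- function(sim, dir) {
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE)
  if (!ok || file.access(dir, 2) != 0) stop_retrotx("directory not writable: %s", dir)
  p <- function(f) file.path(dir, f)
  write_gtf(sim$genes, p("genes.gtf"))
  write_bed12(sim$contigs, p("contigs.bed"))
  write_repeat_table(sim$repeats, p("repeats.tsv"))
  Biostrings::writeXStringSet(sim$genome, p("genome.fa"))
  readr::write_tsv(sim$expr, p("expression.tsv"))
  readr::write_tsv(sim$intervals, p("intervals.tsv"))
  readr::write_tsv(sim$meta, p("metadata.tsv"))
  readr::write_tsv(sim$drivers, p("drivers.tsv"))
  truth <- sim$truth
  truth$theta <- as.list(truth$theta)
  truth$polyA_rate <- as.list(truth$polyA_rate)
  jsonlite::write_json(truth, p("truth.json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "columns", pretty = TRUE)
  files <- c("genes.gtf", "contigs.bed", "repeats.tsv", "genome.fa",
             "expression.tsv", "intervals.tsv", "metadata.tsv",
             "drivers.tsv", "truth.json")
  manifest <- tibble::tibble(file = files,
                             md5 = unname(tools::md5sum(p(files))))
  readr::write_tsv(manifest, p("manifest.tsv"))
  manifest
}

#' Read back a dataset directory
#'
#' @param dir Directory written by [write_dataset()].
#' @return List with the same tabular components as `rte_sim` (genome as
#'   a DNAStringSet; truth as a plain list).
#' @export
read_dataset <- function(dir) {
  p <- function(f) file.path(dir, f)
  list(
    genes = read_gtf(p("genes.gtf")),
    contigs = read_bed12(p("contigs.bed")),
    repeats = read_repeat_table(p("repeats.tsv")),
    genome = Biostrings::readDNAStringSet(p("genome.fa")),
    expr = readr::read_tsv(p("expression.tsv"), show_col_types = FALSE),
    intervals = readr::read_tsv(p("intervals.tsv"), show_col_types = FALSE),
    meta = readr::read_tsv(p("metadata.tsv"), show_col_types = FALSE),
    drivers = readr::read_tsv(p("drivers.tsv"), show_col_types = FALSE),
    truth = jsonlite::read_json(p("truth.json"), simplifyVector = TRUE)
  )
}
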