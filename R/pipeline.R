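# File-in/file-out stage orchestration. Stages communicate only through
# files so every run is inspectable and resumable; a thin command-line
# wrapper over run_stage() ships in inst/cli/retrotx.R.

#' Run one pipeline stage
#'
#' Each stage reads its inputs from `dir`, writes its outputs back into
#' `dir` as TSVs, and returns the primary output tibble. Stages:
#' \describe{
#'   \item{simulate}{[simulate_dataset()] + [write_dataset()].}
#'   \item{classify}{[classify_contigs()] on the dataset files ->
#'     `classification.tsv`.}
#'   \item{select}{[select_overexpressed()] -> `selection.tsv`.}
#'   \item{enrich}{[subfamily_enrichment()] of the selection ->
#'     `enrichment.tsv`.}
#'   \item{signature}{[define_panel()] + [score_samples()] +
#'     [roc_curve()] -> `panel.tsv`, `scores.tsv`, `roc.tsv`.}
#'   \item{survival}{[survival_screen()] + [dual_cohort_filter()] on the
#'     selected features -> `survival_records.tsv`, `prognostic.tsv`.}
#'   \item{introns}{[collapse_gene_counts()] -> `gene_split.tsv`.}
#'   \item{subtype}{[assign_subtype()] + [linear_association()] families ->
#'     `subtypes.tsv`, `associations.tsv`.}
#'   \item{report}{collates stage row counts -> `report.tsv`.}
#' }
#'
#' @param stage Stage name (see above).
#' @param dir Working directory holding the dataset and stage outputs.
#' @param config A [sim_config()] used by the simulate stage (and for the
#'   seed recorded in logs).
#' @param thresholds,criteria,filter Stage configuration objects.
#' @return The stage's primary tibble, invisibly.
#' @export
run_stage <- function(stage, dir, config = sim_config(),
                      thresholds = selection_thresholds(),
                      criteria = panel_criteria(),
                      filter = prognostic_filter()) {
  stages <- c("simulate", "classify", "select", "enrich", "signature",
              "survival", "introns", "subtype", "report")
  if (!stage %in% stages) {
    stop_retrotx("unknown stage '%s' (expected one of: %s)", stage,
                 paste(stages, collapse = ", "))
  }
  p <- function(f) file.path(dir, f)
  need <- function(f, from) {
    if (!file.exists(p(f))) {
      stop_retrotx("missing %s: run the '%s' stage first", f, from)
    }
  }
  out <- switch(
    stage,
    simulate = {
      sim <- simulate_dataset(config)
      write_dataset(sim, dir)
    },
    classify = {
      need("contigs.bed", "simulate")
      genes <- read_gtf(p("genes.gtf"))
      repeats <- read_repeat_table(p("repeats.tsv")) |>
        merge_ltr_internal() |>
        flag_genic_repeats(genes)
      contigs <- read_bed12(p("contigs.bed"))
      cl <- classify_contigs(contigs, genes, repeats) |>
        dplyr::select(-"classes_hit", -"subfamilies_hit")
      readr::write_tsv(cl, p("classification.tsv"))
      cl
    },
    select = {
      need("expression.tsv", "simulate")
      expr <- readr::read_tsv(p("expression.tsv"), show_col_types = FALSE)
      meta <- readr::read_tsv(p("metadata.tsv"), show_col_types = FALSE)
      sel <- select_overexpressed(expr, meta, "EAC", thresholds)
      if (!any(sel$selected)) rlang::warn("empty selection at these thresholds")
      readr::write_tsv(tibble::as_tibble(sel), p("selection.tsv"))
      sel
    },
    enrich = {
      need("selection.tsv", "select")
      need("classification.tsv", "classify")
      sel <- readr::read_tsv(p("selection.tsv"), show_col_types = FALSE)
      cl <- readr::read_tsv(p("classification.tsv"), show_col_types = FALSE)
      membership <- cl |>
        dplyr::filter(!is.na(.data$subfamilies), .data$subfamilies != "") |>
        dplyr::mutate(subfamily = strsplit(.data$subfamilies, ",")) |>
        tidyr::unnest("subfamily") |>
        dplyr::select("transcript_id", "subfamily")
      enr <- subfamily_enrichment(sel$feature_id[sel$selected],
                                  sel$feature_id, membership)
      readr::write_tsv(enr, p("enrichment.tsv"))
      enr
    },
    signature = {
      need("selection.tsv", "select")
      expr <- readr::read_tsv(p("expression.tsv"), show_col_types = FALSE)
      meta <- readr::read_tsv(p("metadata.tsv"), show_col_types = FALSE)
      sel <- readr::read_tsv(p("selection.tsv"), show_col_types = FALSE)
      cand <- dplyr::filter(expr, .data$feature_id %in%
                              sel$feature_id[sel$selected])
      panel <- define_panel(cand, meta, "EAC",
                            negative_conditions = infer_healthy_conditions(meta),
                            criteria = criteria)
      scores <- score_samples(expr, panel)
      labels <- meta$condition[match(scores$sample_id, meta$sample_id)] == "EAC"
      roc <- roc_curve(scores$score, labels)
      readr::write_tsv(tibble::as_tibble(panel), p("panel.tsv"))
      readr::write_tsv(dplyr::mutate(scores, label = labels), p("scores.tsv"))
      readr::write_tsv(
        dplyr::bind_cols(roc$curve, auc = roc$auc), p("roc.tsv"))
      scores
    },
    survival = {
      need("selection.tsv", "select")
      expr <- readr::read_tsv(p("expression.tsv"), show_col_types = FALSE)
      meta <- readr::read_tsv(p("metadata.tsv"), show_col_types = FALSE)
      sel <- readr::read_tsv(p("selection.tsv"), show_col_types = FALSE)
      rec <- survival_screen(expr, meta,
                             features = sel$feature_id[sel$selected])
      prog <- dual_cohort_filter(rec, filter)
      readr::write_tsv(tibble::as_tibble(rec), p("survival_records.tsv"))
      readr::write_tsv(prog, p("prognostic.tsv"))
      prog
    },
    introns = {
      need("intervals.tsv", "simulate")
      intervals <- readr::read_tsv(p("intervals.tsv"), show_col_types = FALSE)
      split <- collapse_gene_counts(intervals)
      readr::write_tsv(split, p("gene_split.tsv"))
      split
    },
    subtype = {
      need("expression.tsv", "simulate")
      need("gene_split.tsv", "introns")
      expr <- readr::read_tsv(p("expression.tsv"), show_col_types = FALSE)
      meta <- readr::read_tsv(p("metadata.tsv"), show_col_types = FALSE)
      truth <- jsonlite::read_json(p("truth.json"), simplifyVector = TRUE)
      cfg <- subtype_config(truth$provirus_id)
      cancer <- meta$sample_id[meta$condition == "EAC"]
      st <- assign_subtype(expr[, c("feature_id", cancer)], cfg)
      split <- readr::read_tsv(p("gene_split.tsv"), show_col_types = FALSE)
      fam <- purrr::imap_dfr(
        list(exon = "exon_value", intron = "intron_value"),
        function(col, nm) {
          wide <- split |>
            dplyr::filter(.data$sample_id %in% cancer) |>
            dplyr::select("gene_id", "sample_id", dplyr::all_of(col)) |>
            tidyr::pivot_wider(names_from = "sample_id",
                               values_from = dplyr::all_of(col)) |>
            dplyr::rename(feature_id = "gene_id")
          linear_association(wide, st, nm)
        })
      tx <- linear_association(expr[, c("feature_id", cancer)], st,
                               "transcripts")
      assoc <- dplyr::bind_rows(tx, fam)
      readr::write_tsv(st, p("subtypes.tsv"))
      readr::write_tsv(assoc, p("associations.tsv"))
      st
    },
    report = {
      outs <- c("classification.tsv", "selection.tsv", "enrichment.tsv",
                "panel.tsv", "prognostic.tsv", "gene_split.tsv",
                "subtypes.tsv", "associations.tsv")
      present <- outs[file.exists(p(outs))]
      rep <- purrr::map_dfr(present, function(f) {
        tibble::tibble(file = f,
                       rows = nrow(readr::read_tsv(p(f), show_col_types = FALSE)))
      })
      readr::write_tsv(rep, p("report.tsv"))
      rep
    })
  invisible(out)
}
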