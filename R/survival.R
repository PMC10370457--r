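# Expression-stratified survival testing and the dual-cohort prognostic
# filter, at transcript and gene (exon/intron) level.

#' Stratify samples into expression tertiles
#'
#' Ranks samples by expression (ties broken by sample id for determinism)
#' and assigns the bottom `floor(n * fraction)` to `low`, the top the same
#' number to `high`, and the remainder to `mid` (excluded downstream).
#'
#' @param values Numeric expression values.
#' @param sample_ids Sample ids aligned with `values`.
#' @param fraction Fraction per extreme group (default 1/3).
#' @return Tibble `sample_id`, `value`, `stratum` in
#'   `{"low","mid","high"}`.
#' @export
stratify_tertiles <- function(values, sample_ids, fraction = 1 / 3) {
  n <- length(values)
  if (n < 6) stop_retrotx("need >= 6 samples to stratify")
  if (length(sample_ids) != n) stop_retrotx("values/sample_ids length mismatch")
  if (max(values) == min(values)) {
    stop_retrotx("no stratification possible: constant values")
  }
  k <- floor(n * fraction)
  ord <- order(values, sample_ids)
  stratum <- rep("mid", n)
  stratum[ord[seq_len(k)]] <- "low"
  stratum[ord[seq.int(n - k + 1, n)]] <- "high"
  tibble::tibble(sample_id = sample_ids, value = values, stratum = stratum)
}

#' Log-rank and Cox comparison of two survival groups
#'
#' Log-rank p between the low and high strata, and a univariate Cox
#' proportional-hazards fit on the binary high-vs-low indicator (Efron tie
#' handling) giving the hazard ratio, its 95% CI and Wald p. Records with
#' a zero-event group are flagged non-estimable.
#'
#' @param strata Tibble from [stratify_tertiles()] (only `low`/`high` rows
#'   are used), or a list with `low`/`high` character vectors.
#' @param surv Tibble `sample_id`, `time` (days, > 0), `event` (0/1).
#' @return One-row tibble: `hr`, `hr_lo`, `hr_hi`, `logrank_p`, `cox_p`,
#'   `n_low`, `n_high`, `events_low`, `events_high`, `estimable`.
#' @export
fit_survival <- function(strata, surv) {
  assert_columns(surv, c("sample_id", "time", "event"), "surv")
  if (any(surv$time <= 0)) stop_retrotx("survival times must be positive")
  if (!all(surv$event %in% c(0, 1))) stop_retrotx("event must be 0/1")
  if (is.data.frame(strata)) {
    low <- strata$sample_id[strata$stratum == "low"]
    high <- strata$sample_id[strata$stratum == "high"]
  } else {
    low <- strata$low; high <- strata$high
  }
  d <- dplyr::inner_join(
    tibble::tibble(sample_id = c(low, high),
                   group = rep(c(0, 1), c(length(low), length(high)))),
    surv, by = "sample_id")
  ev_low <- sum(d$event[d$group == 0])
  ev_high <- sum(d$event[d$group == 1])
  base <- tibble::tibble(hr = NA_real_, hr_lo = NA_real_, hr_hi = NA_real_,
                         logrank_p = NA_real_, cox_p = NA_real_,
                         n_low = sum(d$group == 0), n_high = sum(d$group == 1),
                         events_low = ev_low, events_high = ev_high,
                         estimable = FALSE)
  if (ev_low == 0 || ev_high == 0) return(base)
  s <- survival::Surv(d$time, d$event)
  lr <- survival::survdiff(s ~ d$group)
  lr_p <- stats::pchisq(lr$chisq, df = 1, lower.tail = FALSE)
  cx <- survival::coxph(s ~ d$group, ties = "efron")
  sm <- summary(cx)
  base |>
    dplyr::mutate(hr = unname(sm$conf.int[1, "exp(coef)"]),
                  hr_lo = unname(sm$conf.int[1, "lower .95"]),
                  hr_hi = unname(sm$conf.int[1, "upper .95"]),
                  logrank_p = lr_p,
                  cox_p = unname(sm$coefficients[1, "Pr(>|z|)"]),
                  estimable = TRUE)
}

#' Tertile survival screen over many features
#'
#' For every feature and cohort: stratify samples into expression tertiles
#' and fit [fit_survival()]. This is the per-feature engine behind the
#' dual-cohort prognostic filter.
#'
#' @param expr Wide expression tibble.
#' @param meta Metadata with `sample_id`, `cohort`, `survival_days`,
#'   `event`; only rows with both survival fields are used.
#' @param features Feature ids to screen (default: all rows of `expr`).
#' @param fraction Tertile fraction, see [stratify_tertiles()].
#' @return Object of class `rte_surv_screen`: tibble with one row per
#'   feature x cohort (columns of [fit_survival()] plus `feature_id`,
#'   `cohort`).
#' @export
survival_screen <- function(expr, meta, features = NULL, fraction = 1 / 3) {
  assert_columns(meta, c("sample_id", "cohort", "survival_days", "event"), "meta")
  m <- expr_matrix(expr)
  features <- features %||% rownames(m)
  meta <- dplyr::filter(meta, !is.na(.data$survival_days), !is.na(.data$event),
                        .data$sample_id %in% colnames(m))
  out <- meta |>
    dplyr::group_by(.data$cohort) |>
    dplyr::group_map(function(d, key) {
      surv <- tibble::tibble(sample_id = d$sample_id, time = d$survival_days,
                             event = d$event)
      purrr::map_dfr(features, function(f) {
        v <- m[f, d$sample_id]
        if (max(v) == min(v)) {
          return(tibble::tibble(feature_id = f, cohort = key$cohort,
                                estimable = FALSE))
        }
        st <- stratify_tertiles(v, d$sample_id, fraction)
        fit_survival(st, surv) |>
          dplyr::mutate(feature_id = f, cohort = key$cohort, .before = 1)
      })
    }) |>
    dplyr::bind_rows() |>
    dplyr::relocate("feature_id", "cohort")
  structure(out, class = c("rte_surv_screen", class(out)))
}

#' Prognostic filter configuration
#'
#' @param p_max Per-cohort significance threshold (default 0.05).
#' @param hr_high,hr_low Hazard-ratio magnitude gates on the cross-cohort
#'   geometric mean (defaults 2 and 0.5).
#' @param p_on Which p gate to filter on: `"cox"` (Wald, default) or
#'   `"logrank"`.
#' @param per_cohort_hr If TRUE, the magnitude gate must hold in every
#'   cohort separately rather than on the geometric mean.
#' @return Named list of class `prognostic_filter`.
#' @export
prognostic_filter <- function(p_max = 0.05, hr_high = 2, hr_low = 0.5,
                              p_on = c("cox", "logrank"),
                              per_cohort_hr = FALSE) {
  p_on <- match.arg(p_on)
  stopifnot(hr_low > 0, hr_low < 1, hr_high > 1, p_max > 0, p_max < 1)
  structure(list(p_max = p_max, hr_high = hr_high, hr_low = hr_low,
                 p_on = p_on, per_cohort_hr = per_cohort_hr),
            class = "prognostic_filter")
}

#' Dual-cohort prognostic filter
#'
#' A feature is kept iff it has an estimable record in every cohort, the
#' chosen p-value is below `p_max` in each cohort separately, the hazard
#' directions are concordant across cohorts, and the geometric-mean hazard
#' ratio is at least `hr_high` (adverse) or at most `hr_low` (protective).
#'
#' @param records `rte_surv_screen` tibble (feature x cohort rows).
#' @param filter A [prognostic_filter()] object.
#' @return Tibble with one row per feature present in all cohorts:
#'   `feature_id`, `n_cohorts`, `hr_geomean`, `max_p`, `concordant`,
#'   `prognostic`, `direction` (`"protective"`/`"adverse"`/NA).
#' @export
dual_cohort_filter <- function(records, filter = prognostic_filter()) {
  assert_columns(records, c("feature_id", "cohort", "hr", "estimable"), "records")
  n_cohorts <- dplyr::n_distinct(records$cohort)
  pcol <- if (filter$p_on == "cox") "cox_p" else "logrank_p"
  res <- records |>
    dplyr::group_by(.data$feature_id) |>
    dplyr::summarise(
      n_cohorts = dplyr::n_distinct(.data$cohort),
      all_estimable = all(.data$estimable),
      hr_geomean = exp(mean(log(.data$hr))),
      max_p = max(.data[[pcol]]),
      concordant = all(.data$hr > 1) || all(.data$hr < 1),
      hr_all_high = all(.data$hr >= filter$hr_high),
      hr_all_low = all(.data$hr <= filter$hr_low),
      .groups = "drop")
  incomplete <- res$n_cohorts < n_cohorts | !res$all_estimable
  if (any(incomplete)) {
    rlang::inform(sprintf(
      "%d feature(s) missing or non-estimable in some cohort; excluded",
      sum(incomplete)))
  }
  res |>
    dplyr::mutate(
      mag_ok = if (filter$per_cohort_hr) .data$hr_all_high | .data$hr_all_low
               else .data$hr_geomean >= filter$hr_high |
                    .data$hr_geomean <= filter$hr_low,
      prognostic = !incomplete & .data$max_p < filter$p_max &
        .data$concordant & .data$mag_ok,
      direction = dplyr::case_when(
        !.data$prognostic ~ NA_character_,
        .data$hr_geomean <= filter$hr_low ~ "protective",
        .data$hr_geomean >= filter$hr_high ~ "adverse",
        TRUE ~ NA_character_
      )) |>
    dplyr::select("feature_id", "n_cohorts", "hr_geomean", "max_p",
                  "concordant", "prognostic", "direction")
}

#' Gene-level exon/intron prognostics
#'
#' Runs the tertile screen and dual-cohort filter independently on the
#' exon-collapsed and intron-collapsed layers of gene expression, and
#' reports the intersection of prognostic genes with concordance flags
#' (whether the two layers' geometric-mean hazard ratios point the same
#' way).
#'
#' @param split Gene-level split tibble from [collapse_gene_counts()].
#' @param meta Metadata as in [survival_screen()].
#' @param filter A [prognostic_filter()].
#' @param fraction Tertile fraction.
#' @return List with `exon`, `intron` (dual-cohort filter tibbles) and
#'   `concordance` (tibble `gene_id`, `hr_exon`, `hr_intron`,
#'   `concordant`).
#' @export
gene_level_prognostics <- function(split, meta, filter = prognostic_filter(),
                                   fraction = 1 / 3) {
  layer_expr <- function(col) {
    split |>
      dplyr::select("gene_id", "sample_id", dplyr::all_of(col)) |>
      tidyr::pivot_wider(names_from = "sample_id", values_from = dplyr::all_of(col)) |>
      dplyr::rename(feature_id = "gene_id")
  }
  res <- purrr::map(c(exon = "exon_value", intron = "intron_value"),
                    function(col) {
    dual_cohort_filter(survival_screen(layer_expr(col), meta,
                                       fraction = fraction), filter)
  })
  exon_hits <- dplyr::filter(res$exon, .data$prognostic)
  intron_hits <- dplyr::filter(res$intron, .data$prognostic)
  inter <- dplyr::inner_join(
    dplyr::select(exon_hits, gene_id = "feature_id", hr_exon = "hr_geomean"),
    dplyr::select(intron_hits, gene_id = "feature_id", hr_intron = "hr_geomean"),
    by = "gene_id") |>
    dplyr::mutate(concordant = sign(log(.data$hr_exon)) == sign(log(.data$hr_intron)))
  list(exon = res$exon, intron = res$intron, concordance = inter)
}
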