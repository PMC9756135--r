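#' Pipeline configuration
#'
#' Collects every threshold of the pipeline plus either file paths to the
#' input tables or a [sim_config()] for synthetic mode. Unknown keys and
#' out-of-range thresholds are rejected before any computation.
#'
#' @param lysate_psms,media_psms,annotations Paths to the input TSVs
#'   (ignored in synthetic mode).
#' @param sim A [sim_config()]; when supplied the pipeline simulates its
#'   inputs instead of reading files.
#' @param purity_min,low_intensity_percentile PSM filter thresholds
#'   (see [filter_psms()]).
#' @param protein_fdr,psm_fdr FDR levels (see [fdr_filter()]).
#' @param alpha Significance level for BFA-sensitivity calls.
#' @param bin_edges M/L bin edges (see [bin_signal_peptide_fraction()]).
#' @param conventional_ml_min,candidate_ml_min,tm_ml_min Label thresholds
#'   (see [assign_labels()]).
#' @param top_n Candidate list length.
#' @param control,treatment Condition names in the channel layout.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(lysate_psms = NULL, media_psms = NULL,
                            annotations = NULL, sim = NULL,
                            purity_min = 0.5, low_intensity_percentile = 5,
                            protein_fdr = 0.01, psm_fdr = 0.01,
                            alpha = 0.05, bin_edges = c(0.5, 1, 2, 5, 10, 20),
                            conventional_ml_min = 1, candidate_ml_min = 1,
                            tm_ml_min = 1, top_n = 10,
                            control = "ctrl", treatment = "bfa") {
  stop_cfg <- function(msg) abort(msg, class = "secretr_config_error")
  if (is.null(sim) && (is.null(lysate_psms) || is.null(media_psms))) {
    stop_cfg("Provide either `sim` (synthetic mode) or paths to both PSM tables.")
  }
  if (!is.null(sim)) validate_sim_config(sim)
  if (purity_min < 0 || purity_min > 1) stop_cfg("`purity_min` must be in [0, 1].")
  if (low_intensity_percentile < 0 || low_intensity_percentile >= 100) {
    stop_cfg("`low_intensity_percentile` must be in [0, 100).")
  }
  for (nm in c("protein_fdr", "psm_fdr", "alpha")) {
    v <- get(nm)
    if (v <= 0 || v >= 1) stop_cfg(sprintf("`%s` must be in (0, 1).", nm))
  }
  if (is.unsorted(bin_edges, strictly = TRUE) || any(bin_edges <= 0)) {
    stop_cfg("`bin_edges` must be strictly ascending and positive.")
  }
  if (top_n < 1) stop_cfg("`top_n` must be at least 1.")
  structure(list(
    lysate_psms = lysate_psms, media_psms = media_psms,
    annotations = annotations, sim = sim,
    purity_min = purity_min,
    low_intensity_percentile = low_intensity_percentile,
    protein_fdr = protein_fdr, psm_fdr = psm_fdr, alpha = alpha,
    bin_edges = bin_edges, conventional_ml_min = conventional_ml_min,
    candidate_ml_min = candidate_ml_min, tm_ml_min = tm_ml_min,
    top_n = top_n, control = control, treatment = treatment
  ), class = "pipeline_config")
}

#' Run the full secretome pipeline
#'
#' Executes (optionally) simulate, then filter, deduplicate, protein
#' grouping, target-decoy FDR, quantification of each experiment, M/L
#' ratios, detection summary, M/L binning, the three BFA contrasts,
#' classification, and (in synthetic mode) scoring against the ground
#' truth. When `out_dir` is given, every intermediate table is written as a
#' TSV with a stable column order together with a run log; re-running the
#' same configuration reproduces the bundle byte for byte.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory for the TSV bundle.
#' @return (Invisibly) a list with every intermediate result: `truth`
#'   (synthetic mode), `filter_report`, `groups`, `quant_lysate`,
#'   `quant_media`, `ratio_table`, `detection`, `bins`, `contrasts`,
#'   `calls`, `candidates`, `tm_table`, and `score` (synthetic mode).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (!inherits(config, "pipeline_config")) {
    abort("`config` must be a pipeline_config().", class = "secretr_config_error")
  }

  truth <- NULL
  if (!is.null(config$sim)) {
    truth <- generate_ground_truth(config$sim)
    tables <- simulate_psm_tables(truth, config$sim)
    lysate_raw <- tables$lysate
    media_raw <- tables$media
    annotations <- tables$annotations
  } else {
    lysate_raw <- read_psm_table(config$lysate_psms)
    media_raw <- read_psm_table(config$media_psms)
    annotations <- if (!is.null(config$annotations)) {
      read_annotation_table(config$annotations)
    }
  }

  prep <- function(psms) {
    filtered <- filter_psms(psms, purity_min = config$purity_min,
                            low_intensity_percentile = config$low_intensity_percentile)
    list(psms = deduplicate_peptide_ions(filtered),
         report = psm_filter_report(filtered))
  }
  lysate_p <- prep(lysate_raw)
  media_p <- prep(media_raw)
  lysate_f <- lysate_p$psms
  media_f <- media_p$psms
  filter_report <- bind_rows(lysate_p$report, media_p$report)

  combined <- bind_rows(lysate_f, media_f)
  inference <- infer_protein_groups(combined)
  kept <- fdr_filter(combined, inference$groups, inference$peptide_map,
                     protein_fdr = config$protein_fdr,
                     psm_fdr = config$psm_fdr)

  quant_lysate <- quantify_proteins(
    filter(kept$psms, .data$run_id == "lysate"), inference$peptide_map, "lysate")
  quant_media <- quantify_proteins(
    filter(kept$psms, .data$run_id == "media"), inference$peptide_map, "media")

  ratio_table <- compute_ml_ratios(quant_media, quant_lysate,
                                   annotations = annotations)
  detection <- summarize_detection(quant_media, quant_lysate, annotations)
  bins <- bin_signal_peptide_fraction(ratio_table, config$bin_edges,
                                      condition = config$control)

  contrasts <- bfa_contrasts(quant_lysate, quant_media, ratio_table,
                             control = config$control,
                             treatment = config$treatment)
  diff_ml <- tidy(contrasts$ml)

  calls <- assign_labels(ratio_table, diff_ml, alpha = config$alpha,
                         conventional_ml_min = config$conventional_ml_min,
                         candidate_ml_min = config$candidate_ml_min,
                         tm_ml_min = config$tm_ml_min,
                         condition = config$control)
  candidates <- rank_unconventional_candidates(ratio_table, diff_ml,
                                               top_n = config$top_n,
                                               alpha = config$alpha,
                                               condition = config$control)
  tm_table <- tm_bfa_table(ratio_table, diff_ml, ml_min = config$tm_ml_min,
                           alpha = config$alpha, condition = config$control,
                           treatment = config$treatment)

  score <- if (!is.null(truth)) score_calls(calls, truth, candidates)

  result <- list(
    truth = truth, lysate_psms = lysate_raw, media_psms = media_raw,
    annotations = annotations, filter_report = filter_report,
    groups = kept$groups, quant_lysate = quant_lysate,
    quant_media = quant_media, ratio_table = ratio_table,
    detection = detection, bins = bins, contrasts = contrasts,
    calls = calls, candidates = candidates, tm_table = tm_table,
    score = score
  )

  if (!is.null(out_dir)) write_bundle(result, config, out_dir)
  invisible(result)
}

# Quant matrix in the wide TSV layout: one absolute-intensity column per
# channel, stable column order.
quant_wide <- function(qm) {
  chans <- attr(qm, "channels") %||% unique(qm$channel)
  qm |>
    select("group_id", "reference_intensity", "n_psms_used", "channel",
           "abs_intensity") |>
    mutate(channel = paste0("abs_", .data$channel)) |>
    tidyr::pivot_wider(names_from = "channel", values_from = "abs_intensity") |>
    arrange(.data$group_id)
}

write_bundle <- function(result, config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name) {
    readr::write_tsv(df, file.path(out_dir, name), na = "", progress = FALSE)
  }
  if (!is.null(result$truth)) wt(result$truth, "ground_truth.tsv")
  write_psm_table(result$lysate_psms, file.path(out_dir, "lysate_psms.tsv"))
  write_psm_table(result$media_psms, file.path(out_dir, "media_psms.tsv"))
  if (!is.null(result$annotations)) wt(result$annotations, "annotations.tsv")
  wt(result$filter_report, "filter_report.tsv")
  wt(result$groups, "protein_groups.tsv")
  wt(quant_wide(result$quant_lysate), "quant_lysate.tsv")
  wt(quant_wide(result$quant_media), "quant_media.tsv")
  wt(as_tibble(result$ratio_table), "ratio_table.tsv")
  wt(result$detection, "detection_summary.tsv")
  wt(result$bins, "ml_bins.tsv")
  wt(tidy(result$contrasts$lysate), "diff_lysate.tsv")
  wt(tidy(result$contrasts$media), "diff_media.tsv")
  wt(tidy(result$contrasts$ml), "diff_ml.tsv")
  wt(as_tibble(result$calls), "secretome_calls.tsv")
  wt(result$candidates, "candidates.tsv")
  wt(result$tm_table, "tm_bfa.tsv")
  if (!is.null(result$score)) {
    wt(result$score$confusion, "score_confusion.tsv")
    wt(result$score$conventional, "score_conventional.tsv")
  }
  writeLines(run_log_lines(result, config), file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}

# Plain-text, timestamp-free run log: config echo + filter counts + prior
# estimates, enough to reproduce the bundle.
run_log_lines <- function(result, config) {
  fmt <- function(x) {
    if (is.null(x)) "NULL" else paste(format(x, digits = 15), collapse = ",")
  }
  cfg_keys <- setdiff(names(config), "sim")
  lines <- c("secretr run log",
             paste0("config.", cfg_keys, " = ",
                    vapply(config[cfg_keys], fmt, character(1))))
  if (!is.null(config$sim)) {
    sim <- config$sim
    lines <- c(lines, paste0("sim.", names(sim), " = ",
                             vapply(unclass(sim), fmt, character(1))))
  }
  fr <- result$filter_report
  lines <- c(lines, vapply(seq_len(nrow(fr)), function(i) {
    sprintf("filter.%s: input=%d unlabeled=%d low_purity=%d low_intensity=%d contaminant=%d retained=%d",
            fr$run_id[i], fr$n_input[i], fr$n_unlabeled[i], fr$n_low_purity[i],
            fr$n_low_intensity[i], fr$n_contaminant[i], fr$n_retained[i])
  }, character(1)))
  for (nm in names(result$contrasts)) {
    f <- result$contrasts[[nm]]
    lines <- c(lines, sprintf("contrast.%s: n=%d d0=%.6g s02=%.6g", nm,
                              nrow(f$table), f$prior_df, f$prior_var))
  }
  lines
}
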