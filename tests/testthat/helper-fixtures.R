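# Builders for hand-constructed PSM fixtures and a per-session cache of
# default-configuration pipeline runs shared across test files.

make_psms <- function(n = 1,
                      spectrum_id = sprintf("run1.%06d", seq_len(n)),
                      run_id = "run1",
                      peptide = paste0("pep", seq_len(n)),
                      charge = 2L,
                      modifications = "",
                      proteins = paste0("P", seq_len(n)),
                      is_decoy = FALSE,
                      is_contaminant = FALSE,
                      has_tmt_label = TRUE,
                      pep = 0.001,
                      purity = 0.9,
                      intensities = NULL) {
  if (is.null(intensities)) {
    intensities <- matrix(100, nrow = n, ncol = 2)
  }
  intensities <- matrix(as.numeric(intensities), nrow = n)
  colnames(intensities) <- paste0("intensity_", seq_len(ncol(intensities)))
  dplyr::bind_cols(
    tibble::tibble(
      spectrum_id = rep_len(spectrum_id, n),
      run_id = rep_len(run_id, n),
      peptide = rep_len(peptide, n),
      charge = rep_len(as.integer(charge), n),
      modifications = rep_len(modifications, n),
      proteins = rep_len(proteins, n),
      is_decoy = rep_len(is_decoy, n),
      is_contaminant = rep_len(is_contaminant, n),
      has_tmt_label = rep_len(has_tmt_label, n),
      pep = rep_len(pep, n),
      purity = rep_len(purity, n)
    ),
    tibble::as_tibble(intensities)
  )
}

# A minimal single-accession peptide map for quant tests.
identity_peptide_map <- function(peptides, groups = sub("_.*$", "", peptides)) {
  tibble::tibble(peptide = peptides, group_id = groups, assignment = "unique")
}

# Quant matrix built directly from per-channel absolute intensities (one row
# per protein), for ratio-module tests that do not need the PSM layer.
make_quant <- function(abs_by_channel, experiment_id = "media") {
  df <- tibble::as_tibble(abs_by_channel, rownames = "group_id")
  out <- tidyr::pivot_longer(df, -"group_id", names_to = "channel",
                             values_to = "abs_intensity")
  out$experiment_id <- experiment_id
  out$log2_ratio <- 0
  out$reference_intensity <- 1
  out$n_psms_used <- 1L
  structure(out[c("experiment_id", "group_id", "channel", "log2_ratio",
                  "abs_intensity", "reference_intensity", "n_psms_used")],
            channels = colnames(abs_by_channel))
}

# Default-configuration pipeline runs, computed once per session and shared
# by the trend / contrast / classification / acceptance tests.
.run_cache <- new.env(parent = emptyenv())

default_run <- function(seed) {
  key <- paste0("seed", seed)
  if (is.null(.run_cache[[key]])) {
    cfg <- pipeline_config(sim = sim_config(seed = seed))
    .run_cache[[key]] <- suppressWarnings(run_pipeline(cfg))
  }
  .run_cache[[key]]
}

default_runs <- function(seeds = 1:20) lapply(seeds, default_run)

# log2 M/L estimation error vs ground truth for both-detected proteins.
ml_errors <- function(run) {
  rt <- dplyr::filter(run$ratio_table, detection_status == "both")
  j <- dplyr::inner_join(rt, run$truth, by = c(group_id = "accession"),
                         suffix = c("", ".truth"))
  dplyr::mutate(j, true_ml = media_ctrl / lysate_ctrl,
                err = log2(ml_ctrl) - log2(true_ml))
}
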