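#' Simulate PSM-level TMT tables for the media and lysate experiments
#'
#' Turns a ground-truth proteome into two PSM tables (one per MS experiment)
#' in the package's PSM dialect, plus the protein annotation table. Each run
#' carries `2 * n_replicates` reporter channels (control replicates then BFA
#' replicates). The peptide inventory of a protein -- how many peptides it
#' yields, each peptide's ionization factor, and the number of redundant PSMs
#' per peptide ion -- is drawn once and shared by the two runs (equal
#' sampling depth), so that the summed-reporter reference intensity is
#' comparable between experiments; detection is gated per run by
#' `detection_floor` on the control-condition abundance.
#'
#' A PSM's intensity in channel `c` is
#' `abundance[c] * ionization_factor(peptide) * noise`, with the log-normal
#' noise applied independently per channel at coefficient of variation
#' `noise_cv` (mean 1). Because the ionization factor is shared across
#' channels within a spectrum, within-spectrum channel ratios are unbiased.
#' Designated fractions of extra PSMs are decoys (reversed-accession,
#' uniform posterior error probability), unlabelled, or contaminant-mapped.
#'
#' @param truth Tibble from [generate_ground_truth()].
#' @param config The [sim_config()] used to generate `truth`.
#' @return A list with elements `lysate` and `media` (PSM tibbles in the
#'   [read_psm_table()] dialect) and `annotations` (accession,
#'   `has_signal_peptide`, `has_tm_domain`).
#' @export
simulate_psm_tables <- function(truth, config) {
  validate_sim_config(config)
  if (nrow(truth) == 0) abort("`truth` must be non-empty.", class = "secretr_config_error")
  withr::with_seed(config$seed + 1L, simulate_psm_tables_impl(truth, config))
}

simulate_psm_tables_impl <- function(truth, cfg) {
  R <- cfg$n_replicates
  channels <- c(paste0("ctrl_", seq_len(R)), paste0("bfa_", seq_len(R)))

  # Shared peptide inventory: peptide count, ionization factor, PSM multiplicity.
  n_pep <- pmax(rpois(nrow(truth), cfg$peptides_per_protein_mean), 1L)
  inventory <- tibble(
    accession = rep(truth$accession, n_pep),
    pep_index = sequence(n_pep)
  ) |>
    mutate(
      peptide = paste0(.data$accession, "_pep", .data$pep_index),
      ionization = rlnorm(dplyr::n(), 0, cfg$ionization_logsd),
      n_psm = pmax(rpois(dplyr::n(), cfg$psms_per_peptide_mean), 1L)
    )

  build_run <- function(run_id, abund_by_channel, detected) {
    rows <- inventory |>
      filter(.data$accession %in% truth$accession[detected]) |>
      tidyr::uncount(.data$n_psm)
    n <- nrow(rows)
    # channel abundance matrix for these PSMs
    ab <- abund_by_channel[match(rows$accession, truth$accession), , drop = FALSE]
    noise <- reporter_noise(n * length(channels), cfg$noise_cv)
    inten <- ab * rows$ionization * matrix(noise, nrow = n)
    colnames(inten) <- paste0("intensity_", channels)

    real <- tibble(
      run_id = run_id,
      peptide = rows$peptide,
      charge = 2L,
      modifications = "",
      proteins = rows$accession,
      is_decoy = FALSE,
      is_contaminant = FALSE,
      has_tmt_label = TRUE,
      pep = rbeta(n, 1, 300),
      purity = rbeta(n, cfg$purity_alpha, cfg$purity_beta)
    ) |>
      dplyr::bind_cols(as_tibble(inten))

    extras <- simulate_extra_psms(real, truth, cfg, channels)
    out <- bind_rows(real, extras)
    out$spectrum_id <- sprintf("%s.%06d", run_id, seq_len(nrow(out)))
    select(out, "spectrum_id", dplyr::everything())
  }

  abund_matrix <- function(ctrl, bfa) {
    m <- cbind(matrix(rep(ctrl, R), ncol = R),
               matrix(rep(bfa, R), ncol = R))
    colnames(m) <- channels
    m
  }

  lysate <- build_run(
    "lysate",
    abund_matrix(truth$lysate_ctrl, truth$lysate_bfa),
    truth$lysate_ctrl >= cfg$detection_floor
  )
  media <- build_run(
    "media",
    abund_matrix(truth$media_ctrl, truth$media_bfa),
    truth$media_ctrl >= cfg$detection_floor
  )

  annotations <- truth |>
    select("accession", "has_signal_peptide", "has_tm_domain")

  list(lysate = lysate, media = media, annotations = annotations)
}

# Multiplicative log-normal noise with mean 1 and the given CV.
reporter_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# Decoy, unlabelled and contaminant PSMs appended to a run. Counts are
# rounded fractions of the genuine PSM count; intensities are drawn from the
# global abundance distribution so these spectra behave like ordinary signal
# until the corresponding filter removes them.
simulate_extra_psms <- function(real, truth, cfg, channels) {
  n_real <- nrow(real)
  mk_intensities <- function(n) {
    base <- rlnorm(n, cfg$abundance_logmean, cfg$abundance_logsd)
    noise <- reporter_noise(n * length(channels), cfg$noise_cv)
    inten <- base * matrix(noise, nrow = n)
    colnames(inten) <- paste0("intensity_", channels)
    as_tibble(inten)
  }
  blocks <- list()

  n_dec <- round(n_real * cfg$decoy_psm_fraction)
  if (n_dec > 0) {
    src <- sample(truth$accession, n_dec, replace = TRUE)
    blocks$decoy <- tibble(
      run_id = real$run_id[1],
      peptide = paste0("rev_", src, "_pep", sample.int(3L, n_dec, replace = TRUE)),
      charge = 2L,
      modifications = "",
      proteins = paste0("rev_", src),
      is_decoy = TRUE,
      is_contaminant = FALSE,
      has_tmt_label = TRUE,
      pep = runif(n_dec),
      purity = rbeta(n_dec, cfg$purity_alpha, cfg$purity_beta)
    ) |>
      dplyr::bind_cols(mk_intensities(n_dec))
  }

  n_unl <- round(n_real * cfg$unlabeled_psm_fraction)
  if (n_unl > 0) {
    src <- sample(truth$accession, n_unl, replace = TRUE)
    blocks$unlabeled <- tibble(
      run_id = real$run_id[1],
      peptide = paste0(src, "_unl", seq_len(n_unl)),
      charge = 2L,
      modifications = "",
      proteins = src,
      is_decoy = FALSE,
      is_contaminant = FALSE,
      has_tmt_label = FALSE,
      pep = rbeta(n_unl, 1, 300),
      purity = rbeta(n_unl, cfg$purity_alpha, cfg$purity_beta)
    ) |>
      dplyr::bind_cols(mk_intensities(n_unl))
  }

  n_con <- round(n_real * cfg$contaminant_fraction)
  if (n_con > 0) {
    acc <- sprintf("CON_%03d", sample.int(20L, n_con, replace = TRUE))
    blocks$contaminant <- tibble(
      run_id = real$run_id[1],
      peptide = paste0(acc, "_pep", sample.int(5L, n_con, replace = TRUE)),
      charge = 2L,
      modifications = "",
      proteins = acc,
      is_decoy = FALSE,
      is_contaminant = TRUE,
      has_tmt_label = TRUE,
      pep = rbeta(n_con, 1, 300),
      purity = rbeta(n_con, cfg$purity_alpha, cfg$purity_beta)
    ) |>
      dplyr::bind_cols(mk_intensities(n_con))
  }

  bind_rows(blocks)
}

#' Run the full synthetic-data generator
#'
#' Convenience wrapper: ground truth plus PSM tables in one call.
#'
#' @param config A [sim_config()].
#' @return A list with `truth`, `lysate`, `media`, `annotations`.
#' @export
simulate_experiment <- function(config) {
  truth <- generate_ground_truth(config)
  tables <- simulate_psm_tables(truth, config)
  c(list(truth = truth), tables)
}
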