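#' Configuration for a synthetic secretome experiment
#'
#' Defines the ground-truth model of a conditioned-media / cell-lysate TMT
#' experiment: how many proteins of each trafficking class exist, how abundant
#' they are, what fraction of each secreted protein leaves the cell, how much
#' intracellular content leaks into the media through cell damage, and how
#' strongly brefeldin A (BFA) blocks ER-to-Golgi flux. The measurement layer
#' (peptide sampling, reporter noise, precursor purity, decoy / unlabelled /
#' contaminant spectra) is parameterised separately.
#'
#' The five trafficking classes are: `conventional_secreted` (signal-peptide
#' bearing, exported through ER-Golgi, BFA-sensitive), `intracellular`
#' (cytoplasmic, reaches the media only by leakage), `membrane`
#' (transmembrane-domain proteins; a configurable fraction is "shed" into the
#' media from a post-Golgi pool and is BFA-resistant), `unconventional_secreted`
#' (no signal peptide or TM domain, exported by an ER/Golgi-independent route,
#' BFA-resistant), and `lumenal_resident` (signal-peptide bearing but retained
#' in the ER/lysosomal lumen, not secreted).
#'
#' @param n_proteins Number of target proteins to simulate.
#' @param class_proportions Named numeric vector over the five classes,
#'   summing to 1 (within 1e-9).
#' @param abundance_logmean,abundance_logsd Log-normal parameters of the
#'   baseline synthesis level (arbitrary intensity units).
#' @param secretion_fraction_range Interval in (0, 1]: fraction of a
#'   conventionally secreted protein routed out of the cell, drawn uniformly.
#' @param unconventional_fraction_range Interval in (0, 1]: export fraction
#'   for the unconventional class (typically lower than conventional cargo).
#' @param candidate_abundance_quantile_min Planted unconventional cargo is
#'   drawn from the upper tail of the abundance distribution, at or above
#'   this quantile. Candidate discovery in a ratiometric screen is
#'   conditional on robust quantification in both fractions, so ground-truth
#'   candidates are planted at quantifiable abundance; set to 0 for an
#'   unrestricted draw.
#' @param leakage_fraction Fraction in [0, 1) of every protein's cellular
#'   content released into the media by cell damage.
#' @param bfa_block Fraction in [0, 1] of conventional secretory flux blocked
#'   by BFA; the blocked amount accumulates in the lysate.
#' @param membrane_shed_prob Probability that a membrane protein has its
#'   ectodomain shed into the media (BFA-resistant, post-Golgi).
#' @param shed_fraction_range Interval: shed fraction for shed membrane
#'   proteins.
#' @param n_replicates Biological replicates per condition (>= 2); channel
#'   layout is `ctrl_1..n` then `bfa_1..n`.
#' @param peptides_per_protein_mean Poisson mean of observable peptides per
#'   protein (minimum 1 when the protein is detected in a run).
#' @param psms_per_peptide_mean Poisson mean (floored at 1) of redundant PSMs
#'   per peptide ion.
#' @param ionization_logsd Log-normal sd of the per-peptide ionization factor
#'   (shared across channels and runs, so within-spectrum channel ratios are
#'   unbiased by peptide identity).
#' @param noise_cv Coefficient of variation of the multiplicative log-normal
#'   reporter noise applied per PSM per channel.
#' @param purity_alpha,purity_beta Beta parameters of precursor-ion purity.
#' @param decoy_psm_fraction,unlabeled_psm_fraction,contaminant_fraction
#'   Fractions in [0, 1) of extra PSMs that are decoys, lack a TMT label, or
#'   map to contaminant accessions (relative to the count of genuine PSMs).
#' @param detection_floor True control-condition abundance below which a
#'   protein is absent from a run (emits no PSMs there).
#' @param seed Integer seed; all randomness in the generator flows from it.
#'
#' @return A validated list of class `sim_config`.
#' @seealso [generate_ground_truth()], [simulate_psm_tables()]
#' @export
sim_config <- function(n_proteins = 2000,
                       class_proportions = c(conventional_secreted = 0.12,
                                             intracellular = 0.7075,
                                             membrane = 0.15,
                                             unconventional_secreted = 0.0025,
                                             lumenal_resident = 0.02),
                       abundance_logmean = 11,
                       abundance_logsd = 1.2,
                       secretion_fraction_range = c(0.38, 0.98),
                       unconventional_fraction_range = c(0.72, 0.80),
                       candidate_abundance_quantile_min = 0.5,
                       leakage_fraction = 0.1,
                       bfa_block = 0.9,
                       membrane_shed_prob = 0.38,
                       shed_fraction_range = c(0.30, 0.63),
                       n_replicates = 3,
                       peptides_per_protein_mean = 7,
                       psms_per_peptide_mean = 2,
                       ionization_logsd = 0.9,
                       noise_cv = 0.2,
                       purity_alpha = 8,
                       purity_beta = 2,
                       decoy_psm_fraction = 0.05,
                       unlabeled_psm_fraction = 0.02,
                       contaminant_fraction = 0.02,
                       detection_floor = 500,
                       seed = 1L) {
  cfg <- list(
    n_proteins = n_proteins,
    class_proportions = class_proportions,
    abundance_logmean = abundance_logmean,
    abundance_logsd = abundance_logsd,
    secretion_fraction_range = secretion_fraction_range,
    unconventional_fraction_range = unconventional_fraction_range,
    candidate_abundance_quantile_min = candidate_abundance_quantile_min,
    leakage_fraction = leakage_fraction,
    bfa_block = bfa_block,
    membrane_shed_prob = membrane_shed_prob,
    shed_fraction_range = shed_fraction_range,
    n_replicates = as.integer(n_replicates),
    peptides_per_protein_mean = peptides_per_protein_mean,
    psms_per_peptide_mean = psms_per_peptide_mean,
    ionization_logsd = ionization_logsd,
    noise_cv = noise_cv,
    purity_alpha = purity_alpha,
    purity_beta = purity_beta,
    decoy_psm_fraction = decoy_psm_fraction,
    unlabeled_psm_fraction = unlabeled_psm_fraction,
    contaminant_fraction = contaminant_fraction,
    detection_floor = detection_floor,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

secretome_classes <- c("conventional_secreted", "intracellular", "membrane",
                       "unconventional_secreted", "lumenal_resident")

validate_sim_config <- function(cfg) {
  stop_cfg <- function(msg) abort(msg, class = "secretr_config_error")
  if (!is.numeric(cfg$n_proteins) || cfg$n_proteins < 1) {
    stop_cfg("`n_proteins` must be a positive integer.")
  }
  p <- cfg$class_proportions
  if (!setequal(names(p), secretome_classes)) {
    stop_cfg(paste0("`class_proportions` must be named over: ",
                    paste(secretome_classes, collapse = ", ")))
  }
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
    stop_cfg("`class_proportions` must be non-negative and sum to 1 (within 1e-9).")
  }
  check_interval <- function(x, nm) {
    if (length(x) != 2 || x[1] > x[2] || x[1] <= 0 || x[2] > 1) {
      stop_cfg(sprintf("`%s` must be an ascending interval within (0, 1].", nm))
    }
  }
  check_interval(cfg$secretion_fraction_range, "secretion_fraction_range")
  if (cfg$candidate_abundance_quantile_min < 0 ||
      cfg$candidate_abundance_quantile_min >= 1) {
    stop_cfg("`candidate_abundance_quantile_min` must be in [0, 1).")
  }
  check_interval(cfg$unconventional_fraction_range, "unconventional_fraction_range")
  check_interval(cfg$shed_fraction_range, "shed_fraction_range")
  if (cfg$leakage_fraction < 0 || cfg$leakage_fraction >= 1) {
    stop_cfg("`leakage_fraction` must be in [0, 1).")
  }
  if (cfg$bfa_block < 0 || cfg$bfa_block > 1) {
    stop_cfg("`bfa_block` must be in [0, 1].")
  }
  if (cfg$membrane_shed_prob < 0 || cfg$membrane_shed_prob > 1) {
    stop_cfg("`membrane_shed_prob` must be in [0, 1].")
  }
  if (cfg$n_replicates < 2) stop_cfg("`n_replicates` must be >= 2.")
  for (nm in c("peptides_per_protein_mean", "psms_per_peptide_mean")) {
    if (cfg[[nm]] <= 0) stop_cfg(sprintf("`%s` must be positive.", nm))
  }
  if (cfg$noise_cv < 0) stop_cfg("`noise_cv` must be non-negative.")
  if (cfg$purity_alpha <= 0 || cfg$purity_beta <= 0) {
    stop_cfg("purity Beta parameters must be positive.")
  }
  for (nm in c("decoy_psm_fraction", "unlabeled_psm_fraction", "contaminant_fraction")) {
    if (cfg[[nm]] < 0 || cfg[[nm]] >= 1) stop_cfg(sprintf("`%s` must be in [0, 1).", nm))
  }
  if (cfg$detection_floor < 0) stop_cfg("`detection_floor` must be non-negative.")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>", x$n_proteins, "proteins,",
      x$n_replicates, "replicates/condition, seed", x$seed, "\n")
  cat("  classes:", paste(sprintf("%s=%.2f", names(x$class_proportions),
                                  x$class_proportions), collapse = " "), "\n")
  cat(sprintf("  leakage=%.2g bfa_block=%.2g noise_cv=%.2g floor=%g\n",
              x$leakage_fraction, x$bfa_block, x$noise_cv, x$detection_floor))
  invisible(x)
}

# Largest-remainder apportionment of n among proportions p (named).
# Ties in the fractional remainders are broken by position in p, so the
# result is fully deterministic.
largest_remainder_counts <- function(n, p) {
  exact <- n * p
  base <- floor(exact)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- exact - base
    ord <- order(-frac, seq_along(p))
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  stats::setNames(as.integer(base), names(p))
}
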