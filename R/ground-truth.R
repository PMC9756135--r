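#' Generate the ground-truth proteome of a synthetic secretome experiment
#'
#' Draws one protein per row with its trafficking class, annotation flags,
#' baseline synthesis level and export fraction, and computes the true media
#' and lysate abundances under the control and BFA conditions.
#'
#' The abundance model, with baseline `A`, export fraction `f`, leakage
#' `lambda` and BFA block `b`:
#' \deqn{lysate_{ctrl} = A(1-f), \quad media_{ctrl} = Af + \lambda A(1-f)}
#' Under BFA, a non-resistant protein's exported flux is scaled by `(1-b)`
#' and the blocked amount accumulates in the lysate:
#' \deqn{lysate_{bfa} = A(1-f) + Afb, \quad media_{bfa} = Af(1-b) + \lambda\, lysate_{bfa}}
#' BFA-resistant proteins (unconventional cargo and shed membrane proteins)
#' and proteins with `f = 0` are unchanged by BFA. Class counts follow
#' deterministic largest-remainder rounding of `class_proportions`, and
#' classes are assigned in blocks by accession index.
#'
#' @param config A [sim_config()].
#' @return A tibble with one row per protein: `accession`, `secretion_class`,
#'   `has_signal_peptide`, `has_tm_domain`, `baseline_abundance`,
#'   `secretion_fraction`, `bfa_resistant`, and true abundances
#'   `lysate_ctrl`, `media_ctrl`, `lysate_bfa`, `media_bfa`.
#' @export
generate_ground_truth <- function(config) {
  validate_sim_config(config)
  withr::with_seed(config$seed, generate_ground_truth_impl(config))
}

generate_ground_truth_impl <- function(cfg) {
  counts <- largest_remainder_counts(cfg$n_proteins, cfg$class_proportions)
  cls <- rep(names(counts), counts)
  n <- cfg$n_proteins
  acc <- sprintf("P%05d", seq_len(n))

  A <- rlnorm(n, meanlog = cfg$abundance_logmean, sdlog = cfg$abundance_logsd)

  f <- numeric(n)
  is_conv <- cls == "conventional_secreted"
  is_unconv <- cls == "unconventional_secreted"
  is_mem <- cls == "membrane"

  # Planted candidates are drawn at quantifiable abundance (upper tail).
  if (cfg$candidate_abundance_quantile_min > 0 && any(is_unconv)) {
    q <- runif(sum(is_unconv), cfg$candidate_abundance_quantile_min, 1)
    A[is_unconv] <- stats::qlnorm(q, meanlog = cfg$abundance_logmean,
                                  sdlog = cfg$abundance_logsd)
  }
  f[is_conv] <- runif(sum(is_conv), cfg$secretion_fraction_range[1],
                      cfg$secretion_fraction_range[2])
  f[is_unconv] <- runif(sum(is_unconv), cfg$unconventional_fraction_range[1],
                        cfg$unconventional_fraction_range[2])
  shed <- rep(FALSE, n)
  shed[is_mem] <- runif(sum(is_mem)) < cfg$membrane_shed_prob
  f[shed] <- runif(sum(shed), cfg$shed_fraction_range[1],
                   cfg$shed_fraction_range[2])

  resistant <- is_unconv | shed

  lam <- cfg$leakage_fraction
  b <- cfg$bfa_block

  lysate_ctrl <- A * (1 - f)
  media_ctrl <- A * f + lam * lysate_ctrl

  blocked <- !resistant & f > 0
  lysate_bfa <- ifelse(blocked, A * (1 - f) + A * f * b, lysate_ctrl)
  media_bfa <- ifelse(blocked, A * f * (1 - b) + lam * lysate_bfa, media_ctrl)

  tibble(
    accession = acc,
    secretion_class = cls,
    has_signal_peptide = cls %in% c("conventional_secreted", "lumenal_resident"),
    has_tm_domain = cls == "membrane",
    baseline_abundance = A,
    secretion_fraction = f,
    bfa_resistant = resistant,
    lysate_ctrl = lysate_ctrl,
    media_ctrl = media_ctrl,
    lysate_bfa = lysate_bfa,
    media_bfa = media_bfa
  )
}
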