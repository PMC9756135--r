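#' Per-PSM log2 ratios to the virtual reference channel
#'
#' For each PSM the virtual reference is the geometric mean of its positive,
#' non-missing channel intensities, and each channel's ratio is
#' `log2(intensity / reference)`. PSMs with fewer than two positive channels
#' cannot be ratioed and are dropped (counted in the `"n_dropped"`
#' attribute). Ratios are invariant to rescaling all channels of a spectrum
#' by a constant.
#'
#' @param psms PSM tibble (filtered and deduplicated).
#' @return A long tibble: `spectrum_id`, `run_id`, `peptide`, `channel`,
#'   `intensity`, `log2_ratio`, one row per positive channel.
#' @export
psm_log2_ratios <- function(psms) {
  chans <- channel_ids(psms)
  m <- as.matrix(psms[intensity_cols(psms)])
  lg <- log2(m)
  lg[!is.finite(lg)] <- NA_real_  # missing or non-positive channels
  n_ok <- rowSums(!is.na(lg))
  keep <- n_ok >= 2
  ref <- rowMeans(lg[keep, , drop = FALSE], na.rm = TRUE)
  ratios <- lg[keep, , drop = FALSE] - ref
  colnames(ratios) <- chans

  base <- psms[keep, c("spectrum_id", "run_id", "peptide")]
  inten <- m[keep, , drop = FALSE]
  colnames(inten) <- chans

  out <- dplyr::bind_cols(
    base[rep(seq_len(nrow(base)), times = length(chans)), ],
    tibble(channel = rep(chans, each = nrow(base)),
           intensity = as.vector(inten),
           log2_ratio = as.vector(ratios))
  ) |>
    filter(!is.na(.data$log2_ratio)) |>
    arrange(.data$spectrum_id, factor(.data$channel, levels = chans))

  structure(out, n_dropped = sum(!keep), channels = chans)
}

#' Roll PSM ratios up to protein-level log2 ratios
#'
#' Only peptides assigned (unique or razor) to a group contribute. Per
#' protein group and channel, the protein ratio is the median of the PSM
#' ratios after Tukey-fence outlier removal: with at least four values,
#' values outside `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]` are discarded first; with
#' three or fewer, the plain median is taken. The result is invariant to the
#' order of the input PSMs.
#'
#' @param psm_ratios Long tibble from [psm_log2_ratios()].
#' @param peptide_map Peptide assignment from [infer_protein_groups()].
#' @return Tibble: `group_id`, `channel`, `log2_ratio`, `n_psms_used` (the
#'   number of distinct contributing PSMs per group, before the fence).
#' @export
rollup_protein_ratios <- function(psm_ratios, peptide_map) {
  chans <- attr(psm_ratios, "channels") %||% sort(unique(psm_ratios$channel))
  joined <- psm_ratios |>
    inner_join(select(peptide_map, "peptide", "group_id"), by = "peptide")

  n_used <- joined |>
    group_by(.data$group_id) |>
    summarise(n_psms_used = n_distinct(.data$spectrum_id))

  out <- joined |>
    group_by(.data$group_id, .data$channel) |>
    summarise(log2_ratio = fence_median(.data$log2_ratio), .groups = "drop") |>
    left_join(n_used, by = "group_id") |>
    arrange(.data$group_id, factor(.data$channel, levels = chans))
  structure(out, channels = chans)
}

# Median after Tukey 1.5*IQR fence removal (fence applied only with >= 4
# values; quartiles by the default type-7 quantile).
fence_median <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) return(NA_real_)
  if (length(x) >= 4) {
    q <- quantile(x, c(0.25, 0.75), names = FALSE)
    iqr <- q[2] - q[1]
    inside <- x >= q[1] - 1.5 * iqr & x <= q[2] + 1.5 * iqr
    if (any(inside)) x <- x[inside]
  }
  median(x)
}

#' Reconstruct absolute protein intensities from ratios
#'
#' The per-protein reference intensity is the sum of all non-missing reporter
#' intensities over the protein's contributing PSMs, divided by the number of
#' channels (so a flat-ratio protein's absolute intensity equals its mean
#' per-channel signal). Each channel's absolute intensity is
#' `reference * 2^log2_ratio`, which preserves all cross-channel ratios.
#'
#' @param protein_ratios Tibble from [rollup_protein_ratios()].
#' @param psms The quantification-eligible PSM tibble (same set that fed
#'   [psm_log2_ratios()]).
#' @param peptide_map Peptide assignment from [infer_protein_groups()].
#' @param experiment_id Label for the experiment ("lysate" or "media").
#' @return A quant tibble of class `quant_matrix`: `experiment_id`,
#'   `group_id`, `channel`, `log2_ratio`, `abs_intensity`,
#'   `reference_intensity`, `n_psms_used`.
#' @export
reconstruct_absolute <- function(protein_ratios, psms, peptide_map,
                                 experiment_id = unique(psms$run_id)[1]) {
  n_chan <- length(intensity_cols(psms))
  refs <- psms |>
    mutate(.total = summed_intensity(psms)) |>
    select("peptide", ".total") |>
    inner_join(select(peptide_map, "peptide", "group_id"), by = "peptide") |>
    group_by(.data$group_id) |>
    summarise(reference_intensity = sum(.data$.total) / n_chan)

  out <- protein_ratios |>
    inner_join(refs, by = "group_id") |>
    mutate(experiment_id = experiment_id,
           abs_intensity = .data$reference_intensity * 2^.data$log2_ratio) |>
    select("experiment_id", "group_id", "channel", "log2_ratio",
           "abs_intensity", "reference_intensity", "n_psms_used")
  class(out) <- c("quant_matrix", class(out))
  attr(out, "channels") <- attr(protein_ratios, "channels")
  out
}

#' Quantify proteins from a filtered PSM table
#'
#' Chains [psm_log2_ratios()], [rollup_protein_ratios()] and
#' [reconstruct_absolute()] for one experiment.
#'
#' @inheritParams reconstruct_absolute
#' @param psms Filtered, deduplicated, FDR-passing PSM tibble for one run.
#' @return A `quant_matrix` tibble (see [reconstruct_absolute()]).
#' @export
quantify_proteins <- function(psms, peptide_map,
                              experiment_id = unique(psms$run_id)[1]) {
  ratios <- psm_log2_ratios(psms)
  used <- psms[psms$spectrum_id %in% unique(ratios$spectrum_id), ]
  prot <- rollup_protein_ratios(ratios, peptide_map)
  reconstruct_absolute(prot, used, peptide_map, experiment_id)
}
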