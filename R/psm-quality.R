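#' Apply PSM quality filters
#'
#' Removes, in order: (a) PSMs without a TMT label; (b) PSMs with precursor
#' purity strictly below `purity_min` (a PSM at exactly the threshold is
#' retained); (c) PSMs whose summed reporter intensity (over non-missing
#' channels) falls at or below the run's `low_intensity_percentile`-th
#' percentile, computed per run over the PSMs surviving (a) and (b) using the
#' nearest-rank convention; (d) PSMs mapping to contaminant proteins. The
#' order of survivors is preserved, and per-run removal counts are attached
#' as the `"filter_report"` attribute (also available via
#' [psm_filter_report()]).
#'
#' @param psms PSM tibble (see [read_psm_table()] for the dialect).
#' @param purity_min Minimum precursor purity; strictly-below removed.
#' @param low_intensity_percentile Percentile in \[0, 100) of the summed
#'   reporter intensity below which (inclusive) PSMs are removed.
#' @return The surviving PSMs, same columns, original order.
#' @export
filter_psms <- function(psms, purity_min = 0.5, low_intensity_percentile = 5) {
  if (low_intensity_percentile < 0 || low_intensity_percentile >= 100) {
    abort("`low_intensity_percentile` must be in [0, 100).",
          class = "secretr_config_error")
  }
  if (purity_min < 0 || purity_min > 1) {
    abort("`purity_min` must be in [0, 1].", class = "secretr_config_error")
  }
  if (nrow(psms) == 0) {
    return(structure(psms, filter_report = empty_filter_report()))
  }

  psms$.row <- seq_len(nrow(psms))
  s1 <- filter(psms, .data$has_tmt_label)
  s2 <- filter(s1, .data$purity >= purity_min)

  # Nearest-rank percentile of summed intensity, per run, over the PSMs that
  # survived the label and purity filters; removal is inclusive (<= cutoff).
  s2$.sum <- summed_intensity(s2)
  s3 <- s2 |>
    group_by(.data$run_id) |>
    filter(.data$.sum > nearest_rank_percentile(.data$.sum, low_intensity_percentile)) |>
    ungroup()

  s4 <- filter(s3, !.data$is_contaminant)

  report <- tibble(
    run_id = sort(unique(psms$run_id)),
    n_input = tab_by_run(psms, sort(unique(psms$run_id))),
    n_unlabeled = tab_by_run(psms, sort(unique(psms$run_id))) -
      tab_by_run(s1, sort(unique(psms$run_id))),
    n_low_purity = tab_by_run(s1, sort(unique(psms$run_id))) -
      tab_by_run(s2, sort(unique(psms$run_id))),
    n_low_intensity = tab_by_run(s2, sort(unique(psms$run_id))) -
      tab_by_run(s3, sort(unique(psms$run_id))),
    n_contaminant = tab_by_run(s3, sort(unique(psms$run_id))) -
      tab_by_run(s4, sort(unique(psms$run_id))),
    n_retained = tab_by_run(s4, sort(unique(psms$run_id)))
  )

  out <- s4 |> arrange(.data$.row) |> select(-".row", -".sum")
  structure(out, filter_report = report)
}

tab_by_run <- function(df, runs) {
  as.integer(table(factor(df$run_id, levels = runs)))
}

empty_filter_report <- function() {
  tibble(run_id = character(), n_input = integer(), n_unlabeled = integer(),
         n_low_purity = integer(), n_low_intensity = integer(),
         n_contaminant = integer(), n_retained = integer())
}

#' Per-run PSM filter report
#'
#' @param psms The output of [filter_psms()].
#' @return A tibble of per-run counts removed by each criterion.
#' @export
psm_filter_report <- function(psms) {
  attr(psms, "filter_report") %||% empty_filter_report()
}

# Nearest-rank (inclusive) percentile: the k-th smallest value with
# k = ceiling(p/100 * n). p = 0 gives -Inf (nothing removed).
nearest_rank_percentile <- function(x, p) {
  n <- length(x)
  k <- ceiling(p / 100 * n)
  if (k < 1) return(-Inf)
  sort(x)[k]
}

#' Deduplicate redundant peptide-ion PSMs
#'
#' Within each peptide ion -- the key (`run_id`, `peptide`, `charge`,
#' `modifications`) -- exactly one PSM is kept: the one with the largest
#' summed reporter intensity, ties broken by the lexicographically smallest
#' `spectrum_id`. Input order of the survivors is preserved.
#'
#' @param psms PSM tibble.
#' @return Deduplicated PSM tibble.
#' @export
deduplicate_peptide_ions <- function(psms) {
  if (nrow(psms) == 0) return(psms)
  psms$.row <- seq_len(nrow(psms))
  psms$.sum <- summed_intensity(psms)
  out <- psms |>
    group_by(.data$run_id, .data$peptide, .data$charge, .data$modifications) |>
    arrange(dplyr::desc(.data$.sum), .data$spectrum_id, .by_group = TRUE) |>
    slice(1) |>
    ungroup() |>
    arrange(.data$.row) |>
    select(-".row", -".sum")
  out
}

#' Assemble protein groups and assign unique/razor peptides
#'
#' Accessions with identical peptide sets are merged into one group whose id
#' is the lexicographically smallest member accession. A peptide mapping to a
#' single group is its unique peptide; a peptide shared between groups is
#' razor-assigned to the group with the most peptide evidence (number of
#' distinct peptides mapping to the group), ties broken by smallest group id.
#' The assignment is deterministic: recomputation yields identical output.
#'
#' @param psms Filtered, deduplicated PSM tibble. The `proteins` column holds
#'   semicolon-separated accessions.
#' @return A list with `groups` (tibble: `group_id`, `members`,
#'   `n_peptides`, `n_unique_peptides`, `n_razor_peptides`,
#'   `best_peptide_pep`, `is_decoy`) and `peptide_map` (tibble: `peptide`,
#'   `group_id`, `assignment` of "unique" or "razor").
#' @export
infer_protein_groups <- function(psms) {
  pep_acc <- psms |>
    select("peptide", "proteins") |>
    tidyr::separate_longer_delim("proteins", delim = ";") |>
    rename(accession = "proteins") |>
    distinct()

  # Merge accessions whose peptide sets are identical.
  acc_sig <- pep_acc |>
    group_by(.data$accession) |>
    summarise(signature = paste(sort(unique(.data$peptide)), collapse = "\r")) |>
    group_by(.data$signature) |>
    mutate(group_id = min(.data$accession)) |>
    ungroup()

  groups0 <- acc_sig |>
    group_by(.data$group_id) |>
    summarise(members = paste(sort(unique(.data$accession)), collapse = ";"))

  pep_grp <- pep_acc |>
    left_join(select(acc_sig, "accession", "group_id"), by = "accession") |>
    distinct(.data$peptide, .data$group_id)

  evidence <- pep_grp |> count(.data$group_id, name = "n_peptides")

  assignment <- pep_grp |>
    left_join(evidence, by = "group_id") |>
    group_by(.data$peptide) |>
    mutate(n_groups = n_distinct(.data$group_id)) |>
    arrange(dplyr::desc(.data$n_peptides), .data$group_id, .by_group = TRUE) |>
    slice(1) |>
    ungroup() |>
    mutate(assignment = if_else(.data$n_groups == 1L, "unique", "razor")) |>
    select("peptide", "group_id", "assignment")

  psm_info <- psms |>
    select("peptide", "pep", "is_decoy") |>
    left_join(assignment, by = "peptide")

  stats_tbl <- psm_info |>
    group_by(.data$group_id) |>
    summarise(best_peptide_pep = min(.data$pep),
              is_decoy = all(.data$is_decoy))

  pep_counts <- assignment |>
    group_by(.data$group_id) |>
    summarise(n_unique_peptides = sum(.data$assignment == "unique"),
              n_razor_peptides = sum(.data$assignment == "razor"))

  groups <- groups0 |>
    left_join(evidence, by = "group_id") |>
    left_join(pep_counts, by = "group_id") |>
    left_join(stats_tbl, by = "group_id") |>
    mutate(n_unique_peptides = dplyr::coalesce(.data$n_unique_peptides, 0L),
           n_razor_peptides = dplyr::coalesce(.data$n_razor_peptides, 0L)) |>
    arrange(.data$group_id)

  list(groups = groups, peptide_map = arrange(assignment, .data$peptide))
}

#' Target-decoy FDR filtering of protein groups and PSMs
#'
#' Sequential strategy. Protein level: groups are ranked by
#' `best_peptide_pep` ascending (ties by group id); at each cut the FDR is
#' estimated as `#decoy / max(1, #target)` among groups at or above the cut;
#' the largest cut with an estimate at or below `protein_fdr` defines the
#' eligible prefix, and target groups in the prefix are retained. PSM level:
#' among PSMs whose peptide is assigned to a group in the eligible prefix
#' (targets and decoys, so decoy PSMs still inform the estimate), the same
#' decoy-counting rule is applied on `pep` at `psm_fdr`; target PSMs mapping
#' to retained target groups survive. The decoy count is used without a +1
#' correction by default (`plus_one = TRUE` switches the conservative
#' estimator on).
#'
#' @param psms Filtered, deduplicated PSM tibble.
#' @param groups,peptide_map Output of [infer_protein_groups()].
#' @param protein_fdr,psm_fdr FDR levels in (0, 1).
#' @param plus_one Add 1 to the decoy count (conservative estimator)?
#' @return A list with `psms` and `groups`, each restricted to the retained
#'   target entries.
#' @export
fdr_filter <- function(psms, groups, peptide_map,
                       protein_fdr = 0.01, psm_fdr = 0.01, plus_one = FALSE) {
  if (all(groups$is_decoy)) {
    warn("All protein groups are decoys; returning empty result.")
    return(list(psms = psms[0, ], groups = groups[0, ]))
  }

  ord <- arrange(groups, .data$best_peptide_pep, .data$group_id)
  keep_n <- decoy_cut(ord$is_decoy, protein_fdr, plus_one)
  eligible <- ord$group_id[seq_len(keep_n)]
  retained_groups <- filter(ord, .data$group_id %in% eligible, !.data$is_decoy)

  psms_mapped <- psms |>
    left_join(peptide_map, by = "peptide") |>
    filter(.data$group_id %in% eligible)

  psm_ord <- arrange(psms_mapped, .data$pep, .data$spectrum_id)
  keep_p <- decoy_cut(psm_ord$is_decoy, psm_fdr, plus_one)
  retained_psms <- psm_ord[seq_len(keep_p), ] |>
    filter(!.data$is_decoy, .data$group_id %in% retained_groups$group_id) |>
    select(-"group_id", -"assignment")

  list(psms = retained_psms, groups = arrange(retained_groups, .data$group_id))
}

# Largest prefix length of the decoy indicator vector (already ranked by
# score) whose estimated FDR (#decoy / max(1, #target), optionally +1 on the
# decoy count) is at or below the level. 0 if no prefix qualifies.
decoy_cut <- function(is_decoy, level, plus_one = FALSE) {
  if (length(is_decoy) == 0) return(0L)
  d <- cumsum(is_decoy) + if (plus_one) 1L else 0L
  t <- cumsum(!is_decoy)
  fdr <- d / pmax(t, 1)
  ok <- which(fdr <= level)
  if (length(ok) == 0) 0L else max(ok)
}
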