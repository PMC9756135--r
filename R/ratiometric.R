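#' Default replicate pairing for a control/BFA channel layout
#'
#' Channels named `<condition>_<replicate>` (e.g. `ctrl_1`, `bfa_3`) are
#' paired between the media and lysate experiments by identical channel
#' name: media replicate i of a condition pairs with lysate replicate i.
#'
#' @param channels Character vector of channel ids.
#' @return Tibble: `condition`, `replicate`, `media_channel`,
#'   `lysate_channel`.
#' @export
default_pairing <- function(channels) {
  m <- regmatches(channels, regexec("^(.*)_([0-9]+)$", channels))
  bad <- vapply(m, length, integer(1)) != 3
  if (any(bad)) {
    abort(paste0("Cannot derive a pairing from channel name(s): ",
                 paste(channels[bad], collapse = ", ")),
          class = "secretr_config_error")
  }
  tibble(
    condition = vapply(m, `[`, character(1), 2),
    replicate = as.integer(vapply(m, `[`, character(1), 3)),
    media_channel = channels,
    lysate_channel = channels
  )
}

#' Compute media/lysate (M/L) abundance ratios
#'
#' For every protein group present in both quant matrices, the per-replicate
#' M/L ratio is the media absolute intensity divided by the lysate absolute
#' intensity of the paired channels, and the per-condition summary M/L is
#' the geometric mean over replicates (`2^mean(log2 M/L)`). Proteins present
#' in exactly one matrix get `media_only` / `lysate_only` detection status
#' with undefined ratios. Annotation flags are joined by group id;
#' unannotated groups are flagged `FALSE` for both and their count is
#' reported with a warning.
#'
#' @param media,lysate `quant_matrix` tibbles from [quantify_proteins()].
#' @param pairing Replicate pairing tibble (see [default_pairing()]); by
#'   default derived from the media channel names.
#' @param annotations Tibble: `accession`, `has_signal_peptide`,
#'   `has_tm_domain`.
#' @return A `ratio_table` tibble: `group_id`, `detection_status`,
#'   `has_signal_peptide`, `has_tm_domain`, per-replicate columns
#'   `log2_ml_<condition>_<replicate>`, and per-condition summaries
#'   `ml_<condition>` and `log2_ml_<condition>`.
#' @export
compute_ml_ratios <- function(media, lysate, pairing = NULL, annotations = NULL) {
  chans <- unique(media$channel)
  pairing <- pairing %||% default_pairing(chans)
  req <- c("condition", "replicate", "media_channel", "lysate_channel")
  if (!all(req %in% names(pairing))) {
    abort("`pairing` must have columns condition, replicate, media_channel, lysate_channel.",
          class = "secretr_config_error")
  }
  if (!all(pairing$media_channel %in% media$channel) ||
      !all(pairing$lysate_channel %in% lysate$channel)) {
    abort("`pairing` references channels absent from the quant matrices.",
          class = "secretr_config_error")
  }

  m <- media |>
    select("group_id", media_channel = "channel", media_abs = "abs_intensity")
  l <- lysate |>
    select("group_id", lysate_channel = "channel", lysate_abs = "abs_intensity")

  per_rep <- pairing |>
    inner_join(m, by = "media_channel", relationship = "many-to-many") |>
    inner_join(l, by = c("group_id", "lysate_channel")) |>
    mutate(log2_ml = log2(.data$media_abs / .data$lysate_abs)) |>
    filter(is.finite(.data$log2_ml))

  summaries <- per_rep |>
    group_by(.data$group_id, .data$condition) |>
    summarise(log2_ml = mean(.data$log2_ml), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "condition", values_from = "log2_ml",
                       names_prefix = "log2_ml_")

  rep_wide <- per_rep |>
    mutate(col = paste0("log2_ml_", .data$condition, "_", .data$replicate)) |>
    select("group_id", "col", "log2_ml") |>
    tidyr::pivot_wider(names_from = "col", values_from = "log2_ml")

  media_ids <- unique(media$group_id)
  lysate_ids <- unique(lysate$group_id)
  all_ids <- sort(union(media_ids, lysate_ids))
  status <- tibble(group_id = all_ids) |>
    mutate(detection_status = case_when(
      .data$group_id %in% media_ids & .data$group_id %in% lysate_ids ~ "both",
      .data$group_id %in% media_ids ~ "media_only",
      TRUE ~ "lysate_only"
    ))

  out <- status |>
    left_join(rep_wide, by = "group_id") |>
    left_join(summaries, by = "group_id")
  # columns must exist even when no protein is detected in both fractions
  needed <- c(paste0("log2_ml_", unique(pairing$condition)),
              paste0("log2_ml_", pairing$condition, "_", pairing$replicate))
  for (cl in needed) if (!cl %in% names(out)) out[[cl]] <- NA_real_
  for (cond in unique(pairing$condition)) {
    out[[paste0("ml_", cond)]] <- 2^out[[paste0("log2_ml_", cond)]]
  }

  if (!is.null(annotations)) {
    ann <- annotations |>
      select("accession", "has_signal_peptide", "has_tm_domain")
    out <- left_join(out, ann, by = c(group_id = "accession"))
    n_unann <- sum(is.na(out$has_signal_peptide))
    if (n_unann > 0) {
      warn(sprintf("%d protein group(s) lack annotation; flags set to FALSE.", n_unann))
    }
    out <- out |>
      mutate(has_signal_peptide = dplyr::coalesce(.data$has_signal_peptide, FALSE),
             has_tm_domain = dplyr::coalesce(.data$has_tm_domain, FALSE))
  } else {
    out$has_signal_peptide <- FALSE
    out$has_tm_domain <- FALSE
  }

  out <- select(out, "group_id", "detection_status", "has_signal_peptide",
                "has_tm_domain", dplyr::everything())
  class(out) <- c("ratio_table", class(out))
  attr(out, "conditions") <- unique(pairing$condition)
  attr(out, "replicates") <- sort(unique(pairing$replicate))
  out
}

#' Detection-overlap summary (Venn counts with signal-peptide fractions)
#'
#' @param media_ids,lysate_ids Character vectors of protein group ids
#'   detected in each experiment (or `quant_matrix` tibbles).
#' @param annotations Annotation tibble (`accession`, `has_signal_peptide`,
#'   `has_tm_domain`).
#' @return Tibble: `region` (both / media_only / lysate_only), `n`,
#'   `n_signal_peptide`, `sp_fraction`.
#' @export
summarize_detection <- function(media_ids, lysate_ids, annotations = NULL) {
  if (is.data.frame(media_ids)) media_ids <- unique(media_ids$group_id)
  if (is.data.frame(lysate_ids)) lysate_ids <- unique(lysate_ids$group_id)
  regions <- list(
    both = intersect(media_ids, lysate_ids),
    media_only = setdiff(media_ids, lysate_ids),
    lysate_only = setdiff(lysate_ids, media_ids)
  )
  sp <- character(0)
  if (!is.null(annotations)) {
    sp <- annotations$accession[annotations$has_signal_peptide]
  }
  tibble(
    region = names(regions),
    n = unname(vapply(regions, length, integer(1))),
    n_signal_peptide = unname(vapply(regions, function(ids) sum(ids %in% sp),
                                     integer(1)))
  ) |>
    mutate(sp_fraction = if_else(.data$n > 0,
                                 .data$n_signal_peptide / .data$n, NA_real_))
}

#' Bin proteins by M/L ratio and compute the signal-peptide percentage
#'
#' Both-detected proteins with a defined summary M/L in the chosen condition
#' are placed in half-open bins `(lo, hi]` defined by ascending `bin_edges`;
#' the first bin is `(0, edge1]` and the last is open-ended. Each bin reports
#' its protein count and the percentage of its proteins bearing a signal
#' peptide (undefined for empty bins).
#'
#' @param ratio_table A [compute_ml_ratios()] result.
#' @param bin_edges Ascending positive bin edges.
#' @param condition Which condition's summary M/L to bin (default the first).
#' @return Tibble: `bin`, `lo`, `hi`, `n`, `n_signal_peptide`, `sp_pct`.
#' @export
bin_signal_peptide_fraction <- function(ratio_table,
                                        bin_edges = c(0.5, 1, 2, 5, 10, 20),
                                        condition = NULL) {
  if (is.unsorted(bin_edges, strictly = TRUE) || any(bin_edges <= 0)) {
    abort("`bin_edges` must be strictly ascending and positive.",
          class = "secretr_config_error")
  }
  condition <- condition %||% attr(ratio_table, "conditions")[1] %||% "ctrl"
  ml_col <- paste0("ml_", condition)
  if (!ml_col %in% names(ratio_table)) {
    abort(sprintf("Column `%s` not found in the ratio table.", ml_col),
          class = "secretr_config_error")
  }
  dat <- ratio_table |>
    filter(.data$detection_status == "both", is.finite(.data[[ml_col]]))

  lo <- c(0, bin_edges)
  hi <- c(bin_edges, Inf)
  labels <- c(paste0("<=", bin_edges[1]),
              if (length(bin_edges) > 1)
                sprintf("(%g,%g]", bin_edges[-length(bin_edges)], bin_edges[-1]),
              paste0(">", bin_edges[length(bin_edges)]))
  idx <- cut(dat[[ml_col]], breaks = c(lo[1], hi), labels = FALSE, right = TRUE)

  tibble(bin = labels, lo = lo, hi = hi) |>
    mutate(
      n = vapply(seq_along(labels), function(i) sum(idx == i, na.rm = TRUE), integer(1)),
      n_signal_peptide = vapply(seq_along(labels), function(i) {
        sum(dat$has_signal_peptide[idx == i], na.rm = TRUE)
      }, integer(1)),
      sp_pct = if_else(.data$n > 0, 100 * .data$n_signal_peptide / .data$n, NA_real_)
    )
}
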