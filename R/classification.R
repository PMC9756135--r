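#' Call BFA sensitivity from the M/L contrast
#'
#' A protein is BFA-sensitive when its M/L adjusted p-value is below `alpha`
#' AND its M/L log2 fold change is negative (depletion from the media and/or
#' accumulation in the lysate). Everything else with a defined contrast is
#' resistant; proteins without a defined contrast are `NA` (indeterminate).
#' Proteins with a significant *positive* M/L shift are resistant by this
#' rule and separately flagged (`significant_increase`).
#'
#' @param diff_ml Tidy M/L contrast table (`group_id`, `l2fc`, `adj_p`), e.g.
#'   `tidy(contrasts$ml)`.
#' @param alpha Significance level for the adjusted p-value.
#' @return Tibble: `group_id`, `bfa_sensitive` (logical), `ml_l2fc`,
#'   `ml_adj_p`, `significant_increase`.
#' @export
call_bfa_sensitivity <- function(diff_ml, alpha = 0.05) {
  if (inherits(diff_ml, "moderated_fit")) diff_ml <- tidy(diff_ml)
  diff_ml |>
    mutate(
      bfa_sensitive = if_else(is.na(.data$adj_p), NA,
                              .data$adj_p < alpha & .data$l2fc < 0),
      significant_increase = if_else(is.na(.data$adj_p), NA,
                                     .data$adj_p < alpha & .data$l2fc > 0)
    ) |>
    select("group_id", "bfa_sensitive", ml_l2fc = "l2fc", ml_adj_p = "adj_p",
           "significant_increase")
}

#' Rank candidate unconventionally secreted proteins
#'
#' Among both-detected proteins lacking a signal peptide, ranks by control
#' summary M/L descending (ties broken by accession) and returns the top
#' `top_n` with their BFA-sensitivity call. Candidates also lacking a
#' transmembrane domain are marked `cytosolic`; a BFA-sensitive member is
#' retained in the list but flagged rather than dropped.
#'
#' @param ratio_table A [compute_ml_ratios()] result with annotations.
#' @param diff_ml Tidy M/L contrast (see [call_bfa_sensitivity()]).
#' @param top_n Number of candidates to return.
#' @param alpha Significance level for the sensitivity call.
#' @param condition Condition whose summary M/L is ranked (default the
#'   first, i.e. control).
#' @return Tibble: `rank`, `group_id`, `ml`, `bfa_sensitive`, `cytosolic`,
#'   `has_tm_domain`, `ml_l2fc`, `ml_adj_p`.
#' @export
rank_unconventional_candidates <- function(ratio_table, diff_ml, top_n = 10,
                                           alpha = 0.05, condition = NULL) {
  condition <- condition %||% attr(ratio_table, "conditions")[1] %||% "ctrl"
  ml_col <- paste0("ml_", condition)
  sens <- call_bfa_sensitivity(diff_ml, alpha)
  ratio_table |>
    filter(.data$detection_status == "both",
           !.data$has_signal_peptide,
           is.finite(.data[[ml_col]])) |>
    arrange(dplyr::desc(.data[[ml_col]]), .data$group_id) |>
    head(top_n) |>
    mutate(rank = row_number(), ml = .data[[ml_col]],
           cytosolic = !.data$has_tm_domain) |>
    left_join(sens, by = "group_id") |>
    select("rank", "group_id", "ml", "bfa_sensitive", "cytosolic",
           "has_tm_domain", "ml_l2fc", "ml_adj_p")
}

#' Transmembrane proteins with M/L above threshold and their BFA calls
#'
#' Rows are transmembrane-domain proteins detected in both fractions with a
#' control summary M/L strictly greater than `ml_min`; the table reports the
#' control and BFA summary M/L and the resistance call.
#'
#' @inheritParams rank_unconventional_candidates
#' @param ml_min Strict lower bound on the control summary M/L.
#' @param treatment Name of the treatment condition.
#' @return Tibble: `group_id`, `ml_control`, `ml_treatment`, `resistant`,
#'   `ml_l2fc`, `ml_adj_p`.
#' @export
tm_bfa_table <- function(ratio_table, diff_ml, ml_min = 1, alpha = 0.05,
                         condition = NULL, treatment = "bfa") {
  condition <- condition %||% attr(ratio_table, "conditions")[1] %||% "ctrl"
  ml_col <- paste0("ml_", condition)
  trt_col <- paste0("ml_", treatment)
  sens <- call_bfa_sensitivity(diff_ml, alpha)
  ratio_table |>
    filter(.data$detection_status == "both",
           .data$has_tm_domain,
           is.finite(.data[[ml_col]]),
           .data[[ml_col]] > ml_min) |>
    left_join(sens, by = "group_id") |>
    mutate(resistant = !dplyr::coalesce(.data$bfa_sensitive, FALSE),
           ml_control = .data[[ml_col]],
           ml_treatment = .data[[trt_col]]) |>
    arrange(dplyr::desc(.data$ml_control)) |>
    select("group_id", "ml_control", "ml_treatment", "resistant",
           "ml_l2fc", "ml_adj_p")
}

#' Assign a secretome label to every both-detected protein
#'
#' Applies the decision rules in documented precedence order; each protein
#' receives exactly one label:
#' \describe{
#'   \item{conventional_secreted}{signal peptide, control M/L >
#'     `conventional_ml_min`, and BFA-sensitive.}
#'   \item{unconventional_candidate}{no signal peptide, no TM domain,
#'     control M/L > `candidate_ml_min`, and BFA-resistant.}
#'   \item{post_golgi_tm}{TM domain, control M/L > `tm_ml_min`, and
#'     BFA-resistant.}
#'   \item{intracellular}{control M/L at or below 1 and no earlier label.}
#'   \item{indeterminate}{anything else (e.g. a signal-peptide protein with
#'     high M/L that resists BFA -- conflicting evidence is surfaced, not
#'     silently binned).}
#' }
#'
#' @inheritParams rank_unconventional_candidates
#' @param alpha Significance level for the BFA-sensitivity call.
#' @param conventional_ml_min,candidate_ml_min,tm_ml_min M/L thresholds
#'   (strict) for the respective labels.
#' @return A `secretome_calls` tibble: `group_id`, `label`, `ml_control`,
#'   `has_signal_peptide`, `has_tm_domain`, `ml_l2fc`, `ml_adj_p`,
#'   `bfa_sensitive`, `candidate_rank`.
#' @export
assign_labels <- function(ratio_table, diff_ml, alpha = 0.05,
                          conventional_ml_min = 1, candidate_ml_min = 1,
                          tm_ml_min = 1, condition = NULL) {
  condition <- condition %||% attr(ratio_table, "conditions")[1] %||% "ctrl"
  ml_col <- paste0("ml_", condition)
  sens <- call_bfa_sensitivity(diff_ml, alpha)

  ranked <- ratio_table |>
    filter(.data$detection_status == "both", !.data$has_signal_peptide,
           is.finite(.data[[ml_col]])) |>
    arrange(dplyr::desc(.data[[ml_col]]), .data$group_id) |>
    mutate(candidate_rank = row_number()) |>
    select("group_id", "candidate_rank")

  out <- ratio_table |>
    filter(.data$detection_status == "both") |>
    left_join(sens, by = "group_id") |>
    left_join(ranked, by = "group_id") |>
    mutate(
      ml_control = .data[[ml_col]],
      resistant = !.data$bfa_sensitive,
      label = case_when(
        .data$has_signal_peptide & .data$ml_control > conventional_ml_min &
          !is.na(.data$bfa_sensitive) & .data$bfa_sensitive ~ "conventional_secreted",
        !.data$has_signal_peptide & !.data$has_tm_domain &
          .data$ml_control > candidate_ml_min &
          !is.na(.data$resistant) & .data$resistant ~ "unconventional_candidate",
        .data$has_tm_domain & .data$ml_control > tm_ml_min &
          !is.na(.data$resistant) & .data$resistant ~ "post_golgi_tm",
        !is.na(.data$ml_control) & .data$ml_control <= 1 ~ "intracellular",
        TRUE ~ "indeterminate"
      ),
      candidate_rank = if_else(.data$label == "unconventional_candidate",
                               .data$candidate_rank, NA_integer_)
    ) |>
    select("group_id", "label", "ml_control", "has_signal_peptide",
           "has_tm_domain", "ml_l2fc", "ml_adj_p", "bfa_sensitive",
           "candidate_rank")
  class(out) <- c("secretome_calls", class(out))
  out
}

#' Score secretome calls against a synthetic ground truth
#'
#' Joins calls to the generator's truth by accession and reports the
#' confusion counts plus sensitivity and specificity of the
#' `conventional_secreted` label against the ground-truth conventional
#' class, and the recovery of ground-truth unconventional proteins in the
#' candidate ranking.
#'
#' @param calls An [assign_labels()] result.
#' @param truth A [generate_ground_truth()] tibble.
#' @param candidates Optional [rank_unconventional_candidates()] result.
#' @return A list with `confusion` (label x true-class counts),
#'   `conventional` (tibble with tp/fp/fn/tn, sensitivity, specificity),
#'   and, when `candidates` is given, `candidate_recovery` (fraction of
#'   ground-truth unconventional proteins present in the candidate list).
#' @export
score_calls <- function(calls, truth, candidates = NULL) {
  joined <- calls |>
    inner_join(select(truth, "accession", "secretion_class"),
               by = c(group_id = "accession"))
  confusion <- joined |> count(.data$label, .data$secretion_class)

  is_true_conv <- joined$secretion_class == "conventional_secreted"
  is_called_conv <- joined$label == "conventional_secreted"
  tp <- sum(is_true_conv & is_called_conv)
  fp <- sum(!is_true_conv & is_called_conv)
  fn <- sum(is_true_conv & !is_called_conv)
  tn <- sum(!is_true_conv & !is_called_conv)
  conventional <- tibble(
    tp = tp, fp = fp, fn = fn, tn = tn,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_
  )

  out <- list(confusion = confusion, conventional = conventional)
  if (!is.null(candidates)) {
    true_unconv <- truth$accession[truth$secretion_class == "unconventional_secreted"]
    detected_unconv <- intersect(true_unconv, calls$group_id)
    out$candidate_recovery <- tibble(
      n_true = length(true_unconv),
      n_detected = length(detected_unconv),
      n_in_list = sum(true_unconv %in% candidates$group_id),
      recovery = if (length(true_unconv) > 0)
        sum(true_unconv %in% candidates$group_id) / length(true_unconv)
      else NA_real_
    )
  }
  out
}
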