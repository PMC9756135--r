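#' Empirical-Bayes moderated two-group test
#'
#' Fits, per protein, the two-group equal-variance linear model on log2
#' values and moderates the residual variances by shrinking them towards a
#' common prior. The prior variance `s0^2` and prior degrees of freedom `d0`
#' are estimated from the marginal distribution of the residual variances by
#' matching the moments of `log(s_g^2)` to a scaled-F model; the spread
#' equation is inverted through the trigamma function by monotone Newton
#' iteration (tolerance 1e-8). The posterior variance is
#' `(d0 s0^2 + d_g s_g^2) / (d0 + d_g)`, the moderated t is
#' `l2fc / (s_post * sqrt(1/n1 + 1/n2))` on `d0 + d_g` degrees of freedom,
#' and two-sided p-values are Benjamini-Hochberg adjusted across proteins.
#'
#' With `prior_df = 0` the moderated t reduces exactly to the ordinary
#' equal-variance two-sample t; with `prior_df = Inf` every posterior
#' variance equals the common prior variance. When the spread of the
#' observed log-variances is no larger than expected from chi-square
#' sampling alone, `d0` is estimated as infinite and flagged in `glance()`.
#'
#' @param data A tibble with a `group_id` column and one numeric column per
#'   sample, or a numeric matrix with row names as ids.
#' @param groups Character/factor vector, one entry per sample column, with
#'   exactly two levels.
#' @param reference The level of `groups` treated as the baseline; positive
#'   `l2fc` means higher in the non-reference level.
#' @param prior_df Optional override for `d0` (`NULL` = estimate).
#' @return An object of class `moderated_fit`. `tidy()` returns the
#'   per-protein table (`group_id`, `l2fc`, `s2`, `df_residual`, `s2_post`,
#'   `t`, `p`, `adj_p`, `n_reference`, `n_other`); `glance()` returns the
#'   prior estimates.
#' @export
fit_moderated_test <- function(data, groups, reference = NULL, prior_df = NULL) {
  if (is.data.frame(data)) {
    ids <- as.character(data$group_id)
    mat <- as.matrix(data[setdiff(names(data), "group_id")])
  } else {
    mat <- as.matrix(data)
    ids <- rownames(mat) %||% as.character(seq_len(nrow(mat)))
  }
  groups <- as.character(groups)
  if (length(groups) != ncol(mat)) {
    abort("`groups` must have one entry per sample column.",
          class = "secretr_config_error")
  }
  lev <- unique(groups)
  if (length(lev) != 2) abort("`groups` must have exactly two levels.",
                              class = "secretr_config_error")
  reference <- reference %||% lev[1]
  if (!reference %in% lev) abort("`reference` is not a level of `groups`.",
                                 class = "secretr_config_error")
  other <- setdiff(lev, reference)

  m1 <- mat[, groups == reference, drop = FALSE]
  m2 <- mat[, groups == other, drop = FALSE]
  n1 <- rowSums(is.finite(m1))
  n2 <- rowSums(is.finite(m2))
  usable <- n1 >= 2 & n2 >= 2
  n_excluded <- sum(!usable)

  mean1 <- rowMeans(replace(m1, !is.finite(m1), NA), na.rm = TRUE)
  mean2 <- rowMeans(replace(m2, !is.finite(m2), NA), na.rm = TRUE)
  ss1 <- rowSums((replace(m1, !is.finite(m1), NA) - mean1)^2, na.rm = TRUE)
  ss2 <- rowSums((replace(m2, !is.finite(m2), NA) - mean2)^2, na.rm = TRUE)

  l2fc <- (mean2 - mean1)[usable]
  dg <- (n1 + n2 - 2)[usable]
  s2 <- (ss1 + ss2)[usable] / dg
  n1u <- n1[usable]; n2u <- n2[usable]

  if (is.null(prior_df)) {
    prior <- fit_variance_prior(s2, dg)
  } else {
    prior <- list(d0 = prior_df,
                  s02 = if (length(s2)) exp(mean(log(s2[s2 > 0]))) else NA_real_)
    if (is.infinite(prior_df)) prior$s02 <- mean(s2)
  }
  d0 <- prior$d0; s02 <- prior$s02

  s2_post <- if (is.infinite(d0)) rep(s02, length(s2)) else {
    (d0 * s02 + dg * s2) / (d0 + dg)
  }
  se <- sqrt(s2_post * (1 / n1u + 1 / n2u))
  tstat <- ifelse(se > 0, l2fc / se, ifelse(l2fc == 0, 0, sign(l2fc) * Inf))
  df_total <- d0 + dg
  p <- 2 * pt(-abs(tstat), df = df_total)
  p[se == 0 & l2fc == 0] <- 1
  p[se == 0 & l2fc != 0] <- 0

  table <- tibble(
    group_id = ids[usable],
    l2fc = l2fc,
    s2 = s2,
    df_residual = dg,
    s2_post = s2_post,
    t = tstat,
    p = p,
    adj_p = adjust_bh(p),
    n_reference = n1u,
    n_other = n2u
  )

  structure(list(table = table, prior_df = d0, prior_var = s02,
                 reference = reference, comparison = other,
                 n_excluded = n_excluded),
            class = "moderated_fit")
}

# Estimate (d0, s0^2) from residual variances s2 on dg degrees of freedom
# by moment matching on log(s2) against a scaled-F model.
fit_variance_prior <- function(s2, dg) {
  ok <- s2 > 0 & dg > 0
  if (sum(ok) < 2) return(list(d0 = Inf, s02 = mean(s2), flagged = TRUE))
  z <- log(s2[ok])
  df <- dg[ok]
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- var(e) - mean(trigamma(df / 2))
  if (!is.finite(evar) || evar <= 0) {
    # spread no larger than chi-square sampling alone: infinite prior df
    return(list(d0 = Inf, s02 = mean(s2[ok]), flagged = TRUE))
  }
  d0 <- 2 * trigamma_inverse(evar)
  s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s02 = s02, flagged = FALSE)
}

# Solve trigamma(y) = x for y > 0 by monotone Newton iteration on 1/trigamma,
# tolerance 1e-8.
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:75) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2)
    y <- y + dif
    if (-dif / y < 1e-8) break
  }
  y
}

#' @export
print.moderated_fit <- function(x, ...) {
  cat("<moderated_fit>", nrow(x$table), "proteins;",
      x$comparison, "vs", x$reference, "\n")
  cat(sprintf("  prior df d0 = %.4g, prior variance s0^2 = %.4g, %d excluded\n",
              x$prior_df, x$prior_var, x$n_excluded))
  invisible(x)
}

#' @rdname fit_moderated_test
#' @param x A `moderated_fit` object.
#' @param ... Unused.
#' @export
tidy.moderated_fit <- function(x, ...) x$table

#' @rdname fit_moderated_test
#' @export
glance.moderated_fit <- function(x, ...) {
  tibble(prior_df = x$prior_df, prior_var = x$prior_var,
         n_proteins = nrow(x$table), n_excluded = x$n_excluded,
         reference = x$reference, comparison = x$comparison)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjustment of a vector of p-values; monotone in the input ranks
#' and capped at 1.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values.
#' @export
adjust_bh <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(!is.na(p) & (p < 0 | p > 1))) {
    abort("p-values must lie in [0, 1].", class = "secretr_input_error")
  }
  p.adjust(p, method = "BH")
}

#' BFA-vs-control contrasts on lysate, media and M/L responses
#'
#' Runs [fit_moderated_test()] on three responses: log2 lysate absolute
#' intensities, log2 media absolute intensities, and per-replicate log2 M/L
#' ratios. Positive `l2fc` always means higher under the treatment
#' condition. Proteins absent from a matrix (or detected in only one
#' fraction, for the M/L response) are excluded from that contrast.
#'
#' @param lysate,media `quant_matrix` tibbles.
#' @param ratio_table A [compute_ml_ratios()] result.
#' @param control,treatment Condition names as used in the channel ids.
#' @return A list of class `bfa_contrasts` with `moderated_fit` elements
#'   `lysate`, `media`, `ml`. `tidy()` binds the three per-protein tables
#'   with a `response` column.
#' @export
bfa_contrasts <- function(lysate, media, ratio_table,
                          control = "ctrl", treatment = "bfa") {
  fit_quant <- function(qm) {
    wide <- qm |>
      select("group_id", "channel", "abs_intensity") |>
      mutate(value = log2(.data$abs_intensity)) |>
      select(-"abs_intensity") |>
      tidyr::pivot_wider(names_from = "channel", values_from = "value")
    chans <- setdiff(names(wide), "group_id")
    cond <- sub("_[0-9]+$", "", chans)
    keep <- cond %in% c(control, treatment)
    fit_moderated_test(wide[c("group_id", chans[keep])], cond[keep],
                       reference = control)
  }

  rep_cols <- grep(paste0("^log2_ml_(", control, "|", treatment, ")_[0-9]+$"),
                   names(ratio_table), value = TRUE)
  ml_dat <- ratio_table |>
    filter(.data$detection_status == "both") |>
    select("group_id", dplyr::all_of(rep_cols))
  cond <- sub("^log2_ml_(.*)_[0-9]+$", "\\1", rep_cols)

  fits <- list(
    lysate = fit_quant(lysate),
    media = fit_quant(media),
    ml = fit_moderated_test(ml_dat, cond, reference = control)
  )
  structure(fits, class = "bfa_contrasts")
}

#' @export
print.bfa_contrasts <- function(x, ...) {
  cat("<bfa_contrasts> responses: lysate, media, ml\n")
  for (nm in names(x)) {
    cat(sprintf("  %-6s %d proteins (d0 = %.3g)\n", nm, nrow(x[[nm]]$table),
                x[[nm]]$prior_df))
  }
  invisible(x)
}

#' @rdname bfa_contrasts
#' @param x A `bfa_contrasts` object.
#' @param ... Unused.
#' @export
tidy.bfa_contrasts <- function(x, ...) {
  purrr::imap(unclass(x), function(f, nm) mutate(tidy(f), response = nm)) |>
    bind_rows() |>
    select("response", dplyr::everything())
}
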