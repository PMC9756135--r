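mk_ratio_table <- function(df) {
  out <- tibble::as_tibble(df)
  class(out) <- c("ratio_table", class(out))
  attr(out, "conditions") <- c("ctrl", "bfa")
  out
}

mk_diff <- function(group_id, l2fc, adj_p) {
  tibble::tibble(group_id = group_id, l2fc = l2fc, adj_p = adj_p)
}

test_that("BFA sensitivity combines the adjusted p threshold and the sign rule", {
  d <- mk_diff(c("A", "B", "C", "D"),
               l2fc = c(-2, 1, -2, -0.5),
               adj_p = c(0.01, 0.01, 0.2, NA))
  s <- call_bfa_sensitivity(d, alpha = 0.05)
  expect_equal(s$bfa_sensitive, c(TRUE, FALSE, FALSE, NA))
  expect_equal(s$significant_increase, c(FALSE, TRUE, FALSE, NA))
})

test_that("candidate ranking keeps SP-lacking proteins ordered by control M/L", {
  rt <- mk_ratio_table(tibble::tibble(
    group_id = c("U1", "I1", "I2", "T1", "S1", "M1"),
    detection_status = c(rep("both", 5), "media_only"),
    has_signal_peptide = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE),
    has_tm_domain = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE),
    ml_ctrl = c(5, 0.1, 0.12, 2, 40, NA)
  ))
  d <- mk_diff(rt$group_id, l2fc = c(0.1, 0, 0, 0.2, -3, 0),
               adj_p = c(0.9, 0.8, 0.9, 0.7, 0.001, 0.5))
  cand <- rank_unconventional_candidates(rt, d, top_n = 10)
  # the planted unconventional protein ranks first; SP+ and media-only excluded
  expect_equal(cand$group_id[1], "U1")
  expect_false("S1" %in% cand$group_id)
  expect_false("M1" %in% cand$group_id)
  # TM-bearing candidate stays in the list but is not cytosolic
  expect_true("T1" %in% cand$group_id)
  expect_false(cand$cytosolic[cand$group_id == "T1"])
  expect_true(cand$cytosolic[cand$group_id == "U1"])

  # every protein SP-positive -> empty candidate list
  rt_sp <- mk_ratio_table(dplyr::mutate(rt, has_signal_peptide = TRUE))
  expect_equal(nrow(rank_unconventional_candidates(rt_sp, d)), 0)
})

test_that("a BFA-sensitive candidate is retained but flagged", {
  rt <- mk_ratio_table(tibble::tibble(
    group_id = c("U1", "U2"), detection_status = "both",
    has_signal_peptide = FALSE, has_tm_domain = FALSE,
    ml_ctrl = c(8, 5)
  ))
  d <- mk_diff(c("U1", "U2"), l2fc = c(-2, 0), adj_p = c(0.001, 0.9))
  cand <- rank_unconventional_candidates(rt, d)
  expect_equal(nrow(cand), 2)
  expect_true(cand$bfa_sensitive[cand$group_id == "U1"])
  expect_false(cand$bfa_sensitive[cand$group_id == "U2"])
})

test_that("the TM table applies the strict M/L bound and resistance composition", {
  rt <- mk_ratio_table(tibble::tibble(
    group_id = c("T1", "T2", "T3", "N1"),
    detection_status = "both",
    has_signal_peptide = FALSE,
    has_tm_domain = c(TRUE, TRUE, TRUE, FALSE),
    ml_ctrl = c(1.0, 3, 2, 9),
    ml_bfa = c(1.0, 2.9, 0.4, 9)
  ))
  d <- mk_diff(rt$group_id, l2fc = c(0, -0.1, -2.5, 0),
               adj_p = c(0.9, 0.5, 0.001, 0.9))
  tm <- tm_bfa_table(rt, d, ml_min = 1)
  expect_setequal(tm$group_id, c("T2", "T3"))   # exactly 1.0 excluded, non-TM excluded
  expect_true(tm$resistant[tm$group_id == "T2"])   # adj p 0.5 -> resistant
  expect_false(tm$resistant[tm$group_id == "T3"])
})

test_that("label assignment follows the documented precedence", {
  rt <- mk_ratio_table(tibble::tibble(
    group_id = c("C1", "I1", "X1", "U1", "T1", "L1"),
    detection_status = "both",
    has_signal_peptide = c(TRUE, FALSE, TRUE, FALSE, FALSE, TRUE),
    has_tm_domain = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE),
    ml_ctrl = c(30, 0.2, 30, 5, 3, 0.4),
    ml_bfa = c(1, 0.2, 30, 5, 3, 0.4)
  ))
  d <- mk_diff(rt$group_id,
               l2fc = c(-4, 0, 0.1, 0.05, 0, 0),
               adj_p = c(0.001, 0.9, 0.8, 0.9, 0.7, 0.9))
  calls <- assign_labels(rt, d)
  lab <- function(id) calls$label[calls$group_id == id]
  expect_equal(lab("C1"), "conventional_secreted")   # SP+, high M/L, sensitive
  expect_equal(lab("I1"), "intracellular")           # SP-, TM-, M/L 0.2
  expect_equal(lab("X1"), "indeterminate")           # SP+, high M/L, resistant
  expect_equal(lab("U1"), "unconventional_candidate")
  expect_equal(lab("T1"), "post_golgi_tm")
  expect_equal(lab("L1"), "intracellular")           # SP+ but M/L <= 1
  expect_false(any(is.na(calls$label)))
  expect_equal(calls$candidate_rank[calls$group_id == "U1"], 1L)
})

test_that("raising the candidate M/L threshold never adds candidates", {
  run <- default_run(1)
  d <- tidy(run$contrasts$ml)
  sets <- lapply(c(1, 2, 4), function(thr) {
    calls <- assign_labels(run$ratio_table, d, candidate_ml_min = thr)
    calls$group_id[calls$label == "unconventional_candidate"]
  })
  expect_true(all(sets[[2]] %in% sets[[1]]))
  expect_true(all(sets[[3]] %in% sets[[2]]))
})

test_that("labels partition the both-detected set on synthetic data", {
  run <- default_run(1)
  calls <- run$calls
  both <- run$ratio_table$group_id[run$ratio_table$detection_status == "both"]
  expect_setequal(calls$group_id, both)
  expect_false(any(is.na(calls$label)))
  expect_true(all(calls$label %in% c("conventional_secreted",
                                     "unconventional_candidate",
                                     "post_golgi_tm", "intracellular",
                                     "indeterminate")))
  # invariants on the labelled evidence
  uc <- calls[calls$label == "unconventional_candidate", ]
  expect_false(any(uc$has_signal_peptide))
  pg <- calls[calls$label == "post_golgi_tm", ]
  expect_true(all(pg$has_tm_domain & pg$ml_control > 1))
})

test_that("the TM table recovers ground-truth shed membrane proteins", {
  run <- default_run(1)
  tr <- run$truth
  shed <- tr$accession[tr$has_tm_domain & tr$secretion_fraction > 0]
  # no false positives: every row is a genuinely shed TM protein (unshed
  # membrane proteins sit at M/L = leakage, far below the threshold)
  expect_true(all(run$tm_table$group_id %in% shed))
  # every clearly-shed protein (true M/L >= 1.25) that was quantified in both
  # fractions appears in the table
  both <- run$ratio_table$group_id[run$ratio_table$detection_status == "both"]
  clear <- tr$accession[tr$has_tm_domain &
                          tr$media_ctrl / tr$lysate_ctrl >= 1.25]
  expect_true(all(intersect(clear, both) %in% run$tm_table$group_id))
  expect_true(mean(run$tm_table$resistant) > 0.9)
})

test_that("scoring against ground truth reports a coherent confusion summary", {
  run <- default_run(1)
  sc <- run$score
  conv <- sc$conventional
  expect_equal(conv$tp + conv$fn,
               sum(ml_errors(run)$secretion_class == "conventional_secreted"))
  expect_equal(sum(sc$confusion$n), nrow(run$calls))
  expect_equal(sc$candidate_recovery$n_true, 5L)
})
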