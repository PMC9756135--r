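test_that("label and purity filters apply the documented boundaries", {
  psms <- make_psms(
    n = 4,
    purity = c(0.49, 0.50, 0.99, 0.99),
    has_tmt_label = c(TRUE, TRUE, FALSE, TRUE),
    intensities = matrix(c(100, 100, 100, 100), 4, 2)
  )
  out <- filter_psms(psms, low_intensity_percentile = 0)
  # purity 0.49 removed (strictly below 0.5), 0.50 retained at the boundary;
  # the unlabelled PSM is removed despite high purity
  expect_equal(out$spectrum_id, psms$spectrum_id[c(2, 4)])
  rep <- psm_filter_report(out)
  expect_equal(rep$n_unlabeled, 1L)
  expect_equal(rep$n_low_purity, 1L)
  expect_equal(rep$n_retained, 2L)
})

test_that("low-intensity removal matches a brute-force nearest-rank oracle", {
  oracle <- function(sums, p) {
    k <- ceiling(p / 100 * length(sums))
    cutoff <- if (k >= 1) sort(sums)[k] else -Inf
    which(sums > cutoff)
  }
  sums <- as.numeric(1:100)
  psms <- make_psms(n = 100, peptide = paste0("pep", 1:100), purity = 1,
                    intensities = cbind(sums, 0))
  for (p in c(0, 5, 10, 37.5, 99)) {
    out <- filter_psms(psms, low_intensity_percentile = p)
    expect_equal(out$spectrum_id, psms$spectrum_id[oracle(sums, p)],
                 info = paste("percentile", p))
  }
  expect_error(filter_psms(psms, low_intensity_percentile = 100),
               class = "secretr_config_error")
  expect_error(filter_psms(psms, low_intensity_percentile = -1),
               class = "secretr_config_error")
})

test_that("contaminant PSMs are removed and empty input passes through", {
  psms <- make_psms(n = 3, is_contaminant = c(FALSE, TRUE, FALSE), purity = 1)
  out <- filter_psms(psms, low_intensity_percentile = 0)
  expect_equal(out$spectrum_id, psms$spectrum_id[c(1, 3)])
  expect_equal(nrow(filter_psms(psms[0, ])), 0)
  # survivors all satisfy every predicate (filter is self-consistent)
  expect_true(all(out$has_tmt_label & out$purity >= 0.5 & !out$is_contaminant))
})

test_that("percentile is computed per run over label/purity survivors", {
  # run A sums 1..10, run B sums 101..110; a global percentile would only
  # remove from run A
  psms <- dplyr::bind_rows(
    make_psms(n = 10, run_id = "A", peptide = paste0("a", 1:10),
              spectrum_id = sprintf("A.%02d", 1:10), purity = 1,
              intensities = cbind(1:10, 0)),
    make_psms(n = 10, run_id = "B", peptide = paste0("b", 1:10),
              spectrum_id = sprintf("B.%02d", 1:10), purity = 1,
              intensities = cbind(101:110, 0))
  )
  out <- filter_psms(psms, low_intensity_percentile = 10)
  expect_equal(sum(out$run_id == "A"), 9)
  expect_equal(sum(out$run_id == "B"), 9)
})

test_that("peptide-ion deduplication keeps the highest-sum PSM per ion", {
  psms <- make_psms(
    n = 5,
    spectrum_id = c("r.5", "r.1", "r.2", "r.3", "r.4"),
    peptide = c("pepA", "pepA", "pepA", "pepB", "pepB"),
    charge = c(2L, 2L, 3L, 2L, 2L),
    intensities = rbind(c(300, 200), c(400, 300), c(50, 50),
                        c(10, 10), c(15, 5))
  )
  out <- deduplicate_peptide_ions(psms)
  # pepA z2: sums 500 vs 700 -> the 700 PSM ("r.1"); pepA z3 is a distinct
  # ion; pepB: exact tie at 20 -> smaller spectrum_id "r.3"
  expect_setequal(out$spectrum_id, c("r.1", "r.2", "r.3"))
  # dedup never increases total summed intensity
  tot <- function(x) sum(as.matrix(x[grep("^intensity_", names(x))]), na.rm = TRUE)
  expect_lte(tot(out), tot(psms))
})

test_that("modifications and run distinguish peptide ions", {
  psms <- make_psms(
    n = 4,
    spectrum_id = c("r.1", "r.2", "s.1", "s.2"),
    run_id = c("r", "r", "s", "s"),
    peptide = "pepA",
    modifications = c("", "ox", "", ""),
    intensities = rbind(c(10, 0), c(5, 0), c(9, 0), c(12, 0))
  )
  out <- deduplicate_peptide_ions(psms)
  expect_setequal(out$spectrum_id, c("r.1", "r.2", "s.2"))
})

test_that("protein grouping assigns unique and razor peptides deterministically", {
  # P1 has 3 distinct peptides, P2 has 1; pepS is shared
  psms <- make_psms(
    n = 5,
    peptide = c("pep1", "pep2", "pep3", "pepS", "pep4"),
    proteins = c("P1", "P1", "P1", "P1;P2", "P2"),
    pep = c(0.01, 0.002, 0.03, 0.004, 0.05)
  )
  inf <- infer_protein_groups(psms)
  pm <- inf$peptide_map
  expect_equal(pm$assignment[pm$peptide == "pep1"], "unique")
  shared <- pm[pm$peptide == "pepS", ]
  expect_equal(shared$group_id, "P1")   # razor to the most peptide evidence
  expect_equal(shared$assignment, "razor")
  g1 <- inf$groups[inf$groups$group_id == "P1", ]
  expect_equal(g1$best_peptide_pep, 0.002)
  # stability: recomputation yields identical output
  expect_identical(inf, infer_protein_groups(psms))
})

test_that("indistinguishable accessions merge and razor ties break by group id", {
  psms <- make_psms(
    n = 4,
    peptide = c("pepX", "pepY", "pepZ", "pepS"),
    proteins = c("P9;P2", "P9;P2", "P5", "P5;P9;P2"),
    pep = 0.01
  )
  inf <- infer_protein_groups(psms)
  merged <- inf$groups[inf$groups$group_id == "P2", ]
  expect_equal(merged$members, "P2;P9")  # identical peptide sets -> one group
  # pepS shared between merged group P2 (evidence 3) and P5 (evidence 2):
  # razor to P2
  expect_equal(inf$peptide_map$group_id[inf$peptide_map$peptide == "pepS"], "P2")

  # equal evidence -> smallest group id wins
  psms2 <- make_psms(n = 3, peptide = c("pepA", "pepB", "pepS"),
                     proteins = c("P7", "P3", "P3;P7"), pep = 0.01)
  inf2 <- infer_protein_groups(psms2)
  expect_equal(inf2$peptide_map$group_id[inf2$peptide_map$peptide == "pepS"], "P3")
})

test_that("grouping preserves total summed intensity of retained PSMs", {
  set.seed(5)
  psms <- make_psms(n = 20, peptide = paste0("pep", 1:20),
                    proteins = paste0("P", sample(1:5, 20, replace = TRUE)),
                    intensities = matrix(runif(40, 10, 100), 20, 2))
  inf <- infer_protein_groups(psms)
  expect_equal(sort(unique(inf$peptide_map$peptide)), sort(unique(psms$peptide)))
})

test_that("target-decoy filter retains everything without decoys and nothing decoy-only", {
  psms <- make_psms(n = 6, peptide = paste0("pep", 1:6),
                    proteins = paste0("P", 1:6),
                    pep = c(0.5, 0.2, 0.01, 0.3, 0.9, 0.05))
  inf <- infer_protein_groups(psms)
  kept <- fdr_filter(psms, inf$groups, inf$peptide_map)
  expect_equal(nrow(kept$groups), 6)
  expect_equal(nrow(kept$psms), 6)

  dec <- make_psms(n = 3, peptide = paste0("rev_pep", 1:3),
                   proteins = paste0("rev_P", 1:3), is_decoy = TRUE)
  infd <- infer_protein_groups(dec)
  expect_warning(keptd <- fdr_filter(dec, infd$groups, infd$peptide_map))
  expect_equal(nrow(keptd$groups), 0)
  expect_equal(nrow(keptd$psms), 0)
})

test_that("protein-level cut equals an exhaustive threshold-scan oracle", {
  set.seed(21)
  n_t <- 200; n_d <- 10
  pep <- c(runif(n_t, 0, 0.4), runif(n_d))
  ids <- c(sprintf("P%03d", 1:n_t), sprintf("rev_%03d", 1:n_d))
  psms <- make_psms(n = n_t + n_d, peptide = paste0(ids, "_pep"),
                    proteins = ids, pep = pep,
                    is_decoy = rep(c(FALSE, TRUE), c(n_t, n_d)))
  inf <- infer_protein_groups(psms)

  scan_oracle <- function(groups, level) {
    best <- character(0)
    for (cut in sort(groups$best_peptide_pep)) {
      sel <- groups[groups$best_peptide_pep <= cut, ]
      est <- sum(sel$is_decoy) / max(1, sum(!sel$is_decoy))
      if (est <= level) best <- sel$group_id[!sel$is_decoy]
    }
    sort(best)
  }
  for (level in c(0.01, 0.05, 0.2)) {
    kept <- fdr_filter(psms, inf$groups, inf$peptide_map, protein_fdr = level,
                       psm_fdr = 0.999)
    expect_equal(sort(kept$groups$group_id),
                 scan_oracle(inf$groups, level), info = paste("level", level))
  }
})

test_that("retained-set size is monotone in the FDR levels", {
  set.seed(31)
  n_t <- 150; n_d <- 40
  ids <- c(sprintf("P%03d", 1:n_t), sprintf("rev_%03d", 1:n_d))
  psms <- make_psms(n = n_t + n_d, peptide = paste0(ids, "_pep"),
                    proteins = ids,
                    pep = c(rbeta(n_t, 1, 20), runif(n_d)),
                    is_decoy = rep(c(FALSE, TRUE), c(n_t, n_d)))
  inf <- infer_protein_groups(psms)
  sizes <- sapply(c(0.005, 0.01, 0.05, 0.1, 0.3), function(a) {
    k <- fdr_filter(psms, inf$groups, inf$peptide_map,
                    protein_fdr = a, psm_fdr = a)
    c(nrow(k$groups), nrow(k$psms))
  })
  expect_true(all(diff(sizes[1, ]) >= 0))
  expect_true(all(diff(sizes[2, ]) >= 0))
})
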