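test_that("carrier tables count distinct samples with >= 1 bp overlap", {
  samples <- mk_samples(10, 10)
  locus <- genomic_interval("2", 1e6, 2e6)
  calls <- rbind(
    mk_call("s0001", "2", 0.5e6, 1.2e6, 3),   # overlaps
    mk_call("s0001", "2", 1.5e6, 1.6e6, 3),   # same sample, counted once
    mk_call("s0002", "2", 2e6, 3e6, 3),       # 1 bp overlap counts
    mk_call("s0003", "2", 2e6 + 1, 3e6, 3),   # disjoint
    mk_call("s0011", "2", 1e6, 2e6, 1),       # wrong class
    mk_call("s0012", "2", 1.1e6, 1.9e6, 3))   # control carrier
  tab <- carrier_table(calls, samples, locus, "DUP")
  expect_equal(c(tab$a, tab$b, tab$c, tab$d), c(2, 8, 1, 9))
  empty <- carrier_table(empty_calls_df(), samples, locus, "DUP")
  expect_equal(c(empty$a, empty$b, empty$c, empty$d), c(0, 10, 0, 10))
})

test_that("odds ratios reproduce the published values", {
  expect_equal(round(odds_ratio_ci(carrier_table_counts(23, 1591, 4, 3918))$or, 2),
               14.16)
  expect_equal(round(odds_ratio_ci(carrier_table_counts(27, 1587, 6, 3916))$or, 1),
               11.1)
  expect_equal(round(odds_ratio_ci(carrier_table_counts(64, 1550, 18, 3904))$or, 2),
               8.96)
  expect_equal(round(odds_ratio_ci(carrier_table_counts(28, 1550, 18, 3904))$or, 3),
               3.918)
})

test_that("odds ratio symmetry, balance and Haldane flagging", {
  bal <- odds_ratio_ci(carrier_table_counts(10, 10, 10, 10))
  expect_equal(bal$or, 1)
  expect_equal(log(bal$upper) + log(bal$lower), 0, tolerance = 1e-12)
  fwd <- odds_ratio_ci(carrier_table_counts(23, 1591, 4, 3918))
  swp <- odds_ratio_ci(carrier_table_counts(4, 3918, 23, 1591))
  expect_equal(fwd$or, 1 / swp$or)
  deg <- odds_ratio_ci(carrier_table_counts(5, 5, 0, 10))
  expect_true(deg$haldane)
  expect_true(is.finite(deg$or))
  expect_true(is.infinite(deg$or_raw))
})

test_that("segmental pointwise p matches exhaustive enumeration", {
  # 4 cases (3 carriers) vs 4 controls (0 carriers)
  samples <- mk_samples(4, 4)
  calls <- do.call(rbind, lapply(samples$sample_id[1:3], function(id)
    mk_call(id, "1", 1e6, 1.5e6, 3, 50, 50, "consensus")))
  res <- segmental_test(calls, samples, "DUP", n_perm = 1e5, seed = 11)
  expect_equal(nrow(res), 1)
  expect_equal(res$n_case_carriers, 3)
  # exact enumeration over all C(8,4) = 70 case-label assignments
  chi2 <- function(a, k, n1, n0) {
    N <- n1 + n0; b <- n1 - a; cc <- k - a; d <- n0 - k + a
    N * (a * d - b * cc)^2 / (n1 * n0 * k * (N - k))
  }
  obs <- chi2(3, 3, 4, 4)
  sets <- combn(8, 4)
  exact <- mean(apply(sets, 2, function(idx)
    chi2(sum(idx <= 3), 3, 4, 4) >= obs - 1e-9))
  expect_lt(abs(res$p_point - exact), 0.02)
  expect_equal(res$statistic, obs, tolerance = 1e-12)
})

test_that("balanced carriers give a null pointwise p", {
  samples <- mk_samples(4, 4)
  calls <- do.call(rbind, lapply(samples$sample_id[c(1, 2, 5, 6)],
                                 function(id)
    mk_call(id, "1", 1e6, 1.5e6, 3, 50, 50, "consensus")))
  res <- segmental_test(calls, samples, "DUP", n_perm = 2000, seed = 12)
  expect_gt(res$p_point, 0.5)
})

test_that("corrected p dominates pointwise p and respects the floor", {
  samples <- mk_samples(40, 60)
  set.seed(31)
  calls <- do.call(rbind, lapply(1:30, function(i) {
    s <- sample(1:100, 1)
    st <- runif(1, 1e6, 5e6)
    mk_call(samples$sample_id[s], "1", st, st + runif(1, 5e4, 3e5), 3,
            50, 50, "consensus")
  }))
  res <- segmental_test(calls, samples, "DUP", n_perm = 500, seed = 13)
  expect_true(all(res$p_corr >= res$p_point - 1e-12))
  expect_true(all(res$p_point >= 1 / 501))
  expect_true(all(res$p_corr <= 1))
  # identical carrier sets collapse: no two segments share a carrier profile
  expect_equal(anyDuplicated(res[c("n_case_carriers", "n_control_carriers",
                                   "statistic", "chrom")]) > 0 &&
                 nrow(res) != nrow(unique(res[c("chrom", "start")])), FALSE)
})

test_that("segmental and permutation results are seed-deterministic", {
  samples <- mk_samples(10, 10)
  calls <- do.call(rbind, lapply(samples$sample_id[c(1:4, 11)], function(id)
    mk_call(id, "1", 1e6, 1.5e6, 3, 50, 50, "consensus")))
  r1 <- segmental_test(calls, samples, "DUP", n_perm = 300, seed = 21)
  r2 <- segmental_test(calls, samples, "DUP", n_perm = 300, seed = 21)
  expect_identical(r1$p_point, r2$p_point)
  expect_identical(r1$p_corr, r2$p_corr)
})

test_that("max(T) controls the family-wise error under the null", {
  # 100 null cohorts: the top locus's corrected p should rarely be small
  samples <- mk_samples(30, 30)
  hits <- 0
  for (s in 1:100) {
    set.seed(2000 + s)
    calls <- do.call(rbind, lapply(1:25, function(i) {
      who <- sample(60, 1)
      st <- runif(1, 1e6, 4e6)
      mk_call(samples$sample_id[who], "1", st, st + runif(1, 4e4, 2e5), 3,
              40, 50, "consensus")
    }))
    res <- segmental_test(calls, samples, "DUP", n_perm = 400)
    if (min(res$p_corr) < 0.05) hits <- hits + 1
  }
  expect_lte(hits, 7)  # >= 93% of seeds keep the top corrected p >= 0.05
})

test_that("gene test is conditioned on exonic overlap", {
  samples <- mk_samples(6, 6)
  genes <- toy_gene_models()
  g4 <- genes[genes$name == "G4A", ]
  # duplication inside the gene but covering intron only
  intron_call <- mk_call("s0001", "4", 25560000, 25580000, 3, 20, 50,
                         "consensus")
  # duplication covering exon 1 only
  exon_call <- mk_call("s0002", "4", 25554900, 25557000, 3, 10, 50,
                       "consensus")
  res <- gene_test(rbind(intron_call, exon_call), samples, g4, "DUP",
                   n_perm = 200, seed = 14)
  expect_equal(nrow(res), 1)
  expect_equal(res$locus, "G4A")
  expect_equal(res$n_case_carriers, 1)  # only the exonic call counts
  # gene without exons is skipped
  g0 <- g4; g0$exons <- list(g4$exons[[1]][0, ])
  expect_message(res0 <- gene_test(exon_call, samples, g0, "DUP",
                                   n_perm = 50), "skipping")
  expect_equal(nrow(res0), 0)
})

test_that("gene test recovers a planted exonic duplication", {
  # study-scale cohort with the duplication over G4A exon 1 in 4% of cases
  # and 0.4% of controls: the gene must reach the minimum attainable
  # corrected p at the configured number of permutations
  samples <- mk_samples(1614, 3922)
  genes <- toy_gene_models()
  carriers <- c(samples$sample_id[1:65], samples$sample_id[1615:1630])
  calls <- do.call(rbind, lapply(carriers, function(id)
    mk_call(id, "4", 25554332, 25577184, 3, 23, 50, "consensus")))
  res <- gene_test(calls, samples, genes, "DUP", n_perm = 2000, seed = 15)
  g4 <- res[res$locus == "G4A", ]
  expect_equal(g4$n_case_carriers, 65)
  expect_equal(g4$p_corr, 1 / 2001)
})

test_that("nested carriers are classified by the distinguishing region", {
  samples <- mk_samples(6, 6)
  full_locus <- genomic_interval("10", 47049547, 47703870)
  dist_reg <- genomic_interval("10", 47049547, 47403870)
  calls <- rbind(
    mk_call("s0001", "10", 47049547, 47703870, 3),   # full span
    mk_call("s0002", "10", 47403871, 47703870, 3),   # shared ~300 kb only
    mk_call("s0007", "10", 47403871, 47703870, 3),   # control, partial
    mk_call("s0003", "10", 47049547, 47500000, 3))   # hits the unique part
  lab <- classify_nested_carriers(calls, samples, full_locus, dist_reg)
  expect_equal(lab$label[lab$sample_id == "s0001"], "full")
  expect_equal(lab$label[lab$sample_id == "s0002"], "partial")
  expect_equal(lab$label[lab$sample_id == "s0007"], "partial")
  expect_equal(lab$label[lab$sample_id == "s0003"], "full")
  expect_equal(lab$label[lab$sample_id == "s0004"], "none")
  expect_error(
    classify_nested_carriers(calls, samples, full_locus,
                             genomic_interval("10", 47000000, 47100000)),
    "within full_locus")
})

test_that("the partial-duplication table reproduces the published OR", {
  # partial carriers vs non-carriers at the locus (full carriers excluded
  # from the reference): 28 of 1614 cases, 18 of 3922 controls, with 36/0
  # full carriers also out of the reference
  or <- odds_ratio_ci(carrier_table_counts(28, 1614 - 64, 18, 3922 - 18))$or
  expect_equal(round(or, 2), 3.92)
})

test_that("subtype chi-square follows the Pearson formula", {
  # 4 locus groups x 3 subtypes: df = 6
  tab <- matrix(c(10, 5, 10,
                  8, 4, 15,
                  12, 2, 30,
                  20, 9, 40), nrow = 4, byrow = TRUE)
  res <- subtype_chisq(tab)
  expect_equal(res$df, 6)
  # a table proportional to its margins has statistic 0
  null_tab <- outer(c(10, 20), c(3, 7)) / 10
  res0 <- subtype_chisq(null_tab)
  expect_equal(res0$statistic, 0, tolerance = 1e-12)
  expect_equal(res0$p_value, 1)
  # closed-form check on a 2x2
  res22 <- subtype_chisq(matrix(c(10, 20, 20, 10), 2, byrow = TRUE))
  n <- 60; hand <- n * (10 * 10 - 20 * 20)^2 / (30 * 30 * 30 * 30)
  expect_equal(res22$statistic, hand, tolerance = 1e-12)
  expect_error(subtype_chisq(matrix(c(0, 0, 1, 2), 2)), "margin")
  expect_error(subtype_chisq(matrix(1:3, 3, 1)), "at least 2")
})

test_that("association significance survives the unrelated-subset re-test", {
  map <- tiny_map(2000)
  cfg <- cohort_config(
    n_cases = 150, n_controls = 250, del_rate = 0, dup_rate = 0,
    risk_loci = list(risk_locus("L1", "1", 1.4e6, 1.6e6, 0.12, 0.005)),
    common_loci = list(), qc_fail_frac = 0, family_frac = 0.2, seed = 55)
  ch <- generate_cohort(cfg, map)
  calls <- data.frame(
    sample_id = ch$truth$sample_id, chrom = ch$truth$chrom,
    start = ch$truth$start, end = ch$truth$end,
    copy_state = ch$truth$copy_state,
    n_markers = as.integer((ch$truth$end - ch$truth$start) / 1000 + 1),
    confidence = 50, caller = "consensus", stringsAsFactors = FALSE)
  full <- segmental_test(calls, ch$samples, "DUP", n_perm = 1000, seed = 56)
  unrel <- keep_unrelated(ch$samples)
  expect_lt(nrow(unrel), nrow(ch$samples))
  sub <- segmental_test(calls[calls$sample_id %in% unrel$sample_id, ],
                        unrel, "DUP", n_perm = 1000, seed = 56)
  expect_lt(min(full$p_corr), 0.05)
  expect_lt(min(sub$p_corr), 0.05)
})
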