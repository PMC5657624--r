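make_geno <- function(calls) {
  L <- ncol(calls)
  rownames(calls) <- sprintf("s%02d", seq_len(nrow(calls)))
  genotype_matrix(calls, data.frame(marker_id = sprintf("snp%03d", seq_len(L)),
                                    chrom = 1L, pos_bp = seq_len(L) * 1000L))
}

test_that("sample call-rate filter removes exactly the low-call-rate sample", {
  calls <- matrix(1L, 10, 100)
  calls[3, 1:6] <- NA_integer_  # rate 0.94 < 0.95
  G <- make_geno(calls)
  res <- sample_call_rate_filter(G, 0.95)
  expect_identical(res$report$id, "s03")
  expect_equal(res$report$value, 0.94)
  expect_equal(nrow(res$genotypes$calls), 9)

  full <- sample_call_rate_filter(make_geno(matrix(0:2, 6, 30)), 0.95)
  expect_equal(nrow(full$report), 0)
  all_kept <- sample_call_rate_filter(G, 0)
  expect_equal(nrow(all_kept$genotypes$calls), 10)
})

test_that("heterozygosity filter removes outliers against a hand oracle", {
  set.seed(4)
  n <- 21
  calls <- matrix(0L, n, 200)
  # ~0.30 het with small jitter, one extreme low-het sample
  for (i in 1:20) calls[i, sample(200, 60 + sample(-3:3, 1))] <- 1L
  calls[21, sample(200, 10)] <- 1L  # het 0.05
  G <- make_geno(calls)
  res <- heterozygosity_filter(G, 3)
  expect_identical(res$report$id, "s21")
  expect_identical(res$report$reason, "het_low")
  # oracle recomputation
  expect_identical(sort(res$report$id), sort(oracle_het(calls = {
    rownames(calls) <- sprintf("s%02d", seq_len(n)); calls
  }, k_sd = 3)))

  # identical rates: SD = 0, nothing removed
  same <- make_geno(matrix(rep(c(0L, 1L), each = 50), 4, 100, byrow = TRUE))
  expect_equal(nrow(heterozygosity_filter(same, 3)$report), 0)
  expect_equal(nrow(heterozygosity_filter(G, Inf)$report), 0)
})

test_that("heterozygosity filter flags undefined rates separately", {
  calls <- matrix(c(0L, 1L, 2L), 4, 30)
  calls[4, ] <- NA_integer_
  res <- heterozygosity_filter(make_geno(calls), 3)
  expect_true("undefined_het_rate" %in% res$report$reason)
  expect_equal(nrow(res$genotypes$calls), 3)
})

test_that("SNP call-rate filter uses a strict > threshold", {
  calls <- matrix(1L, 28, 3)
  calls[1, 2] <- NA_integer_        # 27/28 = 0.9643 > 0.964 -> kept
  calls[1:2, 3] <- NA_integer_     # 26/28 = 0.9286 -> removed
  res <- snp_call_rate_filter(make_geno(calls), 0.964)
  expect_identical(res$report$id, "snp003")
  expect_identical(res$genotypes$map$marker_id, c("snp001", "snp002"))

  complete <- snp_call_rate_filter(make_geno(matrix(0:2, 6, 10)), 0.964)
  expect_equal(nrow(complete$report), 0)
  only_complete <- snp_call_rate_filter(make_geno(calls), 1)
  expect_identical(only_complete$genotypes$map$marker_id, "snp001")
})

test_that("monomorphic and unmatched SNPs are removed with one reason each", {
  calls <- cbind(rep(0L, 6), c(0L, 1L, 2L, 0L, 1L, 2L), c(1L, 1L, 1L, 1L, 1L, 1L))
  G <- make_geno(calls)
  panel <- data.frame(marker_id = c("snp001", "snp002"),
                      freqCEU = 0.5, freqYRI = 0.5)
  res <- monomorphic_and_unmatched_filter(G, panel)
  expect_setequal(res$report$id, c("snp001", "snp003"))
  expect_identical(res$report$reason[res$report$id == "snp003"], "unmatched")
  expect_identical(res$report$reason[res$report$id == "snp001"], "monomorphic")
  expect_identical(res$genotypes$map$marker_id, "snp002")
  expect_equal(table(res$report$id)[["snp001"]], 1L)  # exactly one reason
})

test_that("frequency concordance flags |obs - 0.8 freqYRI - 0.2 freqCEU| > 0.3", {
  # hand oracle: expected = 0.8*0.9 + 0.2*0.1 = 0.74; obs 0.40 -> diff 0.34
  calls <- cbind(c(1L, 1L, 1L, 1L, 0L), c(1L, 1L, 1L, 1L, 0L))
  G <- make_geno(calls)
  panel <- data.frame(marker_id = c("snp001", "snp002"),
                      freqCEU = c(0.1, 0.5), freqYRI = c(0.9, 0.35))
  res <- allele_freq_concordance_filter(G, panel, w_eur = 0.2, max_diff = 0.3)
  expect_identical(res$report$id, "snp001")
  expect_equal(res$report$value, 0.34)
  # snp002: expected = 0.8*0.35 + 0.2*0.5 = 0.38, obs 0.40 -> retained
  expect_identical(res$genotypes$map$marker_id, "snp002")

  none <- allele_freq_concordance_filter(G, panel, max_diff = 1)
  expect_equal(nrow(none$report), 0)
  flag_only <- allele_freq_concordance_filter(G, panel, remove = FALSE)
  expect_equal(ncol(flag_only$genotypes$calls), 2)
  expect_equal(nrow(flag_only$report), 1)
})

test_that("every filter is idempotent", {
  G <- random_geno(31)
  panel <- random_panel(G)
  for (f in list(function(g) sample_call_rate_filter(g, 0.95),
                 function(g) heterozygosity_filter(g, 3),
                 function(g) snp_call_rate_filter(g, 0.964),
                 function(g) monomorphic_and_unmatched_filter(g, panel),
                 function(g) allele_freq_concordance_filter(g, panel))) {
    once <- f(G)$genotypes
    again <- f(once)
    expect_equal(nrow(again$report), 0)
  }
})

test_that("filters agree with brute-force removal sets on random matrices", {
  for (seed in c(101, 102, 103, 104, 105)) {
    G <- random_geno(seed)
    panel <- random_panel(G, seed)
    panel <- panel[-sample(nrow(panel), 3), ]  # a few unmatched SNPs
    ids <- G$map$marker_id

    expect_setequal(sample_call_rate_filter(G, 0.95)$report$id,
                    oracle_sample_call_rate(G$calls, 0.95))
    expect_setequal(heterozygosity_filter(G, 2)$report$id,
                    oracle_het(G$calls, 2))
    expect_setequal(snp_call_rate_filter(G, 0.964)$report$id,
                    oracle_snp_call_rate(G$calls, ids, 0.964))
    expect_setequal(monomorphic_and_unmatched_filter(G, panel)$report$id,
                    oracle_mono_unmatched(G$calls, ids, panel$marker_id))
    Gm <- monomorphic_and_unmatched_filter(G, panel)$genotypes
    expect_setequal(
      allele_freq_concordance_filter(Gm, panel, 0.2, 0.2)$report$id,
      oracle_freq_concordance(Gm$calls, Gm$map$marker_id, panel, 0.2, 0.2))
  }
})

test_that("the QC cascade runs stages in order with non-increasing counts", {
  G <- random_geno(55)
  panel <- random_panel(G)
  res <- qc_pipeline(G, panel)
  expect_identical(res$stage_counts$stage,
                   c("input", "sample_call_rate", "heterozygosity",
                     "snp_call_rate", "panel_match", "freq_concordance"))
  expect_true(all(diff(res$stage_counts$n_samples) <= 0))
  expect_true(all(diff(res$stage_counts$n_snps) <= 0))
  expect_true(all(res$report$stage %in% res$stage_counts$stage))
})
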