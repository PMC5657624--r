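test_that("tract ancestry hits the Bernoulli boundaries at m = 0 and m = 1", {
  map <- make_marker_map(c(20L, 20L))
  set.seed(1)
  expect_true(all(simulate_haploid_tracts(50, 1, 7, map) == 1L))
  expect_true(all(simulate_haploid_tracts(50, 0, 7, map) == 0L))
})

test_that("tract chain matches stationary mean and analytic switch rate", {
  # analytic oracle: stationary EUR fraction m; switch probability between
  # markers at distance d Morgans is 2 m (1-m) (1 - exp(-g d))
  m <- 0.2; g <- 7
  map <- make_marker_map(201L, spacing_cM = 0.25)
  set.seed(42)
  h <- simulate_haploid_tracts(10000, m, g, map)
  frac <- rowMeans(h)
  se_mean <- sd(frac) / sqrt(length(frac))
  expect_lt(abs(mean(frac) - m), 3 * se_mean)

  d <- 0.25 / 100
  exp_switches <- 200 * 2 * m * (1 - m) * (1 - exp(-g * d))
  switches <- rowSums(abs(h[, -1] - h[, -ncol(h)]))
  se_sw <- sd(switches) / sqrt(length(switches))
  expect_lt(abs(mean(switches) - exp_switches), 3 * se_sw)
})

test_that("tract lengths are approximately exponential", {
  # EUR exit intensity g(1-m) per Morgan; coarse KS check on a dense map
  m <- 0.3; g <- 7
  map <- make_marker_map(10000L, spacing_cM = 0.05)
  set.seed(7)
  h <- simulate_haploid_tracts(300, m, g, map)
  lens <- numeric(0)
  for (i in seq_len(nrow(h))) {
    r <- rle(h[i, ])
    if (length(r$lengths) >= 3) {  # interior EUR tracts only (uncensored)
      inner <- 2:(length(r$lengths) - 1)
      lens <- c(lens, r$lengths[inner][r$values[inner] == 1L])
    }
  }
  lens_morgan <- lens * 0.05 / 100
  ks <- suppressWarnings(ks.test(lens_morgan, "pexp", rate = g * (1 - m)))
  expect_gt(length(lens), 1000)
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("Balding-Nichols panel frequencies match the Beta moments", {
  set.seed(11)
  pf <- simulate_panel_freqs(10000, fst = 0.15)
  expect_true(all(pf$freqCEU >= 0 & pf$freqCEU <= 1))
  expect_true(all(pf$freqYRI >= 0 & pf$freqYRI <= 1))
  # Var(freq | p) = p(1-p) F  => normalized squared deviations average to F
  ratio <- c((pf$freqCEU - pf$ancestral)^2, (pf$freqYRI - pf$ancestral)^2) /
    rep(pf$ancestral * (1 - pf$ancestral), 2)
  se <- sd(ratio) / sqrt(length(ratio))
  expect_lt(abs(mean(ratio) - 0.15), 3 * se)

  set.seed(12)
  tight <- simulate_panel_freqs(2000, fst = 0.001)
  expect_lt(max(abs(tight$freqCEU - tight$ancestral)), 0.1)
  expect_error(simulate_panel_freqs(10, fst = 1.2), "fst")
})

test_that("null cohorts keep mean ancestry at m everywhere", {
  cfg <- simulation_config(n_cases = 2000, markers_per_chrom = c(10L, 10L),
                           admixture_m = 0.2, relative_risk = 1,
                           genotypes = FALSE, seed = 5)
  co <- simulate_cohort(cfg)
  M <- rowMeans(co$ancestry$q)
  expect_lt(abs(mean(M) - 0.2), 3 * sd(M) / sqrt(length(M)))
})

test_that("ascertainment enriches the risk locus to the closed-form mean", {
  cfg <- simulation_config(n_cases = 5000, markers_per_chrom = c(25L, 25L),
                           admixture_m = 0.2,
                           risk_locus = list(chrom = 1L, index = 13L),
                           relative_risk = 2, risk_model = "multiplicative",
                           genotypes = FALSE, seed = 8)
  co <- simulate_cohort(cfg)
  risk_col <- 13
  q_risk <- co$ancestry$q[, risk_col]
  target <- closed_form_case_ancestry(0.2, 2)  # 1/3
  expect_lt(abs(mean(q_risk) - target), 3 * sd(q_risk) / sqrt(length(q_risk)))
  # unlinked chromosome unaffected by ascertainment
  q_other <- co$ancestry$q[, 26:50]
  M2 <- rowMeans(q_other)
  expect_lt(abs(mean(M2) - 0.2), 3 * sd(M2) / sqrt(length(M2)))
})

test_that("ancestry observation noise preserves support and mean", {
  cfg0 <- simulation_config(n_cases = 300, markers_per_chrom = 20L,
                            genotypes = FALSE, seed = 3)
  co0 <- simulate_cohort(cfg0)
  expect_true(all(co0$ancestry$q %in% c(0, 0.5, 1)))  # kappa = Inf

  cfg1 <- simulation_config(n_cases = 300, markers_per_chrom = 20L,
                            ancestry_noise_kappa = 30, genotypes = FALSE,
                            seed = 3)
  co1 <- simulate_cohort(cfg1)
  expect_true(all(co1$ancestry$q >= 0 & co1$ancestry$q <= 1))
  expect_false(all(co1$ancestry$q %in% c(0, 0.5, 1)))
  expect_lt(abs(mean(co1$ancestry$q) - mean(co0$ancestry$q)), 0.02)
})

test_that("a fixed seed reproduces the cohort bit-for-bit", {
  cfg <- simulation_config(n_cases = 40, markers_per_chrom = c(15L, 15L),
                           risk_locus = list(chrom = 1L, index = 8L),
                           relative_risk = 2.5, seed = 77)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$ancestry$q, b$ancestry$q)
  expect_identical(a$genotypes$calls, b$genotypes$calls)
  expect_identical(a$panel, b$panel)
  c2 <- simulate_cohort(simulation_config(n_cases = 40,
                                          markers_per_chrom = c(15L, 15L),
                                          seed = 78, genotypes = FALSE))
  expect_false(identical(a$ancestry$q, c2$ancestry$q))
})

test_that("genotype layer respects panel frequencies and missingness knobs", {
  cfg <- simulation_config(n_cases = 400, markers_per_chrom = 50L,
                           admixture_m = 0, snp_missing_rate = 0,
                           sample_missing = list(rates = 0, weights = 1),
                           genotype_error_rate = 0, seed = 21)
  co <- simulate_cohort(cfg)  # all-African: allele freq should track freqYRI
  obs <- colMeans(co$genotypes$calls) / 2
  expect_lt(mean(abs(obs - co$panel$freqYRI)), 0.05)
  expect_false(anyNA(co$genotypes$calls))

  cfg2 <- simulation_config(n_cases = 200, markers_per_chrom = 50L,
                            sample_missing = list(rates = c(0, 0.5),
                                                  weights = c(0.5, 0.5)),
                            snp_missing_rate = 0, seed = 22)
  co2 <- simulate_cohort(cfg2)
  miss <- rowMeans(is.na(co2$genotypes$calls))
  expect_gt(sum(miss > 0.3), 0)  # high-dropout component present
  expect_gt(sum(miss < 0.05), 0)
})

test_that("config validation rejects out-of-domain parameters", {
  expect_error(simulation_config(admixture_m = 1.2))
  expect_error(simulation_config(generations_g = 0.5))
  expect_error(simulation_config(relative_risk = -1))
  expect_error(simulation_config(risk_locus = list(chrom = 30L, index = 1L)))
  expect_error(simulation_config(risk_locus = list(chrom = 1L, index = 99L)))
  map_bad <- data.frame(marker_id = c("a", "b"), chrom = 1L,
                        pos_bp = c(10L, 10L))
  expect_error(simulate_haploid_tracts(5, 0.2, 7, map_bad),
               "strictly increasing")
})
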