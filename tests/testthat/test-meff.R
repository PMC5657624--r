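test_that("ancestry correlation equals brute-force pairwise Pearson", {
  set.seed(3)
  X <- matrix(runif(50), 10, 5)
  cc <- ancestry_correlation(X)
  attr(cc, "n_dropped") <- NULL
  brute <- diag(5)
  for (i in 1:5) for (j in 1:5) brute[i, j] <- cor(X[, i], X[, j])
  expect_equal(unname(cc), brute, tolerance = 1e-12)

  dup <- cbind(X, X[, 2])
  expect_equal(unname(ancestry_correlation(dup)[2, 6]), 1)
  refl <- cbind(X, 1 - X[, 3])
  expect_equal(unname(ancestry_correlation(refl)[3, 6]), -1)
})

test_that("zero-variance loci are dropped and counted", {
  set.seed(4)
  X <- cbind(matrix(runif(40), 10, 4), 0.5)
  cc <- ancestry_correlation(X)
  expect_equal(ncol(cc), 4)
  expect_equal(attr(cc, "n_dropped"), 1)
  expect_error(ancestry_correlation(matrix(0.5, 10, 3)), "nonzero variance")
})

test_that("effective test count hits the analytic limits", {
  expect_equal(effective_tests_chromosome(diag(10)), 10)       # independent
  ones <- matrix(1, 10, 10)                                    # rank one
  expect_equal(effective_tests_chromosome(ones), 1, tolerance = 1e-8)
  r2 <- matrix(c(1, 0.5, 0.5, 1), 2)                           # lambda 1.5, 0.5
  expect_equal(effective_tests_chromosome(r2), 4 / 2.5)
  expect_error(effective_tests_chromosome(matrix(c(1, 0.2, 0.5, 1), 2)),
               "symmetric")
})

test_that("SVD spectrum matches direct eigendecomposition when N < n", {
  set.seed(9)
  X <- matrix(runif(30 * 80), 30, 80)  # rank-deficient correlation
  lam_svd <- admixscan:::ancestry_eigenvalues(X)$lambda
  lam_eig <- eigen(cor(X), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sort(lam_svd, decreasing = TRUE),
               sort(pmax(lam_eig, 0), decreasing = TRUE), tolerance = 1e-8)
  expect_equal(sum(lam_svd), 80, tolerance = 1e-6 * 80)  # trace = n
})

test_that("M_c is invariant to locus permutation, label swap and duplication", {
  Q <- random_Q(21, n = 25, L = 40, n_chrom = 1)
  m0 <- effective_tests_chromosome(ancestry_correlation(Q$q))
  expect_gte(m0, 1); expect_lte(m0, 40)

  perm <- Q$q[, sample(40)]
  expect_equal(effective_tests_chromosome(ancestry_correlation(perm)), m0)
  expect_equal(effective_tests_chromosome(ancestry_correlation(1 - Q$q)), m0)
  # duplicating every column: checked against an independent eigen recompute
  dup <- cbind(Q$q, Q$q)
  m_dup <- effective_tests_chromosome(ancestry_correlation(dup))
  lam <- eigen(cor(dup), symmetric = TRUE, only.values = TRUE)$values
  lam <- pmax(lam, 0)
  expect_equal(m_dup, sum(lam)^2 / sum(lam^2), tolerance = 1e-8)
  expect_equal(m_dup, m0, tolerance = 1e-6)
})

test_that("genome-wide count sums per-chromosome counts", {
  Q <- random_Q(31, n = 20, L = 40, n_chrom = 2)
  res <- effective_tests_genome(Q)
  expect_equal(nrow(res$per_chrom), 2)
  expect_equal(res$m_total, sum(res$per_chrom$m_eff))

  # two chromosomes with identical q blocks double the total
  q2 <- cbind(Q$q[, 1:20], Q$q[, 1:20])
  map2 <- make_marker_map(c(20L, 20L))
  res2 <- effective_tests_genome(ancestry_matrix(q2, map2))
  expect_equal(res2$per_chrom$m_eff[1], res2$per_chrom$m_eff[2])
  expect_equal(res2$m_total, 2 * res2$per_chrom$m_eff[1])

  # single chromosome: total equals the chromosome count
  Q1 <- random_Q(32, n = 20, L = 30, n_chrom = 1)
  res1 <- effective_tests_genome(Q1)
  expect_equal(res1$m_total, res1$per_chrom$m_eff[1])
  expect_equal(res1$m_total,
               effective_tests_chromosome(ancestry_correlation(Q1$q)),
               tolerance = 1e-8)
})

test_that("simulated cohorts give M_eff matching an independent recompute", {
  co <- simulate_cohort(simulation_config(
    n_cases = 100, markers_per_chrom = c(200L, 200L), genotypes = FALSE,
    seed = 17))
  res <- effective_tests_genome(co$ancestry)
  # independent path: direct eigendecomposition per chromosome
  m_ind <- 0
  for (ch in 1:2) {
    q <- co$ancestry$q[, co$ancestry$map$chrom == ch]
    q <- q[, apply(q, 2, sd) > 0, drop = FALSE]
    lam <- pmax(eigen(cor(q), symmetric = TRUE, only.values = TRUE)$values, 0)
    m_ind <- m_ind + sum(lam)^2 / sum(lam^2)
  }
  expect_equal(res$m_total, m_ind, tolerance = 1e-6)
  expect_true(all(res$per_chrom$m_eff >= 1 &
                    res$per_chrom$m_eff <= res$per_chrom$n_loci))
})

test_that("Li-Ji alternative estimator is available and sane", {
  expect_equal(effective_tests_chromosome(diag(8), method = "liji"), 8)
  ones <- matrix(1, 8, 8)
  expect_equal(effective_tests_chromosome(ones, method = "liji"), 1,
               tolerance = 1e-8)
  Q <- random_Q(41, n = 30, L = 20, n_chrom = 1)
  m_li <- effective_tests_genome(Q, method = "liji")$m_total
  expect_gte(m_li, 1); expect_lte(m_li, 20)
})

test_that("threshold arithmetic follows alpha / M", {
  t1 <- genomewide_threshold(1)
  expect_equal(t1$p_threshold, 0.05)
  expect_error(genomewide_threshold(0.8), "m_total")
  tq <- genomewide_threshold(200, alpha = 0.01)
  expect_equal(tq$p_threshold, 5e-5)
  expect_equal(tq$neglog10, -log10(5e-5))
  # accepts an effective_tests object directly
  Q <- random_Q(51, n = 10, L = 20)
  et <- effective_tests_genome(Q)
  expect_equal(genomewide_threshold(et)$m_total, et$m_total)
})
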