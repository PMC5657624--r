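# Independent brute-force oracles and fixture builders used across tests.
# These deliberately use plain loops / first-principles formulas, not the
# package's own code paths.

# genotype matrix with injected missingness and outlier samples
random_geno <- function(seed, n = 50, L = 200, p_miss = 0.03,
                        n_bad_samples = 2, n_bad_snps = 5,
                        n_outlier_het = 1) {
  set.seed(seed)
  p <- runif(L, 0.05, 0.95)
  calls <- sapply(p, function(pp) rbinom(n, 2, pp))
  calls[matrix(runif(n * L) < p_miss, n, L)] <- NA_integer_
  if (n_bad_samples > 0)  # heavy per-sample dropout
    for (i in seq_len(n_bad_samples))
      calls[i, runif(L) < 0.4] <- NA_integer_
  if (n_bad_snps > 0)     # heavy per-SNP dropout
    for (j in seq_len(n_bad_snps))
      calls[runif(n) < 0.4, L - j + 1] <- NA_integer_
  if (n_outlier_het > 0)  # near-zero heterozygosity sample
    for (i in seq_len(n_outlier_het)) {
      row <- calls[n_bad_samples + i, ]
      row[!is.na(row) & row == 1L] <- 0L
      calls[n_bad_samples + i, ] <- row
    }
  map <- data.frame(marker_id = sprintf("s%04d", seq_len(L)),
                    chrom = 1L, pos_bp = seq_len(L) * 1000L)
  genotype_matrix(calls, map)
}

random_panel <- function(G, seed = 1) {
  set.seed(seed)
  L <- ncol(G$calls)
  data.frame(marker_id = G$map$marker_id,
             freqCEU = runif(L), freqYRI = runif(L),
             stringsAsFactors = FALSE)
}

# brute-force removal sets, plain loops over the raw matrix
oracle_sample_call_rate <- function(calls, min_rate) {
  bad <- character()
  for (i in seq_len(nrow(calls))) {
    cr <- sum(!is.na(calls[i, ])) / ncol(calls)
    if (!(cr > min_rate)) bad <- c(bad, rownames(calls)[i])
  }
  bad
}

oracle_het <- function(calls, k_sd) {
  het <- rep(NA_real_, nrow(calls))
  for (i in seq_len(nrow(calls))) {
    x <- calls[i, ]
    x <- x[!is.na(x)]
    if (length(x) > 0) het[i] <- sum(x == 1) / length(x)
  }
  mu <- mean(het, na.rm = TRUE)
  sdv <- sd(het, na.rm = TRUE)
  bad <- character()
  for (i in seq_len(nrow(calls))) {
    if (is.na(het[i]) || het[i] < mu - k_sd * sdv || het[i] > mu + k_sd * sdv)
      bad <- c(bad, rownames(calls)[i])
  }
  bad
}

oracle_snp_call_rate <- function(calls, ids, min_rate) {
  bad <- character()
  for (j in seq_len(ncol(calls))) {
    cr <- sum(!is.na(calls[, j])) / nrow(calls)
    if (!(cr > min_rate)) bad <- c(bad, ids[j])
  }
  bad
}

oracle_mono_unmatched <- function(calls, ids, panel_ids) {
  bad <- character()
  for (j in seq_len(ncol(calls))) {
    x <- calls[, j]
    x <- x[!is.na(x)]
    if (!(ids[j] %in% panel_ids) || length(unique(x)) <= 1)
      bad <- c(bad, ids[j])
  }
  bad
}

oracle_freq_concordance <- function(calls, ids, panel, w_eur, max_diff) {
  bad <- character()
  for (j in seq_len(ncol(calls))) {
    x <- calls[, j]
    x <- x[!is.na(x)]
    k <- match(ids[j], panel$marker_id)
    if (length(x) == 0) { bad <- c(bad, ids[j]); next }
    obs <- sum(x) / (2 * length(x))
    expd <- (1 - w_eur) * panel$freqYRI[k] + w_eur * panel$freqCEU[k]
    if (abs(obs - expd) > max_diff) bad <- c(bad, ids[j])
  }
  bad
}

# closed-form case ancestry under the multiplicative model (independent of
# the package's binomial-sum implementation)
closed_form_case_ancestry <- function(m, r) m * r / (1 - m + m * r)

# build a minimal ancestry_scan object from raw per-locus values
toy_scan <- function(chrom, pos_bp, z, delta_pi = z * 0.01) {
  out <- data.frame(
    marker_id = sprintf("t%03d", seq_along(z)),
    chrom = chrom, pos_bp = pos_bp, delta_pi = delta_pi, z = z,
    p_right = pnorm(z, lower.tail = FALSE), p_left = pnorm(z),
    neglog10_p_right = -pnorm(z, lower.tail = FALSE, log.p = TRUE) / log(10),
    neglog10_p_left = -pnorm(z, log.p = TRUE) / log(10),
    stringsAsFactors = FALSE)
  attr(out, "pooled_sd") <- 0.01
  class(out) <- c("ancestry_scan", "data.frame")
  out
}

random_Q <- function(seed, n = 12, L = 30, n_chrom = 2) {
  set.seed(seed)
  map <- make_marker_map(rep(L / n_chrom, n_chrom))
  ancestry_matrix(matrix(runif(n * L), n, L), map)
}
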