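#' Locus-locus correlation of local ancestry on one chromosome
#'
#' Pearson correlation across samples between locus columns of the ancestry
#' matrix. Zero-variance columns carry no test and are dropped (their count
#' is recorded in the `n_dropped` attribute).
#'
#' @param q_chrom numeric matrix, samples x loci, restricted to one
#'   chromosome (or an [ancestry_matrix()], in which case all its loci are
#'   used).
#' @return correlation matrix with attribute `n_dropped`.
#' @export
ancestry_correlation <- function(q_chrom) {
  if (inherits(q_chrom, "ancestry_matrix")) q_chrom <- q_chrom$q
  v <- apply(q_chrom, 2, stats::var)
  keep <- which(v > 0)
  if (length(keep) < 2) stop("fewer than 2 loci with nonzero variance")
  cc <- stats::cor(q_chrom[, keep, drop = FALSE])
  attr(cc, "n_dropped") <- ncol(q_chrom) - length(keep)
  cc
}

participation_ratio <- function(lambda) sum(lambda)^2 / sum(lambda^2)

li_ji <- function(lambda) {
  # Li & Ji (2005)-style estimator: each eigenvalue contributes its integer
  # part capped at 1 plus its fractional part.
  sum(ifelse(lambda >= 1, 1, 0) + (lambda - floor(lambda)))
}

check_eigenvalues <- function(lambda, n) {
  if (any(lambda < -1e-8 * max(n, 1)))
    stop("correlation matrix has substantially negative eigenvalues")
  pmax(lambda, 0)
}

#' Effective number of independent tests for one chromosome
#'
#' From the eigenvalues lambda_1..lambda_n of the local-ancestry correlation
#' matrix, the effective test count is the participation ratio
#' M_c = (sum lambda)^2 / sum lambda^2 (default), which equals n for
#' independent loci and 1 for perfectly correlated loci. A Li-Ji-style
#' estimator is available for sensitivity analysis. Small negative
#' eigenvalues from floating-point are clipped to zero.
#'
#' @param corr symmetric correlation matrix (unit diagonal).
#' @param method `"pr"` (participation ratio) or `"liji"`.
#' @return scalar M_c in \[1, n\].
#' @export
effective_tests_chromosome <- function(corr, method = c("pr", "liji")) {
  method <- match.arg(method)
  if (!isSymmetric(unname(corr), tol = 1e-8)) stop("correlation matrix must be symmetric")
  lambda <- eigen(corr, symmetric = TRUE, only.values = TRUE)$values
  lambda <- check_eigenvalues(lambda, nrow(corr))
  switch(method, pr = participation_ratio(lambda), liji = li_ji(lambda))
}

## Eigenvalues of cor(X) via the SVD of the standardized data matrix:
## numerically stable in the rank-deficient N < n regime and identical (to
## ~1e-8) to direct eigendecomposition.
ancestry_eigenvalues <- function(q_chrom) {
  v <- apply(q_chrom, 2, stats::var)
  keep <- which(v > 0)
  if (length(keep) < 2) stop("fewer than 2 loci with nonzero variance")
  X <- scale(q_chrom[, keep, drop = FALSE])
  d <- svd(X, nu = 0, nv = 0)$d
  lambda <- numeric(length(keep))
  lambda[seq_along(d)] <- d^2 / (nrow(X) - 1)
  list(lambda = lambda, n = length(keep),
       n_dropped = ncol(q_chrom) - length(keep))
}

#' Genome-wide effective number of independent tests
#'
#' Computes the eigenvalue spectrum of the local-ancestry correlation matrix
#' per chromosome, converts each to an effective test count, and sums over
#' chromosomes: M_total = sum_c M_c.
#'
#' @param Q an [ancestry_matrix()].
#' @param method effective-test estimator, see
#'   [effective_tests_chromosome()].
#' @return object of class `effective_tests`: list with `per_chrom`
#'   (data.frame: `chrom`, `n_loci`, `n_dropped`, `m_eff`), `eigenvalues`
#'   (list per chromosome), `m_total`, `method`.
#' @export
effective_tests_genome <- function(Q, method = c("pr", "liji")) {
  stopifnot(inherits(Q, "ancestry_matrix"))
  method <- match.arg(method)
  chroms <- unique(Q$map$chrom)
  rows <- list()
  eigs <- list()
  for (ch in chroms) {
    res <- ancestry_eigenvalues(Q$q[, Q$map$chrom == ch, drop = FALSE])
    lambda <- check_eigenvalues(res$lambda, res$n)
    m_c <- switch(method, pr = participation_ratio(lambda), liji = li_ji(lambda))
    rows[[as.character(ch)]] <- data.frame(chrom = ch, n_loci = res$n,
                                           n_dropped = res$n_dropped,
                                           m_eff = m_c)
    eigs[[as.character(ch)]] <- lambda
  }
  per_chrom <- do.call(rbind, unname(rows))
  structure(list(per_chrom = per_chrom, eigenvalues = eigs,
                 m_total = sum(per_chrom$m_eff), method = method),
            class = "effective_tests")
}

#' @export
print.effective_tests <- function(x, ...) {
  cat(sprintf("effective_tests (%s): M_total = %.1f over %d chromosome(s), %d loci\n",
              x$method, x$m_total, nrow(x$per_chrom), sum(x$per_chrom$n_loci)))
  invisible(x)
}

#' Genome-wide significance threshold from the effective test count
#'
#' Bonferroni-style family-wise threshold p = alpha / M_total, applied
#' per ancestry tail. Summaries report the threshold to 3 significant
#' figures and its -log10 to 2 decimals.
#'
#' @param m_total effective number of independent tests (>= 1), e.g.
#'   `effective_tests_genome(Q)$m_total`.
#' @param alpha family-wise error level (default 0.05).
#' @return object of class `significance_threshold`: list with `alpha`,
#'   `m_total`, `p_threshold`, `neglog10`, and the rounded summary fields
#'   `p_threshold_3sig`, `neglog10_2dp`.
#' @export
genomewide_threshold <- function(m_total, alpha = 0.05) {
  if (inherits(m_total, "effective_tests")) m_total <- m_total$m_total
  if (!(m_total >= 1)) stop("m_total must be >= 1")
  stopifnot(alpha > 0, alpha < 1)
  p <- alpha / m_total
  structure(list(alpha = alpha, m_total = m_total, p_threshold = p,
                 neglog10 = -log10(p),
                 p_threshold_3sig = signif(p, 3),
                 neglog10_2dp = round(-log10(p), 2)),
            class = "significance_threshold")
}

#' @export
print.significance_threshold <- function(x, ...) {
  cat(sprintf(
    "significance_threshold: alpha = %g, M = %.1f -> p = %.3g (-log10 = %.2f)\n",
    x$alpha, x$m_total, x$p_threshold_3sig, x$neglog10_2dp))
  invisible(x)
}
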