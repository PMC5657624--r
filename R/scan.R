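#' Global ancestry per individual
#'
#' M_i = mean over all L loci of the individual's local European ancestry
#' q_il: the genome-wide European ancestry proportion.
#'
#' @param Q an [ancestry_matrix()].
#' @return named numeric vector of length N.
#' @export
global_ancestry <- function(Q) {
  stopifnot(inherits(Q, "ancestry_matrix"))
  if (ncol(Q$q) < 1) stop("ancestry matrix has no loci")
  rowMeans(Q$q)
}

#' Per-locus excess European ancestry
#'
#' The case-only scan statistic's numerator:
#' Delta_Pi_l = (1/N) sum_i (q_il - M_i), the case-average deviation of
#' local ancestry at locus l from each case's global ancestry. By
#' construction the vector sums to zero over loci.
#'
#' @param Q an [ancestry_matrix()].
#' @return named numeric vector of length L.
#' @export
excess_ancestry <- function(Q) {
  stopifnot(inherits(Q, "ancestry_matrix"))
  if (ncol(Q$q) < 2) stop("need at least 2 loci for mean-centering")
  colMeans(Q$q) - mean(rowMeans(Q$q))
}

#' Pooled standard deviation of the excess-ancestry vector
#'
#' The common SD used to standardize every locus: the root-mean-square of
#' Delta_Pi_l about its across-locus mean (structurally zero), with
#' denominator L (population form). Fixed so results are exactly
#' reproducible; at genome scale the denominator choice is immaterial.
#'
#' @param delta_pi numeric vector of per-locus excess ancestry.
#' @return positive scalar.
#' @export
pooled_sd <- function(delta_pi) {
  if (length(delta_pi) < 2) stop("need at least 2 loci")
  s <- sqrt(mean((delta_pi - mean(delta_pi))^2))
  if (s == 0) stop("degenerate excess-ancestry vector (all values identical)")
  s
}

#' Case-only excess-ancestry Z scan
#'
#' Standardizes each locus's excess ancestry by the pooled SD,
#' Z_l = Delta_Pi_l / SD(Delta_Pi), and reports one-sided normal p-values in
#' both ancestry directions: `p_right` = 1 - Phi(Z_l) tests excess European
#' ancestry, `p_left` = Phi(Z_l) tests excess African ancestry. Both tails
#' are always computed. The normal approximation rests on large N x L; no
#' small-sample correction is applied.
#'
#' @param Q an [ancestry_matrix()].
#' @return object of class `ancestry_scan`: a data.frame with one row per
#'   locus (`marker_id`, `chrom`, `pos_bp`, `delta_pi`, `z`, `p_right`,
#'   `p_left`, `neglog10_p_right`, `neglog10_p_left`) and attribute
#'   `pooled_sd`.
#' @export
z_scan <- function(Q) {
  stopifnot(inherits(Q, "ancestry_matrix"))
  dp <- excess_ancestry(Q)
  s <- pooled_sd(dp)
  z <- dp / s
  p_right <- stats::pnorm(z, lower.tail = FALSE)
  p_left <- stats::pnorm(z)
  out <- data.frame(
    marker_id = Q$map$marker_id,
    chrom = Q$map$chrom,
    pos_bp = Q$map$pos_bp,
    delta_pi = unname(dp),
    z = unname(z),
    p_right = unname(p_right),
    p_left = unname(p_left),
    neglog10_p_right = -stats::pnorm(z, lower.tail = FALSE, log.p = TRUE) / log(10),
    neglog10_p_left = -stats::pnorm(z, log.p = TRUE) / log(10),
    stringsAsFactors = FALSE
  )
  attr(out, "pooled_sd") <- s
  class(out) <- c("ancestry_scan", "data.frame")
  out
}

#' @export
print.ancestry_scan <- function(x, ...) {
  cat(sprintf("ancestry_scan: %d loci on %d chromosome(s), pooled SD = %.5f\n",
              nrow(x), length(unique(x$chrom)), attr(x, "pooled_sd")))
  top <- x[which.max(x$z), ]
  cat(sprintf("  max European excess: %s (chr%d:%d), delta = %.4f, -log10 p = %.2f\n",
              top$marker_id, top$chrom, top$pos_bp, top$delta_pi,
              top$neglog10_p_right))
  invisible(x)
}
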