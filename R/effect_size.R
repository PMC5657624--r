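#' Expected case local ancestry at a risk locus
#'
#' Under case-only ascertainment, an individual carries j ~ Binomial(2, m)
#' European haplotypes at the locus and is a case with probability
#' proportional to risk(j), where risk(j) = r^j (multiplicative) or
#' 1 + j(r - 1) (additive). The expected diploid European ancestry among
#' cases is then
#' E\[j/2 | case\] = sum_j (j/2) P(j) risk(j) / sum_j P(j) risk(j).
#' The multiplicative model has the closed form m r / (1 - m + m r).
#'
#' @param m baseline European ancestry proportion per haplotype, in (0, 1).
#' @param r relative risk per European haplotype (> 0; the additive model
#'   additionally requires 1 + 2(r - 1) > 0, i.e. r > 1/2).
#' @param model `"multiplicative"` or `"additive"`.
#' @return expected case ancestry in (0, 1).
#' @export
expected_case_ancestry <- function(m, r, model = c("multiplicative", "additive")) {
  model <- match.arg(model)
  stopifnot(m > 0, m < 1, r > 0)
  w <- risk_weights(r, model)
  pj <- stats::dbinom(0:2, 2, m)
  sum((0:2) / 2 * pj * w) / sum(pj * w)
}

#' Estimate the ancestry relative risk from an observed excess
#'
#' Inverts [expected_case_ancestry()]: finds the unique r with expected case
#' ancestry m + delta. Expected ancestry is strictly increasing in r for
#' m in (0, 1) (both models), so the root is unique; it is found by
#' root-bracketing over r in \[1e-6, 1e6\] to residual < 1e-10.
#'
#' @param delta observed excess ancestry (case minus baseline); must satisfy
#'   m + delta in (0, 1) and lie in the model's attainable range (limits as
#'   r -> 0 and r -> infinity).
#' @param m baseline European ancestry proportion, in (0, 1). Explicit by
#'   design: reported risks are sensitive to it.
#' @param model `"multiplicative"` or `"additive"`.
#' @return the relative risk r.
#' @export
estimate_rr <- function(delta, m, model = c("multiplicative", "additive")) {
  model <- match.arg(model)
  stopifnot(m > 0, m < 1)
  target <- m + delta
  if (!(target > 0 && target < 1))
    stop("m + delta must lie in (0, 1)")
  r_lo <- if (model == "additive") 0.5 + 1e-9 else 1e-6
  r_hi <- 1e6
  f <- function(r) expected_case_ancestry(m, r, model) - target
  f_lo <- f(r_lo)
  f_hi <- f(r_hi)
  if (f_lo > 0 || f_hi < 0) {
    stop(sprintf(
      "delta = %g outside the attainable range for m = %g (%s model): expected ancestry spans (%.6g, %.6g)",
      delta, m, model, m + f_lo, m + f_hi))
  }
  if (delta == 0) return(1)
  stats::uniroot(f, lower = r_lo, upper = r_hi, tol = 1e-12,
                 f.lower = f_lo, f.upper = f_hi)$root
}

#' Attainable excess-ancestry range of a risk model
#'
#' The interval of excess values delta = E\[q | case\] - m reachable as r
#' ranges over (0, infinity) (additive: (1/2, infinity)).
#'
#' @inheritParams expected_case_ancestry
#' @return numeric length-2 vector (lower, upper), open interval.
#' @export
attainable_excess_range <- function(m, model = c("multiplicative", "additive")) {
  model <- match.arg(model)
  stopifnot(m > 0, m < 1)
  r_lo <- if (model == "additive") 0.5 + 1e-9 else 1e-9
  c(expected_case_ancestry(m, r_lo, model) - m,
    expected_case_ancestry(m, 1e9, model) - m)
}
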