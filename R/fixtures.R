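#' Deterministic null cohort fixture
#'
#' A small admixed case cohort with no risk locus: 28 cases, 22 chromosomes
#' of 50 markers, European admixture fraction 0.27, 7 generations since
#' admixture. Byte-stable for a fixed seed. Used by the test suite as the
#' stand-in for a real cohort's local-ancestry and genotype data.
#'
#' @param seed RNG seed.
#' @param genotypes also simulate genotypes and a reference panel.
#' @return list with `ancestry`, `genotypes`, `panel`, `config` (see
#'   [simulate_cohort()]).
#' @export
make_null_fixture <- function(seed = 1L, genotypes = TRUE) {
  simulate_cohort(simulation_config(
    n_cases = 28, markers_per_chrom = rep(50L, 22), admixture_m = 0.27,
    generations_g = 7, relative_risk = 1, seed = seed,
    genotypes = genotypes))
}

#' Deterministic signal cohort fixture
#'
#' An ascertained case cohort with one designated risk locus
#' (chromosome 1, middle marker) under the multiplicative risk model, so
#' that the expected excess ancestry at the locus equals
#' `expected_case_ancestry(m, r) - m` by construction. Ancestry only (no
#' genotypes), noise-free. The default map is genome-wide (22 chromosomes)
#' so the single-locus signal perturbs each case's global ancestry only
#' negligibly; on short maps the global-ancestry centering visibly shrinks
#' the observed excess.
#'
#' @param seed RNG seed.
#' @param r relative risk per European haplotype.
#' @param m European admixture fraction.
#' @param n_cases cohort size.
#' @param markers_per_chrom marker counts (default 22 chromosomes of 100).
#' @return list as from [simulate_cohort()], plus `risk_col`, the risk
#'   locus's column index in the ancestry matrix.
#' @export
make_signal_fixture <- function(seed = 1L, r = 2.8, m = 0.2, n_cases = 500,
                                markers_per_chrom = rep(100L, 22)) {
  rl <- list(chrom = 1L, index = as.integer(ceiling(markers_per_chrom[1] / 2)))
  cohort <- simulate_cohort(simulation_config(
    n_cases = n_cases, markers_per_chrom = markers_per_chrom,
    admixture_m = m, generations_g = 7, risk_locus = rl, relative_risk = r,
    risk_model = "multiplicative", seed = seed, genotypes = FALSE))
  cohort$risk_col <- which(cohort$ancestry$map$chrom == rl$chrom)[rl$index]
  cohort
}
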