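#' Simulation configuration for an admixed case cohort
#'
#' Collects every knob of the generative model: a single-pulse
#' (hybrid-isolation) admixture event `g` generations ago with European
#' mixture fraction `m`, Balding-Nichols reference-panel divergence, optional
#' case ascertainment at one risk locus, and the observation-noise /
#' missingness layers that emulate degraded (FFPE-derived) genotyping.
#'
#' @param n_cases number of ascertained cases to generate.
#' @param markers_per_chrom integer vector of marker counts per chromosome
#'   (default 22 chromosomes of 50 markers).
#' @param marker_spacing_cM map distance between adjacent markers (cM).
#' @param admixture_m European admixture fraction in \[0, 1\].
#' @param generations_g generations since the admixture pulse (>= 1);
#'   ancestry switch intensity is `g` per Morgan.
#' @param risk_locus `NULL`, or `list(chrom =, index =)` giving the marker
#'   (1-based index within its chromosome) where disease risk depends on
#'   local ancestry.
#' @param relative_risk per-European-haplotype relative risk r (>= 0).
#' @param risk_model `"additive"` (risk(j) = 1 + j(r-1)) or
#'   `"multiplicative"` (risk(j) = r^j), j = number of European haplotypes.
#' @param fst_panel Fst between the two reference panels and their common
#'   ancestral population (Balding-Nichols).
#' @param ancestry_noise_kappa concentration of Beta observation noise on q
#'   (`Inf` = no noise, q exactly in \{0, 1/2, 1\}).
#' @param sample_missing list with `rates` and `weights`: mixture over
#'   per-sample genotype missingness rates (a small high-missingness
#'   component emulates FFPE dropout samples).
#' @param snp_missing_rate baseline per-call missingness.
#' @param genotype_error_rate per-allele symmetric flip probability.
#' @param seed RNG seed recorded in the config and used for all draws.
#' @param genotypes logical; simulate genotypes + panel (TRUE) or local
#'   ancestry only.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(n_cases = 100,
                              markers_per_chrom = rep(50L, 22),
                              marker_spacing_cM = 0.5,
                              admixture_m = 0.2,
                              generations_g = 7,
                              risk_locus = NULL,
                              relative_risk = 1,
                              risk_model = c("multiplicative", "additive"),
                              fst_panel = 0.15,
                              ancestry_noise_kappa = Inf,
                              sample_missing = list(rates = c(0.01, 0.30),
                                                    weights = c(0.8, 0.2)),
                              snp_missing_rate = 0.005,
                              genotype_error_rate = 0.001,
                              seed = 1L,
                              genotypes = TRUE) {
  risk_model <- match.arg(risk_model)
  stopifnot(n_cases >= 1,
            admixture_m >= 0, admixture_m <= 1,
            generations_g >= 1,
            relative_risk >= 0,
            fst_panel > 0, fst_panel < 1,
            snp_missing_rate >= 0, snp_missing_rate <= 1,
            genotype_error_rate >= 0, genotype_error_rate <= 1,
            all(sample_missing$rates >= 0), all(sample_missing$rates <= 1),
            length(sample_missing$rates) == length(sample_missing$weights))
  if (!is.null(risk_locus)) {
    stopifnot(is.list(risk_locus),
              risk_locus$chrom %in% seq_along(markers_per_chrom),
              risk_locus$index >= 1,
              risk_locus$index <= markers_per_chrom[risk_locus$chrom])
  }
  structure(list(n_cases = as.integer(n_cases),
                 markers_per_chrom = as.integer(markers_per_chrom),
                 marker_spacing_cM = marker_spacing_cM,
                 admixture_m = admixture_m,
                 generations_g = generations_g,
                 risk_locus = risk_locus,
                 relative_risk = relative_risk,
                 risk_model = risk_model,
                 fst_panel = fst_panel,
                 ancestry_noise_kappa = ancestry_noise_kappa,
                 sample_missing = sample_missing,
                 snp_missing_rate = snp_missing_rate,
                 genotype_error_rate = genotype_error_rate,
                 seed = as.integer(seed),
                 genotypes = isTRUE(genotypes)),
            class = "simulation_config")
}

#' Simulate haploid ancestry tracts
#'
#' Single-pulse admixture: along each chromosome, haplotype ancestry follows
#' a two-state Markov chain with stationary distribution (m, 1-m) for
#' (European, African) and total switch intensity g per Morgan. Between
#' adjacent markers at map distance d Morgans,
#' P(EUR -> AFR) = (1-m)(1 - exp(-g d)) and P(AFR -> EUR) = m(1 - exp(-g d));
#' each chromosome starts from the stationary Bernoulli(m). Uses the current
#' R RNG state.
#'
#' @param n_hap number of haplotypes.
#' @param m European admixture fraction.
#' @param g generations since admixture (switch intensity per Morgan).
#' @param map marker map with genetic positions (`pos_cM`; defaults to
#'   1 cM/Mb from `pos_bp` if absent).
#' @return integer matrix `n_hap` x L, 1 = European, 0 = African.
#' @export
simulate_haploid_tracts <- function(n_hap, m, g, map) {
  stopifnot(m >= 0, m <= 1, g >= 1, n_hap >= 1)
  map <- validate_marker_map(map)
  L <- nrow(map)
  anc <- matrix(0L, nrow = n_hap, ncol = L,
                dimnames = list(NULL, map$marker_id))
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    state <- as.integer(stats::runif(n_hap) < m)
    anc[, idx[1]] <- state
    if (length(idx) > 1) {
      d <- diff(map$pos_cM[idx]) / 100            # Morgans
      p_any <- 1 - exp(-g * d)                    # switch opportunity
      for (k in seq_along(d)) {
        thr <- ifelse(state == 1L, (1 - m) * p_any[k], m * p_any[k])
        flip <- stats::runif(n_hap) < thr
        state <- ifelse(flip, 1L - state, state)
        anc[, idx[k + 1]] <- state
      }
    }
  }
  anc
}

#' Simulate reference-panel allele frequencies
#'
#' Balding-Nichols model of panel divergence: for each marker an ancestral
#' frequency p ~ Uniform(0.05, 0.95), then each panel's frequency is an
#' independent draw from Beta(p(1-F)/F, (1-p)(1-F)/F), whose mean is p and
#' variance p(1-p)F.
#'
#' @param n_markers number of markers.
#' @param fst divergence parameter F in (0, 1).
#' @param marker_id optional marker IDs (default `snp1..n`).
#' @return data.frame with columns `marker_id`, `freqCEU`, `freqYRI`,
#'   `ancestral`.
#' @export
simulate_panel_freqs <- function(n_markers, fst = 0.15, marker_id = NULL) {
  if (!(fst > 0 && fst < 1)) stop("fst must be in (0, 1)")
  p <- stats::runif(n_markers, 0.05, 0.95)
  a <- p * (1 - fst) / fst
  b <- (1 - p) * (1 - fst) / fst
  data.frame(
    marker_id = marker_id %||% sprintf("snp%d", seq_len(n_markers)),
    freqCEU = stats::rbeta(n_markers, a, b),
    freqYRI = stats::rbeta(n_markers, a, b),
    ancestral = p,
    stringsAsFactors = FALSE
  )
}

risk_weights <- function(r, model) {
  j <- 0:2
  w <- switch(model,
              multiplicative = r^j,
              additive = 1 + j * (r - 1))
  if (any(w < 0))
    stop("risk model yields negative risk weights (additive requires r > 1/2)")
  w
}

#' Simulate an ascertained admixed case cohort
#'
#' Pairs two haploid ancestry tracts per individual. If a risk locus is
#' configured, candidates are retained as cases by rejection sampling with
#' probability risk(j) / max_j risk(j), where j is the candidate's count of
#' European haplotypes at the risk locus; generation repeats until `n_cases`
#' are retained, so ascertainment enriches European ancestry at (and, through
#' tract structure, around) the risk locus. Local ancestry is
#' q = (European haplotypes)/2, optionally blurred by mean-preserving Beta
#' noise. Genotypes are drawn per haplotype from the panel frequency of that
#' haplotype's ancestry, then per-allele flip errors and per-sample/per-call
#' missingness are applied.
#'
#' @param config a [simulation_config()].
#' @return list with elements `ancestry` ([ancestry_matrix]), `genotypes`
#'   ([genotype_matrix] or NULL), `panel` (panel frequency data.frame or
#'   NULL), `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  map <- make_marker_map(config$markers_per_chrom, config$marker_spacing_cM)
  L <- nrow(map)
  m <- config$admixture_m
  g <- config$generations_g
  n <- config$n_cases

  risk_col <- NULL
  accept_p <- NULL
  if (!is.null(config$risk_locus) && config$relative_risk != 1) {
    rl <- config$risk_locus
    risk_col <- which(map$chrom == rl$chrom)[rl$index]
    w <- risk_weights(config$relative_risk, config$risk_model)
    accept_p <- w / max(w)
  }

  hap1 <- hap2 <- matrix(0L, nrow = n, ncol = L)
  got <- 0L
  while (got < n) {
    batch <- max(n - got, 256L)
    if (!is.null(accept_p)) batch <- ceiling(batch / max(mean(accept_p), 0.05))
    batch <- min(batch, max(256L, floor(2e7 / L)))  # bound per-batch memory
    h1 <- simulate_haploid_tracts(batch, m, g, map)
    h2 <- simulate_haploid_tracts(batch, m, g, map)
    if (is.null(accept_p)) {
      keep <- seq_len(batch)
    } else {
      j <- h1[, risk_col] + h2[, risk_col]
      keep <- which(stats::runif(batch) < accept_p[j + 1L])
    }
    if (length(keep) == 0) next
    take <- keep[seq_len(min(length(keep), n - got))]
    rows <- got + seq_along(take)
    hap1[rows, ] <- h1[take, , drop = FALSE]
    hap2[rows, ] <- h2[take, , drop = FALSE]
    got <- got + length(take)
  }

  q <- (hap1 + hap2) / 2
  kappa <- config$ancestry_noise_kappa
  if (is.finite(kappa)) {
    interior <- q > 0 & q < 1
    qn <- q
    qn[interior] <- stats::rbeta(sum(interior),
                                 kappa * q[interior],
                                 kappa * (1 - q[interior]))
    q <- pmin(pmax(qn, 0), 1)
  }
  rownames(q) <- sprintf("case%04d", seq_len(n))
  anc <- ancestry_matrix(q, map)

  geno <- NULL
  panel <- NULL
  if (config$genotypes) {
    panel <- simulate_panel_freqs(L, config$fst_panel, marker_id = map$marker_id)
    pmat_ceu <- matrix(panel$freqCEU, nrow = n, ncol = L, byrow = TRUE)
    pmat_yri <- matrix(panel$freqYRI, nrow = n, ncol = L, byrow = TRUE)
    a1 <- matrix(stats::rbinom(n * L, 1, ifelse(hap1 == 1L, pmat_ceu, pmat_yri)),
                 nrow = n)
    a2 <- matrix(stats::rbinom(n * L, 1, ifelse(hap2 == 1L, pmat_ceu, pmat_yri)),
                 nrow = n)
    e <- config$genotype_error_rate
    if (e > 0) {
      f1 <- matrix(stats::runif(n * L) < e, nrow = n)
      f2 <- matrix(stats::runif(n * L) < e, nrow = n)
      a1 <- ifelse(f1, 1L - a1, a1)
      a2 <- ifelse(f2, 1L - a2, a2)
    }
    calls <- a1 + a2
    comp <- sample.int(length(config$sample_missing$rates), n, replace = TRUE,
                       prob = config$sample_missing$weights)
    rate_i <- config$sample_missing$rates[comp]
    p_miss <- outer(rate_i, rep(1, L)) +
      config$snp_missing_rate * (1 - outer(rate_i, rep(1, L)))
    calls[matrix(stats::runif(n * L), nrow = n) < p_miss] <- NA_integer_
    rownames(calls) <- rownames(q)
    geno <- genotype_matrix(calls, map)
  }

  list(ancestry = anc, genotypes = geno, panel = panel, config = config)
}
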