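#' Pipeline configuration
#'
#' Validates the full set of run parameters and rejects unknown keys.
#' Either `ancestry_path` (real-data mode) or `sim` (a
#' [simulation_config()]) must be given; genotype/panel inputs switch the
#' QC stage on.
#'
#' @param ancestry_path local-ancestry TSV (see [read_ancestry_tsv()]), or
#'   NULL to simulate.
#' @param sim a [simulation_config()] used when `ancestry_path` is NULL.
#' @param genotype_path optional genotype VCF / dosage TSV for QC.
#' @param panel_path optional panel frequency TSV (required for QC).
#' @param out_dir output directory (created if needed).
#' @param alpha family-wise significance level.
#' @param region_cutoff_neglog10 region-calling cutoff; the string
#'   `"genomewide"` uses the computed genome-wide threshold.
#' @param min_markers,merge_gap_bp region-calling parameters.
#' @param qc named list of QC thresholds passed to [qc_pipeline()]
#'   (defaults used for entries not given).
#' @param meff_method effective-test estimator (`"pr"` or `"liji"`).
#' @param seed seed recorded in the manifest (the simulation uses its own
#'   config seed).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(ancestry_path = NULL, sim = NULL,
                            genotype_path = NULL, panel_path = NULL,
                            out_dir = "admixscan_out", alpha = 0.05,
                            region_cutoff_neglog10 = "genomewide",
                            min_markers = 5, merge_gap_bp = 1e6,
                            qc = list(), meff_method = "pr", seed = 1L) {
  if (is.null(ancestry_path) && is.null(sim))
    stop("give either ancestry_path or sim")
  if (!is.null(sim)) stopifnot(inherits(sim, "simulation_config"))
  stopifnot(alpha > 0, alpha < 1, min_markers >= 1, merge_gap_bp >= 0)
  known_qc <- c("sample_min_rate", "het_k_sd", "snp_min_rate", "w_eur",
                "max_freq_diff", "apply_concordance")
  if (length(setdiff(names(qc), known_qc)))
    stop("unknown qc key(s): ",
         paste(setdiff(names(qc), known_qc), collapse = ", "))
  if (!identical(region_cutoff_neglog10, "genomewide"))
    stopifnot(is.numeric(region_cutoff_neglog10), region_cutoff_neglog10 > 0)
  structure(list(ancestry_path = ancestry_path, sim = sim,
                 genotype_path = genotype_path, panel_path = panel_path,
                 out_dir = out_dir, alpha = alpha,
                 region_cutoff_neglog10 = region_cutoff_neglog10,
                 min_markers = min_markers, merge_gap_bp = merge_gap_bp,
                 qc = qc, meff_method = meff_method, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full case-only admixture-mapping pipeline
#'
#' Stages: load or simulate inputs -> genotype QC (when genotypes and a
#' panel are available) -> excess-ancestry Z scan -> effective number of
#' independent tests -> genome-wide threshold -> region calling in both
#' ancestry tails -> ancestry relative risks at region excesses. Writes all
#' artifacts plus a JSON run manifest into `out_dir`; a rerun with the same
#' config and inputs is bit-identical. Progress and per-stage counts go to
#' stderr.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with `scan`, `meff`, `threshold`,
#'   `regions_eur`, `regions_afr`, `effect_sizes`, `qc`, `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  stage <- function(name, expr) {
    message(sprintf("[admixscan] %s ...", name))
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  manifest <- list(package_version = as.character(utils::packageVersion("admixscan")),
                   seed = config$seed, alpha = config$alpha,
                   meff_method = config$meff_method,
                   min_markers = config$min_markers,
                   merge_gap_bp = config$merge_gap_bp)

  # inputs
  geno <- NULL; panel <- NULL
  if (is.null(config$ancestry_path)) {
    cohort <- stage("simulate", simulate_cohort(config$sim))
    Q <- cohort$ancestry
    geno <- cohort$genotypes
    panel <- cohort$panel
    manifest$input <- list(mode = "simulated",
                           sim = config$sim[setdiff(names(config$sim),
                                                    "risk_locus")],
                           risk_locus = config$sim$risk_locus)
    write_ancestry_tsv(Q, file.path(config$out_dir, "ancestry.tsv"))
    if (!is.null(geno))
      write_genotypes_vcf(geno, file.path(config$out_dir, "genotypes.vcf"))
    if (!is.null(panel))
      write_panel_tsv(panel, file.path(config$out_dir, "panel_freqs.tsv"))
  } else {
    Q <- stage("load_ancestry", read_ancestry_tsv(config$ancestry_path))
    if (!is.null(config$genotype_path))
      geno <- stage("load_genotypes", read_genotypes(config$genotype_path))
    if (!is.null(config$panel_path))
      panel <- stage("load_panel", read_panel_tsv(config$panel_path))
    manifest$input <- list(mode = "files", ancestry = config$ancestry_path,
                           genotypes = config$genotype_path,
                           panel = config$panel_path)
  }
  message(sprintf("[admixscan] input: %d samples x %d markers",
                  nrow(Q$q), ncol(Q$q)))

  # QC (genotype side; the ancestry matrix itself is validated at load)
  qc_res <- NULL
  if (!is.null(geno) && !is.null(panel)) {
    qc_res <- stage("qc", do.call(qc_pipeline, c(list(geno, panel), config$qc)))
    utils::write.table(qc_res$report, file.path(config$out_dir, "qc_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(qc_res$stage_counts,
                         file.path(config$out_dir, "qc_counts.json"))
    message(paste(sprintf("[admixscan]   %s: %d samples, %d SNPs",
                          qc_res$stage_counts$stage,
                          qc_res$stage_counts$n_samples,
                          qc_res$stage_counts$n_snps), collapse = "\n"))
  }

  scan <- stage("scan", z_scan(Q))
  write_scan_tsv(scan, file.path(config$out_dir, "scan.tsv"))

  meff <- stage("meff", effective_tests_genome(Q, method = config$meff_method))
  thr <- genomewide_threshold(meff, alpha = config$alpha)
  jsonlite::write_json(
    list(per_chrom = meff$per_chrom, m_total = meff$m_total,
         method = meff$method, alpha = thr$alpha,
         p_threshold = thr$p_threshold, neglog10 = thr$neglog10),
    file.path(config$out_dir, "meff.json"),
    auto_unbox = TRUE, digits = NA)
  message(sprintf("[admixscan]   M_total = %.1f, threshold -log10 p = %.2f",
                  meff$m_total, thr$neglog10))

  cutoff <- if (identical(config$region_cutoff_neglog10, "genomewide"))
    thr$neglog10 else config$region_cutoff_neglog10
  regions <- list()
  for (tl in c("eur", "afr")) {
    rg <- stage(paste0("regions_", tl),
                call_regions(scan, cutoff_neglog10 = cutoff, tail = tl,
                             min_markers = config$min_markers,
                             merge_gap_bp = config$merge_gap_bp))
    rg <- region_report(rg, thr)
    write_regions(rg,
                  bed_path = file.path(config$out_dir,
                                       sprintf("regions_%s.bed", tl)),
                  tsv_path = file.path(config$out_dir,
                                       sprintf("regions_%s.tsv", tl)))
    regions[[tl]] <- rg
  }

  # ancestry relative risks at each called region's mean and peak excess
  m_hat <- mean(global_ancestry(Q))
  es <- stage("effect_size", {
    rows <- list()
    for (tl in names(regions)) {
      rg <- regions[[tl]]
      for (i in seq_len(nrow(rg))) {
        for (what in c("mean_excess", "peak")) {
          delta <- if (what == "mean_excess") rg$mean_excess[i] else
            scan$delta_pi[scan$chrom == rg$chrom[i] &
                            scan$pos_bp == rg$peak_bp[i]]
          for (model in c("multiplicative", "additive")) {
            rr <- tryCatch(estimate_rr(delta, m_hat, model),
                           error = function(e) NA_real_)
            rows[[length(rows) + 1]] <- data.frame(
              tail = tl, chrom = rg$chrom[i], peak_bp = rg$peak_bp[i],
              excess_type = what, delta = delta, m = m_hat, model = model,
              relative_risk = rr, stringsAsFactors = FALSE)
          }
        }
      }
    }
    if (length(rows)) do.call(rbind, rows) else
      data.frame(tail = character(), chrom = integer(), peak_bp = integer(),
                 excess_type = character(), delta = numeric(), m = numeric(),
                 model = character(), relative_risk = numeric())
  })
  utils::write.table(es, file.path(config$out_dir, "effect_sizes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  manifest$n_samples <- nrow(Q$q)
  manifest$n_markers <- ncol(Q$q)
  manifest$m_total <- meff$m_total
  manifest$threshold_neglog10 <- thr$neglog10
  manifest$region_cutoff_neglog10 <- cutoff
  manifest$mean_global_ancestry <- m_hat
  manifest$n_regions <- vapply(regions, nrow, integer(1))
  if (!is.null(qc_res)) manifest$qc_stage_counts <- qc_res$stage_counts
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  message(sprintf("[admixscan] done in %.1f s",
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  invisible(list(scan = scan, meff = meff, threshold = thr,
                 regions_eur = regions$eur, regions_afr = regions$afr,
                 effect_sizes = es, qc = qc_res, manifest = manifest))
}
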