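## Genotype QC cascade: sample call rate -> heterozygosity outliers ->
## SNP call rate -> panel match / monomorphic -> panel-frequency concordance.
## Each filter returns the filtered matrix plus a report of removals; the
## pipeline logs surviving counts per stage.

qc_report_row <- function(id, type, stage, reason, value) {
  data.frame(id = id, type = type, stage = stage, reason = reason,
             value = value, stringsAsFactors = FALSE)
}

empty_report <- function() {
  data.frame(id = character(), type = character(), stage = character(),
             reason = character(), value = numeric(), stringsAsFactors = FALSE)
}

#' Filter samples by genotyping call rate
#'
#' Retains samples whose fraction of non-missing calls is strictly greater
#' than `min_rate`; a complete sample (rate exactly 1) always passes, so
#' `min_rate = 1` keeps exactly the complete samples.
#'
#' @param G a [genotype_matrix()].
#' @param min_rate call-rate threshold (default 0.95).
#' @return list with `genotypes` (filtered) and `report` (removed samples).
#' @export
sample_call_rate_filter <- function(G, min_rate = 0.95) {
  stopifnot(inherits(G, "genotype_matrix"))
  if (nrow(G$calls) == 0 || ncol(G$calls) == 0) stop("empty genotype matrix")
  cr <- rowMeans(!is.na(G$calls))
  drop <- which(!(cr > min_rate | cr == 1))
  report <- if (length(drop))
    qc_report_row(rownames(G$calls)[drop], "sample", "sample_call_rate",
                  "low_call_rate", cr[drop])
  else empty_report()
  G$calls <- G$calls[setdiff(seq_len(nrow(G$calls)), drop), , drop = FALSE]
  list(genotypes = G, report = report)
}

#' Filter samples by heterozygosity outliers
#'
#' Heterozygosity rate is (#calls equal to 1) / (#non-missing calls) per
#' sample. Samples whose rate lies outside mean +/- `k_sd` * SD are removed;
#' the mean and SD are computed once over the samples entering this stage
#' (single pass, not iterated). Both tails are removed and the reason code
#' records which; samples with no non-missing calls have an undefined rate
#' and are removed with their own reason code.
#'
#' @param G a [genotype_matrix()].
#' @param k_sd width of the retained band in standard deviations (default 3;
#'   `Inf` removes nothing).
#' @return list with `genotypes` and `report`.
#' @export
heterozygosity_filter <- function(G, k_sd = 3) {
  stopifnot(inherits(G, "genotype_matrix"))
  if (nrow(G$calls) < 2) stop("need at least 2 samples")
  nonmiss <- rowSums(!is.na(G$calls))
  het <- rowSums(G$calls == 1L, na.rm = TRUE) / nonmiss
  undef <- which(nonmiss == 0)
  mu <- mean(het[nonmiss > 0])
  sdv <- stats::sd(het[nonmiss > 0])
  lo <- het < mu - k_sd * sdv
  hi <- het > mu + k_sd * sdv
  lo[undef] <- hi[undef] <- FALSE
  rep_list <- list()
  if (length(undef))
    rep_list[[1]] <- qc_report_row(rownames(G$calls)[undef], "sample",
                                   "heterozygosity", "undefined_het_rate",
                                   NA_real_)
  if (any(lo, na.rm = TRUE))
    rep_list[[length(rep_list) + 1]] <-
      qc_report_row(rownames(G$calls)[which(lo)], "sample", "heterozygosity",
                    "het_low", het[which(lo)])
  if (any(hi, na.rm = TRUE))
    rep_list[[length(rep_list) + 1]] <-
      qc_report_row(rownames(G$calls)[which(hi)], "sample", "heterozygosity",
                    "het_high", het[which(hi)])
  report <- if (length(rep_list)) do.call(rbind, rep_list) else empty_report()
  drop <- sort(unique(c(undef, which(lo), which(hi))))
  G$calls <- G$calls[setdiff(seq_len(nrow(G$calls)), drop), , drop = FALSE]
  list(genotypes = G, report = report)
}

#' Filter SNPs by call rate
#'
#' Retains SNPs with call rate strictly greater than `min_rate`; a complete
#' SNP (rate exactly 1) always passes, so `min_rate = 1` keeps exactly the
#' complete SNPs.
#'
#' @param G a [genotype_matrix()].
#' @param min_rate SNP call-rate threshold (default 0.964).
#' @return list with `genotypes` and `report`.
#' @export
snp_call_rate_filter <- function(G, min_rate = 0.964) {
  stopifnot(inherits(G, "genotype_matrix"))
  if (nrow(G$calls) == 0 || ncol(G$calls) == 0) stop("empty genotype matrix")
  cr <- colMeans(!is.na(G$calls))
  drop <- which(!(cr > min_rate | cr == 1))
  report <- if (length(drop))
    qc_report_row(G$map$marker_id[drop], "snp", "snp_call_rate",
                  "low_call_rate", cr[drop])
  else empty_report()
  keep <- setdiff(seq_len(ncol(G$calls)), drop)
  G$calls <- G$calls[, keep, drop = FALSE]
  G$map <- G$map[keep, , drop = FALSE]
  list(genotypes = G, report = report)
}

#' Remove monomorphic SNPs and SNPs absent from the reference panel
#'
#' Drops SNPs that cannot be matched to the panel frequency table (by
#' `marker_id`) and SNPs whose non-missing calls are all identical (no
#' variation in the sample). SNPs with zero non-missing calls count as
#' monomorphic.
#'
#' @param G a [genotype_matrix()].
#' @param panel data.frame with at least `marker_id`, `freqCEU`, `freqYRI`.
#' @return list with `genotypes` and `report`.
#' @export
monomorphic_and_unmatched_filter <- function(G, panel) {
  stopifnot(inherits(G, "genotype_matrix"))
  unmatched <- which(!(G$map$marker_id %in% panel$marker_id))
  nvals <- apply(G$calls, 2, function(x) length(unique(x[!is.na(x)])))
  mono <- setdiff(which(nvals <= 1), unmatched)  # one primary reason each
  rep_list <- list()
  if (length(unmatched))
    rep_list[[1]] <- qc_report_row(G$map$marker_id[unmatched], "snp",
                                   "panel_match", "unmatched", NA_real_)
  if (length(mono))
    rep_list[[length(rep_list) + 1]] <-
      qc_report_row(G$map$marker_id[mono], "snp", "panel_match",
                    "monomorphic", NA_real_)
  report <- if (length(rep_list)) do.call(rbind, rep_list) else empty_report()
  keep <- setdiff(seq_len(ncol(G$calls)), c(unmatched, mono))
  G$calls <- G$calls[, keep, drop = FALSE]
  G$map <- G$map[keep, , drop = FALSE]
  list(genotypes = G, report = report)
}

#' Flag SNPs whose observed frequency departs from the panel mixture
#'
#' Observed alternate-allele frequency is (sum of dosages)/(2 * non-missing);
#' the expected frequency under admixture is
#' `(1 - w_eur) * freqYRI + w_eur * freqCEU`. SNPs with
#' |observed - expected| > `max_diff` are flagged (absolute difference; the
#' caller is responsible for consistent allele orientation between matrix
#' and panel). SNPs with zero non-missing calls are flagged as undefined.
#' Removal is optional: scans can be run with and without these SNPs.
#'
#' @param G a [genotype_matrix()].
#' @param panel panel frequency table (`marker_id`, `freqCEU`, `freqYRI`).
#' @param w_eur mixture weight on the European panel (default 0.2).
#' @param max_diff flag threshold on the absolute difference (default 0.3).
#' @param remove drop flagged SNPs from the returned matrix (default TRUE).
#' @return list with `genotypes` and `report` (flagged SNPs with the
#'   observed-minus-expected difference as `value`).
#' @export
allele_freq_concordance_filter <- function(G, panel, w_eur = 0.2,
                                           max_diff = 0.3, remove = TRUE) {
  stopifnot(inherits(G, "genotype_matrix"))
  idx <- match(G$map$marker_id, panel$marker_id)
  if (anyNA(idx))
    stop("all SNPs must be present in the panel (run the panel-match filter first)")
  nonmiss <- colSums(!is.na(G$calls))
  obs <- colSums(G$calls, na.rm = TRUE) / (2 * nonmiss)
  expd <- (1 - w_eur) * panel$freqYRI[idx] + w_eur * panel$freqCEU[idx]
  diffs <- abs(obs - expd)
  undef <- which(nonmiss == 0)
  flag <- setdiff(which(diffs > max_diff), undef)
  rep_list <- list()
  if (length(undef))
    rep_list[[1]] <- qc_report_row(G$map$marker_id[undef], "snp",
                                   "freq_concordance", "undefined_freq",
                                   NA_real_)
  if (length(flag))
    rep_list[[length(rep_list) + 1]] <-
      qc_report_row(G$map$marker_id[flag], "snp", "freq_concordance",
                    "freq_discordant", diffs[flag])
  report <- if (length(rep_list)) do.call(rbind, rep_list) else empty_report()
  if (remove) {
    keep <- setdiff(seq_len(ncol(G$calls)), c(undef, flag))
    G$calls <- G$calls[, keep, drop = FALSE]
    G$map <- G$map[keep, , drop = FALSE]
  }
  list(genotypes = G, report = report)
}

#' Run the full QC cascade
#'
#' Applies, in order: sample call rate, heterozygosity outliers, SNP call
#' rate, panel match / monomorphic removal, and (optionally) panel-frequency
#' concordance. Stage-surviving counts are recorded.
#'
#' @param G a [genotype_matrix()].
#' @param panel panel frequency table.
#' @param sample_min_rate,het_k_sd,snp_min_rate,w_eur,max_freq_diff stage
#'   thresholds (see the individual filters).
#' @param apply_concordance remove frequency-discordant SNPs (TRUE) or only
#'   flag them in the report (FALSE).
#' @return list with `genotypes` (post-QC), `report` (all removals/flags),
#'   `stage_counts` (data.frame of samples/SNPs surviving each stage).
#' @export
qc_pipeline <- function(G, panel,
                        sample_min_rate = 0.95, het_k_sd = 3,
                        snp_min_rate = 0.964, w_eur = 0.2,
                        max_freq_diff = 0.3, apply_concordance = TRUE) {
  stages <- list()
  counts <- data.frame(stage = "input", n_samples = nrow(G$calls),
                       n_snps = ncol(G$calls), stringsAsFactors = FALSE)
  step <- function(G, name, res) {
    stages[[name]] <<- res$report
    counts <<- rbind(counts, data.frame(stage = name,
                                        n_samples = nrow(res$genotypes$calls),
                                        n_snps = ncol(res$genotypes$calls)))
    res$genotypes
  }
  G <- step(G, "sample_call_rate", sample_call_rate_filter(G, sample_min_rate))
  G <- step(G, "heterozygosity", heterozygosity_filter(G, het_k_sd))
  G <- step(G, "snp_call_rate", snp_call_rate_filter(G, snp_min_rate))
  G <- step(G, "panel_match", monomorphic_and_unmatched_filter(G, panel))
  G <- step(G, "freq_concordance",
            allele_freq_concordance_filter(G, panel, w_eur, max_freq_diff,
                                           remove = apply_concordance))
  list(genotypes = G, report = do.call(rbind, unname(stages)),
       stage_counts = counts)
}
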