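## Readers/writers for the pipeline's plain-text artifacts. Local-ancestry
## and dosage TSVs are marker-major: header `marker_id chrom pos_bp
## sample1 ... sampleN`, one row per marker, positions 1-based. BED output
## is 0-based half-open. Readers validate and reject rather than coerce.

#' Write a local-ancestry matrix to TSV
#'
#' Canonical formatting: tab-separated, one row per marker, q values with 6
#' decimal places; write-read-write round-trips byte-identically.
#'
#' @param Q an [ancestry_matrix()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ancestry_tsv <- function(Q, path) {
  stopifnot(inherits(Q, "ancestry_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("marker_id", "chrom", "pos_bp", rownames(Q$q)),
                   collapse = "\t"), con)
  qt <- t(Q$q)
  body <- paste(Q$map$marker_id, Q$map$chrom, Q$map$pos_bp,
                apply(matrix(sprintf("%.6f", qt), nrow = nrow(qt)), 1,
                      paste, collapse = "\t"),
                sep = "\t")
  writeLines(body, con)
  invisible(path)
}

#' Read a local-ancestry matrix from TSV
#'
#' Validates completeness, q bounds (naming the offending marker and
#' sample), marker uniqueness and sorted, strictly increasing positions.
#'
#' @param path TSV written by [write_ancestry_tsv()] (or equivalent).
#' @return an [ancestry_matrix()].
#' @export
read_ancestry_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("marker_id", "chrom", "pos_bp")
  if (!all(need %in% names(df)[1:3]))
    stop("ancestry TSV must start with columns marker_id, chrom, pos_bp")
  samples <- names(df)[-(1:3)]
  if (!length(samples)) stop("ancestry TSV has no sample columns")
  if (anyDuplicated(df$marker_id))
    stop("duplicate marker_id: ", df$marker_id[duplicated(df$marker_id)][1])
  q <- t(as.matrix(df[, samples, drop = FALSE]))
  if (anyNA(q)) stop("ancestry TSV contains missing q values")
  if (any(q < 0 | q > 1)) {
    bad <- which(q < 0 | q > 1, arr.ind = TRUE)[1, ]
    stop(sprintf("q out of [0,1] at marker '%s', sample '%s'",
                 df$marker_id[bad[2]], samples[bad[1]]))
  }
  rownames(q) <- samples
  map <- data.frame(marker_id = df$marker_id, chrom = df$chrom,
                    pos_bp = df$pos_bp, stringsAsFactors = FALSE)
  ancestry_matrix(q, map)
}

#' Write a scan result to TSV
#'
#' Columns: marker_id, chrom, pos_bp, delta_pi, z, p_right, p_left,
#' neglog10_p_right, neglog10_p_left.
#'
#' @param scan an [z_scan()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_scan_tsv <- function(scan, path) {
  stopifnot(inherits(scan, "ancestry_scan"))
  df <- as.data.frame(scan)
  num <- vapply(df, is.numeric, logical(1)) & names(df) != "chrom" &
    names(df) != "pos_bp"
  df[num] <- lapply(df[num], function(x) sprintf("%.6g", x))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a genotype matrix from VCF or dosage TSV
#'
#' VCF (`.vcf`/`.vcf.gz`, parsed with vcfR): dosage is the count of
#' alternate alleles in the diploid GT field; `./.` is missing;
#' multi-allelic records are skipped with a warning giving their count.
#' Dosage TSV: same marker-major layout as the ancestry TSV with integer
#' calls 0/1/2 or NA.
#'
#' @param path input file.
#' @return a [genotype_matrix()].
#' @export
read_genotypes <- function(path) {
  if (grepl("\\.vcf(\\.gz)?$", path)) read_genotypes_vcf(path)
  else read_genotypes_tsv(path)
}

read_genotypes_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  samples <- names(df)[-(1:3)]
  calls <- t(as.matrix(df[, samples, drop = FALSE]))
  rownames(calls) <- samples
  map <- data.frame(marker_id = df$marker_id, chrom = df$chrom,
                    pos_bp = df$pos_bp, stringsAsFactors = FALSE)
  genotype_matrix(calls, map)
}

read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi))
    warning(sum(multi), " multi-allelic record(s) skipped")
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[!multi, , drop = FALSE]
  fix <- fix[!multi, , drop = FALSE]
  dosage_one <- function(x) {
    al <- strsplit(x, "[/|]")
    vapply(al, function(a) {
      if (length(a) != 2 || any(a == ".") || any(is.na(a))) NA_integer_
      else sum(a == "1")
    }, integer(1))
  }
  calls <- t(apply(gt, 2, dosage_one))
  if (nrow(fix) == 1) calls <- matrix(calls, ncol = 1,
                                      dimnames = list(colnames(gt), NULL))
  map <- data.frame(marker_id = fix[, "ID"],
                    chrom = as.integer(fix[, "CHROM"]),
                    pos_bp = as.integer(fix[, "POS"]),
                    stringsAsFactors = FALSE)
  genotype_matrix(calls, map)
}

#' Write a genotype matrix as a minimal plain-text VCF
#'
#' VCFv4.2, diploid unphased GT only (`0/0`, `0/1`, `1/1`, missing `./.`),
#' placeholder REF/ALT alleles A/G.
#'
#' @param G a [genotype_matrix()].
#' @param path output file (uncompressed `.vcf`).
#' @return `path`, invisibly.
#' @export
write_genotypes_vcf <- function(G, path) {
  stopifnot(inherits(G, "genotype_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(G$calls)), collapse = "\t")),
             con)
  gt_code <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow = ncol(G$calls), ncol = nrow(G$calls))
  cl <- t(G$calls)
  ok <- !is.na(cl)
  gt[ok] <- gt_code[cl[ok] + 1L]
  body <- paste(G$map$chrom, G$map$pos_bp, G$map$marker_id, "A", "G", ".",
                "PASS", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(body, con)
  invisible(path)
}

#' Write / read a reference-panel frequency table
#'
#' TSV with columns `marker_id`, `freqCEU`, `freqYRI` (and `ancestral` when
#' available).
#'
#' @param panel panel data.frame.
#' @param path file path.
#' @return `path` (writer) / data.frame (reader).
#' @export
write_panel_tsv <- function(panel, path) {
  utils::write.table(panel, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_panel_tsv
#' @export
read_panel_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("marker_id", "freqCEU", "freqYRI") %in% names(df)))
    stop("panel TSV must have columns marker_id, freqCEU, freqYRI")
  bad <- df$freqCEU < 0 | df$freqCEU > 1 | df$freqYRI < 0 | df$freqYRI > 1
  if (any(bad)) stop("panel frequencies out of [0,1] at marker ",
                     df$marker_id[which(bad)[1]])
  df
}

#' Write called regions as BED and annotated TSV
#'
#' BED uses the 0-based half-open convention (`start_bp - 1`, `end_bp`);
#' the TSV carries all region annotations with 1-based coordinates.
#'
#' @param regions an [call_regions()] (optionally [region_report()]ed)
#'   data.frame.
#' @param bed_path,tsv_path output files (either may be NULL to skip).
#' @return invisibly, the paths written.
#' @export
write_regions <- function(regions, bed_path = NULL, tsv_path = NULL) {
  if (!is.null(bed_path)) {
    bed <- data.frame(chrom = sprintf("chr%s", regions$chrom),
                      start = regions$start_bp - 1L,
                      end = regions$end_bp,
                      name = if (nrow(regions)) sprintf("%s_excess_%d",
                                                        regions$tail,
                                                        seq_len(nrow(regions)))
                             else character(0))
    utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  if (!is.null(tsv_path)) {
    df <- as.data.frame(regions)
    df$secondary_peaks_bp <- NULL
    utils::write.table(df, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(c(bed = bed_path, tsv = tsv_path))
}
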