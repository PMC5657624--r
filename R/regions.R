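#' Call regions of excess ancestry from a scan
#'
#' Converts a per-locus scan into candidate regions for one ancestry tail:
#' maximal runs of consecutive markers with -log10(p_tail) >= `cutoff`;
#' runs on the same chromosome separated by at most `merge_gap_bp` are
#' merged; merged runs containing fewer than `min_markers` qualifying
#' markers are dropped. The peak is the qualifying marker with maximal |Z|
#' in the tested direction (ties broken toward the smaller position);
#' `mean_excess` and `n_markers` summarize the qualifying markers. Output
#' is ordered by (chromosome, start).
#'
#' @param scan an [z_scan()] result.
#' @param cutoff_neglog10 required -log10(p) for a marker to qualify. No
#'   default: the boundary rule is procedure-dependent and the cutoff must
#'   be an explicit analysis choice.
#' @param tail `"eur"` (right tail, excess European ancestry) or `"afr"`
#'   (left tail).
#' @param min_markers minimum qualifying markers per region (default 5).
#' @param merge_gap_bp merge runs separated by at most this many bp
#'   (default 1e6).
#' @param secondary_peaks also report, per region, local maxima of |Z|
#'   separated from each other by at least `merge_gap_bp` and within 10% of
#'   the peak |Z| (default FALSE).
#' @return object of class `ancestry_regions`: data.frame with columns
#'   `chrom`, `start_bp`, `end_bp`, `peak_bp`, `peak_z`, `peak_neglog10`,
#'   `mean_excess`, `n_markers`, `tail` (and `secondary_peaks_bp` when
#'   requested).
#' @export
call_regions <- function(scan, cutoff_neglog10, tail = c("eur", "afr"),
                         min_markers = 5, merge_gap_bp = 1e6,
                         secondary_peaks = FALSE) {
  stopifnot(inherits(scan, "ancestry_scan"))
  tail <- match.arg(tail)
  if (missing(cutoff_neglog10)) stop("cutoff_neglog10 must be given explicitly")
  for (ch in unique(scan$chrom)) {
    if (is.unsorted(scan$pos_bp[scan$chrom == ch], strictly = TRUE))
      stop("scan must be sorted by position within chromosome")
  }
  nl <- if (tail == "eur") scan$neglog10_p_right else scan$neglog10_p_left
  zdir <- if (tail == "eur") scan$z else -scan$z
  out <- list()
  for (ch in unique(scan$chrom)) {
    idx <- which(scan$chrom == ch)
    qual <- idx[nl[idx] >= cutoff_neglog10]
    if (!length(qual)) next
    # maximal runs of consecutive qualifying markers
    runs <- split(qual, cumsum(c(1, diff(qual) != 1)))
    # merge runs whose bp gap is within merge_gap_bp
    merged <- list(runs[[1]])
    for (r in runs[-1]) {
      last <- merged[[length(merged)]]
      gap <- scan$pos_bp[r[1]] - scan$pos_bp[last[length(last)]]
      if (gap <= merge_gap_bp) merged[[length(merged)]] <- c(last, r)
      else merged[[length(merged) + 1]] <- r
    }
    for (mk in merged) {
      if (length(mk) < min_markers) next
      zz <- zdir[mk]
      peak_i <- mk[which(zz == max(zz))]
      peak_i <- peak_i[which.min(scan$pos_bp[peak_i])]
      row <- data.frame(
        chrom = ch,
        start_bp = scan$pos_bp[mk[1]],
        end_bp = scan$pos_bp[mk[length(mk)]],
        peak_bp = scan$pos_bp[peak_i],
        peak_z = scan$z[peak_i],
        peak_neglog10 = nl[peak_i],
        mean_excess = mean(scan$delta_pi[mk]),
        n_markers = length(mk),
        tail = tail,
        stringsAsFactors = FALSE
      )
      if (secondary_peaks) {
        row$secondary_peaks_bp <- I(list(find_secondary_peaks(
          scan$pos_bp[mk], zdir[mk], merge_gap_bp)))
      }
      out[[length(out) + 1]] <- row
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = integer(), start_bp = integer(), end_bp = integer(),
               peak_bp = integer(), peak_z = numeric(),
               peak_neglog10 = numeric(), mean_excess = numeric(),
               n_markers = integer(), tail = character(),
               stringsAsFactors = FALSE)
  res <- res[order(res$chrom, res$start_bp), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("ancestry_regions", "data.frame")
  res
}

# local maxima of z along positions, >= gap apart, within 10% of the max
find_secondary_peaks <- function(pos, z, gap_bp) {
  n <- length(z)
  if (n == 0) return(integer())
  is_max <- vapply(seq_len(n), function(i) {
    (i == 1 || z[i] >= z[i - 1]) && (i == n || z[i] >= z[i + 1])
  }, logical(1))
  cand <- which(is_max & z >= 0.9 * max(z))
  cand <- cand[order(-z[cand], pos[cand])]
  sel <- integer()
  for (i in cand) {
    if (!length(sel) || all(abs(pos[i] - pos[sel]) >= gap_bp)) sel <- c(sel, i)
  }
  sort(pos[sel])
}

#' Annotate called regions against a genome-wide threshold
#'
#' Marks each region genome-wide significant iff its peak -log10(p) is at
#' least the threshold's -log10 value (>= convention at the boundary), and
#' carries forward the peak and mean excess-ancestry summaries.
#'
#' @param regions an [call_regions()] result.
#' @param threshold a [genomewide_threshold()] object.
#' @return the regions data.frame with added columns `significant` and
#'   `threshold_neglog10`.
#' @export
region_report <- function(regions, threshold) {
  stopifnot(inherits(regions, "ancestry_regions"),
            inherits(threshold, "significance_threshold"))
  regions$significant <- regions$peak_neglog10 >= threshold$neglog10
  regions$threshold_neglog10 <- rep(threshold$neglog10, nrow(regions))
  regions
}

#' @export
print.ancestry_regions <- function(x, ...) {
  cat(sprintf("ancestry_regions: %d region(s)\n", nrow(x)))
  if (nrow(x)) {
    for (i in seq_len(nrow(x)))
      cat(sprintf(
        "  chr%d %.1f-%.1f Mb (peak %.1f Mb, -log10 p = %.2f, mean excess %.3f, %d markers, %s tail)\n",
        x$chrom[i], x$start_bp[i] / 1e6, x$end_bp[i] / 1e6, x$peak_bp[i] / 1e6,
        x$peak_neglog10[i], x$mean_excess[i], x$n_markers[i], x$tail[i]))
  }
  invisible(x)
}
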