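#' Manhattan-style plot of an excess-ancestry scan
#'
#' Position versus -log10(p) for the chosen ancestry tail, chromosomes in
#' alternating shades, with an optional genome-wide threshold line.
#'
#' @param scan an [z_scan()] result.
#' @param tail `"eur"` or `"afr"`.
#' @param threshold optional [genomewide_threshold()] object (drawn as a
#'   dashed line).
#' @param file optional PNG path; when given the plot is written there.
#' @param ... further arguments passed to [graphics::plot()].
#' @return invisibly, NULL.
#' @export
plot_scan <- function(scan, tail = c("eur", "afr"), threshold = NULL,
                      file = NULL, ...) {
  stopifnot(inherits(scan, "ancestry_scan"))
  tail <- match.arg(tail)
  y <- if (tail == "eur") scan$neglog10_p_right else scan$neglog10_p_left
  chroms <- unique(scan$chrom)
  offs <- c(0, cumsum(vapply(chroms, function(ch)
    max(scan$pos_bp[scan$chrom == ch]), numeric(1))))
  x <- scan$pos_bp + offs[match(scan$chrom, chroms)]
  if (!is.null(file)) {
    grDevices::png(file, width = 1200, height = 400)
    on.exit(grDevices::dev.off())
  }
  graphics::plot(x, y, pch = 20, cex = 0.5,
                 col = c("grey30", "steelblue")[1 + match(scan$chrom, chroms) %% 2],
                 xlab = "genome position", xaxt = "n",
                 ylab = sprintf("-log10 p (%s excess)",
                                if (tail == "eur") "European" else "African"),
                 ...)
  graphics::axis(1, at = (offs[-length(offs)] + offs[-1]) / 2, labels = chroms,
                 tick = FALSE)
  if (!is.null(threshold))
    graphics::abline(h = threshold$neglog10, lty = 2, col = "red")
  invisible(NULL)
}
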