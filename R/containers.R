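#' Build a marker map
#'
#' A marker map gives every SNP an identifier, an autosome (1-22 by
#' convention), a physical position and a genetic position. When only
#' physical positions are available the genetic map defaults to 1 cM/Mb.
#'
#' @param markers_per_chrom integer vector, number of markers on each
#'   chromosome; chromosome numbers are `seq_along(markers_per_chrom)`.
#' @param spacing_cM genetic distance between adjacent markers, in cM.
#' @param bp_per_cM physical-to-genetic scale used to lay out `pos_bp`.
#' @param start_cM genetic position of the first marker on each chromosome.
#' @return data.frame with columns `marker_id`, `chrom`, `pos_bp`, `pos_cM`,
#'   sorted by (chrom, position).
#' @export
make_marker_map <- function(markers_per_chrom, spacing_cM = 0.5,
                            bp_per_cM = 1e6, start_cM = spacing_cM) {
  stopifnot(length(markers_per_chrom) >= 1, all(markers_per_chrom >= 1),
            spacing_cM > 0)
  chrom <- rep(seq_along(markers_per_chrom), markers_per_chrom)
  idx <- unlist(lapply(markers_per_chrom, seq_len), use.names = FALSE)
  pos_cM <- start_cM + (idx - 1) * spacing_cM
  map <- data.frame(
    marker_id = sprintf("chr%d_m%04d", chrom, idx),
    chrom = chrom,
    pos_bp = as.integer(round(pos_cM * bp_per_cM)),
    pos_cM = pos_cM,
    stringsAsFactors = FALSE
  )
  validate_marker_map(map)
  map
}

#' Validate a marker map
#'
#' Checks uniqueness of marker IDs and strictly increasing positions within
#' each chromosome; fills `pos_cM` at 1 cM/Mb when absent.
#'
#' @param map data.frame with columns `marker_id`, `chrom`, `pos_bp` and
#'   optionally `pos_cM`.
#' @return the validated (possibly completed) map, invisibly usable.
#' @export
validate_marker_map <- function(map) {
  need <- c("marker_id", "chrom", "pos_bp")
  if (!all(need %in% names(map)))
    stop("marker map must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(map$marker_id))
    stop("duplicate marker_id in map: ",
         map$marker_id[duplicated(map$marker_id)][1])
  if (is.unsorted(order(map$chrom, map$pos_bp)))
    stop("marker map must be sorted by (chrom, pos_bp)")
  for (ch in unique(map$chrom)) {
    p <- map$pos_bp[map$chrom == ch]
    if (any(diff(p) <= 0))
      stop("positions not strictly increasing on chromosome ", ch)
  }
  if (is.null(map$pos_cM)) map$pos_cM <- map$pos_bp / 1e6
  map
}

#' Construct an ancestry matrix
#'
#' The scan's sole required input: an N x L matrix of diploid European
#' local-ancestry proportions `q[i, l]` in \[0, 1\] (0 = both haplotypes
#' African, 1 = both European), together with its marker map. Entries must be
#' complete; upstream local-ancestry inference yields complete matrices and
#' imputation is out of scope here.
#'
#' @param q numeric matrix, samples in rows, markers in columns. Row names
#'   are sample IDs (generated if absent); column names must match
#'   `map$marker_id` (set from the map if absent).
#' @param map marker map (see [make_marker_map()]).
#' @return an object of class `ancestry_matrix`: list with elements `q`, `map`.
#' @export
ancestry_matrix <- function(q, map) {
  map <- validate_marker_map(map)
  q <- as.matrix(q)
  if (ncol(q) != nrow(map))
    stop("q has ", ncol(q), " columns but map has ", nrow(map), " markers")
  if (anyNA(q)) stop("ancestry matrix must be complete (no missing q)")
  if (any(q < 0 | q > 1)) {
    bad <- which(q < 0 | q > 1, arr.ind = TRUE)[1, ]
    stop(sprintf("q out of [0,1] at sample '%s', marker '%s'",
                 rownames(q)[bad[1]] %||% bad[1], map$marker_id[bad[2]]))
  }
  if (is.null(rownames(q))) rownames(q) <- sprintf("sample%03d", seq_len(nrow(q)))
  colnames(q) <- map$marker_id
  structure(list(q = q, map = map), class = "ancestry_matrix")
}

#' @export
print.ancestry_matrix <- function(x, ...) {
  cat(sprintf("ancestry_matrix: %d samples x %d markers on %d chromosome(s)\n",
              nrow(x$q), ncol(x$q), length(unique(x$map$chrom))))
  cat(sprintf("  mean q = %.4f\n", mean(x$q)))
  invisible(x)
}

#' Construct a genotype matrix
#'
#' Alternate-allele dosage calls in \{0, 1, 2, NA\}, samples in rows.
#'
#' @param calls integer matrix N x L with values 0/1/2 or NA.
#' @param map marker map matching the columns.
#' @return object of class `genotype_matrix`: list with `calls`, `map`.
#' @export
genotype_matrix <- function(calls, map) {
  map <- validate_marker_map(map)
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (ncol(calls) != nrow(map))
    stop("calls has ", ncol(calls), " columns but map has ", nrow(map), " markers")
  ok <- is.na(calls) | calls %in% 0:2
  if (!all(ok)) stop("genotype dosages must be 0, 1, 2 or NA")
  if (is.null(rownames(calls)))
    rownames(calls) <- sprintf("sample%03d", seq_len(nrow(calls)))
  colnames(calls) <- map$marker_id
  structure(list(calls = calls, map = map), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d markers, %.2f%% missing\n",
              nrow(x$calls), ncol(x$calls), 100 * mean(is.na(x$calls))))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
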