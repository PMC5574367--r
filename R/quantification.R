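#' Promoter expression requantification
#'
#' Tag counts under each peak are accumulated per library from CTSS records
#' (same strand, position inside the half-open peak interval), then
#' normalized to tags per million (TPM) after scaling by RLE (relative log
#' expression, median-of-ratios) factors. The per-million denominator is the
#' genome-wide mapped-tag total of the library, so edits to the peak set do
#' not perturb unrelated peaks' TPM values.
#'
#' @name quantification
NULL

#' Count CTSS tags under peaks per library
#'
#' @param peaks peak data.frame (same-strand non-overlapping: fair + new).
#' @param ctss_by_library named list of CTSS data.frames, one per library.
#' @return list with `raw_counts` (peaks x libraries integer matrix, row
#'   names = `coord_id`) and `library_totals` (genome-wide tag totals).
#' @export
count_tags <- function(peaks, ctss_by_library) {
  stopifnot(is.list(ctss_by_library), length(ctss_by_library) > 0L)
  libs <- names(ctss_by_library)
  if (is.null(libs) || any(!nzchar(libs))) {
    stop("ctss_by_library must be a named list", call. = FALSE)
  }
  counts <- matrix(0L, nrow = nrow(peaks), ncol = length(libs),
                   dimnames = list(peaks$coord_id, libs))
  totals <- stats::setNames(numeric(length(libs)), libs)
  pk_gr <- if (nrow(peaks) > 0L) intervals_to_gr(peaks) else NULL
  for (j in seq_along(libs)) {
    ctss <- ctss_by_library[[j]]
    totals[j] <- sum(ctss$count)
    if (is.null(pk_gr) || nrow(ctss) == 0L) next
    hits <- GenomicRanges::findOverlaps(pk_gr, ctss_to_gr(ctss),
                                        ignore.strand = FALSE)
    if (length(hits) == 0L) next
    agg <- tapply(ctss$count[S4Vectors::subjectHits(hits)],
                  S4Vectors::queryHits(hits), sum)
    counts[as.integer(names(agg)), j] <- as.integer(agg)
  }
  list(raw_counts = counts, library_totals = totals)
}

#' RLE (median-of-ratios) scale factors
#'
#' For peaks with strictly positive counts in every library, each count is
#' divided by the peak's across-library geometric mean; a library's factor
#' is the median of those ratios (even-length medians are the midpoint of
#' the two central values). Factors are rescaled so their geometric mean is
#' 1, making them pure relative corrections on top of per-million scaling.
#'
#' @param raw_counts peaks x libraries count matrix.
#' @return numeric vector of per-library factors, geometric mean 1.
#' @export
rle_factors <- function(raw_counts) {
  stopifnot(is.matrix(raw_counts), ncol(raw_counts) >= 1L)
  pos <- rowSums(raw_counts > 0) == ncol(raw_counts)
  if (!any(pos)) {
    stop(paste("no peak has positive counts in every library;",
               "prefilter to pooled-expressed peaks first"), call. = FALSE)
  }
  m <- raw_counts[pos, , drop = FALSE]
  gm <- exp(rowMeans(log(m)))
  factors <- apply(m / gm, 2L, stats::median)
  factors <- factors / exp(mean(log(factors)))
  stats::setNames(factors, colnames(raw_counts))
}

#' Normalize counts to TPM
#'
#' `tpm[i, j] = raw[i, j] / (library_total[j] * factor[j]) * 1e6`.
#'
#' @param raw_counts peaks x libraries count matrix.
#' @param library_totals genome-wide tag totals per library (all > 0).
#' @param factors RLE factors per library.
#' @return numeric TPM matrix with the same dimnames.
#' @export
normalize_tpm <- function(raw_counts, library_totals, factors) {
  stopifnot(length(library_totals) == ncol(raw_counts),
            length(factors) == ncol(raw_counts))
  if (any(library_totals <= 0)) {
    stop("library totals must be positive", call. = FALSE)
  }
  sweep(raw_counts, 2L, library_totals * factors, "/") * 1e6
}

#' Build a full expression matrix
#'
#' Convenience wrapper: counts, RLE factors, TPM.
#'
#' @inheritParams count_tags
#' @return list (`raw_counts`, `library_totals`, `rle_factors`, `tpm`).
#' @export
quantify_peaks <- function(peaks, ctss_by_library) {
  q <- count_tags(peaks, ctss_by_library)
  factors <- rle_factors(q$raw_counts)
  tpm <- normalize_tpm(q$raw_counts, q$library_totals, factors)
  list(raw_counts = q$raw_counts, library_totals = q$library_totals,
       rle_factors = factors, tpm = tpm)
}
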