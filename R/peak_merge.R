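#' Integration of newly called DPI peaks with converted fair peaks
#'
#' New peaks called directly on the new assembly (DPI output) are merged
#' with the converted fair set: a new peak is added only when it overlaps no
#' fair peak on the same strand by at least one base (the `intersectBed -s`
#' convention, no reciprocal-fraction requirement).
#'
#' @name peak_merge
NULL

#' Strand-aware interval intersection
#'
#' All pairs (a, b) with the same strand and >= 1 bp overlap, half-open
#' coordinates.
#'
#' @param set_a,set_b interval data.frames on the same assembly.
#' @return data.frame of row indices `a_idx`, `b_idx`.
#' @export
intersect_stranded <- function(set_a, set_b) {
  validate_intervals(set_a, "set_a")
  validate_intervals(set_b, "set_b")
  stranded_overlap_pairs(set_a, set_b)
}

#' Merge DPI peaks into the fair set
#'
#' @param fair converted fair peak data.frame (new assembly).
#' @param dpi_peaks newly called peak data.frame (new assembly); must be
#'   internally same-strand non-overlapping (a property of the peak caller,
#'   validated here).
#' @return merged peak data.frame; added peaks carry `state = "new"`.
#' @export
merge_new_peaks <- function(fair, dpi_peaks) {
  if (length(find_overlap_groups(dpi_peaks)) > 0L) {
    stop("dpi_peaks contains internal same-strand overlaps", call. = FALSE)
  }
  pairs <- intersect_stranded(dpi_peaks, fair)
  novel <- setdiff(seq_len(nrow(dpi_peaks)), unique(pairs$a_idx))
  add <- dpi_peaks[novel, , drop = FALSE]
  if (nrow(add) > 0L) add$state <- "new"
  merged <- rbind(fair[intersect(names(fair), names(add))],
                  add[intersect(names(fair), names(add))])
  rownames(merged) <- NULL
  merged
}

#' Two-sided overlap summary of fair vs DPI peaks
#'
#' Counts, from each side, how many peaks overlap at least one peak of the
#' other set (same strand, >= 1 bp), with percentages.
#'
#' @param fair,dpi_peaks peak data.frames on the same assembly.
#' @return data.frame with one row per side: `set`, `n_total`,
#'   `n_overlapped`, `n_non_overlapped`, `pct_overlapped`.
#' @export
overlap_summary <- function(fair, dpi_peaks) {
  pairs <- intersect_stranded(fair, dpi_peaks)
  n_fair_ov <- length(unique(pairs$a_idx))
  n_dpi_ov <- length(unique(pairs$b_idx))
  pct <- function(k, n) if (n == 0L) NA_real_ else 100 * k / n
  data.frame(
    set = c("converted_fair", "dpi"),
    n_total = c(nrow(fair), nrow(dpi_peaks)),
    n_overlapped = c(n_fair_ov, n_dpi_ov),
    n_non_overlapped = c(nrow(fair) - n_fair_ov, nrow(dpi_peaks) - n_dpi_ov),
    pct_overlapped = c(pct(n_fair_ov, nrow(fair)),
                       pct(n_dpi_ov, nrow(dpi_peaks))),
    stringsAsFactors = FALSE
  )
}
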