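#' @importFrom GenomicRanges GRanges findOverlaps
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits
NULL

STRANDS <- c("+", "-")

#' Normalize strand symbols
#'
#' Maps the Unicode minus sign (U+2212), sometimes found in published tables,
#' onto the ASCII `-` used throughout BED files.
#'
#' @param strand character vector of strand symbols.
#' @return character vector containing only `+` and `-`.
#' @keywords internal
normalize_strand <- function(strand) {
  s <- gsub("−", "-", strand)
  s
}

## Validate the core interval columns shared by peaks and CTSS tables.
## `what` names the offending object in error messages.
validate_intervals <- function(df, what = "interval set") {
  stopifnot(is.data.frame(df))
  required <- c("chrom", "start", "end", "strand")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("%s lacks required column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (nrow(df) == 0L) return(invisible(df))
  if (any(df$start < 0L)) {
    stop(sprintf("%s: negative start coordinate", what), call. = FALSE)
  }
  bad <- which(df$end <= df$start)
  if (length(bad) > 0L) {
    stop(sprintf("%s: end <= start at row %d (%s:%d..%d)", what, bad[1L],
                 df$chrom[bad[1L]], df$start[bad[1L]], df$end[bad[1L]]),
         call. = FALSE)
  }
  if (!all(df$strand %in% STRANDS)) {
    stop(sprintf("%s: strand must be one of '+', '-'", what), call. = FALSE)
  }
  invisible(df)
}

## BED (0-based half-open) data.frame -> GRanges (1-based closed).
## All strand-aware interval arithmetic in the package goes through this.
intervals_to_gr <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = df$strand
  )
}

## Single-base CTSS data.frame (chrom, pos, strand) -> GRanges.
ctss_to_gr <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$pos + 1L, width = 1L),
    strand = df$strand
  )
}

## Same-strand overlap pairs (>= 1 bp) between two BED data.frames.
## Returns a data.frame of row indices (a_idx, b_idx).
stranded_overlap_pairs <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) {
    return(data.frame(a_idx = integer(0), b_idx = integer(0)))
  }
  hits <- GenomicRanges::findOverlaps(intervals_to_gr(a), intervals_to_gr(b),
                                      ignore.strand = FALSE)
  data.frame(a_idx = S4Vectors::queryHits(hits),
             b_idx = S4Vectors::subjectHits(hits))
}

## Deterministic genomic sort order: chrom, start, end, strand.
genomic_order <- function(df) {
  order(df$chrom, df$start, df$end, df$strand)
}

## Empty peak table with the canonical column set.
empty_peaks <- function() {
  data.frame(chrom = character(0), start = integer(0), end = integer(0),
             strand = character(0), coord_id = character(0),
             accession = character(0), assembly = character(0),
             state = character(0), provenance = character(0),
             stringsAsFactors = FALSE)
}
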