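#' Re-annotation of peaks against transcript models
#'
#' A peak is associated with transcripts whose TSS lies within a flanking
#' window of the peak on the same chromosome and strand: 500 bp for
#' transcripts initiated by RNA polymerase II, 50 bp for 5' ends not derived
#' from Pol-II initiation (snoRNA-like classes). Among candidates the
#' nearest transcript wins (distance 0 inside the peak, else base pairs to
#' the nearest peak edge); gene and protein links follow the chosen
#' transcript. Human-readable short names have the form
#' `p<serial>@<gene symbol>` with serials unique per gene across assemblies.
#'
#' @name annotation
NULL

TRANSCRIPT_COLS <- c("transcript_id", "chrom", "strand", "tss", "gene_id",
                     "gene_symbol", "tss_class", "protein_id")

#' Read a transcript-model table
#'
#' Tab-separated with header columns `transcript_id`, `chrom`, `strand`,
#' `tss` (0-based single-base TSS position, already 5'-end oriented),
#' `gene_id`, `gene_symbol`, `tss_class` (`pol2`/`non_pol2`), `protein_id`.
#' An optional `source_rank` column (1 = most curated) breaks nearest-TSS
#' ties; it defaults to 1.
#'
#' @param path TSV file.
#' @return transcript data.frame.
#' @export
read_transcripts <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  missing <- setdiff(TRANSCRIPT_COLS, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("transcript table lacks column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  df$tss <- as.integer(df$tss)
  df$strand <- normalize_strand(df$strand)
  if (!"source_rank" %in% names(df)) df$source_rank <- 1L
  df$source_rank <- as.integer(df$source_rank)
  if (!all(df$tss_class %in% c("pol2", "non_pol2"))) {
    stop("tss_class must be 'pol2' or 'non_pol2'", call. = FALSE)
  }
  df
}

## Distance from a peak [start, end) to a TSS position: 0 inside, signed
## outside (negative when the TSS lies left of the peak on the genome).
peak_tss_distance <- function(start, end, tss) {
  ifelse(tss >= start & tss < end, 0L,
         ifelse(tss < start, tss - start, tss - end + 1L))
}

#' Associate peaks with transcripts, genes and proteins
#'
#' @param peaks peak data.frame on the annotated assembly.
#' @param transcripts transcript data.frame (see [read_transcripts()]).
#' @param window_pol2 flanking window for Pol-II transcripts, bp, inclusive.
#' @param window_non_pol2 flanking window for non-Pol-II 5' ends, bp.
#' @return annotation data.frame, one row per peak: `coord_id`, `accession`,
#'   `transcript_ids` (comma-joined minimum-distance set), `transcript_id`
#'   (priority winner), `distance` (signed, `NA` if unannotated),
#'   `gene_id`, `gene_symbol`, `protein_id`, `annotated`.
#' @export
associate_peaks <- function(peaks, transcripts, window_pol2 = 500L,
                            window_non_pol2 = 50L) {
  stopifnot(window_non_pol2 <= window_pol2)
  n <- nrow(peaks)
  out <- data.frame(
    coord_id = peaks$coord_id,
    accession = if ("accession" %in% names(peaks)) peaks$accession else NA,
    transcript_ids = NA_character_, transcript_id = NA_character_,
    distance = NA_integer_, gene_id = NA_character_,
    gene_symbol = NA_character_, protein_id = NA_character_,
    annotated = FALSE, stringsAsFactors = FALSE
  )
  if (n == 0L || nrow(transcripts) == 0L) return(out)
  for (i in seq_len(n)) {
    cand <- transcripts[transcripts$chrom == peaks$chrom[i] &
                          transcripts$strand == peaks$strand[i], ,
                        drop = FALSE]
    if (nrow(cand) == 0L) next
    d <- peak_tss_distance(peaks$start[i], peaks$end[i], cand$tss)
    w <- ifelse(cand$tss_class == "pol2", window_pol2, window_non_pol2)
    cand <- cand[abs(d) <= w, , drop = FALSE]
    d <- d[abs(d) <= w]
    if (nrow(cand) == 0L) next
    dmin <- min(abs(d))
    sel <- which(abs(d) == dmin)
    # tie-break among equidistant transcripts: curation rank, then id
    win <- sel[order(cand$source_rank[sel], cand$transcript_id[sel])][1L]
    out$transcript_ids[i] <- paste(sort(cand$transcript_id[sel]),
                                   collapse = ",")
    out$transcript_id[i] <- cand$transcript_id[win]
    out$distance[i] <- d[win]
    out$gene_id[i] <- cand$gene_id[win]
    sym <- cand$gene_symbol[win]
    # symbol source priority: nomenclature symbol (HGNC/MGI) over bare id
    out$gene_symbol[i] <- if (!is.na(sym) && nzchar(sym)) sym else
      cand$gene_id[win]
    pid <- cand$protein_id[win]
    out$protein_id[i] <- if (!is.na(pid) && nzchar(pid)) pid else
      NA_character_
    out$annotated[i] <- TRUE
  }
  out
}

#' Assign human-readable short names
#'
#' Converted peaks keep a prior short name when the registry records one.
#' Peaks newly gaining a gene receive `p<serial>@<symbol>` with the smallest
#' serial for that gene not yet used, assigned across peaks of the gene in
#' descending pooled-expression order. Unannotated peaks are named
#' `p@<coord_id>`. Names are unique per species across assemblies; a
#' collision with the registry is an internal error.
#'
#' @param annotations annotation data.frame from [associate_peaks()].
#' @param existing_names character vector of names already in use (registry),
#'   possibly carrying names inherited from the old assembly as
#'   `names(existing_names) = coord_id` for carry-over.
#' @param pooled_expression numeric vector parallel to `annotations`
#'   (pooled tag counts), used only to order new serials; default all equal.
#' @return annotations with a `short_name` column added.
#' @export
assign_short_names <- function(annotations, existing_names = character(0),
                               pooled_expression = rep(0, nrow(annotations))) {
  stopifnot(length(pooled_expression) == nrow(annotations))
  ann <- annotations
  ann$short_name <- NA_character_
  used <- unname(existing_names)
  carry <- names(existing_names)
  if (!is.null(carry)) {
    m <- match(ann$coord_id, carry)
    ann$short_name <- ifelse(is.na(m), NA_character_, existing_names[m])
  }
  todo <- which(is.na(ann$short_name))
  gene_of <- ifelse(ann$annotated, ann$gene_symbol, NA_character_)
  for (g in unique(stats::na.omit(gene_of[todo]))) {
    idx <- todo[!is.na(gene_of[todo]) & gene_of[todo] == g]
    idx <- idx[order(-pooled_expression[idx], ann$coord_id[idx])]
    taken <- used[grepl(sprintf("^p[0-9]+@%s$", gsub("([^[:alnum:]])",
                                                     "\\\\\\1", g)), used)]
    taken_serials <- as.integer(sub("^p([0-9]+)@.*$", "\\1", taken))
    serial <- 1L
    for (i in idx) {
      while (serial %in% taken_serials) serial <- serial + 1L
      nm <- sprintf("p%d@%s", serial, g)
      if (nm %in% used) stop("short-name collision with registry: ", nm)
      ann$short_name[i] <- nm
      taken_serials <- c(taken_serials, serial)
      used <- c(used, nm)
    }
  }
  rest <- which(is.na(ann$short_name))
  ann$short_name[rest] <- sprintf("p@%s", ann$coord_id[rest])
  ann
}

#' Summarize annotations by gene category
#'
#' @param annotations annotation data.frame.
#' @param gene_categories data.frame mapping `gene_id` to `category`
#'   (`protein-coding`, `pseudogene`, `miscRNA/miRNA`, `snRNA/snoRNA`,
#'   `other/unknown`).
#' @return list with `totals` (annotated counts by link type) and
#'   `by_category` (data.frame of annotated-peak counts per category;
#'   categories absent from the map count as `other/unknown`).
#' @export
annotation_category_summary <- function(annotations, gene_categories = NULL) {
  categories <- c("protein-coding", "pseudogene", "miscRNA/miRNA",
                  "snRNA/snoRNA", "other/unknown")
  ann <- annotations[annotations$annotated, , drop = FALSE]
  cat_of <- rep("other/unknown", nrow(ann))
  if (!is.null(gene_categories) && nrow(ann) > 0L) {
    m <- match(ann$gene_id, gene_categories$gene_id)
    cat_of[!is.na(m)] <- gene_categories$category[m[!is.na(m)]]
  }
  counts <- vapply(categories, function(cc) sum(cat_of == cc), 0L)
  list(
    totals = data.frame(
      link = c("transcript", "gene", "protein"),
      n = c(nrow(ann), sum(!is.na(ann$gene_id)),
            sum(!is.na(ann$protein_id))),
      stringsAsFactors = FALSE
    ),
    by_category = data.frame(category = categories, n = unname(counts),
                             stringsAsFactors = FALSE)
  )
}

#' Write the annotation table
#'
#' Tab-delimited: accession, full identifier, short name, nearest
#' transcript(s), signed distance, gene id/symbol, protein id.
#'
#' @param annotations annotation data.frame with `short_name`.
#' @param peaks parallel peak data.frame (for full identifiers).
#' @param path output file.
#' @export
write_annotation <- function(annotations, peaks, path) {
  full_id <- ifelse(!is.na(peaks$accession),
                    format_full_id(peaks$assembly, peaks$coord_id,
                                   peaks$accession),
                    peaks$coord_id)
  out <- data.frame(
    accession = annotations$accession,
    full_id = full_id,
    short_name = annotations$short_name,
    transcript_ids = annotations$transcript_ids,
    distance = annotations$distance,
    gene_id = annotations$gene_id,
    gene_symbol = annotations$gene_symbol,
    protein_id = annotations$protein_id,
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}
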