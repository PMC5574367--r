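#' File formats: BED peaks, CTSS BED, OSC tables, curation tables
#'
#' All on-disk coordinates are BED: 0-based, half-open. Readers are strict by
#' default (any malformed line is a hard error naming the line); an opt-in
#' `strict = FALSE` mode skips malformed lines with a warning instead.
#'
#' @name genomic_io
NULL

read_bed_fields <- function(path, min_cols, strict, what) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) return(list(fields = list(), lineno = integer(0)))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < min_cols)
  if (length(bad) > 0L) {
    msg <- sprintf("%s: line %d has %d column(s), need >= %d: '%s'",
                   what, bad[1L], nf[bad[1L]], min_cols,
                   substr(lines[bad[1L]], 1L, 80L))
    if (strict) stop(msg, call. = FALSE)
    warning(sprintf("%s; skipping %d malformed line(s)", msg, length(bad)),
            call. = FALSE)
    keep <- setdiff(seq_along(fields), bad)
    return(list(fields = fields[keep], lineno = keep))
  }
  list(fields = fields, lineno = seq_along(fields))
}

#' Read a stranded CAGE peak BED file
#'
#' Column 4 holds either a bare coordinate identifier
#' (`chr1:564639..564649,+`) or a full cross-assembly identifier
#' (`hg19::chr1:564639..564649,+;hg_2.1`); the accession is extracted when
#' present. A BED file with fewer than 6 columns (no strand) is a hard error.
#'
#' @param path BED file (>= 6 columns).
#' @param assembly_label assembly the coordinates refer to (e.g. `"hg19"`).
#' @param strict if `FALSE`, skip malformed lines with a warning.
#' @return peak data.frame (`chrom`, `start`, `end`, `strand`, `coord_id`,
#'   `accession`, `assembly`, `state = "input"`, `provenance`), in file order.
#' @export
read_peaks <- function(path, assembly_label, strict = TRUE) {
  parsed <- read_bed_fields(path, 6L, strict, sprintf("peak BED '%s'", path))
  if (length(parsed$fields) == 0L) return(empty_peaks())
  m <- parsed$fields
  chrom <- vapply(m, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(m, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(m, `[[`, "", 3L)))
  name <- vapply(m, `[[`, "", 4L)
  strand <- normalize_strand(vapply(m, `[[`, "", 6L))
  bad <- which(is.na(start) | is.na(end) | end <= start |
                 !(strand %in% STRANDS))
  if (length(bad) > 0L) {
    msg <- sprintf("peak BED '%s': invalid coordinates or strand at line %d",
                   path, parsed$lineno[bad[1L]])
    if (strict) stop(msg, call. = FALSE)
    warning(msg, call. = FALSE)
    keep <- setdiff(seq_along(m), bad)
    chrom <- chrom[keep]; start <- start[keep]; end <- end[keep]
    name <- name[keep]; strand <- strand[keep]
  }
  name <- normalize_strand(name)
  is_full <- grepl("::.+;", name)
  coord_id <- name
  accession <- rep(NA_character_, length(name))
  if (any(is_full)) {
    pf <- parse_full_id(name[is_full])
    coord_id[is_full] <- pf$coord_id
    accession[is_full] <- pf$accession
  }
  df <- data.frame(chrom = chrom, start = start, end = end, strand = strand,
                   coord_id = coord_id, accession = accession,
                   assembly = assembly_label, state = "input",
                   provenance = "", stringsAsFactors = FALSE)
  validate_intervals(df, sprintf("peak BED '%s'", path))
  df
}

#' Write peaks as BED6
#'
#' The name column carries the full identifier when an accession is present,
#' else the coordinate identifier; score is 0.
#'
#' @param peaks peak data.frame.
#' @param path output file.
#' @param use_full_id prefix name with origin assembly and append accession
#'   where available.
#' @export
write_peaks <- function(peaks, path, use_full_id = TRUE) {
  validate_intervals(peaks, "peak set")
  name <- peaks$coord_id
  if (use_full_id && "accession" %in% names(peaks)) {
    has <- !is.na(peaks$accession) & nzchar(peaks$accession)
    if (any(has)) {
      name[has] <- format_full_id(peaks$assembly[has], peaks$coord_id[has],
                                  peaks$accession[has])
    }
  }
  out <- data.frame(peaks$chrom, peaks$start, peaks$end, name, 0L,
                    peaks$strand)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a CTSS BED file
#'
#' CTSS records are single-base 5'-end positions with integer tag counts in
#' the BED score column. Any interval whose width is not exactly one base,
#' or whose count is not a non-negative integer, is rejected.
#'
#' @param path single-base BED file.
#' @param library_id library identifier attached to every record.
#' @param strict if `FALSE`, skip malformed lines with a warning.
#' @return data.frame (`chrom`, `pos`, `strand`, `count`, `library_id`).
#' @export
read_ctss <- function(path, library_id, strict = TRUE) {
  parsed <- read_bed_fields(path, 6L, strict, sprintf("CTSS BED '%s'", path))
  if (length(parsed$fields) == 0L) {
    return(data.frame(chrom = character(0), pos = integer(0),
                      strand = character(0), count = integer(0),
                      library_id = character(0), stringsAsFactors = FALSE))
  }
  m <- parsed$fields
  chrom <- vapply(m, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(m, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(m, `[[`, "", 3L)))
  score <- vapply(m, `[[`, "", 5L)
  strand <- normalize_strand(vapply(m, `[[`, "", 6L))
  count <- suppressWarnings(as.numeric(score))
  bad <- which(is.na(start) | is.na(end) | (end - start) != 1L |
                 is.na(count) | count < 0 | count != floor(count) |
                 !(strand %in% STRANDS))
  if (length(bad) > 0L) {
    msg <- sprintf(
      "CTSS BED '%s': line %d is not a single-base record with an integer count",
      path, parsed$lineno[bad[1L]])
    if (strict) stop(msg, call. = FALSE)
    warning(msg, call. = FALSE)
    keep <- setdiff(seq_along(m), bad)
    chrom <- chrom[keep]; start <- start[keep]; strand <- strand[keep]
    count <- count[keep]
  }
  data.frame(chrom = chrom, pos = start, strand = strand,
             count = as.integer(count), library_id = library_id,
             stringsAsFactors = FALSE)
}

#' Write CTSS records as single-base BED6
#'
#' @param ctss CTSS data.frame.
#' @param path output file.
#' @export
write_ctss <- function(ctss, path) {
  out <- data.frame(ctss$chrom, ctss$pos, ctss$pos + 1L, ".",
                    ctss$count, ctss$strand)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Pool CTSS records across libraries
#'
#' Sums tag counts per (chrom, pos, strand) over all libraries; the pooled
#' view is produced by summation, never by file concatenation.
#'
#' @param ctss_list list of CTSS data.frames (one per library) or a single
#'   data.frame.
#' @return pooled CTSS data.frame with `library_id = "pooled"`.
#' @export
pool_ctss <- function(ctss_list) {
  if (is.data.frame(ctss_list)) ctss_list <- list(ctss_list)
  all <- do.call(rbind, ctss_list)
  if (is.null(all) || nrow(all) == 0L) {
    return(data.frame(chrom = character(0), pos = integer(0),
                      strand = character(0), count = integer(0),
                      library_id = character(0), stringsAsFactors = FALSE))
  }
  agg <- stats::aggregate(count ~ chrom + pos + strand, data = all, FUN = sum)
  agg <- agg[order(agg$chrom, agg$pos, agg$strand), , drop = FALSE]
  rownames(agg) <- NULL
  agg$library_id <- "pooled"
  agg
}

#' Write an expression matrix as an OSC table
#'
#' OSC (Order Switchable Column) tables carry `##key=value` metadata header
#' lines, then one tab-separated column-name row (first column `id`), then
#' one row per peak. The emitted metadata is a minimal documented set:
#' `FormatVersion`, `ValueType`, plus any caller-supplied entries.
#'
#' @param values numeric matrix with row names (peak identifiers) and column
#'   names (library identifiers).
#' @param path output file.
#' @param metadata named character vector/list of extra header entries.
#' @param value_type free-text label for the values (e.g. `"raw"`, `"tpm"`).
#' @export
write_osc <- function(values, path, metadata = NULL, value_type = "raw") {
  stopifnot(is.matrix(values))
  if (ncol(values) == 0L) stop("OSC table needs >= 1 library column",
                               call. = FALSE)
  if (is.null(rownames(values)) || anyDuplicated(rownames(values))) {
    stop("OSC table requires unique row identifiers", call. = FALSE)
  }
  meta <- c(FormatVersion = "1", ValueType = value_type, metadata)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("##%s=%s", names(meta), unlist(meta)), con)
  writeLines(paste(c("id", colnames(values)), collapse = "\t"), con)
  body <- cbind(rownames(values),
                apply(values, 2L, function(x) {
                  format(x, trim = TRUE, scientific = FALSE, digits = 15L)
                }))
  writeLines(apply(body, 1L, paste, collapse = "\t"), con)
  invisible(path)
}

#' Read an OSC table
#'
#' @param path OSC file written by [write_osc()].
#' @return list with `values` (numeric matrix, row/col names set) and
#'   `metadata` (named character vector).
#' @export
read_osc <- function(path) {
  lines <- readLines(path)
  is_meta <- startsWith(lines, "##")
  meta_lines <- sub("^##", "", lines[is_meta])
  kv <- strsplit(meta_lines, "=", fixed = TRUE)
  metadata <- vapply(kv, function(x) paste(x[-1L], collapse = "="), "")
  names(metadata) <- vapply(kv, `[[`, "", 1L)
  body <- lines[!is_meta]
  if (length(body) == 0L) stop("OSC table has no column-name row",
                               call. = FALSE)
  header <- strsplit(body[1L], "\t", fixed = TRUE)[[1L]]
  rows <- strsplit(body[-1L], "\t", fixed = TRUE)
  ids <- vapply(rows, `[[`, "", 1L)
  if (anyDuplicated(ids)) stop("duplicate row identifiers in OSC table",
                               call. = FALSE)
  values <- matrix(0, nrow = length(rows), ncol = length(header) - 1L,
                   dimnames = list(ids, header[-1L]))
  for (i in seq_along(rows)) {
    values[i, ] <- as.numeric(rows[[i]][-1L])
  }
  list(values = values, metadata = metadata)
}

CURATION_ACTIONS <- c("rescue_to_fair", "keep_problematic", "set_interval",
                      "keep_as_is")

#' Read a manual-curation table
#'
#' Tab-separated with header columns `coord_id`, `action`, `new_interval`,
#' `note`. `action` is one of `rescue_to_fair`, `keep_problematic`,
#' `set_interval`, `keep_as_is` (exactly). `new_interval` is a coordinate
#' identifier, required iff `action == "set_interval"`.
#'
#' @param path TSV file.
#' @return data.frame (`coord_id`, `action`, `new_interval`, `note`).
#' @export
read_curation <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) <= 1L) {
    return(data.frame(coord_id = character(0), action = character(0),
                      new_interval = character(0), note = character(0),
                      stringsAsFactors = FALSE))
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("coord_id", "action")
  if (!all(need %in% names(df))) {
    stop("curation table needs columns 'coord_id' and 'action'",
         call. = FALSE)
  }
  if (!"new_interval" %in% names(df)) df$new_interval <- ""
  if (!"note" %in% names(df)) df$note <- ""
  df$coord_id <- normalize_strand(df$coord_id)
  bad <- which(!(df$action %in% CURATION_ACTIONS))
  if (length(bad) > 0L) {
    stop(sprintf("curation table: unknown action '%s' (row %d)",
                 df$action[bad[1L]], bad[1L]), call. = FALSE)
  }
  needs_iv <- df$action == "set_interval"
  has_iv <- nzchar(df$new_interval) & !is.na(df$new_interval)
  if (any(needs_iv & !has_iv)) {
    stop(sprintf("curation row %d: set_interval without coordinates",
                 which(needs_iv & !has_iv)[1L]), call. = FALSE)
  }
  if (any(!needs_iv & has_iv)) {
    stop(sprintf("curation row %d: new_interval given for action '%s'",
                 which(!needs_iv & has_iv)[1L],
                 df$action[which(!needs_iv & has_iv)[1L]]), call. = FALSE)
  }
  if (any(has_iv)) parse_coord_id(df$new_interval[has_iv])  # validates
  df[c("coord_id", "action", "new_interval", "note")]
}

#' Write a manual-curation table
#'
#' @param curation curation data.frame as from [read_curation()].
#' @param path output file.
#' @export
write_curation <- function(curation, path) {
  utils::write.table(curation, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
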