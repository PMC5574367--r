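#' Coordinate identifiers, versioned accessions and the accession registry
#'
#' CAGE peaks are referred to in three ways: a coordinate identifier tied to
#' one assembly ("chr1:564639..564649,+", BED coordinates verbatim), a
#' coordinate-free versioned accession ("hg_2.1" =
#' `<species prefix>_<serial>.<version>`), and a full identifier that chains
#' the two across assemblies
#' ("hg19::chr1:564639..564649,+;hg_2.1"). The registry guarantees that a
#' serial, once used, is never reused, so accessions stay stable across
#' reprocessing rounds.
#'
#' @name identifiers
NULL

#' Format a coordinate identifier
#'
#' @param chrom chromosome name(s).
#' @param start 0-based inclusive start(s).
#' @param end 0-based exclusive end(s).
#' @param strand `+` or `-`.
#' @return character vector `"<chrom>:<start>..<end>,<strand>"`.
#' @examples
#' format_coord_id("chr1", 564639, 564649, "+")
#' @export
format_coord_id <- function(chrom, start, end, strand) {
  strand <- normalize_strand(strand)
  stopifnot(all(strand %in% STRANDS), all(end > start), all(start >= 0))
  sprintf("%s:%d..%d,%s", chrom, as.integer(start), as.integer(end), strand)
}

#' Parse a coordinate identifier
#'
#' Accepts both the ASCII `-` and the typographic minus for the strand field.
#'
#' @param id character vector of coordinate identifiers.
#' @return data.frame with columns `chrom`, `start`, `end`, `strand`.
#' @export
parse_coord_id <- function(id) {
  id <- normalize_strand(id)
  re <- "^(.+):([0-9]+)\\.\\.([0-9]+),([+-])$"
  ok <- grepl(re, id)
  if (!all(ok)) {
    stop(sprintf("malformed coordinate identifier: '%s'", id[!ok][1L]),
         call. = FALSE)
  }
  df <- data.frame(
    chrom = sub(re, "\\1", id),
    start = as.integer(sub(re, "\\2", id)),
    end = as.integer(sub(re, "\\3", id)),
    strand = sub(re, "\\4", id),
    stringsAsFactors = FALSE
  )
  validate_intervals(df, "coordinate identifier")
  df
}

#' Format a versioned accession
#'
#' @param species_prefix `"hg"` or `"mm"`.
#' @param serial positive integer serial number.
#' @param version positive integer version, 1 for all first-round accessions.
#' @return character vector `"<prefix>_<serial>.<version>"`.
#' @export
format_accession <- function(species_prefix, serial, version = 1L) {
  stopifnot(all(species_prefix %in% c("hg", "mm")),
            all(serial >= 1), all(version >= 1))
  sprintf("%s_%d.%d", species_prefix, as.integer(serial), as.integer(version))
}

#' Parse a versioned accession
#'
#' @param accession character vector like `"hg_2.1"`.
#' @return data.frame with `species_prefix`, `serial`, `version`.
#' @export
parse_accession <- function(accession) {
  re <- "^(hg|mm)_([0-9]+)\\.([0-9]+)$"
  ok <- grepl(re, accession)
  if (!all(ok)) {
    stop(sprintf("malformed accession: '%s'", accession[!ok][1L]),
         call. = FALSE)
  }
  data.frame(
    species_prefix = sub(re, "\\1", accession),
    serial = as.integer(sub(re, "\\2", accession)),
    version = as.integer(sub(re, "\\3", accession)),
    stringsAsFactors = FALSE
  )
}

#' Format a full cross-assembly identifier
#'
#' The identifier concatenates the origin-assembly coordinate identifier with
#' the versioned accession: `"<assembly>::<coord_id>;<accession>"`. Peaks born
#' on the new assembly use their new-assembly coordinate identifier with the
#' new assembly label.
#'
#' @param assembly assembly label the coordinate identifier refers to
#'   (e.g. `"hg19"`, or the new assembly for newly called peaks).
#' @param coord_id coordinate identifier on that assembly.
#' @param accession versioned accession.
#' @return character vector of full identifiers.
#' @examples
#' format_full_id("hg19", "chr1:564639..564649,+", "hg_2.1")
#' @export
format_full_id <- function(assembly, coord_id, accession) {
  parse_accession(accession)  # validates
  sprintf("%s::%s;%s", assembly, coord_id, accession)
}

#' Parse a full cross-assembly identifier
#'
#' @param id character vector of full identifiers.
#' @return data.frame with `assembly`, `coord_id`, `accession`.
#' @export
parse_full_id <- function(id) {
  id <- normalize_strand(id)
  re <- "^([^:]+)::(.+);((hg|mm)_[0-9]+\\.[0-9]+)$"
  ok <- grepl(re, id)
  if (!all(ok)) {
    stop(sprintf("malformed full identifier: '%s'", id[!ok][1L]),
         call. = FALSE)
  }
  data.frame(
    assembly = sub(re, "\\1", id),
    coord_id = sub(re, "\\2", id),
    accession = sub(re, "\\3", id),
    stringsAsFactors = FALSE
  )
}

#' Create an empty accession registry
#'
#' @return zero-row registry data.frame (`accession`, `serial`, `version`,
#'   `coord_id`, `assembly`).
#' @export
new_registry <- function() {
  data.frame(accession = character(0), serial = integer(0),
             version = integer(0), coord_id = character(0),
             assembly = character(0), stringsAsFactors = FALSE)
}

validate_registry <- function(registry) {
  stopifnot(is.data.frame(registry))
  if (anyDuplicated(registry$accession)) {
    dup <- registry$accession[duplicated(registry$accession)][1L]
    stop(sprintf("duplicate accession in registry: '%s'", dup), call. = FALSE)
  }
  if (nrow(registry) > 0L && anyDuplicated(registry$serial)) {
    stop("duplicate serial in registry", call. = FALSE)
  }
  invisible(registry)
}

#' Assign versioned accessions to peaks
#'
#' Peaks already carrying an accession keep it (assignment is idempotent).
#' Peaks without one receive fresh serials starting at
#' `max(registry serial) + 1`, in genomic sort order of the new peaks, all at
#' version 1. Serials are never reused.
#'
#' @param peaks peak data.frame with `coord_id`, `assembly` and an
#'   `accession` column (`NA` where unassigned).
#' @param registry registry data.frame as from [new_registry()].
#' @param species_prefix `"hg"` or `"mm"`.
#' @return list with `peaks` (accessions filled) and `registry` (updated).
#' @export
assign_accessions <- function(peaks, registry = new_registry(),
                              species_prefix = "hg") {
  validate_registry(registry)
  if (!"accession" %in% names(peaks)) peaks$accession <- NA_character_
  has <- !is.na(peaks$accession) & nzchar(peaks$accession)
  if (any(has)) {
    parsed <- parse_accession(peaks$accession[has])
    known <- peaks$accession[has] %in% registry$accession
    if (any(!known)) {
      add <- which(has)[!known]
      registry <- rbind(registry, data.frame(
        accession = peaks$accession[add],
        serial = parsed$serial[!known],
        version = parsed$version[!known],
        coord_id = peaks$coord_id[add],
        assembly = peaks$assembly[add],
        stringsAsFactors = FALSE
      ))
      validate_registry(registry)
    }
  }
  todo <- which(!has)
  if (length(todo) > 0L) {
    todo <- todo[order(peaks$chrom[todo], peaks$start[todo],
                       peaks$end[todo], peaks$strand[todo])]
    base <- if (nrow(registry) > 0L) max(registry$serial) else 0L
    serials <- base + seq_along(todo)
    acc <- format_accession(species_prefix, serials, 1L)
    peaks$accession[todo] <- acc
    registry <- rbind(registry, data.frame(
      accession = acc, serial = serials, version = 1L,
      coord_id = peaks$coord_id[todo], assembly = peaks$assembly[todo],
      stringsAsFactors = FALSE
    ))
  }
  validate_registry(registry)
  list(peaks = peaks, registry = registry)
}

#' Read / write the accession registry
#'
#' The registry is persisted as a header-bearing TSV with columns
#' `accession`, `serial`, `version`, `coord_id`, `assembly`.
#'
#' @param path file path.
#' @return `read_registry` returns the registry data.frame.
#' @export
read_registry <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(accession = "character",
                                         serial = "integer",
                                         version = "integer",
                                         coord_id = "character",
                                         assembly = "character"))
  validate_registry(df)
  df
}

#' @rdname read_registry
#' @param registry registry data.frame.
#' @export
write_registry <- function(registry, path) {
  validate_registry(registry)
  utils::write.table(registry, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
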