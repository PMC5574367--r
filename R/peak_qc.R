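#' QC classification of lifted CAGE peaks
#'
#' Lifted peaks are vetted in a fixed order: read-evidence support, length
#' change across indels, same-strand overlap detection, overlap-group
#' resolution, then manual-curation overrides. Peaks surviving every check
#' are `fair`; mapped peaks failing any check are `problematic`; unmappable
#' peaks are `dropped` upstream by the lift. Every input peak ends in exactly
#' one of the three fates.
#'
#' @name peak_qc
NULL

#' Check CTSS read support of peaks
#'
#' A peak is supported iff at least one pooled CTSS with the same strand,
#' positive tag count, and position inside `[start, end)` exists. The pooled
#' CTSS (summed over all libraries) is used: any realigned read evidence
#' counts.
#'
#' @param peaks peak data.frame on the new assembly.
#' @param ctss_pooled pooled CTSS data.frame (see [pool_ctss()]).
#' @return logical vector, `TRUE` where supported.
#' @export
check_support <- function(peaks, ctss_pooled) {
  if (nrow(peaks) == 0L) return(logical(0))
  ctss <- ctss_pooled[ctss_pooled$count > 0, , drop = FALSE]
  if (nrow(ctss) == 0L) return(rep(FALSE, nrow(peaks)))
  hits <- GenomicRanges::findOverlaps(intervals_to_gr(peaks),
                                      ctss_to_gr(ctss),
                                      ignore.strand = FALSE)
  supported <- rep(FALSE, nrow(peaks))
  supported[unique(S4Vectors::queryHits(hits))] <- TRUE
  supported
}

#' Find same-strand overlap groups
#'
#' Peaks are not supposed to overlap on the same strand; groups are the
#' connected components (size >= 2) of the same-strand >= 1 bp overlap graph.
#'
#' @param peaks peak data.frame (one assembly).
#' @return list of integer vectors of row indices, one per group, ordered by
#'   leftmost member.
#' @export
find_overlap_groups <- function(peaks) {
  if (nrow(peaks) < 2L) return(list())
  pairs <- stranded_overlap_pairs(peaks, peaks)
  pairs <- pairs[pairs$a_idx < pairs$b_idx, , drop = FALSE]
  if (nrow(pairs) == 0L) return(list())
  g <- igraph::graph_from_edgelist(cbind(pairs$a_idx, pairs$b_idx),
                                   directed = FALSE)
  comp <- igraph::components(g)
  members <- split(seq_len(igraph::vcount(g)), comp$membership)
  groups <- Filter(function(m) length(m) >= 2L, members)
  groups <- lapply(groups, function(m) sort(as.integer(m)))
  first <- vapply(groups, function(m) min(peaks$start[m]), 0)
  unname(groups[order(vapply(groups, function(m) peaks$chrom[m[1L]], ""),
                      first)])
}

#' Resolve one overlap group
#'
#' Greedily excludes peaks until no same-strand overlap remains. Exclusion
#' priority among currently-overlapping members: (1) peaks flagged as
#' length-changed (the unintentional-stretch case), (2) shorter lifted
#' length, ties broken by excluding the peak later in coordinate order.
#'
#' @param group peak data.frame of the group members (size >= 2).
#' @param length_changed logical vector parallel to `group`.
#' @return list with `kept` and `excluded` integer row indices into `group`.
#' @export
resolve_overlap_group <- function(group, length_changed = rep(FALSE, nrow(group))) {
  stopifnot(nrow(group) >= 2L, length(length_changed) == nrow(group))
  active <- rep(TRUE, nrow(group))
  len <- group$end - group$start
  repeat {
    sub <- group[active, , drop = FALSE]
    pairs <- stranded_overlap_pairs(sub, sub)
    pairs <- pairs[pairs$a_idx < pairs$b_idx, , drop = FALSE]
    if (nrow(pairs) == 0L) break
    ai <- which(active)
    involved <- ai[unique(c(pairs$a_idx, pairs$b_idx))]
    # highest exclusion priority first: length-changed, then shorter, then
    # (on ties) the peak later in coordinate order
    ord <- order(!length_changed[involved], len[involved],
                 group$chrom[involved], group$start[involved],
                 group$end[involved], group$coord_id[involved],
                 method = "radix",
                 decreasing = c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE))
    active[involved[ord[1L]]] <- FALSE
  }
  list(kept = which(active), excluded = which(!active))
}

#' Flag peaks whose length changed through the lift
#'
#' A peak is flagged iff its length changed by more than one base between
#' the old and the new assembly (insertions/deletions in the update).
#'
#' @param old_len,new_len integer vectors of peak lengths.
#' @return logical vector, `TRUE` where `|new_len - old_len| > 1`.
#' @export
detect_length_changes <- function(old_len, new_len) {
  abs(new_len - old_len) > 1L
}

#' Apply manual-curation overrides
#'
#' `rescue_to_fair` and `keep_problematic` override the computed state;
#' `set_interval` replaces the lifted interval and re-runs the support check
#' on that peak (a replacement without CTSS support stays problematic, with
#' a warning); `keep_as_is` only records provenance. A record naming an
#' unknown peak is an error.
#'
#' @param peaks classified peak data.frame (states `fair`/`problematic`).
#' @param curation curation data.frame (see [read_curation()]).
#' @param ctss_pooled pooled CTSS, needed for `set_interval` re-checks.
#' @return peak data.frame with overrides applied and provenance noted.
#' @export
apply_curation <- function(peaks, curation, ctss_pooled = NULL) {
  if (is.null(curation) || nrow(curation) == 0L) return(peaks)
  for (k in seq_len(nrow(curation))) {
    rec <- curation[k, ]
    i <- which(peaks$coord_id == rec$coord_id)
    if (length(i) == 0L) {
      stop(sprintf("curation record names unknown peak '%s'", rec$coord_id),
           call. = FALSE)
    }
    i <- i[1L]
    note <- if (nzchar(rec$note)) sprintf(" (%s)", rec$note) else ""
    if (rec$action == "rescue_to_fair") {
      peaks$state[i] <- "fair"
      peaks$provenance[i] <- paste0(peaks$provenance[i],
                                    "curation:rescue_to_fair", note, ";")
    } else if (rec$action == "keep_problematic") {
      peaks$state[i] <- "problematic"
      peaks$provenance[i] <- paste0(peaks$provenance[i],
                                    "curation:keep_problematic", note, ";")
    } else if (rec$action == "set_interval") {
      iv <- parse_coord_id(rec$new_interval)
      peaks$chrom[i] <- iv$chrom
      peaks$start[i] <- iv$start
      peaks$end[i] <- iv$end
      peaks$strand[i] <- iv$strand
      peaks$provenance[i] <- paste0(peaks$provenance[i],
                                    "curation:set_interval", note, ";")
      if (!is.null(ctss_pooled)) {
        if (check_support(peaks[i, , drop = FALSE], ctss_pooled)) {
          peaks$state[i] <- "fair"
        } else {
          peaks$state[i] <- "problematic"
          warning(sprintf(
            "curated interval for '%s' has no CTSS support; kept problematic",
            rec$coord_id), call. = FALSE)
        }
      }
    } else if (rec$action == "keep_as_is") {
      peaks$provenance[i] <- paste0(peaks$provenance[i],
                                    "curation:keep_as_is", note, ";")
    }
  }
  peaks
}

#' Classify lifted peaks into fair and problematic
#'
#' Runs the QC pipeline on the output of [lift_peaks()]: support check,
#' length-change flags, overlap-group detection and resolution, then manual
#' curation. Returns the classified peaks together with a report carrying
#' the category counts, per-chromosome breakdowns, overlap groups and
#' length-change table.
#'
#' @param lifted list from [lift_peaks()] (`mapped` + `dropped`).
#' @param ctss_pooled pooled CTSS on the new assembly.
#' @param curation optional curation data.frame.
#' @return list with `peaks` (mapped peaks, states set), `dropped`, and
#'   `report` (a `qc_report` list).
#' @export
classify_peaks <- function(lifted, ctss_pooled, curation = NULL) {
  peaks <- lifted$mapped
  dropped <- lifted$dropped
  n_input <- nrow(peaks) + nrow(dropped)
  if (nrow(peaks) > 0L) {
    supported <- check_support(peaks, ctss_pooled)
    length_changed <- detect_length_changes(peaks$old_end - peaks$old_start,
                                            peaks$end - peaks$start)
    peaks$supported <- supported
    peaks$length_changed <- length_changed
    peaks$state <- ifelse(supported, "fair", "problematic")
    peaks$provenance <- ifelse(supported, peaks$provenance,
                               paste0(peaks$provenance, "qc:no_ctss_support;"))
    peaks$provenance <- ifelse(length_changed,
                               paste0(peaks$provenance, "qc:length_changed;"),
                               peaks$provenance)
    groups <- find_overlap_groups(peaks)
    for (g in groups) {
      res <- resolve_overlap_group(peaks[g, , drop = FALSE],
                                   peaks$length_changed[g])
      excl <- g[res$excluded]
      peaks$state[excl] <- "problematic"
      peaks$provenance[excl] <- paste0(peaks$provenance[excl],
                                       "qc:overlap_excluded;")
    }
    peaks <- apply_curation(peaks, curation, ctss_pooled)
  } else {
    groups <- list()
    length_changed <- logical(0)
  }
  report <- qc_report(peaks, dropped, groups)
  list(peaks = peaks, dropped = dropped, report = report)
}

qc_report <- function(peaks, dropped, groups) {
  n_fair <- sum(peaks$state == "fair")
  n_problematic <- sum(peaks$state == "problematic")
  n_dropped <- nrow(dropped)
  chrom_table <- function(df) {
    if (nrow(df) == 0L) return(data.frame(chrom = character(0), n = integer(0)))
    t <- as.data.frame(table(df$chrom), stringsAsFactors = FALSE)
    names(t) <- c("chrom", "n")
    t
  }
  lc <- peaks[isTRUE_vec(peaks$length_changed), , drop = FALSE]
  structure(list(
    n_input = n_fair + n_problematic + n_dropped,
    n_fair = n_fair,
    n_problematic = n_problematic,
    n_dropped = n_dropped,
    problematic_by_chrom = chrom_table(peaks[peaks$state == "problematic", ,
                                             drop = FALSE]),
    dropped_by_chrom = chrom_table(dropped),
    overlap_groups = lapply(groups, function(g) peaks$coord_id[g]),
    length_changed = data.frame(
      coord_id = lc$coord_id,
      old_len = lc$old_end - lc$old_start,
      new_len = lc$end - lc$start,
      stringsAsFactors = FALSE
    )
  ), class = "qc_report")
}

isTRUE_vec <- function(x) if (is.null(x)) logical(0) else !is.na(x) & x

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("QC report: %d input peaks\n", x$n_input))
  cat(sprintf("  fair        %d\n  problematic %d\n  dropped     %d\n",
              x$n_fair, x$n_problematic, x$n_dropped))
  cat(sprintf("  overlap groups: %d; length-changed: %d\n",
              length(x$overlap_groups), nrow(x$length_changed)))
  invisible(x)
}
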