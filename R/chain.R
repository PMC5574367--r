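#' UCSC chain files and minMatch interval lifting
#'
#' A chain describes one pairwise alignment between an old (target) and a new
#' (query) assembly as ordered ungapped blocks separated by gaps on either
#' side. Lifting an interval selects, among chains overlapping it on the old
#' assembly, the single chain covering the most of its bases with aligned
#' blocks; the interval maps only if that coverage fraction reaches
#' `min_match` (default 1, i.e. every base must be alignable through one
#' chain). The mapped interval spans from the image of the first to the image
#' of the last covered base, so its length can grow across new-assembly
#' insertions (dq gaps) and the strand flips through minus-strand chains.
#'
#' @name chain_liftover
NULL

new_chain <- function(score, old_chrom, old_size, old_start, old_end,
                      new_chrom, new_size, new_strand, new_start, new_end,
                      chain_id, blocks) {
  blocks$size <- as.integer(blocks$size)
  blocks$dt <- as.integer(blocks$dt)
  blocks$dq <- as.integer(blocks$dq)
  ch <- list(score = score, old_chrom = old_chrom,
             old_size = as.integer(old_size),
             old_start = as.integer(old_start),
             old_end = as.integer(old_end),
             new_chrom = new_chrom, new_size = as.integer(new_size),
             new_strand = new_strand, new_start = as.integer(new_start),
             new_end = as.integer(new_end), chain_id = chain_id,
             blocks = blocks)
  # block start offsets on each assembly (chain coordinate space)
  ch$ostart <- old_start + c(0L, cumsum(blocks$size + blocks$dt))[seq_len(nrow(blocks))]
  ch$nstart <- new_start + c(0L, cumsum(blocks$size + blocks$dq))[seq_len(nrow(blocks))]
  ch
}

validate_chain <- function(ch) {
  b <- ch$blocks
  if (nrow(b) == 0L || any(b$size <= 0L) || any(b$dt < 0L) || any(b$dq < 0L)) {
    stop(sprintf("chain %s: invalid block table", ch$chain_id), call. = FALSE)
  }
  if (b$dt[nrow(b)] != 0L || b$dq[nrow(b)] != 0L) {
    stop(sprintf("chain %s: last block must have zero trailing gaps",
                 ch$chain_id), call. = FALSE)
  }
  if (sum(b$size + b$dt) != ch$old_end - ch$old_start) {
    stop(sprintf("chain %s: blocks span %d bases on the old assembly, header says %d",
                 ch$chain_id, sum(b$size + b$dt), ch$old_end - ch$old_start),
         call. = FALSE)
  }
  if (sum(b$size + b$dq) != ch$new_end - ch$new_start) {
    stop(sprintf("chain %s: blocks span %d bases on the new assembly, header says %d",
                 ch$chain_id, sum(b$size + b$dq), ch$new_end - ch$new_start),
         call. = FALSE)
  }
  invisible(ch)
}

#' Parse a UCSC chain file
#'
#' Each chain is a `chain` header line (score, target name/size/strand/span,
#' query name/size/strand/span, id) followed by `size dt dq` triples and a
#' terminating bare block size. The old (target) assembly is always plus
#' strand. Block sums are verified against the header spans for every chain.
#'
#' @param path chain file.
#' @return object of class `chain_set`: a list of chains indexed by old
#'   chromosome (see `attr(x, "by_chrom")`).
#' @export
parse_chains <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines, which = "right")
  lines <- lines[!startsWith(lines, "#")]
  chains <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    if (!nzchar(lines[i])) { i <- i + 1L; next }
    f <- strsplit(lines[i], "[ \t]+")[[1L]]
    if (f[1L] != "chain" || length(f) < 13L) {
      stop(sprintf("chain file '%s': expected 'chain' header at line %d",
                   path, i), call. = FALSE)
    }
    if (f[5L] != "+") {
      stop(sprintf("chain %s: old-assembly strand must be '+'", f[13L]),
           call. = FALSE)
    }
    hdr <- list(score = as.numeric(f[2L]), old_chrom = f[3L],
                old_size = as.integer(f[4L]), old_start = as.integer(f[6L]),
                old_end = as.integer(f[7L]), new_chrom = f[8L],
                new_size = as.integer(f[9L]), new_strand = f[10L],
                new_start = as.integer(f[11L]), new_end = as.integer(f[12L]),
                chain_id = f[13L])
    i <- i + 1L
    size <- integer(0); dt <- integer(0); dq <- integer(0)
    repeat {
      if (i > n || !nzchar(lines[i])) {
        stop(sprintf("chain %s: truncated block list", hdr$chain_id),
             call. = FALSE)
      }
      b <- as.integer(strsplit(lines[i], "[ \t]+")[[1L]])
      i <- i + 1L
      if (length(b) == 1L) {
        size <- c(size, b); dt <- c(dt, 0L); dq <- c(dq, 0L)
        break
      }
      if (length(b) != 3L) {
        stop(sprintf("chain %s: malformed block line", hdr$chain_id),
             call. = FALSE)
      }
      size <- c(size, b[1L]); dt <- c(dt, b[2L]); dq <- c(dq, b[3L])
    }
    ch <- new_chain(hdr$score, hdr$old_chrom, hdr$old_size, hdr$old_start,
                    hdr$old_end, hdr$new_chrom, hdr$new_size, hdr$new_strand,
                    hdr$new_start, hdr$new_end, hdr$chain_id,
                    data.frame(size = size, dt = dt, dq = dq))
    validate_chain(ch)
    chains[[length(chains) + 1L]] <- ch
  }
  as_chain_set(chains)
}

as_chain_set <- function(chains) {
  by_chrom <- split(seq_along(chains),
                    vapply(chains, `[[`, "", "old_chrom"))
  structure(chains, by_chrom = by_chrom, class = "chain_set")
}

#' @export
print.chain_set <- function(x, ...) {
  cat(sprintf("chain_set: %d chain(s) over %d old chromosome(s)\n",
              length(x), length(attr(x, "by_chrom"))))
  invisible(x)
}

#' Write chains in UCSC chain format
#'
#' @param chains `chain_set` or list of chains.
#' @param path output file.
#' @export
write_chains <- function(chains, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in chains) {
    writeLines(sprintf("chain %s %s %d + %d %d %s %d %s %d %d %s",
                       format(ch$score, scientific = FALSE), ch$old_chrom,
                       ch$old_size, ch$old_start, ch$old_end, ch$new_chrom,
                       ch$new_size, ch$new_strand, ch$new_start, ch$new_end,
                       ch$chain_id), con)
    b <- ch$blocks
    k <- nrow(b)
    if (k > 1L) {
      writeLines(sprintf("%d %d %d", b$size[-k], b$dt[-k], b$dq[-k]), con)
    }
    writeLines(c(sprintf("%d", b$size[k]), ""), con)
  }
  invisible(path)
}

## Aligned-base coverage of the old-assembly interval [s, e) by one chain.
chain_coverage <- function(ch, s, e) {
  lo <- pmax(ch$ostart, s)
  hi <- pmin(ch$ostart + ch$blocks$size, e)
  sum(pmax(0L, hi - lo))
}

## Map one old-assembly base through a chain; NA when it falls in a gap.
chain_map_base <- function(ch, pos) {
  idx <- findInterval(pos, ch$ostart)
  if (idx < 1L) return(NA_integer_)
  off <- pos - ch$ostart[idx]
  if (off >= ch$blocks$size[idx]) return(NA_integer_)
  ch$nstart[idx] + off
}

#' Lift one interval through a chain set
#'
#' Implements the single-chain minMatch acceptance rule: the chain covering
#' the most bases of the interval with aligned blocks is selected (ties by
#' higher score, then lower chain id); the interval maps iff
#' `coverage / length >= min_match`. Failures are reported as `dropped` with
#' a reason: `unmapped` (no aligned base under any chain), `split` (only a
#' combination of chains reaches `min_match`), or `partial`.
#'
#' @param iv list or one-row data.frame with `chrom`, `start`, `end`,
#'   `strand` (BED coordinates).
#' @param chains `chain_set` from [parse_chains()] or [derive_chain()].
#' @param min_match minimum fraction of bases that must map through a single
#'   chain, in (0, 1]; default 1.
#' @return list with `status` (`"mapped"`/`"dropped"`), `new_interval`
#'   (data.frame or `NULL`), `matched_fraction`, `drop_reason`
#'   (`NA` when mapped), and `chain_id` of the selected chain.
#' @export
lift_interval <- function(iv, chains, min_match = 1.0) {
  stopifnot(min_match > 0, min_match <= 1)
  s <- as.integer(iv$start); e <- as.integer(iv$end)
  strand <- normalize_strand(iv$strand)
  len <- e - s
  stopifnot(len > 0L, strand %in% STRANDS)
  idx <- attr(chains, "by_chrom")[[iv$chrom]]
  dropped <- function(reason, mf) {
    list(status = "dropped", new_interval = NULL, matched_fraction = mf,
         drop_reason = reason, chain_id = NA_character_)
  }
  if (is.null(idx)) return(dropped("unmapped", 0))
  cov <- vapply(idx, function(i) chain_coverage(chains[[i]], s, e), 0L)
  if (all(cov == 0L)) return(dropped("unmapped", 0))
  score <- vapply(idx, function(i) chains[[i]]$score, 0)
  cid <- vapply(idx, function(i) chains[[i]]$chain_id, "")
  best <- order(-cov, -score, cid)[1L]
  mf <- cov[best] / len
  if (mf < min_match) {
    # distinguish a true partial from an interval only coverable by
    # combining chains (minMatch=1 demands a single chain)
    covered <- rep(FALSE, len)
    for (i in idx) {
      ch <- chains[[i]]
      lo <- pmax(ch$ostart, s); hi <- pmin(ch$ostart + ch$blocks$size, e)
      for (k in which(hi > lo)) covered[(lo[k] - s + 1L):(hi[k] - s)] <- TRUE
    }
    reason <- if (sum(covered) / len >= min_match) "split" else "partial"
    return(dropped(reason, mf))
  }
  ch <- chains[[idx[best]]]
  # first and last covered base of the interval under the selected chain
  lo <- pmax(ch$ostart, s)
  hi <- pmin(ch$ostart + ch$blocks$size, e)
  hit <- which(hi > lo)
  b1 <- min(lo[hit]); b2 <- max(hi[hit]) - 1L
  n1 <- chain_map_base(ch, b1)
  n2 <- chain_map_base(ch, b2)
  if (ch$new_strand == "-") {
    new_start <- ch$new_size - 1L - n2
    new_end <- ch$new_size - n1
    out_strand <- setdiff(STRANDS, strand)
  } else {
    new_start <- n1
    new_end <- n2 + 1L
    out_strand <- strand
  }
  list(status = "mapped",
       new_interval = data.frame(chrom = ch$new_chrom, start = new_start,
                                 end = new_end, strand = out_strand,
                                 stringsAsFactors = FALSE),
       matched_fraction = mf, drop_reason = NA_character_,
       chain_id = ch$chain_id)
}

#' Lift a peak set through a chain set
#'
#' Partitions the input exhaustively into mapped peaks (carrying their new
#' intervals, old intervals and original coordinate identifiers) and dropped
#' peaks (carrying a drop reason), mirroring the fair-vs-dropped arithmetic
#' of a conversion report.
#'
#' @param peaks peak data.frame on the old assembly.
#' @param chains `chain_set`.
#' @param min_match single-chain coverage threshold, default 1.
#' @param new_assembly_label label stamped on mapped peaks (e.g. `"hg38"`).
#' @return list with `mapped` (new coordinates plus `old_chrom`, `old_start`,
#'   `old_end`, `matched_fraction`), `dropped` (original coordinates plus
#'   `drop_reason`), and `drop_by_chrom` (per-old-chromosome drop tally).
#' @export
lift_peaks <- function(peaks, chains, min_match = 1.0,
                       new_assembly_label = NA_character_) {
  validate_intervals(peaks, "peak set")
  n <- nrow(peaks)
  mapped_rows <- vector("list", n)
  is_mapped <- logical(n)
  reason <- character(n)
  mf <- numeric(n)
  for (i in seq_len(n)) {
    res <- lift_interval(peaks[i, ], chains, min_match)
    mf[i] <- res$matched_fraction
    if (res$status == "mapped") {
      is_mapped[i] <- TRUE
      mapped_rows[[i]] <- res$new_interval
    } else {
      reason[i] <- res$drop_reason
    }
  }
  mapped <- peaks[is_mapped, , drop = FALSE]
  if (nrow(mapped) > 0L) {
    nv <- do.call(rbind, mapped_rows[is_mapped])
    mapped$old_chrom <- mapped$chrom
    mapped$old_start <- mapped$start
    mapped$old_end <- mapped$end
    mapped$chrom <- nv$chrom
    mapped$start <- nv$start
    mapped$end <- nv$end
    mapped$strand <- nv$strand
    mapped$matched_fraction <- mf[is_mapped]
    if (!is.na(new_assembly_label)) mapped$assembly <- new_assembly_label
  }
  dropped <- peaks[!is_mapped, , drop = FALSE]
  if (nrow(dropped) > 0L) {
    dropped$state <- "dropped"
    dropped$drop_reason <- reason[!is_mapped]
    dropped$matched_fraction <- mf[!is_mapped]
  }
  rownames(mapped) <- NULL
  rownames(dropped) <- NULL
  tallies <- if (nrow(dropped) > 0L) {
    t <- table(dropped$chrom)
    data.frame(chrom = names(t), n_dropped = as.integer(t),
               stringsAsFactors = FALSE)
  } else {
    data.frame(chrom = character(0), n_dropped = integer(0))
  }
  list(mapped = mapped, dropped = dropped, drop_by_chrom = tallies)
}
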