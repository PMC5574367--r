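#' Synthetic assembly pairs, true chains and planted peak sets
#'
#' The fixture generator emulates the real inputs of an assembly-migration
#' run without downloads: a pair of genomes related by a known edit script
#' (substitutions, insertions, deletions, duplications, inversions), the
#' chain file that exactly encodes the unedited segments, planted peaks
#' covering every engineered fate (clean, dropped-in-deletion, unsupported,
#' overlap-excluded, length-changed across insertions), DPI-like newly
#' called peaks, transcript models, and simulated per-library CTSS whose
#' library scale factors are known — so liftover, QC, merging, annotation
#' and RLE/TPM quantification are all testable against truth labels. All
#' randomness flows from one explicit seed.
#'
#' @name synthetic_fixtures
NULL

EDIT_TYPES <- c("substitution", "insertion", "deletion", "duplication",
                "inversion")

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

## 0-based substring of a 0-based half-open interval
substr0 <- function(s, start, end) {
  if (end <= start) return("")
  substr(s, start + 1L, end)
}

empty_edit_script <- function() {
  data.frame(chrom = character(0), type = character(0), pos = integer(0),
             len = integer(0), src_start = integer(0), seq = character(0),
             stringsAsFactors = FALSE)
}

validate_edit_script <- function(edits, chrom_sizes) {
  if (nrow(edits) == 0L) return(invisible(edits))
  stopifnot(all(edits$type %in% EDIT_TYPES), all(edits$len > 0L))
  span_end <- edits$pos + ifelse(edits$type %in% c("insertion", "duplication"),
                                 0L, edits$len)
  for (cc in unique(edits$chrom)) {
    sel <- edits$chrom == cc
    ord <- order(edits$pos[sel])
    p <- edits$pos[sel][ord]
    e <- span_end[sel][ord]
    if (any(p < 1L) || any(e > chrom_sizes[[cc]] - 1L)) {
      stop("edits must leave >= 1 unedited base at each chromosome end",
           call. = FALSE)
    }
    if (length(p) > 1L && any(p[-1L] <= e[-length(e)])) {
      stop("edits overlap or touch on the old assembly", call. = FALSE)
    }
  }
  invisible(edits)
}

#' Generate a random edit script
#'
#' Edits are placed on a lattice of non-overlapping segments so they never
#' overlap or touch; sequence payloads (inserted/substituted bases) are
#' drawn here so that applying the script is deterministic.
#'
#' @param chrom_sizes named integer vector of old-assembly chromosome sizes.
#' @param edit_density expected edits per base (e.g. `1e-3`); 0 gives an
#'   empty script.
#' @return edit-script data.frame (`chrom`, `type`, `pos`, `len`,
#'   `src_start`, `seq`).
#' @export
random_edit_script <- function(chrom_sizes, edit_density) {
  out <- empty_edit_script()
  if (edit_density <= 0) return(out)
  for (cc in names(chrom_sizes)) {
    size <- chrom_sizes[[cc]]
    n_edits <- min(round(edit_density * size), max(0L, size %/% 200L - 2L))
    if (n_edits < 1L) next
    # one edit per 200 bp segment, away from the chromosome ends
    segs <- sort(sample(seq_len(size %/% 200L - 2L), n_edits))
    for (sg in segs) {
      pos <- sg * 200L + sample(0:100, 1L)
      type <- sample(EDIT_TYPES, 1L)
      len <- switch(type,
                    substitution = sample(1:20, 1L),
                    insertion = sample(1:30, 1L),
                    deletion = sample(1:30, 1L),
                    duplication = sample(10:30, 1L),
                    inversion = sample(20:50, 1L))
      src_start <- if (type == "duplication") {
        max(1L, pos - 120L)  # copy a nearby upstream block
      } else NA_integer_
      seq <- if (type %in% c("substitution", "insertion")) {
        random_dna(len)
      } else NA_character_
      out <- rbind(out, data.frame(chrom = cc, type = type, pos = pos,
                                   len = len, src_start = src_start,
                                   seq = seq, stringsAsFactors = FALSE))
    }
  }
  validate_edit_script(out, chrom_sizes)
  out
}

#' Apply an edit script to a genome
#'
#' @param genome named character vector of chromosome sequences (old
#'   assembly).
#' @param edits edit-script data.frame.
#' @return named character vector of new-assembly sequences.
#' @export
apply_edit_script <- function(genome, edits) {
  validate_edit_script(edits, vapply(genome, nchar, 0L))
  out <- genome
  for (cc in names(genome)) {
    e <- edits[edits$chrom == cc, , drop = FALSE]
    if (nrow(e) == 0L) next
    e <- e[order(e$pos), , drop = FALSE]
    old <- genome[[cc]]
    pieces <- character(0)
    cursor <- 0L
    for (k in seq_len(nrow(e))) {
      pieces <- c(pieces, substr0(old, cursor, e$pos[k]))
      if (e$type[k] == "substitution") {
        pieces <- c(pieces, e$seq[k]); cursor <- e$pos[k] + e$len[k]
      } else if (e$type[k] == "insertion") {
        pieces <- c(pieces, e$seq[k]); cursor <- e$pos[k]
      } else if (e$type[k] == "deletion") {
        cursor <- e$pos[k] + e$len[k]
      } else if (e$type[k] == "duplication") {
        pieces <- c(pieces, substr0(old, e$src_start[k],
                                    e$src_start[k] + e$len[k]))
        cursor <- e$pos[k]
      } else if (e$type[k] == "inversion") {
        pieces <- c(pieces,
                    revcomp_chr(substr0(old, e$pos[k], e$pos[k] + e$len[k])))
        cursor <- e$pos[k] + e$len[k]
      }
    }
    pieces <- c(pieces, substr0(old, cursor, nchar(old)))
    out[[cc]] <- paste(pieces, collapse = "")
  }
  out
}

#' Build a seeded pair of assemblies
#'
#' @param seed integer seed fixing all randomness.
#' @param chrom_sizes named integer vector of old-assembly sizes.
#' @param edit_density expected edits per base.
#' @return list with `old`, `new` (named character vectors) and `edits`.
#' @export
build_assembly_pair <- function(seed, chrom_sizes, edit_density = 1e-3) {
  set.seed(seed)
  old <- vapply(chrom_sizes, random_dna, "")
  edits <- random_edit_script(chrom_sizes, edit_density)
  list(old = old, new = apply_edit_script(old, edits), edits = edits)
}

## New-assembly position of an old-assembly base, from the edit script
## alone (the coordinate oracle, independent of chain arithmetic).
## NA for bases inside deletions or substitutions; inversions map reversed.
map_old_point <- function(edits, chrom, pos) {
  e <- edits[edits$chrom == chrom, , drop = FALSE]
  vapply(pos, function(p) {
    gain <- sum(e$len[e$type %in% c("insertion", "duplication") & e$pos <= p])
    loss <- sum(e$len[e$type == "deletion" & (e$pos + e$len) <= p])
    inside_del <- any(e$type %in% c("deletion", "substitution") &
                        e$pos <= p & p < e$pos + e$len)
    if (inside_del) return(NA_integer_)
    inv <- which(e$type == "inversion" & e$pos <= p & p < e$pos + e$len)
    if (length(inv) == 1L) {
      a <- e$pos[inv]; b <- a + e$len[inv]
      return(as.integer(a + gain + (b - 1L - p)))
    }
    as.integer(p + gain - loss)
  }, 0L)
}

## New interval of an old interval that crosses no deletion, substitution
## or inversion (insertions inside it stretch the result).
map_old_interval <- function(edits, chrom, start, end) {
  s <- map_old_point(edits, chrom, start)
  e <- map_old_point(edits, chrom, end - 1L)
  stopifnot(!is.na(s), !is.na(e))
  c(s, e + 1L)
}

#' Derive the true chain set of an edit script
#'
#' Blocks encode exactly the unedited segments: deletions become old-side
#' (dt) gaps, insertions and duplicated destination copies become new-side
#' (dq) gaps (the destination copy is not chained, mimicking ambiguous new
#' sequence), substitutions become double-sided gaps, and each inversion
#' yields an additional minus-strand chain covering the inverted segment.
#'
#' @param edits edit-script data.frame.
#' @param chrom_sizes named integer vector of old-assembly sizes.
#' @return `chain_set` (see [parse_chains()]).
#' @export
derive_chain <- function(edits, chrom_sizes) {
  validate_edit_script(edits, chrom_sizes)
  chains <- list()
  cid <- 0L
  for (cc in names(chrom_sizes)) {
    old_size <- chrom_sizes[[cc]]
    e <- edits[edits$chrom == cc, , drop = FALSE]
    e <- e[order(e$pos), , drop = FALSE]
    new_size <- old_size +
      sum(e$len[e$type %in% c("insertion", "duplication")]) -
      sum(e$len[e$type == "deletion"])
    size <- integer(0); dt <- integer(0); dq <- integer(0)
    block_start <- 0L
    inv_list <- list()
    for (k in seq_len(nrow(e))) {
      size <- c(size, e$pos[k] - block_start)
      if (e$type[k] %in% c("insertion", "duplication")) {
        dt <- c(dt, 0L); dq <- c(dq, e$len[k])
        block_start <- e$pos[k]
      } else if (e$type[k] == "deletion") {
        dt <- c(dt, e$len[k]); dq <- c(dq, 0L)
        block_start <- e$pos[k] + e$len[k]
      } else {  # substitution or inversion: unaligned on both sides
        dt <- c(dt, e$len[k]); dq <- c(dq, e$len[k])
        block_start <- e$pos[k] + e$len[k]
        if (e$type[k] == "inversion") inv_list[[length(inv_list) + 1L]] <- k
      }
    }
    size <- c(size, old_size - block_start); dt <- c(dt, 0L); dq <- c(dq, 0L)
    cid <- cid + 1L
    main <- new_chain(score = sum(size), old_chrom = cc,
                      old_size = old_size, old_start = 0L,
                      old_end = old_size, new_chrom = cc,
                      new_size = new_size, new_strand = "+",
                      new_start = 0L, new_end = new_size,
                      chain_id = as.character(cid),
                      blocks = data.frame(size = size, dt = dt, dq = dq))
    validate_chain(main)
    chains[[length(chains) + 1L]] <- main
    for (k in unlist(inv_list)) {
      a <- e$pos[k]; len <- e$len[k]
      plus_start <- map_old_point(e, cc, a - 1L) + 1L  # base after left flank
      cid <- cid + 1L
      inv_chain <- new_chain(score = len, old_chrom = cc,
                             old_size = old_size, old_start = a,
                             old_end = a + len, new_chrom = cc,
                             new_size = new_size, new_strand = "-",
                             new_start = new_size - (plus_start + len),
                             new_end = new_size - plus_start,
                             chain_id = as.character(cid),
                             blocks = data.frame(size = len, dt = 0L,
                                                 dq = 0L))
      validate_chain(inv_chain)
      chains[[length(chains) + 1L]] <- inv_chain
    }
  }
  as_chain_set(chains)
}

## negative-binomial-like CTSS count model: per-position base rate x
## per-library scale x small multiplicative noise
sim_counts <- function(lambda, scales, noise_sd = 0.05) {
  vapply(scales, function(s) {
    stats::rpois(length(lambda), lambda * s * exp(stats::rnorm(length(lambda),
                                                               0, noise_sd)))
  }, integer(length(lambda)))
}

#' Simulate a complete seeded fixture
#'
#' Builds an old/new assembly pair, its true chain set, planted peaks of
#' five engineered fates in controlled proportions (clean; inside a deletion
#' -> dropped; CTSS withheld -> problematic/unsupported; same-strand overlap
#' pairs -> one member excluded; straddling an insertion -> length-changed),
#' DPI-like called peaks (lifted clean peaks plus peaks in novel inserted
#' sequence), transcript models near clean peaks, per-library CTSS simulated
#' under known library scale factors, and the truth labels for everything.
#'
#' @param seed integer seed fixing all randomness.
#' @param n_peaks number of planted peaks (>= 20); default 240.
#' @param n_libraries number of CTSS libraries; must match
#'   `length(scale_factors)`.
#' @param scale_factors true per-library scale factors; default `c(1, 2, 4)`.
#' @param fate_fractions named fractions of peaks per fate
#'   (`clean`, `dropped`, `unsupported`, `overlap`, `length_changed`).
#' @param n_novel number of DPI peaks planted in novel (inserted) sequence.
#' @param old_assembly,new_assembly assembly labels.
#' @return list: `old`, `new` (genomes), `edits`, `chains`, `peaks` (old
#'   assembly, state `input`), `dpi_peaks` (new assembly), `transcripts`,
#'   `ctss` (named list per library), `truth` (per planted peak),
#'   `dpi_truth` (per DPI peak), `scale_factors`, assembly labels.
#' @export
simulate_fixture <- function(seed, n_peaks = 240L, n_libraries = 3L,
                             scale_factors = c(1, 2, 4),
                             fate_fractions = c(clean = 0.6, dropped = 0.1,
                                                unsupported = 0.1,
                                                overlap = 0.1,
                                                length_changed = 0.1),
                             n_novel = 20L,
                             old_assembly = "asmOld",
                             new_assembly = "asmNew") {
  stopifnot(n_peaks >= 20L, length(scale_factors) == n_libraries,
            abs(sum(fate_fractions) - 1) < 1e-8)
  set.seed(seed)
  n_pair_peaks <- 2L * max(1L, round(fate_fractions[["overlap"]] * n_peaks / 2))
  n_dropped <- max(1L, round(fate_fractions[["dropped"]] * n_peaks))
  n_unsup <- max(1L, round(fate_fractions[["unsupported"]] * n_peaks))
  n_len <- max(1L, round(fate_fractions[["length_changed"]] * n_peaks))
  n_clean <- n_peaks - n_pair_peaks - n_dropped - n_unsup - n_len
  stopifnot(n_clean >= 1L)
  n_bg <- 8L
  n_extra <- 9L  # decorative substitution/duplication/inversion edits
  n_slots <- n_clean + n_dropped + n_unsup + n_pair_peaks %/% 2L + n_len +
    n_novel + n_bg + n_extra
  slot_w <- 400L
  chrom <- "chrT"
  chrom_size <- (n_slots + 2L) * slot_w
  old <- stats::setNames(random_dna(chrom_size), chrom)

  fates <- c(rep("clean", n_clean), rep("dropped", n_dropped),
             rep("unsupported", n_unsup),
             rep("overlap_pair", n_pair_peaks %/% 2L),
             rep("length_changed", n_len), rep("novel", n_novel),
             rep("background", n_bg), rep("extra_edit", n_extra))
  slot_of <- sample(seq_len(n_slots))  # shuffle slot order
  slot_start <- (slot_of) * slot_w  # slot 0 and the last slot stay empty

  edits <- empty_edit_script()
  add_edit <- function(type, pos, len, src_start = NA_integer_,
                       seq = NA_character_) {
    edits <<- rbind(edits, data.frame(chrom = chrom, type = type,
                                      pos = as.integer(pos),
                                      len = as.integer(len),
                                      src_start = as.integer(src_start),
                                      seq = seq, stringsAsFactors = FALSE))
  }

  pk <- list()   # planted peaks, old coordinates
  add_peak <- function(start, w, strand, fate, expected_lift, expected_state,
                       expected_length_changed, expected_supported) {
    pk[[length(pk) + 1L]] <<- data.frame(
      chrom = chrom, start = as.integer(start), end = as.integer(start + w),
      strand = strand, fate = fate, expected_lift = expected_lift,
      expected_state = expected_state,
      expected_length_changed = expected_length_changed,
      expected_supported = expected_supported, stringsAsFactors = FALSE)
  }

  novel_slots <- integer(0)
  bg_slots <- integer(0)
  extra_i <- 0L
  for (k in seq_along(fates)) {
    s0 <- slot_start[k]
    w <- sample(10:40, 1L)
    strand <- sample(STRANDS, 1L)
    p0 <- s0 + 100L
    if (fates[k] == "clean") {
      add_peak(p0, w, strand, "clean", "mapped", "fair", FALSE, TRUE)
    } else if (fates[k] == "dropped") {
      add_peak(p0, w, strand, "dropped", "dropped", "dropped", FALSE, FALSE)
      add_edit("deletion", p0 - 5L, w + 10L)
    } else if (fates[k] == "unsupported") {
      add_peak(p0, w, strand, "unsupported", "mapped", "problematic",
               FALSE, FALSE)
    } else if (fates[k] == "overlap_pair") {
      # A longer, B shorter, same strand, 10 bp overlap: B gets excluded
      add_peak(p0, 30L, strand, "overlap_kept", "mapped", "fair",
               FALSE, TRUE)
      add_peak(p0 + 20L, 20L, strand, "overlap_excluded", "mapped",
               "problematic", FALSE, TRUE)
    } else if (fates[k] == "length_changed") {
      ins_len <- sample(2:8, 1L)
      add_peak(p0, w, strand, "length_changed", "mapped", "fair",
               TRUE, TRUE)
      add_edit("insertion", p0 + w %/% 2L, ins_len,
               seq = random_dna(ins_len))
      # an extra base of engineered stretch is guaranteed: ins_len >= 2
    } else if (fates[k] == "novel") {
      add_edit("insertion", p0, 80L, seq = random_dna(80L))
      novel_slots <- c(novel_slots, p0)
    } else if (fates[k] == "background") {
      bg_slots <- c(bg_slots, s0)
    } else if (fates[k] == "extra_edit") {
      extra_i <- extra_i + 1L
      if (extra_i %% 3L == 0L) {
        add_edit("substitution", p0, sample(5:15, 1L))
      } else if (extra_i %% 3L == 1L) {
        add_edit("duplication", p0, 20L, src_start = s0 + 10L)
      } else {
        add_edit("inversion", p0, 40L)
      }
    }
  }
  # substitution payload must match its length
  subs <- which(edits$type == "substitution")
  for (i in subs) edits$seq[i] <- random_dna(edits$len[i])
  edits <- edits[order(edits$pos), , drop = FALSE]
  rownames(edits) <- NULL
  chrom_sizes <- stats::setNames(chrom_size, chrom)
  validate_edit_script(edits, chrom_sizes)

  new <- apply_edit_script(old, edits)
  chains <- derive_chain(edits, chrom_sizes)

  peaks_truth <- do.call(rbind, pk)
  peaks <- data.frame(
    chrom = peaks_truth$chrom, start = peaks_truth$start,
    end = peaks_truth$end, strand = peaks_truth$strand,
    coord_id = format_coord_id(peaks_truth$chrom, peaks_truth$start,
                               peaks_truth$end, peaks_truth$strand),
    accession = NA_character_, assembly = old_assembly, state = "input",
    provenance = "", stringsAsFactors = FALSE
  )
  truth <- cbind(coord_id = peaks$coord_id,
                 peaks_truth[c("fate", "expected_lift", "expected_state",
                               "expected_length_changed",
                               "expected_supported")])

  # new-assembly intervals of every mapped peak, from the edit-script
  # coordinate oracle (independent of the chain machinery)
  mapped_idx <- which(truth$expected_lift == "mapped")
  new_iv <- t(vapply(mapped_idx, function(i) {
    map_old_interval(edits, chrom, peaks$start[i], peaks$end[i])
  }, c(0L, 0L)))

  # CTSS simulation: supported peaks get 1-3 positions inside their new
  # interval; background slots add genome-wide tags outside any peak
  lib_ids <- sprintf("lib%02d", seq_len(n_libraries))
  ctss_pos <- integer(0); ctss_strand <- character(0)
  ctss_lambda <- numeric(0)
  for (r in seq_along(mapped_idx)) {
    i <- mapped_idx[r]
    if (!truth$expected_supported[i]) next
    npos <- sample(1:3, 1L)
    lo <- new_iv[r, 1L]; hi <- new_iv[r, 2L] - 1L
    pos <- sort(sample(lo:hi, min(npos, hi - lo + 1L)))
    ctss_pos <- c(ctss_pos, pos)
    ctss_strand <- c(ctss_strand, rep(peaks$strand[i], length(pos)))
    ctss_lambda <- c(ctss_lambda, stats::runif(length(pos), 5, 50))
  }
  novel_dpi <- list()
  for (p0 in novel_slots) {
    # the 80 bp inserted block occupies new [map(p0) - 80, map(p0))
    ins_start <- map_old_point(edits, chrom, p0) - 80L
    w <- sample(12:30, 1L)
    strand <- sample(STRANDS, 1L)
    novel_dpi[[length(novel_dpi) + 1L]] <- data.frame(
      chrom = chrom, start = ins_start + 10L, end = ins_start + 10L + w,
      strand = strand, stringsAsFactors = FALSE)
    pos <- sort(sample((ins_start + 10L):(ins_start + 9L + w), 2L))
    ctss_pos <- c(ctss_pos, pos)
    ctss_strand <- c(ctss_strand, rep(strand, 2L))
    ctss_lambda <- c(ctss_lambda, stats::runif(2L, 5, 50))
  }
  for (s0 in bg_slots) {
    pos <- s0 + sort(sample(0:(slot_w - 1L), 5L))
    new_pos <- map_old_point(edits, chrom, pos)
    keep <- !is.na(new_pos)
    ctss_pos <- c(ctss_pos, new_pos[keep])
    ctss_strand <- c(ctss_strand, sample(STRANDS, sum(keep), replace = TRUE))
    ctss_lambda <- c(ctss_lambda, stats::runif(sum(keep), 1, 5))
  }
  counts <- matrix(sim_counts(ctss_lambda, scale_factors),
                   ncol = n_libraries)
  ctss <- stats::setNames(lapply(seq_len(n_libraries), function(j) {
    keep <- counts[, j] > 0L
    data.frame(chrom = chrom, pos = ctss_pos[keep],
               strand = ctss_strand[keep], count = counts[keep, j],
               library_id = lib_ids[j], stringsAsFactors = FALSE)
  }), lib_ids)

  # DPI set: lifted clean peaks plus the novel-sequence peaks
  clean_rows <- which(truth$fate == "clean")
  clean_new <- t(vapply(clean_rows, function(i) {
    map_old_interval(edits, chrom, peaks$start[i], peaks$end[i])
  }, c(0L, 0L)))
  dpi <- rbind(
    data.frame(chrom = chrom, start = clean_new[, 1L], end = clean_new[, 2L],
               strand = peaks$strand[clean_rows], stringsAsFactors = FALSE),
    do.call(rbind, novel_dpi)
  )
  dpi$coord_id <- format_coord_id(dpi$chrom, dpi$start, dpi$end, dpi$strand)
  dpi$accession <- NA_character_
  dpi$assembly <- new_assembly
  dpi$state <- "input"
  dpi$provenance <- "dpi"
  dpi_truth <- data.frame(coord_id = dpi$coord_id,
                          expected_added = c(rep(FALSE, length(clean_rows)),
                                             rep(TRUE, length(novel_dpi))),
                          stringsAsFactors = FALSE)

  # transcript models: TSS at the new start of the first clean peaks
  n_tx <- min(30L, length(clean_rows))
  tx_rows <- clean_rows[seq_len(n_tx)]
  transcripts <- data.frame(
    transcript_id = sprintf("TX%04d", seq_len(n_tx)),
    chrom = chrom,
    strand = peaks$strand[tx_rows],
    tss = clean_new[seq_len(n_tx), 1L],
    gene_id = sprintf("G%04d", seq_len(n_tx)),
    gene_symbol = sprintf("GENE%d", seq_len(n_tx)),
    tss_class = rep(c("pol2", "pol2", "non_pol2"), length.out = n_tx),
    protein_id = ifelse(seq_len(n_tx) %% 2L == 0L,
                        sprintf("P%04d", seq_len(n_tx)), ""),
    source_rank = 1L,
    stringsAsFactors = FALSE
  )
  # minus-strand transcripts take the 5'-most base at the right edge
  minus <- transcripts$strand == "-"
  transcripts$tss[minus] <- clean_new[seq_len(n_tx), 2L][minus] - 1L

  list(old = old, new = new, edits = edits, chains = chains, peaks = peaks,
       dpi_peaks = dpi, transcripts = transcripts, ctss = ctss,
       truth = truth, dpi_truth = dpi_truth, scale_factors = scale_factors,
       old_assembly = old_assembly, new_assembly = new_assembly,
       chrom_sizes = chrom_sizes)
}

#' Write a fixture bundle to disk
#'
#' Emits FASTA genomes, the chain file, peak/DPI/CTSS BED files, and
#' transcript/truth TSV tables, ready to drive [run_pipeline()].
#'
#' @param fx fixture list from [simulate_fixture()].
#' @param dir output directory (created if needed).
#' @return named character vector of written file paths.
#' @export
write_fixture <- function(fx, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(fx$old),
                              p("old_genome.fa"))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(fx$new),
                              p("new_genome.fa"))
  write_chains(fx$chains, p("old_to_new.chain"))
  write_peaks(fx$peaks, p("peaks_old.bed"), use_full_id = FALSE)
  write_peaks(fx$dpi_peaks, p("dpi_peaks.bed"), use_full_id = FALSE)
  ctss_paths <- character(0)
  for (lib in names(fx$ctss)) {
    f <- p(sprintf("ctss_%s.bed", lib))
    write_ctss(fx$ctss[[lib]], f)
    ctss_paths[lib] <- f
  }
  utils::write.table(fx$transcripts, p("transcripts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(fx$truth, p("truth_labels.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(fx$dpi_truth, p("dpi_truth_labels.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  c(old_genome = p("old_genome.fa"), new_genome = p("new_genome.fa"),
    chain = p("old_to_new.chain"), peaks = p("peaks_old.bed"),
    dpi = p("dpi_peaks.bed"), ctss_paths,
    transcripts = p("transcripts.tsv"), truth = p("truth_labels.tsv"),
    dpi_truth = p("dpi_truth_labels.tsv"))
}
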