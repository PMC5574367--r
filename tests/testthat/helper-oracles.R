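# Independent oracles and generators used across the suite.

# Map one old-assembly base through a chain by walking the blocks one by
# one (no shared arithmetic with the implementation).
oracle_map_base <- function(ch, b) {
  o <- ch$old_start
  n <- ch$new_start
  for (k in seq_len(nrow(ch$blocks))) {
    sz <- ch$blocks$size[k]
    if (b >= o && b < o + sz) return(n + (b - o))
    o <- o + sz + ch$blocks$dt[k]
    n <- n + sz + ch$blocks$dq[k]
  }
  NA_integer_
}

# Brute-force lift: map every base of the interval individually, pick the
# chain with the most mapped bases (score desc, chain id asc on ties), and
# span the mapped images.
oracle_lift <- function(iv, chains, min_match = 1.0) {
  bases <- iv$start:(iv$end - 1L)
  len <- length(bases)
  cand <- Filter(Negate(is.null), lapply(chains, function(ch) {
    if (ch$old_chrom != iv$chrom) return(NULL)
    mapped <- vapply(bases, function(b) oracle_map_base(ch, b), 0L)
    list(ch = ch, mapped = mapped, n = sum(!is.na(mapped)))
  }))
  drop <- function(reason, mf) {
    list(status = "dropped", new_interval = NULL, matched_fraction = mf,
         drop_reason = reason)
  }
  if (length(cand) == 0L) return(drop("unmapped", 0))
  n <- vapply(cand, `[[`, 0L, "n")
  if (all(n == 0L)) return(drop("unmapped", 0))
  score <- vapply(cand, function(x) x$ch$score, 0)
  id <- vapply(cand, function(x) x$ch$chain_id, "")
  best <- cand[[order(-n, -score, id)[1L]]]
  mf <- best$n / len
  if (mf < min_match) {
    union_cov <- sum(Reduce(`|`, lapply(cand, function(x) !is.na(x$mapped))))
    reason <- if (union_cov / len >= min_match) "split" else "partial"
    return(drop(reason, mf))
  }
  ch <- best$ch
  pos <- best$mapped[!is.na(best$mapped)]
  if (ch$new_strand == "-") {
    start <- ch$new_size - 1L - max(pos)
    end <- ch$new_size - min(pos)
    strand <- setdiff(c("+", "-"), iv$strand)
  } else {
    start <- min(pos)
    end <- max(pos) + 1L
    strand <- iv$strand
  }
  list(status = "mapped",
       new_interval = data.frame(chrom = ch$new_chrom, start = start,
                                 end = end, strand = strand,
                                 stringsAsFactors = FALSE),
       matched_fraction = mf, drop_reason = NA_character_)
}

# Random small chain for property tests.
random_test_chain <- function(id, old_chrom = "chrO", new_chrom = "chrN") {
  nb <- sample(1:5, 1L)
  size <- sample(1:30, nb, replace = TRUE)
  dt <- c(sample(0:15, max(nb - 1L, 0L), replace = TRUE), 0L)
  dq <- c(sample(0:15, max(nb - 1L, 0L), replace = TRUE), 0L)
  old_start <- sample(0:50, 1L)
  new_start <- sample(0:50, 1L)
  old_span <- sum(size + dt)
  new_span <- sum(size + dq)
  peaklift:::new_chain(
    score = sample(1:1000, 1L), old_chrom = old_chrom,
    old_size = old_start + old_span + sample(0:20, 1L),
    old_start = old_start, old_end = old_start + old_span,
    new_chrom = new_chrom,
    new_size = new_start + new_span + sample(0:20, 1L),
    new_strand = sample(c("+", "-"), 1L),
    new_start = new_start, new_end = new_start + new_span,
    chain_id = as.character(id),
    blocks = data.frame(size = size, dt = dt, dq = dq)
  )
}

# Identity chain over [0, size) of one chromosome.
identity_chain <- function(chrom = "chr1", size = 1000L, id = "1") {
  peaklift:::new_chain(score = size, old_chrom = chrom, old_size = size,
                       old_start = 0L, old_end = size, new_chrom = chrom,
                       new_size = size, new_strand = "+", new_start = 0L,
                       new_end = size, chain_id = id,
                       blocks = data.frame(size = size, dt = 0L, dq = 0L))
}

chain_set_of <- function(...) peaklift:::as_chain_set(list(...))

# Swap the two sides of a plus-strand chain.
invert_chain <- function(ch) {
  peaklift:::new_chain(score = ch$score, old_chrom = ch$new_chrom,
                       old_size = ch$new_size, old_start = ch$new_start,
                       old_end = ch$new_end, new_chrom = ch$old_chrom,
                       new_size = ch$old_size, new_strand = "+",
                       new_start = ch$old_start, new_end = ch$old_end,
                       chain_id = ch$chain_id,
                       blocks = data.frame(size = ch$blocks$size,
                                           dt = ch$blocks$dq,
                                           dq = ch$blocks$dt))
}

# Quadratic strand-aware overlap oracle.
oracle_overlap_pairs <- function(a, b) {
  out <- list()
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] == b$chrom[j] && a$strand[i] == b$strand[j] &&
          a$start[i] < b$end[j] && b$start[j] < a$end[i]) {
        out[[length(out) + 1L]] <- c(i, j)
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(a_idx = integer(0), b_idx = integer(0)))
  }
  m <- do.call(rbind, out)
  data.frame(a_idx = m[, 1L], b_idx = m[, 2L])
}

# Minimal peak data.frame builder.
mk_peaks <- function(start, end, strand, chrom = "chr1") {
  n <- length(start)
  data.frame(chrom = rep(chrom, length.out = n), start = as.integer(start),
             end = as.integer(end), strand = strand,
             coord_id = format_coord_id(rep(chrom, length.out = n),
                                        start, end, strand),
             accession = NA_character_, assembly = "test", state = "input",
             provenance = "", stringsAsFactors = FALSE)
}

mk_ctss <- function(pos, strand, count = 1L, chrom = "chr1",
                    library_id = "lib1") {
  data.frame(chrom = chrom, pos = as.integer(pos), strand = strand,
             count = as.integer(rep(count, length.out = length(pos))),
             library_id = library_id, stringsAsFactors = FALSE)
}
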