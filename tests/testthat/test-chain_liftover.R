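test_that("chain files parse, validate block sums, and round-trip", {
  f <- withr::local_tempfile()
  writeLines(c("chain 100 chr1 1000 + 0 1000 chr1 1000 + 0 1000 1",
               "1000", ""), f)
  cs <- parse_chains(f)
  expect_length(cs, 1L)
  expect_equal(nrow(cs[[1]]$blocks), 1L)
  expect_equal(cs[[1]]$blocks$size, 1000L)

  # blocks summing short of the header span
  writeLines(c("chain 100 chr1 1000 + 0 1000 chr1 1000 + 0 1000 7",
               "900", ""), f)
  expect_error(parse_chains(f), "chain 7")

  # two chains on different chromosomes index separately
  writeLines(c("chain 5 chr1 100 + 0 100 chrA 100 + 0 100 1", "100", "",
               "chain 5 chr2 50 + 0 50 chrB 50 + 0 50 2", "50", ""), f)
  cs <- parse_chains(f)
  expect_setequal(names(attr(cs, "by_chrom")), c("chr1", "chr2"))

  g <- withr::local_tempfile()
  write_chains(cs, g)
  cs2 <- parse_chains(g)
  expect_equal(lapply(cs2, `[`, c("old_chrom", "old_start", "old_end",
                                  "new_chrom", "new_strand", "blocks")),
               lapply(cs, `[`, c("old_chrom", "old_start", "old_end",
                                 "new_chrom", "new_strand", "blocks")))
})

test_that("identity chains lift intervals onto themselves", {
  cs <- chain_set_of(identity_chain("chr1", 1000L))
  res <- lift_interval(list(chrom = "chr1", start = 100L, end = 110L,
                            strand = "+"), cs, 1.0)
  expect_equal(res$status, "mapped")
  expect_equal(res$new_interval$start, 100L)
  expect_equal(res$new_interval$end, 110L)
  expect_equal(res$new_interval$strand, "+")
  expect_equal(res$matched_fraction, 1.0)
  set.seed(3)
  for (i in 1:20) {
    s <- sample(0:990, 1L)
    iv <- list(chrom = "chr1", start = s, end = s + sample(1:10, 1L),
               strand = sample(c("+", "-"), 1L))
    r <- lift_interval(iv, cs, 1.0)
    expect_equal(r$new_interval$start, iv$start)
    expect_equal(r$new_interval$end, iv$end)
    expect_equal(r$new_interval$strand, iv$strand)
  }
})

test_that("block arithmetic stretches intervals across new-assembly gaps", {
  # blocks: 100 aligned, 20 bp inserted on the new side, 100 aligned
  ch <- peaklift:::new_chain(score = 1, old_chrom = "chr1", old_size = 300L,
                             old_start = 0L, old_end = 200L,
                             new_chrom = "chrN", new_size = 300L,
                             new_strand = "+", new_start = 0L,
                             new_end = 220L, chain_id = "1",
                             blocks = data.frame(size = c(100L, 100L),
                                                 dt = c(0L, 0L),
                                                 dq = c(20L, 0L)))
  cs <- chain_set_of(ch)
  r <- lift_interval(list(chrom = "chr1", start = 150L, end = 160L,
                          strand = "+"), cs, 1.0)
  expect_equal(r$status, "mapped")
  expect_equal(r$new_interval$start, 170L)
  expect_equal(r$new_interval$end, 180L)
  # an interval spanning the gap grows by the insertion length
  r2 <- lift_interval(list(chrom = "chr1", start = 90L, end = 110L,
                           strand = "+"), cs, 1.0)
  expect_equal(r2$new_interval$end - r2$new_interval$start, 40L)
  expect_equal(r2$matched_fraction, 1.0)
})

test_that("partial coverage drops at minMatch=1 with the right fraction", {
  ch <- peaklift:::new_chain(score = 1, old_chrom = "chr1", old_size = 200L,
                             old_start = 0L, old_end = 100L,
                             new_chrom = "chrN", new_size = 100L,
                             new_strand = "+", new_start = 0L,
                             new_end = 100L, chain_id = "1",
                             blocks = data.frame(size = 100L, dt = 0L,
                                                 dq = 0L))
  cs <- chain_set_of(ch)
  r <- lift_interval(list(chrom = "chr1", start = 90L, end = 110L,
                          strand = "+"), cs, 1.0)
  expect_equal(r$status, "dropped")
  expect_equal(r$drop_reason, "partial")
  expect_equal(r$matched_fraction, 0.5)
  # the same interval passes at min_match 0.5
  r2 <- lift_interval(list(chrom = "chr1", start = 90L, end = 110L,
                           strand = "+"), cs, 0.5)
  expect_equal(r2$status, "mapped")
  expect_equal(r2$new_interval$start, 90L)
  expect_equal(r2$new_interval$end, 100L)
})

test_that("intervals coverable only by combining chains drop as split", {
  mk <- function(old_start, new_start, id) {
    peaklift:::new_chain(score = 1, old_chrom = "chr1", old_size = 200L,
                         old_start = old_start, old_end = old_start + 50L,
                         new_chrom = "chrN", new_size = 500L,
                         new_strand = "+", new_start = new_start,
                         new_end = new_start + 50L, chain_id = id,
                         blocks = data.frame(size = 50L, dt = 0L, dq = 0L))
  }
  cs <- chain_set_of(mk(0L, 0L, "1"), mk(50L, 300L, "2"))
  r <- lift_interval(list(chrom = "chr1", start = 40L, end = 60L,
                          strand = "+"), cs, 1.0)
  expect_equal(r$status, "dropped")
  expect_equal(r$drop_reason, "split")
  expect_equal(r$matched_fraction, 0.5)
})

test_that("minus-strand chains flip coordinates and strand", {
  ch <- peaklift:::new_chain(score = 1, old_chrom = "chr1", old_size = 100L,
                             old_start = 10L, old_end = 60L,
                             new_chrom = "chrN", new_size = 200L,
                             new_strand = "-", new_start = 20L,
                             new_end = 70L, chain_id = "1",
                             blocks = data.frame(size = 50L, dt = 0L,
                                                 dq = 0L))
  cs <- chain_set_of(ch)
  iv <- list(chrom = "chr1", start = 10L, end = 20L, strand = "+")
  r <- lift_interval(iv, cs, 1.0)
  expect_equal(r$status, "mapped")
  expect_equal(r$new_interval$strand, "-")
  # agreement with the per-base oracle on the flip arithmetic
  o <- oracle_lift(iv, cs, 1.0)
  expect_equal(r$new_interval, o$new_interval)
})

test_that("lifting agrees with the per-base oracle on random chains", {
  set.seed(202)
  for (rep in 1:200) {
    chains <- lapply(seq_len(sample(1:3, 1L)), random_test_chain)
    cs <- peaklift:::as_chain_set(chains)
    lo <- min(vapply(chains, `[[`, 0L, "old_start"))
    hi <- max(vapply(chains, `[[`, 0L, "old_end"))
    s <- sample(max(0L, lo - 5L):(hi + 5L), 1L)
    iv <- list(chrom = "chrO", start = s, end = s + sample(1:25, 1L),
               strand = sample(c("+", "-"), 1L))
    mm <- sample(c(1.0, 0.8, 0.5), 1L)
    got <- lift_interval(iv, cs, mm)
    want <- oracle_lift(iv, cs, mm)
    expect_equal(got$status, want$status)
    expect_equal(got$matched_fraction, want$matched_fraction)
    expect_equal(got$drop_reason, want$drop_reason)
    expect_equal(got$new_interval, want$new_interval)
  }
})

test_that("lift_peaks partitions exhaustively and tallies drops", {
  cs <- chain_set_of(identity_chain("chr1", 1000L))
  pk <- rbind(mk_peaks(c(10, 500), c(20, 520), c("+", "-")),
              mk_peaks(5, 15, "+", chrom = "chrZ"))  # absent chromosome
  res <- lift_peaks(pk, cs, 1.0, "new")
  expect_equal(nrow(res$mapped) + nrow(res$dropped), nrow(pk))
  expect_equal(res$dropped$drop_reason, "unmapped")
  expect_equal(res$dropped$chrom, "chrZ")
  expect_equal(res$mapped$assembly, c("new", "new"))
  expect_equal(res$mapped$old_start, c(10L, 500L))
  expect_equal(res$drop_by_chrom$n_dropped, 1L)
  # all peaks inside one identity chain: dropped list empty
  res2 <- lift_peaks(mk_peaks(c(1, 50), c(9, 70), c("+", "+")), cs)
  expect_equal(nrow(res2$dropped), 0L)
})

test_that("lifting forward then through the inverse chain returns the input", {
  set.seed(404)
  for (rep in 1:25) {
    ch <- random_test_chain(1)
    ch$new_strand <- "+"
    ch <- peaklift:::new_chain(ch$score, ch$old_chrom, ch$old_size,
                               ch$old_start, ch$old_end, ch$new_chrom,
                               ch$new_size, "+", ch$new_start, ch$new_end,
                               ch$chain_id, ch$blocks)
    fwd <- chain_set_of(ch)
    rev <- chain_set_of(invert_chain(ch))
    # pick an interval fully inside one aligned block: no bases lost
    k <- sample(nrow(ch$blocks), 1L)
    bs <- ch$ostart[k]
    w <- min(ch$blocks$size[k], sample(1:10, 1L))
    iv <- list(chrom = ch$old_chrom, start = bs, end = bs + w, strand = "+")
    there <- lift_interval(iv, fwd, 1.0)
    expect_equal(there$status, "mapped")
    back <- lift_interval(list(chrom = there$new_interval$chrom,
                               start = there$new_interval$start,
                               end = there$new_interval$end,
                               strand = there$new_interval$strand),
                          rev, 1.0)
    expect_equal(back$new_interval$start, iv$start)
    expect_equal(back$new_interval$end, iv$end)
  }
})
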