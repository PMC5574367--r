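test_that("assembly pairs are seeded, deterministic, and edit-consistent", {
  a <- build_assembly_pair(5, c(chrA = 4000L), edit_density = 0)
  expect_identical(a$old, a$new)
  expect_equal(nrow(a$edits), 0L)

  b1 <- build_assembly_pair(6, c(chrA = 6000L, chrB = 4000L),
                            edit_density = 2e-3)
  b2 <- build_assembly_pair(6, c(chrA = 6000L, chrB = 4000L),
                            edit_density = 2e-3)
  expect_identical(b1, b2)
  expect_gt(nrow(b1$edits), 0L)

  # a single deletion shortens the new chromosome by its length
  edits <- data.frame(chrom = "chrA", type = "deletion", pos = 500L,
                      len = 100L, src_start = NA_integer_,
                      seq = NA_character_, stringsAsFactors = FALSE)
  new <- apply_edit_script(a$old[1], edits)
  expect_equal(nchar(new), nchar(a$old[1]) - 100L)
  # everything outside the deletion is untouched
  expect_equal(substr(new, 1, 500), substr(a$old[1], 1, 500))
  expect_equal(substr(new, 501, nchar(new)),
               substr(a$old[1], 601, nchar(a$old[1])))
})

test_that("derived chains encode edits as the right gaps", {
  sizes <- c(chrA = 2000L)
  # empty script: one identity chain per chromosome
  cs0 <- derive_chain(peaklift:::empty_edit_script(), sizes)
  expect_length(cs0, 1L)
  expect_equal(cs0[[1]]$blocks, data.frame(size = 2000L, dt = 0L, dq = 0L))

  # deletion of d at pos p: two blocks with dt = d between them
  del <- data.frame(chrom = "chrA", type = "deletion", pos = 700L,
                    len = 50L, src_start = NA_integer_, seq = NA_character_,
                    stringsAsFactors = FALSE)
  cs <- derive_chain(del, sizes)
  expect_equal(cs[[1]]$blocks$size, c(700L, 1250L))
  expect_equal(cs[[1]]$blocks$dt, c(50L, 0L))
  expect_equal(cs[[1]]$blocks$dq, c(0L, 0L))
  expect_equal(cs[[1]]$new_size, 1950L)
  # flanking probes: left side fixed, right side shifted by -d
  left <- lift_interval(list(chrom = "chrA", start = 100L, end = 120L,
                             strand = "+"), cs, 1.0)
  expect_equal(left$new_interval$start, 100L)
  right <- lift_interval(list(chrom = "chrA", start = 800L, end = 820L,
                              strand = "+"), cs, 1.0)
  expect_equal(right$new_interval$start, 750L)

  # insertion becomes a dq gap
  ins <- data.frame(chrom = "chrA", type = "insertion", pos = 700L,
                    len = 30L, src_start = NA_integer_, seq = strrep("A", 30),
                    stringsAsFactors = FALSE)
  csi <- derive_chain(ins, sizes)
  expect_equal(csi[[1]]$blocks$dq, c(30L, 0L))
  expect_equal(csi[[1]]$new_size, 2030L)

  # inversion adds a minus-strand chain over the inverted segment
  inv <- data.frame(chrom = "chrA", type = "inversion", pos = 1000L,
                    len = 40L, src_start = NA_integer_, seq = NA_character_,
                    stringsAsFactors = FALSE)
  csv <- derive_chain(inv, sizes)
  expect_length(csv, 2L)
  expect_equal(csv[[2]]$new_strand, "-")
  r <- lift_interval(list(chrom = "chrA", start = 1010L, end = 1020L,
                          strand = "+"), csv, 1.0)
  expect_equal(r$status, "mapped")
  expect_equal(r$new_interval$strand, "-")
  # reversal arithmetic: old [1010,1020) sits 10 bp into the inversion, so
  # its image ends 10 bp before the inversion's right edge (still at 1040)
  expect_equal(r$new_interval$start, 1020L)
  expect_equal(r$new_interval$end, 1030L)
})

test_that("random derived chains satisfy block-sum invariants and match the
           per-base oracle on probe intervals", {
  for (seed in 1:3) {
    pair <- build_assembly_pair(seed, c(chrA = 8000L), edit_density = 2e-3)
    cs <- derive_chain(pair$edits, c(chrA = 8000L))
    # validate_chain runs inside derive_chain; also check genome lengths
    expect_equal(nchar(pair$new[["chrA"]]),
                 cs[[1]]$new_size)
    # probe intervals vs the brute-force per-base oracle
    set.seed(seed + 100)
    for (k in 1:30) {
      s <- sample(0:7950, 1L)
      iv <- list(chrom = "chrA", start = s, end = s + sample(1:40, 1L),
                 strand = sample(c("+", "-"), 1L))
      got <- lift_interval(iv, cs, 1.0)
      want <- oracle_lift(iv, cs, 1.0)
      expect_equal(got$status, want$status)
      expect_equal(got$new_interval, want$new_interval)
      expect_equal(got$matched_fraction, want$matched_fraction)
    }
  }
})

test_that("chain files written by the fixture re-parse identically", {
  pair <- build_assembly_pair(9, c(chrA = 6000L), edit_density = 2e-3)
  cs <- derive_chain(pair$edits, c(chrA = 6000L))
  f <- withr::local_tempfile()
  write_chains(cs, f)
  cs2 <- parse_chains(f)
  expect_equal(length(cs2), length(cs))
  for (i in seq_along(cs)) {
    expect_equal(cs2[[i]]$blocks, cs[[i]]$blocks)
    expect_equal(cs2[[i]]$new_strand, cs[[i]]$new_strand)
    expect_equal(cs2[[i]]$new_start, cs[[i]]$new_start)
  }
})

test_that("fixtures are reproducible and cover every engineered fate", {
  fx1 <- simulate_fixture(3, n_peaks = 60)
  fx2 <- simulate_fixture(3, n_peaks = 60)
  expect_identical(fx1, fx2)
  expect_setequal(unique(fx1$truth$fate),
                  c("clean", "dropped", "unsupported", "overlap_kept",
                    "overlap_excluded", "length_changed"))
  # a different seed produces different data
  expect_false(identical(simulate_fixture(4, n_peaks = 60)$peaks, fx1$peaks))
  # planted peaks within a fixture never share a coordinate identifier
  expect_false(anyDuplicated(fx1$peaks$coord_id) > 0)
  # written bundles round-trip through the package readers
  dir <- withr::local_tempdir()
  paths <- write_fixture(fx1, dir)
  pk <- read_peaks(paths[["peaks"]], "asmOld")
  expect_equal(pk[c("chrom", "start", "end", "strand", "coord_id")],
               fx1$peaks[c("chrom", "start", "end", "strand", "coord_id")])
  cs <- parse_chains(paths[["chain"]])
  expect_equal(length(cs), length(fx1$chains))
  ct <- read_ctss(paths[["lib01"]], "lib01")
  expect_equal(ct, fx1$ctss$lib01, ignore_attr = TRUE)
})
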