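mk_tx <- function(tss, strand = "+", class = "pol2", id = "T1",
                  gene = "G1", symbol = "GENE1", protein = "",
                  rank = 1L, chrom = "chr1") {
  n <- max(length(tss), length(id))
  data.frame(transcript_id = rep(id, length.out = n),
             chrom = chrom, strand = rep(strand, length.out = n),
             tss = as.integer(rep(tss, length.out = n)),
             gene_id = rep(gene, length.out = n),
             gene_symbol = rep(symbol, length.out = n),
             tss_class = rep(class, length.out = n),
             protein_id = rep(protein, length.out = n),
             source_rank = rep(rank, length.out = n),
             stringsAsFactors = FALSE)
}

test_that("TSS inside the peak annotates at distance zero", {
  pk <- mk_peaks(1000, 1020, "+")
  ann <- associate_peaks(pk, mk_tx(1010))
  expect_true(ann$annotated)
  expect_equal(ann$distance, 0L)
  expect_equal(ann$gene_symbol, "GENE1")
})

test_that("class-dependent windows are inclusive at the boundary", {
  pk <- mk_peaks(1000, 1020, "+")
  # Pol-II: 500 bp beyond the edge annotates, 501 does not
  expect_true(associate_peaks(pk, mk_tx(1019 + 500))$annotated)
  expect_false(associate_peaks(pk, mk_tx(1019 + 501))$annotated)
  expect_true(associate_peaks(pk, mk_tx(1000 - 500))$annotated)
  expect_false(associate_peaks(pk, mk_tx(1000 - 501))$annotated)
  # non-Pol-II 5' ends: 50 bp limit
  expect_true(associate_peaks(pk, mk_tx(1019 + 50, class = "non_pol2"))$annotated)
  expect_false(associate_peaks(pk, mk_tx(1019 + 60, class = "non_pol2"))$annotated)
})

test_that("annotation is strand-matched and chooses the nearest TSS", {
  pk <- mk_peaks(1000, 1020, "+")
  expect_false(associate_peaks(pk, mk_tx(1010, strand = "-"))$annotated)
  tx <- rbind(mk_tx(1100, id = "FAR", gene = "GF", symbol = "FAR"),
              mk_tx(1030, id = "NEAR", gene = "GN", symbol = "NEAR"))
  ann <- associate_peaks(pk, tx)
  expect_equal(ann$transcript_id, "NEAR")
  expect_equal(ann$gene_symbol, "NEAR")
  expect_equal(ann$distance, 11L)  # signed: downstream of the peak
  # equidistant: all recorded, curated source wins the gene link
  tx2 <- rbind(mk_tx(990, id = "PRED", gene = "GP", symbol = "PRED",
                     rank = 2L),
               mk_tx(1029, id = "CUR", gene = "GC", symbol = "CUR",
                     rank = 1L))
  ann2 <- associate_peaks(pk, tx2)
  expect_equal(ann2$transcript_ids, "CUR,PRED")
  expect_equal(ann2$gene_symbol, "CUR")
})

test_that("missing gene symbols fall back to the gene id", {
  pk <- mk_peaks(1000, 1020, "+")
  ann <- associate_peaks(pk, mk_tx(1010, gene = "100132287", symbol = ""))
  expect_equal(ann$gene_symbol, "100132287")
  # no transcript hit leaves all gene fields empty
  ann2 <- associate_peaks(pk, mk_tx(5000))
  expect_false(ann2$annotated)
  expect_true(is.na(ann2$gene_id))
  expect_true(is.na(ann2$protein_id))
})

test_that("shrinking the window only removes annotations", {
  set.seed(21)
  s <- sample(0:5000, 40)
  pk <- mk_peaks(s, s + 20, sample(c("+", "-"), 40, replace = TRUE))
  tx <- mk_tx(sample(0:5000, 30), id = sprintf("T%02d", 1:30))
  tx$strand <- sample(c("+", "-"), 30, replace = TRUE)
  wide <- associate_peaks(pk, tx, window_pol2 = 500L)
  narrow <- associate_peaks(pk, tx, window_pol2 = 100L)
  expect_true(all(which(narrow$annotated) %in% which(wide$annotated)))
})

test_that("short names reuse the smallest free serial per gene", {
  pk <- mk_peaks(c(100, 300), c(120, 330), c("+", "+"))
  ann <- associate_peaks(pk, mk_tx(c(110, 310), id = c("T1", "T2")))
  # existing p1@GENE1 and p3@GENE1: the newcomer takes p2
  named <- assign_short_names(ann[1, ], c("p1@GENE1", "p3@GENE1"))
  expect_equal(named$short_name, "p2@GENE1")
  # expression rank orders serials: highest pooled count gets p1
  named2 <- assign_short_names(ann, character(0),
                               pooled_expression = c(10, 90))
  expect_equal(named2$short_name, c("p2@GENE1", "p1@GENE1"))
  # carried-over names are kept verbatim
  prior <- stats::setNames("p3@MTND1P23", ann$coord_id[1])
  named3 <- assign_short_names(ann, prior)
  expect_equal(named3$short_name[1], "p3@MTND1P23")
  # unannotated peaks fall back to the coordinate identifier
  un <- associate_peaks(mk_peaks(4000, 4010, "-"), mk_tx(110))
  named4 <- assign_short_names(un)
  expect_equal(named4$short_name, sprintf("p@%s", un$coord_id))
})

test_that("short names stay unique across a simulated registry", {
  set.seed(31)
  s <- seq(0, 9000, by = 300)
  pk <- mk_peaks(s, s + 20, "+")
  tx <- mk_tx(s + 5, id = sprintf("T%02d", seq_along(s)),
              gene = sprintf("G%d", seq_along(s) %% 7),
              symbol = sprintf("GENE%d", seq_along(s) %% 7))
  ann <- associate_peaks(pk, tx)
  named <- assign_short_names(ann, c("p1@GENE1", "p2@GENE3"),
                              pooled_expression = stats::runif(nrow(pk)))
  expect_false(anyDuplicated(named$short_name) > 0)
  expect_false(any(named$short_name %in% c("p1@GENE1", "p2@GENE3")))
})

test_that("category summaries tally annotated peaks per gene class", {
  pk <- mk_peaks(seq(0, 2500, by = 500), seq(20, 2520, by = 500), "+")
  tx <- mk_tx(pk$start + 5, id = sprintf("T%d", 1:6),
              gene = sprintf("G%d", 1:6), symbol = sprintf("S%d", 1:6))
  ann <- associate_peaks(pk, tx)
  cats <- data.frame(gene_id = sprintf("G%d", 1:5),
                     category = c("protein-coding", "protein-coding",
                                  "pseudogene", "miscRNA/miRNA",
                                  "protein-coding"),
                     stringsAsFactors = FALSE)
  s <- annotation_category_summary(ann, cats)
  expect_equal(s$by_category$n[s$by_category$category == "protein-coding"], 3L)
  expect_equal(s$by_category$n[s$by_category$category == "pseudogene"], 1L)
  expect_equal(s$by_category$n[s$by_category$category == "other/unknown"], 1L)
  expect_equal(sum(s$by_category$n), sum(ann$annotated))
  # empty annotation set: all zeros
  s0 <- annotation_category_summary(ann[0, ], cats)
  expect_true(all(s0$by_category$n == 0L))
})

test_that("transcript tables read with validation", {
  f <- withr::local_tempfile()
  utils::write.table(mk_tx(c(10, 20), id = c("A", "B")), f, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  tx <- read_transcripts(f)
  expect_equal(tx$tss, c(10L, 20L))
  bad <- mk_tx(10)
  bad$tss_class <- "rna_pol3"
  utils::write.table(bad, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_transcripts(f), "tss_class")
})
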