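cfg <- pipeline_config()

test_that("small-peptide genes are discounted exactly at the 3:1 boundary", {
  tx <- GenomicRanges::GRanges("c1", IRanges::IRanges(1001, 1280), "+")
  g <- GenomicRanges::GRanges("c1", IRanges::IRanges(1101, 1190), "-")
  g$gene_id <- "pep1"
  # gene 90 nt inside a 280-nt transcript: 280 > 3 x 90 -> removed
  expect_equal(length(effective_genes(tx, g, cfg)), 0L)
  # 270-nt transcript: 270 is not strictly greater than 270 -> retained
  tx270 <- GenomicRanges::GRanges("c1", IRanges::IRanges(1001, 1270), "+")
  expect_equal(length(effective_genes(tx270, g, cfg)), 1L)
  # a 100-nt gene is not a small peptide -> retained even in a long transcript
  g100 <- GenomicRanges::GRanges("c1", IRanges::IRanges(1101, 1200), "-")
  g100$gene_id <- "g100"
  tx400 <- GenomicRanges::GRanges("c1", IRanges::IRanges(1001, 1400), "+")
  expect_equal(length(effective_genes(tx400, g100, cfg)), 1L)
})

test_that("classification thresholds behave as inclusive 'at least' bounds", {
  # genes 35 nt away on both strands, no overlap -> intergenic
  genes <- rbind(gene_row(100, 400, "+", "gA"),
                 gene_row(636, 900, "-", "gB"))
  rec <- classify_case(436, 600, "+", genes)  # gaps: 436-400-1=35, 636-600-1=35
  expect_equal(rec$label, "intergenic")
  expect_equal(rec$nearest_same, 35L)
  expect_equal(rec$nearest_opposite, 35L)

  # same-strand gene 40 nt away; opposite-strand overlap exactly 10 -> antisense
  genes <- rbind(gene_row(100, 400, "+", "gA"),
                 gene_row(700, 1000, "-", "gB"))
  rec <- classify_case(441, 709, "+", genes)
  expect_equal(rec$label, "antisense")
  expect_equal(rec$antisense_genes[[1]]$overlap_nt, 10L)

  # opposite overlap 9 -> fails the bound; not intergenic either (gap 0)
  rec <- classify_case(441, 708, "+", genes)
  expect_equal(rec$label, "ambiguous")

  # 1-nt same-strand overlap -> coding
  genes <- gene_row(100, 400, "+", "gA")
  rec <- classify_case(400, 600, "+", genes)
  expect_equal(rec$label, "coding")

  # opposite-strand gene exactly 29 nt away, no overlap -> ambiguous
  genes <- gene_row(100, 400, "-", "gA")
  rec <- classify_case(430, 600, "+", genes)  # gap 430-400-1 = 29
  expect_equal(rec$label, "ambiguous")
  # and at 30 -> intergenic
  rec <- classify_case(431, 600, "+", genes)
  expect_equal(rec$label, "intergenic")
})

test_that("multiple antisense partners are ranked by overlap then id", {
  genes <- rbind(gene_row(450, 560, "-", "gB"),
                 gene_row(100, 500, "-", "gA"),
                 gene_row(570, 700, "-", "gC"))
  rec <- classify_case(440, 620, "+", genes)
  expect_equal(rec$label, "antisense")
  ag <- rec$antisense_genes[[1]]
  expect_equal(ag$gene_id, c("gB", "gA", "gC"))
  expect_equal(ag$overlap_nt, c(111L, 61L, 51L))
})

test_that("every transcript gets exactly one label", {
  set.seed(42)
  sim <- generate_community(n_contigs = 3, n_genes = 30, n_srnas = 30,
                            seed = 42)
  rec <- classify_transcripts(sim$transcripts, sim$annotation, cfg)
  expect_true(all(rec$label %in% c("intergenic", "antisense", "coding",
                                   "ambiguous")))
  expect_equal(nrow(rec), length(sim$transcripts))
})

test_that("tightening distance/overlap rules never grows the called sets", {
  sim <- generate_community(n_contigs = 3, n_genes = 40, n_srnas = 60,
                            seed = 11)
  n_int <- integer(0); n_as <- integer(0)
  for (d in c(10L, 30L, 60L, 120L)) {
    r <- classify_transcripts(sim$transcripts, sim$annotation,
                              pipeline_config(min_gene_distance = d))
    n_int <- c(n_int, sum(r$label == "intergenic"))
  }
  expect_true(all(diff(n_int) <= 0))
  for (ov in c(1L, 10L, 40L, 80L)) {
    r <- classify_transcripts(sim$transcripts, sim$annotation,
                              pipeline_config(min_antisense_overlap = ov))
    n_as <- c(n_as, sum(r$label == "antisense"))
  }
  expect_true(all(diff(n_as) <= 0))
})

test_that("longest reading frame matches a brute-force six-frame oracle", {
  expect_equal(longest_orf_fraction(strrep("A", 90)), 1.0)
  expect_equal(longest_orf_fraction("TAATAATAA"),
               oracle_orf_fraction("TAATAATAA"))
  expect_equal(longest_orf_fraction("AC"), 0)
  set.seed(77)
  for (i in 1:200) {
    s <- random_seq(sample(50:500, 1))
    expect_equal(longest_orf_fraction(s), oracle_orf_fraction(s))
  }
})

test_that("length and reading-frame filters pass exactly at their bounds", {
  L <- 20000L
  seq <- stop_seq <- srnapipe:::stop_dense_seq(L)
  ann <- make_annotation(c(c1 = L), sequences = c(c1 = seq))
  mk <- function(len, start = 1001L) {
    make_transcripts(data.frame(contig = "c1", start = start,
                                end = start + len - 1L, strand = "+",
                                transcript_id = paste0("t", len),
                                stringsAsFactors = FALSE))
  }
  for (case in list(c(49, TRUE), c(50, FALSE), c(500, FALSE), c(501, TRUE))) {
    tx <- mk(case[[1]])
    cat <- discover_srnas(ann, tx, cfg)
    expect_equal(cat$records$label, "intergenic")
    expect_equal(cat$records$length_fail, as.logical(case[[2]]),
                 info = paste("length", case[[1]]))
  }
  # reading-frame fraction just above one third fails
  tx <- mk(300L)
  ann_open <- make_annotation(
    c(c1 = L),
    sequences = c(c1 = paste0(substr(seq, 1, 1000), strrep("A", 300),
                              substr(seq, 1301, L)))
  )
  cat <- discover_srnas(ann_open, tx, cfg)
  expect_true(cat$records$orf_fail)
  expect_equal(cat$records$orf_fraction, 1.0)
})

test_that("edge-scan p-values agree with direct binomial tail summation", {
  # 30 of 100 candidates within 50 nt of an edge where p0(50) = 0.10
  contigs <- setNames(rep(1000L, 10L), sprintf("c%d", 1:10))
  ed <- c(rep(10L, 30L), rep(400L, 70L))
  rec <- data.frame(edge_distance = ed)
  er <- compute_edge_threshold(rec, contigs, cfg)
  row50 <- er$grid[er$grid$d == 50, ]
  expect_equal(row50$p0, 0.10)
  expect_equal(row50$k_in_zone, 30L)
  expect_equal(row50$pvalue, oracle_binom_tail(30, 100, 0.10),
               tolerance = 1e-12)
  # enrichment this strong pushes the threshold past 50 nt
  expect_gte(er$chosen_d, 50L)

  # candidates at contig centers -> no zone counts, threshold 0
  rec0 <- data.frame(edge_distance = rep(450L, 50L))
  expect_equal(compute_edge_threshold(rec0, contigs, cfg)$chosen_d, 0L)

  # no candidates -> empty report
  er0 <- compute_edge_threshold(data.frame(edge_distance = integer(0)),
                                contigs, cfg)
  expect_equal(er0$chosen_d, 0L)
  expect_equal(nrow(er0$grid), 0L)
})

test_that("discovery is deterministic and its provenance telescopes", {
  sim <- generate_community(n_contigs = 4, n_genes = 40, n_srnas = 50,
                            seed = 5)
  c1 <- discover_srnas(sim$annotation, sim$transcripts, cfg)
  c2 <- discover_srnas(sim$annotation, sim$transcripts, cfg)
  expect_identical(c1$records, c2$records)
  prov <- c1$provenance
  expect_true(all(prov$n_out[-nrow(prov)] == prov$n_in[-1]))
  surv <- surviving_records(c1)
  expect_equal(nrow(surv), prov$n_out[[nrow(prov)]])

  empty <- discover_srnas(sim$annotation, sim$transcripts[0], cfg)
  expect_equal(nrow(empty$records), 0L)
  expect_true(all(empty$provenance$n_in == 0L))

  bad_tx <- make_transcripts(data.frame(contig = "nope", start = 1, end = 100,
                                        strand = "+", transcript_id = "t",
                                        stringsAsFactors = FALSE))
  expect_error(discover_srnas(sim$annotation, bad_tx, cfg), "nope")
})
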