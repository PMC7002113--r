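test_that("contig taxonomy is a rank-wise weighted majority vote", {
  # unanimous two-rank lineage
  lin <- contig_taxonomy(c("Archaea;Halobacteria", "Archaea;Halobacteria"),
                         c(1, 1))
  expect_equal(unname(lin$names), c("Archaea", "Halobacteria"))
  expect_equal(unname(lin$support), c(1, 1))
  # weighted vote: 600 vs 300 -> Archaea at 2/3
  lin <- contig_taxonomy(c("Archaea", "Bacteria"), c(600, 300))
  expect_equal(unname(lin$names), "Archaea")
  expect_equal(unname(lin$support), 2 / 3)
  # an exact 0.5/0.5 tie keeps the lexicographically first name, flagged
  lin <- contig_taxonomy(c("Archaea", "Bacteria"), c(5, 5))
  expect_equal(unname(lin$names), "Archaea")
  expect_true(unname(lin$tie[[1]]))
  # descent stops when support drops below half
  lin <- contig_taxonomy(c("Archaea;Halobacteria", "Archaea;Methanomicrobia",
                           "Archaea;Nanohaloarchaea"), c(4, 3, 3))
  expect_equal(unname(lin$names), "Archaea")
  # empty input -> empty lineage
  expect_equal(length(contig_taxonomy(character(0), numeric(0))$names), 0L)
})

test_that("the vote ignores gene order and weight scale", {
  set.seed(17)
  lins <- c("Archaea;Halobacteria;Haloferacaceae", "Archaea;Halobacteria",
            "Bacteria;Cyanobacteria", "Archaea;Nanohaloarchaea")
  w <- c(900, 400, 700, 200)
  ref <- contig_taxonomy(lins, w)
  for (i in 1:5) {
    p <- sample(4)
    expect_equal(contig_taxonomy(lins[p], w[p]), ref)
  }
  expect_equal(contig_taxonomy(lins, w * 3.7), ref)
})

test_that("records inherit their contig's taxonomy", {
  rec <- record_rows(3)
  rec$contig <- c("c1", "c1", "c9")
  catalog <- make_catalog(rec)
  taxa <- list(c1 = contig_taxonomy("Archaea;Halobacteria", 1))
  expect_warning(out <- assign_srna_taxonomy(catalog, taxa), "c9")
  expect_equal(out$records$taxonomy,
               c("Archaea;Halobacteria", "Archaea;Halobacteria", NA))
  expect_identical(out$records$taxonomy[[1]], out$records$taxonomy[[2]])
})

test_that("overlap geometry projects onto the mRNA 5'->3' axis", {
  # plus-strand gene [101,200], antisense transcript [101,150] -> [0, 0.5]
  p <- overlap_profile(101, 150, 101, 200, "+")
  expect_equal(p$rel_start, 0)
  expect_equal(p$rel_end, 0.5)
  expect_equal(p$overlap_nt, 50L)
  # minus-strand gene: 5' end is the right edge
  p <- overlap_profile(151, 200, 101, 200, "-")
  expect_equal(p$rel_start, 0)
  expect_equal(p$rel_end, 0.5)
  # full-gene coverage
  p <- overlap_profile(51, 400, 101, 200, "+")
  expect_equal(c(p$rel_start, p$rel_end), c(0, 1))
  expect_error(overlap_profile(500, 600, 101, 200, "+"), "overlap")
})

test_that("overlap geometry is mirror-symmetric", {
  # mirroring both features about the contig midpoint and flipping strand
  # leaves relative coordinates unchanged
  L <- 10000
  set.seed(23)
  for (i in 1:20) {
    gs <- sample(1000:5000, 1); ge <- gs + sample(200:800, 1)
    as <- sample(gs:(ge - 50), 1); ae <- as + sample(60:900, 1)
    p1 <- overlap_profile(as, ae, gs, ge, "+")
    p2 <- overlap_profile(L - ae + 1, L - as + 1, L - ge + 1, L - gs + 1, "-")
    expect_equal(p2$rel_start, p1$rel_start)
    expect_equal(p2$rel_end, p1$rel_end)
  }
})

test_that("pair correlations recover exact relationships and flag NAs", {
  x <- matrix(seq(10, 100, by = 10), nrow = 1,
              dimnames = list("a1", sprintf("s%02d", 1:10)))
  ym <- rbind(x[1, ] * 2 + 5, -x[1, ] + 200, rep(4, 10))
  rownames(ym) <- c("pos", "neg", "flat")
  pairs <- data.frame(asrna_id = "a1", target_id = c("pos", "neg", "flat"),
                      stringsAsFactors = FALSE)
  pc <- pair_correlations(expression_matrix(x, "tpm"),
                          expression_matrix(ym, "tpm"), pairs)
  expect_equal(pc$pearson_r[1:2], c(1, -1))
  expect_true(pc$significant[[2]])
  expect_true(is.na(pc$pearson_r[[3]]))
  expect_error(
    pair_correlations(expression_matrix(x[, 1:2, drop = FALSE], "tpm"),
                      expression_matrix(ym, "tpm"), pairs),
    "3 shared samples")
})

test_that("upstream regions are strand-aware and truncate at contig edges", {
  set.seed(29)
  seq <- random_seq(300)
  ann <- make_annotation(c(c1 = 300L), sequences = c(c1 = seq))
  rec <- function(s, e, str) {
    data.frame(contig = "c1", start = s, end = e, strand = str,
               stringsAsFactors = FALSE)
  }
  # plus strand starting at 101: bases [51, 100]
  u <- extract_upstream(rec(101L, 200L, "+"), ann)
  expect_equal(u$sequence, substr(seq, 51, 100))
  expect_false(u$truncated)
  # minus strand ending at 200: reverse complement of [201, 250]
  u <- extract_upstream(rec(120L, 200L, "-"), ann)
  expect_equal(u$sequence, oracle_revcomp(substr(seq, 201, 250)))
  # start at 21 leaves only 20 nt -> truncated
  u <- extract_upstream(rec(21L, 100L, "+"), ann)
  expect_equal(nchar(u$sequence), 20L)
  expect_true(u$truncated)
  # no upstream room at all
  u <- extract_upstream(rec(1L, 100L, "+"), ann)
  expect_equal(u$sequence, "")
  expect_true(u$truncated)
})

test_that("interaction density keeps the top-ranked records and conserves mass", {
  recs <- data.frame(
    srna_id = "s1",
    target_id = sprintf("m%03d", 1:150),
    srna_start = 10L, srna_end = 20L,
    energy = -5, pvalue = seq(1e-6, 0.15, length.out = 150),
    stringsAsFactors = FALSE
  )
  d <- interaction_density(recs[1:100, ], 100L)
  expect_equal(d$counts[10:20], rep(100L, 11))
  expect_equal(sum(d$counts), 100L * 11L)
  expect_equal(d$peak, 10L)
  # 150 supplied, only the 100 lowest p contribute
  d <- interaction_density(recs, 100L)
  expect_equal(d$n_used, 100L)
  expect_equal(max(d$counts), 100L)
  # mass conservation against spans
  set.seed(37)
  recs2 <- data.frame(
    srna_id = "s1", target_id = sprintf("m%03d", 1:80),
    srna_start = sample(1:50, 80, TRUE),
    energy = runif(80, -20, -1), pvalue = runif(80),
    stringsAsFactors = FALSE
  )
  recs2$srna_end <- recs2$srna_start + sample(0:40, 80, TRUE)
  d2 <- interaction_density(recs2, 100L)
  expect_equal(sum(d2$counts),
               sum(recs2$srna_end - recs2$srna_start + 1L))
  # empty input and bad positions
  expect_equal(sum(interaction_density(recs[0, ], 50L)$counts), 0L)
  bad <- recs[1, ]; bad$srna_end <- 200L
  expect_error(interaction_density(bad, 100L), "outside")
})

test_that("ranking by energy is available and breaks ties deterministically", {
  recs <- data.frame(
    srna_id = "s1", target_id = c("b", "a", "c"),
    srna_start = c(1L, 20L, 40L), srna_end = c(5L, 25L, 45L),
    energy = c(-20, -10, -5), pvalue = c(0.5, 0.01, 0.01),
    stringsAsFactors = FALSE
  )
  cfg1 <- pipeline_config(top_n_interactions = 1)
  by_p <- interaction_density(recs, 50L, cfg1)
  expect_equal(which(by_p$counts > 0), 20:25)  # lowest p, tie -> lower energy
  by_e <- interaction_density(recs, 50L, cfg1, rank_by = "energy")
  expect_equal(which(by_e$counts > 0), 1:5)    # lowest energy
})
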