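test_that("coverage thresholds pass at the bound and fail below it", {
  rec <- rbind(record_rows(3, label = "intergenic"),
               record_rows(2, label = "antisense"))
  rec$transcript_id <- sprintf("t%03d", 1:5)
  rec$coverage <- c(5.0, 4.9, 80, 9.9, 10.0)
  out <- apply_coverage_thresholds(make_catalog(rec))
  expect_equal(out$records$coverage_fail, c(FALSE, TRUE, FALSE, TRUE, FALSE))
  # absent coverage fails, with a warning
  rec$coverage[[3]] <- NA
  expect_warning(out <- apply_coverage_thresholds(make_catalog(rec)), "t003")
  expect_true(out$records$coverage_fail[[3]])
})

em <- function(vals, kind, map = NULL) {
  expression_matrix(vals, kind = kind, feature_to_contig = map)
}

test_that("contig normalization is the documented ratio and is shift-invariant", {
  tv <- matrix(c(20, 0, 40, 10), nrow = 2,
               dimnames = list(c("t1", "t2"), c("s1", "s2")))
  cv <- matrix(c(1000, 500, 2000, 1000), nrow = 2,
               dimnames = list(c("c1", "c2"), c("s1", "s2")))
  map <- c(t1 = "c1", t2 = "c2")
  norm <- normalize_counts(em(tv, "raw_count", map), em(cv, "raw_count"))
  expect_equal(norm$values["t1", "s1"], 20 / 1000 * 1e6)
  expect_equal(norm$values["t2", "s1"], 0)
  # doubling one contig's reads (transcript and contig alike) changes nothing
  tv2 <- tv; cv2 <- cv
  tv2["t1", "s2"] <- tv2["t1", "s2"] * 2
  cv2["c1", "s2"] <- cv2["c1", "s2"] * 2
  norm2 <- normalize_counts(em(tv2, "raw_count", map), em(cv2, "raw_count"))
  expect_equal(norm2$values["t1", "s2"], norm$values["t1", "s2"])
  # a transcript with reads on a read-free contig is inconsistent input
  cv3 <- cv; cv3["c1", "s1"] <- 0
  expect_error(normalize_counts(em(tv, "raw_count", map), em(cv3, "raw_count")),
               "inconsistent")
})

test_that("standardized TPM is the transcript/contig TPM ratio", {
  tv <- matrix(c(50, 120, 0), nrow = 3,
               dimnames = list(c("t1", "t2", "t3"), "s1"))
  cv <- matrix(c(50, 40, 0), nrow = 3,
               dimnames = list(c("c1", "c2", "c3"), "s1"))
  map <- c(t1 = "c1", t2 = "c2", t3 = "c3")
  st <- standardized_tpm(em(tv, "tpm", map), em(cv, "tpm"))
  expect_equal(unname(st$values[, "s1"]), c(1.0, 3.0, 0))
})

test_that("bh_fdr matches a hand-stepped adjustment", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
  set.seed(31)
  p <- runif(200)
  expect_equal(bh_fdr(p), oracle_bh(p))
  expect_true(all(bh_fdr(p) >= p))
})

sim_counts <- function(nf, n, mu1, mu2 = mu1, size = 10, seed = 1) {
  set.seed(seed)
  m <- cbind(matrix(rnbinom(nf * n, mu = mu1, size = size), nrow = nf),
             matrix(rnbinom(nf * n, mu = mu2, size = size), nrow = nf))
  dimnames(m) <- list(sprintf("f%04d", 1:nf),
                      c(sprintf("a%02d", 1:n), sprintf("b%02d", 1:n)))
  m
}

design_for <- function(m, n) {
  setNames(rep(c("g1", "g2"), each = n), colnames(m))
}

test_that("degenerate features are handled explicitly", {
  m <- sim_counts(50, 5, 100)
  m[1, ] <- 7      # identical counts -> no change, p ~ 1
  m[2, ] <- 0      # all-zero -> excluded, NA
  de <- differential_expression(em(m, "normalized_count"),
                                design_for(m, 5))
  expect_equal(de$log2fc[[1]], 0)
  expect_gt(de$pvalue[[1]], 0.95)
  expect_true(is.na(de$pvalue[[2]]))
  expect_false(de$significant[[2]])
  # group with < 2 samples is an error
  bad_design <- setNames(c("g1", rep("g2", 9)), colnames(m))
  expect_error(differential_expression(em(m, "normalized_count"), bad_design),
               "at least 2")
})

test_that("DE is invariant to sample order and label swap flips the sign", {
  m <- sim_counts(200, 6, 100, 160, seed = 8)
  d <- design_for(m, 6)
  de <- differential_expression(em(m, "normalized_count"), d)
  perm <- sample(ncol(m))
  de_perm <- differential_expression(em(m[, perm], "normalized_count"),
                                     d[perm])
  expect_equal(de_perm$pvalue, de$pvalue)
  expect_equal(de_perm$log2fc, de$log2fc)
  # relabel so the former group 2 becomes group 1
  d_swap <- setNames(ifelse(d == "g1", "zz", "aa"), names(d))
  de_swap <- differential_expression(
    em(m, "normalized_count"), factor(d_swap, levels = c("aa", "zz")))
  expect_equal(de_swap$log2fc, -de$log2fc)
  expect_equal(de_swap$pvalue, de$pvalue)
})

test_that("the count scale does not affect DE decisions", {
  tv <- sim_counts(150, 5, 150, 300, seed = 12)
  cv <- matrix(rep(colSums(tv), each = 2) + 5000, nrow = 2,
               dimnames = list(c("c1", "c2"), colnames(tv)))
  map <- setNames(rep(c("c1", "c2"), length.out = nrow(tv)), rownames(tv))
  d <- design_for(tv, 5)
  de1 <- differential_expression(
    normalize_counts(em(tv, "raw_count", map), em(cv, "raw_count"),
                     pipeline_config(count_scale = 1e6)), d)
  de2 <- differential_expression(
    normalize_counts(em(tv, "raw_count", map), em(cv, "raw_count"),
                     pipeline_config(count_scale = 37)), d)
  expect_equal(de1$pvalue, de2$pvalue, tolerance = 1e-12)
  expect_equal(de1$significant, de2$significant)
})

test_that("the significant set shrinks as the FDR cutoff tightens", {
  m <- sim_counts(300, 6, 100, 170, seed = 21)
  d <- design_for(m, 6)
  n_sig <- vapply(c(0.1, 0.05, 0.01), function(a) {
    sum(differential_expression(em(m, "normalized_count"), d,
                                pipeline_config(de_fdr = a))$significant)
  }, numeric(1))
  expect_true(all(diff(n_sig) <= 0))
})
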