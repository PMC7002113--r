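# Run code under a fixed seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# 15-mer whose tiling keeps the longest stop-free stretch at <= 12 nt in all
# six reading frames, so a planted noncoding transcript of any length >= 50
# has a reading-frame fraction <= 0.24 < 1/3 regardless of phase.
STOP_DENSE_UNIT <- "AACCGTTAGTTAATT"

stop_dense_seq <- function(len, phase = 0L) {
  u <- STOP_DENSE_UNIT
  tiled <- strrep(u, ceiling((len + phase) / nchar(u)) + 1L)
  substr(tiled, phase + 1L, phase + len)
}

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

#' Generate a ground-truthed synthetic community
#'
#' Builds a complete fixture bundle for the discovery pipeline: an assembly
#' (FASTA), a gene annotation (GFF3), assembled transcripts with coverage
#' and TPM attributes (GTF), and a truth table of planted labels. Planted
#' intergenic sRNAs sit 40 nt (a safety margin past the 30-nt rule) from
#' their flanking genes; planted antisense sRNAs overlap an opposite-strand
#' gene by 60 nt; decoys sit exactly one nt inside each rule boundary
#' (29/30 nt gap, 9/10 nt overlap, 49/50/500/501 nt length, 4.9/5.0 and
#' 9.9/10.0 coverage), plus small-peptide discounting cases at the stated
#' 3:1 boundary and a reading-frame-fail decoy. Planted noncoding sequences
#' are stop-dense in all six frames; every feature keeps >= 600 nt from
#' contig ends so the edge filter is exercised only by its own simulations.
#' Output is deterministic for a given seed.
#'
#' @param n_contigs Number of contigs (>= 1). Default 5.
#' @param n_genes Minimum number of gene features; background genes are
#'   added beyond those the planted cassettes require. Default 100.
#' @param n_srnas Number of planted regular sRNAs (intergenic + antisense +
#'   coding decoys), on top of the fixed boundary-decoy set. Default 200.
#' @param seed Integer seed.
#' @param cfg A \code{\link{pipeline_config}}; thresholds define the planted
#'   margins.
#' @param out_dir Optional directory; when given, writes
#'   \code{assembly.fasta}, \code{genes.gff3}, \code{transcripts.gtf} and
#'   \code{truth.tsv} there.
#' @return A list: \code{annotation} (a \code{\link{genome_annotation}}),
#'   \code{transcripts} (GRanges), \code{truth} (data frame with
#'   \code{transcript_id}, \code{kind}, \code{true_label} and expected flag
#'   columns), and \code{paths} when \code{out_dir} was given.
#' @export
generate_community <- function(n_contigs = 5L, n_genes = 100L,
                               n_srnas = 200L, seed = 1L,
                               cfg = pipeline_config(), out_dir = NULL) {
  stopifnot(n_contigs >= 1L, n_srnas >= 0L)
  with_seed(seed, {
    edge_pad <- 600L
    gap_between <- 200L
    d_safe <- cfg$min_gene_distance + 10L   # planted margin: 40 nt
    ov_safe <- cfg$min_antisense_overlap + 50L  # planted overlap: 60 nt
    gene_len <- 300L
    cov_pass <- 50

    genes <- list(); txs <- list(); truth <- list()
    cursor <- rep(edge_pad, n_contigs)
    gi <- 0L; ti <- 0L

    add_gene <- function(contig, start, len, strand) {
      gi <<- gi + 1L
      genes[[gi]] <<- data.frame(contig = contig, start = start,
                                 end = start + len - 1L, strand = strand,
                                 gene_id = sprintf("gene_%04d", gi),
                                 stringsAsFactors = FALSE)
      genes[[gi]]
    }
    add_tx <- function(contig, start, len, strand, cov, tpm, kind, label,
                       length_fail = FALSE, coverage_fail = FALSE,
                       orf_fail = FALSE, seq_kind = "stop_dense",
                       margin = NA_real_) {
      ti <<- ti + 1L
      txs[[ti]] <<- data.frame(contig = contig, start = start,
                               end = start + len - 1L, strand = strand,
                               transcript_id = sprintf("tx_%04d", ti),
                               coverage = cov, tpm = tpm,
                               seq_kind = seq_kind,
                               stringsAsFactors = FALSE)
      truth[[ti]] <<- data.frame(transcript_id = sprintf("tx_%04d", ti),
                                 kind = kind, true_label = label,
                                 length_fail = length_fail,
                                 coverage_fail = coverage_fail,
                                 orf_fail = orf_fail, margin = margin,
                                 stringsAsFactors = FALSE)
      txs[[ti]]
    }

    # each cassette returns the nt it consumed on the contig
    cassette <- function(contig, at, kind) {
      s <- sample(c("+", "-"), 1L)
      o <- if (s == "+") "-" else "+"
      switch(kind,
        intergenic = {
          L <- sample(60:220, 1L)
          add_gene(contig, at, gene_len, s)
          add_tx(contig, at + gene_len + d_safe, L, s, cov_pass, 10,
                 "intergenic", "intergenic", margin = d_safe)
          add_gene(contig, at + gene_len + d_safe + L + d_safe, gene_len, o)
          2L * gene_len + 2L * d_safe + L
        },
        antisense = {
          gl <- 400L
          L <- sample(80:260, 1L)
          add_gene(contig, at, gl, o)
          # overlap the gene's right end by ov_safe, extend rightward
          add_tx(contig, at + gl - ov_safe, L, s, cov_pass, 10,
                 "antisense", "antisense", margin = ov_safe)
          gl - ov_safe + L
        },
        coding = {
          L <- 150L
          add_gene(contig, at, gene_len, s)
          add_tx(contig, at + 100L, L, s, cov_pass, 10, "coding", "coding")
          gene_len
        },
        decoy_gap = {
          # opposite-strand gene exactly (min_gene_distance - 1) nt away
          d <- cfg$min_gene_distance - 1L
          L <- 120L
          add_gene(contig, at, gene_len, o)
          add_tx(contig, at + gene_len + d, L, s, cov_pass, 10,
                 "decoy_gap_29", "ambiguous", margin = d)
          gene_len + d + L
        },
        boundary_gap = {
          d <- cfg$min_gene_distance
          L <- 120L
          add_gene(contig, at, gene_len, o)
          add_tx(contig, at + gene_len + d, L, s, cov_pass, 10,
                 "boundary_gap_30", "intergenic", margin = d)
          gene_len + d + L
        },
        decoy_same_gap = {
          # same-strand gene one nt inside the rule -> ambiguous
          d <- cfg$min_gene_distance - 1L
          L <- 120L
          add_gene(contig, at, gene_len, s)
          add_tx(contig, at + gene_len + d, L, s, cov_pass, 10,
                 "decoy_same_gap_29", "ambiguous", margin = d)
          gene_len + d + L
        },
        decoy_overlap = {
          ov <- cfg$min_antisense_overlap - 1L
          gl <- 400L; L <- 120L
          add_gene(contig, at, gl, o)
          add_tx(contig, at + gl - ov, L, s, cov_pass, 10,
                 "decoy_overlap_9", "ambiguous", margin = ov)
          gl - ov + L
        },
        boundary_overlap = {
          ov <- cfg$min_antisense_overlap
          gl <- 400L; L <- 120L
          add_gene(contig, at, gl, o)
          add_tx(contig, at + gl - ov, L, s, cov_pass, 10,
                 "boundary_overlap_10", "antisense", margin = ov)
          gl - ov + L
        },
        len_edge = {
          # four length cases in one call via closure state
          NULL
        },
        smallpep_removed = {
          # 90-nt same-strand gene inside a 280-nt transcript: 280 > 3 x 90,
          # gene discounted -> intergenic
          gl <- 90L; L <- 280L
          add_gene(contig, at, gene_len, o)
          tx_start <- at + gene_len + d_safe
          add_tx(contig, tx_start, L, s, cov_pass, 10,
                 "smallpep_removed", "intergenic")
          add_gene(contig, tx_start + 100L, gl, s)
          add_gene(contig, tx_start + L + d_safe, gene_len, o)
          2L * gene_len + 2L * d_safe + L
        },
        smallpep_kept = {
          # 90-nt gene inside a 270-nt transcript: 270 is NOT > 3 x 90,
          # gene kept -> coding
          gl <- 90L; L <- 270L
          add_gene(contig, at, gene_len, o)
          tx_start <- at + gene_len + d_safe
          add_tx(contig, tx_start, L, s, cov_pass, 10,
                 "smallpep_kept", "coding")
          add_gene(contig, tx_start + 100L, gl, s)
          add_gene(contig, tx_start + L + d_safe, gene_len, o)
          2L * gene_len + 2L * d_safe + L
        },
        orf_fail = {
          L <- 150L
          add_gene(contig, at, gene_len, s)
          add_tx(contig, at + gene_len + d_safe, L, s, cov_pass, 10,
                 "orf_fail", "intergenic", orf_fail = TRUE,
                 seq_kind = "open_frame")
          add_gene(contig, at + gene_len + d_safe + L + d_safe, gene_len, o)
          2L * gene_len + 2L * d_safe + L
        },
        gene_only = {
          add_gene(contig, at, gene_len, s)
          gene_len
        },
        stop("unknown cassette kind: ", kind)
      )
    }

    len_cassette <- function(contig, at, L, expect_fail) {
      s <- sample(c("+", "-"), 1L)
      o <- if (s == "+") "-" else "+"
      add_gene(contig, at, gene_len, s)
      add_tx(contig, at + gene_len + d_safe, L, s, cov_pass, 10,
             sprintf("len_%d", L), "intergenic",
             length_fail = expect_fail, margin = L)
      add_gene(contig, at + gene_len + d_safe + L + d_safe, gene_len, o)
      2L * gene_len + 2L * d_safe + L
    }
    cov_cassette <- function(contig, at, cov, kind, expect_fail) {
      s <- sample(c("+", "-"), 1L)
      o <- if (s == "+") "-" else "+"
      if (kind == "intergenic") {
        L <- 120L
        add_gene(contig, at, gene_len, s)
        add_tx(contig, at + gene_len + d_safe, L, s, cov, 10,
               sprintf("cov_it_%.1f", cov), "intergenic",
               coverage_fail = expect_fail, margin = cov)
        add_gene(contig, at + gene_len + d_safe + L + d_safe, gene_len, o)
        2L * gene_len + 2L * d_safe + L
      } else {
        gl <- 400L; L <- 120L
        add_gene(contig, at, gl, o)
        add_tx(contig, at + gl - ov_safe, L, s, cov, 10,
               sprintf("cov_as_%.1f", cov), "antisense",
               coverage_fail = expect_fail, margin = cov)
        gl - ov_safe + L
      }
    }

    # plan: regular sRNAs + one of each boundary/decoy case
    n_it <- max(0L, round(n_srnas * 0.4))
    n_as <- max(0L, round(n_srnas * 0.4))
    n_cd <- max(0L, n_srnas - n_it - n_as)
    plan <- c(rep("intergenic", n_it), rep("antisense", n_as),
              rep("coding", n_cd),
              "decoy_gap", "boundary_gap", "decoy_same_gap",
              "decoy_overlap", "boundary_overlap",
              "smallpep_removed", "smallpep_kept", "orf_fail")
    plan <- sample(plan)  # shuffle across contigs

    ci <- 0L
    for (kind in plan) {
      ci <- ci %% n_contigs + 1L
      used <- cassette(ci, cursor[[ci]], kind)
      cursor[[ci]] <- cursor[[ci]] + used + gap_between
    }
    # fixed-length and coverage boundary cases
    for (L in c(49L, 50L, 500L, 501L)) {
      ci <- ci %% n_contigs + 1L
      used <- len_cassette(ci, cursor[[ci]], L, L < cfg$min_len | L > cfg$max_len)
      cursor[[ci]] <- cursor[[ci]] + used + gap_between
    }
    cov_cases <- list(
      list(cfg$cov_threshold_intergenic - 0.1, "intergenic", TRUE),
      list(cfg$cov_threshold_intergenic, "intergenic", FALSE),
      list(cfg$cov_threshold_antisense - 0.1, "antisense", TRUE),
      list(cfg$cov_threshold_antisense, "antisense", FALSE)
    )
    for (cc in cov_cases) {
      ci <- ci %% n_contigs + 1L
      used <- cov_cassette(ci, cursor[[ci]], cc[[1]], cc[[2]], cc[[3]])
      cursor[[ci]] <- cursor[[ci]] + used + gap_between
    }
    # top up background genes
    while (gi < n_genes) {
      ci <- ci %% n_contigs + 1L
      used <- cassette(ci, cursor[[ci]], "gene_only")
      cursor[[ci]] <- cursor[[ci]] + used + gap_between
    }

    genes <- do.call(rbind, genes)
    txs <- do.call(rbind, txs)
    truth <- do.call(rbind, truth)
    contig_names <- sprintf("contig_%02d", seq_len(n_contigs))
    contig_lengths <- setNames(cursor + edge_pad, contig_names)

    # contig sequences: random background, planted transcripts overwritten
    seqs <- vapply(contig_lengths, random_dna, character(1))
    for (i in seq_len(nrow(txs))) {
      tgt <- contig_names[[txs$contig[[i]]]]
      L <- txs$end[[i]] - txs$start[[i]] + 1L
      frag <- if (txs$seq_kind[[i]] == "open_frame") {
        strrep("A", L)  # no stop in any frame -> fraction 1
      } else {
        stop_dense_seq(L, phase = sample(0:14, 1L))
      }
      substr(seqs[[tgt]], txs$start[[i]], txs$end[[i]]) <- frag
    }
    sequences <- Biostrings::DNAStringSet(seqs)
    names(sequences) <- contig_names

    genes_gr <- GenomicRanges::GRanges(
      seqnames = contig_names[genes$contig],
      ranges = IRanges::IRanges(genes$start, genes$end),
      strand = genes$strand
    )
    genes_gr$gene_id <- genes$gene_id
    annotation <- genome_annotation(contig_lengths, genes_gr,
                                    sequences = sequences)
    tx_gr <- GenomicRanges::GRanges(
      seqnames = contig_names[txs$contig],
      ranges = IRanges::IRanges(txs$start, txs$end),
      strand = txs$strand
    )
    tx_gr$transcript_id <- txs$transcript_id
    tx_gr$coverage <- txs$coverage
    tx_gr$tpm <- txs$tpm

    out <- list(annotation = annotation, transcripts = tx_gr, truth = truth)
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      paths <- list(
        fasta = file.path(out_dir, "assembly.fasta"),
        gff = file.path(out_dir, "genes.gff3"),
        gtf = file.path(out_dir, "transcripts.gtf"),
        truth = file.path(out_dir, "truth.tsv")
      )
      Biostrings::writeXStringSet(sequences, paths$fasta)
      gg <- genes_gr
      gg$type <- "CDS"
      gg$source <- "srnapipe_sim"
      gg$phase <- 0L
      gg$ID <- gg$gene_id
      rtracklayer::export(gg, paths$gff, format = "gff3")
      tg <- tx_gr
      tg$type <- "transcript"
      tg$source <- "srnapipe_sim"
      tg$cov <- sprintf("%.6f", tx_gr$coverage)
      tg$TPM <- sprintf("%.6f", tx_gr$tpm)
      tg$coverage <- NULL
      tg$tpm <- NULL
      rtracklayer::export(tg, paths$gtf, format = "gtf")
      write.table(truth, paths$truth, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      out$paths <- paths
    }
    out
  })
}

#' Simulate transcript and contig count tables with planted truth
#'
#' Negative-binomial counts per transcript (mean-dispersion
#' parameterization: variance = mu + dispersion * mu^2) for two groups of
#' replicates. Contig-level abundance shifts (organism abundance changes,
#' distinct from transcript-level regulation) multiply the means of every
#' feature on the contig in group 2; transcript-level effects multiply only
#' that transcript. Contig counts are the sum of member transcript counts
#' plus a negative-binomial background (the contig's non-transcript reads),
#' which also carries the contig shift.
#'
#' @param feature_to_contig Named character vector mapping transcript id to
#'   contig id.
#' @param n_per_group Replicates per group (>= 2). Default 10.
#' @param nb_mean Baseline transcript mean. Default 200.
#' @param nb_dispersion NB dispersion. Default 0.1.
#' @param abundance_shift Named numeric vector contig -> fold change of
#'   organism abundance in group 2 (1 = none).
#' @param effect Named numeric vector transcript -> true log2 fold change in
#'   group 2 (0 = none).
#' @param background_mean Mean of the per-contig non-transcript read count.
#'   Default 2000.
#' @param seed Integer seed.
#' @return A list: \code{transcript_counts}, \code{contig_counts} (matrices
#'   with sample columns \code{g1_*}, \code{g2_*}), \code{design} (named
#'   group vector), \code{truth} (per-transcript true log2fc and contig
#'   shift).
#' @export
generate_counts <- function(feature_to_contig, n_per_group = 10L,
                            nb_mean = 200, nb_dispersion = 0.1,
                            abundance_shift = NULL, effect = NULL,
                            background_mean = 2000, seed = 1L) {
  if (n_per_group < 2L) stop("n_per_group must be >= 2")
  if (nb_mean <= 0 || nb_dispersion <= 0) {
    stop("nb_mean and nb_dispersion must be > 0")
  }
  tids <- names(feature_to_contig)
  contigs <- unique(unname(feature_to_contig))
  shift <- setNames(rep(1, length(contigs)), contigs)
  if (!is.null(abundance_shift)) {
    shift[names(abundance_shift)] <- abundance_shift
  }
  lfc <- setNames(rep(0, length(tids)), tids)
  if (!is.null(effect)) lfc[names(effect)] <- effect
  with_seed(seed, {
    samples <- c(sprintf("g1_%02d", seq_len(n_per_group)),
                 sprintf("g2_%02d", seq_len(n_per_group)))
    design <- setNames(rep(c("group1", "group2"), each = n_per_group),
                       samples)
    size <- 1 / nb_dispersion
    tmat <- matrix(0, nrow = length(tids), ncol = length(samples),
                   dimnames = list(tids, samples))
    for (j in seq_along(samples)) {
      in_g2 <- design[[j]] == "group2"
      mu <- nb_mean * (if (in_g2) 2^lfc else rep(1, length(tids))) *
        (if (in_g2) shift[feature_to_contig[tids]] else rep(1, length(tids)))
      tmat[, j] <- rnbinom(length(tids), mu = mu, size = size)
    }
    bg <- matrix(0, nrow = length(contigs), ncol = length(samples),
                 dimnames = list(contigs, samples))
    for (j in seq_along(samples)) {
      in_g2 <- design[[j]] == "group2"
      mu <- background_mean * (if (in_g2) shift else rep(1, length(contigs)))
      bg[, j] <- rnbinom(length(contigs), mu = mu, size = size)
    }
    cmat <- bg
    for (i in seq_along(tids)) {
      cmat[feature_to_contig[[i]], ] <-
        cmat[feature_to_contig[[i]], ] + tmat[i, ]
    }
    list(transcript_counts = tmat, contig_counts = cmat, design = design,
         truth = data.frame(transcript_id = tids,
                            contig = unname(feature_to_contig),
                            true_log2fc = unname(lfc),
                            contig_shift = unname(shift[feature_to_contig]),
                            stringsAsFactors = FALSE))
  })
}

#' @importFrom stats rnbinom runif
NULL

#' Simulate perfectly anticorrelated expression pairs
#'
#' Emits paired antisense/target expression profiles with an exact affine
#' negative relationship (y = c - x), so Pearson's r is exactly -1: the
#' planted-truth case for the correlation module.
#'
#' @param n_pairs Number of pairs.
#' @param n_samples Replicates (>= 3).
#' @param seed Integer seed.
#' @return A list of two \code{expr_matrix} objects (\code{asrna},
#'   \code{target}, kind \code{tpm}) and a \code{pairs} data frame.
#' @export
generate_anticorrelated_pairs <- function(n_pairs = 10L, n_samples = 10L,
                                          seed = 1L) {
  with_seed(seed, {
    samples <- sprintf("s%02d", seq_len(n_samples))
    aid <- sprintf("as_%03d", seq_len(n_pairs))
    tid <- sprintf("mrna_%03d", seq_len(n_pairs))
    x <- matrix(runif(n_pairs * n_samples, 1, 100), nrow = n_pairs,
                dimnames = list(aid, samples))
    y <- 110 - x
    rownames(y) <- tid
    list(asrna = expression_matrix(x, kind = "tpm"),
         target = expression_matrix(y, kind = "tpm"),
         pairs = data.frame(asrna_id = aid, target_id = tid,
                            stringsAsFactors = FALSE))
  })
}
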