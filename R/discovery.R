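#' Effective gene set for one transcript
#'
#' Small-peptide genes are discounted when they are plausibly mis-annotations
#' inside a longer noncoding transcript: a gene shorter than
#' \code{small_peptide_max} nt that lies fully within the transcript is
#' removed when the transcript is more than
#' \code{small_peptide_transcript_ratio} times the gene's length (strictly).
#' All other genes are retained.
#'
#' @param transcript A length-1 \code{GRanges} (one transcript).
#' @param genes \code{GRanges} of genes on the transcript's contig.
#' @param cfg A \code{\link{pipeline_config}}.
#' @return The filtered \code{GRanges} of genes.
#' @export
effective_genes <- function(transcript, genes, cfg) {
  if (!length(genes)) return(genes)
  tw <- BiocGenerics::width(transcript)
  gw <- BiocGenerics::width(genes)
  inside <- BiocGenerics::start(genes) >= BiocGenerics::start(transcript) &
    BiocGenerics::end(genes) <= BiocGenerics::end(transcript)
  drop <- inside & gw < cfg$small_peptide_max &
    tw > cfg$small_peptide_transcript_ratio * gw
  genes[!drop]
}

# Gap in nt between two 1-based closed intervals; 0 when they overlap or
# touch. Vectorized over the b intervals.
interval_gap <- function(a1, a2, b1, b2) {
  pmax(pmax(b1 - a2, a1 - b2) - 1L, 0L)
}

# Core single-transcript classification against a pre-subset gene set.
classify_one <- function(tstart, tend, tstrand, genes, contig_len, cfg) {
  edge_distance <- min(tstart - 1L, contig_len - tend)
  if (length(genes)) {
    gs <- BiocGenerics::start(genes)
    ge <- BiocGenerics::end(genes)
    gstr <- as.character(BiocGenerics::strand(genes))
    same <- gstr == tstrand
    ov <- pmax(0L, pmin(tend, ge) - pmax(tstart, gs) + 1L)
    gap <- interval_gap(tstart, tend, gs, ge)
    nearest_same <- if (any(same)) min(gap[same]) else NA_integer_
    nearest_opp <- if (any(!same)) min(gap[!same]) else NA_integer_
    opp_ov <- !same & ov > 0L
    as_genes <- data.frame(gene_id = genes$gene_id[opp_ov],
                           overlap_nt = ov[opp_ov],
                           stringsAsFactors = FALSE)
    if (nrow(as_genes)) {
      as_genes <- as_genes[order(-as_genes$overlap_nt, as_genes$gene_id), ,
                           drop = FALSE]
      rownames(as_genes) <- NULL
    }
    same_overlap <- any(same & ov > 0L)
  } else {
    nearest_same <- NA_integer_
    nearest_opp <- NA_integer_
    as_genes <- data.frame(gene_id = character(0), overlap_nt = integer(0),
                           stringsAsFactors = FALSE)
    same_overlap <- FALSE
  }
  # distances treat "no gene at all" as infinitely far
  d_same <- if (is.na(nearest_same)) Inf else nearest_same
  d_opp <- if (is.na(nearest_opp)) Inf else nearest_opp
  max_opp_ov <- if (nrow(as_genes)) max(as_genes$overlap_nt) else 0L
  label <- if (same_overlap) {
    "coding"
  } else if (min(d_same, d_opp) >= cfg$min_gene_distance) {
    "intergenic"
  } else if (d_same >= cfg$min_gene_distance &&
             max_opp_ov >= cfg$min_antisense_overlap) {
    "antisense"
  } else {
    "ambiguous"
  }
  list(label = label, antisense_genes = as_genes,
       nearest_same = nearest_same, nearest_opposite = nearest_opp,
       edge_distance = as.integer(edge_distance))
}

#' Classify one transcript as intergenic, antisense, coding or ambiguous
#'
#' A transcript is \emph{intergenic} when its gap to the nearest gene on
#' either strand is at least \code{min_gene_distance} nt (overlap means gap
#' 0); \emph{antisense} when it keeps that distance from every same-strand
#' gene but overlaps an opposite-strand gene by at least
#' \code{min_antisense_overlap} nt; \emph{coding} when it overlaps a
#' same-strand gene; \emph{ambiguous} otherwise. Small-peptide genes are
#' first discounted via \code{\link{effective_genes}}.
#'
#' @param transcript A length-1 \code{GRanges} with a \code{transcript_id}
#'   (and optionally \code{coverage}, \code{tpm}) metadata column.
#' @param annotation A \code{\link{genome_annotation}}.
#' @param cfg A \code{\link{pipeline_config}}.
#' @return A one-row record data frame (see \code{\link{srna_catalog}}).
#' @export
classify_transcript <- function(transcript, annotation, cfg = pipeline_config()) {
  classify_transcripts(transcript, annotation, cfg)
}

#' Classify a set of transcripts
#'
#' Vector form of \code{\link{classify_transcript}}; one record row per
#' transcript, in deterministic (contig, start, id) order.
#'
#' @inheritParams classify_transcript
#' @param transcripts A \code{GRanges} of transcripts.
#' @return A record data frame.
#' @export
classify_transcripts <- function(transcripts, annotation,
                                 cfg = pipeline_config()) {
  ctg <- as.character(GenomeInfoDb::seqnames(transcripts))
  unknown <- setdiff(ctg, names(annotation$contig_lengths))
  if (length(unknown)) {
    stop("transcript(s) on unknown contig(s): ",
         paste(unknown, collapse = ", "))
  }
  genes_by_contig <- split(annotation$genes,
                           as.character(GenomeInfoDb::seqnames(annotation$genes)))
  n <- length(transcripts)
  tid <- if (!is.null(transcripts$transcript_id)) {
    as.character(transcripts$transcript_id)
  } else {
    sprintf("transcript_%d", seq_len(n))
  }
  cov <- if (!is.null(transcripts$coverage)) as.numeric(transcripts$coverage)
         else rep(NA_real_, n)
  tpm <- if (!is.null(transcripts$tpm)) as.numeric(transcripts$tpm)
         else rep(NA_real_, n)
  tstart <- BiocGenerics::start(transcripts)
  tend <- BiocGenerics::end(transcripts)
  tstrand <- as.character(BiocGenerics::strand(transcripts))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    g <- genes_by_contig[[ctg[[i]]]]
    if (is.null(g)) g <- annotation$genes[0]
    g <- effective_genes(transcripts[i], g, cfg)
    out[[i]] <- classify_one(tstart[[i]], tend[[i]], tstrand[[i]], g,
                             annotation$contig_lengths[[ctg[[i]]]], cfg)
  }
  rec <- data.frame(
    transcript_id = tid, contig = ctg,
    start = tstart, end = tend, strand = tstrand,
    length = tend - tstart + 1L,
    coverage = cov, tpm = tpm,
    label = vapply(out, `[[`, character(1), "label"),
    nearest_same = vapply(out, `[[`, integer(1), "nearest_same"),
    nearest_opposite = vapply(out, `[[`, integer(1), "nearest_opposite"),
    edge_distance = vapply(out, `[[`, integer(1), "edge_distance"),
    orf_fraction = rep(NA_real_, n),
    stringsAsFactors = FALSE
  )
  rec$antisense_genes <- I(lapply(out, `[[`, "antisense_genes"))
  for (f in FLAG_COLUMNS) rec[[f]] <- rep(FALSE, n)
  rec$conserved <- rep(FALSE, n)
  rec$rfam_family <- rep(NA_character_, n)
  rec$taxonomy <- rep(NA_character_, n)
  ord <- order(rec$contig, rec$start, rec$transcript_id)
  rec <- rec[ord, , drop = FALSE]
  rownames(rec) <- NULL
  rec
}

#' Longest reading frame as a fraction of sequence length
#'
#' Scans all six reading frames (three of the sequence and three of its
#' reverse complement) and returns the longest stop-codon-free stretch, in
#' nt (a multiple of 3), divided by the sequence length. Stops are TAA, TAG
#' and TGA; an N never forms a stop. With \code{method = "atg"} the stretch
#' must begin at an ATG codon.
#'
#' @param seq A nucleotide string (ACGTN).
#' @param method \code{"stop_free"} (default) or \code{"atg"}.
#' @return The fraction in [0, 1]; 0 for sequences shorter than 3 nt.
#' @export
longest_orf_fraction <- function(seq, method = c("stop_free", "atg")) {
  method <- match.arg(method)
  seq <- toupper(as.character(seq))
  n <- nchar(seq)
  if (n < 3L) return(0)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  stops <- c("TAA", "TAG", "TGA")
  best <- 0L
  for (s in c(seq, rc)) {
    for (f in 0:2) {
      starts <- seq.int(1L + f, n - 2L, by = 3L)
      if (!length(starts)) next
      codons <- substring(s, starts, starts + 2L)
      open <- !(codons %in% stops)
      if (method == "stop_free") {
        r <- rle(open)
        runs <- r$lengths[r$values]
        if (length(runs)) best <- max(best, max(runs) * 3L)
      } else {
        # longest ATG-initiated stretch ending before a stop (or frame end)
        is_atg <- codons == "ATG"
        run_len <- 0L
        i <- 1L
        while (i <= length(codons)) {
          if (!open[i]) { i <- i + 1L; next }
          j <- i
          while (j <= length(codons) && open[j]) j <- j + 1L
          atg_in <- which(is_atg[i:(j - 1L)])
          if (length(atg_in)) {
            run_len <- (j - 1L) - (i + atg_in[[1L]] - 1L) + 1L
            best <- max(best, run_len * 3L)
          }
          i <- j
        }
      }
    }
  }
  best / n
}

#' Noncoding filters: length and reading frame
#'
#' Flags candidate records (intergenic or antisense) whose length falls
#' outside \code{[min_len, max_len]} (bounds pass) or whose longest reading
#' frame exceeds \code{max_orf_fraction} of their length. Flagged records
#' stay in the catalog; they simply leave the surviving set.
#'
#' @param catalog An \code{srna_catalog}.
#' @param annotation A \code{\link{genome_annotation}} with sequences
#'   (needed for the reading-frame scan).
#' @return The updated catalog, with \code{length} and \code{orf}
#'   provenance entries.
#' @export
apply_noncoding_filters <- function(catalog, annotation) {
  cfg <- catalog$config
  rec <- catalog$records
  cand <- rec$label %in% c("intergenic", "antisense")

  n_in <- n_surviving(catalog)
  rec$length_fail <- rec$length_fail |
    (cand & (rec$length < cfg$min_len | rec$length > cfg$max_len))
  catalog$records <- rec
  catalog <- add_provenance(catalog, "length", n_in, n_surviving(catalog))

  n_in <- n_surviving(catalog)
  need <- which(cand)
  if (length(need) && is.null(annotation$sequences)) {
    stop("missing contig sequences for reading-frame filter (contig(s): ",
         paste(unique(rec$contig[need]), collapse = ", "), ")")
  }
  for (i in need) {
    s <- extract_sequence(annotation, rec$contig[[i]], rec$start[[i]],
                          rec$end[[i]], rec$strand[[i]])
    rec$orf_fraction[[i]] <- longest_orf_fraction(s, method = cfg$orf_method)
  }
  rec$orf_fail <- rec$orf_fail |
    (cand & !is.na(rec$orf_fraction) &
       rec$orf_fraction > cfg$max_orf_fraction)
  catalog$records <- rec
  catalog <- add_provenance(catalog, "orf", n_in, n_surviving(catalog))
  catalog
}

#' Dynamic contig-edge threshold by enrichment scan
#'
#' Candidates very close to contig ends are often assembly artifacts. For
#' each distance d on a grid, the probability that a uniformly placed
#' candidate lands within d of a contig end is
#' p0(d) = sum_c min(2d, L_c) / sum_c L_c; the observed count of candidates
#' with edge distance < d is compared with Binomial(n, p0(d)) by a one-sided
#' exact test (enrichment tail), Bonferroni-corrected across the grid so the
#' scan is calibrated family-wise at \code{edge_alpha}. The chosen threshold
#' is the smallest grid distance beyond which no test is significant;
#' candidates closer than that are flagged.
#'
#' @param records Record data frame with \code{edge_distance} (typically the
#'   surviving candidates of a catalog).
#' @param contig_lengths Named vector of contig lengths (nt).
#' @param cfg A \code{\link{pipeline_config}} (grid, alpha, sidedness).
#' @return A list with \code{grid} (data frame: \code{d},
#'   \code{n_candidates}, \code{k_in_zone}, \code{p0}, \code{pvalue}) and
#'   \code{chosen_d}.
#' @export
compute_edge_threshold <- function(records, contig_lengths,
                                   cfg = pipeline_config()) {
  n <- nrow(records)
  if (n == 0L) {
    return(list(grid = data.frame(d = integer(0), n_candidates = integer(0),
                                  k_in_zone = integer(0), p0 = numeric(0),
                                  pvalue = numeric(0)),
                chosen_d = 0L))
  }
  grid <- seq.int(0L, cfg$edge_grid_max, by = cfg$edge_grid_step)
  totL <- sum(as.numeric(contig_lengths))
  ed <- records$edge_distance
  p0 <- vapply(grid, function(d) {
    sum(pmin(2 * as.numeric(d), as.numeric(contig_lengths))) / totL
  }, numeric(1))
  k <- vapply(grid, function(d) sum(ed < d), integer(1))
  pv <- vapply(seq_along(grid), function(i) {
    if (grid[[i]] == 0L) return(1)
    up <- pbinom(k[[i]] - 1L, n, p0[[i]], lower.tail = FALSE)
    if (cfg$edge_sided == "one") up
    else min(1, 2 * min(up, pbinom(k[[i]], n, p0[[i]])))
  }, numeric(1))
  m <- sum(grid > 0L)
  sig <- pv < cfg$edge_alpha / m
  chosen_d <- if (!any(sig)) {
    0L
  } else if (max(which(sig)) == length(grid)) {
    cfg$edge_grid_max
  } else {
    grid[[max(which(sig)) + 1L]]
  }
  list(grid = data.frame(d = grid, n_candidates = n, k_in_zone = k,
                         p0 = p0, pvalue = pv),
       chosen_d = as.integer(chosen_d))
}

#' Discover small noncoding RNAs
#'
#' Runs the geometric discovery stages in order: classification against the
#' gene annotation, contig-edge enrichment correction, length filter, and
#' reading-frame filter. Coverage thresholds
#' (\code{\link{apply_coverage_thresholds}}) and homology/Rfam exclusions
#' are applied by later stages. The returned catalog retains every
#' transcript with its label and flags; the provenance log telescopes the
#' surviving-candidate count through the stages.
#'
#' @param annotation A \code{\link{genome_annotation}} with sequences.
#' @param transcripts A \code{GRanges} of assembled transcripts
#'   (\code{\link{read_transcripts}}).
#' @param cfg A \code{\link{pipeline_config}}.
#' @return An \code{srna_catalog}.
#' @export
discover_srnas <- function(annotation, transcripts, cfg = pipeline_config()) {
  validate_config(cfg)
  rec <- classify_transcripts(transcripts, annotation, cfg)
  catalog <- srna_catalog(rec, cfg)
  catalog <- add_provenance(catalog, "classify", length(transcripts),
                            n_surviving(catalog))

  n_in <- n_surviving(catalog)
  er <- compute_edge_threshold(surviving_records(catalog),
                               annotation$contig_lengths, cfg)
  catalog$edge_report <- er
  cand <- catalog$records$label %in% c("intergenic", "antisense")
  catalog$records$edge_fail <- catalog$records$edge_fail |
    (cand & catalog$records$edge_distance < er$chosen_d)
  catalog <- add_provenance(catalog, "edge", n_in, n_surviving(catalog))

  apply_noncoding_filters(catalog, annotation)
}
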