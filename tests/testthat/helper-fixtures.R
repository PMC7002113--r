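# In-code fixture builders shared across test files.

# A genome_annotation from a compact gene spec:
# genes = data.frame(contig, start, end, strand, gene_id)
make_annotation <- function(contig_lengths, genes = NULL, sequences = NULL) {
  if (is.null(genes) || nrow(genes) == 0L) {
    gr <- GenomicRanges::GRanges()
    gr$gene_id <- character(0)
  } else {
    gr <- GenomicRanges::GRanges(
      seqnames = genes$contig,
      ranges = IRanges::IRanges(genes$start, genes$end),
      strand = genes$strand
    )
    gr$gene_id <- genes$gene_id
  }
  if (!is.null(sequences) && !inherits(sequences, "DNAStringSet")) {
    sequences <- Biostrings::DNAStringSet(sequences)
  }
  genome_annotation(contig_lengths, gr, sequences = sequences)
}

make_transcripts <- function(df) {
  gr <- GenomicRanges::GRanges(
    seqnames = df$contig,
    ranges = IRanges::IRanges(df$start, df$end),
    strand = df$strand
  )
  gr$transcript_id <- df$transcript_id
  gr$coverage <- if (is.null(df$coverage)) rep(50, nrow(df)) else df$coverage
  gr$tpm <- if (is.null(df$tpm)) rep(10, nrow(df)) else df$tpm
  gr
}

# One-call classification of a single transcript geometry.
classify_case <- function(tx_start, tx_end, tx_strand, genes,
                          contig_len = 100000L, cfg = pipeline_config()) {
  ann <- make_annotation(c(c1 = contig_len), genes)
  tx <- make_transcripts(data.frame(contig = "c1", start = tx_start,
                                    end = tx_end, strand = tx_strand,
                                    transcript_id = "t1",
                                    stringsAsFactors = FALSE))
  classify_transcript(tx, ann, cfg)
}

gene_row <- function(start, end, strand, id = "g1") {
  data.frame(contig = "c1", start = start, end = end, strand = strand,
             gene_id = id, stringsAsFactors = FALSE)
}

write_lines_tmp <- function(lines, ext) {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

write_fasta_tmp <- function(seqs) {
  ss <- Biostrings::DNAStringSet(seqs)
  path <- tempfile(fileext = ".fasta")
  Biostrings::writeXStringSet(ss, path)
  path
}

# Minimal catalog wrapping hand-made records for filter tests.
make_catalog <- function(records, cfg = pipeline_config()) {
  defaults <- list(coverage = 50, tpm = 10, orf_fraction = NA_real_,
                   nearest_same = NA_integer_, nearest_opposite = NA_integer_,
                   edge_distance = 1000L, conserved = FALSE,
                   rfam_family = NA_character_, taxonomy = NA_character_)
  for (f in names(defaults)) {
    if (is.null(records[[f]])) records[[f]] <- rep(defaults[[f]], nrow(records))
  }
  for (f in srnapipe:::FLAG_COLUMNS) {
    if (is.null(records[[f]])) records[[f]] <- rep(FALSE, nrow(records))
  }
  if (is.null(records$antisense_genes)) {
    records$antisense_genes <- I(replicate(
      nrow(records),
      data.frame(gene_id = character(0), overlap_nt = integer(0)),
      simplify = FALSE
    ))
  }
  if (is.null(records$length)) {
    records$length <- records$end - records$start + 1L
  }
  srna_catalog(records, cfg)
}

record_rows <- function(n, label = "intergenic", coverage = 50) {
  data.frame(transcript_id = sprintf("t%03d", seq_len(n)),
             contig = rep("c1", n),
             start = seq_len(n) * 1000L, end = seq_len(n) * 1000L + 99L,
             strand = rep("+", n), label = rep(label, n),
             coverage = rep(coverage, n),
             stringsAsFactors = FALSE)
}
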