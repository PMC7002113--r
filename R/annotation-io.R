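#' @importFrom methods is as
#' @importFrom stats var coef lm pnorm pt pbinom p.adjust cor.test setNames
#' @importFrom utils read.delim write.table head packageVersion
NULL

#' Genome annotation container
#'
#' Bundles the coordinate frame every classification step runs against:
#' contig lengths (and optionally sequences) plus a stranded interval index
#' of gene features. All coordinates are 1-based inclusive, the
#' GFF/GenomicRanges convention.
#'
#' @param contig_lengths Named integer vector of contig lengths (nt).
#' @param genes A \code{GRanges} of gene features with a \code{gene_id}
#'   metadata column (a \code{product} column is optional).
#' @param sequences Optional \code{DNAStringSet} of contig sequences; names
#'   and widths must match \code{contig_lengths}.
#' @return A \code{genome_annotation} object.
#' @export
genome_annotation <- function(contig_lengths, genes, sequences = NULL) {
  stopifnot(is.numeric(contig_lengths), !is.null(names(contig_lengths)))
  contig_lengths <- setNames(as.integer(contig_lengths), names(contig_lengths))
  if (any(contig_lengths < 1L)) stop("contig lengths must be >= 1")
  genes <- as(genes, "GRanges")
  bad <- setdiff(as.character(GenomeInfoDb::seqnames(genes)),
                 names(contig_lengths))
  if (length(bad)) {
    stop("gene feature(s) reference unknown contig(s): ",
         paste(unique(bad), collapse = ", "))
  }
  if (is.null(genes$gene_id)) {
    genes$gene_id <- sprintf("feat_%d", seq_along(genes))
  }
  oob <- BiocGenerics::start(genes) < 1L |
    BiocGenerics::end(genes) >
      contig_lengths[as.character(GenomeInfoDb::seqnames(genes))]
  if (any(oob)) {
    stop("gene feature(s) outside contig bounds: ",
         paste(genes$gene_id[oob], collapse = ", "))
  }
  # deterministic order: contig, start, gene id
  ord <- order(as.character(GenomeInfoDb::seqnames(genes)),
               BiocGenerics::start(genes), genes$gene_id)
  genes <- genes[ord]
  if (!is.null(sequences)) {
    sequences <- as(sequences, "DNAStringSet")
    if (!all(names(contig_lengths) %in% names(sequences))) {
      stop("sequences missing for contig(s): ",
           paste(setdiff(names(contig_lengths), names(sequences)),
                 collapse = ", "))
    }
    sequences <- sequences[names(contig_lengths)]
    if (!all(Biostrings::width(sequences) == contig_lengths)) {
      stop("sequence width disagrees with contig length")
    }
  }
  structure(list(contig_lengths = contig_lengths,
                 genes = genes,
                 sequences = sequences),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("genome_annotation:", length(x$contig_lengths), "contig(s),",
      length(x$genes), "gene feature(s),",
      if (is.null(x$sequences)) "no sequences" else "with sequences", "\n")
  invisible(x)
}

# Pre-validates raw GFF/GTF lines so errors carry line numbers; rtracklayer
# does the actual parsing afterwards.
validate_gff_lines <- function(path, known_seqids = NULL) {
  lines <- readLines(path, warn = FALSE)
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (!nzchar(ln) || startsWith(ln, "#")) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 8L) {
      stop("malformed feature line ", i, " in ", path,
           ": expected >= 8 tab-separated columns")
    }
    st <- suppressWarnings(as.integer(f[[4]]))
    en <- suppressWarnings(as.integer(f[[5]]))
    if (is.na(st) || is.na(en)) {
      stop("non-numeric coordinates on line ", i, " in ", path)
    }
    if (en < st) {
      stop("end < start on line ", i, " in ", path,
           " (", st, " > ", en, ")")
    }
    if (!is.null(known_seqids) && !(f[[1]] %in% known_seqids)) {
      stop("line ", i, " in ", path, " references unknown contig '",
           f[[1]], "'")
    }
  }
  invisible(TRUE)
}

#' Read a genome annotation from GFF3 + FASTA
#'
#' Contig lengths (and sequences) come from the FASTA; gene intervals from
#' the GFF3. Every GFF seqid must exist in the FASTA and coordinates must be
#' ordered; violations are reported with the offending id or line number.
#'
#' @param gff_path Path to a GFF3 file (1-based inclusive coordinates).
#' @param fasta_path Path to the assembly FASTA; ids must match GFF seqids.
#' @param feature_types Optional character vector restricting which feature
#'   types (GFF column 3) are indexed as genes; \code{NULL} keeps all.
#' @param load_sequences Keep contig sequences in memory (needed by the
#'   reading-frame filter and sequence extraction). Default \code{TRUE}.
#' @return A \code{\link{genome_annotation}}.
#' @export
read_annotation <- function(gff_path, fasta_path, feature_types = NULL,
                            load_sequences = TRUE) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  lens <- setNames(Biostrings::width(seqs), names(seqs))
  validate_gff_lines(gff_path, known_seqids = names(lens))
  gr <- rtracklayer::import(gff_path, format = "gff3")
  if (!is.null(feature_types) && length(gr)) {
    gr <- gr[as.character(gr$type) %in% feature_types]
  }
  ids <- if (length(gr)) {
    id <- if (!is.null(gr$ID)) as.character(gr$ID) else rep(NA_character_, length(gr))
    if (!is.null(gr$gene_id)) {
      id <- ifelse(is.na(id), as.character(gr$gene_id), id)
    }
    ifelse(is.na(id), sprintf("feat_%d", seq_along(gr)), id)
  } else {
    character(0)
  }
  genes <- GenomicRanges::GRanges(
    seqnames = GenomeInfoDb::seqnames(gr),
    ranges = IRanges::ranges(gr),
    strand = BiocGenerics::strand(gr)
  )
  genes$gene_id <- ids
  genes$product <- if (!is.null(gr$product)) as.character(gr$product) else
    rep(NA_character_, length(gr))
  genome_annotation(lens, genes,
                    sequences = if (load_sequences) seqs else NULL)
}

# Case-insensitive metadata-column lookup (StringTie emits `cov`/`TPM` with
# varying capitalization across versions); case variants within one file
# land in separate columns and are coalesced row-wise.
mcol_ci <- function(gr, key) {
  nm <- names(S4Vectors::mcols(gr))
  hit <- nm[tolower(nm) == tolower(key)]
  if (!length(hit)) return(NULL)
  out <- S4Vectors::mcols(gr)[[hit[[1]]]]
  for (h in hit[-1]) {
    more <- S4Vectors::mcols(gr)[[h]]
    out <- ifelse(is.na(out), more, out)
  }
  out
}

#' Read assembled transcripts from a StringTie-style GTF
#'
#' Keeps \code{transcript} rows only; exon rows are ignored (single-exon
#' prokaryotic model). The \code{cov} and \code{TPM} attributes are matched
#' case-insensitively; a transcript missing either is kept with an \code{NA}
#' value and a warning, so the downstream coverage threshold can reject and
#' log it.
#'
#' @param gtf_path Path to the GTF file.
#' @return A \code{GRanges} with metadata columns \code{transcript_id},
#'   \code{coverage} and \code{tpm}, preserving file order.
#' @export
read_transcripts <- function(gtf_path) {
  validate_gff_lines(gtf_path)
  gr <- rtracklayer::import(gtf_path, format = "gtf")
  if (length(gr)) gr <- gr[as.character(gr$type) == "transcript"]
  tid <- mcol_ci(gr, "transcript_id")
  if (is.null(tid) && length(gr)) {
    stop("GTF transcript rows lack a transcript_id attribute: ", gtf_path)
  }
  cov <- mcol_ci(gr, "cov")
  if (is.null(cov)) cov <- mcol_ci(gr, "coverage")
  tpm <- mcol_ci(gr, "tpm")
  out <- GenomicRanges::GRanges(
    seqnames = GenomeInfoDb::seqnames(gr),
    ranges = IRanges::ranges(gr),
    strand = BiocGenerics::strand(gr)
  )
  out$transcript_id <- if (length(gr)) as.character(tid) else character(0)
  out$coverage <- if (is.null(cov)) rep(NA_real_, length(gr)) else
    suppressWarnings(as.numeric(as.character(cov)))
  out$tpm <- if (is.null(tpm)) rep(NA_real_, length(gr)) else
    suppressWarnings(as.numeric(as.character(tpm)))
  n_nocov <- sum(is.na(out$coverage))
  if (n_nocov > 0) {
    warning(n_nocov, " transcript(s) missing a cov attribute; ",
            "coverage set to NA (will fail the coverage threshold)")
  }
  out
}

#' Read a 12-column BLAST tabular file (outfmt 6)
#'
#' Query cover is recomputed from the aligned query span
#' (\code{|qend - qstart| + 1}) over the query length, so hits in either
#' orientation and all BLAST dialects behave identically.
#'
#' @param path Path to the tab-separated hit table (no header).
#' @param query_lengths Named integer vector mapping query id to length (nt).
#' @return A data frame of hits with a computed \code{query_cover} (%)
#'   column.
#' @export
read_blast_table <- function(path, query_lengths) {
  cols <- c("query_id", "subject_id", "identity", "align_len", "mismatch",
            "gapopen", "qstart", "qend", "sstart", "send", "evalue",
            "bitscore")
  raw <- tryCatch(
    read.delim(path, header = FALSE, col.names = cols,
               colClasses = c("character", "character", rep("numeric", 10)),
               comment.char = "#"),
    error = function(e) {
      if (grepl("no lines available", conditionMessage(e))) return(NULL)
      # locate the offending line for the error message
      lines <- readLines(path, warn = FALSE)
      lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
      for (i in seq_along(lines)) {
        f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
        num <- suppressWarnings(as.numeric(f[-(1:2)]))
        if (length(f) != 12L || anyNA(num)) {
          stop("malformed BLAST tabular line ", i, " in ", path)
        }
      }
      stop("failed to parse BLAST table ", path, ": ", conditionMessage(e))
    }
  )
  if (is.null(raw) || nrow(raw) == 0L) {
    out <- data.frame(query_id = character(0), subject_id = character(0),
                      identity = numeric(0), align_len = numeric(0),
                      qstart = numeric(0), qend = numeric(0),
                      sstart = numeric(0), send = numeric(0),
                      evalue = numeric(0), bitscore = numeric(0),
                      query_cover = numeric(0), stringsAsFactors = FALSE)
    return(out)
  }
  qlen <- query_lengths[raw$query_id]
  if (anyNA(qlen)) {
    missing_q <- unique(raw$query_id[is.na(qlen)])
    warning("no query length for: ", paste(missing_q, collapse = ", "),
            "; query_cover set to NA for those hits")
  }
  span <- abs(raw$qend - raw$qstart) + 1
  data.frame(query_id = raw$query_id, subject_id = raw$subject_id,
             identity = raw$identity, align_len = raw$align_len,
             qstart = raw$qstart, qend = raw$qend,
             sstart = raw$sstart, send = raw$send,
             evalue = raw$evalue, bitscore = raw$bitscore,
             query_cover = as.numeric(span / qlen * 100),
             stringsAsFactors = FALSE)
}

#' Read an Rfam / cmscan-like hit table
#'
#' Minimal tab-separated column set (with header): \code{query_id},
#' \code{family_accession}, \code{family_name}, \code{clan}, \code{evalue},
#' \code{score}. The pipeline never runs Infernal itself; it consumes such
#' pre-computed tables.
#'
#' @param path Path to the TSV.
#' @return A data frame of Rfam hits.
#' @export
read_rfam_table <- function(path) {
  df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("query_id", "family_accession", "family_name", "evalue", "score")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("Rfam table ", path, " missing column(s): ",
         paste(miss, collapse = ", "))
  }
  if (is.null(df$clan)) df$clan <- NA_character_
  if (any(df$evalue < 0)) stop("negative E-value in Rfam table ", path)
  df
}

#' Read a feature-by-sample count table
#'
#' Plain TSV, features as rows, samples as columns, first column the feature
#' id (the featureCounts-like layout).
#'
#' @param path Path to the TSV.
#' @return A numeric matrix with feature ids as rownames.
#' @export
read_count_table <- function(path) {
  df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                   check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  m
}

#' Extract a (strand-aware) subsequence from a contig
#'
#' @param annotation A \code{\link{genome_annotation}} with sequences.
#' @param contig_id Contig id.
#' @param start,end 1-based inclusive interval, \code{start <= end}.
#' @param strand \code{"+"} or \code{"-"}; minus returns the reverse
#'   complement.
#' @return A character scalar (nucleotide string).
#' @export
extract_sequence <- function(annotation, contig_id, start, end, strand = "+") {
  if (is.null(annotation$sequences)) {
    stop("annotation holds no sequences; reload with load_sequences = TRUE")
  }
  if (!contig_id %in% names(annotation$sequences)) {
    stop("unknown contig '", contig_id, "'")
  }
  L <- annotation$contig_lengths[[contig_id]]
  if (start > end) stop("empty or inverted interval [", start, ", ", end, "]")
  if (start < 1L || end > L) {
    stop("interval [", start, ", ", end, "] outside contig '", contig_id,
         "' of length ", L)
  }
  s <- Biostrings::subseq(annotation$sequences[[contig_id]], start, end)
  if (identical(as.character(strand), "-")) {
    s <- Biostrings::reverseComplement(s)
  }
  as.character(s)
}

#' Write an sRNA catalog as GFF3
#'
#' One \code{ncRNA} feature per record, 1-based inclusive, with the class
#' (intergenic/antisense/...), filter flags and linked antisense gene ids in
#' the attribute column. Output order is deterministic (contig, start, id)
#' and the file round-trips through \code{\link{read_annotation}}.
#'
#' @param catalog An \code{srna_catalog}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_srna_gff <- function(catalog, path) {
  rec <- catalog$records
  if (nrow(rec) == 0L) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  ord <- order(rec$contig, rec$start, rec$transcript_id)
  rec <- rec[ord, , drop = FALSE]
  gr <- GenomicRanges::GRanges(
    seqnames = rec$contig,
    ranges = IRanges::IRanges(start = rec$start, end = rec$end),
    strand = rec$strand
  )
  gr$source <- "srnapipe"
  gr$type <- "ncRNA"
  gr$ID <- rec$transcript_id
  gr$srna_class <- rec$label
  flags <- record_flag_strings(rec)
  gr$filter_flags <- ifelse(nzchar(flags), flags, "none")
  gr$antisense_genes <- vapply(rec$antisense_genes, function(x) {
    if (is.null(x) || nrow(x) == 0L) return("none")
    paste(sprintf("%s:%d", x$gene_id, x$overlap_nt), collapse = ",")
  }, character(1))
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
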