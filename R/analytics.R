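RANK_NAMES <- c("domain", "phylum", "class", "order", "family", "genus",
                "species")

parse_lineage <- function(x) {
  if (is.na(x) || !nzchar(x)) return(character(0))
  trimws(strsplit(x, ";", fixed = TRUE)[[1]])
}

#' Weighted-vote taxonomy of a contig
#'
#' A contig's taxonomy is the weighted consensus of the lineages of the
#' genes it carries (weights default to gene lengths). Rank by rank from
#' domain downward, the name with the largest weight fraction wins; the
#' lineage descends while the winner's support is at least 0.5 of the total
#' weight of genes informative at that rank. A 0.5/0.5 tie keeps the
#' lexicographically first name and is flagged. Deeper ranks are absent.
#'
#' @param lineages Character vector of semicolon-separated ranked lineages
#'   (domain;phylum;...), one per gene; shorter lineages are allowed.
#' @param weights Positive numeric weights (gene lengths by default use).
#' @return A list with \code{names} (named character vector by rank),
#'   \code{support} (weight fraction per kept rank) and \code{tie}
#'   (logical per kept rank).
#' @export
contig_taxonomy <- function(lineages, weights = rep(1, length(lineages))) {
  stopifnot(length(lineages) == length(weights))
  if (!length(lineages)) {
    return(list(names = setNames(character(0), character(0)),
                support = numeric(0), tie = logical(0)))
  }
  if (any(weights <= 0)) stop("weights must be > 0")
  parsed <- lapply(as.character(lineages), parse_lineage)
  depth <- max(lengths(parsed), 0L)
  out_names <- character(0); out_support <- numeric(0); out_tie <- logical(0)
  for (r in seq_len(min(depth, length(RANK_NAMES)))) {
    has <- lengths(parsed) >= r
    if (!any(has)) break
    nm <- vapply(parsed[has], `[[`, character(1), r)
    w <- weights[has]
    tot <- sum(w)
    sup <- vapply(split(w, nm), sum, numeric(1)) / tot
    sup <- sup[order(-sup, names(sup))]  # ties -> lexicographically first
    if (sup[[1]] < 0.5) break
    out_names <- c(out_names, names(sup)[[1]])
    out_support <- c(out_support, unname(sup[[1]]))
    out_tie <- c(out_tie, length(sup) > 1L && sup[[2]] == sup[[1]])
  }
  ranks <- RANK_NAMES[seq_along(out_names)]
  list(names = setNames(out_names, ranks),
       support = setNames(out_support, ranks),
       tie = setNames(out_tie, ranks))
}

#' Read a gene taxonomy table
#'
#' TSV with header columns \code{gene_id}, \code{contig_id},
#' \code{lineage} (semicolon-ranked) and optional \code{weight} (gene
#' length used when absent requires a \code{weight} column; otherwise 1).
#'
#' @param path Path to the TSV.
#' @return A data frame.
#' @export
read_taxonomy_table <- function(path) {
  df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("gene_id", "contig_id", "lineage")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("taxonomy table ", path, " missing column(s): ",
         paste(miss, collapse = ", "))
  }
  if (is.null(df$weight)) df$weight <- 1
  df
}

#' Contig taxonomies from a gene taxonomy table
#'
#' Applies \code{\link{contig_taxonomy}} per contig.
#'
#' @param tax Data frame from \code{\link{read_taxonomy_table}}.
#' @return Named list of lineage objects, one per contig.
#' @export
contig_taxonomies <- function(tax) {
  lapply(split(tax, tax$contig_id), function(d) {
    contig_taxonomy(d$lineage, d$weight)
  })
}

lineage_string <- function(lin) {
  if (!length(lin$names)) NA_character_ else paste(lin$names, collapse = ";")
}

#' Assign taxonomy to catalog records
#'
#' Each small RNA inherits the taxonomy of the contig it lies on. Records on
#' contigs without a taxonomy stay unassigned, with a warning.
#'
#' @param catalog An \code{srna_catalog}.
#' @param contig_taxa Named list of lineages (\code{\link{contig_taxonomies}}).
#' @return The updated catalog.
#' @export
assign_srna_taxonomy <- function(catalog, contig_taxa) {
  rec <- catalog$records
  strs <- vapply(contig_taxa, lineage_string, character(1))
  idx <- match(rec$contig, names(contig_taxa))
  miss <- unique(rec$contig[is.na(idx)])
  if (length(miss)) {
    warning("no taxonomy for contig(s): ", paste(miss, collapse = ", "))
  }
  rec$taxonomy <- ifelse(is.na(idx), NA_character_, strs[idx])
  catalog$records <- rec
  catalog
}

#' Overlap geometry of an antisense RNA on its target mRNA
#'
#' Projects the overlap interval onto the mRNA axis oriented 5' to 3' (for a
#' minus-strand gene, position 0 is the gene's right edge) and reports
#' relative coordinates as fractions of gene length, plus the overlap in nt.
#'
#' @param asrna_start,asrna_end 1-based inclusive antisense transcript
#'   interval.
#' @param gene_start,gene_end 1-based inclusive gene interval on the same
#'   contig.
#' @param gene_strand \code{"+"} or \code{"-"}.
#' @return A list with \code{rel_start}, \code{rel_end} in [0, 1]
#'   (\code{rel_start < rel_end}) and \code{overlap_nt}.
#' @export
overlap_profile <- function(asrna_start, asrna_end, gene_start, gene_end,
                            gene_strand) {
  os <- max(asrna_start, gene_start)
  oe <- min(asrna_end, gene_end)
  if (os > oe) stop("antisense transcript does not overlap the gene")
  len <- gene_end - gene_start + 1
  if (identical(as.character(gene_strand), "+")) {
    rel_start <- (os - gene_start) / len
    rel_end <- (oe - gene_start + 1) / len
  } else {
    rel_start <- (gene_end - oe) / len
    rel_end <- (gene_end - os + 1) / len
  }
  list(rel_start = rel_start, rel_end = rel_end,
       overlap_nt = as.integer(oe - os + 1))
}

#' Pearson correlation of antisense RNA / target expression across replicates
#'
#' For each pair, tracks the two expression profiles across shared samples
#' and computes Pearson's r with its two-sided p-value (t distribution,
#' n - 2 df); a pair is significant at \code{p < corr_alpha}. Pairs with a
#' zero-variance profile are reported NA.
#'
#' @param asrna_expr,target_expr \code{expr_matrix} objects sharing sample
#'   columns (standardized TPM recommended).
#' @param pairs Data frame with columns \code{asrna_id}, \code{target_id}.
#' @param cfg A \code{\link{pipeline_config}}.
#' @return A data frame: pair ids, \code{n}, \code{pearson_r},
#'   \code{pvalue}, \code{significant}.
#' @export
pair_correlations <- function(asrna_expr, target_expr, pairs,
                              cfg = pipeline_config()) {
  av <- asrna_expr$values
  tv <- target_expr$values
  shared <- intersect(colnames(av), colnames(tv))
  if (length(shared) < 3L) stop("need at least 3 shared samples")
  av <- av[, shared, drop = FALSE]
  tv <- tv[, shared, drop = FALSE]
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    a <- pairs$asrna_id[[i]]; t <- pairs$target_id[[i]]
    if (!a %in% rownames(av) || !t %in% rownames(tv)) {
      return(data.frame(asrna_id = a, target_id = t, n = NA_integer_,
                        pearson_r = NA_real_, pvalue = NA_real_,
                        significant = NA, stringsAsFactors = FALSE))
    }
    x <- av[a, ]; y <- tv[t, ]
    if (var(x) == 0 || var(y) == 0) {
      return(data.frame(asrna_id = a, target_id = t, n = length(x),
                        pearson_r = NA_real_, pvalue = NA_real_,
                        significant = NA, stringsAsFactors = FALSE))
    }
    ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
    data.frame(asrna_id = a, target_id = t, n = length(x),
               pearson_r = unname(ct$estimate), pvalue = ct$p.value,
               significant = ct$p.value < cfg$corr_alpha,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Extract the upstream region of a small RNA
#'
#' Returns the \code{upstream_len} (50 by default) nucleotides immediately
#' 5' of the transcript start: for a plus-strand record the sequence ending
#' one base before its start; for a minus-strand record the reverse
#' complement of the sequence beginning one base after its end. Truncated
#' (and flagged) when the contig edge intrudes; promoter motif searches run
#' on the emitted sequences externally.
#'
#' @param record One catalog record row (data frame with \code{contig},
#'   \code{start}, \code{end}, \code{strand}).
#' @param annotation A \code{\link{genome_annotation}} with sequences.
#' @param cfg A \code{\link{pipeline_config}}.
#' @return A list with \code{sequence} (possibly empty) and
#'   \code{truncated}.
#' @export
extract_upstream <- function(record, annotation, cfg = pipeline_config()) {
  L <- annotation$contig_lengths[[record$contig]]
  k <- cfg$upstream_len
  if (identical(record$strand, "+")) {
    from <- max(1L, record$start - k)
    to <- record$start - 1L
    if (to < from) return(list(sequence = "", truncated = TRUE))
    s <- extract_sequence(annotation, record$contig, from, to, "+")
  } else {
    from <- record$end + 1L
    to <- min(L, record$end + k)
    if (to < from) return(list(sequence = "", truncated = TRUE))
    s <- extract_sequence(annotation, record$contig, from, to, "-")
  }
  list(sequence = s, truncated = nchar(s) < k)
}

#' Write upstream regions of surviving sRNAs as FASTA
#'
#' @param catalog An \code{srna_catalog}.
#' @param annotation A \code{\link{genome_annotation}} with sequences.
#' @param path Output path.
#' @return Invisibly, a data frame of ids and truncation flags.
#' @export
write_upstream_fasta <- function(catalog, annotation, path) {
  rec <- surviving_records(catalog)
  seqs <- character(nrow(rec)); trunc <- logical(nrow(rec))
  for (i in seq_len(nrow(rec))) {
    u <- extract_upstream(rec[i, ], annotation, catalog$config)
    seqs[[i]] <- u$sequence; trunc[[i]] <- u$truncated
  }
  keep <- nzchar(seqs)
  ss <- Biostrings::DNAStringSet(seqs[keep])
  names(ss) <- paste0(rec$transcript_id[keep],
                      ifelse(trunc[keep], " truncated", ""))
  Biostrings::writeXStringSet(ss, path)
  invisible(data.frame(transcript_id = rec$transcript_id,
                       truncated = trunc, written = keep,
                       stringsAsFactors = FALSE))
}

#' Read an sRNA-target interaction table
#'
#' Minimal tab-separated column set (with header): \code{srna_id},
#' \code{target_id}, \code{srna_start}, \code{srna_end} (1-based inclusive
#' positions on the sRNA), \code{energy} (kcal/mol), \code{pvalue}.
#' Hybridization prediction itself runs externally; only its table is
#' consumed.
#'
#' @param path Path to the TSV.
#' @return A data frame.
#' @export
read_interaction_table <- function(path) {
  df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("srna_id", "target_id", "srna_start", "srna_end", "energy",
            "pvalue")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("interaction table ", path, " missing column(s): ",
         paste(miss, collapse = ", "))
  }
  df
}

#' Per-position interaction density along a small RNA
#'
#' Keeps the top \code{top_n_interactions} records for one sRNA, ranked by
#' ascending p-value by default (\code{rank_by = "energy"} ranks by lowest
#' hybridization energy instead; ties break by the other key, then target
#' id), and accumulates, for every position of the sRNA, how many kept
#' interactions span it. The peak is the first position of maximal density.
#'
#' @param records Interaction data frame (one sRNA) from
#'   \code{\link{read_interaction_table}}.
#' @param srna_length Length of the sRNA (nt).
#' @param cfg A \code{\link{pipeline_config}}.
#' @param rank_by \code{"pvalue"} (default) or \code{"energy"}.
#' @return A list with \code{counts} (integer vector of length
#'   \code{srna_length}), \code{peak} (position, NA when no interactions)
#'   and \code{n_used}.
#' @export
interaction_density <- function(records, srna_length,
                                cfg = pipeline_config(),
                                rank_by = c("pvalue", "energy")) {
  rank_by <- match.arg(rank_by)
  counts <- integer(srna_length)
  if (!nrow(records)) {
    return(list(counts = counts, peak = NA_integer_, n_used = 0L))
  }
  if (any(records$srna_start < 1L | records$srna_end > srna_length |
            records$srna_start > records$srna_end)) {
    stop("interaction position(s) outside [1, ", srna_length, "]")
  }
  ord <- if (rank_by == "pvalue") {
    order(records$pvalue, records$energy, records$target_id)
  } else {
    order(records$energy, records$pvalue, records$target_id)
  }
  kept <- records[ord, , drop = FALSE]
  kept <- head(kept, cfg$top_n_interactions)
  for (i in seq_len(nrow(kept))) {
    span <- kept$srna_start[[i]]:kept$srna_end[[i]]
    counts[span] <- counts[span] + 1L
  }
  peak <- if (all(counts == 0L)) NA_integer_ else which.max(counts)
  list(counts = counts, peak = as.integer(peak), n_used = nrow(kept))
}
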