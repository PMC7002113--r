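#' Pipeline configuration
#'
#' Collects every numeric threshold used across the pipeline into a single
#' validated object. Defaults are the published operating points of the
#' methodology: intergenic transcripts must be at least 30 nt from any gene
#' on both strands, antisense transcripts must overlap an opposite-strand
#' gene by at least 10 nt, small noncoding RNAs are 50-500 nt, assembly
#' coverage must reach 5x (intergenic) or 10x (antisense), no reading frame
#' may exceed one third of the transcript, and protein homology /
#' conservation cutoffs follow the published BLAST criteria.
#'
#' @param min_gene_distance Minimum gap (nt) to any gene for an intergenic
#'   call, and to any same-strand gene for an antisense call. Default 30.
#' @param min_antisense_overlap Minimum overlap (nt) with an opposite-strand
#'   gene for an antisense call. Default 10.
#' @param small_peptide_max Genes shorter than this (nt) are small peptides,
#'   eligible for exclusion from the gene set. Default 100.
#' @param small_peptide_transcript_ratio A small-peptide gene fully inside a
#'   transcript is dropped when the transcript is more than this many times
#'   the gene's length. Default 3.
#' @param max_orf_fraction Maximum allowed fraction of a transcript occupied
#'   by a single stop-free reading frame (any of six frames). Default 1/3.
#' @param min_len,max_len Inclusive length bounds (nt) for a small RNA.
#'   Defaults 50 and 500.
#' @param cov_threshold_intergenic,cov_threshold_antisense Minimum assembly
#'   coverage (x) for intergenic and antisense records. Defaults 5 and 10.
#' @param prot_min_qcov,prot_min_bitscore,prot_max_evalue,prot_min_identity
#'   Protein-homology exclusion: a hit flags a record when query cover >
#'   \code{prot_min_qcov} (%), bitscore > \code{prot_min_bitscore}, E-value <
#'   \code{prot_max_evalue} and identity > \code{prot_min_identity} (%), all
#'   strict. Defaults 30, 50, 1e-4, 30.
#' @param cons_max_evalue,cons_min_identity,cons_min_qcov Nucleotide
#'   conservation annotation: inclusive bounds (E-value at most, identity and
#'   query cover at least). Defaults 1e-3, 70, 50.
#' @param de_fdr FDR cutoff for differential expression calls. Default 0.05.
#' @param corr_alpha P-value cutoff for a significant expression correlation.
#'   Default 0.01.
#' @param upstream_len Length (nt) of the upstream region extracted for motif
#'   searches. Default 50.
#' @param top_n_interactions Number of top-ranked interactions used for the
#'   per-position interaction density. Default 100.
#' @param edge_alpha Family-wise significance level of the contig-edge
#'   enrichment scan. Default 0.05.
#' @param edge_grid_step,edge_grid_max Grid (nt) of candidate edge distances
#'   scanned by the enrichment test. Defaults 10 and 500.
#' @param edge_sided \code{"one"} (default, enrichment only) or \code{"two"}.
#' @param orf_method \code{"stop_free"} (default): longest stop-free stretch
#'   in any frame; \code{"atg"}: longest ATG-initiated open reading frame.
#' @param cons_cover_on \code{"query"} (default) or \code{"subject"}: which
#'   coverage the conservation filter applies to.
#' @param count_scale Multiplier applied to contig-normalized counts so
#'   values are readable (counts per million of parent-contig reads).
#'   Default 1e6. Any positive value yields identical DE decisions.
#' @param rng_seed Integer seed used by stochastic helpers. Default 1.
#'
#' @return An object of class \code{pipeline_config} (a named list).
#' @examples
#' cfg <- pipeline_config()
#' cfg$min_gene_distance
#' @export
pipeline_config <- function(min_gene_distance = 30L,
                            min_antisense_overlap = 10L,
                            small_peptide_max = 100L,
                            small_peptide_transcript_ratio = 3,
                            max_orf_fraction = 1 / 3,
                            min_len = 50L,
                            max_len = 500L,
                            cov_threshold_intergenic = 5,
                            cov_threshold_antisense = 10,
                            prot_min_qcov = 30,
                            prot_min_bitscore = 50,
                            prot_max_evalue = 1e-4,
                            prot_min_identity = 30,
                            cons_max_evalue = 1e-3,
                            cons_min_identity = 70,
                            cons_min_qcov = 50,
                            de_fdr = 0.05,
                            corr_alpha = 0.01,
                            upstream_len = 50L,
                            top_n_interactions = 100L,
                            edge_alpha = 0.05,
                            edge_grid_step = 10L,
                            edge_grid_max = 500L,
                            edge_sided = c("one", "two"),
                            orf_method = c("stop_free", "atg"),
                            cons_cover_on = c("query", "subject"),
                            count_scale = 1e6,
                            rng_seed = 1L) {
  cfg <- list(
    min_gene_distance = as.integer(min_gene_distance),
    min_antisense_overlap = as.integer(min_antisense_overlap),
    small_peptide_max = as.integer(small_peptide_max),
    small_peptide_transcript_ratio = as.numeric(small_peptide_transcript_ratio),
    max_orf_fraction = as.numeric(max_orf_fraction),
    min_len = as.integer(min_len),
    max_len = as.integer(max_len),
    cov_threshold_intergenic = as.numeric(cov_threshold_intergenic),
    cov_threshold_antisense = as.numeric(cov_threshold_antisense),
    prot_min_qcov = as.numeric(prot_min_qcov),
    prot_min_bitscore = as.numeric(prot_min_bitscore),
    prot_max_evalue = as.numeric(prot_max_evalue),
    prot_min_identity = as.numeric(prot_min_identity),
    cons_max_evalue = as.numeric(cons_max_evalue),
    cons_min_identity = as.numeric(cons_min_identity),
    cons_min_qcov = as.numeric(cons_min_qcov),
    de_fdr = as.numeric(de_fdr),
    corr_alpha = as.numeric(corr_alpha),
    upstream_len = as.integer(upstream_len),
    top_n_interactions = as.integer(top_n_interactions),
    edge_alpha = as.numeric(edge_alpha),
    edge_grid_step = as.integer(edge_grid_step),
    edge_grid_max = as.integer(edge_grid_max),
    edge_sided = match.arg(edge_sided),
    orf_method = match.arg(orf_method),
    cons_cover_on = match.arg(cons_cover_on),
    count_scale = as.numeric(count_scale),
    rng_seed = as.integer(rng_seed)
  )
  class(cfg) <- "pipeline_config"
  validate_config(cfg)
  cfg
}

#' Validate a pipeline configuration
#'
#' Checks the invariants every stage relies on: length bounds ordered,
#' thresholds positive, the reading-frame fraction strictly inside (0, 1).
#'
#' @param cfg A \code{pipeline_config}.
#' @return \code{cfg}, invisibly, or an error describing the violation.
#' @export
validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (cfg$min_len > cfg$max_len) {
    stop("invalid config: min_len (", cfg$min_len,
         ") exceeds max_len (", cfg$max_len, ")")
  }
  pos <- c("min_gene_distance", "min_antisense_overlap", "small_peptide_max",
           "small_peptide_transcript_ratio", "min_len", "max_len",
           "cov_threshold_intergenic", "cov_threshold_antisense",
           "prot_min_qcov", "prot_min_bitscore", "prot_max_evalue",
           "prot_min_identity", "cons_max_evalue", "cons_min_identity",
           "cons_min_qcov", "de_fdr", "corr_alpha", "upstream_len",
           "top_n_interactions", "edge_alpha", "edge_grid_step",
           "edge_grid_max", "count_scale")
  bad <- pos[vapply(pos, function(f) !is.finite(cfg[[f]]) || cfg[[f]] <= 0,
                    logical(1))]
  if (length(bad)) {
    stop("invalid config: non-positive threshold(s): ",
         paste(bad, collapse = ", "))
  }
  if (cfg$max_orf_fraction <= 0 || cfg$max_orf_fraction >= 1) {
    stop("invalid config: max_orf_fraction must lie strictly in (0, 1)")
  }
  invisible(cfg)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("Pipeline configuration:\n")
  for (f in names(x)) {
    cat(sprintf("  %-32s %s\n", f, format(x[[f]])))
  }
  invisible(x)
}
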