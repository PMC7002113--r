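#' Flag records with significant protein homology
#'
#' A candidate small RNA cannot have significant homology with any known
#' protein. A record is flagged when a single hit simultaneously satisfies
#' all four published conditions, each a strict inequality: query cover >
#' \code{prot_min_qcov}%, bitscore > \code{prot_min_bitscore}, E-value <
#' \code{prot_max_evalue}, identity > \code{prot_min_identity}%.
#'
#' @param catalog An \code{srna_catalog}.
#' @param hits Hit data frame from \code{\link{read_blast_table}} (queries
#'   keyed by transcript id).
#' @return The updated catalog with a \code{protein_homology} provenance
#'   entry.
#' @export
filter_protein_homology <- function(catalog, hits) {
  cfg <- catalog$config
  n_in <- n_surviving(catalog)
  if (nrow(hits)) {
    unknown <- setdiff(unique(hits$query_id), catalog$records$transcript_id)
    if (length(unknown)) {
      warning("ignoring hit(s) for unknown transcript(s): ",
              paste(unknown, collapse = ", "))
      hits <- hits[!hits$query_id %in% unknown, , drop = FALSE]
    }
    sig <- !is.na(hits$query_cover) &
      hits$query_cover > cfg$prot_min_qcov &
      hits$bitscore > cfg$prot_min_bitscore &
      hits$evalue < cfg$prot_max_evalue &
      hits$identity > cfg$prot_min_identity
    flagged_ids <- unique(hits$query_id[sig])
    catalog$records$protein_homology <- catalog$records$protein_homology |
      catalog$records$transcript_id %in% flagged_ids
  }
  add_provenance(catalog, "protein_homology", n_in, n_surviving(catalog))
}

#' Default housekeeping RNA family names
#'
#' tRNA, RNase P and signal recognition particle (SRP) RNAs: abundant
#' conserved housekeeping ncRNAs excluded from the regulatory sRNA set.
#'
#' @return A character vector of family names.
#' @export
housekeeping_families <- function() c("tRNA", "RNase P", "SRP")

#' Annotate Rfam hits and flag housekeeping families
#'
#' Every record with an Rfam hit gets its best (lowest E-value) family name
#' recorded; records hitting a housekeeping family (tRNA, RNase P, SRP by
#' default) are flagged \code{rfam_housekeeping}. Flagged records leave the
#' regulatory sRNA set but remain in the ncRNA catalog
#' (\code{\link{ncrna_records}}), so known ncRNAs such as riboswitches stay
#' reportable.
#'
#' @param catalog An \code{srna_catalog}.
#' @param rfam_hits Data frame from \code{\link{read_rfam_table}}.
#' @param housekeeping Family names/accessions treated as housekeeping;
#'   matched exactly against \code{family_name}, \code{family_accession} and
#'   \code{clan}.
#' @return The updated catalog with an \code{rfam} provenance entry.
#' @export
flag_rfam <- function(catalog, rfam_hits,
                      housekeeping = housekeeping_families()) {
  n_in <- n_surviving(catalog)
  if (nrow(rfam_hits)) {
    rfam_hits <- rfam_hits[order(rfam_hits$query_id, rfam_hits$evalue,
                                 rfam_hits$family_name), , drop = FALSE]
    best <- rfam_hits[!duplicated(rfam_hits$query_id), , drop = FALSE]
    idx <- match(catalog$records$transcript_id, best$query_id)
    hit <- !is.na(idx)
    catalog$records$rfam_family[hit] <- best$family_name[idx[hit]]
    hk <- rfam_hits$family_name %in% housekeeping |
      rfam_hits$family_accession %in% housekeeping |
      (!is.na(rfam_hits$clan) & rfam_hits$clan %in% housekeeping)
    hk_ids <- unique(rfam_hits$query_id[hk])
    catalog$records$rfam_housekeeping <- catalog$records$rfam_housekeeping |
      catalog$records$transcript_id %in% hk_ids
  }
  add_provenance(catalog, "rfam", n_in, n_surviving(catalog))
}

#' Annotate nucleotide-level conservation
#'
#' Marks a record conserved when some nucleotide hit satisfies all three
#' inclusive bounds: E-value at most \code{cons_max_evalue}, identity at
#' least \code{cons_min_identity}%, coverage at least
#' \code{cons_min_qcov}%. Coverage is query cover by default; with
#' \code{cfg$cons_cover_on = "subject"} it is recomputed on the subject via
#' \code{subject_lengths}.
#'
#' @param catalog An \code{srna_catalog}.
#' @param nt_hits Hit data frame from \code{\link{read_blast_table}}.
#' @param subject_lengths Named vector of subject lengths; only needed when
#'   \code{cons_cover_on = "subject"}.
#' @return The updated catalog (conservation annotates, never filters).
#' @export
flag_conserved <- function(catalog, nt_hits, subject_lengths = NULL) {
  cfg <- catalog$config
  if (!nrow(nt_hits)) return(catalog)
  cover <- if (cfg$cons_cover_on == "query") {
    nt_hits$query_cover
  } else {
    if (is.null(subject_lengths)) {
      stop("cons_cover_on = 'subject' requires subject_lengths")
    }
    span <- abs(nt_hits$send - nt_hits$sstart) + 1
    as.numeric(span / subject_lengths[nt_hits$subject_id] * 100)
  }
  keep <- !is.na(cover) &
    nt_hits$evalue <= cfg$cons_max_evalue &
    nt_hits$identity >= cfg$cons_min_identity &
    cover >= cfg$cons_min_qcov
  ids <- unique(nt_hits$query_id[keep])
  catalog$records$conserved <- catalog$records$conserved |
    catalog$records$transcript_id %in% ids
  catalog
}
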