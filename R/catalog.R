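# Filter flags a record can accumulate on its way through the pipeline.
FLAG_COLUMNS <- c("length_fail", "orf_fail", "edge_fail", "coverage_fail",
                  "protein_homology", "rfam_housekeeping")

record_flag_strings <- function(rec) {
  apply(as.matrix(rec[, FLAG_COLUMNS, drop = FALSE]), 1L, function(r) {
    paste(FLAG_COLUMNS[as.logical(r)], collapse = ",")
  })
}

#' sRNA catalog
#'
#' The central result container: one row per classified transcript, with the
#' label (\code{intergenic}, \code{antisense}, \code{coding},
#' \code{ambiguous}), geometric quantities (nearest-gene distances, contig
#' edge distance, reading-frame fraction), accumulated filter flags, and
#' downstream annotation (Rfam family, conservation, taxonomy). A provenance
#' log records the candidate count entering and leaving each stage.
#'
#' @param records Data frame of classified records.
#' @param config The \code{\link{pipeline_config}} used.
#' @param edge_report Optional edge-enrichment report
#'   (\code{\link{compute_edge_threshold}}).
#' @param provenance Data frame with columns \code{step}, \code{n_in},
#'   \code{n_out}.
#' @return An \code{srna_catalog} object.
#' @export
srna_catalog <- function(records, config,
                         edge_report = NULL,
                         provenance = data.frame(step = character(0),
                                                 n_in = integer(0),
                                                 n_out = integer(0))) {
  stopifnot(is.data.frame(records), inherits(config, "pipeline_config"))
  structure(list(records = records, config = config,
                 edge_report = edge_report, provenance = provenance),
            class = "srna_catalog")
}

add_provenance <- function(catalog, step, n_in, n_out) {
  catalog$provenance <- rbind(
    catalog$provenance,
    data.frame(step = step, n_in = as.integer(n_in),
               n_out = as.integer(n_out), stringsAsFactors = FALSE)
  )
  catalog
}

# Number of current survivors: candidate labels, no flags set.
n_surviving <- function(catalog) nrow(surviving_records(catalog))

#' Surviving regulatory sRNA records
#'
#' Records labeled intergenic or antisense with no filter flag set: the
#' regulatory sRNA set.
#'
#' @param catalog An \code{srna_catalog}.
#' @return The surviving subset of \code{catalog$records}.
#' @export
surviving_records <- function(catalog) {
  rec <- catalog$records
  cand <- rec$label %in% c("intergenic", "antisense")
  nofail <- !Reduce(`|`, lapply(FLAG_COLUMNS, function(f) rec[[f]]))
  rec[cand & nofail, , drop = FALSE]
}

#' Noncoding RNA catalog records
#'
#' The two-tier output keeps known Rfam housekeeping RNAs (tRNA, RNase P,
#' SRP) in the ncRNA catalog while excluding them from the regulatory set
#' (\code{\link{surviving_records}}). This returns records passing every
#' filter except the housekeeping exclusion.
#'
#' @param catalog An \code{srna_catalog}.
#' @return The ncRNA subset of \code{catalog$records}.
#' @export
ncrna_records <- function(catalog) {
  rec <- catalog$records
  cand <- rec$label %in% c("intergenic", "antisense")
  other <- setdiff(FLAG_COLUMNS, "rfam_housekeeping")
  nofail <- !Reduce(`|`, lapply(other, function(f) rec[[f]]))
  rec[cand & nofail, , drop = FALSE]
}

#' @export
print.srna_catalog <- function(x, ...) {
  rec <- x$records
  cat("srna_catalog:", nrow(rec), "record(s)\n")
  if (nrow(rec)) {
    tb <- table(rec$label)
    cat("  labels:", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "),
        "\n")
    cat("  surviving regulatory sRNAs:", nrow(surviving_records(x)), "\n")
  }
  if (nrow(x$provenance)) {
    cat("  provenance:\n")
    for (i in seq_len(nrow(x$provenance))) {
      cat(sprintf("    %-18s %6d -> %6d\n", x$provenance$step[i],
                  x$provenance$n_in[i], x$provenance$n_out[i]))
    }
  }
  invisible(x)
}

#' Write the per-record filter-flag table
#'
#' Tab-separated companion to the catalog GFF: one row per record with its
#' label, geometry, flags and annotation, in deterministic (contig, start,
#' id) order.
#'
#' @param catalog An \code{srna_catalog}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_flag_table <- function(catalog, path) {
  rec <- catalog$records
  if (nrow(rec)) {
    rec <- rec[order(rec$contig, rec$start, rec$transcript_id), ,
               drop = FALSE]
  }
  out <- data.frame(
    transcript_id = rec$transcript_id, contig = rec$contig,
    start = rec$start, end = rec$end, strand = rec$strand,
    length = rec$length, coverage = rec$coverage, tpm = rec$tpm,
    label = rec$label,
    nearest_same = rec$nearest_same,
    nearest_opposite = rec$nearest_opposite,
    edge_distance = rec$edge_distance,
    orf_fraction = rec$orf_fraction,
    flags = if (nrow(rec)) record_flag_strings(rec) else character(0),
    conserved = rec$conserved, rfam_family = rec$rfam_family,
    taxonomy = rec$taxonomy,
    stringsAsFactors = FALSE
  )
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
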