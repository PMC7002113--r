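#' Feature-by-sample expression matrix
#'
#' Thin container pairing a non-negative numeric matrix with its kind
#' (\code{raw_count}, \code{normalized_count}, \code{tpm},
#' \code{standardized_tpm}) and the feature-to-contig map needed for
#' contig normalization.
#'
#' @param values Numeric matrix, features as rows (rownames = feature ids),
#'   samples as columns.
#' @param kind One of the four kinds above.
#' @param feature_to_contig Named character vector mapping feature id to
#'   contig id. Contig-level matrices may omit it (features are contigs).
#' @return An \code{expr_matrix} object.
#' @export
expression_matrix <- function(values,
                              kind = c("raw_count", "normalized_count",
                                       "tpm", "standardized_tpm"),
                              feature_to_contig = NULL) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values))) stop("values must carry feature rownames")
  if (any(values < 0, na.rm = TRUE)) stop("expression values must be >= 0")
  if (!is.null(feature_to_contig)) {
    miss <- setdiff(rownames(values), names(feature_to_contig))
    if (length(miss)) {
      stop("no contig mapping for feature(s): ", paste(miss, collapse = ", "))
    }
    feature_to_contig <- feature_to_contig[rownames(values)]
  }
  structure(list(values = values, kind = kind,
                 feature_to_contig = feature_to_contig),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat("expr_matrix [", x$kind, "]: ", nrow(x$values), " feature(s) x ",
      ncol(x$values), " sample(s)\n", sep = "")
  invisible(x)
}

#' Coverage thresholds for intergenic and antisense candidates
#'
#' Candidate enrichment by assembly coverage: intergenic records need at
#' least \code{cov_threshold_intergenic} (5x) and antisense records at least
#' \code{cov_threshold_antisense} (10x); the bound itself passes. Records
#' without a coverage value fail with a warning.
#'
#' @param catalog An \code{srna_catalog}.
#' @return The updated catalog with a \code{coverage} provenance entry.
#' @export
apply_coverage_thresholds <- function(catalog) {
  cfg <- catalog$config
  rec <- catalog$records
  n_in <- n_surviving(catalog)
  nocov <- rec$label %in% c("intergenic", "antisense") & is.na(rec$coverage)
  if (any(nocov)) {
    warning(sum(nocov), " candidate record(s) without coverage fail the ",
            "coverage threshold: ",
            paste(rec$transcript_id[nocov], collapse = ", "))
  }
  fail_i <- rec$label == "intergenic" &
    (is.na(rec$coverage) | rec$coverage < cfg$cov_threshold_intergenic)
  fail_a <- rec$label == "antisense" &
    (is.na(rec$coverage) | rec$coverage < cfg$cov_threshold_antisense)
  rec$coverage_fail <- rec$coverage_fail | fail_i | fail_a
  catalog$records <- rec
  add_provenance(catalog, "coverage", n_in, n_surviving(catalog))
}

ratio_normalize <- function(transcripts, contigs, scale, out_kind) {
  tv <- transcripts$values
  cv <- contigs$values
  map <- transcripts$feature_to_contig
  if (is.null(map)) {
    stop("transcript matrix carries no feature-to-contig map")
  }
  miss <- setdiff(unique(map), rownames(cv))
  if (length(miss)) {
    stop("contig matrix lacks row(s): ", paste(miss, collapse = ", "))
  }
  if (!identical(colnames(tv), colnames(cv))) {
    common <- intersect(colnames(tv), colnames(cv))
    if (length(common) < ncol(tv)) {
      stop("transcript and contig matrices have different samples")
    }
    cv <- cv[, colnames(tv), drop = FALSE]
  }
  denom <- cv[map, , drop = FALSE]
  bad <- tv > 0 & denom == 0
  if (any(bad, na.rm = TRUE)) {
    w <- which(bad, arr.ind = TRUE)
    stop("transcript count > 0 with contig count 0 (inconsistent input), ",
         "e.g. feature ", rownames(tv)[w[1, 1]], " sample ",
         colnames(tv)[w[1, 2]])
  }
  out <- tv / denom * scale
  out[tv == 0] <- 0
  expression_matrix(out, kind = out_kind, feature_to_contig = map)
}

#' Contig-normalize transcript read counts
#'
#' Divides each transcript's read count by the total read count of the
#' contig it lies on (times \code{count_scale}, counts per million of
#' parent-contig reads by default). This removes organism-abundance changes,
#' so only transcript-level regulation remains: scaling a contig's reads in
#' one sample leaves the normalized values of its transcripts unchanged.
#' A transcript count of 0 normalizes to 0 regardless of the contig count;
#' a positive transcript count on a zero-count contig is an input error.
#'
#' @param transcripts An \code{expr_matrix} of kind \code{raw_count} with a
#'   feature-to-contig map.
#' @param contigs An \code{expr_matrix} of kind \code{raw_count}, rows =
#'   contigs, same samples.
#' @param cfg A \code{\link{pipeline_config}} (for \code{count_scale}).
#' @return An \code{expr_matrix} of kind \code{normalized_count}.
#' @export
normalize_counts <- function(transcripts, contigs, cfg = pipeline_config()) {
  stopifnot(transcripts$kind == "raw_count", contigs$kind == "raw_count")
  ratio_normalize(transcripts, contigs, cfg$count_scale, "normalized_count")
}

#' Standardize transcript TPM by contig TPM
#'
#' TPM analogue of \code{\link{normalize_counts}}: transcript TPM divided by
#' the parent contig's TPM (scale 1), giving organism-abundance-adjusted
#' expression for ranking within samples.
#'
#' @param transcripts An \code{expr_matrix} of kind \code{tpm} with a
#'   feature-to-contig map.
#' @param contigs An \code{expr_matrix} of kind \code{tpm}, rows = contigs.
#' @return An \code{expr_matrix} of kind \code{standardized_tpm}.
#' @export
standardized_tpm <- function(transcripts, contigs) {
  stopifnot(transcripts$kind == "tpm", contigs$kind == "tpm")
  ratio_normalize(transcripts, contigs, 1, "standardized_tpm")
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjustment of a p-value vector (the standard FDR control used to
#' call differential expression).
#'
#' @param pvalues Numeric vector of p-values in [0, 1] (NAs pass through).
#' @return Adjusted values, same length and order.
#' @export
bh_fdr <- function(pvalues) {
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  p.adjust(pvalues, method = "BH")
}

#' Negative-binomial Wald test for two-group differential expression
#'
#' Per-feature two-group comparison on contig-normalized counts, modeled as
#' negative binomial with variance mu + alpha * mu^2. In relative terms that
#' law reads var/mu^2 = 1/mu + alpha, so the per-feature squared coefficient
#' of variation (method of moments on the pooled within-group variance) is
#' shrunk in log space toward a 1/mu trend fitted across features; working
#' on the relative scale makes the test exactly invariant to the count
#' scale. The Wald statistic is the log2 fold change (group2 over group1)
#' over its delta-method standard error, referred to a t distribution with
#' n1 + n2 - 2 df (better small-sample calibration than the normal
#' reference), two-sided. FDR control is Benjamini-Hochberg over
#' the tested features; a feature is significant at \code{fdr <= de_fdr}.
#' All-zero features are excluded from testing and reported as NA.
#'
#' @param norm An \code{expr_matrix} (normalized counts).
#' @param design Named character vector or factor mapping sample id to one
#'   of two group labels; the first factor level (or, for a character
#'   vector, the alphabetically first label) is group 1.
#' @param cfg A \code{\link{pipeline_config}} (for \code{de_fdr}).
#' @param prior_df Weight (pseudo-degrees of freedom) of the dispersion
#'   trend in the shrinkage. Default 3.
#' @param disp_floor Lower bound on the dispersion. Default 1e-8.
#' @return A data frame: \code{feature_id}, \code{base_mean}, \code{log2fc},
#'   \code{wald_stat}, \code{pvalue}, \code{fdr}, \code{significant}.
#' @export
differential_expression <- function(norm, design, cfg = pipeline_config(),
                                    prior_df = 3, disp_floor = 1e-8) {
  m <- norm$values
  if (is.factor(design)) {
    lv <- levels(design)
    design <- setNames(as.character(design), names(design))
  } else {
    # deterministic group order for plain character designs
    design <- setNames(as.character(design), names(design))
    lv <- sort(unique(design))
  }
  if (length(lv) != 2L) stop("design must define exactly two groups")
  if (is.null(names(design)) || !all(colnames(m) %in% names(design))) {
    stop("design must name every sample in the matrix")
  }
  design <- design[colnames(m)]
  g1 <- which(design == lv[[1]])
  g2 <- which(design == lv[[2]])
  if (length(g1) < 2L || length(g2) < 2L) {
    stop("each group needs at least 2 samples (got ", length(g1), " and ",
         length(g2), ")")
  }
  n1 <- length(g1); n2 <- length(g2)
  m1 <- rowMeans(m[, g1, drop = FALSE])
  m2 <- rowMeans(m[, g2, drop = FALSE])
  tested <- (m1 + m2) > 0
  v1 <- apply(m[, g1, drop = FALSE], 1L, var)
  v2 <- apply(m[, g2, drop = FALSE], 1L, var)
  s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  mu <- (n1 * m1 + n2 * m2) / (n1 + n2)
  musq <- (n1 * m1^2 + n2 * m2^2) / (n1 + n2)
  # NB mean-variance law in relative terms: var/mu^2 = 1/mu + alpha, so the
  # squared CV is modeled as b0 + b1/mu across features; this keeps the fit
  # exactly invariant to the count scale (b1 absorbs it).
  cv2 <- pmax(s2 / musq, disp_floor)
  ok <- tested & is.finite(cv2) & mu > 0
  cv2_trend <- rep(disp_floor, length(mu))
  if (sum(ok) >= 10L) {
    fit <- lm(cv2[ok] ~ I(1 / mu[ok]))
    b0 <- max(coef(fit)[[1]], disp_floor)
    b1 <- max(coef(fit)[[2]], 0)
    cv2_trend[tested] <- b0 + b1 / mu[tested]
  } else {
    cv2_trend[tested] <- pmax(mean(cv2[ok]), disp_floor)
  }
  df_data <- n1 + n2 - 2
  cv2_shr <- exp((df_data * log(cv2) + prior_df * log(cv2_trend)) /
                   (df_data + prior_df))
  # delta-method SE of the log fold change; a pseudo-mean (half the smallest
  # positive value, scale-equivariant) guards one-group-zero features
  eps <- {
    pos <- m[m > 0]
    if (length(pos)) min(pos) / 2 else 1
  }
  beta <- log2((m2 + ifelse(m2 == 0, eps, 0)) /
                 (m1 + ifelse(m1 == 0, eps, 0)))
  se <- sqrt(cv2_shr * (1 / n1 + 1 / n2)) / log(2)
  stat <- ifelse(is.finite(se) & se > 0, beta / se, 0)
  stat[!tested] <- NA_real_
  pv <- 2 * pt(-abs(stat), df = df_data)
  pv[!tested] <- NA_real_
  fdr <- bh_fdr(pv)
  out <- data.frame(
    feature_id = rownames(m),
    base_mean = mu,
    log2fc = ifelse(tested, beta, NA_real_),
    wald_stat = stat,
    pvalue = pv,
    fdr = fdr,
    significant = !is.na(fdr) & fdr <= cfg$de_fdr,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Write a differential-expression result table
#'
#' Tab-separated, one row per feature, deterministic (input) order.
#'
#' @param de Result data frame from \code{\link{differential_expression}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_de_table <- function(de, path) {
  write.table(de, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a normalized count matrix
#'
#' Writes the matrix as TSV (first column \code{feature_id}) so external DE
#' tools can consume it; \code{round = TRUE} rounds to integers for tools
#' that require count input.
#'
#' @param em An \code{expr_matrix}.
#' @param path Output path.
#' @param round Round values to integers. Default \code{FALSE}.
#' @return \code{path}, invisibly.
#' @export
write_expression_table <- function(em, path, round = FALSE) {
  v <- em$values
  if (round) v <- round(v)
  df <- data.frame(feature_id = rownames(v), v, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
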