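#' Build a run manifest
#'
#' Captures everything that determines a run: the configuration snapshot,
#' md5 digests of the input files, the stage provenance counts, the seed and
#' the package version. The manifest is deliberately free of volatile fields
#' (no timestamps), so identical inputs produce byte-identical manifests.
#'
#' @param config A \code{\link{pipeline_config}}.
#' @param inputs Named character vector of input file paths.
#' @param provenance Provenance data frame (\code{step}, \code{n_in},
#'   \code{n_out}), or NULL.
#' @param seed Integer seed used by the run, or NULL.
#' @return A list suitable for \code{\link{write_manifest}}.
#' @export
run_manifest <- function(config, inputs = character(0), provenance = NULL,
                         seed = NULL) {
  digests <- if (length(inputs)) {
    vapply(inputs, function(p) unname(tools::md5sum(p)), character(1))
  } else {
    character(0)
  }
  list(
    tool = "srnapipe",
    version = as.character(packageVersion("srnapipe")),
    seed = seed,
    config = unclass(config),
    inputs = as.list(digests),
    provenance = if (is.null(provenance)) list() else provenance
  )
}

#' Write a run manifest as JSON
#'
#' @param manifest A manifest from \code{\link{run_manifest}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
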