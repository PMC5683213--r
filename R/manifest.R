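#' Write a run manifest
#'
#' Records, as JSON, everything needed to reproduce an analysis step:
#' the configuration snapshot, the seed(s), package and R versions, a
#' timestamp, and MD5 digests of the input and output files so byte-level
#' reproduction can be verified.
#'
#' @param path manifest file to write (JSON).
#' @param config named list describing the step's parameters.
#' @param seed integer seed(s) used by the step.
#' @param inputs,outputs character vectors of file paths to digest.
#' @return the manifest list, invisibly.
#' @export
write_run_manifest <- function(path, config = list(), seed = NA_integer_,
                               inputs = character(), outputs = character()) {
  digest <- function(files) {
    files <- files[file.exists(files)]
    if (!length(files)) return(list())
    as.list(tools::md5sum(files))
  }
  manifest <- list(
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("fermspec")),
    seed = seed,
    config = config,
    input_digests = digest(inputs),
    output_digests = digest(outputs))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(manifest)
}
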