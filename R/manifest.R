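# Provenance stamping for analysis outputs.

#' Write a run manifest into an output directory
#'
#' Records what produced a directory of results: the command/stage name,
#' root seed, engine identifiers, digests of input files and the package
#' version. Exactly one manifest per output directory.
#'
#' @param out_dir output directory (created if missing).
#' @param command stage or script name.
#' @param seed root seed used for all randomness.
#' @param inputs character vector of input file paths (digested if present).
#' @param engine_ids named character vector of engine identifiers.
#' @return manifest path, invisibly.
#' @export
write_manifest <- function(out_dir, command, seed = NA_integer_,
                           inputs = character(0),
                           engine_ids = character(0)) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  digest1 <- function(p) {
    if (!file.exists(p)) return("missing")
    unname(tools::md5sum(p))
  }
  lines <- c(
    paste0("command\t", command),
    paste0("seed\t", seed),
    paste0("version\t", as.character(utils::packageVersion("codonfit"))),
    paste0("timestamp\t", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    if (length(engine_ids) > 0L)
      paste0("engine\t", names(engine_ids), "=", engine_ids),
    if (length(inputs) > 0L)
      paste0("input\t", inputs, "\t", vapply(inputs, digest1, character(1))))
  path <- file.path(out_dir, "manifest.tsv")
  writeLines(lines, path)
  invisible(path)
}
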