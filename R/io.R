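#' @include AllClasses.R AllGenerics.R
NULL

#' Write a sample table as tidy CSV with a JSON manifest
#'
#' One row per step with the full observable block. Unless `manifest =
#' NULL`, a JSON run manifest (generator, arguments, seed, package
#' version, input hash) is written next to the CSV so the run can be
#' reproduced exactly.
#'
#' @param table a [SampleTable]
#' @param path output CSV path
#' @param manifest output manifest path, default `path` with a
#'   ".manifest.json" suffix; NULL suppresses it
#' @return `path`, invisibly
#' @export
writeSampleTable <- function(table, path,
                             manifest = paste0(path, ".manifest.json")) {
  stopifnot(is(table, "SampleTable"))
  utils::write.csv(table@data, path, row.names = FALSE)
  if (!is.null(manifest)) {
    prov <- table@provenance
    prov$package <- "uniCycle"
    prov$version <- as.character(utils::packageVersion("uniCycle"))
    prov$columns <- names(table@data)
    prov$nRows <- nrow(table@data)
    prov$contentHash <- sum(as.numeric(
      utils::head(unlist(table@data, use.names = FALSE), 1000)))
    jsonlite::write_json(prov, manifest, auto_unbox = TRUE, digits = NA,
                         null = "null")
  }
  invisible(path)
}

#' Read a sample table written by [writeSampleTable()]
#'
#' @param path CSV path
#' @param manifest manifest path, or NULL to skip provenance
#' @return a [SampleTable]
#' @export
readSampleTable <- function(path,
                            manifest = paste0(path, ".manifest.json")) {
  df <- utils::read.csv(path)
  prov <- if (!is.null(manifest) && file.exists(manifest))
    jsonlite::read_json(manifest, simplifyVector = TRUE) else list()
  new("SampleTable", data = df, provenance = as.list(prov))
}
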