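#' Write a result object to disk
#'
#' Tabular results (study grids, sensitivity tables, trajectories) go to
#' CSV; structured single results (design results, OC sets) go to JSON.
#' Floating point values are serialized at full precision so that a
#' round-trip read returns equal values.
#'
#' @param x the object: a data frame (CSV or JSON) or a `DesignResult` /
#'   `OscillationCharacteristics` / plain list (JSON).
#' @param path output file path.
#' @param format `"csv"` or `"json"`; defaults from the file extension.
#' @return `path`, invisibly.
#' @export
writeResults <- function(x, path, format = NULL) {
  format <- format %||% tolower(tools::file_ext(path))
  if (!format %in% c("csv", "json")) {
    stop("unsupported results format: ", format, call. = FALSE)
  }
  if (format == "csv") {
    if (!is.data.frame(x)) stop("CSV output requires a data frame", call. = FALSE)
    utils::write.csv(x, path, row.names = FALSE)
  } else {
    jsonlite::write_json(.serializable(x), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, null = "null")
  }
  invisible(path)
}

#' Read back a result file written by [writeResults()]
#'
#' @param path file path.
#' @param format `"csv"` or `"json"`; defaults from the extension.
#' @return Data frame (CSV) or list (JSON).
#' @export
readResults <- function(path, format = NULL) {
  format <- format %||% tolower(tools::file_ext(path))
  switch(format,
    csv = utils::read.csv(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    stop("unsupported results format: ", format, call. = FALSE)
  )
}

# strip classes / environments so jsonlite serializes plainly
.serializable <- function(x) {
  if (inherits(x, "DesignResult")) {
    x <- x[c("chosen_species", "best_point", "losses", "feasible",
             "converged", "amplitude_design_error", "phase_design_error")]
    return(lapply(x, .serializable))
  }
  if (inherits(x, "OscillationCharacteristics") ||
      inherits(x, "KineticParameters")) {
    return(lapply(unclass(x), .serializable))
  }
  if (is.data.frame(x)) return(x)
  if (is.list(x)) return(lapply(x, .serializable))
  if (is.numeric(x) && !is.null(names(x))) return(as.list(x))
  x
}
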