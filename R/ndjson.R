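# NDJSON ("flat FHIR") serialization: one complete JSON object per line,
# one resource type per file, UTF-8, \n line endings. This layout is what
# lets downstream analytics stream a file of a single type without parsing
# a containing array.

NDJSON_MIME <- "application/fhir+ndjson"

resource_to_json <- function(r) {
  jsonlite::toJSON(resource_to_list(r), auto_unbox = TRUE, digits = NA,
                   null = "null")
}

#' Write resources as NDJSON
#'
#' Serializes an ordered collection of resources of a single type, one JSON
#' object per line. Mixing types in one call violates the one-type-per-file
#' flat layout and is an error.
#'
#' @param resources list of [fhir_resource] objects, all of one type.
#' @param path file path, or a writable connection.
#' @return (invisibly) the number of lines written.
#' @examples
#' p <- fhir_resource("Patient", "p1", "2020-01-01T00:00:00Z")
#' f <- tempfile(fileext = ".ndjson")
#' write_ndjson(list(p), f)
#' readLines(f)
#' @export
write_ndjson <- function(resources, path) {
  types <- unique(vapply(resources, function(r) r$resource_type,
                         character(1)))
  if (length(types) > 1L) {
    stop(layout_error(sprintf(
      "flat FHIR layout violation: one resource type per file, got {%s}",
      paste(types, collapse = ", "))))
  }
  lines <- vapply(resources, function(r) {
    tryCatch(as.character(resource_to_json(r)),
             error = function(e) stop(sprintf(
               "cannot serialize resource '%s': %s",
               resource_key(r), conditionMessage(e)), call. = FALSE))
  }, character(1))
  con <- if (is.character(path)) {
    file(path, open = "wb")
  } else path
  if (is.character(path)) on.exit(close(con))
  if (length(lines)) {
    writeLines(lines, con, sep = "\n", useBytes = TRUE)
  }
  invisible(length(lines))
}

ndjson_lines <- function(resources) {
  # In-memory variant used by the engine's file store.
  n <- write_ndjson(resources, con <- rawConnection(raw(0), "wb"))
  on.exit(close(con))
  txt <- rawToChar(rawConnectionValue(con))
  list(text = txt, count = n)
}

#' Read resources from NDJSON
#'
#' Parses one resource per nonempty line, preserving order. A blank
#' trailing line is tolerated. Malformed lines raise a parse error naming
#' the 1-based line number; objects lacking `resourceType` or `id` raise a
#' validation error with the line number.
#'
#' @param source file path, a connection, or a character scalar holding the
#'   raw NDJSON text.
#' @return list of [fhir_resource] objects in input order.
#' @export
read_ndjson <- function(source) {
  lines <- if (is.character(source) && length(source) == 1L &&
               (grepl("\n", source) || grepl("^\\s*\\{", source))) {
    strsplit(source, "\n", fixed = TRUE)[[1]]
  } else if (is.character(source)) {
    readLines(source, encoding = "UTF-8", warn = FALSE)
  } else {
    readLines(source, encoding = "UTF-8", warn = FALSE)
  }
  out <- vector("list", length(lines))
  keep <- logical(length(lines))
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (!nzchar(trimws(ln))) next
    obj <- tryCatch(
      jsonlite::fromJSON(ln, simplifyVector = FALSE),
      error = function(e) stop(parse_error(sprintf(
        "NDJSON parse error at line %d: %s", i, conditionMessage(e)),
        line = i)))
    res <- tryCatch(
      resource_from_list(obj),
      error = function(e) stop(parse_error(sprintf(
        "invalid resource at line %d: %s", i, conditionMessage(e)),
        line = i)))
    out[[i]] <- res
    keep[i] <- TRUE
  }
  out[keep]
}

layout_error <- function(msg) {
  structure(class = c("bulkfhir_layout_error", "error", "condition"),
            list(message = msg, call = NULL))
}

parse_error <- function(msg, line) {
  structure(class = c("bulkfhir_parse_error", "error", "condition"),
            list(message = msg, call = NULL, line = line))
}
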