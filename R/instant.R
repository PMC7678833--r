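# RFC3339 instants (FHIR `instant`): timezone-aware timestamps used for
# meta.lastUpdated, `_since` filtering, token expiry and manifest times.
# Stored internally as POSIXct in UTC so comparisons are total-ordered.

.instant_re <- paste0(
  "^[0-9]{4}-[0-9]{2}-[0-9]{2}T[0-9]{2}:[0-9]{2}:[0-9]{2}",
  "(\\.[0-9]+)?(Z|[+-][0-9]{2}:?[0-9]{2})$"
)

#' Parse RFC3339 instants
#'
#' Parses timestamp strings of the FHIR `instant` form
#' (`2020-01-01T12:30:00Z`, `2020-01-01T12:30:00.5+01:00`) into POSIXct in
#' UTC. An explicit timezone (either `Z` or a numeric offset) is required:
#' naive timestamps would make `_since` comparisons ambiguous.
#'
#' @param x character vector of timestamps.
#' @return POSIXct vector in UTC; `NA` for elements that do not parse.
#' @examples
#' parse_instant("2020-01-01T00:00:00Z")
#' parse_instant(c("2020-06-01T08:00:00+02:00", "yesterday"))
#' @export
parse_instant <- function(x) {
  x <- as.character(x)
  ok <- !is.na(x) & grepl(.instant_re, x)
  norm <- x
  norm <- sub("Z$", "+0000", norm)
  norm <- sub("([+-][0-9]{2}):([0-9]{2})$", "\\1\\2", norm)
  out <- rep(as.POSIXct(NA, tz = "UTC"), length(x))
  if (any(ok)) {
    parsed <- strptime(norm[ok], "%Y-%m-%dT%H:%M:%OS%z", tz = "UTC")
    out[ok] <- as.POSIXct(parsed, tz = "UTC")
  }
  out
}

#' Format an instant as RFC3339 UTC
#'
#' @param t POSIXct (any timezone) or a number of seconds since the epoch.
#' @return character vector like `"2020-01-01T00:00:00Z"` (whole seconds).
#' @export
format_instant <- function(t) {
  if (is.numeric(t)) t <- as.POSIXct(t, origin = "1970-01-01", tz = "UTC")
  format(t, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
}

#' @rdname parse_instant
#' @return `is_instant()` returns a logical vector: does each element parse?
#' @export
is_instant <- function(x) !is.na(parse_instant(x))

# Current time as POSIXct UTC (single place to stub in tests).
now_utc <- function() as.POSIXct(Sys.time(), tz = "UTC")
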