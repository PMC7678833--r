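# The bulk data download client: authenticate via SMART Backend Services
# when credentials are given, kick off an export, poll the status endpoint
# honoring Retry-After, download every manifest file, and validate the
# NDJSON payloads. Protocol violations raise classed conditions naming the
# stage at which they occurred, so scripted callers can exit nonzero with
# a precise diagnostic.

client_error <- function(stage, msg, ...) {
  structure(class = c(paste0("bulkfhir_client_error_", stage),
                      "bulkfhir_client_error", "error", "condition"),
            list(message = sprintf("[%s stage] %s", stage, msg),
                 call = NULL, stage = stage, ...))
}

#' Credentials for SMART Backend Services
#'
#' @param client_id the id pre-assigned by the server.
#' @param private_key RSA private key (an openssl key object, or a path to
#'   a PEM file).
#' @param token_url the server's token endpoint.
#' @param scopes scopes to request (default: wildcard system read).
#' @return an object of class `backend_credentials`.
#' @export
backend_credentials <- function(client_id, private_key, token_url,
                                scopes = "system/*.read") {
  if (is.character(private_key)) {
    private_key <- openssl::read_key(private_key)
  }
  structure(list(client_id = client_id, private_key = private_key,
                 token_url = token_url, scopes = scopes),
            class = "backend_credentials")
}

fetch_token <- function(conn, credentials) {
  assertion <- build_client_assertion(credentials$client_id,
                                      credentials$private_key,
                                      credentials$token_url)
  form <- paste(
    "grant_type=client_credentials",
    paste0("scope=", utils::URLencode(paste(credentials$scopes,
                                            collapse = " "),
                                      reserved = TRUE)),
    paste0("client_assertion_type=",
           utils::URLencode(CLIENT_ASSERTION_TYPE, reserved = TRUE)),
    paste0("client_assertion=", assertion),
    sep = "&")
  res <- perform(conn, "POST", credentials$token_url,
                 headers = c("Content-Type" =
                               "application/x-www-form-urlencoded"),
                 body = form)
  if (res$status != 200L) {
    stop(client_error("auth", sprintf(
      "token endpoint returned %d: %s", res$status, res$body)))
  }
  tok <- jsonlite::fromJSON(res$body)
  if (is.null(tok$access_token) ||
      !identical(tolower(tok$token_type %||% ""), "bearer")) {
    stop(client_error("auth", "token response lacks a bearer access_token"))
  }
  tok$access_token
}

parse_retry_after <- function(v) {
  if (is.null(v)) return(NA_real_)
  n <- suppressWarnings(as.numeric(v))
  if (!is.na(n)) return(n)
  t <- suppressWarnings(as.POSIXct(v, format = "%a, %d %b %Y %H:%M:%S",
                                   tz = "GMT"))
  if (!is.na(t)) return(max(0, as.numeric(t) - as.numeric(Sys.time())))
  NA_real_
}

#' Download a bulk export
#'
#' Runs the full client side of the export workflow against any
#' standard-compliant server and verifies what it receives: each
#' downloaded file must be well-formed NDJSON of a single resource type
#' with a line count matching the manifest.
#'
#' @param base_url the server's FHIR base URL, or a connection from
#'   [http_connection()] / [local_connection()].
#' @param level `"system"`, `"patient"` or `"group"`.
#' @param group_id group id, required when `level = "group"`.
#' @param type optional character vector for `_type`.
#' @param since optional RFC3339 instant for `_since`.
#' @param output_format optional `_outputFormat` label.
#' @param credentials optional [backend_credentials]; when given, a token
#'   is acquired first and sent as a bearer header throughout.
#' @param dest directory for the downloaded files (created if missing).
#' @param max_wait poll timeout in seconds.
#' @param poll_floor wait used when the server sends no `Retry-After`.
#' @return a `download_summary`: job status, per-file type/path/line
#'   count/bytes, totals, elapsed wall-clock seconds and any validation
#'   issues. Protocol violations raise conditions of class
#'   `bulkfhir_client_error_<stage>` with stage one of `auth`, `kickoff`,
#'   `status`, `file`, `validation`.
#' @export
export_download <- function(base_url, level = "system", group_id = NULL,
                            type = NULL, since = NULL,
                            output_format = NULL, credentials = NULL,
                            dest = tempfile("bulkdl"),
                            max_wait = 600, poll_floor = 1) {
  conn <- if (inherits(base_url, "bulk_connection")) base_url
          else http_connection(base_url)
  dir.create(dest, recursive = TRUE, showWarnings = FALSE)
  t_start <- Sys.time()

  token <- NULL
  if (!is.null(credentials)) token <- fetch_token(conn, credentials)
  auth_header <- if (!is.null(token)) {
    c(Authorization = paste("Bearer", token))
  } else character(0)

  kick_path <- switch(level,
    system = "/$export",
    patient = "/Patient/$export",
    group = {
      if (is.null(group_id)) stop(client_error("kickoff",
                                               "group export needs group_id"))
      paste0("/Group/", group_id, "/$export")
    },
    stop(client_error("kickoff", paste("unknown level:", level))))
  params <- c(
    if (!is.null(type)) paste0("_type=", paste(type, collapse = "%2C")),
    if (!is.null(since)) paste0("_since=", utils::URLencode(since,
                                                            reserved = TRUE)),
    if (!is.null(output_format)) paste0(
      "_outputFormat=", utils::URLencode(output_format, reserved = TRUE)))
  kick_url <- paste0(conn$base_url, kick_path,
                     if (length(params)) paste0("?", paste(params,
                                                           collapse = "&")))

  res <- perform(conn, "GET", kick_url, headers = c(
    Accept = "application/fhir+json", Prefer = "respond-async",
    auth_header))
  if (res$status != 202L) {
    stop(client_error("kickoff", sprintf(
      "expected 202 Accepted, got %d: %s", res$status, res$body),
      status = res$status))
  }
  status_url <- res$headers[["content-location"]]
  if (is.null(status_url) || !nzchar(status_url)) {
    stop(client_error("kickoff", "202 response lacks Content-Location"))
  }

  deadline <- as.numeric(Sys.time()) + max_wait
  manifest <- NULL
  polls <- 0L
  repeat {
    res <- perform(conn, "GET", status_url, headers = auth_header)
    polls <- polls + 1L
    if (res$status == 200L) {
      manifest <- tryCatch(jsonlite::fromJSON(res$body,
                                              simplifyVector = FALSE),
                           error = function(e) NULL)
      if (is.null(manifest)) {
        stop(client_error("status", "completion manifest is not valid JSON"))
      }
      break
    }
    if (res$status == 202L) {
      if (as.numeric(Sys.time()) > deadline) {
        stop(client_error("status", sprintf(
          "export not complete after %ds (%d polls)", max_wait, polls)))
      }
      wait <- parse_retry_after(res$headers[["retry-after"]])
      if (is.na(wait)) wait <- poll_floor
      conn_wait(wait)
      next
    }
    stop(client_error("status", sprintf(
      "status endpoint returned %d: %s", res$status, res$body),
      status = res$status))
  }

  for (f in c("transactionTime", "request", "requiresAccessToken",
              "output", "error")) {
    if (is.null(manifest[[f]]) &&
        !f %in% c("output", "error")) {
      stop(client_error("status", paste("manifest lacks field", f)))
    }
  }
  outputs <- manifest$output %||% list()
  issues <- character(0)
  files <- list()
  per_type_seen <- integer(0)

  for (o in outputs) {
    if (is.null(o$type) || is.null(o$url)) {
      stop(client_error("status", "manifest output entry lacks type or url"))
    }
    fres <- perform(conn, "GET", o$url, headers = auth_header)
    if (fres$status != 200L) {
      stop(client_error("file", sprintf(
        "download of %s returned %d", o$url, fres$status),
        status = fres$status))
    }
    ctype <- fres$headers[["content-type"]] %||% ""
    if (!grepl("application/fhir\\+ndjson", ctype)) {
      issues <- c(issues, sprintf("file %s served as '%s', not %s",
                                  o$url, ctype, NDJSON_MIME))
    }
    k <- sum(vapply(files, function(x) x$type == o$type,
                    logical(1))) + 1L
    path <- file.path(dest, sprintf("%s.%d.ndjson", o$type, k))
    writeLines(sub("\n$", "", fres$body), path, sep = "\n",
               useBytes = TRUE)
    resources <- tryCatch(read_ndjson(fres$body), error = function(e) e)
    if (inherits(resources, "error")) {
      stop(client_error("validation", sprintf(
        "file %s is not well-formed NDJSON: %s", o$url,
        conditionMessage(resources)),
        line = resources$line))
    }
    tys <- unique(vapply(resources, function(r) r$resource_type,
                         character(1)))
    if (length(tys) > 1L || (length(tys) == 1L && tys != o$type)) {
      stop(client_error("validation", sprintf(
        "file %s violates single-type purity (declared %s, found {%s})",
        o$url, o$type, paste(tys, collapse = ", "))))
    }
    n <- length(resources)
    if (!is.null(o$count) && n != o$count) {
      stop(client_error("validation", sprintf(
        "file %s has %d resources but manifest declares %d",
        o$url, n, o$count)))
    }
    files[[length(files) + 1L]] <- list(
      type = o$type, path = path, url = o$url, count = n,
      bytes = file.size(path))
  }

  structure(list(
    status = "complete",
    transaction_time = manifest$transactionTime,
    requires_access_token = isTRUE(manifest$requiresAccessToken),
    files = files,
    total_resources = sum(vapply(files, function(x) x$count, numeric(1))),
    polls = polls,
    elapsed_seconds = as.numeric(difftime(Sys.time(), t_start,
                                          units = "secs")),
    issues = issues,
    dest = dest),
    class = "download_summary")
}

#' @export
print.download_summary <- function(x, ...) {
  cat(sprintf("Bulk export complete: %d resources in %d file(s), %.1fs, %d poll(s)\n",
              x$total_resources, length(x$files), x$elapsed_seconds,
              x$polls))
  for (f in x$files) {
    cat(sprintf("  %-14s %6d resources  %7.0f B  %s\n", f$type, f$count,
                f$bytes, basename(f$path)))
  }
  if (length(x$issues)) {
    cat("Issues:\n"); for (i in x$issues) cat("  -", i, "\n")
  }
  invisible(x)
}

#' Read back every file of a download summary
#'
#' @param summary a `download_summary` from [export_download()].
#' @return list of [fhir_resource] across all downloaded files.
#' @export
summary_resources <- function(summary) {
  out <- list()
  for (f in summary$files) out <- c(out, read_ndjson(f$path))
  out
}
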