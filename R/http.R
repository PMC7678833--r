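# The wire binding: the three $export kickoff endpoints, the token
# endpoint, opaque status and file endpoints, with the protocol's exact
# headers and status codes. The app is a plain request -> response
# function, so it can be exercised in-process or served over a real
# socket with httpuv.

#' Server configuration
#'
#' @param base_url absolute URL of the FHIR base (used to build status and
#'   file locations).
#' @param token_lifetime access-token life in seconds.
#' @param retry_after suggested poll interval (seconds) in `Retry-After`.
#' @param retention_minutes how long completed exports stay hosted.
#' @param requires_access_token enforce SMART Backend Services
#'   authorization on kickoff, status and file endpoints.
#' @param serve_files_separately host output files under a distinct path
#'   prefix outside the FHIR base (emulating a separate file server).
#' @param max_lines_per_file split large per-type outputs into several
#'   files of at most this many lines.
#' @param simulation a [sim_config] for fault injection.
#' @param registrations list of [client_registration] objects.
#' @param fixture either a [population_config] (the repository is
#'   generated on boot) or a path to an NDJSON fixture directory.
#' @param supported_types the closed set of exportable resource types.
#' @return an object of class `server_config`.
#' @export
server_config <- function(base_url = "http://localhost:8080/fhir",
                          token_lifetime = 300,
                          retry_after = 1,
                          retention_minutes = 60,
                          requires_access_token = FALSE,
                          serve_files_separately = FALSE,
                          max_lines_per_file = Inf,
                          simulation = sim_config("none"),
                          registrations = list(),
                          fixture = population_config(),
                          supported_types = FHIR_TYPES) {
  stopifnot(token_lifetime > 0, retry_after >= 0, retention_minutes > 0,
            grepl("^https?://", base_url))
  structure(list(base_url = sub("/$", "", base_url),
                 token_lifetime = token_lifetime,
                 retry_after = retry_after,
                 retention_minutes = retention_minutes,
                 requires_access_token = requires_access_token,
                 serve_files_separately = serve_files_separately,
                 max_lines_per_file = max_lines_per_file,
                 simulation = simulation,
                 registrations = registrations,
                 fixture = fixture,
                 supported_types = supported_types),
            class = "server_config")
}

url_origin <- function(url) sub("^(https?://[^/]+).*$", "\\1", url)
url_path <- function(url) {
  p <- sub("^https?://[^/]+", "", url)
  if (!nzchar(p)) "/" else p
}

#' Build a bulk data server application
#'
#' Assembles repository, authorization service and export engine into a
#' request handler. The handler speaks plain R structures: a request is a
#' list with `method`, `path` (path plus query string), `headers` (named
#' character) and optional `body`; a response is a list with `status`,
#' `headers` and `body`.
#'
#' @param config a [server_config].
#' @return an object of class `bulk_app`.
#' @export
bulk_app <- function(config = server_config()) {
  stopifnot(inherits(config, "server_config"))
  repository <- if (inherits(config$fixture, "population_config")) {
    generate_population(config$fixture)
  } else if (is.character(config$fixture)) {
    load_fixture(config$fixture)
  } else stop("fixture must be a population_config or a directory path",
              call. = FALSE)

  base_path <- url_path(config$base_url)
  token_url <- paste0(url_origin(config$base_url), "/auth/token")
  files_prefix <- if (config$serve_files_separately) "/files" else
    paste0(base_path, "/__files")

  app <- new.env(parent = emptyenv())
  app$config <- config
  app$repository <- repository
  app$auth <- auth_service(config$registrations, token_url,
                           config$token_lifetime,
                           config$supported_types)
  app$engine <- bulk_engine(repository,
                            retry_after = config$retry_after,
                            retention_minutes = config$retention_minutes,
                            max_lines_per_file = config$max_lines_per_file,
                            supported_types = config$supported_types,
                            simulation = config$simulation)
  app$engine$requires_access_token <- config$requires_access_token
  app$base_path <- base_path
  app$token_url <- token_url
  app$files_prefix <- files_prefix
  app$log <- list()
  class(app) <- "bulk_app"
  app
}

#' @export
print.bulk_app <- function(x, ...) {
  cat(sprintf("<bulk_app> base=%s resources=%d auth=%s\n",
              x$config$base_url, length(x$repository$resources),
              if (x$config$requires_access_token) "required" else "open"))
  invisible(x)
}

resp <- function(status, headers = list(), body = "") {
  list(status = as.integer(status), headers = headers, body = body)
}

oo_json <- function(severity, code, diagnostics) {
  as.character(resource_to_json(operation_outcome(severity, code,
                                                  diagnostics)))
}

resp_oo <- function(status, code, diagnostics) {
  resp(status, list("Content-Type" = "application/fhir+json"),
       oo_json(if (status >= 500) "error" else "error", code, diagnostics))
}

resp_json <- function(status, x, headers = list()) {
  headers[["Content-Type"]] <- "application/json"
  resp(status, headers,
       as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                                     null = "null")))
}

parse_query <- function(path) {
  if (!grepl("?", path, fixed = TRUE)) return(list(path = path,
                                                   query = list()))
  parts <- strsplit(path, "?", fixed = TRUE)[[1]]
  q <- list()
  for (kv in strsplit(parts[2], "&", fixed = TRUE)[[1]]) {
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq > 0) {
      k <- utils::URLdecode(substr(kv, 1, eq - 1))
      v <- utils::URLdecode(substr(kv, eq + 1, nchar(kv)))
    } else {
      k <- utils::URLdecode(kv); v <- ""
    }
    q[[k]] <- v
  }
  list(path = parts[1], query = q)
}

parse_form <- function(body) {
  if (is.raw(body)) body <- rawToChar(body)
  q <- list()
  for (kv in strsplit(body, "&", fixed = TRUE)[[1]]) {
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq > 0) {
      q[[utils::URLdecode(substr(kv, 1, eq - 1))]] <-
        utils::URLdecode(chartr("+", " ", substr(kv, eq + 1, nchar(kv))))
    }
  }
  q
}

header_get <- function(headers, name) {
  if (is.null(headers)) return(NULL)
  hit <- which(tolower(names(headers)) == tolower(name))
  if (!length(hit)) NULL else as.character(headers[[hit[1]]])
}

bearer_token <- function(headers) {
  a <- header_get(headers, "Authorization")
  if (is.null(a) || !grepl("^[Bb]earer ", a)) return(NULL)
  sub("^[Bb]earer ", "", a)
}

# Which resource types a kickoff needs read access to.
needed_types_for <- function(app, query_type) {
  if (!is.null(query_type)) {
    strsplit(query_type, ",", fixed = TRUE)[[1]]
  } else {
    app$config$supported_types
  }
}

#' Route one HTTP request through a bulk data app
#'
#' @param app a [bulk_app].
#' @param req list with `method`, `path` (path and query string, absolute
#'   URLs also accepted), `headers` (named character vector or list) and
#'   optional `body` (character or raw; used by the token endpoint).
#' @param now evaluation instant (POSIXct), injectable for expiry tests.
#' @return response list with `status`, `headers`, `body`.
#' @export
route <- function(app, req, now = now_utc()) {
  method <- toupper(req$method %||% "GET")
  rawpath <- req$path %||% "/"
  if (grepl("^https?://", rawpath)) rawpath <- url_path(rawpath)
  pq <- parse_query(rawpath)
  path <- pq$path
  query <- pq$query
  headers <- req$headers %||% character(0)
  app$log[[length(app$log) + 1L]] <- list(method = method, path = path,
                                          time = as.numeric(now))

  if (path == "/health") {
    return(resp_json(200L, list(status = "ok")))
  }
  if (path == "/auth/token" && method == "POST") {
    out <- token_endpoint_handler(app$auth, parse_form(req$body %||% ""),
                                  now = now)
    return(resp_json(out$status, out$body,
                     list("Cache-Control" = "no-store")))
  }

  bp <- app$base_path
  rel <- if (startsWith(path, paste0(bp, "/"))) {
    substr(path, nchar(bp) + 1L, nchar(path))
  } else if (path == bp) "/" else NA_character_

  # separate file host prefix
  if (app$config$serve_files_separately &&
      startsWith(path, "/files/")) {
    return(handle_file(app, substr(path, 8L, nchar(path)), headers, now))
  }

  if (is.na(rel)) {
    return(resp_oo(404L, "not-found", paste("no route for", path)))
  }

  if (rel == "/$export" && method == "GET") {
    return(handle_kickoff(app, "system", NULL, query, headers, rawpath, now))
  }
  if (rel == "/Patient/$export" && method == "GET") {
    return(handle_kickoff(app, "patient", NULL, query, headers, rawpath,
                          now))
  }
  m <- regmatches(rel, regexec("^/Group/([^/]+)/\\$export$", rel))[[1]]
  if (length(m) == 2L && method == "GET") {
    return(handle_kickoff(app, "group", m[2], query, headers, rawpath, now))
  }
  m <- regmatches(rel, regexec("^/__status/([A-Za-z0-9]+)$", rel))[[1]]
  if (length(m) == 2L) {
    if (method == "GET") return(handle_status(app, m[2], headers, now))
    if (method == "DELETE") return(handle_cancel(app, m[2], headers, now))
  }
  m <- regmatches(rel,
                  regexec("^/__files/([A-Za-z0-9]+)/([^/]+)$", rel))[[1]]
  if (length(m) == 3L && method == "GET") {
    return(handle_file(app, paste0(m[2], "/", m[3]), headers, now))
  }
  resp_oo(404L, "not-found", paste("no route for", method, path))
}

require_auth <- function(app, headers, needed_types, now) {
  if (!app$config$requires_access_token) return(TRUE)
  tok <- bearer_token(headers)
  if (is.null(tok)) {
    return(resp_oo(401L, "login", "missing bearer token"))
  }
  dec <- authorize(app$auth, tok, needed_types, now = now)
  if (inherits(dec, "auth_denial")) {
    status <- if (dec$kind == "unauthenticated") 401L else 403L
    return(resp_oo(status, if (status == 401L) "login" else "forbidden",
                   dec$message))
  }
  dec
}

handle_kickoff <- function(app, level, group_id, query, headers, rawpath,
                           now) {
  if (!is.null(query[["_typeFilter"]])) {
    return(resp_oo(422L, "not-supported",
                   "unsupported parameter: _typeFilter"))
  }
  unknown <- setdiff(names(query),
                     c("_outputFormat", "_since", "_type"))
  if (length(unknown)) {
    return(resp_oo(422L, "not-supported",
                   paste("unsupported parameter:", unknown[1])))
  }
  dec <- require_auth(app, headers,
                      needed_types_for(app, query[["_type"]]), now)
  if (!isTRUE(dec) && !inherits(dec, "auth_decision")) return(dec)

  request <- export_request(
    level = level, group_id = group_id,
    type_filter = if (!is.null(query[["_type"]]))
      strsplit(query[["_type"]], ",", fixed = TRUE)[[1]] else NULL,
    since = query[["_since"]],
    output_format = query[["_outputFormat"]],
    policy_group = if (inherits(dec, "auth_decision")) dec$policy_group
                   else NULL)
  job <- engine_kickoff(app$engine, request, headers,
                        request_url = paste0(url_origin(app$config$base_url),
                                             rawpath),
                        now = now)
  if (inherits(job, "kickoff_failure")) {
    return(resp_oo(job$status, job$code, job$diagnostics))
  }
  resp(202L, list(
    "Content-Location" = paste0(app$config$base_url, "/__status/",
                                job$job_id)), "")
}

file_url_fn <- function(app) {
  origin <- url_origin(app$config$base_url)
  prefix <- app$files_prefix
  function(job_id, file_id) paste0(origin, prefix, "/", job_id, "/",
                                   file_id)
}

handle_status <- function(app, job_id, headers, now) {
  dec <- require_auth(app, headers, character(0), now)
  if (!isTRUE(dec) && !inherits(dec, "auth_decision")) return(dec)
  out <- engine_poll(app$engine, job_id, now = now,
                     url_fn = file_url_fn(app))
  switch(out$status,
    not_found = resp_oo(404L, "not-found", "unknown export job"),
    server_error = resp(500L,
                        list("Content-Type" = "application/fhir+json"),
                        as.character(resource_to_json(out$outcome))),
    failed = resp(500L, list("Content-Type" = "application/fhir+json"),
                  as.character(resource_to_json(out$outcome))),
    in_progress = resp(202L, list(
      "X-Progress" = out$progress_text,
      "Retry-After" = as.character(out$retry_after)), ""),
    complete = resp_json(200L, out$manifest, list(
      "Expires" = format(as.POSIXct(out$expires_at,
                                    origin = "1970-01-01", tz = "GMT"),
                         "%a, %d %b %Y %H:%M:%S GMT")))
  )
}

handle_cancel <- function(app, job_id, headers, now) {
  dec <- require_auth(app, headers, character(0), now)
  if (!isTRUE(dec) && !inherits(dec, "auth_decision")) return(dec)
  out <- engine_cancel(app$engine, job_id)
  if (out$status == "cancelled") {
    resp_oo(202L, "informational", "export job cancelled")
  } else {
    resp_oo(404L, "not-found", "unknown export job")
  }
}

handle_file <- function(app, job_file, headers, now) {
  parts <- strsplit(job_file, "/", fixed = TRUE)[[1]]
  if (length(parts) != 2L) {
    return(resp_oo(404L, "not-found", "unknown file"))
  }
  dec <- require_auth(app, headers, character(0), now)
  if (!isTRUE(dec) && !inherits(dec, "auth_decision")) return(dec)
  out <- engine_get_file(app$engine, parts[1], parts[2], now = now)
  if (out$status != "ok") {
    return(resp_oo(404L, "not-found", "unknown or expired file"))
  }
  resp(200L, list("Content-Type" = out$content_type), out$text)
}

#' Serve a bulk data app over HTTP
#'
#' Binds the app to a TCP port with httpuv. The returned handle must be
#' stopped with [bulk_server_stop()]. Requests are served whenever the
#' later event loop runs (`later::run_now()`), which the bundled client
#' transport pumps automatically, so a server and its client can share one
#' R process.
#'
#' @param app a [bulk_app]; its configured `base_url` should use the same
#'   host and port.
#' @param host interface to bind (default loopback).
#' @param port TCP port (default: parsed from the app's base URL).
#' @return a `bulk_server` handle with fields `url` and `port`.
#' @export
bulk_serve <- function(app, host = "127.0.0.1", port = NULL) {
  if (is.null(port)) {
    m <- regmatches(app$config$base_url,
                    regexec("^https?://[^:/]+:([0-9]+)", app$config$base_url))[[1]]
    port <- if (length(m) == 2L) as.integer(m[2]) else 8080L
  }
  srv <- httpuv::startServer(host, port, list(call = function(hreq) {
    hdrs <- character(0)
    for (nm in ls(hreq)) {
      if (startsWith(nm, "HTTP_")) {
        hdrs[gsub("_", "-", substr(nm, 6, nchar(nm)))] <- hreq[[nm]]
      }
    }
    body <- tryCatch(hreq$rook.input$read(), error = function(e) raw(0))
    qs <- hreq$QUERY_STRING %||% ""
    out <- route(app, list(method = hreq$REQUEST_METHOD,
                           path = paste0(hreq$PATH_INFO, qs),
                           headers = hdrs, body = body))
    list(status = out$status, headers = out$headers, body = out$body)
  }))
  structure(list(server = srv, app = app, host = host, port = port,
                 url = sprintf("http://%s:%d", host, port)),
            class = "bulk_server")
}

#' @rdname bulk_serve
#' @param server the handle returned by `bulk_serve()`.
#' @export
bulk_server_stop <- function(server) {
  httpuv::stopServer(server$server)
  invisible(NULL)
}
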