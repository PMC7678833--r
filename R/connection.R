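# Transport abstraction: the client and the conformance suite speak to a
# server through a connection object — either a real HTTP connection
# (curl, pumped through the later event loop so an httpuv server in the
# same R process stays responsive) or an in-process connection that calls
# a bulk_app handler directly.

#' Connect to a bulk data server
#'
#' `http_connection()` talks to any server over HTTP;
#' `local_connection()` routes requests straight into a [bulk_app] in the
#' current process (no sockets), which keeps protocol tests fast and
#' deterministic.
#'
#' @param base_url the server's FHIR base URL.
#' @return a connection object with class `bulk_connection`.
#' @export
http_connection <- function(base_url) {
  structure(list(kind = "http", base_url = sub("/$", "", base_url)),
            class = "bulk_connection")
}

#' @rdname http_connection
#' @param app a [bulk_app].
#' @export
local_connection <- function(app,
                             base_url = app$config$base_url) {
  structure(list(kind = "local", app = app,
                 base_url = sub("/$", "", base_url)),
            class = "bulk_connection")
}

#' @rdname http_connection
#' @param handler function `(method, url, headers, body)` returning a
#'   response list (`status`, `headers`, `body`); `mock_connection()`
#'   wraps it so client code can be exercised against scripted — including
#'   deliberately broken — server behavior.
#' @export
mock_connection <- function(handler, base_url = "http://mock.test/fhir") {
  structure(list(kind = "mock", handler = handler,
                 base_url = sub("/$", "", base_url)),
            class = "bulk_connection")
}

#' Perform one request over a connection
#'
#' @param conn a connection from [http_connection()] or
#'   [local_connection()].
#' @param method HTTP method.
#' @param url absolute URL, or a path relative to the connection's base.
#' @param headers named character vector of request headers.
#' @param body optional request body (character).
#' @param timeout seconds before a transport failure is reported.
#' @return list with `status` (integer), `headers` (named character,
#'   lower-cased names) and `body` (character).
#' @export
perform <- function(conn, method, url, headers = character(0),
                    body = NULL, timeout = 30) {
  if (!grepl("^https?://", url)) {
    # relative paths resolve against the FHIR base (not just the origin)
    url <- paste0(conn$base_url, url)
  }
  if (conn$kind == "mock") {
    out <- conn$handler(method, url, headers, body)
    hdrs <- as.list(unlist(out$headers))
    names(hdrs) <- tolower(names(hdrs))
    return(list(status = as.integer(out$status), headers = hdrs,
                body = as.character(out$body %||% "")))
  }
  if (conn$kind == "local") {
    out <- route(conn$app, list(method = method, path = url,
                                headers = headers, body = body))
    hdrs <- as.list(unlist(out$headers))
    names(hdrs) <- tolower(names(hdrs))
    return(list(status = out$status, headers = hdrs,
                body = as.character(out$body %||% "")))
  }
  h <- curl::new_handle(url = url, customrequest = method,
                        timeout = timeout)
  if (length(headers)) do.call(curl::handle_setheaders,
                               c(list(h), as.list(headers)))
  if (!is.null(body)) {
    curl::handle_setopt(h, postfields = body)
  }
  done <- FALSE; res <- NULL; err <- NULL
  curl::multi_add(h,
                  done = function(x) { done <<- TRUE; res <<- x },
                  fail = function(e) { done <<- TRUE; err <<- e })
  t0 <- Sys.time()
  while (!done) {
    later::run_now(0.002)
    # non-blocking pass: a positive sub-second timeout makes libcurl wait
    # on its own schedule, starving the in-process event loop
    curl::multi_run(timeout = 0)
    if (as.numeric(Sys.time()) - as.numeric(t0) > timeout) {
      curl::multi_cancel(h)
      stop("request timed out: ", url, call. = FALSE)
    }
  }
  if (!is.null(err)) stop("transport failure for ", url, ": ", err,
                          call. = FALSE)
  hdr_lines <- curl::parse_headers(res$headers)
  hdr_lines <- hdr_lines[grepl(":", hdr_lines, fixed = TRUE)]
  nms <- tolower(sub(":.*$", "", hdr_lines))
  vals <- trimws(sub("^[^:]+:", "", hdr_lines))
  list(status = as.integer(res$status_code),
       headers = stats::setNames(as.list(vals), nms),
       body = rawToChar(res$content))
}

#' @rdname perform
#' @details `conn_wait()` sleeps for `seconds` while keeping the later
#'   event loop (and therefore any in-process httpuv server) running.
#' @param seconds how long to wait.
#' @export
conn_wait <- function(seconds) {
  end <- as.numeric(Sys.time()) + seconds
  repeat {
    left <- end - as.numeric(Sys.time())
    if (left <= 0) break
    later::run_now(min(0.05, left))
  }
  invisible(NULL)
}
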