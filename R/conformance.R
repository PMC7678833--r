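# Executable protocol conformance suite: an enumerable catalogue of
# checks (kickoff / status / files / auth groups), each pairing a scripted
# request flow with response predicates, runnable against any bulk data
# server base URL. Outcomes are pass / fail / skip with request/response
# evidence; the report serializes to a versioned JSON schema.

CONFORMANCE_SCHEMA_VERSION <- "1.0"

ev <- function(...) paste0(...)

check_result <- function(outcome, evidence) {
  list(outcome = outcome, evidence = evidence)
}

pass_if <- function(cond, evidence) {
  check_result(if (isTRUE(cond)) "pass" else "fail", evidence)
}

# Each check: id, group, description, severity, run(ctx).
# ctx: conn, auth_headers(), flow(group) -> cached export flow artifacts.
conformance_catalogue <- function() {
  list(

  list(id = "kickoff-accepted", group = "kickoff", severity = "required",
       description = "A valid system kickoff returns 202 Accepted with a Content-Location status URL.",
       run = function(ctx) {
         r <- ctx$kickoff()
         pass_if(r$status == 202L &&
                   nzchar(r$headers[["content-location"]] %||% ""),
                 ev("GET $export -> ", r$status, "; Content-Location: ",
                    r$headers[["content-location"]] %||% "<absent>"))
       }),

  list(id = "kickoff-prefer-required", group = "kickoff",
       severity = "required",
       description = "Kickoff without 'Prefer: respond-async' is rejected with a client error and an OperationOutcome body.",
       run = function(ctx) {
         r <- ctx$request("GET", "/$export",
                          c(Accept = "application/fhir+json"))
         oo <- grepl("OperationOutcome", r$body, fixed = TRUE)
         pass_if(r$status >= 400L && r$status < 500L && oo,
                 ev("GET $export without Prefer -> ", r$status,
                    "; OperationOutcome body: ", oo))
       }),

  list(id = "kickoff-output-format-rejected", group = "kickoff",
       severity = "required",
       description = "An unsupported _outputFormat is rejected at kickoff.",
       run = function(ctx) {
         r <- ctx$request("GET",
                          "/$export?_outputFormat=application%2Fxml",
                          ctx$kick_headers())
         pass_if(r$status >= 400L && r$status < 500L,
                 ev("_outputFormat=application/xml -> ", r$status))
       }),

  list(id = "kickoff-unknown-type-rejected", group = "kickoff",
       severity = "required",
       description = "A _type naming an unsupported resource type is rejected at kickoff.",
       run = function(ctx) {
         r <- ctx$request("GET", "/$export?_type=NotAResource",
                          ctx$kick_headers())
         pass_if(r$status >= 400L && r$status < 500L,
                 ev("_type=NotAResource -> ", r$status))
       }),

  list(id = "kickoff-malformed-since-rejected", group = "kickoff",
       severity = "required",
       description = "An unparseable _since instant is rejected at kickoff.",
       run = function(ctx) {
         r <- ctx$request("GET", "/$export?_since=yesterday",
                          ctx$kick_headers())
         pass_if(r$status >= 400L && r$status < 500L,
                 ev("_since=yesterday -> ", r$status))
       }),

  list(id = "status-progress-headers", group = "status",
       severity = "required",
       description = "While the export runs, status responses are 202 with X-Progress and Retry-After headers.",
       run = function(ctx) {
         fl <- ctx$flow()
         if (!length(fl$in_progress)) {
           return(check_result("skip",
                               "export completed before any in-progress response could be observed"))
         }
         r <- fl$in_progress[[1]]
         pass_if(nzchar(r$headers[["x-progress"]] %||% "") &&
                   nzchar(r$headers[["retry-after"]] %||% ""),
                 ev("first in-progress poll -> 202; X-Progress: '",
                    r$headers[["x-progress"]] %||% "<absent>",
                    "'; Retry-After: '",
                    r$headers[["retry-after"]] %||% "<absent>", "'"))
       }),

  list(id = "status-complete-manifest", group = "status",
       severity = "required",
       description = "Completion is 200 with a JSON manifest carrying transactionTime, request, requiresAccessToken, output and error fields.",
       run = function(ctx) {
         fl <- ctx$flow()
         m <- fl$manifest
         missing <- setdiff(c("transactionTime", "request",
                              "requiresAccessToken", "output", "error"),
                            names(m))
         pass_if(fl$final$status == 200L && !length(missing),
                 ev("completion -> ", fl$final$status,
                    if (length(missing)) paste0("; missing manifest fields: ",
                                                paste(missing,
                                                      collapse = ", "))
                    else "; all required manifest fields present"))
       }),

  list(id = "status-expires-header", group = "status",
       severity = "required",
       description = "The completion response carries an Expires header bounding file hosting.",
       run = function(ctx) {
         fl <- ctx$flow()
         pass_if(nzchar(fl$final$headers[["expires"]] %||% ""),
                 ev("completion Expires: '",
                    fl$final$headers[["expires"]] %||% "<absent>", "'"))
       }),

  list(id = "status-delete-cancels", group = "status",
       severity = "required",
       description = "DELETE on the status URL cancels the job; subsequent polls return 404.",
       run = function(ctx) {
         k <- ctx$kickoff()
         if (k$status != 202L) {
           return(check_result("fail", ev("kickoff for cancellation -> ",
                                          k$status)))
         }
         su <- k$headers[["content-location"]]
         d <- ctx$request("DELETE", su, ctx$auth_headers())
         p <- ctx$request("GET", su, ctx$auth_headers())
         pass_if(d$status %in% c(202L, 200L, 204L) && p$status == 404L,
                 ev("DELETE status URL -> ", d$status,
                    "; subsequent poll -> ", p$status))
       }),

  list(id = "file-content-type", group = "files", severity = "required",
       description = "Output files are served with Content-Type application/fhir+ndjson.",
       run = function(ctx) {
         fl <- ctx$flow()
         if (!length(fl$files)) return(check_result("skip",
                                                    "export produced no files"))
         bad <- Filter(function(f)
           !grepl("application/fhir\\+ndjson", f$content_type), fl$files)
         pass_if(!length(bad),
                 ev(length(fl$files), " file(s); content types: ",
                    paste(unique(vapply(fl$files,
                                        function(f) f$content_type,
                                        character(1))), collapse = ", ")))
       }),

  list(id = "file-single-type-purity", group = "files",
       severity = "required",
       description = "Every output file parses as NDJSON and contains exactly the resource type the manifest declares.",
       run = function(ctx) {
         fl <- ctx$flow()
         if (!length(fl$files)) return(check_result("skip",
                                                    "export produced no files"))
         for (f in fl$files) {
           res <- tryCatch(read_ndjson(f$body), error = function(e) e)
           if (inherits(res, "error")) {
             return(check_result("fail", ev("file ", f$url,
                                            " failed to parse: ",
                                            conditionMessage(res))))
           }
           tys <- unique(vapply(res, function(r) r$resource_type,
                                character(1)))
           if (length(tys) > 1L || (length(tys) == 1L &&
                                    !identical(tys, f$type))) {
             return(check_result("fail", ev("file ", f$url, " declared ",
                                            f$type, " but contains {",
                                            paste(tys, collapse = ", "),
                                            "}")))
           }
         }
         check_result("pass", ev("all ", length(fl$files),
                                 " file(s) single-type and well-formed"))
       }),

  list(id = "file-count-integrity", group = "files",
       severity = "required",
       description = "Each manifest count equals the file's NDJSON line count.",
       run = function(ctx) {
         fl <- ctx$flow()
         if (!length(fl$files)) return(check_result("skip",
                                                    "export produced no files"))
         for (f in fl$files) {
           n <- length(read_ndjson(f$body))
           if (!identical(as.integer(n), as.integer(f$count))) {
             return(check_result("fail", ev("file ", f$url, " has ", n,
                                            " lines, manifest declares ",
                                            f$count)))
           }
         }
         check_result("pass", ev("counts match for ", length(fl$files),
                                 " file(s)"))
       }),

  list(id = "auth-token-roundtrip", group = "auth", severity = "required",
       description = "A signed client assertion is exchanged for a bearer access token with expires_in.",
       run = function(ctx) {
         if (is.null(ctx$credentials)) {
           return(check_result("skip", "no credentials configured"))
         }
         r <- ctx$token_request()
         tok <- tryCatch(jsonlite::fromJSON(r$body),
                         error = function(e) list())
         pass_if(r$status == 200L && !is.null(tok$access_token) &&
                   identical(tolower(tok$token_type %||% ""), "bearer") &&
                   !is.null(tok$expires_in),
                 ev("POST token endpoint -> ", r$status,
                    "; token_type: ", tok$token_type %||% "<absent>",
                    "; expires_in: ", tok$expires_in %||% "<absent>"))
       }),

  list(id = "auth-tampered-assertion-rejected", group = "auth",
       severity = "required",
       description = "A client assertion with a corrupted signature is rejected.",
       run = function(ctx) {
         if (is.null(ctx$credentials)) {
           return(check_result("skip", "no credentials configured"))
         }
         r <- ctx$token_request(tamper = TRUE)
         pass_if(r$status >= 400L && r$status < 500L,
                 ev("tampered assertion -> ", r$status))
       }),

  list(id = "auth-unauthenticated-rejected", group = "auth",
       severity = "required",
       description = "When the server requires access tokens, a kickoff without one returns 401.",
       run = function(ctx) {
         if (!ctx$requires_token()) {
           return(check_result("skip",
                               "server does not require access tokens"))
         }
         r <- ctx$request("GET", "/$export",
                          c(Accept = "application/fhir+json",
                            Prefer = "respond-async"))
         pass_if(r$status == 401L,
                 ev("kickoff without token -> ", r$status))
       }),

  list(id = "auth-insufficient-scope-rejected", group = "auth",
       severity = "required",
       description = "A token scoped to one resource type cannot kick off an export of another (403).",
       run = function(ctx) {
         if (is.null(ctx$credentials) || !ctx$requires_token()) {
           return(check_result("skip",
                               "needs credentials and enforced tokens"))
         }
         tok <- ctx$narrow_token("system/Patient.read")
         if (is.null(tok)) {
           return(check_result("skip",
                               "server would not grant a narrowed scope"))
         }
         r <- ctx$request("GET", "/$export?_type=Observation",
                          c(Accept = "application/fhir+json",
                            Prefer = "respond-async",
                            Authorization = paste("Bearer", tok)))
         pass_if(r$status == 403L,
                 ev("Patient-scoped token, _type=Observation -> ",
                    r$status))
       })
  )
}

#' List the conformance check catalogue
#'
#' @return data.frame with one row per check: `id`, `group`
#'   (kickoff/status/files/auth), `severity` (required/optional) and
#'   `description`. Ids are unique and stable.
#' @export
list_checks <- function() {
  cat_ <- conformance_catalogue()
  data.frame(id = vapply(cat_, `[[`, character(1), "id"),
             group = vapply(cat_, `[[`, character(1), "group"),
             severity = vapply(cat_, `[[`, character(1), "severity"),
             description = vapply(cat_, `[[`, character(1), "description"),
             stringsAsFactors = FALSE)
}

conformance_context <- function(conn, credentials) {
  ctx <- new.env(parent = emptyenv())
  ctx$conn <- conn
  ctx$credentials <- credentials
  ctx$token <- NULL
  ctx$flows <- new.env(parent = emptyenv())

  ctx$auth_headers <- function() {
    if (is.null(credentials)) return(character(0))
    if (is.null(ctx$token)) {
      ctx$token <- tryCatch(fetch_token(conn, credentials),
                            error = function(e) NA_character_)
    }
    if (is.na(ctx$token)) return(character(0))
    c(Authorization = paste("Bearer", ctx$token))
  }
  ctx$kick_headers <- function() {
    c(Accept = "application/fhir+json", Prefer = "respond-async",
      ctx$auth_headers())
  }
  ctx$request <- function(method, url, headers = character(0),
                          body = NULL) {
    perform(conn, method, url, headers, body)
  }
  ctx$kickoff <- function(path = "/$export") {
    ctx$request("GET", path, ctx$kick_headers())
  }
  ctx$requires_token <- function() {
    r <- ctx$request("GET", "/$export",
                     c(Accept = "application/fhir+json",
                       Prefer = "respond-async"))
    r$status == 401L
  }
  ctx$token_request <- function(tamper = FALSE, scope = NULL) {
    cred <- credentials
    assertion <- build_client_assertion(cred$client_id, cred$private_key,
                                        cred$token_url)
    if (tamper) {
      # flip one character of the signature segment
      substr(assertion, nchar(assertion) - 5, nchar(assertion) - 5) <-
        if (substr(assertion, nchar(assertion) - 5,
                   nchar(assertion) - 5) == "A") "B" else "A"
    }
    form <- paste(
      "grant_type=client_credentials",
      paste0("scope=", utils::URLencode(scope %||%
                                          paste(cred$scopes,
                                                collapse = " "),
                                        reserved = TRUE)),
      paste0("client_assertion_type=",
             utils::URLencode(CLIENT_ASSERTION_TYPE, reserved = TRUE)),
      paste0("client_assertion=", assertion),
      sep = "&")
    ctx$request("POST", cred$token_url,
                c("Content-Type" = "application/x-www-form-urlencoded"),
                body = form)
  }
  ctx$narrow_token <- function(scope) {
    r <- ctx$token_request(scope = scope)
    if (r$status != 200L) return(NULL)
    jsonlite::fromJSON(r$body)$access_token
  }
  # One completed export flow, shared by the checks of a run.
  ctx$flow <- function() {
    if (!is.null(ctx$flows$main)) return(ctx$flows$main)
    k <- ctx$kickoff()
    if (k$status != 202L) {
      stop(sprintf("flow kickoff failed: HTTP %d %s", k$status, k$body),
           call. = FALSE)
    }
    su <- k$headers[["content-location"]]
    in_progress <- list()
    final <- NULL
    for (i in 1:200) {
      r <- ctx$request("GET", su, ctx$auth_headers())
      if (r$status == 202L) {
        in_progress[[length(in_progress) + 1L]] <- r
        conn_wait(min(1, parse_retry_after(r$headers[["retry-after"]]) %|na|% 0.1))
        next
      }
      final <- r
      break
    }
    if (is.null(final) || final$status != 200L) {
      stop(sprintf("flow did not complete: HTTP %s %s",
                   if (is.null(final)) "<none>" else final$status,
                   if (is.null(final)) "" else final$body), call. = FALSE)
    }
    manifest <- jsonlite::fromJSON(final$body, simplifyVector = FALSE)
    files <- lapply(manifest$output %||% list(), function(o) {
      fr <- ctx$request("GET", o$url, ctx$auth_headers())
      list(type = o$type, url = o$url, count = o$count,
           status = fr$status,
           content_type = fr$headers[["content-type"]] %||% "",
           body = fr$body)
    })
    ctx$flows$main <- list(kickoff = k, in_progress = in_progress,
                           final = final, manifest = manifest,
                           files = files)
    ctx$flows$main
  }
  ctx
}

`%|na|%` <- function(a, b) if (is.na(a)) b else a

#' Run conformance checks against a server
#'
#' Executes the selected checks from [list_checks()]. A server that cannot
#' be reached, or a flow that cannot complete, marks the affected checks
#' failed with transport evidence rather than aborting.
#'
#' @param base_url server FHIR base URL, or a connection object.
#' @param selection `"all"`, a group name (`"kickoff"`, `"status"`,
#'   `"files"`, `"auth"`), or a single check id.
#' @param credentials optional [backend_credentials] for the auth group
#'   and token-protected servers.
#' @return a `conformance_report`: per-check outcomes with evidence,
#'   totals, target, timestamp and schema version.
#' @export
run_conformance <- function(base_url, selection = "all",
                            credentials = NULL) {
  conn <- if (inherits(base_url, "bulk_connection")) base_url
          else http_connection(base_url)
  cat_ <- conformance_catalogue()
  ids <- vapply(cat_, `[[`, character(1), "id")
  groups <- vapply(cat_, `[[`, character(1), "group")
  selected <- if (identical(selection, "all")) {
    cat_
  } else if (selection %in% groups) {
    cat_[groups == selection]
  } else if (selection %in% ids) {
    cat_[ids == selection]
  } else {
    stop("unknown selection: ", selection, call. = FALSE)
  }

  ctx <- conformance_context(conn, credentials)
  results <- lapply(selected, function(chk) {
    out <- tryCatch(chk$run(ctx), error = function(e)
      check_result("fail", paste("transport/flow failure:",
                                 conditionMessage(e))))
    list(id = chk$id, group = chk$group, severity = chk$severity,
         description = chk$description,
         outcome = out$outcome, evidence = out$evidence)
  })
  outcomes <- vapply(results, `[[`, character(1), "outcome")
  structure(list(
    schema_version = CONFORMANCE_SCHEMA_VERSION,
    target = conn$base_url,
    timestamp = format_instant(now_utc()),
    results = results,
    totals = list(pass = sum(outcomes == "pass"),
                  fail = sum(outcomes == "fail"),
                  skip = sum(outcomes == "skip"),
                  total = length(outcomes))),
    class = "conformance_report")
}

#' @export
print.conformance_report <- function(x, ...) {
  cat(sprintf("Conformance report for %s (%s)\n", x$target, x$timestamp))
  for (r in x$results) {
    cat(sprintf("  [%s] %-34s (%s/%s)\n", toupper(r$outcome), r$id,
                r$group, r$severity))
    if (r$outcome == "fail") cat("        ", r$evidence, "\n")
  }
  cat(sprintf("  %d pass, %d fail, %d skip of %d\n", x$totals$pass,
              x$totals$fail, x$totals$skip, x$totals$total))
  invisible(x)
}

#' Write a conformance report as JSON
#'
#' @param report a `conformance_report`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_conformance_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
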