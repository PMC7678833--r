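# The asynchronous export computation. A kickoff validates parameters and
# snapshots a selection plan; the job then advances one resource type per
# poll "tick" (so clients observe genuine in-progress states), partitioning
# the selection into one-type NDJSON files; completion exposes a JSON
# manifest until a retention deadline passes.

SUPPORTED_OUTPUT_FORMATS <- c("application/fhir+ndjson",
                              "application/ndjson", "ndjson")

#' Describe an export request
#'
#' @param level `"system"` (all resources), `"patient"` (all Patients plus
#'   clinical resources whose subject resolves) or `"group"` (a group's
#'   Patients and their clinical resources).
#' @param group_id required exactly when `level = "group"`.
#' @param type_filter optional character vector of resource types
#'   (`_type`): restrict output to these types.
#' @param since optional RFC3339 instant (`_since`): keep only resources
#'   updated strictly after it.
#' @param output_format optional `_outputFormat` label; only NDJSON labels
#'   are supported.
#' @param policy_group optional group id from the authorization decision;
#'   an account policy intersecting the export with that group's patients.
#' @return an object of class `export_request`.
#' @export
export_request <- function(level = c("system", "patient", "group"),
                           group_id = NULL, type_filter = NULL,
                           since = NULL, output_format = NULL,
                           policy_group = NULL) {
  level <- match.arg(level)
  if (identical(level, "group") && is.null(group_id)) {
    stop("group-level export requires group_id", call. = FALSE)
  }
  if (!identical(level, "group") && !is.null(group_id)) {
    stop("group_id is only valid for group-level export", call. = FALSE)
  }
  structure(list(level = level, group_id = group_id,
                 type_filter = type_filter, since = since,
                 output_format = output_format,
                 policy_group = policy_group),
            class = "export_request")
}

#' Configure server behavior simulation
#'
#' Mirrors the adjustable reference-server behaviors used for client
#' testing: deterministic fault injection at a named stage of the export
#' flow.
#'
#' @param stage where the fault manifests: `"none"` (identity), `"kickoff"`
#'   (kickoff returns a transient server error), `"status"` (status polls
#'   return a server error), `"file"` (a downloaded file carries one
#'   corrupted NDJSON line).
#' @param times how many occurrences are affected before the server
#'   recovers (`Inf` for a persistent fault).
#' @param corrupt_line 1-based line to corrupt for the file stage; when
#'   `NULL` the line is derived deterministically from `seed`.
#' @param seed integer controlling the corruption position.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(stage = c("none", "kickoff", "status", "file"),
                       times = 1, corrupt_line = NULL, seed = 1L) {
  stage <- tryCatch(match.arg(stage), error = function(e)
    stop(structure(class = c("bulkfhir_config_error", "error", "condition"),
                   list(message = paste("invalid simulation stage:",
                                        stage[1]),
                        call = NULL, field = "stage"))))
  structure(list(stage = stage, times = times,
                 corrupt_line = corrupt_line, seed = as.integer(seed)),
            class = "sim_config")
}

#' Create an export engine
#'
#' @param repository the [fhir_repository] to export from.
#' @param retry_after suggested poll interval in seconds (the
#'   `Retry-After` value).
#' @param retention_minutes how long completed files stay downloadable.
#' @param max_lines_per_file split an output type into several files once
#'   it exceeds this many lines (`Inf`: one file per type).
#' @param supported_types the closed set of exportable resource types.
#' @param simulation a [sim_config].
#' @param file_dir directory for the engine's file store (a fresh
#'   temporary directory by default).
#' @return an `bulk_engine` object (an environment).
#' @export
bulk_engine <- function(repository,
                        retry_after = 1,
                        retention_minutes = 60,
                        max_lines_per_file = Inf,
                        supported_types = FHIR_TYPES,
                        simulation = sim_config("none"),
                        file_dir = tempfile("bulkstore")) {
  stopifnot(inherits(repository, "fhir_repository"),
            inherits(simulation, "sim_config"),
            retry_after >= 0, retention_minutes > 0, max_lines_per_file > 0)
  dir.create(file_dir, recursive = TRUE, showWarnings = FALSE)
  e <- new.env(parent = emptyenv())
  e$repository <- repository
  e$retry_after <- retry_after
  e$retention_minutes <- retention_minutes
  e$max_lines_per_file <- max_lines_per_file
  e$supported_types <- supported_types
  e$sim <- simulation
  e$sim_left <- simulation$times
  e$file_dir <- file_dir
  e$jobs <- new.env(parent = emptyenv())
  class(e) <- "bulk_engine"
  e
}

sim_active <- function(engine, stage) {
  engine$sim$stage == stage && engine$sim_left > 0
}

sim_consume <- function(engine) {
  engine$sim_left <- engine$sim_left - 1
}

kickoff_failure <- function(status, code, diagnostics) {
  structure(list(status = as.integer(status), code = code,
                 diagnostics = diagnostics),
            class = "kickoff_failure")
}

#' Select the resources an export request covers
#'
#' The selection predicate at the heart of the export:
#' level scope, intersected with the account-policy group (if any), the
#' `_type` filter (if any), and the strict `last_updated > _since` filter
#' (if any).
#'
#' @param repository a [fhir_repository].
#' @param request an [export_request].
#' @return list of [fhir_resource] in repository order.
#' @export
select_resources <- function(repository, request) {
  res <- repo_resources(repository)
  pat_ids <- repo_patient_ids(repository)

  scope_keep <- function(r, members) {
    # membership scope shared by group level and policy restriction:
    # the group's Patients and clinical resources referencing them
    if (r$resource_type == "Patient") return(r$id %in% members)
    if (!is.null(r$subject_ref)) {
      return(sub("^Patient/", "", r$subject_ref) %in% members)
    }
    FALSE
  }

  keep <- switch(request$level,
    system = rep(TRUE, length(res)),
    patient = vapply(res, function(r) {
      if (r$resource_type == "Patient") return(TRUE)
      if (!is.null(r$subject_ref)) {
        return(sub("^Patient/", "", r$subject_ref) %in% pat_ids)
      }
      FALSE
    }, logical(1)),
    group = {
      members <- repository$groups[[request$group_id]]
      vapply(res, scope_keep, logical(1), members = members)
    })

  if (!is.null(request$policy_group)) {
    members <- repository$groups[[request$policy_group]] %||% character(0)
    keep <- keep & vapply(res, scope_keep, logical(1), members = members)
  }
  res <- res[keep]

  if (!is.null(request$type_filter)) {
    res <- Filter(function(r) r$resource_type %in% request$type_filter, res)
  }
  if (!is.null(request$since)) {
    cutoff <- parse_instant(request$since)
    lu <- parse_instant(vapply(res, function(r) r$last_updated,
                               character(1)))
    res <- res[!is.na(lu) & lu > cutoff]
  }
  res
}

#' Start an export job
#'
#' Validates the kickoff (required `Prefer: respond-async` header, known
#' group, supported `_outputFormat` and `_type`, parseable `_since`) and,
#' on success, snapshots the selection and registers an in-progress job
#' with an unguessable id.
#'
#' @param engine a [bulk_engine].
#' @param request an [export_request].
#' @param headers named character vector of request headers (names
#'   case-insensitive).
#' @param request_url the kickoff URL echoed into the manifest.
#' @param now kickoff instant (POSIXct), recorded as `transactionTime`.
#' @return the job (class `export_job`) or a `kickoff_failure` carrying a
#'   422/404/503-equivalent status and diagnostics.
#' @export
engine_kickoff <- function(engine, request, headers = c(
                             Prefer = "respond-async",
                             Accept = "application/fhir+json"),
                           request_url = "urn:local:$export",
                           now = now_utc()) {
  if (sim_active(engine, "kickoff")) {
    sim_consume(engine)
    return(kickoff_failure(503L, "transient",
                           "simulated kickoff fault; try again later"))
  }
  hdr <- stats::setNames(as.list(as.character(headers)),
                         tolower(names(headers)))
  prefer <- hdr[["prefer"]] %||% ""
  if (!grepl("respond-async", prefer, fixed = TRUE)) {
    return(kickoff_failure(422L, "required",
                           "kickoff requires the 'Prefer: respond-async' header"))
  }
  accept <- hdr[["accept"]] %||% ""
  if (!grepl("application/fhir\\+json|application/json|\\*/\\*", accept)) {
    return(kickoff_failure(422L, "required",
                           "kickoff requires 'Accept: application/fhir+json'"))
  }
  if (!is.null(request$output_format) &&
      !request$output_format %in% SUPPORTED_OUTPUT_FORMATS) {
    return(kickoff_failure(422L, "not-supported", sprintf(
      "_outputFormat '%s' is not supported; supported formats: %s",
      request$output_format,
      paste(SUPPORTED_OUTPUT_FORMATS, collapse = ", "))))
  }
  if (!is.null(request$since) && !is_instant(request$since)) {
    return(kickoff_failure(422L, "invalid", sprintf(
      "_since '%s' is not a valid RFC3339 instant", request$since)))
  }
  if (!is.null(request$type_filter)) {
    bad <- setdiff(request$type_filter, engine$supported_types)
    if (length(bad)) {
      return(kickoff_failure(422L, "not-supported", sprintf(
        "_type names unsupported resource type(s) %s; supported types: %s",
        paste(bad, collapse = ", "),
        paste(engine$supported_types, collapse = ", "))))
    }
  }
  if (identical(request$level, "group") &&
      is.null(engine$repository$groups[[request$group_id]])) {
    return(kickoff_failure(404L, "not-found", sprintf(
      "no such group: %s", request$group_id)))
  }

  selection <- select_resources(engine$repository, request)
  types <- unique(vapply(selection, function(r) r$resource_type,
                         character(1)))
  job_id <- paste(as.character(openssl::rand_bytes(16)), collapse = "")
  job <- new.env(parent = emptyenv())
  job$job_id <- job_id
  job$request <- request
  job$request_url <- request_url
  job$state <- "in_progress"
  job$transaction_time <- now
  job$selection <- selection
  job$pending_types <- types
  job$n_types <- length(types)
  job$outputs <- list()   # list of (type, file_id, count)
  job$errors <- list()
  job$expires_at <- NULL
  class(job) <- "export_job"
  engine$jobs[[job_id]] <- job
  dir.create(file.path(engine$file_dir, job_id), showWarnings = FALSE)
  job
}

#' @export
print.export_job <- function(x, ...) {
  cat(sprintf("<export_job %s> level=%s state=%s outputs=%d\n",
              substr(x$job_id, 1, 8), x$request$level, x$state,
              length(x$outputs)))
  invisible(x)
}

job_progress_text <- function(job) {
  sprintf("%d of %d resource types exported",
          job$n_types - length(job$pending_types), job$n_types)
}

# Advance one unit of work: write all files for one pending resource type;
# finalize when nothing is pending.
engine_tick <- function(engine, job, now = now_utc()) {
  if (!identical(job$state, "in_progress")) return(invisible(job))
  if (length(job$pending_types)) {
    ty <- job$pending_types[1]
    job$pending_types <- job$pending_types[-1]
    batch <- Filter(function(r) r$resource_type == ty, job$selection)
    chunks <- split(batch, ceiling(seq_along(batch) /
                                     min(engine$max_lines_per_file,
                                         length(batch))))
    res <- tryCatch({
      for (k in seq_along(chunks)) {
        file_id <- sprintf("%s.%d.ndjson", ty, k)
        path <- file.path(engine$file_dir, job$job_id, file_id)
        n <- write_ndjson(chunks[[k]], path)
        job$outputs[[length(job$outputs) + 1L]] <-
          list(type = ty, file_id = file_id, count = n)
      }
      TRUE
    }, error = function(e) e)
    if (!isTRUE(res)) {
      # mid-run failure: no partial outputs listed as successes
      job$state <- "failed"
      job$outputs <- list()
      oo <- operation_outcome("error", "exception", conditionMessage(res))
      err_id <- "OperationOutcome.error.ndjson"
      write_ndjson(list(oo), file.path(engine$file_dir, job$job_id, err_id))
      job$errors <- list(list(type = "OperationOutcome",
                              file_id = err_id))
      return(invisible(job))
    }
  }
  if (!length(job$pending_types)) {
    job$state <- "complete"
    job$completed_at <- now
    job$expires_at <- as.numeric(now) + engine$retention_minutes * 60
  }
  invisible(job)
}

#' Run an in-progress job to completion
#'
#' @param engine a [bulk_engine].
#' @param job the job returned by [engine_kickoff()].
#' @param now completion instant.
#' @return the completed (or failed) job, invisibly.
#' @export
run_job <- function(engine, job, now = now_utc()) {
  while (identical(job$state, "in_progress")) engine_tick(engine, job, now)
  invisible(job)
}

build_manifest <- function(engine, job, url_fn = NULL) {
  if (is.null(url_fn)) {
    url_fn <- function(job_id, file_id)
      sprintf("urn:local:%s/%s", job_id, file_id)
  }
  list(
    transactionTime = format_instant(job$transaction_time),
    request = job$request_url,
    requiresAccessToken = isTRUE(engine$requires_access_token),
    output = lapply(job$outputs, function(o)
      list(type = o$type, url = url_fn(job$job_id, o$file_id),
           count = o$count)),
    error = lapply(job$errors, function(o)
      list(type = "OperationOutcome", url = url_fn(job$job_id, o$file_id)))
  )
}

expire_if_due <- function(engine, job, now) {
  if (!is.null(job$expires_at) && as.numeric(now) > job$expires_at) {
    drop_job(engine, job$job_id)
    return(TRUE)
  }
  FALSE
}

drop_job <- function(engine, job_id) {
  unlink(file.path(engine$file_dir, job_id), recursive = TRUE)
  if (!is.null(engine$jobs[[job_id]])) rm(list = job_id,
                                          envir = engine$jobs)
}

#' Poll an export job
#'
#' @param engine a [bulk_engine].
#' @param job_id the job id.
#' @param now evaluation instant.
#' @param url_fn optional function `(job_id, file_id) -> url` used to
#'   build manifest file locations.
#' @return a list whose `status` field is one of `"in_progress"` (with
#'   `progress_text` and `retry_after`), `"complete"` (with `manifest` and
#'   `expires_at`), `"failed"` (with an `outcome` OperationOutcome),
#'   `"not_found"`, or `"server_error"` (injected fault). Polling an
#'   in-progress job advances its work by one resource type.
#' @export
engine_poll <- function(engine, job_id, now = now_utc(), url_fn = NULL) {
  job <- engine$jobs[[job_id]]
  if (is.null(job) || identical(job$state, "cancelled")) {
    return(list(status = "not_found"))
  }
  if (expire_if_due(engine, job, now)) return(list(status = "not_found"))
  if (sim_active(engine, "status")) {
    sim_consume(engine)
    return(list(status = "server_error",
                outcome = operation_outcome(
                  "error", "transient", "simulated status fault")))
  }
  if (identical(job$state, "failed")) {
    return(list(status = "failed",
                outcome = operation_outcome(
                  "error", "exception", "export job failed"),
                manifest = build_manifest(engine, job, url_fn)))
  }
  if (identical(job$state, "in_progress")) {
    out <- list(status = "in_progress",
                progress_text = job_progress_text(job),
                retry_after = engine$retry_after)
    engine_tick(engine, job, now)
    return(out)
  }
  list(status = "complete",
       manifest = build_manifest(engine, job, url_fn),
       expires_at = job$expires_at)
}

#' Fetch one output file of a completed job
#'
#' @param engine a [bulk_engine].
#' @param job_id,file_id job and file identifiers from the manifest.
#' @param now evaluation instant (hosting-deadline check).
#' @return list with `status` `"ok"` (then `text`: the NDJSON payload and
#'   `content_type`) or `"not_found"`.
#' @export
engine_get_file <- function(engine, job_id, file_id, now = now_utc()) {
  job <- engine$jobs[[job_id]]
  if (is.null(job) || identical(job$state, "cancelled")) {
    return(list(status = "not_found"))
  }
  if (expire_if_due(engine, job, now)) return(list(status = "not_found"))
  path <- file.path(engine$file_dir, job_id, file_id)
  known <- c(vapply(job$outputs, function(o) o$file_id, character(1)),
             vapply(job$errors, function(o) o$file_id, character(1)))
  if (!file_id %in% known || !file.exists(path)) {
    return(list(status = "not_found"))
  }
  txt <- readChar(path, file.size(path), useBytes = TRUE)
  if (sim_active(engine, "file")) {
    sim_consume(engine)
    txt <- corrupt_ndjson(txt, engine$sim)
  }
  list(status = "ok", text = txt, content_type = NDJSON_MIME)
}

# Replace one line (seed-chosen unless explicit) with invalid JSON.
corrupt_ndjson <- function(txt, sim) {
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  if (!length(lines)) return("{corrupt\n")
  at <- sim$corrupt_line %||% (1L + sim$seed %% length(lines))
  at <- min(max(1L, at), length(lines))
  lines[at] <- "{corrupt"
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' Cancel an export job
#'
#' Removes the job and its files; subsequent polls and downloads return
#' not-found.
#'
#' @param engine a [bulk_engine].
#' @param job_id the job id.
#' @return list with `status` `"cancelled"` or `"not_found"`.
#' @export
engine_cancel <- function(engine, job_id) {
  job <- engine$jobs[[job_id]]
  if (is.null(job) || identical(job$state, "cancelled")) {
    return(list(status = "not_found"))
  }
  job$state <- "cancelled"
  drop_job(engine, job_id)
  list(status = "cancelled")
}

#' Build an OperationOutcome resource
#'
#' @param severity issue severity (`"error"`, `"warning"`, ...).
#' @param code FHIR issue type code.
#' @param diagnostics human-readable detail.
#' @return a [fhir_resource] of type OperationOutcome.
#' @export
operation_outcome <- function(severity, code, diagnostics) {
  fhir_resource("OperationOutcome",
                paste(as.character(openssl::rand_bytes(6)), collapse = ""),
                format_instant(now_utc()),
                content = list(issue = list(list(
                  severity = severity, code = code,
                  diagnostics = diagnostics))))
}
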