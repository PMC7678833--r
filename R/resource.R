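# Minimal FHIR resource model. A resource is a shallow wrapper around the
# fields the bulk-export protocol actually touches (type, id, lastUpdated,
# subject reference); everything else rides along verbatim in `content`, so
# profile-level structure is passed through untouched.

#' Supported FHIR resource types
#'
#' The closed default set of resource types the toolkit handles: one
#' administrative type (Patient), a roster type (Group), three clinical
#' types referencing a patient, and OperationOutcome for errors.
#' @export
FHIR_TYPES <- c("Patient", "Group", "Observation", "Condition", "Encounter",
                "OperationOutcome")

#' Clinical resource types (carry a subject reference to a Patient)
#' @export
CLINICAL_TYPES <- c("Observation", "Condition", "Encounter")

#' Construct a FHIR resource
#'
#' @param resource_type one of the supported resource types (see
#'   [FHIR_TYPES]; a different closed set may be configured on a server).
#' @param id resource id, unique within its type.
#' @param last_updated RFC3339 instant string for `meta.lastUpdated`.
#' @param subject_ref optional `"Patient/<id>"` reference; clinical
#'   resources use it to link to their patient.
#' @param content named list of all remaining fields, kept verbatim
#'   (JSON objects as named lists, arrays as unnamed lists, scalars as
#'   length-1 vectors).
#' @return an object of class `fhir_resource`.
#' @examples
#' fhir_resource("Patient", "p1", "2020-01-01T00:00:00Z",
#'               content = list(gender = "female"))
#' @export
fhir_resource <- function(resource_type, id, last_updated,
                          subject_ref = NULL, content = list()) {
  if (!is.character(resource_type) || length(resource_type) != 1L ||
      !nzchar(resource_type)) {
    stop("resource_type must be a nonempty string", call. = FALSE)
  }
  if (!is.character(id) || length(id) != 1L || !nzchar(id)) {
    stop("id must be a nonempty string", call. = FALSE)
  }
  structure(
    list(resource_type = resource_type, id = id,
         last_updated = as.character(last_updated),
         subject_ref = subject_ref, content = normalize_tree(content)),
    class = "fhir_resource"
  )
}

# Canonicalize a content tree so that serialize-then-parse is the identity:
# JSON does not distinguish 140 from 140.0, so whole finite doubles are
# stored as integers (the form jsonlite parses them back into).
normalize_tree <- function(x) {
  if (is.list(x)) return(lapply(x, normalize_tree))
  if (is.double(x) && length(x) == 1L && is.finite(x) &&
      x == trunc(x) && abs(x) < .Machine$integer.max) {
    return(as.integer(x))
  }
  x
}

#' @export
print.fhir_resource <- function(x, ...) {
  cat(sprintf("<%s/%s> lastUpdated=%s%s\n", x$resource_type, x$id,
              x$last_updated,
              if (!is.null(x$subject_ref)) paste0(" subject=", x$subject_ref)
              else ""))
  invisible(x)
}

# Convert a resource to the plain list that serializes to its JSON form.
# Field order is fixed (resourceType, id, meta, subject, rest) so equal
# resources serialize to identical bytes.
resource_to_list <- function(r) {
  out <- list(resourceType = r$resource_type, id = r$id)
  meta <- r$content$meta
  if (is.null(meta)) meta <- list()
  meta$lastUpdated <- r$last_updated
  out$meta <- meta
  if (!is.null(r$subject_ref)) {
    subj <- r$content$subject
    if (is.null(subj)) subj <- list()
    subj$reference <- r$subject_ref
    out$subject <- subj
  }
  rest <- r$content
  rest$meta <- NULL
  rest$subject <- NULL
  for (k in names(rest)) out[[k]] <- rest[[k]]
  out
}

# Inverse of resource_to_list: lift a parsed JSON object into fhir_resource.
resource_from_list <- function(x) {
  rt <- x$resourceType
  id <- x$id
  if (is.null(rt) || is.null(id) || !nzchar(as.character(rt)[1]) ||
      !nzchar(as.character(id)[1])) {
    stop("resource lacks resourceType or id", call. = FALSE)
  }
  lu <- x$meta$lastUpdated
  if (is.null(lu)) lu <- NA_character_
  subject_ref <- x$subject$reference
  content <- x
  content$resourceType <- NULL
  content$id <- NULL
  if (!is.null(content$meta)) {
    content$meta$lastUpdated <- NULL
    if (length(content$meta) == 0L) content$meta <- NULL
  }
  if (!is.null(content$subject)) {
    content$subject$reference <- NULL
    if (length(content$subject) == 0L) content$subject <- NULL
  }
  fhir_resource(as.character(rt), as.character(id), as.character(lu),
                subject_ref = if (is.null(subject_ref)) NULL
                              else as.character(subject_ref),
                content = content)
}

resource_key <- function(r) paste0(r$resource_type, "/", r$id)

#' Construct a resource repository
#'
#' A repository is the server-side store behind the export endpoints: a
#' collection of resources (unique by type/id) plus a map from group id to
#' member patient ids.
#'
#' @param resources list of [fhir_resource] objects.
#' @param groups named list mapping group id to a character vector of
#'   patient ids; every member must name a Patient in `resources`.
#' @return an object of class `fhir_repository`.
#' @export
fhir_repository <- function(resources = list(), groups = list()) {
  keys <- vapply(resources, resource_key, character(1))
  if (anyDuplicated(keys)) {
    stop("duplicate (resource_type, id) pair: ",
         keys[duplicated(keys)][1], call. = FALSE)
  }
  names(resources) <- keys
  pat_ids <- vapply(
    Filter(function(r) r$resource_type == "Patient", resources),
    function(r) r$id, character(1))
  for (g in names(groups)) {
    groups[[g]] <- as.character(groups[[g]])
    missing <- setdiff(groups[[g]], pat_ids)
    if (length(missing)) {
      stop("group ", g, " has non-Patient member(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  structure(list(resources = resources, groups = groups),
            class = "fhir_repository")
}

#' @export
print.fhir_repository <- function(x, ...) {
  tys <- repo_types(x)
  cat(sprintf("<fhir_repository> %d resources (%s), %d group(s)\n",
              length(x$resources),
              paste(sprintf("%s: %d", tys,
                            vapply(tys, function(t)
                              length(repo_resources(x, t)), integer(1))),
                    collapse = ", "),
              length(x$groups)))
  invisible(x)
}

#' Repository accessors
#'
#' `repo_types()` lists the resource types present; `repo_resources()`
#' returns the resources of one type (or all) in insertion order;
#' `repo_patient_ids()` returns the ids of all Patients.
#' @param repo a [fhir_repository].
#' @param type optional resource type to filter on.
#' @export
repo_resources <- function(repo, type = NULL) {
  res <- unname(repo$resources)
  if (is.null(type)) return(res)
  Filter(function(r) r$resource_type %in% type, res)
}

#' @rdname repo_resources
#' @export
repo_types <- function(repo) {
  unique(vapply(repo$resources, function(r) r$resource_type, character(1)))
}

#' @rdname repo_resources
#' @export
repo_patient_ids <- function(repo) {
  vapply(repo_resources(repo, "Patient"), function(r) r$id, character(1))
}

#' Validate a resource against a repository
#'
#' Checks the invariants the export engine relies on: type and id present
#' and the type supported, `last_updated` parseable as an RFC3339 instant,
#' and the subject reference (if any) resolving to a Patient in the
#' repository. Issues are returned as a character vector, never raised.
#'
#' @param resource a [fhir_resource].
#' @param repository a [fhir_repository] to resolve references against, or
#'   `NULL` to skip reference resolution.
#' @param types the closed set of supported resource types.
#' @return character vector of issue descriptions; empty when valid.
#' @export
validate_resource <- function(resource, repository = NULL,
                              types = FHIR_TYPES) {
  issues <- character(0)
  if (!resource$resource_type %in% types) {
    issues <- c(issues, sprintf("unsupported resource type '%s'",
                                resource$resource_type))
  }
  if (!is_instant(resource$last_updated)) {
    issues <- c(issues, sprintf(
      "meta.lastUpdated '%s' is not a parseable RFC3339 instant",
      resource$last_updated))
  }
  if (!is.null(resource$subject_ref)) {
    if (!grepl("^Patient/.+$", resource$subject_ref)) {
      issues <- c(issues, sprintf("subject reference '%s' is not of the form Patient/<id>",
                                  resource$subject_ref))
    } else if (!is.null(repository) &&
               !resource$subject_ref %in% names(repository$resources)) {
      issues <- c(issues, sprintf("dangling subject reference '%s'",
                                  resource$subject_ref))
    }
  }
  issues
}
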