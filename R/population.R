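# Seeded synthetic multi-patient repository: minimal plausible Patients,
# Poisson-distributed clinical resources linked to them, patient Groups,
# and lastUpdated instants drawn uniformly over a configured window. The
# point is to exercise the export protocol (grouping, type partitioning,
# `_since` filtering), not clinical realism.

.given_names <- c("Alex", "Sam", "Jordan", "Taylor", "Morgan", "Casey",
                  "Riley", "Avery", "Quinn", "Jamie", "Dana", "Robin")
.family_names <- c("Rivera", "Chen", "Okafor", "Nguyen", "Silva", "Haddad",
                   "Kowalski", "Mbeki", "Larsen", "Rossi", "Tanaka", "Novak")

.obs_codes <- list(
  list(code = "8867-4", display = "Heart rate", unit = "/min",
       lo = 50, hi = 110),
  list(code = "8480-6", display = "Systolic blood pressure", unit = "mm[Hg]",
       lo = 95, hi = 165),
  list(code = "29463-7", display = "Body weight", unit = "kg",
       lo = 45, hi = 120),
  list(code = "2339-0", display = "Glucose", unit = "mg/dL",
       lo = 60, hi = 220)
)
.cond_codes <- list(
  list(code = "44054006", display = "Type 2 diabetes mellitus"),
  list(code = "38341003", display = "Hypertensive disorder"),
  list(code = "195967001", display = "Asthma"),
  list(code = "13645005", display = "Chronic obstructive lung disease")
)
.enc_classes <- c("AMB", "EMER", "IMP")

#' Synthetic population configuration
#'
#' Knobs for the seeded generator. Defaults describe a small but
#' protocol-complete EHR snapshot: 100 patients, a handful of clinical
#' resources each, two overlapping patient groups, and last-updated
#' instants spread over roughly two years so `_since` filters bite at
#' every point of the range.
#'
#' @param n_patients number of Patient resources.
#' @param resources_per_patient named numeric vector of mean per-patient
#'   counts by clinical resource type; counts are drawn Poisson(mean).
#' @param n_groups number of Group resources.
#' @param group_fill fraction in `[0, 1]` of patients assigned to each
#'   group (drawn without replacement, independently per group).
#' @param time_window length-2 character vector of RFC3339 instants
#'   `(start, end)` bounding every `meta.lastUpdated`.
#' @param seed integer RNG seed; identical configs (seed included) yield
#'   byte-identical repositories.
#' @return an object of class `population_config`.
#' @export
population_config <- function(n_patients = 100L,
                              resources_per_patient = c(Observation = 5,
                                                        Condition = 2,
                                                        Encounter = 3),
                              n_groups = 2L,
                              group_fill = 0.3,
                              time_window = c("2019-01-01T00:00:00Z",
                                              "2020-11-01T00:00:00Z"),
                              seed = 1L) {
  bad <- function(field, why) {
    stop(structure(class = c("bulkfhir_config_error", "error", "condition"),
                   list(message = sprintf("invalid %s: %s", field, why),
                        call = NULL, field = field)))
  }
  if (length(n_patients) != 1L || is.na(n_patients) || n_patients < 0)
    bad("n_patients", "must be a nonnegative integer")
  if (length(resources_per_patient) &&
      (is.null(names(resources_per_patient)) ||
       any(!nzchar(names(resources_per_patient)))))
    bad("resources_per_patient", "must be a named vector of means")
  if (any(resources_per_patient < 0) || anyNA(resources_per_patient))
    bad("resources_per_patient", "means must be nonnegative")
  if (!all(names(resources_per_patient) %in% CLINICAL_TYPES))
    bad("resources_per_patient",
        paste("types must be clinical:",
              paste(CLINICAL_TYPES, collapse = ", ")))
  if (length(n_groups) != 1L || is.na(n_groups) || n_groups < 0)
    bad("n_groups", "must be a nonnegative integer")
  if (length(group_fill) != 1L || is.na(group_fill) ||
      group_fill < 0 || group_fill > 1)
    bad("group_fill", "must lie in [0, 1]")
  tw <- parse_instant(time_window)
  if (length(tw) != 2L || anyNA(tw)) bad("time_window",
                                         "must be two RFC3339 instants")
  if (!(tw[1] < tw[2])) bad("time_window", "start must precede end")
  if (length(seed) != 1L || is.na(seed)) bad("seed", "must be an integer")
  structure(list(n_patients = as.integer(n_patients),
                 resources_per_patient = resources_per_patient,
                 n_groups = as.integer(n_groups),
                 group_fill = group_fill,
                 time_window = as.character(time_window),
                 seed = as.integer(seed)),
            class = "population_config")
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  force(code)
}

rand_instant <- function(n, t0, t1) {
  # uniform over the window, whole seconds
  secs <- floor(stats::runif(n, as.numeric(t0), as.numeric(t1)))
  format_instant(secs)
}

#' Generate a synthetic FHIR repository
#'
#' Deterministic under the config's seed. Per-patient clinical resource
#' counts are the first random draws (one `rpois` vector per configured
#' type, types in sorted order), so totals can be replayed independently
#' with the same seed; patient demographics, timestamps, resource content
#' and group membership follow in a fixed order.
#'
#' @param config a [population_config].
#' @return a [fhir_repository] containing `n_patients` Patients, their
#'   clinical resources (every `subject_ref` resolving), and `n_groups`
#'   Group resources whose membership map is mirrored in `repo$groups`.
#' @examples
#' repo <- generate_population(population_config(n_patients = 5, seed = 42))
#' repo
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "population_config"))
  tw <- parse_instant(config$time_window)
  n <- config$n_patients
  with_seed(config$seed, {
    types <- sort(names(config$resources_per_patient))
    counts <- matrix(0L, nrow = max(n, 0L), ncol = length(types),
                     dimnames = list(NULL, types))
    for (ty in types) {
      counts[, ty] <- stats::rpois(n, config$resources_per_patient[[ty]])
    }

    resources <- list()
    pat_ids <- character(0)
    if (n > 0) {
      pat_ids <- sprintf("pat-%06d", seq_len(n))
      given <- sample(.given_names, n, replace = TRUE)
      family <- sample(.family_names, n, replace = TRUE)
      gender <- sample(c("female", "male"), n, replace = TRUE)
      birth <- format(as.Date("1930-01-01") +
                        floor(stats::runif(n, 0, 365.25 * 80)), "%Y-%m-%d")
      lu <- rand_instant(n, tw[1], tw[2])
      for (i in seq_len(n)) {
        resources[[length(resources) + 1L]] <- fhir_resource(
          "Patient", pat_ids[i], lu[i],
          content = list(
            name = list(list(given = list(given[i]), family = family[i])),
            gender = gender[i], birthDate = birth[i]))
      }
    }

    counters <- stats::setNames(rep(0L, length(types)), types)
    for (i in seq_len(n)) {
      for (ty in types) {
        k <- counts[i, ty]
        if (k == 0) next
        lu <- rand_instant(k, tw[1], tw[2])
        for (j in seq_len(k)) {
          counters[[ty]] <- counters[[ty]] + 1L
          id <- sprintf("%s-%06d", tolower(substr(ty, 1, 3)), counters[[ty]])
          content <- switch(ty,
            Observation = {
              cd <- .obs_codes[[sample.int(length(.obs_codes), 1L)]]
              val <- round(stats::runif(1, cd$lo, cd$hi), 1)
              list(status = "final",
                   code = list(coding = list(list(
                     system = "http://loinc.org", code = cd$code,
                     display = cd$display))),
                   valueQuantity = list(value = val, unit = cd$unit))
            },
            Condition = {
              cd <- .cond_codes[[sample.int(length(.cond_codes), 1L)]]
              list(clinicalStatus = list(coding = list(list(
                     code = "active"))),
                   code = list(coding = list(list(
                     system = "http://snomed.info/sct", code = cd$code,
                     display = cd$display))))
            },
            Encounter = {
              list(status = "finished",
                   class = list(code = .enc_classes[
                     sample.int(length(.enc_classes), 1L)]))
            })
          resources[[length(resources) + 1L]] <- fhir_resource(
            ty, id, lu[j], subject_ref = paste0("Patient/", pat_ids[i]),
            content = content)
        }
      }
    }

    groups <- list()
    if (config$n_groups > 0 && n > 0) {
      size <- as.integer(round(config$group_fill * n))
      for (g in seq_len(config$n_groups)) {
        gid <- sprintf("grp-%03d", g)
        members <- sort(sample(pat_ids, size, replace = FALSE))
        groups[[gid]] <- members
        resources[[length(resources) + 1L]] <- fhir_resource(
          "Group", gid, rand_instant(1, tw[1], tw[2]),
          content = list(
            type = "person", actual = TRUE,
            member = lapply(members, function(m)
              list(entity = list(reference = paste0("Patient/", m))))))
      }
    }

    fhir_repository(resources, groups)
  })
}

#' Write a repository to an NDJSON fixture directory
#'
#' One `<ResourceType>.ndjson` file per type present, plus a `groups.json`
#' sidecar mapping group ids to member patient ids.
#'
#' @param repository a [fhir_repository].
#' @param directory target directory (created if missing).
#' @return (invisibly) character vector of the files written.
#' @export
export_fixture <- function(repository, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory)) {
    stop("cannot create fixture directory: ", directory, call. = FALSE)
  }
  written <- character(0)
  for (ty in repo_types(repository)) {
    path <- file.path(directory, paste0(ty, ".ndjson"))
    write_ndjson(repo_resources(repository, ty), path)
    written <- c(written, path)
  }
  sidecar <- file.path(directory, "groups.json")
  gr <- repository$groups
  jsonlite::write_json(if (length(gr)) gr else stats::setNames(list(), character(0)),
                       sidecar, auto_unbox = FALSE)
  invisible(c(written, sidecar))
}

#' Load a repository from an NDJSON fixture directory
#'
#' Inverse of [export_fixture()]: reads every `*.ndjson` file and the
#' `groups.json` sidecar (if present).
#'
#' @param directory directory holding `<ResourceType>.ndjson` files.
#' @return a [fhir_repository].
#' @export
load_fixture <- function(directory) {
  files <- list.files(directory, pattern = "\\.ndjson$", full.names = TRUE)
  resources <- list()
  for (f in sort(files)) {
    resources <- c(resources, read_ndjson(f))
  }
  sidecar <- file.path(directory, "groups.json")
  groups <- list()
  if (file.exists(sidecar)) {
    groups <- lapply(jsonlite::fromJSON(sidecar, simplifyVector = FALSE),
                     function(m) unlist(m, use.names = FALSE))
  }
  # preserve generator ordering: Patients first, then clinical, then Group
  ord <- order(match(vapply(resources, function(r) r$resource_type,
                            character(1)),
                     c("Patient", CLINICAL_TYPES, "Group",
                       "OperationOutcome")))
  fhir_repository(resources[ord], groups)
}
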