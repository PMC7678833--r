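# Shared fixtures and the independent brute-force selection oracle.

# One RSA keypair per test run; 2048-bit generation is cheap but not free.
.test_key_cache <- new.env(parent = emptyenv())
test_key <- function(name = "default") {
  if (is.null(.test_key_cache[[name]])) {
    .test_key_cache[[name]] <- openssl::rsa_keygen(2048)
  }
  .test_key_cache[[name]]
}

test_population <- function(n_patients = 30, seed = 1, ...) {
  population_config(n_patients = n_patients, seed = seed, ...)
}

# A configured in-process server plus client-side plumbing.
new_test_setup <- function(n_patients = 30, seed = 1,
                           n_groups = 2, group_fill = 0.3,
                           requires_access_token = FALSE,
                           registrations = NULL,
                           retry_after = 0, ...) {
  key <- test_key()
  if (is.null(registrations)) {
    registrations <- list(client_registration("test-client", key$pubkey))
  }
  cfg <- server_config(
    base_url = "http://bulk.test/fhir",
    requires_access_token = requires_access_token,
    retry_after = retry_after,
    registrations = registrations,
    fixture = population_config(n_patients = n_patients, seed = seed,
                                n_groups = n_groups,
                                group_fill = group_fill),
    ...)
  app <- bulk_app(cfg)
  list(app = app,
       conn = local_connection(app),
       key = key,
       creds = backend_credentials("test-client", key, app$token_url))
}

# Canonical multiset representation of a resource collection.
res_multiset <- function(resources) {
  sort(vapply(resources, function(r)
    paste(r$resource_type, r$id, r$last_updated, sep = "|"),
    character(1)))
}

# Brute-force selection oracle: an independent, naive re-statement of the
# export predicate (per-resource loop, direct strptime comparison). Kept
# deliberately separate from select_resources().
oracle_select <- function(repo, level, group_id = NULL,
                          policy_group = NULL, types = NULL,
                          since = NULL) {
  pts <- repo_patient_ids(repo)
  since_t <- if (!is.null(since)) {
    s <- sub("Z$", "+0000", since)
    s <- sub("([+-][0-9]{2}):([0-9]{2})$", "\\1\\2", s)
    as.numeric(strptime(s, "%Y-%m-%dT%H:%M:%OS%z", tz = "UTC"))
  } else NULL
  in_group <- function(r, members) {
    if (r$resource_type == "Patient") return(r$id %in% members)
    if (is.null(r$subject_ref)) return(FALSE)
    sub("Patient/", "", r$subject_ref, fixed = TRUE) %in% members
  }
  out <- list()
  for (r in repo_resources(repo)) {
    ok <- switch(level,
      system = TRUE,
      patient = r$resource_type == "Patient" ||
        (!is.null(r$subject_ref) &&
           sub("Patient/", "", r$subject_ref, fixed = TRUE) %in% pts),
      group = in_group(r, repo$groups[[group_id]]))
    if (ok && !is.null(policy_group)) {
      ok <- in_group(r, repo$groups[[policy_group]])
    }
    if (ok && !is.null(types)) ok <- r$resource_type %in% types
    if (ok && !is.null(since_t)) {
      s <- sub("Z$", "+0000", r$last_updated)
      s <- sub("([+-][0-9]{2}):([0-9]{2})$", "\\1\\2", s)
      lu <- as.numeric(strptime(s, "%Y-%m-%dT%H:%M:%OS%z", tz = "UTC"))
      ok <- !is.na(lu) && lu > since_t
    }
    if (ok) out[[length(out) + 1L]] <- r
  }
  out
}

# Random export request parameters under the current RNG state.
random_request_params <- function(repo) {
  level <- sample(c("system", "patient", "group"), 1)
  group_id <- if (level == "group") sample(names(repo$groups), 1) else NULL
  types <- NULL
  if (stats::runif(1) < 0.6) {
    pool <- c("Patient", "Observation", "Condition", "Encounter", "Group")
    types <- sample(pool, sample.int(length(pool), 1))
  }
  since <- NULL
  u <- stats::runif(1)
  if (u < 0.4) {
    # inside the generation window
    t0 <- parse_instant("2019-01-01T00:00:00Z")
    t1 <- parse_instant("2020-11-01T00:00:00Z")
    since <- format_instant(stats::runif(1, as.numeric(t0),
                                         as.numeric(t1)))
  } else if (u < 0.55) {
    since <- sample(c("2000-01-01T00:00:00Z", "2030-01-01T00:00:00Z"), 1)
  }
  list(level = level, group_id = group_id, types = types, since = since)
}
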