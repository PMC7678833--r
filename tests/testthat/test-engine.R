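# Export engine: kickoff validation, selection semantics vs the
# brute-force oracle, job lifecycle, manifests, cancellation, splitting.

engine_for <- function(repo, ...) bulk_engine(repo, retry_after = 0, ...)

complete_job <- function(engine, request, ...) {
  job <- engine_kickoff(engine, request, ...)
  expect_s3_class(job, "export_job")
  run_job(engine, job)
  job
}

job_outputs_multiset <- function(engine, job) {
  out <- list()
  for (o in job$outputs) {
    got <- engine_get_file(engine, job$job_id, o$file_id)
    out <- c(out, read_ndjson(got$text))
  }
  out
}

test_that("kickoff validates headers and parameters with precise failures", {
  repo <- generate_population(test_population(n_patients = 5, seed = 2))
  eng <- engine_for(repo)

  f <- engine_kickoff(eng, export_request("system"), headers = character(0))
  expect_s3_class(f, "kickoff_failure")
  expect_equal(f$status, 422L)
  expect_match(f$diagnostics, "respond-async")
  expect_length(ls(eng$jobs), 0)  # no job created

  f <- engine_kickoff(eng, export_request("system"),
                      headers = c(Prefer = "respond-async"))
  expect_equal(f$status, 422L)
  expect_match(f$diagnostics, "Accept")

  f <- engine_kickoff(eng, export_request("system",
                                          output_format = "text/csv"))
  expect_match(f$diagnostics, "application/fhir\\+ndjson")

  f <- engine_kickoff(eng, export_request("system", since = "yesterday"))
  expect_equal(f$status, 422L)

  f <- engine_kickoff(eng, export_request("system",
                                          type_filter = "Medication"))
  expect_match(f$diagnostics, "supported types")

  f <- engine_kickoff(eng, export_request("group", group_id = "nope"))
  expect_equal(f$status, 404L)

  ok <- engine_kickoff(eng, export_request(
    "system", output_format = "application/fhir+ndjson"))
  expect_s3_class(ok, "export_job")
  expect_match(ok$job_id, "^[0-9a-f]{32}$")
})

test_that("type filter restricts outputs to the named types", {
  repo <- generate_population(test_population(n_patients = 8, seed = 4))
  eng <- engine_for(repo)
  job <- complete_job(eng, export_request("system",
                                          type_filter = "Patient"))
  tys <- unique(vapply(job$outputs, function(o) o$type, character(1)))
  expect_equal(tys, "Patient")
  expect_equal(sum(vapply(job$outputs, function(o) o$count, numeric(1))),
               length(repo_resources(repo, "Patient")))
})

test_that("a _since beyond every timestamp completes with an empty output array", {
  repo <- generate_population(test_population(n_patients = 5, seed = 6))
  eng <- engine_for(repo)
  job <- complete_job(eng, export_request("system",
                                          since = "2030-01-01T00:00:00Z"))
  expect_equal(job$state, "complete")
  expect_length(job$outputs, 0)
  m <- bulkfhir:::build_manifest(eng, job)
  expect_length(m$output, 0)
})

test_that("group exports cover exactly the group members' resources", {
  repo <- generate_population(test_population(n_patients = 10, seed = 8,
                                              n_groups = 2,
                                              group_fill = 0.3))
  eng <- engine_for(repo)
  g <- names(repo$groups)[1]
  job <- complete_job(eng, export_request("group", group_id = g))
  got <- job_outputs_multiset(eng, job)
  expect_identical(res_multiset(got),
                   res_multiset(oracle_select(repo, "group", group_id = g)))
  # the Group resource itself is not part of the output
  expect_false("Group" %in% vapply(got, function(r) r$resource_type,
                                   character(1)))
})

test_that("_since at the median timestamp matches the brute-force filter per type", {
  repo <- generate_population(test_population(n_patients = 40, seed = 10))
  lu <- sort(parse_instant(vapply(repo_resources(repo),
                                  function(r) r$last_updated,
                                  character(1))))
  since <- format_instant(lu[length(lu) %/% 2])
  eng <- engine_for(repo)
  job <- complete_job(eng, export_request("system", since = since))
  got <- job_outputs_multiset(eng, job)
  want <- oracle_select(repo, "system", since = since)
  expect_identical(res_multiset(got), res_multiset(want))
  # per-type counts recorded in outputs match the oracle
  for (o in job$outputs) {
    expect_equal(o$count, sum(vapply(want, function(r)
      r$resource_type == o$type, logical(1))))
  }
})

test_that("selection levels and policy groups match the oracle under randomized requests", {
  repo <- generate_population(test_population(n_patients = 20, seed = 12,
                                              n_groups = 3))
  withr::local_seed(99)
  for (i in 1:15) {
    p <- random_request_params(repo)
    policy <- if (stats::runif(1) < 0.3) sample(names(repo$groups), 1)
              else NULL
    req <- export_request(p$level, group_id = p$group_id,
                          type_filter = p$types, since = p$since,
                          policy_group = policy)
    sel <- select_resources(repo, req)
    want <- oracle_select(repo, p$level, group_id = p$group_id,
                          policy_group = policy, types = p$types,
                          since = p$since)
    expect_identical(res_multiset(sel), res_multiset(want))
  }
})

test_that("_since filtering is monotone and strict", {
  repo <- generate_population(test_population(n_patients = 15, seed = 14))
  lu <- sort(vapply(repo_resources(repo), function(r) r$last_updated,
                    character(1)))
  cuts <- c(NA, lu[c(5, 20, 40)], "2030-01-01T00:00:00Z")
  prev <- NULL
  for (s in cuts) {
    req <- export_request("system",
                          since = if (is.na(s)) NULL else s)
    sel <- res_multiset(select_resources(repo, req))
    if (!is.null(prev)) expect_true(all(sel %in% prev))
    prev <- sel
  }
  # boundary: a resource stamped exactly at _since is excluded
  boundary <- lu[10]
  sel <- select_resources(repo, export_request("system",
                                               since = boundary))
  expect_false(any(vapply(sel, function(r)
    identical(r$last_updated, boundary), logical(1))))
})

test_that("polling advances work, reports progress and idempotent manifests", {
  repo <- generate_population(test_population(n_patients = 6, seed = 16))
  eng <- engine_for(repo)
  job <- engine_kickoff(eng, export_request("system"))
  p1 <- engine_poll(eng, job$job_id)
  expect_equal(p1$status, "in_progress")
  expect_match(p1$progress_text, "of [0-9]+ resource types exported")
  while (engine_poll(eng, job$job_id)$status == "in_progress") NULL
  m1 <- engine_poll(eng, job$job_id)
  m2 <- engine_poll(eng, job$job_id)
  expect_equal(m1$status, "complete")
  expect_identical(m1$manifest, m2$manifest)
  expect_equal(sum(vapply(m1$manifest$output, function(o) o$count,
                          numeric(1))),
               length(repo_resources(repo)))
  # unknown job
  expect_equal(engine_poll(eng, "deadbeef")$status, "not_found")
})

test_that("files expire after the retention window", {
  repo <- generate_population(test_population(n_patients = 3, seed = 18))
  eng <- bulk_engine(repo, retry_after = 0, retention_minutes = 1)
  job <- complete_job(eng, export_request("system"))
  fid <- job$outputs[[1]]$file_id
  expect_equal(engine_get_file(eng, job$job_id, fid)$status, "ok")
  late <- now_utc() + 120
  expect_equal(engine_get_file(eng, job$job_id, fid, now = late)$status,
               "not_found")
  expect_equal(engine_poll(eng, job$job_id, now = late)$status,
               "not_found")
})

test_that("cancellation removes the job and its files", {
  repo <- generate_population(test_population(n_patients = 4, seed = 20))
  eng <- engine_for(repo)
  job <- engine_kickoff(eng, export_request("system"))
  expect_equal(engine_cancel(eng, job$job_id)$status, "cancelled")
  expect_equal(engine_poll(eng, job$job_id)$status, "not_found")
  expect_equal(engine_cancel(eng, job$job_id)$status, "not_found")

  job2 <- complete_job(eng, export_request("system"))
  fid <- job2$outputs[[1]]$file_id
  engine_cancel(eng, job2$job_id)
  expect_equal(engine_get_file(eng, job2$job_id, fid)$status, "not_found")
})

test_that("large outputs split into several files of one type with exact counts", {
  repo <- generate_population(test_population(n_patients = 12, seed = 22))
  eng <- bulk_engine(repo, retry_after = 0, max_lines_per_file = 10)
  job <- complete_job(eng, export_request("system",
                                          type_filter = "Observation"))
  expect_gt(length(job$outputs), 1)
  counts <- vapply(job$outputs, function(o) o$count, numeric(1))
  expect_true(all(counts <= 10))
  expect_equal(sum(counts), length(repo_resources(repo, "Observation")))
  got <- job_outputs_multiset(eng, job)
  expect_identical(res_multiset(got),
                   res_multiset(repo_resources(repo, "Observation")))
})

test_that("fault injection manifests exactly at the configured stage, then recovers", {
  repo <- generate_population(test_population(n_patients = 4, seed = 24))

  eng <- bulk_engine(repo, retry_after = 0,
                     simulation = sim_config("kickoff", times = 1))
  f <- engine_kickoff(eng, export_request("system"))
  expect_s3_class(f, "kickoff_failure")
  expect_equal(f$status, 503L)
  expect_s3_class(engine_kickoff(eng, export_request("system")),
                  "export_job")

  eng2 <- bulk_engine(repo, retry_after = 0,
                      simulation = sim_config("status", times = 1))
  job <- engine_kickoff(eng2, export_request("system"))
  expect_equal(engine_poll(eng2, job$job_id)$status, "server_error")
  expect_equal(engine_poll(eng2, job$job_id)$status, "in_progress")

  eng3 <- bulk_engine(repo, retry_after = 0,
                      simulation = sim_config("file", corrupt_line = 2,
                                              seed = 31))
  job3 <- complete_job(eng3, export_request("system",
                                            type_filter = "Patient"))
  got <- engine_get_file(eng3, job3$job_id, job3$outputs[[1]]$file_id)
  err <- tryCatch(read_ndjson(got$text), error = function(e) e)
  expect_s3_class(err, "bulkfhir_parse_error")
  expect_equal(err$line, 2)
  # recovered: second download is clean
  got2 <- engine_get_file(eng3, job3$job_id, job3$outputs[[1]]$file_id)
  expect_length(read_ndjson(got2$text), job3$outputs[[1]]$count)
})

test_that("zero-fault simulation behaves identically to an unconfigured engine", {
  repo <- generate_population(test_population(n_patients = 5, seed = 26))
  e1 <- bulk_engine(repo, retry_after = 0)
  e2 <- bulk_engine(repo, retry_after = 0,
                    simulation = sim_config("none"))
  j1 <- complete_job(e1, export_request("system"))
  j2 <- complete_job(e2, export_request("system"))
  expect_identical(res_multiset(job_outputs_multiset(e1, j1)),
                   res_multiset(job_outputs_multiset(e2, j2)))
})

test_that("invalid simulation stage is a configuration error", {
  expect_error(sim_config("teardown"), class = "bulkfhir_config_error")
})
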