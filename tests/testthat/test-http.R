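# HTTP surface: routes, exact headers and status codes, auth enforcement,
# separate file hosting, opaque job URLs, and a real-socket round trip.

kick_headers <- c(Accept = "application/fhir+json",
                  Prefer = "respond-async")

test_that("the full happy-path flow carries every mandated header", {
  ts <- new_test_setup(n_patients = 8, seed = 30)
  conn <- ts$conn

  k <- perform(conn, "GET", "/$export", kick_headers)
  expect_equal(k$status, 202L)
  status_url <- k$headers[["content-location"]]
  expect_match(status_url, "^http://bulk\\.test/fhir/__status/")

  r <- perform(conn, "GET", status_url)
  expect_equal(r$status, 202L)
  expect_match(r$headers[["x-progress"]], "resource types exported")
  expect_false(is.null(r$headers[["retry-after"]]))

  repeat {
    r <- perform(conn, "GET", status_url)
    if (r$status != 202L) break
  }
  expect_equal(r$status, 200L)
  expect_false(is.null(r$headers[["expires"]]))
  expect_match(r$headers[["content-type"]], "application/json")
  manifest <- jsonlite::fromJSON(r$body, simplifyVector = FALSE)
  expect_setequal(names(manifest),
                  c("transactionTime", "request", "requiresAccessToken",
                    "output", "error"))
  expect_match(manifest$request, "\\$export")

  f <- perform(conn, "GET", manifest$output[[1]]$url)
  expect_equal(f$status, 200L)
  expect_equal(f$headers[["content-type"]], "application/fhir+ndjson")
  expect_length(read_ndjson(f$body), manifest$output[[1]]$count)
})

test_that("kickoff without the async preference header is a 4XX with no job", {
  ts <- new_test_setup(n_patients = 3, seed = 32)
  r <- perform(ts$conn, "GET", "/$export",
               c(Accept = "application/fhir+json"))
  expect_equal(r$status, 422L)
  expect_true(is.null(r$headers[["content-location"]]))
  expect_match(r$body, "OperationOutcome")
  expect_length(ls(ts$app$engine$jobs), 0)
})

test_that("the three kickoff endpoints map to the three export levels", {
  ts <- new_test_setup(n_patients = 10, seed = 34)
  g <- names(ts$app$repository$groups)[1]
  for (spec in list(list(path = "/$export", level = "system"),
                    list(path = "/Patient/$export", level = "patient"),
                    list(path = paste0("/Group/", g, "/$export"),
                         level = "group"))) {
    k <- perform(ts$conn, "GET", spec$path, kick_headers)
    expect_equal(k$status, 202L)
    jobs <- ls(ts$app$engine$jobs)
    job <- ts$app$engine$jobs[[jobs[length(jobs)]]]
    latest <- Find(function(j) TRUE, lapply(jobs, function(id)
      ts$app$engine$jobs[[id]]))
  }
  levels <- vapply(ls(ts$app$engine$jobs), function(id)
    ts$app$engine$jobs[[id]]$request$level, character(1))
  expect_setequal(levels, c("system", "patient", "group"))
  # unknown group is 404
  r <- perform(ts$conn, "GET", "/Group/ghost/$export", kick_headers)
  expect_equal(r$status, 404L)
})

test_that("the experimental _typeFilter parameter is rejected as unsupported", {
  ts <- new_test_setup(n_patients = 3, seed = 36)
  r <- perform(ts$conn, "GET",
               "/$export?_typeFilter=Observation%3Fstatus%3Dfinal",
               kick_headers)
  expect_equal(r$status, 422L)
  expect_match(r$body, "_typeFilter")
})

test_that("DELETE on the status URL cancels and later polls are 404", {
  ts <- new_test_setup(n_patients = 3, seed = 38)
  k <- perform(ts$conn, "GET", "/$export", kick_headers)
  su <- k$headers[["content-location"]]
  d <- perform(ts$conn, "DELETE", su)
  expect_equal(d$status, 202L)
  expect_equal(perform(ts$conn, "GET", su)$status, 404L)
})

test_that("status URLs are opaque: probing adjacent ids finds nothing", {
  ts <- new_test_setup(n_patients = 3, seed = 40)
  k <- perform(ts$conn, "GET", "/$export", kick_headers)
  su <- k$headers[["content-location"]]
  id <- sub(".*/", "", su)
  expect_match(id, "^[0-9a-f]{32}$")  # 128 random bits, not sequential
  for (probe in c(paste0(substr(id, 1, 31), "0"),
                  paste0(substr(id, 1, 31), "f"),
                  "00000000000000000000000000000001")) {
    if (probe == id) next
    r <- perform(ts$conn, "GET",
                 paste0("/__status/", probe))
    expect_equal(r$status, 404L)
  }
})

test_that("auth is enforced at kickoff, status and file endpoints", {
  ts <- new_test_setup(n_patients = 5, seed = 42,
                       requires_access_token = TRUE)
  conn <- ts$conn
  # no token: 401 everywhere
  expect_equal(perform(conn, "GET", "/$export", kick_headers)$status,
               401L)
  # token via the wire form
  tok <- bulkfhir:::fetch_token(conn, ts$creds)
  auth <- c(Authorization = paste("Bearer", tok))
  k <- perform(conn, "GET", "/$export", c(kick_headers, auth))
  expect_equal(k$status, 202L)
  su <- k$headers[["content-location"]]
  expect_equal(perform(conn, "GET", su)$status, 401L)
  expect_true(perform(conn, "GET", su, auth)$status %in% c(200L, 202L))

  # insufficient scope at kickoff is 403
  r <- perform(conn, "POST", ts$app$token_url,
               c("Content-Type" = "application/x-www-form-urlencoded"),
               body = paste0(
                 "grant_type=client_credentials&scope=system%2FPatient.read",
                 "&client_assertion_type=",
                 utils::URLencode(bulkfhir:::CLIENT_ASSERTION_TYPE,
                                  reserved = TRUE),
                 "&client_assertion=",
                 build_client_assertion("test-client", ts$key,
                                        ts$app$token_url)))
  narrow <- jsonlite::fromJSON(r$body)$access_token
  r2 <- perform(conn, "GET", "/$export?_type=Observation",
                c(kick_headers,
                  Authorization = paste("Bearer", narrow)))
  expect_equal(r2$status, 403L)
})

test_that("account policy restricts every export to the client's group", {
  key <- test_key()
  ts <- new_test_setup(
    n_patients = 12, seed = 44, requires_access_token = TRUE,
    registrations = list(
      client_registration("payor", key$pubkey, "system/*.read",
                          policy_group = "grp-001")))
  creds <- backend_credentials("payor", key, ts$app$token_url)
  s <- export_download(ts$conn, level = "system", credentials = creds,
                       poll_floor = 0)
  got <- summary_resources(s)
  want <- oracle_select(ts$app$repository, "system",
                        policy_group = "grp-001")
  expect_identical(res_multiset(got), res_multiset(want))
  expect_gt(length(want), 0)
  expect_lt(length(want), length(repo_resources(ts$app$repository)))
})

test_that("separate file hosting moves urls outside the FHIR base but keeps them working", {
  ts <- new_test_setup(n_patients = 4, seed = 46,
                       serve_files_separately = TRUE)
  s <- export_download(ts$conn, poll_floor = 0)
  for (f in s$files) {
    expect_match(f$url, "^http://bulk\\.test/files/")
    expect_false(grepl("/fhir/", f$url))
  }
  expect_false(s$requires_access_token)
})

test_that("only the allowed status codes appear across a scripted flow", {
  ts <- new_test_setup(n_patients = 5, seed = 48)
  conn <- ts$conn
  seen <- integer(0)
  k <- perform(conn, "GET", "/$export", kick_headers)
  seen <- c(seen, k$status)
  su <- k$headers[["content-location"]]
  repeat {
    r <- perform(conn, "GET", su)
    seen <- c(seen, r$status)
    if (r$status != 202L) break
  }
  manifest <- jsonlite::fromJSON(r$body, simplifyVector = FALSE)
  for (o in manifest$output) {
    seen <- c(seen, perform(conn, "GET", o$url)$status)
  }
  seen <- c(seen, perform(conn, "GET", "/nonsense")$status)
  expect_true(all(seen %in% c(200L, 202L, 404L)))
})

test_that("the server works over a real TCP socket end to end", {
  port <- httpuv::randomPort()
  base <- sprintf("http://127.0.0.1:%d/fhir", port)
  cfg <- server_config(base_url = base, retry_after = 0,
                       fixture = population_config(n_patients = 6,
                                                   seed = 50))
  app <- bulk_app(cfg)
  srv <- bulk_serve(app)
  on.exit(bulk_server_stop(srv))
  s <- export_download(base, poll_floor = 0)
  expect_equal(s$status, "complete")
  expect_identical(
    res_multiset(summary_resources(s)),
    res_multiset(oracle_select(app$repository, "system")))
})
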