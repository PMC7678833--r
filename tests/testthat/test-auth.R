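# SMART Backend Services: signatures, token issuance, scope algebra,
# expiry boundaries, replay rejection.

make_auth <- function(regs = NULL, lifetime = 300) {
  key <- test_key()
  if (is.null(regs)) {
    regs <- list(client_registration("c1", key$pubkey, "system/*.read"))
  }
  list(auth = auth_service(regs, "http://as.test/auth/token", lifetime),
       key = key)
}

test_that("a client assertion verifies under its own public key only", {
  key <- test_key()
  other <- test_key("other")
  a <- build_client_assertion("c1", key, "http://as.test/auth/token")
  expect_true(jwt_decode(a, key$pubkey)$valid)
  expect_false(jwt_decode(a, other$pubkey)$valid)
  claims <- jwt_decode(a)$claims
  expect_equal(claims$iss, "c1")
  expect_equal(claims$sub, "c1")
  expect_equal(claims$aud, "http://as.test/auth/token")
})

test_that("assertion lifetime is capped at five minutes", {
  expect_error(build_client_assertion("c1", test_key(), "http://x",
                                      lifetime = 301), "300")
})

test_that("issuance: happy path, scope narrowing, rejections are distinguishable", {
  s <- make_auth(list(
    client_registration("wide", test_key()$pubkey, "system/*.read"),
    client_registration("narrow", test_key()$pubkey,
                        "system/Patient.read")))
  now <- now_utc()

  a <- build_client_assertion("wide", test_key(), s$auth$token_endpoint)
  tok <- issue_token(s$auth, a, "system/*.read", now = now)
  expect_s3_class(tok, "access_token")
  expect_equal(tok$granted_scopes, "system/*.read")
  expect_lte(tok$expires_at - as.numeric(now), 300)

  # narrow client asking beyond its registration: empty intersection
  a2 <- build_client_assertion("narrow", test_key(), s$auth$token_endpoint)
  rej <- issue_token(s$auth, a2, "system/Observation.read", now = now)
  expect_s3_class(rej, "token_rejection")
  expect_equal(rej$error, "invalid_scope")

  # unknown client
  a3 <- build_client_assertion("ghost", test_key(), s$auth$token_endpoint)
  expect_equal(issue_token(s$auth, a3, "system/*.read")$error,
               "invalid_client")

  # audience mismatch
  a4 <- build_client_assertion("wide", test_key(), "http://elsewhere/token")
  expect_equal(issue_token(s$auth, a4, "system/*.read")$error,
               "invalid_client")

  # expired assertion
  a5 <- build_client_assertion("wide", test_key(), s$auth$token_endpoint,
                               now = now - 400, lifetime = 300)
  expect_equal(issue_token(s$auth, a5, "system/*.read", now = now)$error,
               "invalid_client")
})

test_that("a replayed assertion is rejected as invalid_grant", {
  s <- make_auth()
  a <- build_client_assertion("c1", test_key(), s$auth$token_endpoint)
  expect_s3_class(issue_token(s$auth, a, "system/*.read"), "access_token")
  rej <- issue_token(s$auth, a, "system/*.read")
  expect_s3_class(rej, "token_rejection")
  expect_equal(rej$error, "invalid_grant")
})

test_that("authorize grants by scope coverage and denies expiry at the boundary", {
  s <- make_auth()
  now <- now_utc()
  a <- build_client_assertion("c1", test_key(), s$auth$token_endpoint)
  tok <- issue_token(s$auth, a, "system/*.read", now = now)

  dec <- authorize(s$auth, tok$value, c("Patient", "Observation"),
                   now = now)
  expect_s3_class(dec, "auth_decision")

  # valid up to (not at) expires_at
  dec2 <- authorize(s$auth, tok$value, "Patient",
                    now = as.POSIXct(tok$expires_at - 1,
                                     origin = "1970-01-01", tz = "UTC"))
  expect_s3_class(dec2, "auth_decision")
  den <- authorize(s$auth, tok$value, "Patient",
                   now = as.POSIXct(tok$expires_at, origin = "1970-01-01",
                                    tz = "UTC"))
  expect_s3_class(den, "auth_denial")
  expect_equal(den$kind, "unauthenticated")

  # unknown token
  expect_equal(authorize(s$auth, "nonsense", "Patient")$kind,
               "unauthenticated")
})

test_that("insufficient scope is forbidden, not unauthenticated", {
  s <- make_auth(list(client_registration("c1", test_key()$pubkey,
                                          "system/Patient.read")))
  a <- build_client_assertion("c1", test_key(), s$auth$token_endpoint)
  tok <- issue_token(s$auth, a, "system/Patient.read")
  den <- authorize(s$auth, tok$value, c("Patient", "Observation"))
  expect_s3_class(den, "auth_denial")
  expect_equal(den$kind, "forbidden")
})

test_that("granting never widens beyond allowed scopes (property sweep)", {
  withr::local_seed(77)
  all_scopes <- sprintf("system/%s.read",
                        c("Patient", "Group", "Observation", "Condition",
                          "Encounter", "*"))
  expand <- function(scopes) {
    if ("system/*.read" %in% scopes) all_scopes else scopes
  }
  for (i in 1:25) {
    allowed <- sample(all_scopes, sample.int(length(all_scopes), 1))
    requested <- sample(all_scopes, sample.int(length(all_scopes), 1))
    s <- make_auth(list(client_registration("c1", test_key()$pubkey,
                                            allowed)))
    a <- build_client_assertion("c1", test_key(), s$auth$token_endpoint)
    tok <- issue_token(s$auth, a, paste(requested, collapse = " "))
    if (inherits(tok, "access_token")) {
      expect_true(all(tok$granted_scopes %in% requested))
      expect_true(all(tok$granted_scopes %in% expand(allowed)))
    } else {
      expect_equal(tok$error, "invalid_scope")
    }
  }
})

test_that("round-trip trust holds for every registered client; any mutation breaks it", {
  keys <- list(a = test_key(), b = test_key("other"))
  regs <- list(client_registration("client-a", keys$a$pubkey),
               client_registration("client-b", keys$b$pubkey))
  auth <- auth_service(regs, "http://as.test/auth/token")
  for (nm in c("a", "b")) {
    cid <- paste0("client-", nm)
    assertion <- build_client_assertion(cid, keys[[nm]],
                                        auth$token_endpoint)
    tok <- issue_token(auth, assertion, "system/*.read")
    expect_s3_class(tok, "access_token")
    expect_s3_class(authorize(auth, tok$value, "Patient"),
                    "auth_decision")
  }
  # single-character mutations anywhere in the assertion break issuance
  assertion <- build_client_assertion("client-a", keys$a,
                                      auth$token_endpoint)
  withr::local_seed(3)
  for (i in 1:12) {
    at <- sample.int(nchar(assertion), 1)
    ch <- substr(assertion, at, at)
    repl <- if (ch == "A") "B" else "A"
    mutated <- paste0(substr(assertion, 1, at - 1), repl,
                      substr(assertion, at + 1, nchar(assertion)))
    res <- issue_token(auth, mutated, "system/*.read")
    expect_s3_class(res, "token_rejection")
  }
})

test_that("the token endpoint handler speaks the OAuth wire form", {
  s <- make_auth()
  a <- build_client_assertion("c1", test_key(), s$auth$token_endpoint)
  form <- list(grant_type = "client_credentials",
               scope = "system/*.read",
               client_assertion_type = bulkfhir:::CLIENT_ASSERTION_TYPE,
               client_assertion = a)
  out <- bulkfhir:::token_endpoint_handler(s$auth, form)
  expect_equal(out$status, 200L)
  expect_equal(out$body$token_type, "bearer")
  expect_true(out$body$expires_in <= 300)
  expect_match(out$body$access_token, "^[0-9a-f]+$")

  out2 <- bulkfhir:::token_endpoint_handler(s$auth,
                                            list(grant_type = "password"))
  expect_equal(out2$status, 400L)
  expect_equal(out2$body$error, "invalid_request")
})
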