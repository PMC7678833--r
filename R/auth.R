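# SMART Backend Services authorization: a client holds a pre-registered
# RSA keypair, signs a short-lived JWT assertion, POSTs it to the token
# endpoint, and receives a short-lived bearer token carrying system-level
# scopes of the form system/<ResourceType or *>.read. Servers may further
# limit a client's exports to one patient group via an account policy.

CLIENT_ASSERTION_TYPE <-
  "urn:ietf:params:oauth:client-assertion-type:jwt-bearer"

.scope_re <- "^system/([A-Za-z]+|\\*)\\.read$"

b64url_encode <- function(x) {
  if (is.character(x)) x <- charToRaw(x)
  gsub("=+$", "", chartr("+/", "-_", openssl::base64_encode(x)))
}

b64url_decode <- function(x) {
  x <- chartr("-_", "+/", x)
  pad <- (4 - nchar(x) %% 4) %% 4
  openssl::base64_decode(paste0(x, strrep("=", pad)))
}

#' Sign and verify compact JWTs (RS384)
#'
#' Minimal JSON Web Token support for the backend-services flow: RSA
#' PKCS#1 v1.5 signatures over SHA-384, compact serialization.
#'
#' @param claims named list of JWT claims.
#' @param key an openssl RSA private key (`openssl::rsa_keygen()`), at
#'   least 2048 bits.
#' @return `jwt_sign()`: the compact JWT string.
#' @export
jwt_sign <- function(claims, key) {
  header <- list(alg = "RS384", typ = "JWT")
  signing_input <- paste(
    b64url_encode(jsonlite::toJSON(header, auto_unbox = TRUE)),
    b64url_encode(jsonlite::toJSON(claims, auto_unbox = TRUE, digits = NA)),
    sep = ".")
  sig <- openssl::signature_create(charToRaw(signing_input),
                                   hash = openssl::sha384, key = key)
  paste(signing_input, b64url_encode(sig), sep = ".")
}

#' @rdname jwt_sign
#' @param jwt a compact JWT string.
#' @param pubkey the matching RSA public key; if `NULL`, the signature is
#'   not checked (decode only).
#' @return `jwt_decode()`: list with `header`, `claims`, and `valid`
#'   (logical: did the signature verify).
#' @export
jwt_decode <- function(jwt, pubkey = NULL) {
  parts <- strsplit(jwt, ".", fixed = TRUE)[[1]]
  if (length(parts) != 3L) stop("not a compact JWT", call. = FALSE)
  header <- jsonlite::fromJSON(rawToChar(b64url_decode(parts[1])),
                               simplifyVector = TRUE)
  claims <- jsonlite::fromJSON(rawToChar(b64url_decode(parts[2])),
                               simplifyVector = TRUE)
  valid <- NA
  if (!is.null(pubkey)) {
    valid <- tryCatch(
      openssl::signature_verify(
        charToRaw(paste(parts[1], parts[2], sep = ".")),
        b64url_decode(parts[3]), hash = openssl::sha384, pubkey = pubkey),
      error = function(e) FALSE)
  }
  list(header = header, claims = claims, valid = isTRUE(valid))
}

#' Register a backend client
#'
#' @param client_id identifier pre-assigned by the server.
#' @param public_key the client's RSA public key (openssl `pubkey`).
#' @param allowed_scopes scopes the server will grant this client; each
#'   must match `system/<ResourceType or *>.read`.
#' @param policy_group optional group id: an account policy restricting
#'   every export by this client to that group's patients (e.g. a payor
#'   limited to its own plan members).
#' @return an object of class `client_registration`.
#' @export
client_registration <- function(client_id, public_key,
                                allowed_scopes = "system/*.read",
                                policy_group = NULL) {
  stopifnot(is.character(client_id), nzchar(client_id))
  bad <- allowed_scopes[!grepl(.scope_re, allowed_scopes)]
  if (length(bad)) {
    stop("malformed scope(s): ", paste(bad, collapse = ", "),
         " (expected system/<ResourceType or *>.read)", call. = FALSE)
  }
  structure(list(client_id = client_id, public_key = public_key,
                 allowed_scopes = allowed_scopes,
                 policy_group = policy_group),
            class = "client_registration")
}

#' Build a signed client assertion
#'
#' The authentication JWT a backend client posts to the token endpoint:
#' `iss` and `sub` are both the client id, `aud` is the token endpoint
#' URL, `exp` bounds its life (at most 5 minutes), and `jti` is a
#' single-use identifier enabling replay rejection.
#'
#' @param client_id the pre-assigned client id.
#' @param signing_key the client's RSA private key.
#' @param token_endpoint absolute URL of the token endpoint (the
#'   assertion's audience).
#' @param now issue instant (POSIXct); defaults to the current time.
#' @param lifetime seconds until expiry, at most 300.
#' @return the compact-serialized JWT (character scalar).
#' @export
build_client_assertion <- function(client_id, signing_key, token_endpoint,
                                   now = now_utc(), lifetime = 300) {
  if (lifetime > 300) {
    stop("client assertion lifetime must be at most 300 seconds",
         call. = FALSE)
  }
  claims <- list(
    iss = client_id, sub = client_id, aud = token_endpoint,
    exp = as.numeric(now) + lifetime, iat = as.numeric(now),
    jti = paste(as.character(openssl::rand_bytes(16)), collapse = ""))
  jwt_sign(claims, signing_key)
}

#' Create an authorization service
#'
#' Holds the client registry, issued-token store and assertion replay
#' cache for one server process.
#'
#' @param registrations list of [client_registration] objects.
#' @param token_endpoint the URL clients must use as assertion audience.
#' @param token_lifetime access-token life in seconds (default 300).
#' @param supported_types resource types scopes are expanded over.
#' @return an `auth_service` object (an environment).
#' @export
auth_service <- function(registrations = list(),
                         token_endpoint = "http://localhost/auth/token",
                         token_lifetime = 300,
                         supported_types = FHIR_TYPES) {
  ids <- vapply(registrations, function(r) r$client_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate client_id", call. = FALSE)
  e <- new.env(parent = emptyenv())
  e$clients <- stats::setNames(registrations, ids)
  e$token_endpoint <- token_endpoint
  e$token_lifetime <- token_lifetime
  e$supported_types <- supported_types
  e$tokens <- new.env(parent = emptyenv())
  e$seen_jti <- new.env(parent = emptyenv())
  class(e) <- "auth_service"
  e
}

token_rejection <- function(error, description) {
  structure(list(error = error, error_description = description),
            class = "token_rejection")
}

#' @export
print.token_rejection <- function(x, ...) {
  cat(sprintf("<token rejection> %s: %s\n", x$error, x$error_description))
  invisible(x)
}

# Does `allowed` (possibly wildcard) cover the single scope `s`?
scope_covered <- function(s, allowed) {
  if (s %in% allowed) return(TRUE)
  ty <- sub(.scope_re, "\\1", s)
  ty != "*" && "system/*.read" %in% allowed
}

#' Issue an access token for a client assertion
#'
#' Verifies the assertion (known client, valid signature, audience match,
#' unexpired, unused `jti`), intersects the requested scopes with the
#' client's allowed scopes, and mints a short-lived opaque bearer token.
#' Failure modes are distinguishable OAuth errors: `invalid_client`
#' (unknown client, bad signature, expired or mis-addressed assertion),
#' `invalid_grant` (replayed assertion), `invalid_scope` (nothing
#' grantable), `invalid_request` (malformed input).
#'
#' @param auth an [auth_service].
#' @param assertion the compact JWT from [build_client_assertion()].
#' @param requested_scopes character vector (or space-separated string) of
#'   requested scopes.
#' @param now evaluation instant (POSIXct).
#' @return on success a list of class `access_token` with `value`,
#'   `granted_scopes`, `expires_at`, `client_id`; otherwise a
#'   `token_rejection`.
#' @export
issue_token <- function(auth, assertion, requested_scopes,
                        now = now_utc()) {
  requested_scopes <- unlist(strsplit(requested_scopes, " ", fixed = TRUE))
  requested_scopes <- requested_scopes[nzchar(requested_scopes)]
  if (!length(requested_scopes)) {
    return(token_rejection("invalid_request", "no scope requested"))
  }
  if (any(!grepl(.scope_re, requested_scopes))) {
    return(token_rejection("invalid_scope", paste(
      "malformed scope:",
      requested_scopes[!grepl(.scope_re, requested_scopes)][1])))
  }
  dec <- tryCatch(jwt_decode(assertion), error = function(e) NULL)
  if (is.null(dec)) {
    return(token_rejection("invalid_client", "unparseable client assertion"))
  }
  cid <- dec$claims$iss
  if (is.null(cid) || !identical(dec$claims$sub, cid) ||
      is.null(auth$clients[[cid]])) {
    return(token_rejection("invalid_client", "unknown or inconsistent client"))
  }
  reg <- auth$clients[[cid]]
  dec <- jwt_decode(assertion, reg$public_key)
  if (!dec$valid) {
    return(token_rejection("invalid_client", "assertion signature invalid"))
  }
  if (!identical(as.character(dec$claims$aud), auth$token_endpoint)) {
    return(token_rejection("invalid_client", sprintf(
      "assertion audience '%s' is not this token endpoint",
      as.character(dec$claims$aud))))
  }
  if (is.null(dec$claims$exp) ||
      as.numeric(dec$claims$exp) <= as.numeric(now)) {
    return(token_rejection("invalid_client", "client assertion expired"))
  }
  jti <- as.character(dec$claims$jti)
  if (!length(jti) || !nzchar(jti)) {
    return(token_rejection("invalid_client", "assertion lacks a jti"))
  }
  if (!is.null(auth$seen_jti[[jti]])) {
    return(token_rejection("invalid_grant", "client assertion replayed"))
  }
  auth$seen_jti[[jti]] <- as.numeric(dec$claims$exp)
  granted <- requested_scopes[vapply(requested_scopes, scope_covered,
                                     logical(1),
                                     allowed = reg$allowed_scopes)]
  if (!length(granted)) {
    return(token_rejection("invalid_scope",
                           "no requested scope is grantable"))
  }
  value <- paste(as.character(openssl::rand_bytes(24)), collapse = "")
  tok <- structure(list(value = value, granted_scopes = granted,
                        expires_at = as.numeric(now) + auth$token_lifetime,
                        client_id = cid),
                   class = "access_token")
  auth$tokens[[value]] <- tok
  tok
}

auth_denial <- function(kind, msg) {
  structure(list(kind = kind, message = msg), class = "auth_denial")
}

#' Authorize an export request against a bearer token
#'
#' Grants when the token is known and unexpired and every needed resource
#' type is covered by `system/<T>.read` or `system/*.read`. The decision
#' carries the client's `policy_group` so the export engine can restrict
#' output to that group's patients.
#'
#' @param auth an [auth_service].
#' @param token_value the bearer token string.
#' @param needed_types resource types the request wants to read.
#' @param now evaluation instant (POSIXct).
#' @return on success a list of class `auth_decision` with `granted_types`
#'   and `policy_group`; otherwise an `auth_denial` with `kind`
#'   `"unauthenticated"` (unknown/expired token, HTTP 401) or
#'   `"forbidden"` (insufficient scope, HTTP 403).
#' @export
authorize <- function(auth, token_value, needed_types, now = now_utc()) {
  tok <- if (is.character(token_value) && length(token_value) == 1L)
    auth$tokens[[token_value]] else NULL
  if (is.null(tok)) {
    return(auth_denial("unauthenticated", "unknown access token"))
  }
  if (as.numeric(now) >= tok$expires_at) {
    return(auth_denial("unauthenticated", "access token expired"))
  }
  uncovered <- needed_types[!vapply(
    needed_types,
    function(ty) scope_covered(sprintf("system/%s.read", ty),
                               tok$granted_scopes),
    logical(1))]
  if (length(uncovered)) {
    return(auth_denial("forbidden", sprintf(
      "token scope does not cover resource type(s): %s",
      paste(uncovered, collapse = ", "))))
  }
  reg <- auth$clients[[tok$client_id]]
  structure(list(granted_types = needed_types,
                 client_id = tok$client_id,
                 policy_group = reg$policy_group),
            class = "auth_decision")
}

# Handle the token-endpoint form POST (application/x-www-form-urlencoded).
# Returns list(status, body) where body is the OAuth JSON object.
token_endpoint_handler <- function(auth, form, now = now_utc()) {
  if (!identical(form[["grant_type"]], "client_credentials") ||
      !identical(form[["client_assertion_type"]], CLIENT_ASSERTION_TYPE)) {
    return(list(status = 400L, body = list(
      error = "invalid_request",
      error_description = "expected client_credentials grant with jwt-bearer assertion")))
  }
  res <- issue_token(auth, form[["client_assertion"]],
                     form[["scope"]] %||% "", now = now)
  if (inherits(res, "token_rejection")) {
    status <- if (res$error == "invalid_client") 401L else 400L
    return(list(status = status,
                body = list(error = res$error,
                            error_description = res$error_description)))
  }
  list(status = 200L, body = list(
    access_token = res$value, token_type = "bearer",
    expires_in = as.integer(res$expires_at - as.numeric(now)),
    scope = paste(res$granted_scopes, collapse = " ")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
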