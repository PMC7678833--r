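---
title: "Bulk FHIR export: protocol, model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bulk FHIR export: protocol, model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bulkfhir)
```

## What this package models

Bulk FHIR export is the population-scale counterpart to per-patient FHIR
REST access: instead of paging through individual resources, a client asks
a server to prepare files covering an entire cohort — all patients, one
enumerated `Group` of patients, or every resource the server holds — and
collects them when ready. Because such exports can be large, the protocol
is deliberately asynchronous: the server acknowledges the request
immediately and the client polls until files are prepared. The output
layout ("flat FHIR") is newline-delimited JSON with **one resource type
per file**, which lets analytic engines stream a file of a homogeneous
type without holding a containing array in memory.

`bulkfhir` implements both sides of this contract plus the trust layer
between them, and ships a conformance suite and a synthetic data generator
so every moving part can be exercised against the others in a single R
process.

## The resource model

A `fhir_resource` keeps only the fields the transport layer interprets —
`resourceType`, `id`, `meta.lastUpdated`, and the `subject.reference`
linking clinical resources (Observation, Condition, Encounter) to their
Patient. Everything else travels verbatim in a content tree. This is a
deliberate scope decision: the protocol under test is transport and
format, not profile validation, so the package never rejects a resource
for lacking, say, a coded gender — schema-level validation (US Core /
USCDI) is out of scope, and the package is agnostic about which FHIR
release the content trees conform to.

Two representational choices matter for correctness:

* **Timestamps** are RFC3339 instants with explicit timezone, compared as
  UTC epochs. Naive timestamps would make `_since` comparisons ambiguous
  across offsets, so `parse_instant()` rejects them.
* **Round-trip identity.** JSON does not distinguish `140` from `140.0`,
  so content trees are canonicalized (whole finite doubles stored as
  integers) at construction. With that, write-then-read of any NDJSON
  file is `identical()` to its source — an invariant the test suite
  asserts across seeds, and the property that makes multiset comparisons
  against oracles exact rather than approximate.

## The export semantics

A kickoff is validated for: the required `Prefer: respond-async` and
`Accept: application/fhir+json` headers, a known group id, a parseable
`_since`, `_type` values inside the closed supported set, and an
`_outputFormat` among the NDJSON aliases (`application/fhir+ndjson`,
`application/ndjson`, `ndjson`). Anything else fails fast with an
`OperationOutcome`; the experimental `_typeFilter` parameter is rejected
as unsupported rather than silently ignored, so clients cannot mistake a
full export for a filtered one.

The selection a job exports is the intersection of four predicates:

1. **Level scope** — `system`: every resource; `patient`: all Patients
   plus clinical resources whose subject resolves; `group`: the group's
   Patients and their clinical resources. The `Group` resource itself is
   *not* included in a group-level export: the roster is the cohort
   definition, not cohort data. (System-level exports do include Group
   resources, since there the roster is part of "all data".)
2. **Account policy** — if the authenticated client's registration names
   a `policy_group`, the selection is intersected with that group's
   membership scope, mirroring a payor restricted to its own plan
   members.
3. **`_type`** — a comma-separated list in the query string.
4. **`_since`** — *strictly* `last_updated > since`. "Updated after the
   given timestamp" reads as strict inequality; a resource stamped
   exactly at the cutoff is excluded, and the suite pins this boundary
   with a handcrafted repository. The filter applies uniformly to
   Patients and clinical resources at every export level.

An empty selection completes successfully with an empty `output` array —
an empty cohort is a result, not an error.

### Job lifecycle and pacing

Jobs advance one resource type per status poll ("tick"), so a client
always observes at least one genuine in-progress response
(`202` + `X-Progress` of the form `"k of n resource types exported"` +
`Retry-After`), and progress text changes monotonically. `run_job()`
drives the same machinery to completion synchronously for engine-level
use. This poll-driven design keeps the server single-threaded and
deterministic — there is no background worker whose scheduling could make
tests flaky — while still exercising every state a real client must
handle.

Defaults, all configurable in `server_config()`: `Retry-After` 1 s
(delta-seconds form; desk-scale pacing — tests and the acceptance sweep
set it to 0), file retention 60 minutes after completion (the `Expires`
deadline; afterwards status and file URLs return 404 and the files are
deleted), access-token and client-assertion lifetimes 300 s, kickoff
success code 202. Job ids are 128 random bits rendered as hex: status
URLs embed nothing enumerable, which the suite checks by probing adjacent
ids. Large per-type outputs can be split into several manifest entries of
the same type via `max_lines_per_file`; counts are recorded per file and
always equal line counts.

## Authorization

The backend-services profile is system-to-system: no human in the loop.
A registered client holds an RSA keypair (2048 bits or more); each token
request is a compact JWT signed RS384 whose `iss`/`sub` are the client
id, `aud` is the token endpoint URL, `exp` caps its life at five
minutes, and `jti` is single-use. The server checks, in order: parseable
assertion, known and consistent client, signature under the registered
public key, audience, expiry, then replay — and distinguishes the
failures (`invalid_client` / `invalid_grant` / `invalid_scope`) so a
client can tell a configuration error from a replayed credential.
Replay protection is an in-memory `jti` cache per server process, which
matches the package's desk scale; the contract, not the storage
technology, is what is specified and tested.

Scopes are `system/<ResourceType>.read` with `*` as wildcard. Granted
scopes are the requested ones covered by the registration — granting can
narrow but never widen, a property the suite sweeps with random scope
sets. Authorization of an export needs every requested type covered;
unknown or expired tokens map to 401 and insufficient scope to 403, and
token validity is half-open: valid strictly before `expires_at`, denied
at it. Whether scopes may be narrowed per request beyond the account
policy is not pinned down by the profile's prose; the package exposes
only `policy_group` as the server-side limiting mechanism and leaves
finer per-request narrowing out.

## The synthetic population

The generator emulates the shape of a multi-patient EHR extract, not its
medicine: Patients carry minimal plausible demographics (name pools,
gender, birthDate); Observations, Conditions and Encounters carry a
handful of realistic codings and link to their patient; Groups are
rosters sampled without replacement. Defaults: 100 patients; mean
per-patient counts Observation 5, Condition 2, Encounter 3 (drawn
Poisson, so some patients have none — exercising empty edge cases); two
groups at 30% fill (overlapping, so group and policy intersections are
non-trivial); `lastUpdated` uniform over 2019-01-01 to 2020-11-01, a
roughly two-year window that makes `_since` cuts bite at every point of
the range. Uniformity is chosen over any clustered scheme precisely
because it keeps the brute-force filtering oracle trivial.

Determinism is part of the contract: identical configs (seed included)
yield identical repositories; ids are seeded counters
(`pat-000017`), not UUIDs, so fixtures diff cleanly. The per-patient
Poisson counts are the *first* RNG draws after seeding (one `rpois`
vector per configured type, types in sorted order), which lets an
independent oracle replay expected totals with nothing but `set.seed()`
and documented call order.

What passing tests on this population do **not** show: robustness to
schema-invalid real-world content, terminology drift, clustered update
storms (e.g. batch ETL timestamps), or servers whose groups change while
a job runs. The generator's regularity is a feature for oracle testing
and a limitation for realism.

## Oracle-based verification

The central correctness claim — every downloaded export equals its
specification — is checked against a brute-force selection oracle: an
independent, naive re-statement of the four predicates as a per-resource
loop with its own timestamp parsing, kept in the test code and in
`scripts/acceptance.R`, never shared with the engine. The acceptance
sweep runs randomized requests (all three levels, random `_type`
subsets, `_since` inside and outside the window) over seeded 200-patient
repositories through the full client/server stack and compares resource
multisets. Problem sizes (4 repositories × 5 randomized requests, 200
patients ≈ 2,200 resources each) were chosen to cover all predicate
combinations repeatedly while keeping the sweep comfortably inside a
coffee break; at these sizes it completes in well under a minute.

## Transport and fault injection

The client and conformance suite speak to servers through a connection
abstraction: `local_connection()` routes requests straight into an app in
the same process (fast, deterministic, no sockets), `http_connection()`
speaks real HTTP, and `mock_connection()` scripts arbitrary — including
deliberately broken — server behavior for client robustness tests.
`bulk_serve()` binds an app to a TCP port with httpuv; because the HTTP
client pumps the event loop while waiting, one R process can serve and
download simultaneously, which the suite uses for a real-socket
end-to-end test.

Fault injection mirrors the adjustable behaviors client developers need
from a reference server: a transient 503 at kickoff, a 500 at status
polls, or one corrupted NDJSON line in a downloaded file (position
derived from the simulation seed, so the client's reported 1-based line
number can be asserted exactly). Faults recover after a configured number
of occurrences; `times = Inf` makes them persistent. The suite asserts a
detection matrix: each fault class produces a stage-specific client
diagnostic *and* fails at least one conformance check in the
corresponding group, while the zero-fault configuration passes every
required check and behaves identically to an unconfigured engine.

## Conformance checking

The catalogue holds 16 checks in four groups (kickoff, status, files,
auth), each a scripted request flow plus response predicates with
captured evidence; one completed export flow is shared within a run, and
checks needing their own job (e.g. cancellation) kick off fresh.
Optional-behavior situations report `skip` rather than `fail` — e.g. the
auth checks when no credentials are configured, or in-progress header
checks against a server that completes before it can be observed.
Reports carry a `schema_version` so downstream tooling can validate
their shape. The catalogue is derived from the protocol's mandated
kickoff/status/download behaviors rather than mirroring any particular
hosted test service's private test list.

## Known limitations

* No `$import`, no `_typeFilter` evaluation, no deletion propagation or
  incremental-update bookkeeping beyond `_since`.
* No TLS, connection limits, or horizontal scaling — the server is a
  reference and test instrument, not a production host.
* NDJSON is the only output format; other `_outputFormat` values are
  rejected at kickoff by design.
* Replay and token state are per-process and in-memory; restarting the
  server forgets issued tokens.
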