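# bulkfhir

An end-to-end R toolkit for the **SMART/HL7 FHIR Bulk Data Access API
(v1.0)** — the standardized, asynchronous interface through which
population-level health data is exported from EHRs and FHIR servers as
newline-delimited JSON ("flat FHIR") files.

It is aimed at clinical-informatics developers and researchers who need to
build, script, or validate bulk export pipelines without access to a
production EHR: the package bundles

* an **export server** — the three kickoff endpoints
  (`[base]/$export`, `[base]/Patient/$export`,
  `[base]/Group/[id]/$export`), an asynchronous job lifecycle behind a
  polling status endpoint, one-type-per-file NDJSON output, and
  configurable fault injection for client testing;
* **SMART Backend Services authorization** — RS384-signed JWT client
  assertions exchanged for short-lived bearer tokens carrying
  `system/[resourceType].read` scopes, with per-client account policies
  that can restrict every export to one patient group;
* a **polling download client** (R API and `bulkfhir export` CLI) that
  honors `Retry-After`, downloads and validates every manifest file, and
  reports protocol violations with stage-specific diagnostics;
* an executable **conformance suite** (16 checks across kickoff / status /
  files / auth groups) runnable against any bulk data server base URL;
* a seeded **synthetic population generator**, so the entire protocol is
  exercisable offline with no external data.

## The protocol in one paragraph

A client `GET`s a kickoff endpoint with `Prefer: respond-async` (plus
`_type`, `_since`, `_outputFormat` query parameters) and receives
`202 Accepted` with a `Content-Location` status URL. Polling that URL
yields `202` + `X-Progress` + `Retry-After` while the server prepares
files, then `200` with an `Expires` header and a JSON manifest
(`transactionTime`, `request`, `requiresAccessToken`, `output`, `error`);
each `output` entry is `{type, url, count}` pointing at an NDJSON file
containing exactly one resource type, served as
`application/fhir+ndjson`. `_since` keeps only resources whose
`meta.lastUpdated` is *strictly after* the given instant. `DELETE` on the
status URL cancels the job.

## Worked example

```r
library(bulkfhir)

# a server over a seeded 20-patient synthetic population, with
# authorization enforced for one registered backend client
key <- openssl::rsa_keygen(2048)
cfg <- server_config(
  base_url = "http://demo.local/fhir",
  requires_access_token = TRUE,
  retry_after = 0,
  registrations = list(client_registration("analytics-app", key$pubkey)),
  fixture = population_config(n_patients = 20, seed = 3))
app  <- bulk_app(cfg)
conn <- local_connection(app)       # in-process; bulk_serve(app) for TCP

creds <- backend_credentials("analytics-app", key, app$token_url)
s <- export_download(conn, level = "system", credentials = creds,
                     poll_floor = 0)
print(s)
#> Bulk export complete: 206 resources in 5 file(s), 0.4s, 6 poll(s)
#>   Patient            20 resources     3586 B  Patient.1.ndjson
#>   Condition          38 resources    11106 B  Condition.1.ndjson
#>   Encounter          49 resources     8884 B  Encounter.1.ndjson
#>   Observation        97 resources    28612 B  Observation.1.ndjson
#>   Group               2 resources      806 B  Group.1.ndjson
```

Each line is one downloaded NDJSON file: 20 Patients plus the Poisson-
distributed clinical resources the generator attached to them, and the two
Group rosters. The count column is both the manifest's declared `count`
and the verified line count of the file.

Conformance-testing the same server:

```r
report <- run_conformance(conn, "all", creds)
print(report)
#>   16 pass, 0 fail, 0 skip of 16
```

The same flows are scriptable from a shell via the bundled executable
(`exec/bulkfhir` in the installed package):

```sh
bulkfhir serve --config server.json
bulkfhir export --base-url http://127.0.0.1:8080/fhir --system --out dl/
bulkfhir conformance --base-url http://127.0.0.1:8080/fhir --report report.json
```

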