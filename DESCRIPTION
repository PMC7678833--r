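Package: bulkfhir
Title: FHIR Bulk Data Access Server, Client and Conformance Toolkit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for the SMART/HL7 FHIR Bulk Data Access
    API (v1.0): an export server with an asynchronous job lifecycle, newline
    delimited JSON ("flat FHIR") output and SMART Backend Services
    authorization; a polling download client; an executable protocol
    conformance suite; and a seeded synthetic-population generator so the
    whole protocol can be exercised with no external data. Exports are
    driven through the three standard kickoff endpoints (system, all
    patients, or a patient group), filtered by resource type and
    last-updated instant, and delivered as one NDJSON file per resource
    type behind a polling status endpoint.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    openssl,
    curl,
    httpuv,
    later,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
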