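Package: miiconsent
Title: Interoperable Representation of Consent-Based Data-Use Permissions
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for representing, exchanging and resolving consent-based
    data-use permissions in the style of the German Medical Informatics
    Initiative (MII) interoperability layer. Provides a minimal consent data
    model (modules, templates, policies, three-valued status labels), an
    OID-based code system that combines policies with status labels together
    with a registry of code systems and value sets, lossless readers and
    writers for HL7 FHIR Consent resources (Releases 3 and 4, JSON) and IHE
    BPPC CDA R2 documents (XML header encoding), mappings from FHIR and gICS
    consent states onto the interoperability status labels, a temporal engine
    that resolves the effective consent status of a patient for a policy at a
    date and runs cohort queries, and a deterministic synthetic-population
    generator for testing consent pipelines end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    xml2,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
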