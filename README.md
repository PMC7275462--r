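# miiconsent

Interoperable representation of consent-based data-use permissions for
health-data sharing, in the style of the German Medical Informatics
Initiative (MII) interoperability layer.

## The problem

University medical centers that share patient data for research each run
their own consent-management stack: some document consent as HL7 FHIR
`Consent` resources (Release 3 or 4), others as IHE Basic Patient Privacy
Consents (BPPC) CDA R2 documents, often fed from consent-management software
such as gICS. These standards disagree on one crucial point: *how the status
of a consent is represented*. FHIR's consent status codes were long unstable
across releases, and BPPC has no status slot at all. Yet a Data Integration
Center must be able to answer, for any patient, policy and date: *is this
permission in effect?*

`miiconsent` implements the pragmatic interoperability layer that solves
this:

* **Three status labels** — `valid`, `not valid`, `unknown` — indicate
  whether the permissions of a *policy* (a consent-template module or a
  regulatory provision) are in effect. `unknown` means absence of
  documentation, never a mapping fallback.
* **Combined policy-status codes.** Because no common standard can carry a
  free-standing status, each registrable code identifies the *combination*
  of one policy in one template version with one status label. Codes are
  OIDs allocated consecutively under a code-system OID
  (`2.16.840.1.113883.3.1937.777.24.5.1`), referenced as bare OIDs (BPPC),
  `urn:oid:` URNs (FHIR) or RetrieveCode URIs, and grouped into one value
  set per policy.
* **Three mandatory data elements** per documented statement: the status for
  a module, the template version (both carried inside the policy-status
  code), and the start of validity (optionally an end). A withdrawal is a
  *new* record carrying the policy's `not valid` code — never an update in
  place.
* **Status mappings** from the six FHIR Consent status tokens (only
  `active` → `valid`) and the four gICS states (only `Accepted` → `valid`)
  onto the three labels.
* **A temporal engine** that resolves the effective status of a patient for
  a policy at a date (latest record wins; deny-biased tie-breaks), runs
  cohort queries, and validates records — including the five-year cap on
  health-insurance modules.

The package bundles a broad-consent template definition (version 1.6a: four
sections, eight opt-in modules), readers/writers for FHIR R3/R4 JSON and
BPPC CDA XML, a YAML-backed code registry, a deterministic synthetic
population generator, and a command-line interface.

## Worked example

```r
library(miiconsent)

reg <- mii_default_registry()       # 8 modules x 3 labels = 24 codes
reg
#> <code_registry> 1 code system(s), 24 code(s), 8 value set(s)

recs <- read_fhir_consent(mii_fhir_example_path(), reg, release = "R4")
recs[[1]]
#> <consent_record> patient=patientf001 policy=mdat_collection@1.6a status=valid period=2018-10-10..2023-10-09 [fhir_r4]
```

The bundled FHIR resource references policy code
`2.16.840.1.113883.3.1937.777.24.5.1.1` — the first child of the code
system, i.e. the combination (first template module, `valid`) — for patient
`patientf001`, in effect 2018-10-10 through 2023-10-09 (both days
inclusive). Converting it to BPPC moves the same code into a
`documentationOf/serviceEvent` with `effectiveTime` low `20181010` and high
`20231009`; nothing is lost because the status travels inside the code:

```r
convert_consent(mii_fhir_example_path(), "fhir-r4", "bppc", reg)
```

The engine answers the operative question:

```r
store <- consent_store()
add_records(store, recs)
effective_status(store, "patientf001", "mdat_collection", "2020-01-01", "1.6a")
#> <status> valid
effective_status(store, "patientf001", "mdat_collection", "2023-10-10", "1.6a")
#> <status> unknown    # the documentation has expired; nothing is in effect
```

The same operations are available from a shell:

```sh
Rscript inst/cli/miiconsent.R convert --from fhir-r4 --to bppc \
    inst/extdata/consent-fhir-r4-example.json
Rscript inst/cli/miiconsent.R map-status --system gics Withdrawn
# not valid
```

## What this package does not do

Consent *collection* (forms, signatures, UIs), automated access-control
enforcement (IHE APPC, XACML-style rules), and live terminology-server
synchronization are out of scope; the engine decides what is documented as
in effect, not who may open which dataset.
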