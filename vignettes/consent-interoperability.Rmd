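---
title: "Representing and resolving consent-based data-use permissions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Representing and resolving consent-based data-use permissions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(miiconsent)
```

## The model

Multi-site health-data sharing requires that the permissions a patient has
granted be readable at every site, whatever software produced them. The
sticking point is status: HL7 FHIR `Consent` resources carry a status token
whose vocabulary was not stable across releases, IHE BPPC documents carry
none at all, and consent-management systems such as gICS use their own
richer state machines.

`miiconsent` follows the minimal-consensus design: reduce status to three
labels and push them *into the code system*. Every registrable code denotes
the combination of one **policy** — a consent-template module or a
regulatory provision — with one **status label**:

* `valid`: the permissions or restrictions of the policy are in effect;
* `not valid`: they are documented as not in effect (declined, withdrawn,
  invalidated, …);
* `unknown`: there is no documentation. `unknown` is *registrable* (every
  policy gets three codes) but it is never the image of a status mapping:
  an unrecognized source token raises an error rather than silently
  becoming `unknown`, because "we don't know" and "we can't parse" must
  stay distinguishable.

A documented statement (a `consent_record`) then needs only three mandatory
elements: the patient, the policy-status code (which internally carries the
module id, the template version and the label), and the start of a validity
period (optionally an end). Both period endpoints are inclusive calendar
days; the worked BPPC encoding (`low 20181010`, `high 20231009`) reads
naturally as inclusive dates and nothing in either standard suggests
open intervals. Dates are timezone-free; the optional `recorded_at`
documentation timestamp is UTC.

Withdrawal is *documentation, not deletion*: a withdrawal appends a new
record referencing the policy's `not valid` code with a later validity
start. The original grant remains in the store, which keeps the history
auditable and makes resolution a pure query.

## The code system

Codes are OIDs allocated as consecutive children of a code-system OID
(default `2.16.840.1.113883.3.1937.777.24.5.1`, with regulatory policies
under the sibling `...24.5.2` to keep template-bound and template-free
policies apart). Allocation order is normative in this package: modules in
template order, and within each module the fixed label order *valid* (1),
*not valid* (2), *unknown* (3). For the bundled eight-module template this
yields codes `.1` through `.24`; the first module's `valid` code is
`...5.1.1`, matching the bundled worked example. One value set per policy
groups its three codes, and the value-set description carries the template
version, so a code always pins down the exact wording a patient saw.

Code references are accepted in the three spellings the supported standards
use — bare OID (BPPC `code/@code`), `urn:oid:` URN, and RetrieveCode-style
URI with `code`/`codeSystem` query parameters (FHIR `policy.uri`) — and the
writers emit the RetrieveCode form for FHIR and the bare OID for BPPC.
Registries persist as a YAML schema (`export_registry()` /
`import_registry()`); the round-trip is the identity on all observable
content.

## Dialects

**FHIR (R4/R3, JSON).** On write the resource gets status `active`
throughout — the interoperable status lives in the policy code, not in the
FHIR token — plus the patient-privacy scope coding (Release 4 only; Release
3 predates `scope`), the LOINC `57016-8` category ("the resource is based
on a consent document"), one policy URI per record, and the period under
`provision` (R4) or at the resource level (R3, which has no `provision`).
On read, the resource's own status token is mapped via `map_fhir_status()`
and kept in record provenance together with a discrepancy flag; it never
overrides the policy code. A single resource carries a single period, so
records with different periods must be split across resources —
`emit_documents()` does this automatically, writing per-patient JSON arrays
of single-record resources.

**BPPC (CDA R2, XML).** Only the header is modeled: both BPPC templateIds,
the LOINC `57016-8` document code, the patient in
`recordTarget/patientRole`, and one `documentationOf/serviceEvent` (class
`ACT`, mood `EVN`) per record with the code and an `effectiveTime` in
`YYYYMMDD`. Each serviceEvent has its own period, so one document can hold
a patient's full history. BPPC has no status slot — which is exactly why
the combined codes exist; the test suite asserts that the label survives a
BPPC cycle although the serialized document never mentions a status.
Per-serviceEvent ids are generated as consecutive children of a
configurable OID namespace (default `...24.999`). Finer-than-day
`effectiveTime` precision is truncated to the day with a warning. The
structured body is an empty placeholder; narrative rendering is out of
scope.

**Status mappings.** The FHIR table maps the six tokens shared by Releases
3 and 4 (only `active` → `valid`); the gICS table maps the four states of
gICS 2.8.6 (only `Accepted` → `valid`). Both maps are total on their
domains and deliberately lossy — `Withdrawn` and `Declined` collapse onto
`not valid` — so readers preserve the original token in provenance, the
only place it remains recoverable.

## The temporal engine

`effective_status(store, patient, policy, date)` filters the records for
the (patient, policy) pair to those whose period contains the date, then
selects the winner by:

1. latest `recorded_at` (a missing timestamp sorts earliest — an undated
   record should never outrank a dated one);
2. latest period start;
3. deny-biased label order `not valid` < `unknown` < `valid`.

The standards define no conflict-resolution rule, so the chain was chosen
for determinism plus safety bias: when documentation genuinely conflicts,
the engine prefers the answer that denies data use. Answers are independent
of insertion order, and for a fixed policy and date the three cohorts
returned by `cohort_query()` partition the store's patients.

Two deliberate semantics deserve emphasis:

* **Expired periods read as `unknown`, not `not valid`.** `not valid` is a
  *documented* state; after an end-dated period elapses there simply is no
  documentation in effect. Downstream, both labels equally deny use, so the
  distinction costs nothing and keeps the meaning of `not valid` sharp.
* **The five-year insurance cap is validated, never silently truncated.**
  `validate_record()` flags permission-granting (`valid`) records of
  health-insurance modules whose period runs past five years from its
  start (an open-ended grant counts as exceeding the cap). Documented
  denials are exempt: an open-ended withdrawal of an insurance module is
  legitimate documentation, not an over-long permission. The latest
  allowed end for a grant starting 2018-10-10 is 2023-10-09 — exactly the
  bundled example period.

## The synthetic population generator

Real consent stores cannot be published, so every end-to-end test runs on
populations from `generate_population()`. The generator emulates the
decision structure of the modular opt-in template: per patient and module
an opt-in draw (default probability 0.3) yields a `valid`- or
`not valid`-coded record with a bounded validity period (uniform 1–7 years,
capped at five for insurance modules); opt-ins are later withdrawn with
default probability 1/6, appending an open-ended `not valid` record 30–540
days after the grant's start. The defaults reproduce the illustrative
cohort arithmetic used throughout the documentation — in 100 patients,
about 30 opt in and about 5 of those withdraw, leaving about 25 consenting.
Draws use R's Mersenne-Twister with a fixed seed, patients outer and
modules inner, so output is reproducible across platforms.

Alongside the records the generator tabulates its own ground truth —
expected effective status per (patient, module, probe date) — derived from
the generation decisions directly, *not* by calling the engine. Probe dates
are chosen to hit edge cases by construction: each period boundary, one day
on either side, the midpoint, and the withdrawal boundary. Agreement
between this table and the engine is the engine's primary harness.

What the generator does **not** emulate: demographics (patients are opaque
identifiers), partial documents, clock skew between `recorded_at` and
validity start beyond the fixed noon convention, vocabulary drift, or
malformed inputs — those are exercised by targeted fixtures instead. A
green synthetic suite therefore shows the *semantics* are right, not that
arbitrary real-world exports will parse.

## Verification sizes and numerical choices

The shipped checks use problem sizes chosen to exercise the properties
thoroughly while keeping a full run comfortable on a laptop: 1,000 seeded
record sets cycled through FHIR R4 → BPPC → FHIR R3 with the core data
elements compared bit-for-bit; 10,000 randomized effective-status queries
over a 120-patient population compared against an independent brute-force
oracle; exhaustive replay of both mapping tables and of the 24-code
allocation; 1,000 random OID/URN round-trips; and 200 randomized five-year
cap classifications straddling the boundary by ±400 days. Date arithmetic
uses R `Date` objects throughout; the five-year boundary is computed by
calendar arithmetic (`seq(start, by = "5 years")`, minus one day for the
inclusive end), so leap years are handled by the calendar, not by a
365-day approximation.

## Known limitations

* Only the subset of FHIR Consent fields needed for the interoperability
  layer is read and written; unknown incoming fields are not preserved.
* The CDA reader is a header reader; a BPPC document whose body contradicts
  its header would not be noticed.
* No enforcement: the engine reports documented status, it does not gate
  access to datasets (APPC/XACML-style rules are a different layer).
* The mapping tables cover exactly the published FHIR and gICS
  vocabularies; extended process states (e.g. an explicit `withdrawn`
  interoperability code) would require new codes, not new mappings.
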