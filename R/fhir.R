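#' Read consent records from a FHIR Consent resource (JSON)
#'
#' Parses an HL7 FHIR `Consent` resource in JSON syntax and resolves every
#' entry of its `policy` list to a registered policy-status code, yielding
#' one [consent_record()] per policy entry. The patient is taken from the
#' `patient.identifier`, the validity period from `provision.period`
#' (Release 4) or the resource-level `period` (Release 3).
#'
#' The resource's own `status` token does not override the status label
#' carried by the policy code — the two coexist: the token and its mapping
#' (via [map_fhir_status()]) are kept as provenance notes on each record,
#' and a disagreement between the two is flagged in the
#' `fhir_status_discrepancy` provenance note.
#'
#' @param x JSON text, or the path of a JSON file.
#' @param registry A [code_registry()] used to resolve policy references.
#' @param release FHIR release, `"R4"` (v4.0.0) or `"R3"` (v3.0.1).
#' @return List of [consent_record()] objects (one per policy entry),
#'   sharing patient and period.
#' @examples
#' reg <- mii_default_registry()
#' recs <- read_fhir_consent(mii_fhir_example_path(), reg, release = "R4")
#' record_core(recs[[1]])
#' @export
read_fhir_consent <- function(x, registry, release = c("R4", "R3")) {
  release <- match.arg(release)
  stopifnot(inherits(registry, "code_registry"))
  doc <- parse_fhir_json(x)
  if (!identical(doc$resourceType, "Consent")) {
    stop(sprintf(
      "expected resourceType 'Consent', found '%s'",
      doc$resourceType %||% "<absent>"
    ), call. = FALSE)
  }
  patient_id <- doc$patient$identifier$value
  if (is.null(patient_id) || !nzchar(patient_id)) {
    stop("FHIR Consent lacks patient.identifier.value", call. = FALSE)
  }
  patient <- patient_ref(patient_id, doc$patient$identifier$system)

  period_node <- if (release == "R4") doc$provision$period else doc$period
  if (is.null(period_node$start)) {
    stop(sprintf(
      "FHIR Consent lacks the validity period start (%s)",
      if (release == "R4") "provision.period.start" else "period.start"
    ), call. = FALSE)
  }
  period <- validity_period(period_node$start, period_node$end)

  if (length(doc$policy) == 0L) {
    stop("FHIR Consent carries no policy references", call. = FALSE)
  }

  fhir_status <- doc$status
  provenance <- list()
  if (!is.null(fhir_status)) {
    provenance$fhir_status <- fhir_status
    provenance$fhir_status_mapped <- as.character(
      tryCatch(map_fhir_status(fhir_status), error = function(e) status_label("unknown"))
    )
  }
  recorded_at <- if (!is.null(doc$dateTime)) parse_fhir_datetime(doc$dateTime) else NULL

  lapply(doc$policy, function(p) {
    if (is.null(p$uri)) {
      stop("policy entry lacks a 'uri'", call. = FALSE)
    }
    code <- registry_lookup(registry, p$uri)
    # A disagreement between the resource's status token and the policy
    # code is expected by design (exporters write "active" throughout);
    # the code wins and the token stays visible in provenance.
    provenance$fhir_status_discrepancy <-
      !is.null(provenance$fhir_status_mapped) &&
        !identical(provenance$fhir_status_mapped, as.character(code$status))
    consent_record(
      patient = patient,
      code = code,
      period = period,
      recorded_at = recorded_at,
      source_dialect = if (release == "R4") "fhir_r4" else "fhir_r3",
      document_id = doc$id,
      provenance = provenance
    )
  })
}

#' Write consent records as a FHIR Consent resource (JSON)
#'
#' Serializes records sharing one patient and one validity period as a
#' single `Consent` resource: FHIR status `"active"` (the interoperable
#' status lives in the policy code, not in the FHIR status token), the
#' patient-privacy scope coding (Release 4 only; Release 3 has no scope
#' element), the LOINC 57016-8 category stating that the resource is based
#' on a consent document, the patient identifier, one RetrieveCode-style
#' policy URI per record, and the period under `provision` (R4) or at the
#' resource level (R3).
#'
#' @param records Non-empty list of [consent_record()] objects sharing one
#'   patient and one period.
#' @param release `"R4"` or `"R3"`.
#' @param pretty Pretty-print the JSON.
#' @return JSON text (class `json`).
#' @export
write_fhir_consent <- function(records, release = c("R4", "R3"), pretty = TRUE) {
  release <- match.arg(release)
  check_shared_patient(records)
  periods <- unique(vapply(records, function(r) {
    paste(format(r$period$start), format(r$period$end %||% "open"))
  }, character(1)))
  if (length(periods) > 1L) {
    stop(paste0(
      "records carry different validity periods; a single Consent resource ",
      "holds one provision.period - split the records into one resource per period"
    ), call. = FALSE)
  }
  patient <- records[[1]]$patient
  period <- records[[1]]$period

  body <- list(resourceType = "Consent", status = "active")
  if (release == "R4") {
    body$scope <- list(coding = list(list(
      system = "http://terminology.hl7.org/CodeSystem/consentscope",
      code = "patient-privacy"
    )))
  }
  body$category <- list(list(coding = list(list(
    system = "http://loinc.org",
    code = LOINC_CONSENT_DOCUMENT
  ))))
  identifier <- list(value = patient$identifier_value)
  if (!is.null(patient$identifier_system)) {
    identifier$system <- patient$identifier_system
  }
  body$patient <- list(identifier = identifier)

  stamps <- unique(vapply(records, function(r) {
    if (is.null(r$recorded_at)) "" else format_fhir_datetime(r$recorded_at)
  }, character(1)))
  if (length(stamps) == 1L && nzchar(stamps)) {
    body$dateTime <- stamps
  }

  body$policy <- lapply(records, function(r) {
    list(uri = retrieve_code_uri(r$code$code_oid, r$code$code_system_oid))
  })
  period_node <- list(start = format(period$start))
  if (!is.null(period$end)) {
    period_node$end <- format(period$end)
  }
  if (release == "R4") {
    body$provision <- list(period = period_node)
  } else {
    body$period <- period_node
  }
  jsonlite::toJSON(body, auto_unbox = TRUE, pretty = pretty)
}

#' Path of the bundled FHIR Release 4 example resource
#'
#' A worked example: one active Consent for patient `patientf001`,
#' referencing code 2.16.840.1.113883.3.1937.777.24.5.1.1 with validity
#' 2018-10-10 through 2023-10-09.
#'
#' @return File path.
#' @export
mii_fhir_example_path <- function() {
  system.file("extdata", "consent-fhir-r4-example.json",
    package = "miiconsent", mustWork = TRUE
  )
}

LOINC_CONSENT_DOCUMENT <- "57016-8"

parse_fhir_json <- function(x) {
  looks_like_json <- length(x) == 1L && grepl("^\\s*[{\\[]", x)
  if (!looks_like_json && length(x) == 1L && file.exists(x)) {
    x <- paste(readLines(x, warn = FALSE, encoding = "UTF-8"), collapse = "\n")
  }
  jsonlite::fromJSON(x, simplifyVector = FALSE)
}

parse_fhir_datetime <- function(x) {
  out <- as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  if (is.na(out)) {
    out <- as.POSIXct(x, tz = "UTC")
  }
  if (is.na(out)) {
    stop(sprintf("unparseable FHIR dateTime '%s'", x), call. = FALSE)
  }
  out
}

format_fhir_datetime <- function(x) {
  format(x, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
}

check_shared_patient <- function(records) {
  if (length(records) == 0L) {
    stop("no records to serialize", call. = FALSE)
  }
  for (r in records) {
    if (!inherits(r, "consent_record")) {
      stop("all elements must be consent_record objects", call. = FALSE)
    }
  }
  ids <- unique(vapply(records, function(r) r$patient$identifier_value, character(1)))
  if (length(ids) > 1L) {
    stop(sprintf(
      "records reference different patients (%s); one document holds one patient",
      paste(ids, collapse = ", ")
    ), call. = FALSE)
  }
  invisible(records)
}
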