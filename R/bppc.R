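#' IHE BPPC template identifiers
#'
#' OIDs required in the header of a Basic Patient Privacy Consents CDA R2
#' document: the two document-level templateIds and the serviceEvent-level
#' templateId.
#'
#' @name bppc-constants
NULL

BPPC_DOC_TEMPLATE_IDS <- c(
  "1.3.6.1.4.1.19376.1.5.3.1.1.1",
  "1.3.6.1.4.1.19376.1.5.3.1.1.7"
)
BPPC_SERVICE_EVENT_TEMPLATE_ID <- "1.3.6.1.4.1.19376.1.5.3.1.2.6"
CDA_NS <- "urn:hl7-org:v3"
LOINC_SYSTEM_OID <- "2.16.840.1.113883.6.1"

#' Read consent records from an IHE BPPC CDA document
#'
#' BPPC has no explicit status slot, which is precisely why the combined
#' policy-status codes exist: the status label is recoverable solely from
#' the code carried by each `documentationOf/serviceEvent`. One record is
#' produced per serviceEvent; the validity period comes from its
#' `effectiveTime` (`low`/`high`, `YYYYMMDD`), the patient from
#' `recordTarget/patientRole/id` (`extension` as identifier value, `root`
#' as identifier system).
#'
#' @param x CDA XML text, a file path, or an `xml2` document.
#' @param registry A [code_registry()] used to resolve serviceEvent codes.
#' @return List of [consent_record()] objects with `source_dialect`
#'   `"bppc"`.
#' @examples
#' reg <- mii_default_registry()
#' recs <- read_bppc(mii_bppc_example_path(), reg)
#' record_core(recs[[1]])
#' @export
read_bppc <- function(x, registry) {
  stopifnot(inherits(registry, "code_registry"))
  doc <- as_cda_document(x)
  root <- xml2::xml_root(doc)
  ns_uri <- xml2::xml_ns(doc)[["d1"]]
  if (!identical(ns_uri, CDA_NS)) {
    stop(sprintf(
      "document is not in the CDA namespace %s (found '%s')", CDA_NS, ns_uri
    ), call. = FALSE)
  }

  id_node <- xml2::xml_find_first(root, ".//d1:recordTarget/d1:patientRole/d1:id")
  if (inherits(id_node, "xml_missing")) {
    stop("BPPC document lacks recordTarget/patientRole/id", call. = FALSE)
  }
  identifier_value <- xml2::xml_attr(id_node, "extension")
  identifier_system <- xml2::xml_attr(id_node, "root")
  if (is.na(identifier_value) || !nzchar(identifier_value)) {
    stop("patientRole/id lacks an 'extension' identifier", call. = FALSE)
  }
  patient <- patient_ref(
    identifier_value,
    if (is.na(identifier_system)) NULL else identifier_system
  )

  events <- xml2::xml_find_all(root, ".//d1:documentationOf/d1:serviceEvent")
  if (length(events) == 0L) {
    stop("BPPC document carries no documentationOf/serviceEvent", call. = FALSE)
  }
  lapply(events, function(ev) {
    code_node <- xml2::xml_find_first(ev, "./d1:code")
    if (inherits(code_node, "xml_missing")) {
      stop("serviceEvent lacks a code element", call. = FALSE)
    }
    code_oid <- xml2::xml_attr(code_node, "code")
    system_oid <- xml2::xml_attr(code_node, "codeSystem")
    if (is.na(code_oid)) {
      stop("serviceEvent code lacks a 'code' attribute", call. = FALSE)
    }
    code <- registry_lookup(registry, code_oid)
    if (!is.na(system_oid) &&
      !identical(system_oid, as.character(code$code_system_oid))) {
      stop(sprintf(
        "serviceEvent declares codeSystem %s but code %s is registered under %s",
        system_oid, code_oid, as.character(code$code_system_oid)
      ), call. = FALSE)
    }
    low <- xml2::xml_find_first(ev, "./d1:effectiveTime/d1:low")
    high <- xml2::xml_find_first(ev, "./d1:effectiveTime/d1:high")
    if (inherits(low, "xml_missing")) {
      stop("serviceEvent effectiveTime lacks a 'low' boundary", call. = FALSE)
    }
    start <- parse_cda_date(xml2::xml_attr(low, "value"))
    end <- if (inherits(high, "xml_missing")) {
      NULL
    } else {
      parse_cda_date(xml2::xml_attr(high, "value"))
    }
    ev_id <- xml2::xml_find_first(ev, "./d1:id")
    consent_record(
      patient = patient,
      code = code,
      period = validity_period(start, end),
      source_dialect = "bppc",
      document_id = if (inherits(ev_id, "xml_missing")) {
        NULL
      } else {
        xml2::xml_attr(ev_id, "root")
      }
    )
  })
}

#' Write consent records as an IHE BPPC CDA document
#'
#' Emits a header-level BPPC document: both document templateIds, the LOINC
#' 57016-8 document code ("PATIENT PRIVACY ACKNOWLEDGEMENT"), the patient
#' in `recordTarget/patientRole`, and one `documentationOf/serviceEvent`
#' (class `ACT`, mood `EVN`) per record, carrying the policy-status code
#' and the validity period as `effectiveTime` in `YYYYMMDD`. The structured
#' body is an empty placeholder; BPPC's narrative body is out of scope
#' here. Unlike a FHIR Consent resource, each serviceEvent carries its own
#' period, so records with different periods coexist in one document.
#'
#' @param records Non-empty list of [consent_record()] sharing one patient.
#' @param event_id_root OID namespace under which per-serviceEvent ids are
#'   generated as consecutive children.
#' @return An `xml2` document.
#' @export
write_bppc <- function(records,
                       event_id_root = "2.16.840.1.113883.3.1937.777.24.999") {
  check_shared_patient(records)
  patient <- records[[1]]$patient
  doc <- xml2::xml_new_root("ClinicalDocument", xmlns = CDA_NS)
  for (tid in BPPC_DOC_TEMPLATE_IDS) {
    xml2::xml_add_child(doc, "templateId", root = tid)
  }
  xml2::xml_add_child(doc, "code",
    code = LOINC_CONSENT_DOCUMENT,
    displayName = "PATIENT PRIVACY ACKNOWLEDGEMENT",
    codeSystem = LOINC_SYSTEM_OID,
    codeSystemName = "LOINC"
  )
  rt <- xml2::xml_add_child(doc, "recordTarget")
  pr <- xml2::xml_add_child(rt, "patientRole")
  id_attrs <- list(extension = patient$identifier_value)
  if (!is.null(patient$identifier_system)) {
    id_attrs$root <- patient$identifier_system
  }
  do.call(xml2::xml_add_child, c(list(pr, "id"), id_attrs))
  xml2::xml_add_child(pr, "addr", use = "HP")
  xml2::xml_add_child(pr, "patient")
  for (i in seq_along(records)) {
    r <- records[[i]]
    dof <- xml2::xml_add_child(doc, "documentationOf", typeCode = "DOC")
    ev <- xml2::xml_add_child(dof, "serviceEvent",
      classCode = "ACT", moodCode = "EVN"
    )
    xml2::xml_add_child(ev, "templateId", root = BPPC_SERVICE_EVENT_TEMPLATE_ID)
    xml2::xml_add_child(ev, "id",
      root = as.character(oid_child(event_id_root, i))
    )
    xml2::xml_add_child(ev, "code",
      code = as.character(r$code$code_oid),
      codeSystem = as.character(r$code$code_system_oid)
    )
    et <- xml2::xml_add_child(ev, "effectiveTime")
    xml2::xml_add_child(et, "low", value = format(r$period$start, "%Y%m%d"))
    if (!is.null(r$period$end)) {
      xml2::xml_add_child(et, "high", value = format(r$period$end, "%Y%m%d"))
    }
  }
  comp <- xml2::xml_add_child(doc, "component")
  xml2::xml_add_child(comp, "structuredBody")
  doc
}

#' Path of the bundled BPPC example document
#'
#' The BPPC counterpart of the bundled FHIR example: the same code,
#' code system and validity period encoded as a CDA header.
#'
#' @return File path.
#' @export
mii_bppc_example_path <- function() {
  system.file("extdata", "consent-bppc-example.xml",
    package = "miiconsent", mustWork = TRUE
  )
}

#' Check a document against the relaxed BPPC header profile
#'
#' Verifies namespace, the presence of both document templateIds, the LOINC
#' document code, a patient id, and per-serviceEvent templateId, code and
#' effectiveTime. This is a structural header check, not full CDA schema
#' validation.
#'
#' @param x CDA XML text, file path, or `xml2` document.
#' @return Character vector of problems; empty when the header conforms.
#' @export
bppc_check_header <- function(x) {
  doc <- as_cda_document(x)
  root <- xml2::xml_root(doc)
  problems <- character(0)
  ns_uri <- tryCatch(xml2::xml_ns(doc)[["d1"]], error = function(e) NA_character_)
  if (!identical(ns_uri, CDA_NS)) {
    return(sprintf("document namespace is not %s", CDA_NS))
  }
  tids <- xml2::xml_attr(
    xml2::xml_find_all(root, "./d1:templateId"), "root"
  )
  for (tid in BPPC_DOC_TEMPLATE_IDS) {
    if (!tid %in% tids) {
      problems <- c(problems, sprintf("missing document templateId %s", tid))
    }
  }
  code_node <- xml2::xml_find_first(root, "./d1:code")
  if (inherits(code_node, "xml_missing")) {
    problems <- c(problems, "missing document code element")
  } else if (!identical(xml2::xml_attr(code_node, "code"), LOINC_CONSENT_DOCUMENT)) {
    problems <- c(problems, sprintf(
      "document code is not LOINC %s", LOINC_CONSENT_DOCUMENT
    ))
  }
  if (inherits(
    xml2::xml_find_first(root, "./d1:recordTarget/d1:patientRole/d1:id"),
    "xml_missing"
  )) {
    problems <- c(problems, "missing recordTarget/patientRole/id")
  }
  events <- xml2::xml_find_all(root, "./d1:documentationOf/d1:serviceEvent")
  if (length(events) == 0L) {
    problems <- c(problems, "no documentationOf/serviceEvent")
  }
  for (ev in events) {
    ev_tids <- xml2::xml_attr(xml2::xml_find_all(ev, "./d1:templateId"), "root")
    if (!BPPC_SERVICE_EVENT_TEMPLATE_ID %in% ev_tids) {
      problems <- c(problems, sprintf(
        "serviceEvent lacks templateId %s", BPPC_SERVICE_EVENT_TEMPLATE_ID
      ))
    }
    if (inherits(xml2::xml_find_first(ev, "./d1:code"), "xml_missing")) {
      problems <- c(problems, "serviceEvent lacks a code")
    }
    if (inherits(
      xml2::xml_find_first(ev, "./d1:effectiveTime/d1:low"), "xml_missing"
    )) {
      problems <- c(problems, "serviceEvent lacks effectiveTime/low")
    }
  }
  problems
}

as_cda_document <- function(x) {
  if (inherits(x, "xml_document")) {
    # Re-parse so that children built in memory pick up the default
    # namespace; xpath with the d1 prefix then works uniformly.
    return(xml2::read_xml(as.character(x)))
  }
  if (length(x) == 1L && !grepl("^\\s*<", x) && file.exists(x)) {
    return(xml2::read_xml(x))
  }
  xml2::read_xml(x)
}

# CDA TS values are day-precision here; finer precisions are truncated to
# the day with a warning.
parse_cda_date <- function(value) {
  if (is.na(value) || !grepl("^[0-9]{8}", value)) {
    stop(sprintf("unparseable effectiveTime value '%s' (expected YYYYMMDD)", value),
      call. = FALSE
    )
  }
  if (nchar(value) > 8L) {
    warning(sprintf(
      "effectiveTime value '%s' is finer than day precision; truncating", value
    ), call. = FALSE)
    value <- substring(value, 1L, 8L)
  }
  d <- as.Date(value, format = "%Y%m%d")
  if (is.na(d)) {
    stop(sprintf("effectiveTime value '%s' is not a calendar date", value),
      call. = FALSE
    )
  }
  d
}
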