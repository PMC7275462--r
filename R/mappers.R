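FHIR_STATUS_MAP <- c(
  "draft" = "not valid",
  "proposed" = "not valid",
  "active" = "valid",
  "rejected" = "not valid",
  "inactive" = "not valid",
  "entered-in-error" = "not valid"
)

GICS_STATUS_MAP <- c(
  "Accepted" = "valid",
  "Declined" = "not valid",
  "Withdrawn" = "not valid",
  "Invalidated" = "not valid"
)

#' Status-label mapping tables
#'
#' Returns the complete mapping from an external system's consent states
#' onto the three interoperability labels. The FHIR table covers the six
#' Consent status tokens of Releases 3 (v3.0.1) and 4 (v4.0.0), which share
#' one label set; the gICS table covers the four states of gICS 2.8.6.
#' `"unknown"` never appears in the range of either table: it is reserved
#' for absence of documentation, not for vocabulary the mapper does not
#' recognize.
#'
#' @param system `"fhir"` or `"gics"`.
#' @return A data frame with columns `source_label` and `status`.
#' @export
mapping_table <- function(system = c("fhir", "gics")) {
  system <- match.arg(system)
  map <- if (system == "fhir") FHIR_STATUS_MAP else GICS_STATUS_MAP
  data.frame(
    source_label = names(map),
    status = unname(map),
    stringsAsFactors = FALSE
  )
}

#' Map a FHIR Consent status token to a status label
#'
#' Only `"active"` maps to `"valid"`; every other documented token
#' (`draft`, `proposed`, `rejected`, `inactive`, `entered-in-error`) maps
#' to `"not valid"`. The mapping is lossy by design: the richer source
#' vocabulary cannot be recovered from the three-label space, so callers
#' that need it keep the original token in record provenance.
#'
#' @param label A FHIR Consent status token.
#' @return A [status_label()].
#' @examples
#' map_fhir_status("active")
#' map_fhir_status("entered-in-error")
#' @export
map_fhir_status <- function(label) {
  map_status_token(label, FHIR_STATUS_MAP, "FHIR")
}

#' Map a gICS consent state to a status label
#'
#' Only `"Accepted"` maps to `"valid"`; `Declined`, `Withdrawn` and
#' `Invalidated` map to `"not valid"`.
#'
#' @param label A gICS state token.
#' @return A [status_label()].
#' @examples
#' map_gics_status("Accepted")
#' map_gics_status("Withdrawn")
#' @export
map_gics_status <- function(label) {
  map_status_token(label, GICS_STATUS_MAP, "gICS")
}

# Out-of-domain tokens raise rather than defaulting to "unknown".
map_status_token <- function(label, map, system_name) {
  if (!is.character(label) || length(label) != 1L || is.na(label)) {
    stop("status token must be a single string", call. = FALSE)
  }
  if (!label %in% names(map)) {
    stop(structure(
      class = c("miiconsent_unmapped_label", "error", "condition"),
      list(
        message = sprintf(
          "unmapped %s status token '%s' (known: %s)",
          system_name, label, paste(names(map), collapse = ", ")
        ),
        call = NULL, label = label
      )
    ))
  }
  status_label(unname(map[label]))
}

DIALECTS <- c("fhir-r4", "fhir-r3", "bppc")

#' Convert a consent document between dialects
#'
#' Parses the input in the source dialect, passes through the shared
#' consent-record model, and serializes in the target dialect. The three
#' core data elements — policy code (carrying module and template version),
#' status, and validity period — are preserved exactly in every direction;
#' this losslessness is what the combined policy-status code system buys.
#'
#' @param x Document text or file path.
#' @param from,to Dialect tokens: `"fhir-r4"`, `"fhir-r3"` or `"bppc"`.
#' @param registry A [code_registry()] resolving policy codes.
#' @return The serialized target document: JSON text for FHIR targets, an
#'   `xml2` document for BPPC.
#' @examples
#' reg <- mii_default_registry()
#' doc <- convert_consent(mii_fhir_example_path(), "fhir-r4", "bppc", reg)
#' @export
convert_consent <- function(x, from, to, registry) {
  records <- read_consent(x, from, registry)
  write_consent(records, to)
}

#' Read a consent document in any supported dialect
#'
#' @param x Document text or file path.
#' @param dialect `"fhir-r4"`, `"fhir-r3"` or `"bppc"`.
#' @param registry A [code_registry()].
#' @return List of [consent_record()] objects.
#' @export
read_consent <- function(x, dialect, registry) {
  dialect <- match.arg(dialect, DIALECTS)
  switch(dialect,
    "fhir-r4" = read_fhir_consent(x, registry, release = "R4"),
    "fhir-r3" = read_fhir_consent(x, registry, release = "R3"),
    "bppc" = read_bppc(x, registry)
  )
}

#' Write consent records in any supported dialect
#'
#' @param records List of [consent_record()] objects sharing one patient.
#' @param dialect `"fhir-r4"`, `"fhir-r3"` or `"bppc"`.
#' @return JSON text for FHIR dialects, an `xml2` document for BPPC.
#' @export
write_consent <- function(records, dialect) {
  dialect <- match.arg(dialect, DIALECTS)
  switch(dialect,
    "fhir-r4" = write_fhir_consent(records, release = "R4"),
    "fhir-r3" = write_fhir_consent(records, release = "R3"),
    "bppc" = write_bppc(records)
  )
}
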