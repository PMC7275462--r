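#' Consent template modules
#'
#' A module is a logically self-contained statement in a consent template to
#' which a patient gives an individual voluntary decision. Under the GDPR
#' opt-in principle every module carries at least the choices `"Yes"` and
#' `"No"`; consent to a module comes into effect only through an active
#' `"Yes"`.
#'
#' @param module_id Short token identifying the module within its template.
#' @param statement_text The statement the patient decides on.
#' @param section_name Name of the template section the module belongs to.
#' @param opt_in_choices Ordered character vector of choice labels; must
#'   contain at least `"Yes"` and `"No"`.
#' @return An object of class `consent_module`.
#' @export
consent_module <- function(module_id, statement_text, section_name,
                           opt_in_choices = c("Yes", "No")) {
  stopifnot(
    is.character(module_id), length(module_id) == 1L, nzchar(module_id),
    is.character(statement_text), length(statement_text) == 1L,
    is.character(section_name), length(section_name) == 1L
  )
  if (!all(c("Yes", "No") %in% opt_in_choices)) {
    stop(sprintf(
      "module '%s': opt_in_choices must contain both 'Yes' and 'No'",
      module_id
    ), call. = FALSE)
  }
  structure(
    list(
      module_id = module_id,
      statement_text = statement_text,
      section_name = section_name,
      opt_in_choices = as.character(opt_in_choices)
    ),
    class = "consent_module"
  )
}

#' Versioned consent templates
#'
#' A consent template is a versioned document of named sections, each
#' holding one or more modules. The template version travels with every
#' policy-status code derived from the template, because the meaning of a
#' module is tied to the exact wording of a specific version.
#'
#' @param template_version Version string, e.g. `"1.6a"`.
#' @param sections Ordered character vector of section names.
#' @param modules List of [consent_module()] objects, in document order.
#' @param name Optional human-readable template name.
#' @return An object of class `consent_template`.
#' @export
consent_template <- function(template_version, sections, modules, name = NULL) {
  stopifnot(
    is.character(template_version), length(template_version) == 1L,
    nzchar(template_version), is.character(sections), is.list(modules)
  )
  if (length(sections) == 0L) {
    stop("template must declare at least one section", call. = FALSE)
  }
  if (anyDuplicated(sections)) {
    stop("template section names must be unique", call. = FALSE)
  }
  for (m in modules) {
    if (!inherits(m, "consent_module")) {
      stop("all modules must be consent_module objects", call. = FALSE)
    }
    if (!m$section_name %in% sections) {
      stop(sprintf(
        "module '%s' references undeclared section '%s'",
        m$module_id, m$section_name
      ), call. = FALSE)
    }
  }
  ids <- vapply(modules, `[[`, character(1), "module_id")
  if (anyDuplicated(ids)) {
    stop(sprintf(
      "duplicate module id(s) in template version %s: %s",
      template_version, paste(unique(ids[duplicated(ids)]), collapse = ", ")
    ), call. = FALSE)
  }
  structure(
    list(
      template_version = template_version,
      name = name,
      sections = as.character(sections),
      modules = modules
    ),
    class = "consent_template"
  )
}

#' @export
print.consent_template <- function(x, ...) {
  cat(sprintf(
    "<consent_template> version %s: %d section(s), %d module(s)\n",
    x$template_version, length(x$sections), length(x$modules)
  ))
  for (m in x$modules) {
    cat(sprintf("  [%s] %s (%s)\n", m$module_id, m$section_name,
                paste(m$opt_in_choices, collapse = "/")))
  }
  invisible(x)
}

#' Data-use policies
#'
#' A policy is either a consent module (carrying the version of the template
#' it comes from) or a regulatory provision such as a law permitting certain
#' data processing without patient consent. Both kinds are combined with
#' status labels into registrable codes in exactly the same way.
#'
#' @param policy_id Token identifying the policy (module id for
#'   consent-module policies).
#' @param kind `"consent_module"` or `"regulatory"`.
#' @param template_version Version string; required for consent-module
#'   policies and disallowed for regulatory ones.
#' @param description Free-text description.
#' @return An object of class `consent_policy`.
#' @export
policy <- function(policy_id, kind = c("consent_module", "regulatory"),
                   template_version = NULL, description = "") {
  kind <- match.arg(kind)
  stopifnot(is.character(policy_id), length(policy_id) == 1L, nzchar(policy_id))
  if (kind == "consent_module" && is.null(template_version)) {
    stop("consent-module policies must carry a template_version", call. = FALSE)
  }
  if (kind == "regulatory" && !is.null(template_version)) {
    stop("regulatory policies may not carry a template_version", call. = FALSE)
  }
  structure(
    list(
      policy_id = policy_id,
      kind = kind,
      template_version = template_version,
      description = description
    ),
    class = "consent_policy"
  )
}

# Key identifying a policy within a registry / store.
policy_key <- function(policy_id, template_version = NULL) {
  if (is.null(template_version)) policy_id else paste0(policy_id, "@", template_version)
}

#' Policy-status codes
#'
#' Neither FHIR (whose consent status codes were not finalized) nor BPPC
#' (which has no status slot at all) can carry a free-standing status label
#' interoperably, so each registrable code identifies the *combination* of
#' one policy with one of the three status labels. The code is an OID that
#' is a direct child of its code system's OID.
#'
#' @param code_oid The code's [oid()]; must be a child of `code_system_oid`.
#' @param code_system_oid The owning code system's [oid()].
#' @param policy The [policy()] the code refers to.
#' @param status The [status_label()] the code asserts.
#' @param display Human-readable display text.
#' @return An object of class `policy_status_code`.
#' @export
policy_status_code <- function(code_oid, code_system_oid, policy, status,
                               display = "") {
  code_oid <- oid(code_oid)
  code_system_oid <- oid(code_system_oid)
  if (!oid_is_child(code_oid, code_system_oid)) {
    stop(sprintf(
      "code OID %s is not a direct child of code system OID %s",
      as.character(code_oid), as.character(code_system_oid)
    ), call. = FALSE)
  }
  if (!inherits(policy, "consent_policy")) {
    stop("'policy' must be a consent_policy object", call. = FALSE)
  }
  structure(
    list(
      code_oid = code_oid,
      code_system_oid = code_system_oid,
      policy = policy,
      status = status_label(status),
      display = display
    ),
    class = "policy_status_code"
  )
}

#' @export
print.policy_status_code <- function(x, ...) {
  cat(sprintf(
    "<code> %s [%s | %s]\n", as.character(x$code_oid),
    policy_key(x$policy$policy_id, x$policy$template_version),
    as.character(x$status)
  ))
  invisible(x)
}

#' Validity periods
#'
#' The period during which a documented status is in effect. The start date
#' is mandatory; the end is optional (open-ended documentation). Both
#' endpoints are inclusive calendar dates.
#'
#' @param start Start date (`Date` or `"YYYY-MM-DD"` string). Required.
#' @param end Optional end date; when present must not precede `start`.
#' @return An object of class `validity_period`.
#' @export
validity_period <- function(start, end = NULL) {
  start <- as_consent_date(start, "period start")
  if (!is.null(end)) {
    end <- as_consent_date(end, "period end")
    if (end < start) {
      stop(sprintf(
        "period end (%s) precedes start (%s)",
        format(end), format(start)
      ), call. = FALSE)
    }
  }
  structure(list(start = start, end = end), class = "validity_period")
}

as_consent_date <- function(x, what = "date") {
  if (is.null(x) || (length(x) == 1L && is.na(x))) {
    stop(sprintf("%s is required", what), call. = FALSE)
  }
  if (inherits(x, "Date")) {
    return(x)
  }
  d <- tryCatch(as.Date(x, format = "%Y-%m-%d"), error = function(e) NA)
  if (length(d) != 1L || is.na(d)) {
    stop(sprintf("%s '%s' is not a valid YYYY-MM-DD date", what, x), call. = FALSE)
  }
  d
}

#' Test whether a date falls inside a validity period
#'
#' Both endpoints are inclusive; an absent end means the period is open.
#'
#' @param period A [validity_period()].
#' @param date A `Date` or date string.
#' @return `TRUE` or `FALSE`.
#' @export
period_contains <- function(period, date) {
  stopifnot(inherits(period, "validity_period"))
  date <- as_consent_date(date)
  date >= period$start && (is.null(period$end) || date <= period$end)
}

#' Patient references
#'
#' @param identifier_value Non-empty identifier string.
#' @param identifier_system Optional identifier namespace (an OID or URI).
#' @return An object of class `patient_ref`.
#' @export
patient_ref <- function(identifier_value, identifier_system = NULL) {
  if (!is.character(identifier_value) || length(identifier_value) != 1L ||
    is.na(identifier_value) || !nzchar(identifier_value)) {
    stop("patient identifier_value must be a non-empty string", call. = FALSE)
  }
  if (!is.null(identifier_system)) {
    stopifnot(is.character(identifier_system), length(identifier_system) == 1L)
  }
  structure(
    list(identifier_value = identifier_value, identifier_system = identifier_system),
    class = "patient_ref"
  )
}

#' Consent records
#'
#' One documented consent statement: which patient, which policy-status
#' code, and from when (optionally until when) the documented status holds.
#' The three mandatory data elements of the interoperability layer — the
#' status for a module, the template version, and the start of validity —
#' are all present by construction: status and version travel inside the
#' policy-status code, the start inside the period.
#'
#' A later withdrawal is *not* an update of an existing record: it is a new
#' record referencing the `"not valid"` code of the same policy with a later
#' validity start.
#'
#' @param patient A [patient_ref()].
#' @param code A [policy_status_code()].
#' @param period A [validity_period()] (start mandatory).
#' @param recorded_at Optional timestamp (`POSIXct` or string, UTC) of when
#'   the record was documented; used for tie-breaking by the engine.
#' @param source_dialect One of `"fhir_r3"`, `"fhir_r4"`, `"bppc"`,
#'   `"native"`.
#' @param document_id Optional source document identifier.
#' @param provenance Optional named list of provenance notes (e.g. the
#'   original FHIR status token and its mapped label).
#' @return An object of class `consent_record`.
#' @export
consent_record <- function(patient, code, period, recorded_at = NULL,
                           source_dialect = c("native", "fhir_r3", "fhir_r4", "bppc"),
                           document_id = NULL, provenance = list()) {
  source_dialect <- match.arg(source_dialect)
  if (!inherits(patient, "patient_ref")) {
    stop("consent record requires a patient reference", call. = FALSE)
  }
  if (!inherits(code, "policy_status_code")) {
    stop("consent record requires a policy-status code", call. = FALSE)
  }
  if (!inherits(period, "validity_period")) {
    stop("consent record requires a validity period with a start date", call. = FALSE)
  }
  if (!is.null(recorded_at)) {
    recorded_at <- as.POSIXct(recorded_at, tz = "UTC")
    if (is.na(recorded_at)) {
      stop("recorded_at is not a valid timestamp", call. = FALSE)
    }
  }
  structure(
    list(
      patient = patient,
      code = code,
      period = period,
      recorded_at = recorded_at,
      source_dialect = source_dialect,
      document_id = document_id,
      provenance = provenance
    ),
    class = "consent_record"
  )
}

#' @export
print.consent_record <- function(x, ...) {
  cat(sprintf(
    "<consent_record> patient=%s policy=%s status=%s period=%s..%s [%s]\n",
    x$patient$identifier_value,
    policy_key(x$code$policy$policy_id, x$code$policy$template_version),
    as.character(x$code$status),
    format(x$period$start),
    if (is.null(x$period$end)) "open" else format(x$period$end),
    x$source_dialect
  ))
  invisible(x)
}

#' Extract the core interoperable data elements of a record
#'
#' The elements every dialect must preserve exactly: patient identifier,
#' policy id and template version, status label, code and code-system OIDs,
#' and the validity period. Used by round-trip and conversion tests.
#'
#' @param record A [consent_record()].
#' @return A named list of plain scalars (`NA` for an open end).
#' @export
record_core <- function(record) {
  stopifnot(inherits(record, "consent_record"))
  list(
    patient = record$patient$identifier_value,
    policy_id = record$code$policy$policy_id,
    template_version = record$code$policy$template_version,
    status = as.character(record$code$status),
    code_oid = as.character(record$code$code_oid),
    code_system_oid = as.character(record$code$code_system_oid),
    start = format(record$period$start),
    end = if (is.null(record$period$end)) NA_character_ else format(record$period$end)
  )
}

#' Compare two record lists on their core data elements
#'
#' @param a,b Lists of [consent_record()] objects.
#' @return `TRUE` iff both lists have the same length and element-wise
#'   identical [record_core()] content.
#' @export
records_core_identical <- function(a, b) {
  if (length(a) != length(b)) {
    return(FALSE)
  }
  for (i in seq_along(a)) {
    if (!identical(record_core(a[[i]]), record_core(b[[i]]))) {
      return(FALSE)
    }
  }
  TRUE
}
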