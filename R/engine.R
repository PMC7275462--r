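#' Create an empty consent store
#'
#' A mutable collection of consent records indexed by (patient, policy),
#' over which the engine resolves effective statuses and runs cohort
#' queries.
#'
#' @return An object of class `consent_store`.
#' @export
consent_store <- function() {
  store <- new.env(parent = emptyenv())
  store$records <- list() # flat list of consent_record
  store$index <- list() # by "patient||policy_key": integer indices
  class(store) <- "consent_store"
  store
}

#' @export
print.consent_store <- function(x, ...) {
  cat(sprintf(
    "<consent_store> %d record(s), %d patient(s)\n",
    length(x$records), length(store_patients(x))
  ))
  invisible(x)
}

store_key <- function(patient_id, pkey) paste0(patient_id, "\x1f", pkey)

#' Add records to a consent store
#'
#' @param store A [consent_store()].
#' @param records A [consent_record()] or list of them.
#' @return The store, invisibly.
#' @export
add_records <- function(store, records) {
  stopifnot(inherits(store, "consent_store"))
  if (inherits(records, "consent_record")) {
    records <- list(records)
  }
  for (r in records) {
    if (!inherits(r, "consent_record")) {
      stop("all elements must be consent_record objects", call. = FALSE)
    }
    idx <- length(store$records) + 1L
    store$records[[idx]] <- r
    key <- store_key(
      r$patient$identifier_value,
      policy_key(r$code$policy$policy_id, r$code$policy$template_version)
    )
    store$index[[key]] <- c(store$index[[key]], idx)
  }
  invisible(store)
}

#' Patients known to a store
#'
#' @param store A [consent_store()].
#' @return Sorted character vector of patient identifier values.
#' @export
store_patients <- function(store) {
  stopifnot(inherits(store, "consent_store"))
  sort(unique(vapply(
    store$records, function(r) r$patient$identifier_value, character(1)
  )))
}

#' Engine configuration
#'
#' Fixed resolution semantics plus the set of modules subject to the
#' five-year health-insurance cap. Elapsed or not-yet-started periods read
#' as `"unknown"` (no documentation in effect) rather than `"not valid"`,
#' which is a *documented* state; both equally deny data use downstream.
#'
#' @param insurance_module_ids Module ids whose records may not span more
#'   than five years.
#' @return An object of class `engine_config`.
#' @export
engine_config <- function(insurance_module_ids = mii_insurance_modules()) {
  structure(
    list(
      tie_break = "latest recorded_at, then latest period start, then deny-biased label order (not valid < unknown < valid)",
      expired_reads_as = "unknown",
      insurance_module_ids = as.character(insurance_module_ids),
      insurance_cap_years = 5L
    ),
    class = "engine_config"
  )
}

#' Resolve the effective consent status of a patient for a policy
#'
#' Among the records for `(patient, policy)` whose validity period contains
#' `at_date`, the winning record is chosen by (1) latest `recorded_at`
#' (records without a timestamp sort earliest), (2) latest period start,
#' (3) deny-biased label order `not valid` before `unknown` before `valid`.
#' Its status label is returned. When no record covers the date — including
#' after an end-dated period has elapsed — the result is `"unknown"`:
#' absence of documentation, not a documented denial.
#'
#' A withdrawal is therefore simply a later record carrying the policy's
#' `"not valid"` code: it outranks the original grant at every date both
#' cover.
#'
#' @param store A [consent_store()].
#' @param patient_id Patient identifier value.
#' @param policy_id Policy (module) id.
#' @param at_date Query date (`Date` or `"YYYY-MM-DD"`).
#' @param template_version Template version qualifying the policy; `NULL`
#'   matches records of a version-free (regulatory) policy.
#' @return A [status_label()].
#' @export
effective_status <- function(store, patient_id, policy_id, at_date,
                             template_version = NULL) {
  stopifnot(inherits(store, "consent_store"))
  at_date <- as_consent_date(at_date)
  idx <- store$index[[store_key(patient_id, policy_key(policy_id, template_version))]]
  if (length(idx) == 0L) {
    return(status_label("unknown"))
  }
  covering <- Filter(
    function(r) period_contains(r$period, at_date),
    store$records[idx]
  )
  if (length(covering) == 0L) {
    return(status_label("unknown"))
  }
  rec_at <- vapply(covering, function(r) {
    if (is.null(r$recorded_at)) -Inf else as.numeric(r$recorded_at)
  }, numeric(1))
  starts <- vapply(covering, function(r) as.numeric(r$period$start), numeric(1))
  deny <- vapply(covering, function(r) {
    DENY_ORDER[[as.character(r$code$status)]]
  }, integer(1))
  ord <- order(-rec_at, -starts, deny)
  covering[[ord[1L]]]$code$status
}

#' Query the cohort of patients with a given effective status
#'
#' Returns exactly the patients of the store whose [effective_status()] for
#' the policy at the date equals `required`. For a fixed policy and date
#' the three cohorts partition the store's patient universe; querying for
#' `"unknown"` returns the patients without covering documentation.
#'
#' @inheritParams effective_status
#' @param required The required [status_label()].
#' @return Sorted character vector of patient identifier values.
#' @export
cohort_query <- function(store, policy_id, at_date, required,
                         template_version = NULL) {
  required <- status_label(required)
  patients <- store_patients(store)
  hits <- vapply(patients, function(p) {
    identical(
      as.character(effective_status(store, p, policy_id, at_date, template_version)),
      as.character(required)
    )
  }, logical(1))
  patients[hits]
}

#' Validate a consent record against a template and engine configuration
#'
#' Violations are data, not exceptions: the report lists (a) records whose
#' policy module is not part of the given template version, (b) insurance-
#' module records granting permission (status `"valid"`) whose validity
#' period spans more than five years (an open-ended grant counts as
#' exceeding the cap), and (c) records lacking a period start. The cap is
#' validated, never silently truncated.
#'
#' @param record A [consent_record()].
#' @param template The [consent_template()] the record should conform to.
#' @param config An [engine_config()].
#' @return A data frame of class `validation_report` with columns `rule`
#'   and `message`; zero rows mean the record is valid.
#' @export
validate_record <- function(record, template, config = engine_config()) {
  stopifnot(
    inherits(record, "consent_record"),
    inherits(template, "consent_template"),
    inherits(config, "engine_config")
  )
  rules <- character(0)
  messages <- character(0)
  pol <- record$code$policy

  if (is.null(record$period$start)) {
    rules <- c(rules, "missing_period_start")
    messages <- c(messages, "record lacks the mandatory period start date")
  }

  if (pol$kind == "consent_module") {
    module_ids <- vapply(template$modules, `[[`, character(1), "module_id")
    if (!identical(pol$template_version, template$template_version) ||
      !pol$policy_id %in% module_ids) {
      rules <- c(rules, "template_mismatch")
      messages <- c(messages, sprintf(
        "policy '%s' (template %s) is not a module of template version %s",
        pol$policy_id, pol$template_version %||% "<none>",
        template$template_version
      ))
    }
  }

  # The cap limits how long a *permission* may run; a documented denial
  # (e.g. an open-ended withdrawal) is not subject to it.
  if (pol$policy_id %in% config$insurance_module_ids &&
    identical(as.character(record$code$status), "valid") &&
    !is.null(record$period$start)) {
    cap_end <- seq(record$period$start,
      by = paste(config$insurance_cap_years, "years"),
      length.out = 2L
    )[2L] - 1L
    if (is.null(record$period$end)) {
      rules <- c(rules, "insurance_cap_exceeded")
      messages <- c(messages, sprintf(
        "insurance module '%s': open-ended period exceeds the %d-year cap (latest allowed end %s)",
        pol$policy_id, config$insurance_cap_years, format(cap_end)
      ))
    } else if (record$period$end > cap_end) {
      rules <- c(rules, "insurance_cap_exceeded")
      messages <- c(messages, sprintf(
        "insurance module '%s': period %s..%s spans more than %d years (latest allowed end %s)",
        pol$policy_id, format(record$period$start),
        format(record$period$end), config$insurance_cap_years, format(cap_end)
      ))
    }
  }

  structure(
    data.frame(rule = rules, message = messages, stringsAsFactors = FALSE),
    class = c("validation_report", "data.frame")
  )
}

#' Test whether a validation report is clean
#'
#' @param report A report from [validate_record()].
#' @return `TRUE` iff the report lists no violations.
#' @export
is_valid_report <- function(report) {
  nrow(report) == 0L
}

#' Load a consent store from a directory of documents
#'
#' Reads every `.json` file as a FHIR Consent resource (release detected
#' from the presence of the Release 4 `scope`/`provision` elements) and
#' every `.xml` file as a BPPC document, adding all records to one store.
#'
#' @param dir Directory path.
#' @param registry A [code_registry()].
#' @return A [consent_store()].
#' @export
load_consent_dir <- function(dir, registry) {
  if (!dir.exists(dir)) {
    stop(sprintf("directory not found: '%s'", dir), call. = FALSE)
  }
  store <- consent_store()
  for (f in sort(list.files(dir, pattern = "\\.json$", full.names = TRUE))) {
    parsed <- parse_fhir_json(f)
    # a file may hold one Consent resource or a JSON array of them
    resources <- if (!is.null(parsed$resourceType)) list(parsed) else parsed
    for (doc in resources) {
      release <- if (!is.null(doc$scope) || !is.null(doc$provision)) "R4" else "R3"
      add_records(store, read_fhir_consent(
        jsonlite::toJSON(doc, auto_unbox = TRUE), registry,
        release = release
      ))
    }
  }
  for (f in sort(list.files(dir, pattern = "\\.xml$", full.names = TRUE))) {
    add_records(store, read_bppc(f, registry))
  }
  store
}
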