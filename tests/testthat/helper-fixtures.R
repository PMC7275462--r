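# Shared fixtures and independent oracles, built in code at test time.

# Registry with all 24 codes of the bundled 1.6a template.
new_test_registry <- function() mii_default_registry()

# Random dotted-integer OID string (for URN round-trip property tests).
random_oid_string <- function() {
  depth <- sample(1:12, 1L)
  paste(sample(0:9999, depth, replace = TRUE), collapse = ".")
}

# A set of records for one patient sharing one period (the shape a single
# FHIR Consent resource can carry), drawn from the registered codes.
random_record_set <- function(registry, patient_id, n_codes = NULL,
                              with_recorded_at = FALSE) {
  all_codes <- names(registry$codes)
  n_codes <- n_codes %||% sample(1:3, 1L)
  picked <- sample(all_codes, n_codes)
  start <- as.Date("2015-01-01") + sample(0:3000, 1L)
  end <- if (stats::runif(1) < 0.8) start + sample(1:2000, 1L) else NULL
  recorded_at <- if (with_recorded_at) {
    as.POSIXct(paste(format(start), "09:30:00"), tz = "UTC")
  } else {
    NULL
  }
  lapply(picked, function(co) {
    consent_record(
      patient = patient_ref(patient_id),
      code = registry_lookup(registry, co),
      period = validity_period(start, end),
      recorded_at = recorded_at
    )
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent effective-status oracle: filter by containment, then pick the
# winner by explicit lexicographic comparison of (recorded_at, period
# start, deny-biased label rank). Kept deliberately separate from the
# engine's implementation.
oracle_status <- function(records, patient_id, policy_id, version, date) {
  date <- as.Date(date)
  covering <- Filter(function(r) {
    r$patient$identifier_value == patient_id &&
      r$code$policy$policy_id == policy_id &&
      identical(r$code$policy$template_version, version) &&
      date >= r$period$start &&
      (is.null(r$period$end) || date <= r$period$end)
  }, records)
  if (length(covering) == 0L) {
    return("unknown")
  }
  sort_key <- function(r) {
    c(
      if (is.null(r$recorded_at)) -Inf else as.numeric(r$recorded_at),
      as.numeric(r$period$start),
      -match(as.character(r$code$status), c("not valid", "unknown", "valid"))
    )
  }
  best <- covering[[1L]]
  if (length(covering) > 1L) {
    for (r in covering[-1L]) {
      ka <- sort_key(r)
      kb <- sort_key(best)
      for (j in 1:3) {
        if (ka[j] > kb[j]) {
          best <- r
          break
        }
        if (ka[j] < kb[j]) break
      }
    }
  }
  as.character(best$code$status)
}
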