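#' Specification of a synthetic consent population
#'
#' Describes a population of patients who each make a per-module Yes/No
#' opt-in decision, may later withdraw consent, and whose documented
#' statuses hold for bounded validity periods. The seed fully determines
#' the output; draws are made patient-by-patient (outer loop) and
#' module-by-module (inner loop) so generation is reproducible across
#' platforms.
#'
#' @param n_patients Number of patients.
#' @param template The [consent_template()] whose modules are decided on.
#' @param opt_in_probability Probability that a patient opts into a module
#'   (one value for all modules, or a vector named by module id).
#' @param withdrawal_probability Probability that an opt-in is later
#'   withdrawn.
#' @param withdrawal_lag Two-element vector: min/max days between the
#'   opt-in's validity start and the withdrawal's validity start.
#' @param period_length Two-element vector: min/max length in days of a
#'   documented validity period (capped so insurance-module periods never
#'   span more than five years).
#' @param start_window Two-element `Date` (or string) vector from which
#'   validity start dates are drawn uniformly.
#' @param insurance_module_ids Modules subject to the five-year cap.
#' @param seed Integer seed.
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(n_patients = 100L,
                            template = mii_template(),
                            opt_in_probability = 0.3,
                            withdrawal_probability = 1 / 6,
                            withdrawal_lag = c(30L, 540L),
                            period_length = c(365L, 2600L),
                            start_window = c("2018-01-01", "2020-12-31"),
                            insurance_module_ids = mii_insurance_modules(),
                            seed = 1L) {
  stopifnot(
    n_patients >= 0L,
    inherits(template, "consent_template"),
    all(opt_in_probability >= 0 & opt_in_probability <= 1),
    withdrawal_probability >= 0, withdrawal_probability <= 1,
    length(withdrawal_lag) == 2L, withdrawal_lag[1] <= withdrawal_lag[2],
    length(period_length) == 2L, period_length[1] <= period_length[2]
  )
  start_window <- as.Date(start_window)
  stopifnot(length(start_window) == 2L, start_window[1] <= start_window[2])
  structure(
    list(
      n_patients = as.integer(n_patients),
      template = template,
      opt_in_probability = opt_in_probability,
      withdrawal_probability = withdrawal_probability,
      withdrawal_lag = as.integer(withdrawal_lag),
      period_length = as.integer(period_length),
      start_window = start_window,
      insurance_module_ids = as.character(insurance_module_ids),
      seed = as.integer(seed)
    ),
    class = "population_spec"
  )
}

module_opt_in_prob <- function(spec, module_id) {
  p <- spec$opt_in_probability
  if (!is.null(names(p)) && module_id %in% names(p)) {
    return(unname(p[[module_id]]))
  }
  unname(p[[1]])
}

#' Generate a synthetic consent population
#'
#' For every patient and module an opt-in draw yields a record carrying the
#' module's `"valid"` or `"not valid"` code with a bounded validity period;
#' for a fraction of opt-ins a later withdrawal appends a second, open-ended
#' record carrying the `"not valid"` code (withdrawal-as-new-record, never
#' an update in place). Insurance-module periods are capped at five years
#' by construction.
#'
#' Alongside the records, a ground-truth table of expected effective
#' statuses is computed during generation — independently of the consent
#' engine — at probe dates chosen to hit the edge cases: each period
#' boundary, one day either side of it, the period midpoint, and the
#' withdrawal boundary.
#'
#' @param spec A [population_spec()].
#' @param registry Optional [code_registry()] already holding codes for the
#'   spec's template; when `NULL` a fresh registry is allocated under
#'   [mii_consent_system_oid()].
#' @return A list with elements `records` (list of [consent_record()]),
#'   `ground_truth` (data frame: `patient`, `module_id`, `date`,
#'   `expected_status`) and `registry`.
#' @export
generate_population <- function(spec, registry = NULL) {
  stopifnot(inherits(spec, "population_spec"))
  if (is.null(registry)) {
    registry <- code_registry()
    allocate_codes(registry, mii_consent_system_oid(), spec$template)
  }
  version <- spec$template$template_version
  code_for <- function(module_id, status) {
    vs <- value_set_for(registry, module_id, version)
    for (o in vs$member_code_oids) {
      code <- registry_lookup(registry, o)
      if (identical(as.character(code$status), status)) {
        return(code)
      }
    }
    stop(sprintf("no '%s' code registered for module '%s'", status, module_id),
      call. = FALSE
    )
  }

  set.seed(spec$seed, kind = "Mersenne-Twister")
  records <- list()
  gt_patient <- character(0)
  gt_module <- character(0)
  gt_date <- as.Date(character(0))
  gt_status <- character(0)
  window_days <- as.integer(spec$start_window[2] - spec$start_window[1])

  for (i in seq_len(spec$n_patients)) {
    pid <- sprintf("P%05d", i)
    patient <- patient_ref(pid)
    for (m in spec$template$modules) {
      start <- spec$start_window[1] +
        as.integer(floor(stats::runif(1) * (window_days + 1L)))
      len <- spec$period_length[1] + as.integer(floor(
        stats::runif(1) * (spec$period_length[2] - spec$period_length[1] + 1L)
      ))
      if (m$module_id %in% spec$insurance_module_ids) {
        cap_end <- seq(start, by = "5 years", length.out = 2L)[2L] - 1L
        end <- min(start + len, cap_end)
      } else {
        end <- start + len
      }
      opted_in <- stats::runif(1) < module_opt_in_prob(spec, m$module_id)
      base_status <- if (opted_in) "valid" else "not valid"
      records[[length(records) + 1L]] <- consent_record(
        patient = patient,
        code = code_for(m$module_id, base_status),
        period = validity_period(start, end),
        recorded_at = as.POSIXct(paste(format(start), "12:00:00"), tz = "UTC"),
        source_dialect = "native"
      )

      withdrawn <- FALSE
      wd_start <- NULL
      if (opted_in && stats::runif(1) < spec$withdrawal_probability) {
        lag <- spec$withdrawal_lag[1] + as.integer(floor(
          stats::runif(1) *
            (spec$withdrawal_lag[2] - spec$withdrawal_lag[1] + 1L)
        ))
        wd_start <- min(start + lag, end) # withdrawal lands inside the period
        withdrawn <- TRUE
        records[[length(records) + 1L]] <- consent_record(
          patient = patient,
          code = code_for(m$module_id, "not valid"),
          period = validity_period(wd_start), # open-ended
          recorded_at = as.POSIXct(paste(format(wd_start), "12:00:00"), tz = "UTC"),
          source_dialect = "native"
        )
      }

      # Expected effective status, derived from the generation decisions
      # themselves (not from the engine): the withdrawal, once started,
      # denies forever; before it, the base decision holds inside its
      # period; outside any period there is no documentation.
      expected_at <- function(d) {
        if (withdrawn && d >= wd_start) {
          "not valid"
        } else if (d >= start && d <= end) {
          base_status
        } else {
          "unknown"
        }
      }
      mid <- start + as.integer(floor(as.integer(end - start) / 2))
      probes <- unique(c(
        start - 1L, start, mid, end, end + 1L,
        if (withdrawn) c(wd_start - 1L, wd_start, end + 30L)
      ))
      for (d in probes) {
        d <- as.Date(d, origin = "1970-01-01")
        gt_patient <- c(gt_patient, pid)
        gt_module <- c(gt_module, m$module_id)
        gt_date <- c(gt_date, d)
        gt_status <- c(gt_status, expected_at(d))
      }
    }
  }

  list(
    records = records,
    ground_truth = data.frame(
      patient = gt_patient,
      module_id = gt_module,
      date = gt_date,
      expected_status = gt_status,
      stringsAsFactors = FALSE
    ),
    registry = registry
  )
}

#' Serialize a generated population to per-patient documents
#'
#' Writes one file per patient: a BPPC CDA document holding all the
#' patient's records as serviceEvents, or — for the FHIR dialects, where a
#' single Consent resource carries a single validity period — a JSON array
#' with one Consent resource per record, in record order. Re-reading the
#' emitted files with [read_consent_documents()] reconstructs the record
#' set exactly (on the core data elements).
#'
#' @param records List of [consent_record()] objects (any mix of patients).
#' @param dialect `"fhir-r4"`, `"fhir-r3"` or `"bppc"`.
#' @param dir Output directory (created if needed).
#' @return Character vector of the files written, invisibly.
#' @export
emit_documents <- function(records, dialect, dir) {
  dialect <- match.arg(dialect, DIALECTS)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (length(records) == 0L) {
    return(invisible(character(0)))
  }
  patients <- vapply(records, function(r) r$patient$identifier_value, character(1))
  written <- character(0)
  for (pid in unique(patients)) {
    mine <- records[patients == pid]
    if (dialect == "bppc") {
      path <- file.path(dir, paste0(pid, ".xml"))
      xml2::write_xml(write_bppc(mine), path)
    } else {
      release <- if (dialect == "fhir-r4") "R4" else "R3"
      resources <- vapply(mine, function(r) {
        as.character(write_fhir_consent(list(r), release = release, pretty = FALSE))
      }, character(1))
      path <- file.path(dir, paste0(pid, ".json"))
      writeLines(paste0("[", paste(resources, collapse = ",\n"), "]"), path)
    }
    written <- c(written, path)
  }
  invisible(written)
}

#' Read back documents emitted by [emit_documents()]
#'
#' @param dir Directory of emitted files.
#' @param dialect The dialect they were emitted in.
#' @param registry A [code_registry()].
#' @return List of [consent_record()] objects in file, then in-file, order.
#' @export
read_consent_documents <- function(dir, dialect, registry) {
  dialect <- match.arg(dialect, DIALECTS)
  ext <- if (dialect == "bppc") "\\.xml$" else "\\.json$"
  files <- sort(list.files(dir, pattern = ext, full.names = TRUE))
  out <- list()
  for (f in files) {
    if (dialect == "bppc") {
      out <- c(out, read_bppc(f, registry))
    } else {
      release <- if (dialect == "fhir-r4") "R4" else "R3"
      parsed <- jsonlite::fromJSON(
        paste(readLines(f, warn = FALSE, encoding = "UTF-8"), collapse = "\n"),
        simplifyVector = FALSE
      )
      resources <- if (!is.null(parsed$resourceType)) list(parsed) else parsed
      for (res in resources) {
        out <- c(out, read_fhir_consent(
          jsonlite::toJSON(res, auto_unbox = TRUE),
          registry,
          release = release
        ))
      }
    }
  }
  out
}
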