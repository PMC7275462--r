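make_record <- function(reg, pid, module, status, start, end = NULL,
                        recorded_at = NULL) {
  vs <- value_set_for(reg, module, "1.6a")
  code <- NULL
  for (o in vs$member_code_oids) {
    c <- registry_lookup(reg, o)
    if (identical(as.character(c$status), status)) code <- c
  }
  consent_record(
    patient = patient_ref(pid),
    code = code,
    period = validity_period(start, end),
    recorded_at = recorded_at
  )
}

test_that("absence of documentation resolves to unknown", {
  store <- consent_store()
  expect_identical(
    as.character(effective_status(store, "nobody", "mdat_collection",
      "2020-01-01", "1.6a"
    )),
    "unknown"
  )
})

test_that("a bounded grant is valid inside its period and unknown after expiry", {
  reg <- new_test_registry()
  store <- consent_store()
  add_records(store, make_record(
    reg, "p1", "mdat_collection", "valid", "2018-10-10", "2023-10-09"
  ))
  expect_identical(
    as.character(effective_status(store, "p1", "mdat_collection", "2020-01-01", "1.6a")),
    "valid"
  )
  # an elapsed end-dated period reads as absence of documentation,
  # not as a documented denial
  expect_identical(
    as.character(effective_status(store, "p1", "mdat_collection", "2023-10-10", "1.6a")),
    "unknown"
  )
  expect_identical(
    as.character(effective_status(store, "p1", "mdat_collection", "2018-10-09", "1.6a")),
    "unknown"
  )
})

test_that("a later withdrawal record overrides the original grant", {
  reg <- new_test_registry()
  store <- consent_store()
  add_records(store, list(
    make_record(reg, "p1", "biomat_collection", "valid", "2018-10-10",
      recorded_at = "2018-10-10 09:00:00"
    ),
    make_record(reg, "p1", "biomat_collection", "not valid", "2020-06-01",
      recorded_at = "2020-06-01 09:00:00"
    )
  ))
  expect_identical(
    as.character(effective_status(store, "p1", "biomat_collection", "2021-01-01", "1.6a")),
    "not valid"
  )
  expect_identical(
    as.character(effective_status(store, "p1", "biomat_collection", "2019-01-01", "1.6a")),
    "valid"
  )
})

test_that("resolution matches the brute-force oracle on randomized stores", {
  reg <- new_test_registry()
  modules <- vapply(mii_template()$modules, `[[`, character(1), "module_id")
  set.seed(977)
  for (rep in 1:40) {
    store <- consent_store()
    records <- list()
    n_pat <- sample(2:4, 1L)
    for (p in seq_len(n_pat)) {
      pid <- paste0("p", p)
      for (k in seq_len(sample(1:6, 1L))) {
        module <- sample(modules, 1L)
        status <- sample(status_labels(), 1L)
        start <- as.Date("2019-01-01") + sample(0:700, 1L)
        end <- if (stats::runif(1) < 0.6) start + sample(0:900, 1L) else NULL
        recorded_at <- if (stats::runif(1) < 0.7) {
          as.POSIXct(paste(format(start), "10:00:00"), tz = "UTC") +
            sample(0:86400, 1L)
        } else {
          NULL
        }
        records[[length(records) + 1L]] <-
          make_record(reg, pid, module, status, start, end, recorded_at)
      }
    }
    add_records(store, records)
    for (q in 1:25) {
      pid <- paste0("p", sample(n_pat, 1L))
      module <- sample(modules, 1L)
      d <- as.Date("2019-01-01") + sample(0:1700, 1L)
      expect_identical(
        as.character(effective_status(store, pid, module, d, "1.6a")),
        oracle_status(records, pid, module, "1.6a", d)
      )
    }
  }
})

test_that("answers are independent of insertion order", {
  reg <- new_test_registry()
  recs <- list(
    make_record(reg, "p1", "mdat_transfer", "valid", "2019-01-01", "2022-01-01",
      recorded_at = "2019-01-01 08:00:00"
    ),
    make_record(reg, "p1", "mdat_transfer", "not valid", "2020-01-01",
      recorded_at = "2020-01-01 08:00:00"
    ),
    make_record(reg, "p1", "mdat_transfer", "valid", "2020-06-01", "2021-06-01",
      recorded_at = "2020-06-01 08:00:00"
    )
  )
  dates <- seq(as.Date("2018-12-01"), as.Date("2022-06-01"), by = "week")
  a <- consent_store()
  add_records(a, recs)
  b <- consent_store()
  add_records(b, rev(recs))
  for (d in as.list(dates)) {
    expect_identical(
      as.character(effective_status(a, "p1", "mdat_transfer", d, "1.6a")),
      as.character(effective_status(b, "p1", "mdat_transfer", d, "1.6a"))
    )
  }
})

test_that("ties break deny-biased when timestamps and starts coincide", {
  reg <- new_test_registry()
  store <- consent_store()
  ts <- "2020-01-01 12:00:00"
  add_records(store, list(
    make_record(reg, "p1", "kkdat_retro", "valid", "2020-01-01", recorded_at = ts),
    make_record(reg, "p1", "kkdat_retro", "not valid", "2020-01-01", recorded_at = ts)
  ))
  expect_identical(
    as.character(effective_status(store, "p1", "kkdat_retro", "2020-06-01", "1.6a")),
    "not valid"
  )
})

test_that("cohorts partition the patient universe", {
  spec <- population_spec(n_patients = 40, seed = 20260915)
  pop <- generate_population(spec)
  store <- consent_store()
  add_records(store, pop$records)
  universe <- store_patients(store)
  for (d in list("2019-06-01", "2021-03-01")) {
    cohorts <- lapply(status_labels(), function(lbl) {
      cohort_query(store, "mdat_collection", d, lbl, "1.6a")
    })
    expect_identical(sort(unlist(cohorts)), universe)
    expect_identical(sum(lengths(cohorts)), length(universe))
  }
})

test_that("opt-in minus withdrawal arithmetic shows up in cohort queries", {
  # 100 patients; 30 opt in on day one; 5 of the 30 later withdraw.
  reg <- new_test_registry()
  store <- consent_store()
  for (i in 1:100) {
    pid <- sprintf("c%03d", i)
    status <- if (i <= 30) "valid" else "not valid"
    add_records(store, make_record(
      reg, pid, "recontact_research", status, "2020-01-01",
      recorded_at = "2020-01-01 09:00:00"
    ))
    if (i <= 5) {
      add_records(store, make_record(
        reg, pid, "recontact_research", "not valid", "2020-07-01",
        recorded_at = "2020-07-01 09:00:00"
      ))
    }
  }
  after <- cohort_query(store, "recontact_research", "2021-01-01", "valid", "1.6a")
  expect_length(after, 25L)
  expect_length(
    cohort_query(store, "recontact_research", "2021-01-01", "not valid", "1.6a"),
    75L
  )
  before <- cohort_query(store, "recontact_research", "2020-03-01", "valid", "1.6a")
  expect_length(before, 30L)
  # empty store
  expect_length(
    cohort_query(consent_store(), "recontact_research", "2021-01-01", "valid", "1.6a"),
    0L
  )
})

test_that("the validator applies the template and five-year-cap rules", {
  reg <- new_test_registry()
  tpl <- mii_template()
  config <- engine_config()

  ok <- make_record(reg, "p1", "kkdat_retro", "valid", "2018-10-10", "2023-10-09")
  expect_true(is_valid_report(validate_record(ok, tpl, config)))

  over <- make_record(reg, "p1", "kkdat_retro", "valid", "2018-10-10", "2024-10-10")
  report <- validate_record(over, tpl, config)
  expect_true("insurance_cap_exceeded" %in% report$rule)

  one_day_over <- make_record(reg, "p1", "kkdat_prosp", "valid", "2018-10-10", "2023-10-10")
  expect_true(
    "insurance_cap_exceeded" %in% validate_record(one_day_over, tpl, config)$rule
  )

  open_grant <- make_record(reg, "p1", "kkdat_retro", "valid", "2018-10-10")
  expect_true(
    "insurance_cap_exceeded" %in% validate_record(open_grant, tpl, config)$rule
  )

  # a withdrawal (documented denial) is not capped
  withdrawal <- make_record(reg, "p1", "kkdat_retro", "not valid", "2019-01-01")
  expect_true(is_valid_report(validate_record(withdrawal, tpl, config)))

  # a non-insurance module may run long
  long <- make_record(reg, "p1", "mdat_collection", "valid", "2018-10-10", "2028-10-10")
  expect_true(is_valid_report(validate_record(long, tpl, config)))

  # module of a different template version
  other_reg <- code_registry()
  other_tpl <- consent_template("2.0", "S", list(consent_module("extra_module", "x", "S")))
  allocate_codes(other_reg, "1.2.9", other_tpl)
  foreign <- consent_record(
    patient = patient_ref("p1"),
    code = registry_lookup(other_reg, "1.2.9.1"),
    period = validity_period("2020-01-01")
  )
  expect_true(
    "template_mismatch" %in% validate_record(foreign, tpl, config)$rule
  )
})
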