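test_that("status labels are a closed three-member set with exact renderings", {
  expect_identical(status_labels(), c("valid", "not valid", "unknown"))
  for (tok in status_labels()) {
    expect_identical(as.character(status_label(tok)), tok)
  }
  expect_identical(as.character(status_label("not_valid")), "not valid")
  expect_error(status_label("pending"), "unknown status label")
  expect_error(status_label("VALID"), "unknown status label")
  expect_error(status_label(c("valid", "valid")), "single string")
})

test_that("OID validation names the offending segment", {
  expect_identical(as.character(oid("1")), "1")
  expect_error(oid("1.a.2"), "segment 2 \\('a'\\)")
  expect_error(oid("1..2"), "segment 2")
  expect_error(oid(""), "non-empty")
  expect_error(oid("1.2."), "segment 3")
  expect_false(is_oid("urn:oid:1.2"))
  expect_true(is_oid("2.16.840.1.113883.3.1937.777.24.5.1"))
})

test_that("OID/URN conversion is exact and invertible", {
  expect_identical(
    oid_to_urn("2.16.840.1.113883.3.1937.777.24.5.1"),
    "urn:oid:2.16.840.1.113883.3.1937.777.24.5.1"
  )
  expect_identical(oid_to_urn("1"), "urn:oid:1")
  expect_identical(
    as.character(urn_to_oid("urn:oid:2.16.840.1.113883.3.1937.777.24.5.1")),
    "2.16.840.1.113883.3.1937.777.24.5.1"
  )
  expect_error(urn_to_oid("urn:isbn:123"), "scheme")
  expect_error(urn_to_oid("urn:oid:1.a.2"), "segment")

  set.seed(42)
  for (i in 1:1000) {
    x <- random_oid_string()
    expect_identical(as.character(urn_to_oid(oid_to_urn(x))), x)
  }
})

test_that("parent/child OID relation is a single-integer prefix extension", {
  parent <- oid("1.2.3")
  expect_identical(as.character(oid_child(parent, 7)), "1.2.3.7")
  expect_true(oid_is_child("1.2.3.7", parent))
  expect_false(oid_is_child("1.2.3.7.1", parent)) # grandchild, not child
  expect_false(oid_is_child("1.2.4", parent))
  expect_error(oid_child(parent, -1), "non-negative")
})

test_that("validity period containment matches a brute-force date scan", {
  set.seed(11)
  window <- seq(as.Date("2014-01-01"), as.Date("2023-12-31"), by = "day")
  for (i in 1:15) {
    start <- sample(window, 1L)
    end <- if (i %% 3 == 0L) NULL else start + sample(0:2500, 1L)
    p <- validity_period(start, end)
    probe <- sort(sample(window, 80L))
    expected <- probe >= start & (is.null(end) | probe <= (end %||% max(window)))
    got <- vapply(probe, function(d) period_contains(p, d), logical(1))
    expect_identical(got, expected)
  }
  # inclusive on both closed endpoints
  p <- validity_period("2018-10-10", "2023-10-09")
  expect_true(period_contains(p, "2018-10-10"))
  expect_true(period_contains(p, "2023-10-09"))
  expect_false(period_contains(p, "2018-10-09"))
  expect_false(period_contains(p, "2023-10-10"))
})

test_that("validity periods require a start and an ordered end", {
  expect_error(validity_period(NULL), "required")
  expect_error(validity_period("2020-01-10", "2020-01-09"), "precedes")
  expect_silent(validity_period("2020-01-10", "2020-01-10"))
  expect_error(validity_period("not-a-date"), "YYYY-MM-DD")
})

test_that("consent records cannot be built without the mandatory elements", {
  reg <- new_test_registry()
  code <- registry_lookup(reg, "2.16.840.1.113883.3.1937.777.24.5.1.1")
  patient <- patient_ref("p1")
  period <- validity_period("2020-01-01")
  expect_s3_class(consent_record(patient, code, period), "consent_record")

  # randomized partial inputs: dropping any mandatory element fails
  parts <- list(patient = patient, code = code, period = period)
  set.seed(3)
  for (i in 1:20) {
    drop <- sample(names(parts), sample(1:3, 1L))
    args <- parts
    for (d in drop) args[[d]] <- switch(d,
      patient = "p1", # wrong type, not a patient_ref
      code = NULL,
      period = NULL
    )
    expect_error(do.call(consent_record, args))
  }
  expect_error(patient_ref(""), "non-empty")
})

test_that("policies tie template versions to consent modules only", {
  expect_error(policy("m1", "consent_module"), "template_version")
  expect_error(
    policy("bavarian_hospital_act", "regulatory", template_version = "1.6a"),
    "may not"
  )
  p <- policy("bavarian_hospital_act", "regulatory",
    description = "intramural research on clinical routine data"
  )
  expect_identical(p$kind, "regulatory")
})

test_that("template loading enforces structure and file order", {
  tpl <- load_template(mii_template_path())
  expect_length(tpl$sections, 4L)
  expect_length(tpl$modules, 8L)
  expect_identical(tpl$template_version, "1.6a")
  for (m in tpl$modules) {
    expect_true(all(c("Yes", "No") %in% m$opt_in_choices))
    expect_true(m$section_name %in% tpl$sections)
  }
  expect_identical(tpl$modules[[1]]$module_id, "mdat_collection")

  # single-section single-module definition
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "version: \"0.1\"",
    "sections:",
    "  - \"Use of clinical routine data\"",
    "modules:",
    "  - id: m1",
    "    section: \"Use of clinical routine data\"",
    "    statement: \"I consent to the use of my clinical routine data.\""
  ), f)
  one <- load_template(f)
  expect_identical(one$modules[[1]]$opt_in_choices, c("Yes", "No"))

  # degenerate: no sections
  g <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("version: \"0.1\"", "sections: []", "modules: []"), g)
  expect_error(load_template(g), "no sections")

  # module without a Yes/No pair
  h <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "version: \"0.1\"",
    "sections: [\"S\"]",
    "modules:",
    "  - id: broken",
    "    section: \"S\"",
    "    statement: \"x\"",
    "    opt_in_choices: [\"Maybe\"]"
  ), h)
  expect_error(load_template(h), "broken")
})
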