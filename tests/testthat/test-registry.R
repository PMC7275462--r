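test_that("allocation yields three consecutive child codes per module", {
  reg <- code_registry()
  tpl <- consent_template(
    template_version = "t1",
    sections = "Permission to re-contact",
    modules = list(consent_module(
      "recontact_research",
      "I consent to being contacted about further research projects.",
      "Permission to re-contact"
    ))
  )
  codes <- allocate_codes(reg, "2.16.840.1.113883.3.1937.777.24.5.1", tpl)
  expect_identical(
    vapply(codes, function(c) as.character(c$code_oid), character(1)),
    paste0("2.16.840.1.113883.3.1937.777.24.5.1.", 1:3)
  )
  expect_identical(
    vapply(codes, function(c) as.character(c$status), character(1)),
    c("valid", "not valid", "unknown")
  )
  # re-allocation of the same (template_version, module_id) conflicts
  expect_error(
    allocate_codes(reg, "2.16.840.1.113883.3.1937.777.24.5.1", tpl),
    "already registered"
  )
})

test_that("full template allocation covers 8 modules x 3 labels, gapless", {
  reg <- code_registry()
  codes <- allocate_codes(reg, mii_consent_system_oid(), mii_template())
  expect_length(codes, 24L)
  expect_length(reg$value_sets, 8L)
  suffixes <- vapply(codes, function(c) {
    as.integer(sub(".*\\.", "", as.character(c$code_oid)))
  }, integer(1))
  expect_identical(suffixes, 1:24) # consecutive, no gaps, allocation order
  # bijection (policy, status) <-> code_oid, exhaustively both ways
  keys <- vapply(codes, function(c) {
    paste(c$policy$policy_id, c$policy$template_version, as.character(c$status))
  }, character(1))
  expect_false(anyDuplicated(keys) > 0)
  oids <- vapply(codes, function(c) as.character(c$code_oid), character(1))
  expect_false(anyDuplicated(oids) > 0)
  for (i in seq_along(codes)) {
    expect_identical(
      as.character(registry_lookup(reg, oids[i])$code_oid), oids[i]
    )
    expect_true(oid_is_child(oids[i], mii_consent_system_oid()))
  }
})

test_that("allocation stays gapless and bijective over random sequences", {
  set.seed(91)
  for (rep in 1:5) {
    reg <- code_registry()
    n_templates <- sample(1:3, 1L)
    expected_total <- 0L
    for (t in seq_len(n_templates)) {
      n_mod <- sample(1:5, 1L)
      tpl <- consent_template(
        template_version = paste0("v", t),
        sections = "S",
        modules = lapply(seq_len(n_mod), function(i) {
          consent_module(paste0("m", i), "stmt", "S")
        })
      )
      allocate_codes(reg, "1.2.3", tpl)
      expected_total <- expected_total + 3L * n_mod
    }
    suffixes <- sort(as.integer(sub(
      ".*\\.", "", names(reg$codes)
    )))
    expect_identical(suffixes, seq_len(expected_total))
  }
})

test_that("empty template allocates nothing", {
  reg <- code_registry()
  tpl <- consent_template("e1", sections = "S", modules = list())
  expect_length(allocate_codes(reg, "1.2.3", tpl), 0L)
  expect_length(reg$value_sets, 0L)
})

test_that("lookup resolves bare OIDs, URNs and RetrieveCode URIs alike", {
  reg <- new_test_registry()
  bare <- "2.16.840.1.113883.3.1937.777.24.5.1.1"
  uri <- paste0(
    "http://art-decor.org/decor/services/RetrieveCode?code=", bare,
    "&codeSystem=2.16.840.1.113883.3.1937.777.24.5.1"
  )
  via_bare <- registry_lookup(reg, bare)
  via_urn <- registry_lookup(reg, paste0("urn:oid:", bare))
  via_uri <- registry_lookup(reg, uri)
  expect_identical(via_bare, via_urn)
  expect_identical(via_bare, via_uri)
  expect_identical(as.character(via_bare$status), "valid")
  expect_identical(via_bare$policy$policy_id, "mdat_collection")
  expect_identical(via_bare$policy$template_version, "1.6a")

  err <- tryCatch(registry_lookup(reg, "9.9.9.9"), error = identity)
  expect_s3_class(err, "miiconsent_not_found")
  expect_identical(err$queried, "9.9.9.9")
})

test_that("value sets hold exactly the three codes of their policy", {
  reg <- new_test_registry()
  vs <- value_set_for(reg, "recontact_research", "1.6a")
  expect_length(vs$member_code_oids, 3L)
  statuses <- vapply(vs$member_code_oids, function(o) {
    as.character(registry_lookup(reg, o)$status)
  }, character(1))
  expect_setequal(unname(statuses), status_labels())
  expect_match(vs$description, "1.6a", fixed = TRUE)

  other <- value_set_for(reg, "mdat_collection", "1.6a")
  expect_length(intersect(vs$member_code_oids, other$member_code_oids), 0L)

  expect_s3_class(
    tryCatch(value_set_for(reg, "nonexistent", "1.6a"), error = identity),
    "miiconsent_not_found"
  )
})

test_that("regulatory policies are allocated under the sibling system", {
  reg <- new_test_registry()
  pol <- policy("bavarian_hospital_act", "regulatory",
    description = "hospital physicians may use routine data for intramural research"
  )
  codes <- allocate_policy_codes(reg, mii_regulatory_system_oid(), pol)
  expect_length(codes, 3L)
  for (c in codes) {
    expect_true(oid_is_child(c$code_oid, mii_regulatory_system_oid()))
    expect_null(c$policy$template_version)
  }
  vs <- value_set_for(reg, "bavarian_hospital_act")
  expect_length(vs$member_code_oids, 3L)
})

test_that("registry export/import round-trip preserves observable content", {
  reg <- new_test_registry()
  allocate_policy_codes(
    reg, mii_regulatory_system_oid(),
    policy("state_law", "regulatory", description = "a regulatory permission")
  )
  f <- withr::local_tempfile(fileext = ".yaml")
  export_registry(reg, f)
  reg2 <- import_registry(f)
  expect_identical(
    miiconsent:::registry_content(reg2),
    miiconsent:::registry_content(reg)
  )

  # empty registry round-trips cleanly
  g <- withr::local_tempfile(fileext = ".yaml")
  export_registry(code_registry(), g)
  empty <- import_registry(g)
  expect_length(empty$codes, 0L)

  # duplicate code OIDs are rejected on import
  h <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "code_systems:",
    "- oid: 1.2.3",
    "  name: dup",
    "  codes:",
    "  - oid: 1.2.3.1",
    "    policy_id: m1",
    "    kind: regulatory",
    "    status: valid",
    "  - oid: 1.2.3.1",
    "    policy_id: m2",
    "    kind: regulatory",
    "    status: valid",
    "value_sets: []"
  ), h)
  expect_error(import_registry(h), "duplicate code OID")
})
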