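#' The OID of the consent code system
#'
#' Root code-system OID under which policy-status codes for the bundled
#' broad-consent template are allocated as consecutive children.
#'
#' @return An [oid()].
#' @export
mii_consent_system_oid <- function() {
  oid("2.16.840.1.113883.3.1937.777.24.5.1")
}

#' The OID of the sibling code system for regulatory policies
#'
#' Regulatory (non-consent) data-use policies are allocated under a sibling
#' code system rather than mixed into the consent template's system.
#'
#' @return An [oid()].
#' @export
mii_regulatory_system_oid <- function() {
  oid("2.16.840.1.113883.3.1937.777.24.5.2")
}

#' Create an empty code registry
#'
#' The registry plays the role of a terminology server such as ART-DECOR:
#' it owns code systems, allocates consecutive policy-status codes under
#' their OIDs, and serves value sets. A registry is a mutable store;
#' allocation functions modify it in place.
#'
#' @return An object of class `code_registry`.
#' @export
code_registry <- function() {
  reg <- new.env(parent = emptyenv())
  reg$systems <- list() # by system OID: list(oid, name, next_child_index, policies)
  reg$codes <- list() # by code OID: policy_status_code
  reg$value_sets <- list() # by policy key: list(valueset_id, description, member_code_oids, ...)
  class(reg) <- "code_registry"
  reg
}

#' @export
print.code_registry <- function(x, ...) {
  cat(sprintf(
    "<code_registry> %d code system(s), %d code(s), %d value set(s)\n",
    length(x$systems), length(x$codes), length(x$value_sets)
  ))
  invisible(x)
}

#' Register a code system
#'
#' @param registry A [code_registry()].
#' @param system_oid The code system's [oid()].
#' @param name Human-readable name.
#' @return The registry, invisibly.
#' @export
add_code_system <- function(registry, system_oid, name = "") {
  stopifnot(inherits(registry, "code_registry"))
  key <- as.character(oid(system_oid))
  if (!is.null(registry$systems[[key]])) {
    stop(sprintf("code system %s is already registered", key), call. = FALSE)
  }
  registry$systems[[key]] <- list(
    system_oid = oid(system_oid),
    name = name,
    next_child_index = 1L,
    policies = character(0)
  )
  invisible(registry)
}

# Allocate the three codes (valid, not valid, unknown — in this fixed order)
# for one policy under `system_oid`, with consecutive child indices, and
# create the policy's value set. Internal workhorse for allocate_codes().
allocate_one_policy <- function(registry, system_key, pol, display_stem) {
  sys <- registry$systems[[system_key]]
  pkey <- policy_key(pol$policy_id, pol$template_version)
  if (pkey %in% sys$policies) {
    stop(sprintf(
      "policy '%s' is already registered in code system %s",
      pkey, system_key
    ), call. = FALSE)
  }
  codes <- vector("list", length(STATUS_LABELS))
  for (i in seq_along(STATUS_LABELS)) {
    child <- oid_child(sys$system_oid, sys$next_child_index)
    sys$next_child_index <- sys$next_child_index + 1L
    code <- policy_status_code(
      code_oid = child,
      code_system_oid = sys$system_oid,
      policy = pol,
      status = STATUS_LABELS[i],
      display = sprintf("%s - %s", display_stem, STATUS_LABELS[i])
    )
    registry$codes[[as.character(child)]] <- code
    codes[[i]] <- code
  }
  sys$policies <- c(sys$policies, pkey)
  registry$systems[[system_key]] <- sys
  vs_desc <- if (is.null(pol$template_version)) {
    sprintf("Status codes for policy '%s'", pol$policy_id)
  } else {
    sprintf(
      "Status codes for module '%s' of consent template version %s",
      pol$policy_id, pol$template_version
    )
  }
  registry$value_sets[[pkey]] <- list(
    valueset_id = paste0("vs-", gsub("[^A-Za-z0-9]+", "-", pkey)),
    policy_id = pol$policy_id,
    template_version = pol$template_version,
    description = vs_desc,
    member_code_oids = vapply(
      codes, function(c) as.character(c$code_oid), character(1)
    )
  )
  codes
}

#' Allocate policy-status codes for every module of a template
#'
#' For each module, one code per status label is created (three codes, in
#' the fixed label order valid, not valid, unknown) with consecutive
#' integer suffixes under the code system's OID, modules in template order.
#' A value set combining the three codes of each module is created
#' alongside; its description carries the template version.
#'
#' @param registry A [code_registry()].
#' @param system_oid OID of a registered code system (registered on the fly
#'   when absent).
#' @param template A [consent_template()] whose modules are not yet
#'   registered in this system.
#' @return List of the newly allocated [policy_status_code()] objects, in
#'   allocation order.
#' @export
allocate_codes <- function(registry, system_oid, template) {
  stopifnot(
    inherits(registry, "code_registry"),
    inherits(template, "consent_template")
  )
  key <- as.character(oid(system_oid))
  if (is.null(registry$systems[[key]])) {
    add_code_system(registry, system_oid,
      name = sprintf("Consent status codes (template %s)", template$template_version)
    )
  }
  out <- list()
  for (m in template$modules) {
    pol <- policy(
      policy_id = m$module_id,
      kind = "consent_module",
      template_version = template$template_version,
      description = m$statement_text
    )
    stem <- sprintf("%s [%s]", m$module_id, template$template_version)
    out <- c(out, allocate_one_policy(registry, key, pol, stem))
  }
  out
}

#' Allocate status codes for a single (e.g. regulatory) policy
#'
#' Statements from regulatory frameworks are combined with status codes in
#' the same way as consent-template modules; by convention they live under
#' their own code system (see [mii_regulatory_system_oid()]).
#'
#' @param registry A [code_registry()].
#' @param system_oid OID of the owning code system.
#' @param pol A [policy()].
#' @return List of the three allocated [policy_status_code()] objects.
#' @export
allocate_policy_codes <- function(registry, system_oid, pol) {
  stopifnot(inherits(registry, "code_registry"), inherits(pol, "consent_policy"))
  key <- as.character(oid(system_oid))
  if (is.null(registry$systems[[key]])) {
    add_code_system(registry, system_oid, name = "Policy status codes")
  }
  allocate_one_policy(registry, key, pol, pol$policy_id)
}

#' Look up a registered policy-status code
#'
#' Accepts a code reference in any of the three spellings used across the
#' supported standards: a bare OID, a `urn:oid:` URN, or a RetrieveCode-style
#' URI with `code` and `codeSystem` query parameters.
#'
#' @param registry A [code_registry()].
#' @param ref Code reference string.
#' @return The registered [policy_status_code()]; unresolvable references
#'   raise an error of class `miiconsent_not_found` carrying the queried
#'   identifier.
#' @export
registry_lookup <- function(registry, ref) {
  stopifnot(inherits(registry, "code_registry"))
  parsed <- parse_code_ref(ref)
  key <- as.character(parsed$code)
  code <- registry$codes[[key]]
  if (is.null(code)) {
    stop(structure(
      class = c("miiconsent_not_found", "error", "condition"),
      list(
        message = sprintf("no code registered for identifier '%s'", key),
        call = NULL, queried = key
      )
    ))
  }
  if (!is.null(parsed$system) &&
    !identical(as.character(parsed$system), as.character(code$code_system_oid))) {
    stop(sprintf(
      "code %s belongs to system %s, not %s",
      key, as.character(code$code_system_oid), as.character(parsed$system)
    ), call. = FALSE)
  }
  code
}

#' Test whether a code reference resolves in the registry
#'
#' @inheritParams registry_lookup
#' @return `TRUE` or `FALSE`.
#' @export
registry_has <- function(registry, ref) {
  parsed <- tryCatch(parse_code_ref(ref), error = function(e) NULL)
  !is.null(parsed) && !is.null(registry$codes[[as.character(parsed$code)]])
}

#' Retrieve the value set of a policy
#'
#' The value set combines exactly the three status codes registered for one
#' policy; its description carries the template version where applicable.
#'
#' @param registry A [code_registry()].
#' @param policy_id Policy (module) id.
#' @param template_version Template version for consent-module policies;
#'   `NULL` for regulatory policies.
#' @return A list with elements `valueset_id`, `policy_id`,
#'   `template_version`, `description` and `member_code_oids`.
#' @export
value_set_for <- function(registry, policy_id, template_version = NULL) {
  stopifnot(inherits(registry, "code_registry"))
  pkey <- policy_key(policy_id, template_version)
  vs <- registry$value_sets[[pkey]]
  if (is.null(vs)) {
    stop(structure(
      class = c("miiconsent_not_found", "error", "condition"),
      list(
        message = sprintf("no value set registered for policy '%s'", pkey),
        call = NULL, queried = pkey
      )
    ))
  }
  vs
}

#' Export a registry to a definition file
#'
#' Writes a YAML document listing every code system with its codes and
#' every value set. [import_registry()] reads the format back; the
#' round-trip preserves all observable registry content.
#'
#' @param registry A [code_registry()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_registry <- function(registry, path) {
  stopifnot(inherits(registry, "code_registry"))
  systems <- lapply(unname(registry$systems), function(sys) {
    member_keys <- names(registry$codes)[vapply(
      registry$codes,
      function(c) identical(as.character(c$code_system_oid), as.character(sys$system_oid)),
      logical(1)
    )]
    codes <- lapply(member_keys, function(k) {
      code <- registry$codes[[k]]
      entry <- list(
        oid = as.character(code$code_oid),
        policy_id = code$policy$policy_id,
        kind = code$policy$kind,
        status = as.character(code$status),
        display = code$display
      )
      if (!is.null(code$policy$template_version)) {
        entry$template_version <- code$policy$template_version
      }
      if (nzchar(code$policy$description)) {
        entry$description <- code$policy$description
      }
      entry
    })
    list(
      oid = as.character(sys$system_oid),
      name = sys$name,
      next_child_index = sys$next_child_index,
      codes = codes
    )
  })
  value_sets <- lapply(unname(registry$value_sets), function(vs) {
    entry <- list(
      id = vs$valueset_id,
      policy_id = vs$policy_id,
      description = vs$description,
      members = as.list(vs$member_code_oids)
    )
    if (!is.null(vs$template_version)) {
      entry$template_version <- vs$template_version
    }
    entry
  })
  yaml::write_yaml(
    list(code_systems = systems, value_sets = value_sets),
    path
  )
  invisible(path)
}

#' Import a registry from a definition file
#'
#' @param path Path to a file written by [export_registry()] (or following
#'   the same schema).
#' @return A [code_registry()].
#' @export
import_registry <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("registry definition not found: '%s'", path), call. = FALSE)
  }
  def <- yaml::read_yaml(path)
  reg <- code_registry()
  for (sys in def$code_systems) {
    add_code_system(reg, sys$oid, name = sys$name %||% "")
    skey <- as.character(oid(sys$oid))
    for (code in sys$codes) {
      ckey <- as.character(oid(code$oid))
      if (!is.null(reg$codes[[ckey]])) {
        stop(sprintf(
          "duplicate code OID %s in registry definition", ckey
        ), call. = FALSE)
      }
      pol <- policy(
        policy_id = code$policy_id,
        kind = code$kind %||% "consent_module",
        template_version = code$template_version,
        description = code$description %||% ""
      )
      reg$codes[[ckey]] <- policy_status_code(
        code_oid = ckey,
        code_system_oid = skey,
        policy = pol,
        status = code$status,
        display = code$display %||% ""
      )
      pkey <- policy_key(pol$policy_id, pol$template_version)
      sysrec <- reg$systems[[skey]]
      if (!pkey %in% sysrec$policies) {
        sysrec$policies <- c(sysrec$policies, pkey)
      }
      reg$systems[[skey]] <- sysrec
    }
    if (!is.null(sys$next_child_index)) {
      sysrec <- reg$systems[[skey]]
      sysrec$next_child_index <- as.integer(sys$next_child_index)
      reg$systems[[skey]] <- sysrec
    }
  }
  for (vs in def$value_sets) {
    members <- unlist(vs$members)
    for (m in members) {
      if (is.null(reg$codes[[as.character(oid(m))]])) {
        stop(sprintf(
          "value set '%s' references unregistered code %s", vs$id, m
        ), call. = FALSE)
      }
    }
    pkey <- policy_key(vs$policy_id, vs$template_version)
    reg$value_sets[[pkey]] <- list(
      valueset_id = vs$id,
      policy_id = vs$policy_id,
      template_version = vs$template_version,
      description = vs$description %||% "",
      member_code_oids = as.character(members)
    )
  }
  reg
}

# Observable registry content as a plain, ordered list — the structural
# equality oracle used by import/export round-trip tests.
registry_content <- function(registry) {
  sys_keys <- sort(names(registry$systems))
  code_keys <- sort(names(registry$codes))
  vs_keys <- sort(names(registry$value_sets))
  list(
    systems = lapply(sys_keys, function(k) {
      s <- registry$systems[[k]]
      list(
        oid = as.character(s$system_oid), name = s$name,
        next_child_index = as.integer(s$next_child_index),
        policies = sort(s$policies)
      )
    }),
    codes = lapply(code_keys, function(k) {
      c <- registry$codes[[k]]
      list(
        oid = as.character(c$code_oid),
        system = as.character(c$code_system_oid),
        policy_id = c$policy$policy_id,
        kind = c$policy$kind,
        template_version = c$policy$template_version,
        status = as.character(c$status),
        display = c$display
      )
    }),
    value_sets = lapply(vs_keys, function(k) {
      v <- registry$value_sets[[k]]
      list(
        id = v$valueset_id, policy_id = v$policy_id,
        template_version = v$template_version,
        description = v$description,
        members = as.character(v$member_code_oids)
      )
    })
  )
}

#' The default registry for the bundled broad-consent template
#'
#' Builds a fresh registry containing the consent code system with all 24
#' policy-status codes (8 modules x 3 labels) of template version 1.6a,
#' allocated consecutively in template order.
#'
#' @return A [code_registry()].
#' @export
mii_default_registry <- function() {
  reg <- code_registry()
  allocate_codes(reg, mii_consent_system_oid(), mii_template())
  reg
}
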