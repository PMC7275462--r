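#' Object identifiers (OIDs)
#'
#' An OID names a node in a hierarchically structured namespace with the
#' shape of a tree: a series of non-negative integers separated by dots,
#' corresponding to the path from the root to the node. Code systems and the
#' codes within them are addressed by OIDs; the URN form `urn:oid:<oid>` is
#' an equivalent spelling used where internet resource identifiers are
#' expected (e.g. the `policy` attribute of a FHIR Consent resource).
#'
#' @param value A single character string, e.g.
#'   `"2.16.840.1.113883.3.1937.777.24.5.1"`.
#' @return An object of class `oid` (a validated character scalar).
#' @examples
#' oid("2.16.840.1.113883.3.1937.777.24.5.1")
#' @export
oid <- function(value) {
  if (inherits(value, "oid")) {
    return(value)
  }
  if (!is.character(value) || length(value) != 1L || is.na(value) || !nzchar(value)) {
    stop("OID must be a single non-empty string", call. = FALSE)
  }
  segments <- strsplit(value, ".", fixed = TRUE)[[1L]]
  if (endsWith(value, ".")) {
    segments <- c(segments, "") # strsplit drops a trailing empty segment
  }
  if (length(segments) == 0L) {
    stop("OID must contain at least one integer segment", call. = FALSE)
  }
  bad <- which(!grepl("^[0-9]+$", segments))
  if (length(bad) > 0L) {
    stop(sprintf(
      "invalid OID '%s': segment %d ('%s') is not a non-negative integer",
      value, bad[1L], segments[bad[1L]]
    ), call. = FALSE)
  }
  structure(value, class = "oid")
}

#' @export
print.oid <- function(x, ...) {
  cat("<oid> ", unclass(x), "\n", sep = "")
  invisible(x)
}

#' @export
format.oid <- function(x, ...) unclass(x)

#' @export
as.character.oid <- function(x, ...) unclass(x)

#' Test whether a string is a well-formed OID
#'
#' @param value A character scalar.
#' @return `TRUE` or `FALSE`.
#' @export
is_oid <- function(value) {
  is.character(value) && length(value) == 1L && !is.na(value) &&
    grepl("^[0-9]+(\\.[0-9]+)*$", value)
}

#' Derive a child OID
#'
#' A child OID equals the parent OID plus `"."` plus a non-negative integer;
#' this prefix relation is what makes consecutive code allocation under a
#' code-system OID well defined.
#'
#' @param parent Parent [oid()].
#' @param index Non-negative integer suffix.
#' @return The child `oid`.
#' @export
oid_child <- function(parent, index) {
  parent <- oid(parent)
  index <- as.integer(index)
  if (is.na(index) || index < 0L) {
    stop("child index must be a non-negative integer", call. = FALSE)
  }
  oid(paste0(as.character(parent), ".", index))
}

#' Test the parent/child prefix relation between two OIDs
#'
#' @param child,parent OIDs (or strings).
#' @return `TRUE` iff `child` equals `parent` plus one dot-separated integer.
#' @export
oid_is_child <- function(child, parent) {
  child <- as.character(oid(child))
  parent <- as.character(oid(parent))
  grepl(paste0("^", gsub(".", "\\.", parent, fixed = TRUE), "\\.[0-9]+$"), child)
}

#' Convert an OID to its URN form
#'
#' @param x An [oid()] or OID string.
#' @return The string `"urn:oid:<oid>"`. [urn_to_oid()] is its exact inverse.
#' @examples
#' oid_to_urn("2.16.840.1.113883.3.1937.777.24.5.1")
#' @export
oid_to_urn <- function(x) {
  paste0("urn:oid:", as.character(oid(x)))
}

#' Convert a `urn:oid:` URN back to an OID
#'
#' @param urn A string beginning with `"urn:oid:"`.
#' @return The validated [oid()] suffix.
#' @examples
#' urn_to_oid("urn:oid:2.16.840.1.113883.3.1937.777.24.5.1")
#' @export
urn_to_oid <- function(urn) {
  if (!is.character(urn) || length(urn) != 1L || is.na(urn)) {
    stop("URN must be a single string", call. = FALSE)
  }
  if (!startsWith(urn, "urn:oid:")) {
    stop(sprintf("not an OID URN (expected scheme 'urn:oid:'): '%s'", urn),
      call. = FALSE
    )
  }
  oid(substring(urn, nchar("urn:oid:") + 1L))
}

# Parse any of the three accepted spellings of a code reference:
# a bare OID, a urn:oid URN, or a RetrieveCode-style URI with query
# parameters `code` and `codeSystem`. Returns list(code =, system = or NULL).
parse_code_ref <- function(ref) {
  if (!is.character(ref) || length(ref) != 1L || is.na(ref) || !nzchar(ref)) {
    stop("code reference must be a single non-empty string", call. = FALSE)
  }
  if (startsWith(ref, "urn:oid:")) {
    return(list(code = urn_to_oid(ref), system = NULL))
  }
  if (grepl("^[0-9.]+$", ref)) {
    return(list(code = oid(ref), system = NULL))
  }
  if (grepl("^https?://", ref) && grepl("?", ref, fixed = TRUE)) {
    query <- sub("^[^?]*\\?", "", ref)
    pairs <- strsplit(strsplit(query, "&", fixed = TRUE)[[1L]], "=", fixed = TRUE)
    params <- stats::setNames(
      vapply(pairs, function(p) utils::URLdecode(p[2L]), character(1)),
      vapply(pairs, `[`, character(1), 1L)
    )
    if (!"code" %in% names(params)) {
      stop(sprintf("code reference URI lacks a 'code' parameter: '%s'", ref),
        call. = FALSE
      )
    }
    system <- if ("codeSystem" %in% names(params)) oid(params[["codeSystem"]]) else NULL
    return(list(code = oid(params[["code"]]), system = system))
  }
  stop(sprintf("unrecognized code reference: '%s'", ref), call. = FALSE)
}

# RetrieveCode-style URI spelling used when writing FHIR policy references.
retrieve_code_uri <- function(code_oid, system_oid,
                              base = "http://art-decor.org/decor/services/RetrieveCode") {
  paste0(
    base, "?code=", as.character(oid(code_oid)),
    "&codeSystem=", as.character(oid(system_oid))
  )
}
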