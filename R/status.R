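#' Consent status labels
#'
#' The interoperability layer reduces the many states that consent-management
#' systems track to exactly three labels: `"valid"`, `"not valid"` and
#' `"unknown"`. A label indicates whether the permissions or restrictions
#' resulting from a referenced policy are in effect. `"unknown"` is reserved
#' for absence of documentation, never used as a fallback for vocabulary the
#' mappers do not recognize.
#'
#' @param x A label token. The canonical renderings `"valid"`, `"not valid"`
#'   and `"unknown"` are accepted, as is the underscore spelling
#'   `"not_valid"`.
#' @return A character scalar of class `status_label`, rendered exactly as
#'   one of the three canonical strings.
#' @examples
#' status_label("valid")
#' status_label("not_valid") # canonicalized to "not valid"
#' @export
status_label <- function(x) {
  if (inherits(x, "status_label")) {
    return(x)
  }
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    stop("status label must be a single string", call. = FALSE)
  }
  canonical <- if (identical(x, "not_valid")) "not valid" else x
  if (!canonical %in% STATUS_LABELS) {
    stop(sprintf(
      "unknown status label '%s' (must be one of: %s)",
      x, paste(sQuote(STATUS_LABELS), collapse = ", ")
    ), call. = FALSE)
  }
  structure(canonical, class = "status_label")
}

#' @export
print.status_label <- function(x, ...) {
  cat("<status> ", unclass(x), "\n", sep = "")
  invisible(x)
}

#' @export
format.status_label <- function(x, ...) unclass(x)

#' @export
as.character.status_label <- function(x, ...) unclass(x)

#' The three status labels
#'
#' @return Character vector `c("valid", "not valid", "unknown")`, in the
#'   order used for code allocation.
#' @export
status_labels <- function() STATUS_LABELS

STATUS_LABELS <- c("valid", "not valid", "unknown")

# Deny-biased ordering used as the final tie-break when resolving the
# effective status: a documented denial outranks missing documentation,
# which outranks a grant.
DENY_ORDER <- c("not valid" = 1L, "unknown" = 2L, "valid" = 3L)
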