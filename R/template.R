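#' Load a consent template from a definition file
#'
#' Template definitions are YAML documents with the keys `version`,
#' optionally `name`, `sections` (ordered list of section names) and
#' `modules` (ordered list; each entry has `id`, `section`, `statement` and
#' optionally `opt_in_choices`, defaulting to Yes/No). Sections and modules
#' are kept in file order.
#'
#' @param path Path to the YAML template definition.
#' @return A [consent_template()].
#' @examples
#' tpl <- load_template(mii_template_path())
#' tpl$template_version
#' @export
load_template <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("template definition not found: '%s'", path), call. = FALSE)
  }
  def <- yaml::read_yaml(path)
  if (is.null(def$version)) {
    stop("template definition lacks a 'version' string", call. = FALSE)
  }
  if (length(def$sections) == 0L) {
    stop("template definition declares no sections", call. = FALSE)
  }
  modules <- lapply(def$modules, function(m) {
    if (is.null(m$id)) {
      stop("template module lacks an 'id'", call. = FALSE)
    }
    choices <- m$opt_in_choices
    if (is.null(choices)) {
      choices <- c("Yes", "No")
    }
    # YAML 1.1 implicit typing can turn unquoted Yes/No into logicals.
    choices <- vapply(choices, function(ch) {
      if (isTRUE(ch)) "Yes" else if (isFALSE(ch)) "No" else as.character(ch)
    }, character(1), USE.NAMES = FALSE)
    if (!all(c("Yes", "No") %in% choices)) {
      stop(sprintf(
        "module '%s': opt-in choices must include 'Yes' and 'No'", m$id
      ), call. = FALSE)
    }
    consent_module(
      module_id = as.character(m$id),
      statement_text = as.character(m$statement %||% ""),
      section_name = as.character(m$section),
      opt_in_choices = choices
    )
  })
  consent_template(
    template_version = as.character(def$version),
    sections = unlist(def$sections),
    modules = modules,
    name = def$name
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Path to the bundled broad-consent template definition (version 1.6a)
#'
#' The bundled template mirrors the structure of the MII broad-consent
#' document in version 1.6a: four sections (use of clinical routine data,
#' use of health insurance data, use of leftover or add-on biosamples,
#' permission to re-contact) with a total of eight opt-in statements.
#'
#' @return File path of the YAML definition shipped with the package.
#' @export
mii_template_path <- function() {
  system.file("extdata", "mii-broad-consent-1.6a.yaml",
    package = "miiconsent", mustWork = TRUE
  )
}

#' The bundled broad-consent template, loaded
#'
#' @return A [consent_template()] with 4 sections and 8 modules.
#' @export
mii_template <- function() {
  load_template(mii_template_path())
}

#' Module ids subject to the five-year health-insurance cap
#'
#' The broad-consent template asks for consent to the use of health
#' insurance data for a maximum of five years; records for these modules
#' must not span longer validity periods.
#'
#' @return Character vector of module ids in the bundled template.
#' @export
mii_insurance_modules <- function() {
  c("kkdat_retro", "kkdat_prosp")
}
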