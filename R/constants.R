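#' Supported potentially toxic elements
#'
#' The eleven metals and metalloids the package models in surface soil:
#' Al, As, Cd, Co, Cr, Cu, Fe, Mn, Ni, Pb, Zn.
#'
#' @return Character vector of element symbols.
#' @export
#' @examples
#' pte_elements()
pte_elements <- function() {
  c("Al", "As", "Cd", "Co", "Cr", "Cu", "Fe", "Mn", "Ni", "Pb", "Zn")
}

#' Recognised site categories
#'
#' @return Character vector of the site-category levels used throughout the
#'   package. Unrecognised labels are normalised to `"uncategorized"`.
#' @export
site_categories <- function() {
  c("urban", "suburban", "rural", "industrial", "agricultural",
    "uncategorized")
}

#' Turkish soil-pollution regulation limits
#'
#' Maximum contaminant levels (MCLs) for surface soil from the Turkish
#' Regulation on Control of Soil Pollution, for the elements it regulates.
#' Al, Fe and Mn carry no limit (crustal elements) and are absent.
#'
#' @return A tibble with columns `element` and `limit_mg_kg` (mg/kg dry soil).
#' @export
#' @examples
#' regulation_limits()
regulation_limits <- function() {
  tibble::tibble(
    element     = c("As", "Cd", "Co", "Cr", "Cu", "Ni", "Pb", "Zn"),
    limit_mg_kg = c(20,   1,    20,   100,  50,   30,   50,   150)
  )
}

#' Default oral toxicity constants
#'
#' Oral reference doses (RfD, mg/(kg day)) and oral slope factors
#' (SF, (mg/(kg day))^-1) drawn from the USEPA IRIS database and the Risk
#' Assessment Information System (RAIS). Chromium appears as its two
#' environmental forms, trivalent Cr(III) and hexavalent Cr(VI); lead has a
#' slope factor but no IRIS reference dose, so only its carcinogenic risk is
#' quantified. Override any entry by passing your own tibble of the same
#' shape to the functions that take a `tox` argument.
#'
#' @return A tibble with columns `element_form`, `rfd`, `sf`. `NA` marks a
#'   constant that is not established for that form.
#' @export
#' @examples
#' default_toxicity()
default_toxicity <- function() {
  tibble::tibble(
    element_form = c("Al", "As", "Cd", "Co", "Cr(III)", "Cr(VI)", "Cu",
                     "Fe", "Mn", "Ni", "Pb", "Zn"),
    rfd = c(1.0, 3e-4, 1e-3, 3e-4, 1.5, 3e-3, 4e-2,
            0.7, 2.4e-2, 2e-2, NA, 0.3),
    sf  = c(NA, 1.5, NA, NA, NA, 0.5, NA,
            NA, NA, NA, 8.5e-3, NA)
  )
}

validate_toxicity <- function(tox) {
  stopifnot(is.data.frame(tox),
            all(c("element_form", "rfd", "sf") %in% names(tox)))
  if (anyDuplicated(tox$element_form)) {
    abort("duplicate element_form entries in toxicity table")
  }
  bad <- (!is.na(tox$rfd) & tox$rfd <= 0) | (!is.na(tox$sf) & tox$sf <= 0)
  if (any(bad)) {
    abort(paste0("non-positive toxicity constants for: ",
                 paste(tox$element_form[bad], collapse = ", ")))
  }
  neither <- is.na(tox$rfd) & is.na(tox$sf)
  if (any(neither)) {
    abort(paste0("toxicity rows with neither RfD nor SF: ",
                 paste(tox$element_form[neither], collapse = ", ")))
  }
  invisible(tox)
}

tox_lookup <- function(tox, element_form, what = c("rfd", "sf")) {
  what <- match.arg(what)
  i <- match(element_form, tox$element_form)
  if (is.na(i)) {
    abort(paste0("no toxicity entry for '", element_form, "'"))
  }
  val <- tox[[what]][i]
  if (is.na(val)) {
    abort(paste0("no ", toupper(what), " available for '", element_form,
                 "'; cannot compute the requested risk"))
  }
  val
}
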