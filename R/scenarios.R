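#' Default deterministic receptor scenarios
#'
#' The age-by-sex receptor groups used for deterministic point risks:
#' adults plus three child windows (newborn 6 weeks to 1 year, 1-6 years,
#' 6-11 years), each in female / male / combined variants.
#'
#' Adults use a soil ingestion rate of 20 mg/day, an exposure frequency of
#' 350 day/yr and an exposure duration (= averaging time = lifetime) of
#' 75 yr. The adult body weights (74.7 / 87.7 / 80.8 kg for female / male /
#' combined) are calibrated defaults consistent with the Exposure Factors
#' Handbook adult means. Child ingestion rates and body weights are Exposure
#' Factors Handbook central values (see the `provenance` column); they are
#' reasonable planning defaults, not population-calibrated quantities, and
#' can be overridden via [exposure_scenario()].
#'
#' @return A tibble of exposure scenarios, one row per receptor group, with
#'   a `provenance` note per entry. Columns as in [exposure_scenario()].
#' @export
#' @examples
#' default_scenarios()
default_scenarios <- function() {
  calib <- "adult BW calibrated default; IR/EF/ED Exposure Factors Handbook"
  efh <- "child IR and BW: Exposure Factors Handbook central values"
  dplyr::bind_rows(
    exposure_scenario("adult_female",      ir = 20, bw = 74.7, provenance = calib),
    exposure_scenario("adult_male",        ir = 20, bw = 87.7, provenance = calib),
    exposure_scenario("adult_combined",    ir = 20, bw = 80.8, provenance = calib),
    exposure_scenario("newborn_female",    ir = 30, bw = 7.5, ed = 1, lt = 75,
                      provenance = efh),
    exposure_scenario("newborn_male",      ir = 30, bw = 8.0, ed = 1, lt = 75,
                      provenance = efh),
    exposure_scenario("newborn_combined",  ir = 30, bw = 7.8, ed = 1, lt = 75,
                      provenance = efh),
    exposure_scenario("child_1_6_female",  ir = 50, bw = 15.0, ed = 5, lt = 75,
                      provenance = efh),
    exposure_scenario("child_1_6_male",    ir = 50, bw = 15.5, ed = 5, lt = 75,
                      provenance = efh),
    exposure_scenario("child_1_6_combined", ir = 50, bw = 15.3, ed = 5, lt = 75,
                      provenance = efh),
    exposure_scenario("child_6_11_female", ir = 50, bw = 31.0, ed = 5, lt = 75,
                      provenance = efh),
    exposure_scenario("child_6_11_male",   ir = 50, bw = 32.0, ed = 5, lt = 75,
                      provenance = efh),
    exposure_scenario("child_6_11_combined", ir = 50, bw = 31.5, ed = 5,
                      lt = 75, provenance = efh)
  )
}

#' Deterministic risk table over scenarios and elements
#'
#' Crosses mean concentrations with receptor scenarios and evaluates the
#' full deterministic chain: average daily dose, hazard quotient with zone,
#' lifetime average daily dose, carcinogenic risk with zone. Total chromium
#' rows are expanded into the Cr(III) and Cr(VI) speciated forms before
#' toxicity lookup. Element forms lacking an RfD or SF yield `NA` for the
#' corresponding risk and are flagged, never dropped.
#'
#' @param element_means A tibble with columns `element` and `mean_mg_kg`
#'   (one row per element), e.g. from [summarize_concentrations()] renamed,
#'   or a named numeric vector of means.
#' @param scenarios A tibble of scenarios, default [default_scenarios()].
#' @param tox Toxicity table, default [default_toxicity()].
#' @param fraction_cr6 Hexavalent fraction used to speciate total Cr.
#' @return A tibble with one row per (scenario, element form):
#'   `label`, `element_form`, `conc_mg_kg`, `add`, `hq`, `hq_zone`,
#'   `ladd`, `cr`, `cr_zone`, `missing_tox` (character flag or `NA`).
#' @export
#' @examples
#' scenario_risk_table(c(As = 188, Al = 21085))
scenario_risk_table <- function(element_means,
                                scenarios = default_scenarios(),
                                tox = default_toxicity(),
                                fraction_cr6 = 0.20) {
  if (is.numeric(element_means) && !is.null(names(element_means))) {
    element_means <- tibble::tibble(element = names(element_means),
                                    mean_mg_kg = unname(element_means))
  }
  stopifnot(is.data.frame(element_means),
            all(c("element", "mean_mg_kg") %in% names(element_means)))
  validate_toxicity(tox)
  if (nrow(element_means) == 0) return(tibble::tibble())

  # expand total Cr into its speciated forms; other elements pass through
  forms <- purrr::map2_dfr(
    element_means$element, element_means$mean_mg_kg,
    function(el, m) {
      if (el == "Cr") {
        sp <- speciate_chromium(m, fraction_cr6)
        tibble::tibble(element_form = c("Cr(III)", "Cr(VI)"),
                       conc_mg_kg = c(sp$cr3, sp$cr6))
      } else {
        tibble::tibble(element_form = el, conc_mg_kg = m)
      }
    })

  grid <- tidyr::expand_grid(scenarios, forms)
  purrr::pmap_dfr(
    list(seq_len(nrow(grid))),
    function(i) {
      row <- grid[i, ]
      s <- as.list(row[c("ir", "ef", "ed", "at", "lt", "bw", "cf")])
      add <- average_daily_dose(row$conc_mg_kg, s)
      ladd <- lifetime_average_daily_dose(row$conc_mg_kg, s)
      ti <- match(row$element_form, tox$element_form)
      rfd <- if (is.na(ti)) NA_real_ else tox$rfd[ti]
      sf <- if (is.na(ti)) NA_real_ else tox$sf[ti]
      hq <- if (is.na(rfd)) NA_real_ else hazard_quotient(add, rfd)
      cr <- if (is.na(sf)) NA_real_ else carcinogenic_risk(ladd, sf)
      missing_tox <- if (is.na(ti)) {
        "no toxicity entry"
      } else if (is.na(rfd) && is.na(sf)) {
        "no RfD or SF"
      } else if (is.na(rfd)) {
        "no RfD"
      } else if (is.na(sf)) {
        "no SF"
      } else NA_character_
      tibble::tibble(
        label = row$label, element_form = row$element_form,
        conc_mg_kg = row$conc_mg_kg, add = add,
        hq = hq,
        hq_zone = if (is.na(hq)) factor(NA, hq_zone_levels(), ordered = TRUE)
                  else classify_hq(hq),
        ladd = ladd, cr = cr,
        cr_zone = if (is.na(cr)) factor(NA, cr_zone_levels(), ordered = TRUE)
                  else classify_cr(cr),
        missing_tox = missing_tox
      )
    }
  )
}
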