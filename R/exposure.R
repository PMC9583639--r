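#' Build an exposure scenario
#'
#' Bundles the exposure factors of one receptor group for the soil-ingestion
#' dose equations. For chronic (noncancer) assessment the averaging time
#' equals the exposure duration, so dose is averaged over the exposed period
#' only; carcinogenic risk averages over the full lifetime instead.
#'
#' @param label Receptor group name, e.g. `"adult_female"`.
#' @param ir Soil ingestion rate, mg/day.
#' @param bw Body weight, kg.
#' @param ef Exposure frequency, day/yr (at most 366).
#' @param ed Exposure duration, yr.
#' @param at Averaging time, yr; defaults to `ed` (chronic convention).
#' @param lt Lifetime, yr (used for the lifetime average daily dose).
#' @param cf Mass conversion factor, kg/mg.
#' @param provenance Free-text note on where the factor values come from.
#' @return A one-row tibble with the scenario fields.
#' @export
#' @examples
#' exposure_scenario("adult_combined", ir = 20, bw = 80.8)
exposure_scenario <- function(label, ir, bw, ef = 350, ed = 75, at = ed,
                              lt = 75, cf = 1e-6, provenance = NA_character_) {
  s <- tibble::tibble(label = label, ir = ir, ef = ef, ed = ed, at = at,
                      lt = lt, bw = bw, cf = cf, provenance = provenance)
  validate_scenario(s)
  s
}

validate_scenario <- function(s) {
  num <- c("ir", "ef", "ed", "at", "lt", "bw", "cf")
  for (f in num) {
    v <- s[[f]]
    if (is.null(v) || any(!is.finite(v)) || any(v <= 0)) {
      abort(paste0("scenario field '", f, "' must be strictly positive"))
    }
  }
  if (any(s$ef > 366)) abort("exposure frequency ef cannot exceed 366 day/yr")
  invisible(s)
}

scenario_fields <- function(scenario) {
  # accept a one-row tibble or a named list
  if (is.data.frame(scenario)) {
    if (nrow(scenario) != 1) abort("scenario must be a single row")
    scenario <- as.list(scenario)
  }
  validate_scenario(tibble::as_tibble(scenario[c("ir", "ef", "ed", "at",
                                                 "lt", "bw", "cf")]))
  scenario
}

#' Average daily dose from accidental soil ingestion
#'
#' ADD = (C x IR x EF x ED x CF) / (BW x AT x 365), in mg/(kg day): soil mass
#' ingested over EF x ED exposure days, converted to kg of soil, normalised
#' by body weight and the averaging period in days.
#'
#' @param conc Soil concentration C, mg/kg; vectorised.
#' @param scenario An exposure scenario (one-row tibble or named list), see
#'   [exposure_scenario()].
#' @return Dose in mg/(kg day), same length as `conc`.
#' @export
#' @examples
#' adult <- exposure_scenario("adult_combined", ir = 20, bw = 80.8)
#' average_daily_dose(188, adult)   # mean nationwide As
average_daily_dose <- function(conc, scenario) {
  s <- scenario_fields(scenario)
  if (any(!is.finite(conc)) || any(conc < 0)) {
    abort("concentration must be finite and non-negative")
  }
  conc * s$ir * s$ef * s$ed * s$cf / (s$bw * s$at * 365)
}

#' Lifetime average daily dose
#'
#' Identical to [average_daily_dose()] with the averaging time replaced by
#' the lifetime LT, so the exposed-period intake is spread over the whole
#' life — the dose metric slope factors are calibrated against.
#'
#' @inheritParams average_daily_dose
#' @return Dose in mg/(kg day).
#' @export
lifetime_average_daily_dose <- function(conc, scenario) {
  s <- scenario_fields(scenario)
  if (any(!is.finite(conc)) || any(conc < 0)) {
    abort("concentration must be finite and non-negative")
  }
  conc * s$ir * s$ef * s$ed * s$cf / (s$bw * s$lt * 365)
}

#' Hazard quotient (chronic toxic risk)
#'
#' HQ = ADD / RfD, the unitless ratio of the average daily dose to the oral
#' reference dose. HQ above 1 flags potential noncancer risk.
#'
#' @param add Average daily dose, mg/(kg day); vectorised.
#' @param rfd Oral reference dose, mg/(kg day).
#' @param element_form Optional label used in error messages.
#' @return Unitless hazard quotient.
#' @export
hazard_quotient <- function(add, rfd, element_form = NULL) {
  if (length(rfd) != 1 || is.na(rfd) || !is.finite(rfd) || rfd <= 0) {
    abort(paste0("a positive oral reference dose is required",
                 if (!is.null(element_form)) paste0(" for '", element_form, "'")))
  }
  if (any(!is.finite(add)) || any(add < 0)) {
    abort("dose must be finite and non-negative")
  }
  add / rfd
}

#' Incremental lifetime carcinogenic risk
#'
#' CR = LADD x SF, the lifetime average daily dose scaled by the oral slope
#' factor of the element's dose-response curve.
#'
#' @param ladd Lifetime average daily dose, mg/(kg day); vectorised.
#' @param sf Oral slope factor, (mg/(kg day))^-1.
#' @param element_form Optional label used in error messages.
#' @return Unitless carcinogenic risk.
#' @export
carcinogenic_risk <- function(ladd, sf, element_form = NULL) {
  if (length(sf) != 1 || is.na(sf) || !is.finite(sf) || sf <= 0) {
    abort(paste0("a positive oral slope factor is required",
                 if (!is.null(element_form)) paste0(" for '", element_form, "'")))
  }
  if (any(!is.finite(ladd)) || any(ladd < 0)) {
    abort("dose must be finite and non-negative")
  }
  ladd * sf
}

hq_zone_levels <- function() c("hq_insignificant", "hq_investigate", "hq_risk")
cr_zone_levels <- function() {
  c("cr_safe", "cr_acceptable", "cr_low_priority", "cr_high_priority")
}

#' Classify a hazard quotient into a risk zone
#'
#' HQ below 0.1 is insignificant; values between 0.1 and 1 (inclusive)
#' indicate a need for further investigation; HQ above 1 poses risk.
#'
#' @param hq Non-negative hazard quotient(s).
#' @return An ordered factor over `hq_insignificant < hq_investigate <
#'   hq_risk`.
#' @export
#' @examples
#' classify_hq(c(0.05, 1, 2.22))
classify_hq <- function(hq) {
  if (any(!is.finite(hq)) || any(hq < 0)) {
    abort("hazard quotient must be finite and non-negative")
  }
  zone <- ifelse(hq < 0.1, "hq_insignificant",
          ifelse(hq <= 1, "hq_investigate", "hq_risk"))
  factor(zone, levels = hq_zone_levels(), ordered = TRUE)
}

#' Classify a carcinogenic risk into a risk zone
#'
#' The nonnegative line is partitioned at 1e-6, 1e-5 and 1e-4: CR <= 1e-6 is
#' the safe (no risk) zone, up to 1e-5 the acceptable zone, up to 1e-4 the
#' low-priority zone, and CR >= 1e-4 the unacceptable high-priority zone.
#'
#' @param cr Non-negative carcinogenic risk(s).
#' @return An ordered factor over `cr_safe < cr_acceptable < cr_low_priority
#'   < cr_high_priority`.
#' @export
#' @examples
#' classify_cr(c(6.28e-7, 2.34e-6, 6.23e-5, 5.14e-4))
classify_cr <- function(cr) {
  if (any(!is.finite(cr)) || any(cr < 0)) {
    abort("carcinogenic risk must be finite and non-negative")
  }
  zone <- ifelse(cr <= 1e-6, "cr_safe",
          ifelse(cr < 1e-5, "cr_acceptable",
          ifelse(cr < 1e-4, "cr_low_priority", "cr_high_priority")))
  factor(zone, levels = cr_zone_levels(), ordered = TRUE)
}
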