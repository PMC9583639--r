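#' Read a PTE concentration table from CSV
#'
#' Reads and validates a table of surface-soil concentration records, one row
#' per measured sample. Required columns are `element`, `concentration_mg_kg`
#' and `site_category`; `province` and `source_id` are carried through when
#' present and filled with `NA` otherwise. Site-category labels are matched
#' case-insensitively and unrecognised labels (including the legacy
#' "noncategorized") collapse to `"uncategorized"` with a warning.
#'
#' Censored observations (below detection limit) may be flagged with an
#' optional logical `censored` column alongside a numeric `detection_limit`
#' column; flagged rows are substituted with half the detection limit, the
#' conventional simple imputation for left-censored environmental data.
#'
#' @param path Path to a UTF-8 CSV file with a header row and "." decimals.
#' @return A tibble of validated concentration records with columns
#'   `element`, `concentration_mg_kg`, `province`, `site_category`,
#'   `source_id`.
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("element,concentration_mg_kg,province,site_category,source_id",
#'              "As,12.5,Izmir,urban,study1"), f)
#' read_concentration_table(f)
read_concentration_table <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  required <- c("element", "concentration_mg_kg", "site_category")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    abort(paste0("schema error: missing required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (nrow(raw) == 0) {
    warn("concentration table has a header but no rows")
    return(tibble::tibble(element = character(), concentration_mg_kg = double(),
                          province = character(), site_category = character(),
                          source_id = character()))
  }
  conc <- suppressWarnings(as.numeric(raw$concentration_mg_kg))
  non_numeric <- which(is.na(conc) & !is.na(raw$concentration_mg_kg))
  if (length(non_numeric) > 0) {
    abort(paste0("validation error: non-numeric concentration in row(s): ",
                 paste(non_numeric, collapse = ", ")))
  }

  rec <- tibble::tibble(
    element = raw$element,
    concentration_mg_kg = conc,
    province = if ("province" %in% names(raw)) raw$province else NA_character_,
    site_category = raw$site_category,
    source_id = if ("source_id" %in% names(raw)) raw$source_id else NA_character_
  )

  # left-censored rows: substitute detection_limit / 2
  if ("censored" %in% names(raw)) {
    if (!"detection_limit" %in% names(raw)) {
      abort("schema error: 'censored' column requires a 'detection_limit' column")
    }
    cens <- tolower(trimws(raw$censored)) %in% c("true", "t", "1", "yes")
    dl <- suppressWarnings(as.numeric(raw$detection_limit))
    if (any(cens & (is.na(dl) | dl <= 0))) {
      abort("validation error: censored rows need a positive detection_limit")
    }
    rec$concentration_mg_kg[cens] <- dl[cens] / 2
  }

  validate_concentration_records(rec)
}

#' Validate a tibble of concentration records
#'
#' Enforces the record invariants: known element symbols, finite non-negative
#' concentrations, normalised site categories. Offending rows are reported by
#' row number.
#'
#' @param records A data frame with at least `element`,
#'   `concentration_mg_kg` and `site_category` columns.
#' @return The validated records as a tibble (invisibly the same data,
#'   with site categories normalised).
#' @export
validate_concentration_records <- function(records) {
  stopifnot(is.data.frame(records))
  required <- c("element", "concentration_mg_kg", "site_category")
  missing <- setdiff(required, names(records))
  if (length(missing) > 0) {
    abort(paste0("schema error: missing required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  records <- tibble::as_tibble(records)
  bad_elem <- which(!records$element %in% pte_elements())
  if (length(bad_elem) > 0) {
    abort(paste0("validation error: unsupported element in row(s): ",
                 paste(head(bad_elem, 20), collapse = ", ")))
  }
  conc <- records$concentration_mg_kg
  bad_conc <- which(!is.finite(conc) | conc < 0)
  if (length(bad_conc) > 0) {
    abort(paste0("validation error: negative or non-finite concentration ",
                 "in row(s): ", paste(head(bad_conc, 20), collapse = ", ")))
  }
  cat_norm <- tolower(trimws(records$site_category))
  cat_norm[cat_norm == "noncategorized"] <- "uncategorized"
  unknown <- !cat_norm %in% site_categories()
  if (any(unknown)) {
    warn(paste0("unrecognised site_category value(s) mapped to ",
                "'uncategorized': ",
                paste(unique(records$site_category[unknown]), collapse = ", ")))
    cat_norm[unknown] <- "uncategorized"
  }
  records$site_category <- cat_norm
  records
}

#' Descriptive statistics of concentrations by group
#'
#' Computes, per group, the sample size, mean, median, 25th/75th/95th
#' percentiles and coefficient of variation (CV = sd/mean, sample sd with
#' n-1 denominator). Percentiles use linear interpolation between order
#' statistics (R quantile type 7), fixed so results are bit-stable.
#' Groups of size one report cv = 0; a zero mean gives cv = NA.
#'
#' @param records A tibble of concentration records (see
#'   [read_concentration_table()]).
#' @param group_by Character vector of grouping columns, any subset of
#'   `c("element", "site_category", "province")`. Empty for a pooled summary.
#' @return A tibble with the grouping columns plus `n`, `mean`, `median`,
#'   `p25`, `p75`, `p95`, `cv`. Concentration statistics are in mg/kg.
#' @export
#' @examples
#' recs <- tibble::tibble(element = "As", concentration_mg_kg = c(2, 4, 6, 8),
#'                        site_category = "urban", province = NA,
#'                        source_id = NA)
#' summarize_concentrations(recs, group_by = "element")
summarize_concentrations <- function(records,
                                     group_by = c("element")) {
  allowed <- c("element", "site_category", "province")
  if (!all(group_by %in% allowed)) {
    abort(paste0("group_by must be a subset of: ",
                 paste(allowed, collapse = ", ")))
  }
  if (nrow(records) == 0) {
    warn("no records to summarize; returning an empty table")
    return(tibble::tibble())
  }
  records |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group_by))) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$concentration_mg_kg),
      median = median(.data$concentration_mg_kg),
      p25 = quantile(.data$concentration_mg_kg, 0.25, type = 7, names = FALSE),
      p75 = quantile(.data$concentration_mg_kg, 0.75, type = 7, names = FALSE),
      p95 = quantile(.data$concentration_mg_kg, 0.95, type = 7, names = FALSE),
      cv = cv_sample(.data$concentration_mg_kg),
      .groups = "drop"
    )
}

cv_sample <- function(x) {
  if (length(x) == 1) return(0)
  m <- mean(x)
  if (m == 0) return(NA_real_)
  sd(x) / m
}

#' Ratio of a mean concentration to its regulation limit
#'
#' @param mean_conc Mean concentration, mg/kg.
#' @param element Element symbol; must be present in `limits`.
#' @param limits Regulation-limit tibble, defaults to [regulation_limits()].
#' @return Unitless exceedance ratio mean / limit; values above 1 exceed the
#'   maximum contaminant level.
#' @export
#' @examples
#' exceedance_ratio(89.2, "Ni") # 2.97-fold the Turkish Ni limit
exceedance_ratio <- function(mean_conc, element, limits = regulation_limits()) {
  stopifnot(is.numeric(mean_conc), all(is.finite(mean_conc)),
            all(mean_conc >= 0))
  i <- match(element, limits$element)
  if (is.na(i)) abort(paste0("no regulation limit for element '", element, "'"))
  mean_conc / limits$limit_mg_kg[i]
}

#' Speciate total chromium into Cr(III) and Cr(VI)
#'
#' Soil chromium partitions between the trivalent and the far more toxic
#' hexavalent form; the default hexavalent fraction is 20% of total Cr.
#' Mass is conserved exactly: the two outputs sum to the input.
#'
#' @param total_cr Total chromium concentration, mg/kg.
#' @param fraction_cr6 Fraction of total Cr present as Cr(VI), in \[0, 1\].
#' @return A tibble with columns `cr3` and `cr6` (mg/kg).
#' @export
#' @examples
#' speciate_chromium(133)          # 80/20 split of the mean total Cr
#' speciate_chromium(100, 1.0)     # all hexavalent
speciate_chromium <- function(total_cr, fraction_cr6 = 0.20) {
  stopifnot(is.numeric(total_cr), is.numeric(fraction_cr6))
  if (any(!is.finite(total_cr)) || any(total_cr < 0)) {
    abort("total_cr must be finite and non-negative")
  }
  if (any(fraction_cr6 < 0) || any(fraction_cr6 > 1)) {
    abort("fraction_cr6 must lie in [0, 1]")
  }
  cr6 <- total_cr * fraction_cr6
  tibble::tibble(cr3 = total_cr - cr6, cr6 = cr6)
}
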