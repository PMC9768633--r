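#' Indicator specifications
#'
#' The nine indicators behind the deprivation index, three per subdimension
#' (education, employment, income). Each spec records the subdimension, the
#' polarity (whether larger values mean more or less deprivation), the
#' transform applied during harmonization, the native spatial level at which
#' the source provides the indicator, the availability window, any
#' within-window gap years, and the corrections that apply.
#'
#' @details Polarity `"increasing"` means larger values indicate more
#' deprivation (e.g. unemployment rate); `"decreasing"` the opposite (e.g.
#' employees with university degree). The availability windows mirror the
#' German INKAR-style source calendar: the two employee-qualification
#' indicators start in 2001 and miss 2012 (a changeover in the reporting
#' procedure on social insurance), gross wage and household income start in
#' 2000, the debtor quota in 2004; the remaining indicators cover 1998-2019.
#' Unemployment and employment rates are GVB-native but resolve only to
#' districts in 1998-2000.
#'
#' @param name optional character vector to subset by indicator name.
#' @return tibble with one row per indicator.
#' @export
#' @examples
#' default_indicator_specs()
default_indicator_specs <- function(name = NULL) {
  specs <- tibble::tribble(
    ~indicator,                             ~dimension,   ~polarity,    ~transform,            ~native_level, ~avail_start, ~avail_end, ~gap_years,   ~district_only_years, ~corrections,
    "employees_with_university_degree",     "education",  "decreasing", "none",                "district",    2001L,        2019L,      list(2012L),  list(integer(0)),     list("break"),
    "employees_without_qualification",      "education",  "increasing", "none",                "district",    2001L,        2019L,      list(2012L),  list(integer(0)),     list(c("break", "east_west")),
    "school_leavers_without_qualification", "education",  "increasing", "none",                "district",    1998L,        2019L,      list(integer(0)), list(integer(0)), list("g8"),
    "employment_rate",                      "employment", "decreasing", "none",                "gvb",         1998L,        2019L,      list(integer(0)), list(1998:2000),  list(character(0)),
    "unemployment_rate",                    "employment", "increasing", "none",                "gvb",         1998L,        2019L,      list(integer(0)), list(1998:2000),  list(character(0)),
    "gross_wage",                           "employment", "decreasing", "log_after_deflation", "district",    2000L,        2019L,      list(integer(0)), list(integer(0)), list(character(0)),
    "household_income",                     "income",     "decreasing", "log_after_deflation", "district",    2000L,        2019L,      list(integer(0)), list(integer(0)), list(character(0)),
    "debtor_quota",                         "income",     "increasing", "none",                "district",    2004L,        2019L,      list(integer(0)), list(integer(0)), list(character(0)),
    "tax_revenue",                          "income",     "decreasing", "log_after_deflation", "gvb",         1998L,        2019L,      list(integer(0)), list(integer(0)), list(character(0))
  )
  if (!is.null(name)) {
    bad <- setdiff(name, specs$indicator)
    if (length(bad)) abort_di(paste0("unknown indicator(s): ", paste(bad, collapse = ", ")), "unknown_indicator")
    specs <- specs[match(name, specs$indicator), ]
  }
  specs
}

#' Validate a set of indicator specs
#'
#' Checks the structural contract: nine indicators, three per subdimension,
#' recognised polarity / transform / native-level values.
#'
#' @param specs tibble as returned by [default_indicator_specs()].
#' @return `specs`, invisibly, if valid; otherwise an error.
#' @export
validate_indicator_specs <- function(specs) {
  need <- c("indicator", "dimension", "polarity", "transform", "native_level",
            "avail_start", "avail_end")
  miss <- setdiff(need, names(specs))
  if (length(miss)) abort_di(paste0("specs missing columns: ", paste(miss, collapse = ", ")), "bad_specs")
  if (nrow(specs) != 9) abort_di("exactly 9 indicator specs are required", "bad_specs")
  per_dim <- table(specs$dimension)
  if (!setequal(names(per_dim), c("education", "employment", "income")) || any(per_dim != 3)) {
    abort_di("each of education, employment, income must have exactly 3 indicators", "bad_specs")
  }
  if (!all(specs$polarity %in% c("increasing", "decreasing"))) {
    abort_di("polarity must be 'increasing' or 'decreasing'", "bad_specs")
  }
  if (!all(specs$transform %in% c("none", "log", "log_after_deflation"))) {
    abort_di("transform must be one of none/log/log_after_deflation", "bad_specs")
  }
  if (!all(specs$native_level %in% c("gvb", "district"))) {
    abort_di("native_level must be 'gvb' or 'district'", "bad_specs")
  }
  invisible(specs)
}

#' Read indicator specs from a YAML file
#'
#' The YAML layout is a list of indicator entries with fields `indicator`,
#' `dimension`, `polarity`, `transform`, `native_level`, `avail_start`,
#' `avail_end`, and optional `gap_years`, `district_only_years`,
#' `corrections`.
#'
#' @param path path to the YAML file.
#' @return validated specs tibble.
#' @export
read_indicator_specs <- function(path) {
  raw <- yaml::read_yaml(path)
  specs <- dplyr::bind_rows(lapply(raw, function(e) {
    tibble::tibble(
      indicator = e$indicator, dimension = e$dimension,
      polarity = e$polarity, transform = e$transform %||% "none",
      native_level = e$native_level,
      avail_start = as.integer(e$avail_start), avail_end = as.integer(e$avail_end),
      gap_years = list(as.integer(e$gap_years %||% integer(0))),
      district_only_years = list(as.integer(e$district_only_years %||% integer(0))),
      corrections = list(as.character(e$corrections %||% character(0)))
    )
  }))
  validate_indicator_specs(specs)
  specs
}

#' Published first-component loadings of the 2022 index revision
#'
#' The per-subdimension first principal-component loadings of the published
#' German Index of Socioeconomic Deprivation (revision 2022 v1), together
#' with the published within-dimension and total-index weight shares (in
#' percent, rounded to one decimal as printed). Useful as an oracle for
#' [shares_from_loadings()] and as a target pattern for the synthetic-data
#' generator.
#'
#' @return tibble with columns `dimension`, `indicator`, `loading`,
#'   `share_dimension_published`, `share_gisd_published`.
#' @export
published_loadings <- function() {
  tibble::tribble(
    ~dimension,   ~indicator,                             ~loading, ~share_dimension_published, ~share_gisd_published,
    "education",  "employees_with_university_degree",     -0.732,   34.1,                       11.4,
    "education",  "employees_without_qualification",       0.771,   37.8,                       12.6,
    "education",  "school_leavers_without_qualification",  0.663,   28.0,                        9.3,
    "employment", "employment_rate",                      -0.640,   23.1,                        7.7,
    "employment", "unemployment_rate",                     0.841,   39.9,                       13.3,
    "employment", "gross_wage",                           -0.810,   37.0,                       12.3,
    "income",     "tax_revenue",                          -0.914,   40.7,                       13.6,
    "income",     "household_income",                     -0.921,   41.3,                       13.8,
    "income",     "debtor_quota",                          0.608,   18.0,                        6.0
  )
}

#' The 2013 European Standard Population in 5-year age groups
#'
#' Standard weights for direct age standardization, summing to 100,000.
#' Shipped as a plain-text table under `inst/extdata/esp2013.csv`; the
#' weights are the published 2013 European Standard Population with the
#' 0 and 1-4 year groups combined into 0-4 and ages 90+ collapsed, giving
#' the 5-year grouping used throughout the epi functions.
#'
#' @return tibble with columns `age_group` (ordered labels) and `weight`.
#' @export
esp2013 <- function() {
  path <- system.file("extdata", "esp2013.csv", package = "deprindex")
  if (path == "") path <- file.path("inst", "extdata", "esp2013.csv")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  tibble::as_tibble(df)
}
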