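#' Indicator panel
#'
#' Long-format region x year x indicator values. Rows may live at different
#' spatial levels (a district-native indicator holds district rows until it
#' is broadcast to GVB), so the panel carries an explicit `level` column.
#' Missingness is represented by absence: a (region, year, indicator) cell
#' without a row is missing. Cells created by gap carry-forward or model
#' imputation are flagged `imputed = TRUE`. The panel also carries a
#' correction ledger (one row per applied correction) used to refuse
#' accidental double application.
#'
#' @param data data frame with columns `region_id`, `level`, `year`,
#'   `indicator`, `value` and optionally `imputed`.
#' @return an object of class `indicator_panel`.
#' @export
indicator_panel <- function(data) {
  need <- c("region_id", "level", "year", "indicator", "value")
  miss <- setdiff(need, names(data))
  if (length(miss)) abort_di(paste0("panel missing columns: ", paste(miss, collapse = ", ")), "bad_panel")
  data <- tibble::as_tibble(data)
  if (!"imputed" %in% names(data)) data$imputed <- FALSE
  data$region_id <- as.character(data$region_id)
  data$level <- as.character(data$level)
  data$year <- as.integer(data$year)
  data$indicator <- as.character(data$indicator)
  data$value <- as.numeric(data$value)
  if (anyDuplicated(data[c("region_id", "year", "indicator")])) {
    d <- data[duplicated(data[c("region_id", "year", "indicator")]), ]
    abort_di(paste0("duplicate (region, year, indicator) rows, e.g. ",
                    d$region_id[1], "/", d$year[1], "/", d$indicator[1]),
             "duplicate_key")
  }
  structure(data, class = c("indicator_panel", class(data)),
            corrections = correction_ledger_empty())
}

correction_ledger_empty <- function() {
  tibble::tibble(indicator = character(0), correction = character(0),
                 params = character(0), rows_touched = integer(0))
}

#' Correction ledger of a panel
#'
#' One row per harmonization step already applied to the panel (indicator,
#' correction name, JSON-encoded parameters, number of rows touched).
#' @param panel an `indicator_panel`.
#' @return tibble ledger.
#' @export
correction_ledger <- function(panel) {
  attr(panel, "corrections") %||% correction_ledger_empty()
}

#' @rdname correction_ledger
#' @param x an `indicator_panel`, or a ledger tibble itself.
#' @param path CSV file to write the ledger to (sidecar file).
#' @export
write_correction_ledger <- function(x, path) {
  led <- if (inherits(x, "indicator_panel")) correction_ledger(x) else tibble::as_tibble(x)
  utils::write.csv(led, path, row.names = FALSE)
  invisible(path)
}

record_correction <- function(panel, indicator, correction, params, rows_touched) {
  led <- correction_ledger(panel)
  attr(panel, "corrections") <- dplyr::bind_rows(led, tibble::tibble(
    indicator = indicator, correction = correction,
    params = jsonlite::toJSON(params, auto_unbox = TRUE) |> as.character(),
    rows_touched = as.integer(rows_touched)))
  panel
}

refuse_if_applied <- function(panel, indicator, correction) {
  led <- correction_ledger(panel)
  if (any(led$indicator == indicator & led$correction == correction)) {
    abort_di(paste0("correction '", correction, "' already applied to '",
                    indicator, "'; refusing to apply twice"), "double_correction")
  }
  invisible(panel)
}

# rebuild the class/ledger after dplyr verbs stripped them
restore_panel <- function(data, template) {
  p <- indicator_panel(as.data.frame(data))
  attr(p, "corrections") <- correction_ledger(template)
  p
}

#' @exportS3Method base::print
print.indicator_panel <- function(x, ...) {
  cat("<indicator_panel> ", nrow(x), " rows; ",
      length(unique(x$indicator)), " indicators; years ",
      min(x$year), "-", max(x$year), "; ",
      sum(x$imputed), " imputed cells; ",
      nrow(correction_ledger(x)), " corrections applied\n", sep = "")
  invisible(x)
}

#' Read an indicator panel CSV
#'
#' Long CSV with columns `region_id,year,indicator,value`. Values may use a
#' decimal point or a decimal comma; the dialect is declared, not guessed.
#' Rows with indicators not present in `specs` are a hard error; rows with
#' years outside the panel window are dropped with a warning. The spatial
#' level of each row is resolved against the hierarchy (municipality, GVB or
#' district ids are all accepted).
#'
#' @param path file path.
#' @param specs indicator specs (see [default_indicator_specs()]).
#' @param hierarchy a `region_hierarchy` used to resolve row levels.
#' @param decimal_mark `"."` or `","`.
#' @param years admissible year window.
#' @return an `indicator_panel`.
#' @export
read_panel <- function(path, specs, hierarchy, decimal_mark = ".",
                       years = 1998:2019) {
  validate_indicator_specs(specs)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(region_id = "character", value = "character"))
  if (decimal_mark == ",") df$value <- sub(",", ".", df$value, fixed = TRUE)
  df$value <- as.numeric(df$value)
  unknown <- setdiff(unique(df$indicator), specs$indicator)
  if (length(unknown)) {
    abort_di(paste0("unknown indicator(s) in panel: ", paste(unknown, collapse = ", ")),
             "unknown_indicator")
  }
  out_of_window <- !(df$year %in% years)
  if (any(out_of_window)) {
    warn_di(paste0("dropping ", sum(out_of_window), " rows outside years ",
                   min(years), "-", max(years)), "year_out_of_window")
    df <- df[!out_of_window, ]
  }
  df$level <- resolve_level(hierarchy, df$region_id)
  if (anyNA(df$level)) {
    bad <- unique(df$region_id[is.na(df$level)])
    abort_di(paste0("region id(s) not found in hierarchy: ",
                    paste(utils::head(bad, 5), collapse = ", ")), "unknown_region")
  }
  indicator_panel(df[c("region_id", "level", "year", "indicator", "value")])
}

#' @rdname read_panel
#' @param panel an `indicator_panel`.
#' @export
write_panel <- function(panel, path) {
  utils::write.csv(as.data.frame(panel)[c("region_id", "year", "indicator", "value", "imputed")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

resolve_level <- function(hierarchy, ids) {
  lv <- rep(NA_character_, length(ids))
  for (level in region_levels()) {
    known <- unique(hierarchy[[id_col_for_level(level)]])
    hit <- is.na(lv) & ids %in% known
    lv[hit] <- level
  }
  lv
}

panel_rows <- function(panel, indicator, years = NULL, level = NULL) {
  keep <- panel$indicator == indicator
  if (!is.null(years)) keep <- keep & panel$year %in% years
  if (!is.null(level)) keep <- keep & panel$level %in% level
  keep
}

#' Broadcast district values to child GVB
#'
#' Assigns each district's value of an indicator to all GVB inside the
#' district for the given years, so the within-district GVB variance is
#' exactly zero for those indicator-years. Used where an indicator resolves
#' only to districts (either structurally, for district-native indicators,
#' or for early years of a GVB-native indicator). Districts without a value
#' leave their GVB missing. Pre-existing GVB rows for those indicator-years
#' are replaced so the zero-variance postcondition holds.
#'
#' @param panel an `indicator_panel`.
#' @param hierarchy a `region_hierarchy`.
#' @param indicator indicator name.
#' @param years years to broadcast.
#' @return updated `indicator_panel`.
#' @export
broadcast_district_to_gvb <- function(panel, hierarchy, indicator, years) {
  src <- as.data.frame(panel)[panel_rows(panel, indicator, years, "district"), ]
  if (!nrow(src)) {
    abort_di(paste0("no district rows for '", indicator, "' in requested years"),
             "missing_source")
  }
  pm <- parent_map(hierarchy, "gvb", "district")
  new_rows <- merge(src, as.data.frame(pm), by.x = "region_id", by.y = "to_id")
  new_rows <- tibble::tibble(
    region_id = new_rows$from_id, level = "gvb", year = new_rows$year,
    indicator = new_rows$indicator, value = new_rows$value,
    imputed = new_rows$imputed)
  keep <- !(panel_rows(panel, indicator, years, "gvb"))
  out <- dplyr::bind_rows(as.data.frame(panel)[keep, ], new_rows)
  out <- restore_panel(out, panel)
  record_correction(out, indicator, "broadcast_district_to_gvb",
                    list(years = years), nrow(new_rows))
}

#' Missing cells of an indicator at a level
#'
#' The full region x year grid at `level` minus the observed rows.
#'
#' @param panel an `indicator_panel`.
#' @param hierarchy a `region_hierarchy`.
#' @param indicator indicator name.
#' @param level spatial level of the grid.
#' @param years year range defining the grid.
#' @return tibble `region_id`, `year` of missing cells.
#' @export
missing_cells <- function(panel, hierarchy, indicator, level, years) {
  ids <- unique(hierarchy[[id_col_for_level(level)]])
  grid <- tidyr::expand_grid(region_id = ids, year = as.integer(years))
  obs <- as.data.frame(panel)[panel_rows(panel, indicator, years, level),
                              c("region_id", "year")]
  dplyr::anti_join(grid, obs, by = c("region_id", "year"))
}
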