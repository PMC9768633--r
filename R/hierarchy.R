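#' Region hierarchy
#'
#' A nested administrative geography with yearly populations, stored at the
#' municipality grain: one row per municipality per year with the identifiers
#' of all parent units. Municipality codes follow the German AGS convention
#' (8-digit fixed-width strings) whose prefixes give the district (first 5
#' digits) and the state (first 2 digits); GVB, spatial-planning-region (ROR)
#' and NUTS-2 units carry their own code columns since they are not AGS
#' prefixes.
#'
#' @param data data frame with columns `region_id` (8-char municipality
#'   code), `gvb_id`, `district_id`, `ror_id`, `nuts2_id`, `state_id`,
#'   `year`, `population`.
#' @param east_states character vector of 2-digit state codes counted as
#'   East for the East-West correction. The real-data default is the five
#'   East German states with Berlin treated as West; for synthetic
#'   hierarchies the set is whatever the generator declares.
#' @return an object of class `region_hierarchy` (a tibble with metadata).
#' @seealso [read_hierarchy()], [level_table()], [region_counts()]
#' @export
region_hierarchy <- function(data, east_states = character(0)) {
  need <- c("region_id", "gvb_id", "district_id", "ror_id", "nuts2_id",
            "state_id", "year", "population")
  miss <- setdiff(need, names(data))
  if (length(miss)) abort_di(paste0("hierarchy missing columns: ", paste(miss, collapse = ", ")), "bad_hierarchy")
  data <- tibble::as_tibble(data)
  id_cols <- c("region_id", "gvb_id", "district_id", "ror_id", "nuts2_id", "state_id")
  data[id_cols] <- lapply(data[id_cols], as.character)
  data$year <- as.integer(data$year)
  data$population <- as.numeric(data$population)
  h <- structure(data, class = c("region_hierarchy", class(data)),
                 east_states = as.character(east_states))
  validate_hierarchy(h)
  h
}

#' @exportS3Method base::print
print.region_hierarchy <- function(x, ...) {
  cnt <- region_counts(x)
  cat("<region_hierarchy> ", cnt[["municipality"]], " municipalities, ",
      cnt[["gvb"]], " GVB, ", cnt[["district"]], " districts, ",
      cnt[["ror"]], " ROR, ", cnt[["nuts2"]], " NUTS-2; years ",
      min(x$year), "-", max(x$year), "\n", sep = "")
  cat("  East states: ", paste(attr(x, "east_states"), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Validate a region hierarchy
#'
#' Checks the structural invariants: complete parent chains (an orphan
#' municipality is a hard error naming its id), unique (municipality, year)
#' keys, non-negative populations, AGS prefix consistency (district = first
#' five digits, state = first two), and unambiguous nesting (each unit has
#' exactly one parent at the next level).
#'
#' @param h a `region_hierarchy`.
#' @return `h` invisibly if valid, otherwise an error.
#' @export
validate_hierarchy <- function(h) {
  parent_cols <- c("gvb_id", "district_id", "ror_id", "nuts2_id", "state_id")
  for (col in parent_cols) {
    bad <- is.na(h[[col]]) | h[[col]] == ""
    if (any(bad)) {
      abort_di(paste0("orphan region(s) without ", col, ": ",
                      paste(utils::head(unique(h$region_id[bad]), 5), collapse = ", ")),
               "orphan_region")
    }
  }
  if (any(is.na(h$population) | h$population < 0)) {
    bad <- unique(h$region_id[is.na(h$population) | h$population < 0])
    abort_di(paste0("negative or missing population for: ",
                    paste(utils::head(bad, 5), collapse = ", ")), "bad_population")
  }
  if (anyDuplicated(h[c("region_id", "year")])) {
    abort_di("duplicate (region_id, year) rows in hierarchy", "duplicate_key")
  }
  if (any(nchar(h$region_id) != 8)) {
    abort_di("municipality region_id must be 8 characters (AGS)", "bad_code")
  }
  if (any(substr(h$region_id, 1, 5) != h$district_id)) {
    bad <- unique(h$region_id[substr(h$region_id, 1, 5) != h$district_id])
    abort_di(paste0("district_id is not the AGS prefix for: ",
                    paste(utils::head(bad, 5), collapse = ", ")), "bad_code")
  }
  if (any(substr(h$region_id, 1, 2) != h$state_id)) {
    abort_di("state_id is not the AGS prefix of region_id", "bad_code")
  }
  # one parent per child at every step of the chain
  chain <- list(c("region_id", "gvb_id"), c("gvb_id", "district_id"),
                c("district_id", "ror_id"), c("ror_id", "nuts2_id"))
  for (pair in chain) {
    m <- unique(as.data.frame(h)[pair])
    if (anyDuplicated(m[[1]])) {
      dup <- m[[1]][duplicated(m[[1]])]
      abort_di(paste0("unit(s) with multiple parents (", pair[1], "->", pair[2], "): ",
                      paste(utils::head(unique(dup), 5), collapse = ", ")), "ambiguous_parent")
    }
  }
  invisible(h)
}

#' Read / write a region hierarchy CSV
#'
#' The CSV layout is one row per municipality per year:
#' `region_id,gvb_id,district_id,ror_id,nuts2_id,state_id,year,population`.
#'
#' @param path file path.
#' @param east_states passed to [region_hierarchy()].
#' @return a validated `region_hierarchy`.
#' @export
read_hierarchy <- function(path, east_states = character(0)) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(region_id = "character", gvb_id = "character",
                                       district_id = "character", ror_id = "character",
                                       nuts2_id = "character", state_id = "character"))
  region_hierarchy(df, east_states = east_states)
}

#' @rdname read_hierarchy
#' @param h a `region_hierarchy`.
#' @export
write_hierarchy <- function(h, path) {
  utils::write.csv(as.data.frame(h), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Spatial levels of the hierarchy, finest first
#' @return character vector of level names.
#' @export
region_levels <- function() c("municipality", "gvb", "district", "ror", "nuts2")

id_col_for_level <- function(level) {
  switch(level,
         municipality = "region_id", gvb = "gvb_id", district = "district_id",
         ror = "ror_id", nuts2 = "nuts2_id", state = "state_id",
         abort_di(paste0("unknown level: ", level), "bad_level"))
}

#' Populations aggregated at a spatial level
#'
#' Sums municipality populations up the parent chain, so population is
#' conserved at every level by construction.
#'
#' @param h a `region_hierarchy`.
#' @param level one of `r paste(region_levels(), collapse = ", ")`.
#' @param years optional year filter.
#' @return tibble `region_id`, `year`, `population` at the requested level.
#' @export
level_table <- function(h, level, years = NULL) {
  col <- id_col_for_level(level)
  df <- tibble::as_tibble(as.data.frame(h))
  if (!is.null(years)) df <- df[df$year %in% years, ]
  out <- df |>
    dplyr::group_by(region_id = .data[[col]], year = .data$year) |>
    dplyr::summarise(population = sum(.data$population), .groups = "drop")
  out
}

#' Number of units at each level
#' @param h a `region_hierarchy`.
#' @return named integer vector over [region_levels()].
#' @export
region_counts <- function(h) {
  vapply(region_levels(), function(lv) {
    length(unique(h[[id_col_for_level(lv)]]))
  }, integer(1))
}

#' East flag for regions
#'
#' A region counts as East when its 2-digit state code is in the hierarchy's
#' configured East-state set. For municipality and district ids the state is
#' the AGS prefix; for other levels it is looked up through the hierarchy.
#'
#' @param h a `region_hierarchy`.
#' @param region_id character vector of ids at any level.
#' @return logical vector.
#' @export
east_flag <- function(h, region_id) {
  east <- attr(h, "east_states")
  # build a lookup across all levels
  lut <- new.env(parent = emptyenv())
  df <- as.data.frame(h)
  for (lv in c(region_levels(), "state")) {
    col <- id_col_for_level(lv)
    m <- unique(df[c(col, "state_id")])
    # units spanning several states (possible for ror/nuts2 in odd configs):
    # take the first; synthetic hierarchies nest states cleanly
    m <- m[!duplicated(m[[col]]), ]
    for (i in seq_len(nrow(m))) assign(m[[col]][i], m$state_id[i], envir = lut)
  }
  states <- vapply(region_id, function(id) {
    if (exists(id, envir = lut, inherits = FALSE)) get(id, envir = lut) else NA_character_
  }, character(1), USE.NAMES = FALSE)
  states %in% east
}

#' Parent lookup table between two levels
#'
#' @param h a `region_hierarchy`.
#' @param from,to level names; `to` must be coarser than `from`.
#' @return tibble with columns `from_id`, `to_id` (unique pairs).
#' @export
parent_map <- function(h, from, to) {
  lv <- region_levels()
  if (match(to, lv) <= match(from, lv)) {
    abort_di("'to' must be a coarser level than 'from'", "bad_level")
  }
  df <- unique(as.data.frame(h)[c(id_col_for_level(from), id_col_for_level(to))])
  names(df) <- c("from_id", "to_id")
  tibble::as_tibble(df[!duplicated(df$from_id), ])
}
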