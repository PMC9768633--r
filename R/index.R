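#' Yearly min-max normalization
#'
#' Rescales score columns to `[0, 1]` within groups (by default within each
#' year): `x <- (x - min) / (max - min)`. Min-max normalization is invariant
#' to affine transforms of its input, which is what makes the final index
#' independent of the factor-scoring convention.
#'
#' @param scores data frame of scores.
#' @param cols character vector of columns to normalize.
#' @param by grouping columns (default `"year"`).
#' @return `scores` with the columns rescaled.
#' @export
normalize_yearly <- function(scores, cols, by = "year") {
  for (col in cols) {
    grp <- interaction(scores[by], drop = TRUE)
    mins <- tapply(scores[[col]], grp, min)
    maxs <- tapply(scores[[col]], grp, max)
    if (any(maxs - mins == 0)) {
      abort_di(paste0("constant '", col, "' within a normalization group"),
               "constant_scores")
    }
    g <- as.character(grp)
    scores[[col]] <- as.numeric((scores[[col]] - mins[g]) / (maxs[g] - mins[g]))
  }
  scores
}

#' Compose the deprivation index from normalized subdimension scores
#'
#' The three normalized subdimension scores are added, so each subdimension
#' enters the composite with a weight of one third (the sum spans `[0, 3]`
#' and is renormalized downstream).
#'
#' @param scores data frame with columns `score_education`,
#'   `score_employment`, `score_income` in `[0, 1]`.
#' @return `scores` with a `gisd_raw` column added.
#' @export
compose_gisd <- function(scores) {
  need <- c("score_education", "score_employment", "score_income")
  miss <- setdiff(need, names(scores))
  if (length(miss)) abort_di(paste0("missing subdimension score(s): ",
                                    paste(miss, collapse = ", ")), "missing_dimension")
  if (anyNA(scores[need])) abort_di("missing subdimension score values", "missing_dimension")
  scores$gisd_raw <- scores$score_education + scores$score_employment + scores$score_income
  scores
}

#' Population-weighted aggregation of scores to a coarser level
#'
#' Each target unit's score is the population-weighted mean of its child
#' municipalities' scores for that year, optionally renormalized to `[0, 1]`
#' within the target level and year. Renormalization should only happen at
#' the final level of a chain: the plain weighted means are associative
#' (municipality to district directly equals municipality to GVB to
#' district), the renormalized ones are not.
#'
#' @param scores data frame of municipality scores with `region_id`, `year`
#'   and score columns.
#' @param hierarchy a `region_hierarchy` supplying yearly populations.
#' @param target_level level to aggregate to.
#' @param cols score columns to aggregate.
#' @param renormalize rescale to `[0, 1]` per year at the target level.
#' @param from_level level of the input scores (default municipality).
#' @return tibble of aggregated scores at the target level.
#' @export
aggregate_scores <- function(scores, hierarchy, target_level,
                             cols = c("score_education", "score_employment",
                                      "score_income", "gisd"),
                             renormalize = TRUE, from_level = "municipality") {
  cols <- intersect(cols, names(scores))
  pm <- parent_map(hierarchy, from_level, target_level)
  pop <- level_table(hierarchy, from_level, years = unique(scores$year))
  df <- dplyr::inner_join(tibble::as_tibble(scores), pop, by = c("region_id", "year"))
  df$parent <- pm$to_id[match(df$region_id, pm$from_id)]
  if (anyNA(df$parent)) abort_di("scores contain regions outside the hierarchy", "unknown_region")
  tot <- tapply(df$population, paste(df$parent, df$year), sum)
  if (any(tot == 0)) abort_di("zero total population in a target unit-year", "zero_population")
  agg <- df |>
    dplyr::group_by(region_id = .data$parent, year = .data$year) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(cols),
                                   ~ stats::weighted.mean(.x, w = .data$population)),
                     .groups = "drop")
  if (renormalize) agg <- normalize_yearly(agg, cols, by = "year")
  agg
}

#' Assign yearly quintiles of the index
#'
#' Regions are ranked by index value within each year and split into five
#' fifths of units: quintile `floor((rank - 1) * 5 / n) + 1` with minimum
#' ranks for ties, so tied regions share the lower quintile and quintile
#' sizes differ by at most one region before ties. Quintile 1 is the lowest
#' deprivation fifth. A three-group collapse (`low` = quintile 1, `mid` =
#' quintiles 2-4, `high` = quintile 5) is added for the epi analyses.
#'
#' @param scores data frame with `region_id`, `year` and a score column.
#' @param col score column to rank on (default `"gisd"`).
#' @return `scores` with `quintile` (integer 1-5) and `group3` columns.
#' @export
assign_quintiles <- function(scores, col = "gisd") {
  out <- lapply(split(tibble::as_tibble(scores), scores$year), function(d) {
    n <- nrow(d)
    if (n < 5) abort_di("need at least 5 regions per year for quintiles", "too_few_regions")
    r <- rank(d[[col]], ties.method = "min")
    d$quintile <- as.integer(floor((r - 1) * 5 / n) + 1)
    d$group3 <- c("low", "mid", "mid", "mid", "high")[d$quintile]
    d
  })
  dplyr::bind_rows(out)
}

#' Map district scores onto a custom geography
#'
#' Population-weighted mean of district scores per custom unit (e.g. zip
#' code areas), from a crosswalk of (district, custom unit, population
#' weight) rows, renormalized to `[0, 1]` per year. If the crosswalk carries
#' a `unit_total` column and the weights of a unit do not sum to it, the
#' weights are normalized internally with a warning.
#'
#' @param district_scores data frame `region_id` (district), `year`, score
#'   columns.
#' @param crosswalk data frame `district_id`, `custom_id`, `weight`, and
#'   optionally `unit_total`.
#' @param cols score columns to map.
#' @param renormalize rescale to `[0, 1]` per year.
#' @return tibble of scores on the custom units.
#' @export
map_to_custom_geography <- function(district_scores, crosswalk,
                                    cols = c("score_education", "score_employment",
                                             "score_income", "gisd"),
                                    renormalize = TRUE) {
  cols <- intersect(cols, names(district_scores))
  cw <- tibble::as_tibble(crosswalk)
  if (any(cw$weight < 0)) abort_di("negative crosswalk weights", "bad_crosswalk")
  if ("unit_total" %in% names(cw)) {
    sums <- tapply(cw$weight, cw$custom_id, sum)
    tot <- tapply(cw$unit_total, cw$custom_id, function(x) x[1])
    off <- abs(sums - tot) > 1e-8 * pmax(1, tot)
    if (any(off)) {
      warn_di(paste0("crosswalk weights do not sum to unit totals for ",
                     sum(off), " unit(s); normalizing internally"), "weight_mismatch")
    }
  }
  df <- dplyr::inner_join(tibble::as_tibble(district_scores), cw,
                          by = c(region_id = "district_id"),
                          relationship = "many-to-many")
  out <- df |>
    dplyr::group_by(region_id = .data$custom_id, year = .data$year) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(cols),
                                   ~ stats::weighted.mean(.x, w = .data$weight)),
                     .groups = "drop")
  if (renormalize) out <- normalize_yearly(out, cols, by = "year")
  out
}

#' Build the deprivation index end to end
#'
#' Runs harmonization, pooled PCA weighting, factor scoring, yearly
#' normalization, composition, population-weighted aggregation and quintile
#' assignment, producing a score panel for every requested spatial level.
#' The GVB level is flagged as carrying greater uncertainty, since only a
#' third of the indicators vary below the district level.
#'
#' @param panel raw `indicator_panel`.
#' @param hierarchy a `region_hierarchy`.
#' @param specs indicator specs.
#' @param config harmonization config (see [harmonize_panel()]); extra
#'   entries: `pool_years` (PCA pool, default 2001-2019), `levels` (levels
#'   to emit, default all five).
#' @return list with `scores` (a `score_panel` tibble: `region_id`, `level`,
#'   `year`, the three normalized subdimension scores, `gisd`, `quintile`,
#'   `group3`, `uncertain`), `loadings`, `tables` (per-dimension loading
#'   tables), `models`, `ledger`.
#' @export
build_gisd <- function(panel, hierarchy, specs, config = list()) {
  years <- config$years %||% 1998:2019
  pool_years <- config$pool_years %||% 2001:2019
  levels_out <- config$levels %||% region_levels()

  harm <- harmonize_panel(panel, hierarchy, specs, config)
  fit <- fit_all_dimensions(harm$panel, hierarchy, specs,
                            pool_years = pool_years, score_years = years,
                            level = "municipality",
                            min_var_explained = config$min_var_explained %||% 0.5)

  wide <- tidyr::pivot_wider(fit$scores, names_from = "dimension",
                             values_from = "score", names_prefix = "score_")
  dim_cols <- c("score_education", "score_employment", "score_income")
  muni <- normalize_yearly(wide, dim_cols, by = "year")
  muni <- compose_gisd(muni)
  muni$gisd <- muni$gisd_raw
  muni <- normalize_yearly(muni, "gisd", by = "year")
  muni$gisd_raw <- NULL

  out <- list()
  for (lv in levels_out) {
    if (lv == "municipality") {
      sc <- muni
    } else {
      sc <- aggregate_scores(muni, hierarchy, lv,
                             cols = c(dim_cols, "gisd"), renormalize = TRUE)
    }
    sc <- assign_quintiles(sc, col = "gisd")
    sc$level <- lv
    sc$uncertain <- lv %in% c("municipality", "gvb")
    out[[lv]] <- sc
  }
  scores <- dplyr::bind_rows(out)
  scores <- scores[c("region_id", "level", "year", dim_cols, "gisd",
                     "quintile", "group3", "uncertain")]
  class(scores) <- c("score_panel", class(scores))

  list(scores = scores, loadings = fit$loadings, tables = fit$tables,
       models = harm$models, ledger = harm$ledger)
}

#' Validate score panel invariants
#'
#' Checks, per level and year: all scores within `[0, 1]`; the index attains
#' 0 and 1; quintile sizes differ by at most one region (before ties); the
#' maximum-score region carries quintile 5.
#'
#' @param scores a `score_panel` tibble.
#' @return `TRUE` invisibly, or an error describing the violation.
#' @export
validate_score_panel <- function(scores) {
  sc_cols <- c("score_education", "score_employment", "score_income", "gisd")
  for (col in sc_cols) {
    v <- scores[[col]]
    if (anyNA(v) || any(v < -1e-9 | v > 1 + 1e-9)) {
      abort_di(paste0("'", col, "' outside [0, 1]"), "invariant_violation")
    }
  }
  by <- split(tibble::as_tibble(scores), paste(scores$level, scores$year))
  for (d in by) {
    if (abs(min(d$gisd)) > 1e-9 || abs(max(d$gisd) - 1) > 1e-9) {
      abort_di("index does not attain 0 and 1 within a level-year", "invariant_violation")
    }
    sizes <- tabulate(d$quintile, nbins = 5)
    if (!anyDuplicated(d$gisd)) {
      if (diff(range(sizes)) > 1) {
        abort_di("quintile sizes differ by more than 1 region", "invariant_violation")
      }
    }
    if (d$quintile[which.max(d$gisd)] != 5L) {
      abort_di("maximum-score region not in quintile 5", "invariant_violation")
    }
  }
  invisible(TRUE)
}

#' Write score panels as per-level CSV files
#'
#' @param scores a `score_panel`.
#' @param dir output directory (one CSV per level).
#' @return the directory, invisibly.
#' @export
write_score_panel <- function(scores, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (lv in unique(scores$level)) {
    utils::write.csv(as.data.frame(scores[scores$level == lv, ]),
                     file.path(dir, paste0("gisd_", lv, ".csv")),
                     row.names = FALSE)
  }
  invisible(dir)
}
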