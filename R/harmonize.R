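#' Deflate a currency indicator and take natural logs
#'
#' Currency-based, open-ended-scale indicators (tax revenue, gross wage,
#' household income) are adjusted for purchasing power by a per-year price
#' index and log-transformed: `value <- log(value / index_year)`. The price
#' index is a user input with a declared base year; with `price_index =
#' NULL` an identity deflator is used and a warning logged, since final
#' scores are invariant to any year-constant rescaling but real purchasing
#' power correction needs a real index.
#'
#' @param panel an `indicator_panel`.
#' @param indicator indicator name.
#' @param price_index data frame `year`, `index` (index > 0), or `NULL` for
#'   the identity deflator.
#' @return updated `indicator_panel`.
#' @export
deflate_and_log <- function(panel, indicator, price_index = NULL) {
  refuse_if_applied(panel, indicator, "deflate_and_log")
  rows <- panel_rows(panel, indicator)
  if (!any(rows)) abort_di(paste0("no rows for indicator '", indicator, "'"), "missing_source")
  vals <- panel$value[rows]
  if (any(vals <= 0)) {
    bad <- which(rows)[vals <= 0]
    ex <- as.data.frame(panel)[utils::head(bad, 5), c("region_id", "year")]
    abort_di(paste0("non-positive values for '", indicator, "' at e.g. ",
                    paste(paste0(ex$region_id, "/", ex$year), collapse = ", ")),
             "nonpositive_value")
  }
  if (is.null(price_index)) {
    warn_di(paste0("no price index supplied for '", indicator,
                   "'; using identity deflator"), "identity_deflator")
    idx <- rep(1, sum(rows))
  } else {
    m <- match(panel$year[rows], price_index$year)
    if (anyNA(m)) abort_di("price index missing for some panel years", "bad_price_index")
    idx <- price_index$index[m]
    if (any(idx <= 0)) abort_di("price index must be strictly positive", "bad_price_index")
  }
  panel$value[rows] <- log(vals / idx)
  record_correction(panel, indicator, "deflate_and_log",
                    list(identity = is.null(price_index)), sum(rows))
}

#' Reporting-break (level-shift) correction
#'
#' A changeover in a reporting procedure can shift the level of a time
#' series at a known year. The jump is estimated net of secular trend by
#' regressing the indicator on region fixed effects, a linear year trend and
#' a post-break step dummy; the step coefficient `delta` is the estimated
#' level change. Applying the correction shifts all pre-break values by
#' `+delta`, adapting the old series to the post-break level.
#'
#' @param panel an `indicator_panel`.
#' @param indicator indicator name.
#' @param break_year first year on the new reporting level; years before it
#'   are "pre-break".
#' @return `fit_break_correction`: an object of class `break_model` with
#'   elements `indicator`, `break_year`, `delta`, `n_regions`, `sigma`.
#' @export
fit_break_correction <- function(panel, indicator, break_year) {
  rows <- as.data.frame(panel)[panel_rows(panel, indicator), ]
  pre <- rows$year < break_year
  if (!any(pre) || !all(c(TRUE, FALSE) %in% unique(pre))) {
    abort_di("need observations on both sides of the break year", "bad_break_window")
  }
  d <- data.frame(value = rows$value, region = factor(rows$region_id),
                  year_c = rows$year - break_year, post = as.numeric(rows$year >= break_year))
  fml <- if (nlevels(d$region) > 1) value ~ region + year_c + post else value ~ year_c + post
  fit <- stats::lm(fml, data = d)
  delta <- unname(coef(fit)["post"])
  if (!is.finite(delta)) abort_di("break shift not estimable (collinear design)", "fit_failure")
  structure(list(indicator = indicator, break_year = break_year, delta = delta,
                 n_regions = nlevels(d$region),
                 sigma = stats::sigma(fit)),
            class = "break_model")
}

#' @rdname fit_break_correction
#' @param model a `break_model`.
#' @export
apply_break_correction <- function(panel, model) {
  stopifnot(inherits(model, "break_model"))
  refuse_if_applied(panel, model$indicator, "break")
  rows <- panel_rows(panel, model$indicator) & panel$year < model$break_year
  panel$value[rows] <- panel$value[rows] + model$delta
  record_correction(panel, model$indicator, "break",
                    list(break_year = model$break_year, delta = model$delta),
                    sum(rows))
}

#' School-reform (double-cohort) correction
#'
#' The shortening of the upper secondary school track produced double
#' graduation cohorts in specific state-years, inflating the denominator of
#' the school-leaver indicator and depressing its value in those cells. The
#' affected (state, year) cells are supplied explicitly. The cell effect is
#' estimated by regressing the indicator on region fixed effects, year fixed
#' effects and a reform-cell dummy; applying the correction subtracts the
#' fitted effect in the affected cells only.
#'
#' @param panel an `indicator_panel`.
#' @param indicator indicator name (the school-leaver indicator).
#' @param reform_cells data frame `state_id`, `year` of affected cells.
#' @param hierarchy a `region_hierarchy` (maps regions to states).
#' @return `fit_g8_correction`: an object of class `g8_model` with the
#'   estimated `effect` (in units of the indicator; negative when the reform
#'   depresses the value) and the usable `cells`.
#' @export
fit_g8_correction <- function(panel, indicator, reform_cells, hierarchy) {
  rows <- as.data.frame(panel)[panel_rows(panel, indicator), ]
  if (!nrow(rows)) abort_di(paste0("no rows for '", indicator, "'"), "missing_source")
  rows$state_id <- region_state(hierarchy, rows$region_id)
  if (is.null(reform_cells) || !nrow(reform_cells)) {
    return(structure(list(indicator = indicator, effect = 0,
                          cells = tibble::tibble(state_id = character(0), year = integer(0))),
                     class = "g8_model"))
  }
  reform_cells <- tibble::as_tibble(reform_cells)
  reform_cells$state_id <- as.character(reform_cells$state_id)
  reform_cells$year <- as.integer(reform_cells$year)
  key <- paste(rows$state_id, rows$year)
  ckey <- paste(reform_cells$state_id, reform_cells$year)
  present <- ckey %in% key
  if (any(!present)) {
    warn_di(paste0("reform cell(s) with no data skipped: ",
                   paste(ckey[!present], collapse = "; ")), "empty_reform_cell")
    reform_cells <- reform_cells[present, ]
    ckey <- ckey[present]
  }
  if (!nrow(reform_cells)) {
    return(structure(list(indicator = indicator, effect = 0,
                          cells = reform_cells), class = "g8_model"))
  }
  d <- data.frame(value = rows$value, region = factor(rows$region_id),
                  year = factor(rows$year), reform = as.numeric(key %in% ckey))
  terms <- c(if (nlevels(d$region) > 1) "region",
             if (nlevels(d$year) > 1) "year", "reform")
  fit <- stats::lm(as.formula(paste("value ~", paste(terms, collapse = " + "))), data = d)
  effect <- unname(coef(fit)["reform"])
  if (!is.finite(effect)) abort_di("reform effect not estimable", "fit_failure")
  structure(list(indicator = indicator, effect = effect, cells = reform_cells),
            class = "g8_model")
}

#' @rdname fit_g8_correction
#' @param model a `g8_model`.
#' @export
apply_g8_correction <- function(panel, model, hierarchy) {
  stopifnot(inherits(model, "g8_model"))
  refuse_if_applied(panel, model$indicator, "g8")
  if (!nrow(model$cells)) {
    return(record_correction(panel, model$indicator, "g8",
                             list(effect = 0, n_cells = 0), 0L))
  }
  state <- region_state(hierarchy, panel$region_id)
  key <- paste(state, panel$year)
  ckey <- paste(model$cells$state_id, model$cells$year)
  rows <- panel_rows(panel, model$indicator) & key %in% ckey
  panel$value[rows] <- panel$value[rows] - model$effect
  record_correction(panel, model$indicator, "g8",
                    list(effect = model$effect, n_cells = nrow(model$cells)),
                    sum(rows))
}

region_state <- function(hierarchy, ids) {
  df <- as.data.frame(hierarchy)
  lut <- unique(rbind(
    setNames(df[c("region_id", "state_id")], c("id", "state_id")),
    setNames(df[c("gvb_id", "state_id")], c("id", "state_id")),
    setNames(df[c("district_id", "state_id")], c("id", "state_id"))))
  lut <- lut[!duplicated(lut$id), ]
  lut$state_id[match(ids, lut$id)]
}

#' East-West distributional correction
#'
#' Where historically grown differences between East and West German regions
#' leave an indicator bimodal (the share of employees without professional
#' qualification sits on a different comparison standard in the East), the
#' average West-East difference `delta = mean(West) - mean(East)` is
#' estimated on the pooled pre-correction panel and added to all East
#' regions, removing the East-West gap. The fitted model records a
#' before/after bimodality diagnostic ([count_density_modes()]).
#'
#' @param panel an `indicator_panel`.
#' @param indicator indicator name.
#' @param hierarchy a `region_hierarchy` carrying the East-state set.
#' @param min_regions minimum regions required on each side.
#' @return `fit_east_west_correction`: an object of class `east_west_model`
#'   with `delta`, region counts, and the pre-correction mode count.
#' @export
fit_east_west_correction <- function(panel, indicator, hierarchy, min_regions = 5) {
  rows <- as.data.frame(panel)[panel_rows(panel, indicator), ]
  if (!nrow(rows)) abort_di(paste0("no rows for '", indicator, "'"), "missing_source")
  east <- east_flag(hierarchy, rows$region_id)
  n_east <- length(unique(rows$region_id[east]))
  n_west <- length(unique(rows$region_id[!east]))
  if (n_east < min_regions || n_west < min_regions) {
    abort_di(paste0("need at least ", min_regions, " regions on each side ",
                    "(East: ", n_east, ", West: ", n_west, ")"), "too_few_regions")
  }
  delta <- mean(rows$value[!east]) - mean(rows$value[east])
  structure(list(indicator = indicator, delta = delta,
                 n_east = n_east, n_west = n_west,
                 modes_before = count_density_modes(rows$value)),
            class = "east_west_model")
}

#' @rdname fit_east_west_correction
#' @param model an `east_west_model`.
#' @param check_indicators optional character vector of other indicators to
#'   correlate with the corrected one (on shared region-years); correlations
#'   and a sign report are attached to the returned panel's ledger entry and
#'   a warning is raised when a correlation sign contradicts the polarity
#'   expectation implied by `specs`.
#' @param specs indicator specs used for the sign expectation.
#' @export
apply_east_west_correction <- function(panel, model, hierarchy,
                                       check_indicators = NULL, specs = NULL) {
  stopifnot(inherits(model, "east_west_model"))
  refuse_if_applied(panel, model$indicator, "east_west")
  rows <- panel_rows(panel, model$indicator)
  east <- east_flag(hierarchy, panel$region_id) & rows
  panel$value[east] <- panel$value[east] + model$delta
  out <- record_correction(panel, model$indicator, "east_west",
                           list(delta = model$delta), sum(east))
  if (!is.null(check_indicators) && !is.null(specs)) {
    rep <- east_west_correlation_check(out, model$indicator, check_indicators, specs)
    bad <- rep$correlation * rep$expected_sign < 0
    if (any(bad, na.rm = TRUE)) {
      warn_di(paste0("unexpected correlation sign after East-West correction: ",
                     paste(rep$other[bad], collapse = ", ")), "unexpected_sign")
    }
    attr(out, "east_west_check") <- rep
  }
  out
}

east_west_correlation_check <- function(panel, indicator, others, specs) {
  df <- as.data.frame(panel)
  base <- df[df$indicator == indicator, c("region_id", "year", "value")]
  pol <- setNames(ifelse(specs$polarity == "increasing", 1, -1), specs$indicator)
  out <- lapply(others, function(o) {
    oth <- df[df$indicator == o, c("region_id", "year", "value")]
    m <- merge(base, oth, by = c("region_id", "year"))
    r <- if (nrow(m) >= 3) stats::cor(m$value.x, m$value.y) else NA_real_
    tibble::tibble(other = o, correlation = r,
                   expected_sign = unname(pol[indicator] * pol[o]))
  })
  dplyr::bind_rows(out)
}

#' Carry a year's values forward into a gap
#'
#' Copies `from_year` values into missing `to_year` cells of an indicator
#' (per region, at the region's own level), flagging them as imputed.
#' Regions missing `from_year` are left to the model-based imputation.
#'
#' @param panel an `indicator_panel`.
#' @param indicator indicator name.
#' @param from_year,to_year donor and target years.
#' @return updated `indicator_panel`.
#' @export
carry_forward_gap <- function(panel, indicator, from_year, to_year) {
  refuse_if_applied(panel, indicator, paste0("carry_forward_", from_year, "_", to_year))
  df <- as.data.frame(panel)
  src <- df[panel_rows(panel, indicator, from_year), ]
  if (!nrow(src)) abort_di(paste0("no '", indicator, "' rows in ", from_year), "missing_source")
  have_to <- df$region_id[panel_rows(panel, indicator, to_year)]
  new_rows <- src[!(src$region_id %in% have_to), ]
  if (nrow(new_rows)) {
    new_rows$year <- as.integer(to_year)
    new_rows$imputed <- TRUE
    out <- restore_panel(dplyr::bind_rows(df, new_rows), panel)
  } else {
    out <- panel
  }
  record_correction(out, indicator, paste0("carry_forward_", from_year, "_", to_year),
                    list(from = from_year, to = to_year), nrow(new_rows))
}

#' Random-intercept imputation of missing years
#'
#' Missing years of an indicator (typically the start of the panel, before
#' the source series begins) are predicted from a linear random-intercept
#' model fitted to the observed region time series: a global intercept and
#' linear year trend, plus a region-level random intercept
#' (`value ~ year + (1 | region)` via [lme4::lmer()]). Observed cells are
#' never overwritten; imputed cells are flagged.
#'
#' @param panel an `indicator_panel`.
#' @param indicator indicator name.
#' @param years_to_fill years whose missing cells should be predicted.
#' @param level spatial level of the grid to complete (default: the level
#'   of the indicator's observed rows).
#' @param hierarchy a `region_hierarchy` defining the region grid.
#' @param min_obs_years minimum observed years required per region for that
#'   region's random intercept to be identified (regions below the minimum
#'   are still predicted, from the fixed trend alone).
#' @return list with elements `panel` (updated) and `model` (class
#'   `imputation_model`: fixed effects, random-intercept table, sigma,
#'   years imputed).
#' @export
impute_random_intercept <- function(panel, indicator, years_to_fill, hierarchy,
                                    level = NULL, min_obs_years = 3) {
  obs <- as.data.frame(panel)[panel_rows(panel, indicator), ]
  if (!nrow(obs)) abort_di(paste0("no observed data for '", indicator, "'"), "missing_source")
  level <- level %||% obs$level[1]
  obs <- obs[obs$level == level, ]
  n_years <- table(obs$region_id)
  if (stats::median(n_years) < min_obs_years) {
    abort_di(paste0("fewer than ", min_obs_years, " observed years for most regions"),
             "too_few_years")
  }
  year0 <- mean(obs$year)
  d <- data.frame(value = obs$value, year_c = obs$year - year0,
                  region = factor(obs$region_id))
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(value ~ year_c + (1 | region), data = d,
               control = lme4::lmerControl(check.conv.singular = "ignore"))))
  todo <- missing_cells(panel, hierarchy, indicator, level, years_to_fill)
  if (nrow(todo)) {
    nd <- data.frame(year_c = todo$year - year0,
                     region = factor(todo$region_id, levels = levels(d$region)))
    pred <- predict(fit, newdata = nd, allow.new.levels = TRUE)
    new_rows <- tibble::tibble(region_id = todo$region_id, level = level,
                               year = as.integer(todo$year), indicator = indicator,
                               value = as.numeric(pred), imputed = TRUE)
    out <- restore_panel(dplyr::bind_rows(as.data.frame(panel), new_rows), panel)
  } else {
    out <- panel
  }
  fe <- lme4::fixef(fit)
  re <- lme4::ranef(fit)$region
  model <- structure(list(indicator = indicator,
                          intercept = unname(fe[1]), slope = unname(fe["year_c"]),
                          year_center = year0,
                          region_effects = tibble::tibble(region_id = rownames(re),
                                                          effect = re[["(Intercept)"]]),
                          sigma = stats::sigma(fit),
                          years_imputed = sort(unique(todo$year))),
                     class = "imputation_model")
  out <- record_correction(out, indicator, "impute_random_intercept",
                           list(years = years_to_fill), nrow(todo))
  list(panel = out, model = model)
}

#' Full harmonization pipeline
#'
#' Runs the harmonization steps in a fixed order chosen so that artefact
#' removal precedes imputation (the imputation model never learns
#' artefacts): district-to-GVB broadcast, deflation/log transforms,
#' reporting-break correction, school-reform correction, East-West
#' correction, gap carry-forward, then random-intercept imputation of the
#' remaining missing years. After harmonization every indicator is complete
#' at its native level for all panel years.
#'
#' @param panel raw `indicator_panel`.
#' @param hierarchy a `region_hierarchy`.
#' @param specs indicator specs.
#' @param config list of harmonization parameters:
#'   `break_year` (named numeric, per break-corrected indicator),
#'   `g8_cells` (data frame `state_id`, `year`),
#'   `gap` (list `from_year`, `to_year`),
#'   `price_index` (data frame `year`, `index` or `NULL`),
#'   `years` (panel window, default 1998:2019).
#' @return list `panel` (complete), `models` (fitted correction models),
#'   `ledger` (the correction ledger).
#' @export
harmonize_panel <- function(panel, hierarchy, specs, config = list()) {
  validate_indicator_specs(specs)
  years <- config$years %||% 1998:2019
  models <- list()

  # 1. broadcast district-resolved years of GVB-native indicators
  for (i in seq_len(nrow(specs))) {
    sp <- specs[i, ]
    dy <- as.integer(unlist(sp$district_only_years))
    if (sp$native_level == "gvb" && length(dy)) {
      panel <- broadcast_district_to_gvb(panel, hierarchy, sp$indicator, dy)
    }
  }

  # 2. deflate + log
  for (ind in specs$indicator[specs$transform == "log_after_deflation"]) {
    panel <- deflate_and_log(panel, ind, price_index = config$price_index)
  }
  for (ind in specs$indicator[specs$transform == "log"]) {
    rows <- panel_rows(panel, ind)
    if (any(panel$value[rows] <= 0)) abort_di("non-positive values under log transform", "nonpositive_value")
    panel$value[rows] <- log(panel$value[rows])
    panel <- record_correction(panel, ind, "log", list(), sum(rows))
  }

  # 3. reporting-break correction
  for (ind in specs$indicator[vapply(specs$corrections, function(x) "break" %in% unlist(x), logical(1))]) {
    cb <- config$break_year
    by <- if (is.null(cb)) NULL else if (!is.null(names(cb))) cb[[ind]] else cb
    if (is.null(by)) abort_di(paste0("break_year not configured for '", ind, "'"), "bad_config")
    m <- fit_break_correction(panel, ind, as.integer(by))
    panel <- apply_break_correction(panel, m)
    models[[paste0("break_", ind)]] <- m
  }

  # 4. school-reform correction
  g8_ind <- specs$indicator[vapply(specs$corrections, function(x) "g8" %in% unlist(x), logical(1))]
  for (ind in g8_ind) {
    m <- fit_g8_correction(panel, ind, config$g8_cells, hierarchy)
    panel <- apply_g8_correction(panel, m, hierarchy)
    models[[paste0("g8_", ind)]] <- m
  }

  # 5. East-West correction
  ew_ind <- specs$indicator[vapply(specs$corrections, function(x) "east_west" %in% unlist(x), logical(1))]
  for (ind in ew_ind) {
    m <- fit_east_west_correction(panel, ind, hierarchy,
                                  min_regions = config$ew_min_regions %||% 5)
    check <- setdiff(specs$indicator[specs$dimension ==
                                       specs$dimension[specs$indicator == ind]], ind)
    panel <- apply_east_west_correction(panel, m, hierarchy,
                                        check_indicators = check, specs = specs)
    models[[paste0("east_west_", ind)]] <- m
  }

  # 6. gap carry-forward
  gap <- config$gap
  if (!is.null(gap)) {
    for (i in seq_len(nrow(specs))) {
      sp <- specs[i, ]
      if (gap$to_year %in% as.integer(unlist(sp$gap_years))) {
        panel <- carry_forward_gap(panel, sp$indicator, gap$from_year, gap$to_year)
      }
    }
  }

  # 7. random-intercept imputation of everything still missing
  for (i in seq_len(nrow(specs))) {
    sp <- specs[i, ]
    todo <- missing_cells(panel, hierarchy, sp$indicator, sp$native_level, years)
    if (nrow(todo)) {
      res <- impute_random_intercept(panel, sp$indicator, unique(todo$year),
                                     hierarchy, level = sp$native_level)
      panel <- res$panel
      models[[paste0("impute_", sp$indicator)]] <- res$model
    }
  }

  # goal state: zero missing cells at native level over the full window
  for (i in seq_len(nrow(specs))) {
    sp <- specs[i, ]
    left <- missing_cells(panel, hierarchy, sp$indicator, sp$native_level, years)
    if (nrow(left)) {
      abort_di(paste0("harmonization left ", nrow(left), " missing cells for '",
                      sp$indicator, "'"), "incomplete_harmonization")
    }
  }

  list(panel = panel, models = models, ledger = correction_ledger(panel))
}
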