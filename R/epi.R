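#' Direct age standardization
#'
#' Standardized rate per 100,000:
#' `100000 * sum_a w_a * (count_a / pop_a) / sum_a w_a`, with `w_a` the
#' standard population weights. Age cells with zero population and zero
#' count are dropped with a warning (the remaining weights renormalize
#' through the denominator); zero population with a nonzero count is an
#' error.
#'
#' @param counts event counts per age group.
#' @param populations person-years per age group (same order).
#' @param standard data frame `age_group`, `weight` (default [esp2013()]);
#'   or a numeric weight vector aligned with `counts`.
#' @param age_group optional age-group labels aligning `counts` with the
#'   standard; defaults to the standard's own order.
#' @return standardized rate per 100,000 (scalar).
#' @export
age_standardize <- function(counts, populations, standard = esp2013(),
                            age_group = NULL) {
  if (is.numeric(standard)) {
    w <- standard
    if (length(w) != length(counts)) abort_di("weights and counts differ in length", "bad_input")
  } else {
    labels <- age_group %||% standard$age_group
    m <- match(labels, standard$age_group)
    if (anyNA(m)) abort_di("age groups not found in the standard", "bad_input")
    w <- standard$weight[m]
  }
  if (length(counts) != length(populations)) {
    abort_di("counts and populations differ in length", "bad_input")
  }
  if (any(w <= 0)) abort_di("standard weights must be positive", "bad_standard")
  zero_pop <- populations == 0
  if (any(zero_pop & counts > 0)) {
    abort_di("zero population in an age cell with nonzero count", "zero_population")
  }
  if (any(zero_pop)) {
    warn_di(paste0("dropping ", sum(zero_pop), " empty age cell(s); ",
                   "standard weights renormalized"), "empty_age_cell")
    counts <- counts[!zero_pop]; populations <- populations[!zero_pop]
    w <- w[!zero_pop]
  }
  1e5 * sum(w * counts / populations) / sum(w)
}

#' Age-standardized rates and declines by deprivation group
#'
#' Joins district outcomes to yearly index quintiles, collapses quintiles
#' to the three-group convention (low = quintile 1, mid = quintiles 2-4,
#' high = quintile 5), sums events and person-years by group, sex, year and
#' age, and standardizes. Declines compare the first and last observed
#' year per group and sex.
#'
#' @param outcomes tibble `district_id`, `year`, `sex`, `age_group`,
#'   `events`, `population`.
#' @param scores district-level score rows (`region_id`, `year`,
#'   `quintile`). Scores for a single year are linked time-constantly (the
#'   usual design when external outcome data are joined to one reference
#'   index year); multi-year scores are matched year by year.
#' @param standard standard population (default [esp2013()]).
#' @return list `rates` (group x sex x year standardized rates per
#'   100,000) and `declines` (absolute and relative first-to-last-year
#'   decline per group and sex).
#' @export
quintile_group_rates <- function(outcomes, scores, standard = esp2013()) {
  sc <- tibble::as_tibble(scores)
  if (!"year" %in% names(sc) || length(unique(sc$year)) == 1) {
    # time-constant linkage to a single reference index year
    df <- dplyr::inner_join(tibble::as_tibble(outcomes),
                            sc[c("region_id", "quintile")],
                            by = c(district_id = "region_id"))
  } else {
    df <- dplyr::inner_join(tibble::as_tibble(outcomes),
                            sc[c("region_id", "year", "quintile")],
                            by = c(district_id = "region_id", year = "year"))
  }
  if (!nrow(df)) abort_di("no overlap between outcomes and scores", "missing_source")
  df$group <- c("low", "mid", "mid", "mid", "high")[df$quintile]
  cells <- df |>
    dplyr::group_by(.data$group, .data$sex, .data$year, .data$age_group) |>
    dplyr::summarise(events = sum(.data$events),
                     population = sum(.data$population), .groups = "drop")
  rates <- cells |>
    dplyr::group_by(.data$group, .data$sex, .data$year) |>
    dplyr::summarise(rate = age_standardize(.data$events, .data$population,
                                            standard = standard,
                                            age_group = .data$age_group),
                     .groups = "drop")
  declines <- rates |>
    dplyr::group_by(.data$group, .data$sex) |>
    dplyr::summarise(first_year = min(.data$year), last_year = max(.data$year),
                     first_rate = .data$rate[which.min(.data$year)],
                     last_rate = .data$rate[which.max(.data$year)],
                     .groups = "drop")
  declines$absolute_decline <- declines$first_rate - declines$last_rate
  declines$relative_decline <- declines$absolute_decline / declines$first_rate
  list(rates = rates, declines = declines)
}

#' Multilevel Poisson incidence rate ratios by deprivation quintile
#'
#' Log-linear model of event counts on 5-year age-group effects and
#' quintile indicators (reference = lowest-deprivation quintile), with the
#' log person-years as offset and, by default, a district-level random
#' intercept (`lme4::glmer`, Poisson). Sexes are modelled separately.
#' Returned rate ratios are exponentiated quintile coefficients with Wald
#' 95% intervals on the log scale. With `random_intercept = FALSE` a plain
#' Poisson GLM is fitted (the single-stratum, two-district case then
#' reproduces the hand-computed ratio exactly).
#'
#' @param outcomes tibble `district_id`, `year`, `sex`, `age_group`,
#'   `events`, `population` (integer events).
#' @param quintiles district quintile assignment: tibble `region_id`,
#'   `quintile` (time-constant) or `region_id`, `year`, `quintile`.
#' @param random_intercept include `(1 | district)`.
#' @param conf_level confidence level for the Wald intervals.
#' @return tibble `sex`, `quintile`, `rr`, `conf_low`, `conf_high`
#'   (`rr = 1` for the reference quintile), plus a `converged` flag.
#' @export
poisson_rate_ratios <- function(outcomes, quintiles, random_intercept = TRUE,
                                conf_level = 0.95) {
  df <- tibble::as_tibble(outcomes)
  if (any(df$events %% 1 != 0)) abort_di("non-integer event counts", "bad_counts")
  q <- tibble::as_tibble(quintiles)
  by <- if ("year" %in% names(q)) c(district_id = "region_id", year = "year") else c(district_id = "region_id")
  df <- dplyr::inner_join(df, q[c(intersect(c("region_id", "year"), names(q)), "quintile")],
                          by = by)
  if (!nrow(df)) abort_di("no overlap between outcomes and quintiles", "missing_source")
  df <- df[df$population > 0, ]
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  out <- lapply(unique(df$sex), function(sx) {
    d <- df[df$sex == sx, ]
    d$age_group <- factor(d$age_group)
    d$quintile_f <- factor(d$quintile, levels = sort(unique(d$quintile)))
    d$district <- factor(d$district_id)
    use_age <- nlevels(d$age_group) > 1
    rhs <- if (use_age) "age_group + quintile_f" else "quintile_f"
    ok <- TRUE
    if (random_intercept) {
      fml <- as.formula(paste("events ~", rhs, "+ (1 | district)"))
      fit <- tryCatch(
        suppressMessages(lme4::glmer(fml, data = d, family = stats::poisson,
                                     offset = log(d$population),
                                     control = lme4::glmerControl(calc.derivs = FALSE))),
        warning = function(w) suppressWarnings(suppressMessages(
          lme4::glmer(fml, data = d, family = stats::poisson,
                      offset = log(d$population),
                      control = lme4::glmerControl(calc.derivs = FALSE)))))
      cf <- lme4::fixef(fit)
      se <- sqrt(diag(as.matrix(vcov(fit))))
    } else {
      fml <- as.formula(paste("events ~", rhs))
      fit <- stats::glm(fml, data = d, family = stats::poisson,
                        offset = log(d$population))
      cf <- coef(fit)
      se <- sqrt(diag(vcov(fit)))
      ok <- fit$converged
    }
    names(se) <- names(cf)
    qlev <- levels(d$quintile_f)
    rows <- lapply(seq_along(qlev), function(i) {
      if (i == 1) {
        tibble::tibble(sex = sx, quintile = as.integer(qlev[1]), rr = 1,
                       conf_low = NA_real_, conf_high = NA_real_, converged = ok)
      } else {
        nm <- paste0("quintile_f", qlev[i])
        b <- cf[[nm]]; s <- se[[nm]]
        if (!is.finite(b) || !is.finite(s)) {
          tibble::tibble(sex = sx, quintile = as.integer(qlev[i]), rr = NA_real_,
                         conf_low = NA_real_, conf_high = NA_real_, converged = FALSE)
        } else {
          tibble::tibble(sex = sx, quintile = as.integer(qlev[i]), rr = exp(b),
                         conf_low = exp(b - z * s), conf_high = exp(b + z * s),
                         converged = ok)
        }
      }
    })
    dplyr::bind_rows(rows)
  })
  dplyr::bind_rows(out)
}

#' Deprivation-gradient regression
#'
#' Least-squares fit of a district-level outcome on the deprivation index.
#' Since the index spans `[0, 1]` at the district level, the slope is the
#' estimated outcome difference between the least and most deprived
#' district; the adjusted R-squared reports the share of regional variation
#' the index accounts for.
#'
#' @param outcome numeric outcome per district.
#' @param gisd index value per district (same order).
#' @param conf_level confidence level for the slope interval.
#' @return list `slope`, `range_estimate` (= slope), `adj_r_squared`,
#'   `conf_low`, `conf_high`, `n`.
#' @export
gradient_regression <- function(outcome, gisd, conf_level = 0.95) {
  if (length(outcome) != length(gisd)) abort_di("outcome and index differ in length", "bad_input")
  keep <- is.finite(outcome) & is.finite(gisd)
  if (sum(keep) < 3) abort_di("need at least 3 districts", "too_few_regions")
  fit <- stats::lm(outcome[keep] ~ gisd[keep])
  slope <- unname(coef(fit)[2])
  ci <- stats::confint(fit, level = conf_level)[2, ]
  list(slope = slope, range_estimate = slope,
       adj_r_squared = summary(fit)$adj.r.squared,
       conf_low = unname(ci[1]), conf_high = unname(ci[2]),
       n = sum(keep))
}

#' Read an aggregated outcome CSV
#'
#' Layout: `district_id,year,sex,age_group,events,population`.
#'
#' @param path file path.
#' @return tibble of outcomes.
#' @export
read_outcomes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(district_id = "character"))
  need <- c("district_id", "year", "sex", "age_group", "events", "population")
  miss <- setdiff(need, names(df))
  if (length(miss)) abort_di(paste0("outcomes missing columns: ",
                                    paste(miss, collapse = ", ")), "bad_input")
  tibble::as_tibble(df)
}
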