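#' Synthetic-data configuration
#'
#' Parameters for the synthetic replica of the German administrative
#' hierarchy and its indicator panel. The scaled default (500
#' municipalities, 200 GVB, 50 districts, 12 ROR, 5 NUTS-2 in 5 states)
#' keeps an end-to-end build fast; `full_scale = TRUE` switches to the real
#' level counts (10,799 / 4,411 / 401 / 96 / 38 in 16 states).
#'
#' The generated panel has, per district and year, three correlated latent
#' deprivation factors (education, employment, income; unit variance, AR(1)
#' over years) whose cross-correlations default to the observed
#' subdimension-score correlations (0.52-0.69). Indicators are noisy affine
#' images of the factors with the published loading pattern, plus injected
#' pathologies: a reporting-break level shift on the two
#' employee-qualification indicators, school-reform dips in configured
#' state-years, an East offset on the employees-without-qualification
#' indicator (bimodality), the source availability calendar (missing early
#' years, a gap year), and district-only resolution of the unemployment and
#' employment rates in 1998-2000.
#'
#' @param seed integer seed; all generation is deterministic given the seed.
#' @param full_scale use the real level counts.
#' @param ... overrides for any config entry (see the function body for the
#'   complete list: level counts, `years`, `rho` (AR(1) coefficient),
#'   `base_weight` (share of factor variance that is region-constant),
#'   `gvb_factor_sd` mixing weight for GVB-level factor noise, indicator
#'   location/scale table `units`, artefact block `artefacts`, population
#'   log-normal parameters, inflation rate).
#' @return a `synth_config` list.
#' @export
synth_config <- function(seed = 1, full_scale = FALSE, ...) {
  cfg <- list(
    seed = as.integer(seed),
    n_municipality = if (full_scale) 10799L else 500L,
    n_gvb          = if (full_scale) 4411L else 200L,
    n_district     = if (full_scale) 401L else 50L,
    n_ror          = if (full_scale) 96L else 12L,
    n_nuts2        = if (full_scale) 38L else 5L,
    n_state        = if (full_scale) 16L else 5L,
    east_states    = if (full_scale) sprintf("%02d", 12:16) else c("04", "05"),
    years = 1998:2019,
    rho = 0.9,            # AR(1) of the latent factors' temporal part
    base_weight = 0.8,    # share of factor variance that is region-constant
    gvb_factor_share = 0.85,  # district-factor share in the GVB-level factor
    dim_cor = matrix(c(1, 0.52, 0.69,
                       0.52, 1, 0.66,
                       0.69, 0.66, 1), 3, 3,
                     dimnames = list(c("education", "employment", "income"),
                                     c("education", "employment", "income"))),
    loadings = published_loadings(),
    # location/scale mapping latent z-scores to natural indicator units;
    # currency indicators are log-normal and inflated by `inflation` per year
    units = tibble::tribble(
      ~indicator,                             ~mu,        ~sigma, ~log_scale,
      "employees_with_university_degree",     12,         4,      FALSE,
      "employees_without_qualification",      12,         1.5,    FALSE,
      "school_leavers_without_qualification", 6,          1.5,    FALSE,
      "employment_rate",                      55,         6,      FALSE,
      "unemployment_rate",                    8,          2.5,    FALSE,
      "gross_wage",                           log(3000),  0.15,   TRUE,
      "household_income",                     log(1800),  0.12,   TRUE,
      "debtor_quota",                         9,          2,      FALSE,
      "tax_revenue",                          log(600),   0.30,   TRUE
    ),
    inflation = 0.02, inflation_base_year = 2015L,
    pop_meanlog = 8, pop_sdlog = 1,
    artefacts = list(
      break_indicators = c("employees_with_university_degree",
                           "employees_without_qualification"),
      break_year = 2013L,   # first year on the new reporting level
      break_delta = 1.5,    # post-break level minus pre-break level
      g8_cells = tibble::tibble(state_id = c("01", "02"), year = c(2011L, 2012L)),
      g8_effect = -2,       # double cohorts depress the school-leaver share
      east_west_indicator = "employees_without_qualification",
      east_west_delta = 6,  # East values sit this far below the West
      gap_from = 2011L, gap_to = 2012L
    ),
    outcomes = list(
      rr_target = c(men = 1.46, women = 1.23),
      rate_target = c(men = 600, women = 450),  # standardized per 100,000 at reference
      age_slope = 0.09,        # log-linear age gradient of the baseline rate
      time_trend = -0.035,     # yearly log-linear decline of rates
      trend_gisd = -0.010,     # extra decline per unit deprivation
      frailty_sd = 0.05,       # district-level log-normal noise
      le_intercept = c(men = 81.5, women = 85.0),
      le_slope = c(men = -6.0, women = -3.2),
      le_noise_sd = c(men = 0.45, women = 0.35)
    )
  )
  dots <- list(...)
  for (nm in names(dots)) cfg[[nm]] <- dots[[nm]]
  structure(cfg, class = "synth_config")
}

#' Configuration for loading-recovery experiments
#'
#' A stripped-down design for checking that the pooled PCA recovers a known
#' loading pattern: a flat hierarchy (one municipality per GVB per
#' district, so every indicator varies at the same grain), independent
#' factor draws across regions and years (no AR persistence, no
#' region-constant component, so the pooled observations are i.i.d.), no
#' artefacts, and no availability calendar. The default 263 regions over
#' 2001-2019 give 4,997 pooled observations per dimension.
#'
#' @param seed integer seed.
#' @param n_regions number of regions (= districts = GVB = municipalities).
#' @param years panel years.
#' @return a `synth_config`.
#' @export
recovery_config <- function(seed = 1, n_regions = 263, years = 2001:2019) {
  synth_config(
    seed,
    n_municipality = as.integer(n_regions), n_gvb = as.integer(n_regions),
    n_district = as.integer(n_regions), n_ror = 12L, n_nuts2 = 5L, n_state = 5L,
    years = years, rho = 0, base_weight = 0,
    apply_calendar = FALSE,
    artefacts = list(break_indicators = character(0), break_year = 2013L,
                     break_delta = 0, g8_cells = NULL, g8_effect = 0,
                     east_west_indicator = "", east_west_delta = 0,
                     gap_from = 2011L, gap_to = 2012L))
}

#' Generating coefficients for a target loading pattern
#'
#' A first principal component's loadings are not the same thing as the
#' signal coefficients of a one-factor generative model: the PC loadings of
#' a correlation matrix with off-diagonals `c_i c_j m_ij` are flatter than
#' the `c_i`. This solver inverts the relationship: given target
#' first-component loadings and a pairwise attenuation matrix `m` (1 for
#' indicator pairs sharing the same latent factor realization, `sqrt(a)`
#' when one of the pair only sees the district share `a` of a GVB-level
#' factor), it finds coefficients `c` in (0, 1) whose implied correlation
#' matrix has exactly the target first-component loadings (least squares
#' when an exact solution does not exist).
#'
#' @param target numeric vector of target loadings (signs ignored).
#' @param mix pairwise attenuation matrix (default: none).
#' @return numeric vector of generating coefficients (unsigned).
#' @export
solve_generating_loadings <- function(target, mix = NULL) {
  tgt <- abs(target)
  k <- length(tgt)
  if (is.null(mix)) mix <- matrix(1, k, k)
  pc1 <- function(R) {
    e <- eigen(R, symmetric = TRUE)
    L <- e$vectors[, 1] * sqrt(e$values[1])
    if (sum(L) < 0) -L else L
  }
  obj <- function(par) {
    cc <- stats::plogis(par)
    R <- outer(cc, cc) * mix
    diag(R) <- 1
    sum((pc1(R) - tgt)^2)
  }
  o <- stats::optim(stats::qlogis(pmin(pmax(tgt, 0.05), 0.95)), obj,
                    method = "BFGS", control = list(maxit = 500))
  if (o$value > 1e-4) {
    warn_di("target loading pattern not exactly representable; using closest fit",
            "inexact_loadings")
  }
  stats::plogis(o$par)
}

# distribute n children over m parents, each parent >= 1 child, deterministic
# under the active RNG state
split_children <- function(n, m) {
  if (n < m) abort_di("level counts not nested-compatible (fewer children than parents)",
                      "bad_counts")
  extra <- stats::rmultinom(1, n - m, prob = rep(1, m))[, 1]
  rep(seq_len(m), times = 1 + extra)
}

#' Generate a synthetic region hierarchy
#'
#' Nested geography with log-normal municipality populations (constant over
#' the years). Codes follow the AGS convention: 2-digit state prefix,
#' 5-digit district, 8-digit municipality; GVB, ROR and NUTS-2 units carry
#' their own code schemes.
#'
#' @param config a `synth_config`.
#' @return a `region_hierarchy`.
#' @export
generate_hierarchy <- function(config = synth_config()) {
  with_seed(config$seed, {
    if (config$n_nuts2 < config$n_state) {
      abort_di("need at least one NUTS-2 region per state", "bad_counts")
    }
    nuts2_state <- sort(split_children(config$n_nuts2, config$n_state))
    ror_nuts2 <- sort(split_children(config$n_ror, config$n_nuts2))
    district_ror <- sort(split_children(config$n_district, config$n_ror))
    gvb_district <- sort(split_children(config$n_gvb, config$n_district))
    muni_gvb <- sort(split_children(config$n_municipality, config$n_gvb))

    state_id <- sprintf("%02d", seq_len(config$n_state))
    nuts2_id <- sprintf("N%02d", seq_len(config$n_nuts2))
    ror_id <- sprintf("R%02d", seq_len(config$n_ror))
    district_state <- state_id[nuts2_state[ror_nuts2[district_ror]]]
    # district codes: state prefix + within-state counter
    within <- stats::ave(seq_along(district_state), district_state, FUN = seq_along)
    district_id <- paste0(district_state, sprintf("%03d", within))
    gvb_within <- stats::ave(seq_along(gvb_district), gvb_district, FUN = seq_along)
    gvb_id <- paste0("G", district_id[gvb_district], sprintf("%02d", gvb_within))
    muni_district <- gvb_district[muni_gvb]
    muni_within <- stats::ave(seq_along(muni_district), muni_district, FUN = seq_along)
    muni_id <- paste0(district_id[muni_district], sprintf("%03d", muni_within))

    pop <- round(stats::rlnorm(config$n_municipality,
                               config$pop_meanlog, config$pop_sdlog)) + 10
    df <- tidyr::expand_grid(idx = seq_len(config$n_municipality),
                             year = as.integer(config$years))
    df <- tibble::tibble(
      region_id = muni_id[df$idx],
      gvb_id = gvb_id[muni_gvb[df$idx]],
      district_id = district_id[muni_district[df$idx]],
      ror_id = ror_id[district_ror[muni_district[df$idx]]],
      nuts2_id = nuts2_id[ror_nuts2[district_ror[muni_district[df$idx]]]],
      state_id = district_state[muni_district[df$idx]],
      year = df$year,
      population = pop[df$idx])
    region_hierarchy(df, east_states = config$east_states)
  })
}

# latent factors: unit-variance, cross-dimension correlated, AR(1) over time
latent_factors <- function(ids, years, dim_cor, rho, base_weight) {
  n <- length(ids); t_n <- length(years); L <- chol(dim_cor)
  base <- matrix(rnorm(n * 3), n, 3) %*% L
  f <- array(0, dim = c(n, t_n, 3))
  u <- matrix(rnorm(n * 3), n, 3) %*% L
  for (t in seq_len(t_n)) {
    if (t > 1) {
      u <- rho * u + sqrt(1 - rho^2) * (matrix(rnorm(n * 3), n, 3) %*% L)
    }
    f[, t, ] <- sqrt(base_weight) * base + sqrt(1 - base_weight) * u
  }
  dimnames(f) <- list(ids, years, c("education", "employment", "income"))
  f
}

#' Generate a synthetic indicator panel with ground truth
#'
#' See [synth_config()] for the generative model and injected pathologies.
#' With all artefact switches off and zero noise, indicators are exact
#' affine images of the latent factors.
#'
#' @param config a `synth_config`.
#' @param hierarchy the matching `region_hierarchy`.
#' @return list `panel` (an `indicator_panel`), `truth` (list with the
#'   district- and GVB-level factor arrays, the signed loadings used, and
#'   the artefact parameters).
#' @export
generate_panel <- function(config, hierarchy) {
  specs <- default_indicator_specs()
  lt <- config$loadings
  lam <- setNames(lt$loading, lt$indicator)
  if (any(lam == 0)) abort_di("zero loading in config", "zero_loadings")
  art <- config$artefacts
  years <- config$years
  noise_scale <- config$noise_scale %||% 1

  # generating coefficients per dimension: chosen so the pooled PCA's
  # first-component loadings reproduce the configured target pattern
  gen_coef <- lam
  for (dm in unique(specs$dimension)) {
    sd_ <- specs[specs$dimension == dm, ]
    nl <- sd_$native_level
    mix <- outer(nl, nl, function(x, y)
      ifelse(x == y, 1, sqrt(config$gvb_factor_share)))
    cc <- solve_generating_loadings(lam[sd_$indicator], mix)
    gen_coef[sd_$indicator] <- sign(lam[sd_$indicator]) * cc
  }

  with_seed(config$seed + 1L, {
    districts <- sort(unique(hierarchy$district_id))
    gvbs <- parent_map(hierarchy, "gvb", "district")
    fd <- latent_factors(districts, years, config$dim_cor, config$rho,
                         config$base_weight)
    # GVB factor = mixture of the parent district factor and GVB noise
    a <- config$gvb_factor_share
    fg <- fd[match(gvbs$to_id, districts), , , drop = FALSE]
    fg <- sqrt(a) * fg + sqrt(1 - a) *
      array(rnorm(length(fg)), dim = dim(fg))
    dimnames(fg) <- list(gvbs$from_id, years, dimnames(fd)[[3]])

    rows <- list()
    infl <- function(yr) (1 + config$inflation)^(yr - config$inflation_base_year)
    for (i in seq_len(nrow(specs))) {
      sp <- specs[i, ]
      un <- config$units[config$units$indicator == sp$indicator, ]
      l <- gen_coef[[sp$indicator]]
      if (sp$native_level == "district") {
        ids <- districts; f <- fd[, , sp$dimension]
      } else {
        ids <- gvbs$from_id; f <- fg[, , sp$dimension]
      }
      z <- l * f + noise_scale * sqrt(max(0, 1 - l^2)) *
        matrix(rnorm(length(f)), nrow(f), ncol(f))
      val <- un$mu + un$sigma * z
      df <- tibble::tibble(region_id = rep(ids, times = length(years)),
                           level = sp$native_level,
                           year = rep(as.integer(years), each = length(ids)),
                           indicator = sp$indicator,
                           value = as.numeric(val))
      if (un$log_scale) df$value <- exp(df$value) * infl(df$year)

      # -- artefacts ---------------------------------------------------
      if (sp$indicator %in% art$break_indicators) {
        pre <- df$year < art$break_year
        df$value[pre] <- df$value[pre] - art$break_delta
      }
      if (sp$indicator == "school_leavers_without_qualification" &&
          !is.null(art$g8_cells) && nrow(art$g8_cells)) {
        st <- substr(df$region_id, 1, 2)
        hit <- paste(st, df$year) %in% paste(art$g8_cells$state_id, art$g8_cells$year)
        df$value[hit] <- df$value[hit] + art$g8_effect
      }
      if (identical(sp$indicator, art$east_west_indicator) &&
          (art$east_west_delta %||% 0) != 0) {
        east <- east_flag(hierarchy, df$region_id)
        df$value[east] <- df$value[east] - art$east_west_delta
      }

      # -- availability calendar --------------------------------------
      apply_calendar <- config$apply_calendar %||% TRUE
      keep <- !apply_calendar |
        (df$year >= sp$avail_start & df$year <= sp$avail_end &
           !(df$year %in% as.integer(unlist(sp$gap_years))))
      df <- df[keep, ]
      dy <- if (apply_calendar) as.integer(unlist(sp$district_only_years)) else integer(0)
      if (sp$native_level == "gvb" && length(dy)) {
        early <- df$year %in% dy
        early_rows <- df[early, ]
        df <- df[!early, ]
        # district rows = population-weighted mean of the (dropped) GVB values
        pops <- level_table(hierarchy, "gvb")
        m <- dplyr::inner_join(early_rows, pops, by = c("region_id", "year"))
        m$district_id <- gvbs$to_id[match(m$region_id, gvbs$from_id)]
        dagg <- m |>
          dplyr::group_by(region_id = .data$district_id, year = .data$year) |>
          dplyr::summarise(value = stats::weighted.mean(.data$value, .data$population),
                           .groups = "drop")
        dagg$level <- "district"; dagg$indicator <- sp$indicator
        df <- dplyr::bind_rows(df, dagg[c("region_id", "level", "year",
                                          "indicator", "value")])
      }
      rows[[sp$indicator]] <- df
    }
    panel <- indicator_panel(dplyr::bind_rows(rows))
    truth <- list(district_factors = fd, gvb_factors = fg,
                  loadings = lam, gen_coef = gen_coef, artefacts = art,
                  deprivation = apply(fd, c(1, 2), mean))
    list(panel = panel, truth = truth)
  })
}

#' Generate synthetic aggregated health outcomes
#'
#' Event counts by district, year, sex and 5-year age group, drawn as
#' `Poisson(pop_age * rate)` with
#' `rate = base(age, sex) * exp(trend * (year - y0) + beta_sex * gisd +
#' frailty_district)`. The deprivation effect `beta_sex` is calibrated so
#' that the expected rate ratio between the mean index values of the top
#' and bottom quintile equals the configured target (1.46 for men, 1.23 for
#' women by default); an extra `trend_gisd` term makes the secular decline
#' stronger in more deprived districts. The baseline is scaled so the
#' standardized rate at the reference (year `y0`, index 0.5) matches the
#' configured target per 100,000.
#'
#' @param config a `synth_config`.
#' @param scores district-level rows of a score panel (columns `region_id`,
#'   `year`, `gisd`, `quintile`).
#' @param hierarchy the matching `region_hierarchy`.
#' @param years outcome years (default 2003-2019).
#' @return tibble `district_id`, `year`, `sex`, `age_group`, `events`,
#'   `population`, with attribute `truth` (the betas and rate model
#'   parameters).
#' @export
generate_health_outcomes <- function(config, scores, hierarchy,
                                     years = 2003:2019) {
  oc <- config$outcomes
  std <- esp2013()
  scores <- tibble::as_tibble(scores)
  # single-year scores = time-constant linkage (outcomes joined to one
  # reference index year); multi-year scores are matched year by year
  constant_link <- length(unique(scores$year)) == 1
  if (!constant_link) {
    scores <- scores[scores$year %in% years, ]
  }
  scores <- scores[, c("region_id", "year", "gisd", "quintile")]
  if (!nrow(scores)) abort_di("no district scores in outcome years", "missing_source")
  y0 <- min(years)
  ref <- if (constant_link) scores else scores[scores$year == y0, ]
  beta <- vapply(names(oc$rr_target), function(sx) {
    spread <- mean(ref$gisd[ref$quintile == 5]) - mean(ref$gisd[ref$quintile == 1])
    log(oc$rr_target[[sx]]) / spread
  }, numeric(1))

  age_mid <- c(seq(2.5, 87.5, by = 5), 92.5)
  base_shape <- exp(oc$age_slope * age_mid)
  w_std <- std$weight / sum(std$weight)
  # scale so the ESP-standardized reference rate (gisd = 0.5) hits the target
  r0 <- vapply(names(oc$rate_target), function(sx) {
    oc$rate_target[[sx]] / 1e5 / sum(w_std * base_shape) / exp(beta[[sx]] * 0.5)
  }, numeric(1))

  with_seed(config$seed + 2L, {
    districts <- sort(unique(scores$region_id))
    pop_d <- level_table(hierarchy, "district")
    # district age structure: national shape with mild district-level noise
    nat_share <- w_std * exp(0.25 * ((age_mid - 45) / 45))  # younger-light tilt
    nat_share <- nat_share / sum(nat_share)
    share <- matrix(0, length(districts), length(age_mid))
    for (d in seq_along(districts)) {
      s <- nat_share * exp(0.1 * rnorm(length(age_mid)))
      share[d, ] <- s / sum(s)
    }
    frailty <- setNames(rnorm(length(districts), 0, oc$frailty_sd), districts)

    grid <- tidyr::expand_grid(district_id = districts, year = as.integer(years),
                               sex = names(oc$rr_target), age_group = std$age_group)
    grid$age_idx <- match(grid$age_group, std$age_group)
    gl <- if (constant_link) {
      scores$gisd[match(grid$district_id, scores$region_id)]
    } else {
      scores$gisd[match(paste(grid$district_id, grid$year),
                        paste(scores$region_id, scores$year))]
    }
    if (anyNA(gl)) abort_di("missing district index values for some outcome years",
                            "missing_source")
    pop_tot <- pop_d$population[match(paste(grid$district_id, grid$year),
                                      paste(pop_d$region_id, pop_d$year))]
    grid$population <- round(pop_tot / 2 *
                               share[cbind(match(grid$district_id, districts),
                                           grid$age_idx)])
    rate <- r0[grid$sex] * base_shape[grid$age_idx] *
      exp((oc$time_trend + oc$trend_gisd * gl) * (grid$year - y0) +
            beta[grid$sex] * gl + frailty[grid$district_id])
    if (any(rate < 0)) abort_di("negative rates generated", "bad_rate")
    grid$events <- stats::rpois(nrow(grid), grid$population * rate)
    out <- grid[c("district_id", "year", "sex", "age_group", "events", "population")]
    attr(out, "truth") <- list(beta = beta, r0 = r0, y0 = y0,
                               time_trend = oc$time_trend,
                               trend_gisd = oc$trend_gisd)
    out
  })
}

#' Generate synthetic district life expectancy
#'
#' One value per district and sex, linear in the deprivation index:
#' `le = intercept + slope * gisd + noise`, with configurable slopes
#' (defaults -6.0 years for men, -3.2 for women over the full index range).
#'
#' @param config a `synth_config`.
#' @param scores district-level score rows for one year.
#' @return tibble `district_id`, `sex`, `life_expectancy`, `gisd`, with
#'   attribute `truth` holding the programmed slopes.
#' @export
generate_life_expectancy <- function(config, scores) {
  oc <- config$outcomes
  scores <- tibble::as_tibble(scores)
  if (length(unique(scores$year)) != 1) {
    abort_di("life expectancy generation expects a single score year", "bad_input")
  }
  with_seed(config$seed + 3L, {
    out <- dplyr::bind_rows(lapply(names(oc$le_slope), function(sx) {
      tibble::tibble(district_id = scores$region_id, sex = sx,
                     life_expectancy = oc$le_intercept[[sx]] +
                       oc$le_slope[[sx]] * scores$gisd +
                       rnorm(nrow(scores), 0, oc$le_noise_sd[[sx]]),
                     gisd = scores$gisd)
    }))
    attr(out, "truth") <- list(slope = oc$le_slope, intercept = oc$le_intercept)
    out
  })
}

#' Generate a complete synthetic bundle
#'
#' Hierarchy plus panel plus ground truth in one call; optionally written
#' to disk (`hierarchy.csv`, `panel.csv`, `truth.json`).
#'
#' @param config a `synth_config`.
#' @param dir optional output directory.
#' @return list `hierarchy`, `panel`, `truth`.
#' @export
generate_synth_bundle <- function(config = synth_config(), dir = NULL) {
  h <- generate_hierarchy(config)
  gp <- generate_panel(config, h)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_hierarchy(h, file.path(dir, "hierarchy.csv"))
    write_panel(gp$panel, file.path(dir, "panel.csv"))
    jsonlite::write_json(list(seed = config$seed,
                              loadings = as.list(gp$truth$loadings),
                              artefacts = gp$truth$artefacts[
                                c("break_year", "break_delta", "g8_effect",
                                  "east_west_delta", "gap_from", "gap_to")]),
                         file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  }
  list(hierarchy = h, panel = gp$panel, truth = gp$truth)
}

#' Default harmonization config matching the synthetic artefacts
#'
#' The harmonization parameters (break year, reform cells, gap years,
#' price index) that undo exactly the pathologies [generate_panel()]
#' injects under the same `synth_config`.
#'
#' @param config a `synth_config`.
#' @return list suitable as the `config` argument of [harmonize_panel()]
#'   and [build_gisd()].
#' @export
synth_harmonize_config <- function(config = synth_config()) {
  art <- config$artefacts
  list(
    years = config$years,
    break_year = art$break_year,
    g8_cells = art$g8_cells,
    gap = list(from_year = art$gap_from, to_year = art$gap_to),
    price_index = tibble::tibble(
      year = as.integer(config$years),
      index = (1 + config$inflation)^(config$years - config$inflation_base_year))
  )
}
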