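# A panel whose three education indicators are exact (polarity-signed)
# copies of one latent factor, at district level on the toy hierarchy.
perfect_education_panel <- function(h, years = 2001:2019) {
  set.seed(5)
  districts <- unique(h$district_id)
  grid <- expand.grid(region_id = districts, year = years,
                      stringsAsFactors = FALSE)
  f <- rnorm(nrow(grid))
  dplyr::bind_rows(
    tibble::tibble(region_id = grid$region_id, level = "district",
                   year = as.integer(grid$year),
                   indicator = "employees_with_university_degree", value = 20 - 2 * f),
    tibble::tibble(region_id = grid$region_id, level = "district",
                   year = as.integer(grid$year),
                   indicator = "employees_without_qualification", value = 10 + 3 * f),
    tibble::tibble(region_id = grid$region_id, level = "district",
                   year = as.integer(grid$year),
                   indicator = "school_leavers_without_qualification", value = 5 + f)
  ) |> indicator_panel()
}

test_that("weight shares follow the squared-loading arithmetic", {
  # published income loadings reproduce the printed share columns
  sh <- shares_from_loadings(c(-0.914, -0.921, 0.608))
  expect_equal(round(sh$share_dimension, 1), c(40.7, 41.3, 18.0))
  expect_equal(round(sh$share_gisd, 1), c(13.6, 13.8, 6.0))
  sh <- shares_from_loadings(c(-0.640, 0.841, -0.810))
  expect_equal(round(sh$share_dimension, 1), c(23.1, 39.9, 37.0))
  # shares sum to 100 within a dimension; total-index shares to 100/3
  expect_equal(sum(sh$share_dimension), 100)
  expect_equal(sum(sh$share_gisd), 100 / 3)
  # single nonzero loading takes the full dimension share
  expect_equal(shares_from_loadings(c(0, 0.5, 0))$share_dimension, c(0, 100, 0))
  expect_error(shares_from_loadings(c(0, 0, 0)), class = "zero_loadings")
})

test_that("perfectly correlated indicators load at one with full eigenvalue", {
  h <- toy_hierarchy(years = 2001:2019)
  p <- perfect_education_panel(h)
  tab <- pooled_pca_dimension(p, h, default_indicator_specs(), "education",
                              level = "district")
  expect_equal(abs(tab$loading), rep(1, 3), tolerance = 1e-9)
  # orientation: deprivation-increasing indicators load positively
  expect_lt(tab$loading[tab$indicator == "employees_with_university_degree"], 0)
  expect_gt(tab$loading[tab$indicator == "employees_without_qualification"], 0)
  expect_equal(attr(tab, "eigenvalues")[1], 3, tolerance = 1e-9)
})

test_that("independent indicators trigger the weak-component warning", {
  h <- toy_hierarchy(years = 2001:2019)
  set.seed(6)
  districts <- unique(h$district_id)
  grid <- expand.grid(region_id = districts, year = 2001:2019,
                      stringsAsFactors = FALSE)
  rows <- lapply(c("employees_with_university_degree",
                   "employees_without_qualification",
                   "school_leavers_without_qualification"), function(ind) {
    tibble::tibble(region_id = grid$region_id, level = "district",
                   year = as.integer(grid$year), indicator = ind,
                   value = rnorm(nrow(grid)))
  })
  p <- indicator_panel(dplyr::bind_rows(rows))
  expect_warning(pooled_pca_dimension(p, h, default_indicator_specs(),
                                      "education", level = "district"),
                 class = "weak_component")
})

test_that("pooled standardization constants are frozen and scores extend to pre-pool years", {
  h <- toy_hierarchy(years = 1998:2019)
  p <- perfect_education_panel(h, years = 1998:2019)
  tab <- pooled_pca_dimension(p, h, default_indicator_specs(), "education",
                              pool_years = 2001:2019, level = "district")
  sc <- factor_scores(p, h, tab, years = 1998:2019)
  # years before the pool are scored on the pooled scale
  expect_setequal(unique(sc$year), 1998:2019)
  # dot-product oracle: recompute one score by hand
  w <- tab$loading / attr(tab, "eigenvalues")[1]
  mu <- attr(tab, "means"); sdev <- attr(tab, "sds")
  wide <- panel_wide(p, h, tab$indicator, 2005, level = "district")
  z <- (as.numeric(wide[2, tab$indicator]) - mu[tab$indicator]) / sdev[tab$indicator]
  expect_equal(sc$score[sc$region_id == wide$region_id[2] & sc$year == 2005],
               sum(w * z))
  # a region-year sitting exactly at the pooled means scores zero
  p3 <- p
  rows3 <- p3$region_id == "01001" & p3$year == 2010
  p3$value[rows3] <- mu[p3$indicator[rows3]]
  sc3 <- factor_scores(p3, h, tab, years = 2010)
  expect_equal(sc3$score[sc3$region_id == "01001"], 0)
})

test_that("loadings and scores are invariant to affine transforms of an indicator", {
  h <- toy_hierarchy(years = 2001:2019)
  p <- perfect_education_panel(h)
  specs <- default_indicator_specs()
  tab1 <- pooled_pca_dimension(p, h, specs, "education", level = "district")
  sc1 <- factor_scores(p, h, tab1, years = 2001:2019)
  p2 <- p
  rows <- p2$indicator == "school_leavers_without_qualification"
  p2$value[rows] <- 100 + 7 * p2$value[rows]
  tab2 <- pooled_pca_dimension(p2, h, specs, "education", level = "district")
  sc2 <- factor_scores(p2, h, tab2, years = 2001:2019)
  expect_equal(tab2$loading, tab1$loading, tolerance = 1e-9)
  expect_equal(sc2$score, sc1$score, tolerance = 1e-9)
})

test_that("synthetic panels with the published loading pattern are recovered", {
  cfg <- recovery_config(seed = 20)
  h <- generate_hierarchy(cfg)
  gp <- generate_panel(cfg, h)
  p <- gp$panel
  idx <- tibble::tibble(year = as.integer(cfg$years),
                        index = (1 + cfg$inflation)^(cfg$years - cfg$inflation_base_year))
  for (ind in default_indicator_specs()$indicator[
    default_indicator_specs()$transform == "log_after_deflation"]) {
    p <- deflate_and_log(p, ind, idx)
  }
  fit <- fit_all_dimensions(p, h, default_indicator_specs(),
                            pool_years = cfg$years, score_years = cfg$years)
  tgt <- published_loadings()
  got <- fit$loadings$loading[match(tgt$indicator, fit$loadings$indicator)]
  expect_equal(got, tgt$loading, tolerance = 0.06)
  # sign-oriented loadings track the generating pattern almost perfectly
  expect_gt(stats::cor(got, tgt$loading), 0.99)
})
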