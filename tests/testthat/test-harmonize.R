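make_break_panel <- function(delta, slope = 0, noise = 0, regions = c("01001", "01002"),
                             years = 2008:2017, break_year = 2013) {
  grid <- expand.grid(region_id = regions, year = years, stringsAsFactors = FALSE)
  base <- 10 + 2 * (match(grid$region_id, regions) - 1)
  grid$value <- base + slope * (grid$year - break_year) +
    delta * (grid$year >= break_year) +
    if (noise > 0) rnorm(nrow(grid), 0, noise) else 0
  toy_panel(grid$region_id, grid$year, "employees_without_qualification", grid$value)
}

test_that("deflation and log transform follow the declared price index", {
  p <- toy_panel(c("01001", "01001"), c(2010, 2011), "tax_revenue", c(1000, 1100))
  idx <- tibble::tibble(year = c(2010L, 2011L), index = c(1.0, 1.1))
  out <- deflate_and_log(p, "tax_revenue", idx)
  expect_equal(out$value, c(log(1000), log(1000)))
  # identity deflator warns
  expect_warning(deflate_and_log(p, "tax_revenue"), class = "identity_deflator")
  # non-positive values are a hard error naming rows
  p2 <- toy_panel("01001", 2010, "tax_revenue", 0)
  err <- expect_error(deflate_and_log(p2, "tax_revenue", idx), class = "nonpositive_value")
  expect_match(conditionMessage(err), "01001")
})

test_that("break correction recovers a pure step exactly and shifts pre-break values", {
  p <- make_break_panel(delta = 3)
  m <- fit_break_correction(p, "employees_without_qualification", 2013)
  expect_equal(m$delta, 3, tolerance = 1e-10)
  out <- apply_break_correction(p, m)
  # corrected pre-break values sit on the post-break level
  expect_equal(out$value, rep(c(13, 15), length(2008:2017)), tolerance = 1e-10)
  # applying twice is refused
  expect_error(apply_break_correction(out, m), class = "double_correction")
})

test_that("break correction separates step from trend and is null-safe", {
  # slope 1/year plus step 3, noiseless: closed-form OLS recovers both
  p <- make_break_panel(delta = 3, slope = 1)
  m <- fit_break_correction(p, "employees_without_qualification", 2013)
  expect_equal(m$delta, 3, tolerance = 1e-9)
  # single-region series 10,10,10 | 13,13,13
  p1 <- toy_panel(rep("01001", 6), 2010:2015, "employees_without_qualification",
                  c(10, 10, 10, 13, 13, 13))
  m1 <- fit_break_correction(p1, "employees_without_qualification", 2013)
  expect_equal(m1$delta, 3, tolerance = 1e-10)
  expect_equal(apply_break_correction(p1, m1)$value, rep(13, 6), tolerance = 1e-10)
  # zero step: delta 0, panel unchanged
  p0 <- make_break_panel(delta = 0, slope = 0.5)
  m0 <- fit_break_correction(p0, "employees_without_qualification", 2013)
  expect_equal(m0$delta, 0, tolerance = 1e-9)
  expect_equal(apply_break_correction(p0, m0)$value, p0$value, tolerance = 1e-12)
  # no data on one side of the break
  pre_only <- toy_panel(rep("01001", 3), 2010:2012, "employees_without_qualification", 1:3)
  expect_error(fit_break_correction(pre_only, "employees_without_qualification", 2013),
               class = "bad_break_window")
})

test_that("school-reform correction recovers a programmed cell effect", {
  h <- toy_hierarchy(years = 2008:2012)
  grid <- expand.grid(region_id = c("01001", "01002", "02001"),
                      year = 2008:2012, stringsAsFactors = FALSE)
  base <- 6 + 0.5 * (match(grid$region_id, c("01001", "01002", "02001")) - 1) +
    0.1 * (grid$year - 2010)
  cells <- tibble::tibble(state_id = "01", year = 2011L)
  hit <- substr(grid$region_id, 1, 2) == "01" & grid$year == 2011
  grid$value <- base + ifelse(hit, -2, 0)
  p <- toy_panel(grid$region_id, grid$year, "school_leavers_without_qualification",
                 grid$value)
  m <- fit_g8_correction(p, "school_leavers_without_qualification", cells, h)
  expect_equal(m$effect, -2, tolerance = 1e-9)
  out <- apply_g8_correction(p, m, h)
  expect_equal(out$value, base, tolerance = 1e-9)
  # the unaffected state's series is identical before and after
  other <- grid$region_id == "02001"
  expect_identical(out$value[other], p$value[other])
  # empty reform set is the identity transform
  m0 <- fit_g8_correction(p, "school_leavers_without_qualification",
                          cells[0, ], h)
  expect_equal(m0$effect, 0)
  expect_equal(apply_g8_correction(p, m0, h)$value, p$value)
  # a reform cell with no data is skipped with a warning
  expect_warning(
    fit_g8_correction(p, "school_leavers_without_qualification",
                      tibble::tibble(state_id = "09", year = 2011L), h),
    class = "empty_reform_cell")
})

test_that("East-West correction equalizes group means and removes bimodality", {
  h <- toy_hierarchy(years = 2010L)
  # East values exactly 5 below the West
  p <- toy_panel(c("01001", "01002", "02001"), 2010,
                 "employees_without_qualification", c(12, 14, 8))
  m <- fit_east_west_correction(p, "employees_without_qualification", h,
                                min_regions = 1)
  expect_equal(m$delta, 5)
  out <- apply_east_west_correction(p, m, h)
  east <- east_flag(h, out$region_id)
  expect_equal(mean(out$value[east]), mean(out$value[!east]))
  # constructed bimodal mixture turns unimodal after the shift
  set.seed(42)
  west <- rnorm(300, 12, 1)
  east_v <- rnorm(200, 5, 1)
  expect_true(is_bimodal(c(west, east_v)))
  expect_false(is_bimodal(c(west, east_v + (mean(west) - mean(east_v)))))
  # an all-West panel has nothing to correct against
  p_west <- toy_panel(c("01001", "01002"), 2010,
                      "employees_without_qualification", c(12, 14))
  expect_error(fit_east_west_correction(p_west, "employees_without_qualification",
                                        h, min_regions = 1),
               class = "too_few_regions")
})

test_that("gap carry-forward copies donor values only into missing cells", {
  p <- toy_panel(c("01001", "01002", "02001", "01001"),
                 c(2011, 2011, 2011, 2012), "debtor_quota",
                 c(8.1, 6.0, 7.5, 9.9))
  out <- carry_forward_gap(p, "debtor_quota", 2011, 2012)
  df <- as.data.frame(out)
  y12 <- df[df$year == 2012, ]
  # region observed in 2012 untouched, the others copied and flagged
  expect_equal(y12$value[y12$region_id == "01001"], 9.9)
  expect_false(y12$imputed[y12$region_id == "01001"])
  expect_equal(sort(y12$value[y12$imputed]), c(6.0, 7.5))
  # flagged count equals the recount of fillable gaps
  expect_equal(sum(df$imputed), 2L)
  expect_error(carry_forward_gap(out, "debtor_quota", 2011, 2012),
               class = "double_correction")
})

test_that("random-intercept imputation is exact in the noiseless limit", {
  h <- toy_hierarchy(years = 1998:2005)
  regions <- unique(h$district_id)
  a <- c(3, 7, 11)  # region intercepts
  grid <- expand.grid(region_id = regions, year = 2001:2005, stringsAsFactors = FALSE)
  grid$value <- a[match(grid$region_id, regions)] + 2 * (grid$year - 2000)
  p <- toy_panel(grid$region_id, grid$year, "debtor_quota", grid$value)
  res <- impute_random_intercept(p, "debtor_quota", 1998:2000, h)
  df <- as.data.frame(res$panel)
  imp <- df[df$imputed, ]
  expect_equal(nrow(imp), 9L)
  expect_equal(imp$value,
               a[match(imp$region_id, regions)] + 2 * (imp$year - 2000),
               tolerance = 1e-6)
  # observed cells never overwritten
  obs <- df[!df$imputed, ]
  expect_equal(obs$value[order(obs$region_id, obs$year)],
               grid$value[order(grid$region_id, grid$year)])
  # a fully observed indicator changes nothing
  res2 <- impute_random_intercept(res$panel, "debtor_quota", 2001:2005, h)
  expect_equal(nrow(res2$panel), nrow(res$panel))
})

test_that("random-intercept imputation error stays within 3x the noise level", {
  set.seed(11)
  n_regions <- 200
  noise_sd <- 0.1
  district_id <- sprintf("01%03d", seq_len(n_regions))
  h <- region_hierarchy(tibble::tibble(
    region_id = paste0(district_id, "001"), gvb_id = paste0("G", district_id, "01"),
    district_id = district_id, ror_id = "R01", nuts2_id = "N01",
    state_id = "01", year = 1998L, population = 100))
  a <- rnorm(n_regions)
  grid <- expand.grid(idx = seq_len(n_regions), year = 1998:2019)
  truth <- a[grid$idx] + 0.5 * (grid$year - 2000)
  grid$value <- truth + rnorm(nrow(grid), 0, noise_sd)
  obs <- grid$year >= 2001
  p <- toy_panel(district_id[grid$idx[obs]], grid$year[obs], "debtor_quota",
                 grid$value[obs])
  res <- impute_random_intercept(p, "debtor_quota", 1998:2000, h)
  df <- as.data.frame(res$panel)
  imp <- df[df$imputed, ]
  expect_equal(nrow(imp), 3L * n_regions)
  key <- paste(district_id[grid$idx], grid$year)
  tr <- truth[match(paste(imp$region_id, imp$year), key)]
  mae <- mean(abs(imp$value - tr))
  expect_lte(mae, 3 * noise_sd)
})

test_that("imputation refuses an indicator with no observed data", {
  h <- toy_hierarchy()
  p <- toy_panel("01001", 2010, "debtor_quota", 5)
  expect_error(impute_random_intercept(p, "unemployment_rate", 1998:2000, h),
               class = "missing_source")
})
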