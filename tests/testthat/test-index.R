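test_that("yearly min-max normalization rescales, is affine-invariant and idempotent", {
  df <- tibble::tibble(region_id = c("a", "b", "c"), year = 2010L,
                       gisd = c(2, 4, 6))
  out <- normalize_yearly(df, "gisd")
  expect_equal(out$gisd, c(0, 0.5, 1))
  # affine transform of inputs leaves outputs identical
  df2 <- df; df2$gisd <- 10 - 3 * df2$gisd
  out2 <- normalize_yearly(df2, "gisd")
  expect_equal(out2$gisd, 1 - out$gisd)  # negative scale flips, magnitudes equal
  df3 <- df; df3$gisd <- 5 + 2 * df3$gisd
  expect_equal(normalize_yearly(df3, "gisd")$gisd, out$gisd)
  # idempotence
  expect_equal(normalize_yearly(out, "gisd")$gisd, out$gisd)
  # constant scores are an error
  dfc <- df; dfc$gisd <- 1
  expect_error(normalize_yearly(dfc, "gisd"), class = "constant_scores")
})

test_that("index composition sums the three normalized subdimension scores", {
  mk <- function(e, m, i) tibble::tibble(score_education = e,
                                         score_employment = m, score_income = i)
  expect_equal(compose_gisd(mk(0, 0, 0))$gisd_raw, 0)
  expect_equal(compose_gisd(mk(1, 1, 1))$gisd_raw, 3)
  expect_equal(compose_gisd(mk(0.2, 0.3, 0.4))$gisd_raw, 0.9)
  # permutation symmetry
  expect_equal(compose_gisd(mk(0.4, 0.2, 0.3))$gisd_raw,
               compose_gisd(mk(0.2, 0.3, 0.4))$gisd_raw)
  expect_error(compose_gisd(mk(0.2, NA, 0.4)), class = "missing_dimension")
  expect_error(compose_gisd(tibble::tibble(score_education = 1)),
               class = "missing_dimension")
})

test_that("aggregation is the population-weighted mean of child scores", {
  h <- toy_hierarchy()
  sc <- tibble::tibble(
    region_id = c("01001001", "01001002", "01001003", "01002001", "01002002",
                  "02001001"),
    year = 2010L, gisd = c(0.2, 0.6, 0.5, 0.1, 0.9, 0.4))
  agg <- aggregate_scores(sc, h, "gvb", cols = "gisd", renormalize = FALSE)
  # children (0.2, pop 1,000) and (0.6, pop 3,000) -> parent 0.5
  expect_equal(agg$gisd[agg$region_id == "G0100101"], 0.5)
  # equal populations -> simple mean: 01002001 (1,500) vs 01002002 (500)
  sc2 <- sc; h2 <- h
  agg2 <- aggregate_scores(sc2[4:5, ], h2, "gvb", cols = "gisd", renormalize = FALSE)
  expect_equal(agg2$gisd, stats::weighted.mean(c(0.1, 0.9), c(1500, 500)))
})

test_that("two-path aggregation agrees with the direct weighted mean", {
  b <- cached_build()
  muni <- b$res$scores[b$res$scores$level == "municipality", ]
  direct <- aggregate_scores(muni, b$hierarchy, "district",
                             cols = "gisd", renormalize = FALSE)
  via_gvb <- aggregate_scores(muni, b$hierarchy, "gvb",
                              cols = "gisd", renormalize = FALSE)
  chained <- aggregate_scores(via_gvb, b$hierarchy, "district",
                              cols = "gisd", renormalize = FALSE,
                              from_level = "gvb")
  m <- dplyr::inner_join(direct, chained, by = c("region_id", "year"))
  expect_equal(m$gisd.x, m$gisd.y, tolerance = 1e-12)
})

test_that("quintile assignment gives unit fifths with lower-quintile ties", {
  sc <- tibble::tibble(region_id = sprintf("r%02d", 1:10), year = 2010L,
                       gisd = (1:10) / 10)
  q <- assign_quintiles(sc)
  expect_equal(as.integer(table(q$quintile)), rep(2L, 5))
  expect_equal(q$group3, c("low", "low", rep("mid", 6), "high", "high"))
  # 401 distinct scores split 81/80/80/80/80
  sc401 <- tibble::tibble(region_id = sprintf("r%03d", 1:401), year = 2010L,
                          gisd = sample(seq(0, 1, length.out = 401)))
  q401 <- assign_quintiles(sc401)
  expect_equal(as.integer(table(q401$quintile)), c(81L, 80L, 80L, 80L, 80L))
  # ties share the lower quintile
  sct <- tibble::tibble(region_id = sprintf("r%02d", 1:10), year = 2010L,
                        gisd = c(0.1, 0.2, rep(0.25, 3), 0.6, 0.7, 0.8, 0.9, 1))
  qt <- assign_quintiles(sct)
  expect_true(all(qt$quintile[qt$gisd == 0.25] == 2L))
  expect_error(assign_quintiles(sc[1:4, ]), class = "too_few_regions")
})

test_that("custom-geography mapping averages district scores by crosswalk weights", {
  d <- tibble::tibble(region_id = c("01001", "01002", "02001"), year = 2010L,
                      gisd = c(0.2, 0.6, 1.0))
  # 50/50 split of two districts scoring 0.2 / 0.6 -> 0.4
  cw <- tibble::tibble(district_id = c("01001", "01002", "02001"),
                       custom_id = c("Z1", "Z1", "Z2"),
                       weight = c(500, 500, 800))
  out <- map_to_custom_geography(d, cw, cols = "gisd", renormalize = FALSE)
  expect_equal(out$gisd[out$region_id == "Z1"], 0.4)
  # unit wholly inside one district inherits that district's score
  expect_equal(out$gisd[out$region_id == "Z2"], 1.0)
  # identity crosswalk reproduces the district panel
  cwi <- tibble::tibble(district_id = d$region_id, custom_id = d$region_id,
                        weight = 1)
  outi <- map_to_custom_geography(d, cwi, cols = "gisd", renormalize = FALSE)
  expect_equal(outi$gisd[match(d$region_id, outi$region_id)], d$gisd)
  # weights not matching a declared unit total are normalized with a warning
  cww <- cw; cww$unit_total <- c(2000, 2000, 800)
  expect_warning(map_to_custom_geography(d, cww, cols = "gisd",
                                         renormalize = FALSE),
                 class = "weight_mismatch")
})

test_that("score panel invariants hold on the full synthetic build", {
  b <- cached_build()
  expect_true(validate_score_panel(b$res$scores))
  sc <- b$res$scores
  expect_setequal(unique(sc$level), region_levels())
  # the maximum-score region carries quintile 5 and label 'high'
  for (lv in c("municipality", "district")) {
    d <- sc[sc$level == lv & sc$year == 2019, ]
    expect_equal(d$quintile[which.max(d$gisd)], 5L)
    expect_equal(d$group3[which.max(d$gisd)], "high")
  }
  # GVB-level values are flagged as more uncertain
  expect_true(all(sc$uncertain[sc$level == "gvb"]))
  expect_false(any(sc$uncertain[sc$level == "district"]))
})

test_that("raising one municipality's score cannot lower its district's rank", {
  b <- cached_build()
  muni <- b$res$scores[b$res$scores$level == "municipality" &
                         b$res$scores$year == 2019, ]
  target <- muni$region_id[which.min(muni$gisd)]
  agg1 <- aggregate_scores(muni, b$hierarchy, "district", cols = "gisd")
  muni2 <- muni
  muni2$gisd[muni2$region_id == target] <-
    min(1, muni2$gisd[muni2$region_id == target] + 0.5)
  agg2 <- aggregate_scores(muni2, b$hierarchy, "district", cols = "gisd")
  dist <- substr(target, 1, 5)
  rank1 <- rank(agg1$gisd)[agg1$region_id == dist]
  rank2 <- rank(agg2$gisd)[agg2$region_id == dist]
  expect_gte(rank2, rank1)
})

test_that("the final index is invariant to affine rescaling of raw indicators", {
  b <- cached_build()
  p2 <- b$panel
  rows <- p2$indicator == "gross_wage"        # log-deflated downstream
  p2$value[rows] <- 2 * p2$value[rows]
  rows <- p2$indicator == "unemployment_rate" # z-scored downstream
  p2$value[rows] <- 3 + 1.7 * p2$value[rows]
  res2 <- build_gisd(p2, b$hierarchy, default_indicator_specs(),
                     synth_harmonize_config(b$cfg))
  expect_equal(res2$scores$gisd, b$res$scores$gisd, tolerance = 1e-6)
  expect_equal(res2$scores$quintile, b$res$scores$quintile)
})
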