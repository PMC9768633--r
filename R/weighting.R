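#' Wide indicator matrix at a spatial level
#'
#' Builds a region x indicator table at the requested level by assigning
#' each unit the finest available value of every indicator: a municipality
#' inherits its GVB's value for GVB-native indicators and its district's
#' value for district-native ones. This downward assignment is what lets
#' all nine indicators be scored at a common base level.
#'
#' @param panel harmonized `indicator_panel`.
#' @param hierarchy a `region_hierarchy`.
#' @param indicators character vector of indicator names.
#' @param years years to include.
#' @param level target level (default `"municipality"`).
#' @return tibble `region_id`, `year`, one column per indicator.
#' @export
panel_wide <- function(panel, hierarchy, indicators, years,
                       level = "municipality") {
  lv <- region_levels()
  target_pos <- match(level, lv)
  units <- unique(hierarchy[[id_col_for_level(level)]])
  out <- tidyr::expand_grid(region_id = units, year = as.integer(years))
  df <- as.data.frame(panel)
  for (ind in indicators) {
    col <- rep(NA_real_, nrow(out))
    # from coarsest to finest so finer levels overwrite
    for (src_level in rev(lv)) {
      rows <- df[df$indicator == ind & df$level == src_level & df$year %in% years, ]
      if (!nrow(rows)) next
      src_pos <- match(src_level, lv)
      if (src_pos == target_pos) {
        key <- rows$region_id
        m <- match(paste(out$region_id, out$year), paste(key, rows$year))
      } else if (src_pos > target_pos) {
        pm <- parent_map(hierarchy, level, src_level)
        anc <- pm$to_id[match(out$region_id, pm$from_id)]
        m <- match(paste(anc, out$year), paste(rows$region_id, rows$year))
      } else {
        next  # finer than target: aggregation is the index module's job
      }
      hit <- !is.na(m)
      col[hit] <- rows$value[m[hit]]
    }
    out[[ind]] <- col
  }
  out
}

#' Pooled principal-component analysis of one subdimension
#'
#' The three indicators of a subdimension are z-standardized over the pooled
#' region x year observations (one pooled mean and SD per indicator, so
#' between-year variation contributes to the correlations), and the first
#' eigenvector of their 3 x 3 correlation matrix is extracted. Loadings are
#' the eigenvector scaled by the square root of the first eigenvalue, i.e.
#' the correlations of the indicators with the first component. The sign of
#' the component is oriented so that deprivation-increasing indicators load
#' positively. The pool excludes early, heavily imputed years by default.
#'
#' @param panel harmonized `indicator_panel`.
#' @param hierarchy a `region_hierarchy`.
#' @param specs indicator specs.
#' @param dimension `"education"`, `"employment"` or `"income"`.
#' @param pool_years years entering the PCA pool (default 2001-2019).
#' @param level spatial level of the pooled observations.
#' @param min_var_explained warn when the first component explains less
#'   than this share of the dimension variance (default 0.5).
#' @return a `loading_table`: tibble `dimension`, `indicator`, `loading`,
#'   `share_dimension`, `share_gisd`, with attributes `eigenvalues`,
#'   `means`, `sds`, `pool_years`, `level`.
#' @export
pooled_pca_dimension <- function(panel, hierarchy, specs, dimension,
                                 pool_years = 2001:2019,
                                 level = "municipality",
                                 min_var_explained = 0.5) {
  validate_indicator_specs(specs)
  sp <- specs[specs$dimension == dimension, ]
  if (nrow(sp) != 3) abort_di(paste0("unknown dimension: ", dimension), "bad_dimension")
  wide <- panel_wide(panel, hierarchy, sp$indicator, pool_years, level)
  X <- as.matrix(wide[sp$indicator])
  if (anyNA(X)) {
    abort_di(paste0("missing cells in the ", dimension, " pool (",
                    sum(is.na(X)), "); harmonize first"), "missing_pool")
  }
  mu <- colMeans(X)
  sdev <- apply(X, 2, stats::sd)
  if (any(sdev == 0)) abort_di("indicator with zero pooled variance", "zero_variance")
  Z <- scale(X, center = mu, scale = sdev)
  C <- stats::cor(Z)
  eig <- eigen(C, symmetric = TRUE)
  eta <- eig$values[1]
  loadings <- eig$vectors[, 1] * sqrt(eta)
  pol <- ifelse(sp$polarity == "increasing", 1, -1)
  if (sum(loadings * pol) < 0) loadings <- -loadings
  if (eta / 3 < min_var_explained) {
    warn_di(sprintf("first component explains only %.1f%% of the %s dimension",
                    100 * eta / 3, dimension), "weak_component")
  }
  sh <- shares_from_loadings(loadings)
  out <- tibble::tibble(dimension = dimension, indicator = sp$indicator,
                        loading = loadings,
                        share_dimension = sh$share_dimension,
                        share_gisd = sh$share_gisd)
  structure(out, class = c("loading_table", class(out)),
            eigenvalues = eig$values, means = mu, sds = sdev,
            pool_years = pool_years, level = level)
}

#' Weight shares from first-component loadings
#'
#' Within-dimension share of indicator i: `s_i = 100 * l_i^2 / sum_j l_j^2`
#' (percent); total-index share: `g_i = s_i / 3`, since each of the three
#' subdimensions enters the composite with weight one third. The sum of
#' squared loadings is the first-component eigenvalue for a
#' correlation-matrix PCA.
#'
#' @param loadings numeric vector of loadings, or a data frame with columns
#'   `indicator`, `loading` and optionally `dimension` (shares then computed
#'   within each dimension).
#' @return for a numeric vector: tibble `share_dimension`, `share_gisd`
#'   plus an `eigenvalue` attribute; for a data frame: the input with
#'   `share_dimension`, `share_gisd`, `eigenvalue` columns added.
#' @export
#' @examples
#' shares_from_loadings(c(-0.914, -0.921, 0.608))
shares_from_loadings <- function(loadings) {
  if (is.data.frame(loadings)) {
    grp <- if ("dimension" %in% names(loadings)) loadings$dimension else rep(1, nrow(loadings))
    parts <- lapply(split(seq_len(nrow(loadings)), grp), function(idx) {
      sh <- shares_from_loadings(loadings$loading[idx])
      out <- loadings[idx, ]
      out$share_dimension <- sh$share_dimension
      out$share_gisd <- sh$share_gisd
      out$eigenvalue <- attr(sh, "eigenvalue")
      out
    })
    return(dplyr::bind_rows(parts))
  }
  if (!length(loadings) || all(loadings == 0)) {
    abort_di("all-zero loadings: shares undefined", "zero_loadings")
  }
  if (any(!is.finite(loadings))) abort_di("non-finite loadings", "bad_loadings")
  ss <- loadings^2
  s <- 100 * ss / sum(ss)
  structure(tibble::tibble(share_dimension = s, share_gisd = s / 3),
            eigenvalue = sum(ss))
}

#' Factor scores for all panel years
#'
#' Combines the standardized indicators of a subdimension with the
#' regression-method component weights `w_i = l_i / eta`. The
#' standardization constants are the pooled means and SDs frozen from the
#' PCA fit, so years outside the pool (the early, imputed years) are scored
#' on the same scale as the pool.
#'
#' @param panel harmonized `indicator_panel`.
#' @param hierarchy a `region_hierarchy`.
#' @param loading_table a `loading_table` from [pooled_pca_dimension()].
#' @param years years to score (default 1998-2019).
#' @return tibble `region_id`, `year`, `dimension`, `score` (standardized
#'   units, higher = more deprived).
#' @export
factor_scores <- function(panel, hierarchy, loading_table, years = 1998:2019) {
  stopifnot(inherits(loading_table, "loading_table"))
  mu <- attr(loading_table, "means")
  sdev <- attr(loading_table, "sds")
  if (any(sdev == 0)) abort_di("zero pooled standard deviation", "zero_variance")
  level <- attr(loading_table, "level")
  eta <- attr(loading_table, "eigenvalues")[1]
  inds <- loading_table$indicator
  wide <- panel_wide(panel, hierarchy, inds, years, level)
  X <- as.matrix(wide[inds])
  if (anyNA(X)) abort_di("missing cells in scoring window; harmonize first", "missing_pool")
  Z <- sweep(sweep(X, 2, mu[inds]), 2, sdev[inds], "/")
  w <- loading_table$loading / eta
  tibble::tibble(region_id = wide$region_id, year = wide$year,
                 dimension = loading_table$dimension[1],
                 score = as.numeric(Z %*% w))
}

#' Fit loadings and scores for all three subdimensions
#'
#' Convenience wrapper running [pooled_pca_dimension()] and
#' [factor_scores()] per dimension.
#'
#' @inheritParams pooled_pca_dimension
#' @param score_years years to score.
#' @return list `loadings` (combined `loading_table` rows), `tables`
#'   (per-dimension `loading_table` objects), `scores` (long tibble of
#'   dimension scores).
#' @export
fit_all_dimensions <- function(panel, hierarchy, specs,
                               pool_years = 2001:2019,
                               score_years = 1998:2019,
                               level = "municipality",
                               min_var_explained = 0.5) {
  dims <- c("education", "employment", "income")
  tables <- lapply(dims, function(d) {
    pooled_pca_dimension(panel, hierarchy, specs, d, pool_years, level,
                         min_var_explained)
  })
  names(tables) <- dims
  scores <- dplyr::bind_rows(lapply(tables, function(tab) {
    factor_scores(panel, hierarchy, tab, years = score_years)
  }))
  list(loadings = dplyr::bind_rows(lapply(tables, tibble::as_tibble)),
       tables = tables, scores = scores)
}

#' Write a loading table as CSV
#'
#' Layout mirrors the published weighting table: dimension, indicator,
#' loading, within-dimension share, total-index share. Diagnostics
#' (eigenvalues, variance explained) go to a JSON sidecar when `diag_path`
#' is given.
#'
#' @param tables list of `loading_table` objects (one per dimension).
#' @param path CSV path.
#' @param diag_path optional JSON path for diagnostics.
#' @export
write_loading_table <- function(tables, path, diag_path = NULL) {
  combined <- dplyr::bind_rows(lapply(tables, tibble::as_tibble))
  utils::write.csv(combined, path, row.names = FALSE)
  if (!is.null(diag_path)) {
    diag <- lapply(tables, function(tab) {
      ev <- attr(tab, "eigenvalues")
      list(eigenvalues = ev, variance_explained = ev[1] / length(ev))
    })
    jsonlite::write_json(diag, diag_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
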