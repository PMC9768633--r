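# Shared fixtures, built in code.

# Small hand-built hierarchy: 2 states, 3 districts, 4 GVB, 6 municipalities.
toy_hierarchy <- function(years = 2010L, east_states = "02") {
  base <- tibble::tribble(
    ~region_id, ~gvb_id,    ~district_id, ~ror_id, ~nuts2_id, ~state_id, ~population,
    "01001001", "G0100101", "01001",      "R01",   "N01",     "01",      1000,
    "01001002", "G0100101", "01001",      "R01",   "N01",     "01",      3000,
    "01001003", "G0100102", "01001",      "R01",   "N01",     "01",      2000,
    "01002001", "G0100201", "01002",      "R01",   "N01",     "01",      1500,
    "01002002", "G0100201", "01002",      "R01",   "N01",     "01",       500,
    "02001001", "G0200101", "02001",      "R02",   "N02",     "02",      4000
  )
  df <- tidyr::expand_grid(base, year = as.integer(years))
  region_hierarchy(df, east_states = east_states)
}

# Long panel rows for one indicator at one level.
toy_panel <- function(region_id, year, indicator, value, level = "district") {
  indicator_panel(tibble::tibble(region_id = region_id, level = level,
                                 year = as.integer(year),
                                 indicator = indicator, value = value))
}

# Expensive artefact-laden synthetic build, computed once per test run.
.synth_store <- new.env(parent = emptyenv())

cached_build <- function(seed = 7) {
  key <- paste0("b", seed)
  if (!exists(key, envir = .synth_store)) {
    cfg <- synth_config(seed = seed)
    h <- generate_hierarchy(cfg)
    gp <- generate_panel(cfg, h)
    res <- build_gisd(gp$panel, h, default_indicator_specs(),
                      synth_harmonize_config(cfg))
    assign(key, list(cfg = cfg, hierarchy = h, panel = gp$panel,
                     truth = gp$truth, res = res),
           envir = .synth_store)
  }
  get(key, envir = .synth_store)
}
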