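#' Packaged Ulva hydrolysis experiment tables
#'
#' The package ships the published 16-run mixed-level (L16-style) hydrolysis
#' experiment as plain-text fixtures: per-run process settings with duplicate
#' outcome measurements summarised as mean and sample standard deviation
#' (`ulva_runs()`), the corresponding larger-the-better signal-to-noise table
#' (`ulva_sn_ratios()`), and the literature bulk composition of *Ulva* biomass
#' in g per kg dry weight used as the base fermentation medium
#' (`ulva_composition()`).
#'
#' Outcomes are concentrations in ug/ml for the four quantified sugars
#' (rhamnose, glucose, xylose, glucuronic acid), the total released mass in
#' ug, the percent yield on dry biomass, and the hydrolysate density in
#' kg/m^3. Two printed cells are known to be suspect (see
#' `ulva_fixture_notes()`): the run-2 xylose sd is garbled in print and is
#' carried as 0.1, and the run-1 glucuronic-acid sd duplicates the total sd
#' of the same run.
#'
#' @return A tibble; `ulva_runs()` has one row per run with factor columns
#'   `temperature_c`, `time_min`, `acid_pct`, `solid_pct` and
#'   `<outcome>_mean` / `<outcome>_sd` column pairs.
#' @examples
#' ulva_runs()
#' ulva_sn_ratios()
#' @export
ulva_runs <- function() {
  read_fixture("ulva_hydrolysis_runs.csv")
}

#' @rdname ulva_runs
#' @export
ulva_sn_ratios <- function() {
  read_fixture("ulva_sn_ratios.csv")
}

#' @rdname ulva_runs
#' @export
ulva_composition <- function() {
  read_fixture("ulva_biomass_composition.csv")
}

#' @rdname ulva_runs
#' @export
ulva_fixture_notes <- function() {
  path <- system.file("extdata", "ulva_fixture_notes.json", package = "ulvahydro")
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' The 16-run mixed-level process design
#'
#' Factor settings only (no outcomes): three 3-level factors (temperature
#' 100/121/134 C, time 30/45/60 min, solid load 5/15/25 % w/v) and one
#' 4-level factor (sulfuric acid 0/0.5/2/5 % w/v) over 16 runs. The array is
#' mixed-level, so per-level run counts are unbalanced (4 to 6 runs per
#' level); all effect averaging in this package uses the actual per-level
#' counts.
#'
#' @return A tibble with columns `run`, `temperature_c`, `time_min`,
#'   `acid_pct`, `solid_pct`.
#' @export
ulva_design <- function() {
  ulva_runs() %>% select(run, all_of(ulva_factors()))
}

#' @rdname ulva_design
#' @export
ulva_factors <- function() {
  c("temperature_c", "time_min", "acid_pct", "solid_pct")
}

#' @rdname ulva_design
#' @export
ulva_outcomes <- function() {
  c("rhamnose", "glucose", "xylose", "glucuronic_acid", "total", "yield", "density")
}

read_fixture <- function(file) {
  path <- system.file("extdata", file, package = "ulvahydro")
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
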