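#' Dry biomass weight of a hydrolysis run
#'
#' Converts the solid load (% w/v) and reaction volume to the dry biomass
#' mass in mg: `m_dw = solid_pct / 100 * volume_ml * 1000`.
#'
#' @param solid_pct solid load in % w/v (> 0).
#' @param volume_ml reaction volume in ml (default 1 ml).
#' @return Dry weight in mg (vectorised).
#' @examples
#' dry_weight(25) # 250 mg
#' @export
dry_weight <- function(solid_pct, volume_ml = 1) {
  if (any(volume_ml <= 0)) abort("`volume_ml` must be positive")
  if (any(solid_pct <= 0)) abort("`solid_pct` must be positive")
  solid_pct / 100 * volume_ml * 1000
}

#' Total released carbohydrate mass in a hydrolysate sample
#'
#' Sums the quantified monosaccharide concentrations (ug/ml) and converts to
#' mass via the reaction volume and an effective dilution factor:
#' `Total = sum(conc) * volume_ml * dilution`. The default dilution of 2.7
#' reflects post-neutralisation dilution of the 1 ml hydrolysis volume
#' inferred from the packaged experiment (the printed totals are uniformly
#' 2.7x the concentration sums); it is a configuration parameter, not part
#' of the formula.
#'
#' @param concentrations numeric vector or runs-by-sugars matrix/data frame
#'   of concentrations in ug/ml.
#' @param volume_ml reaction volume in ml.
#' @param dilution dimensionless effective dilution factor (>= 1).
#' @return Total released mass in ug (one value per run).
#' @examples
#' total_released_mass(c(3036.1, 6538.8, 1339.9, 16010.4)) # ~72698 ug
#' @export
total_released_mass <- function(concentrations, volume_ml = 1, dilution = 2.7) {
  if (any(dilution < 1)) abort("`dilution` must be >= 1")
  if (is.data.frame(concentrations)) concentrations <- as.matrix(concentrations)
  if (is.matrix(concentrations)) {
    if (any(concentrations < 0)) abort("concentrations must be non-negative")
    rowSums(concentrations) * volume_ml * dilution
  } else {
    if (any(concentrations < 0)) abort("concentrations must be non-negative")
    sum(concentrations) * volume_ml * dilution
  }
}

#' Percent carbohydrate yield on dry biomass
#'
#' `yield% = total_ug / (m_dw_mg * 1000) * 100`: the released carbohydrate
#' mass as a percentage of the dry biomass put into the reaction.
#'
#' @param total_ug total released mass in ug.
#' @param m_dw_mg dry biomass weight in mg (> 0).
#' @return Percent yield (full precision; present rounded to 1 decimal).
#' @examples
#' percent_yield(72697.7, 250) # 29.08 -> printed 29.1
#' @export
percent_yield <- function(total_ug, m_dw_mg) {
  if (any(m_dw_mg <= 0)) abort("dry weight must be positive")
  if (any(total_ug < 0)) abort("total mass must be non-negative")
  total_ug / (m_dw_mg * 1000) * 100
}

#' Per-run mass and yield table for a hydrolysis experiment
#'
#' Applies [total_released_mass()], [dry_weight()] and [percent_yield()] to
#' every run of a run table with `<sugar>_mean` concentration columns.
#'
#' @param runs run table such as [ulva_runs()].
#' @param sugars names of the quantified sugars; concentrations are read
#'   from `<sugar>_mean` columns.
#' @param volume_ml,dilution see [total_released_mass()].
#' @return A tibble with columns `run`, `sugar_sum` (ug/ml), `total_ug`,
#'   `dry_weight_mg` and `yield_pct`.
#' @examples
#' hydrolysate_yield(ulva_runs())
#' @export
hydrolysate_yield <- function(runs,
                              sugars = c("rhamnose", "glucose", "xylose", "glucuronic_acid"),
                              volume_ml = 1, dilution = 2.7) {
  runs <- as_tibble(runs)
  cols <- paste0(sugars, "_mean")
  missing_cols <- setdiff(cols, names(runs))
  if (length(missing_cols) > 0) {
    abort(paste("missing concentration columns:", paste(missing_cols, collapse = ", ")))
  }
  conc <- as.matrix(runs[, cols, drop = FALSE])
  total <- total_released_mass(conc, volume_ml = volume_ml, dilution = dilution)
  dw <- dry_weight(runs$solid_pct, volume_ml = volume_ml)
  tibble(
    run = if ("run" %in% names(runs)) runs$run else seq_len(nrow(runs)),
    sugar_sum = rowSums(conc),
    total_ug = total,
    dry_weight_mg = dw,
    yield_pct = percent_yield(total, dw)
  )
}
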