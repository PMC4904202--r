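#' Larger-the-better signal-to-noise ratio
#'
#' Taguchi robust-design statistic for outcomes that should be maximised:
#' \deqn{R = -10 \log_{10}\left(\frac{1}{\#Reps}\sum_{Rep} \frac{1}{m_{Rep}^2}\right)}
#' in decibels, where the `m_Rep` are the replicate measurements of one
#' experimental run. Small replicate values are penalised through the mean of
#' squared reciprocals; measurements below `floor` are raised to `floor`
#' before squaring so that zero concentrations give a finite (strongly
#' negative) ratio instead of `-Inf`. With the default floor of 0.001 a run
#' whose duplicates are both at the detection floor scores exactly -60 dB.
#'
#' @param measurements numeric vector of replicate measurements (same units
#'   as the outcome); must be non-empty and non-negative.
#' @param floor positive measurement floor applied before the reciprocal.
#' @return The signal-to-noise ratio in dB (a single number, full precision;
#'   round only for presentation).
#' @examples
#' snr_larger_better(c(222.377, 215.023)) # 46.79 dB
#' snr_larger_better(c(0.001, 0.001))     # -60 dB
#' @export
snr_larger_better <- function(measurements, floor = 0.001) {
  if (length(measurements) == 0) {
    abort("no replicates")
  }
  if (!is.numeric(measurements) || anyNA(measurements) || any(!is.finite(measurements))) {
    abort("replicate measurements must be finite numbers")
  }
  if (any(measurements < 0)) {
    abort("replicate measurements must be non-negative")
  }
  if (!is.numeric(floor) || length(floor) != 1 || floor <= 0) {
    abort("`floor` must be a single positive number")
  }
  m <- pmax(measurements, floor)
  -10 * log10(mean(1 / m^2))
}

#' Reconstruct duplicate measurements from a printed mean and sd
#'
#' Inverts the "mean +/- sd" presentation of duplicate measurements: for two
#' replicates with sample standard deviation `sd` (n - 1 denominator) the
#' unique pair (up to order) is `mean +/- sd / sqrt(2)`. A reconstructed
#' replicate that would be negative is clamped at zero and flagged.
#'
#' @param mean,sd numeric vectors (recycled to common length); `sd >= 0`.
#' @return A tibble with columns `rep1`, `rep2` (rep1 >= rep2) and `clamped`.
#' @examples
#' reconstruct_duplicates(218.7, 5.2)  # 222.377, 215.023
#' @export
reconstruct_duplicates <- function(mean, sd) {
  if (any(sd < 0, na.rm = TRUE)) {
    abort("`sd` must be non-negative")
  }
  half <- sd / sqrt(2)
  rep1 <- mean + half
  rep2 <- mean - half
  clamped <- rep1 < 0 | rep2 < 0
  if (any(clamped, na.rm = TRUE)) {
    warn(sprintf(
      "%d reconstructed replicate pair(s) contained a negative concentration; clamped at 0",
      sum(clamped, na.rm = TRUE)
    ))
  }
  tibble(
    rep1 = pmax(rep1, 0),
    rep2 = pmax(rep2, 0),
    clamped = clamped
  )
}

#' Signal-to-noise table for a run table
#'
#' Computes the larger-the-better S/N ratio of every outcome for every run.
#' Outcomes may be supplied either as explicit replicate columns
#' (`<outcome>_rep1`, `<outcome>_rep2`, ...) or as duplicate summaries
#' (`<outcome>_mean`, `<outcome>_sd`), in which case the duplicate pair is
#' reconstructed with [reconstruct_duplicates()] first.
#'
#' @param data run table (one row per run) such as [ulva_runs()].
#' @param outcomes character vector of outcome names; defaults to every
#'   outcome for which replicate or mean/sd columns are present.
#' @param factors factor columns to carry through, default [ulva_factors()]
#'   intersected with `data`.
#' @param floor measurement floor passed to [snr_larger_better()].
#' @return A tibble with the run/factor columns and one `r_<outcome>` column
#'   per outcome (dB, full precision).
#' @examples
#' sn_table(ulva_runs(), outcomes = "rhamnose")
#' @export
sn_table <- function(data, outcomes = NULL, factors = NULL, floor = 0.001) {
  data <- as_tibble(data)
  if (is.null(outcomes)) {
    outcomes <- detect_outcomes(data)
  }
  if (length(outcomes) == 0) {
    abort("no outcome columns found (expected `<outcome>_mean`/`_sd` or `<outcome>_rep*`)")
  }
  if (is.null(factors)) {
    factors <- intersect(ulva_factors(), names(data))
  }
  id_cols <- intersect(c("run", factors), names(data))
  out <- data[, id_cols, drop = FALSE]
  for (oc in outcomes) {
    reps <- outcome_replicates(data, oc)
    out[[paste0("r_", oc)]] <- apply(reps, 1, snr_larger_better, floor = floor)
  }
  as_tibble(out)
}

# replicate matrix (runs x reps) for one outcome, from rep columns or mean/sd
outcome_replicates <- function(data, outcome) {
  rep_cols <- grep(paste0("^", outcome, "_rep[0-9]+$"), names(data), value = TRUE)
  if (length(rep_cols) > 0) {
    return(as.matrix(data[, rep_cols, drop = FALSE]))
  }
  mcol <- paste0(outcome, "_mean")
  scol <- paste0(outcome, "_sd")
  if (!all(c(mcol, scol) %in% names(data))) {
    abort(sprintf("outcome '%s' has neither replicate nor mean/sd columns", outcome))
  }
  pair <- reconstruct_duplicates(data[[mcol]], data[[scol]])
  cbind(pair$rep1, pair$rep2)
}

detect_outcomes <- function(data) {
  from_ms <- sub("_mean$", "", grep("_mean$", names(data), value = TRUE))
  from_ms <- from_ms[paste0(from_ms, "_sd") %in% names(data)]
  from_rep <- unique(sub("_rep[0-9]+$", "", grep("_rep[0-9]+$", names(data), value = TRUE)))
  union(from_ms, from_rep)
}

#' Per-level average signal-to-noise ratios
#'
#' For each process factor `P` and level `L`, averages the per-run ratio `R`
#' over the set of runs in which `P` was applied at `L`. The design may be
#' unbalanced (level run counts differ); the average always uses the actual
#' per-level count, never `K / #levels`.
#'
#' @param design data frame of factor settings, one row per run (extra
#'   columns such as `run` are ignored).
#' @param r numeric vector of per-run S/N ratios, one per row of `design`.
#' @param factors which columns of `design` are factors; default all except
#'   `run`.
#' @param levels optional named list of declared levels per factor; declared
#'   levels never used in the design are dropped with a warning.
#' @return A tibble with columns `factor_name`, `level`, `n_runs`, `mean_r`,
#'   sorted by factor then level.
#' @examples
#' sn <- ulva_sn_ratios()
#' level_averages(sn, sn$r_total)
#' @export
level_averages <- function(design, r, factors = NULL, levels = NULL) {
  design <- as_tibble(design)
  if (is.null(factors)) {
    factors <- setdiff(names(design), c("run"))
    factors <- factors[!startsWith(factors, "r_")]
  }
  if (length(r) != nrow(design)) {
    abort("need exactly one S/N value per design row")
  }
  res <- purrr::map_dfr(factors, function(p) {
    tibble(factor_name = p, level = design[[p]], r = r) %>%
      group_by(factor_name, level) %>%
      summarise(n_runs = dplyr::n(), mean_r = base::mean(r), .groups = "drop")
  })
  if (!is.null(levels)) {
    for (p in intersect(names(levels), factors)) {
      used <- res$level[res$factor_name == p]
      unused <- setdiff(levels[[p]], used)
      if (length(unused) > 0) {
        warn(sprintf(
          "factor '%s': declared level(s) %s never used in the design; excluded",
          p, paste(unused, collapse = ", ")
        ))
      }
    }
  }
  arrange(res, factor_name, level)
}

#' Sensitivity (effect range) of each factor
#'
#' The sensitivity Delta of an outcome with respect to a factor is the range
#' of its per-level average ratios: `max(mean_r) - min(mean_r)`. A factor
#' observed at a single level is not varied and raises an error.
#'
#' @param level_avg output of [level_averages()].
#' @return A tibble with columns `factor_name`, `delta` (dB, >= 0).
#' @export
sensitivity <- function(level_avg) {
  counts <- level_avg %>% group_by(factor_name) %>% summarise(k = dplyr::n(), .groups = "drop")
  if (any(counts$k < 2)) {
    abort(sprintf(
      "factor not varied: %s",
      paste(counts$factor_name[counts$k < 2], collapse = ", ")
    ))
  }
  level_avg %>%
    group_by(factor_name) %>%
    summarise(delta = max(mean_r) - min(mean_r), .groups = "drop")
}

#' Rank factors by sensitivity
#'
#' Rank 1 is assigned to the factor with the largest Delta, descending. Ties
#' are broken by the declared factor order (default: temperature, time,
#' %Acid, %Solid) and flagged with a warning.
#'
#' @param deltas tibble with columns `factor_name`, `delta` (from
#'   [sensitivity()]).
#' @param factor_order character vector giving the tie-break order; defaults
#'   to [ulva_factors()] followed by any remaining factors.
#' @return The input with an integer `rank` column added (a permutation of
#'   `1..n`).
#' @export
rank_factors <- function(deltas, factor_order = NULL) {
  if (any(!is.finite(deltas$delta))) {
    abort("all sensitivities must be finite")
  }
  if (is.null(factor_order)) {
    factor_order <- c(ulva_factors(), setdiff(deltas$factor_name, ulva_factors()))
  }
  ord <- match(deltas$factor_name, factor_order)
  if (anyNA(ord)) {
    ord[is.na(ord)] <- max(ord, na.rm = TRUE) + seq_len(sum(is.na(ord)))
  }
  if (anyDuplicated(deltas$delta)) {
    dup <- unique(deltas$delta[duplicated(deltas$delta)])
    warn(sprintf(
      "tied sensitivities (%s); ties broken by declared factor order",
      paste(format(dup), collapse = ", ")
    ))
  }
  idx <- order(-deltas$delta, ord)
  out <- deltas
  out$rank <- integer(nrow(out))
  out$rank[idx] <- seq_len(nrow(out))
  out
}

#' Optimum factor settings
#'
#' For each factor, the level whose per-level average S/N ratio is maximal.
#' Ties are broken toward the lower level and flagged with a warning.
#'
#' @param level_avg output of [level_averages()].
#' @return A tibble with columns `factor_name`, `optimum_level`, `mean_r`.
#' @export
optimum_settings <- function(level_avg) {
  res <- level_avg %>%
    group_by(factor_name) %>%
    arrange(desc(mean_r), level, .by_group = TRUE) %>%
    summarise(
      tie = sum(mean_r == max(mean_r)) > 1,
      optimum_level = level[1], mean_r = mean_r[1],
      .groups = "drop"
    )
  if (any(res$tie)) {
    warn(sprintf(
      "tied level averages for factor(s) %s; lower level selected",
      paste(res$factor_name[res$tie], collapse = ", ")
    ))
  }
  select(res, factor_name, optimum_level, mean_r)
}

#' Full Taguchi effect analysis of a run table
#'
#' Pipeline wrapper: computes the S/N table ([sn_table()]), per-level
#' averages, sensitivities, factor ranks and optimum settings for each
#' outcome.
#'
#' @inheritParams sn_table
#' @return An object of class `taguchi_analysis` with components `sn`
#'   (runs x outcomes S/N tibble), `level_averages`, `sensitivity`, `ranks`
#'   and `optima` (long tibbles keyed by `outcome`), plus `factors` and
#'   `floor`. Use [generics::tidy()] for a per-outcome-and-factor summary,
#'   [generics::glance()] for one row per outcome, and
#'   [ggplot2::autoplot()] for main-effect profiles.
#' @examples
#' fit <- taguchi_analysis(ulva_runs(), outcomes = c("total", "glucuronic_acid"))
#' tidy(fit)
#' @export
taguchi_analysis <- function(data, outcomes = NULL, factors = NULL, floor = 0.001) {
  data <- as_tibble(data)
  if (is.null(factors)) {
    factors <- intersect(ulva_factors(), names(data))
  }
  sn <- sn_table(data, outcomes = outcomes, factors = factors, floor = floor)
  outcomes <- sub("^r_", "", grep("^r_", names(sn), value = TRUE))
  design <- sn[, factors, drop = FALSE]

  per_outcome <- purrr::map(set_names(outcomes), function(oc) {
    la <- level_averages(design, sn[[paste0("r_", oc)]], factors = factors)
    dl <- sensitivity(la)
    list(
      level_avg = la,
      ranks = rank_factors(dl, factor_order = factors),
      optima = optimum_settings(la)
    )
  })
  structure(
    list(
      sn = sn,
      level_averages = purrr::map_dfr(per_outcome, "level_avg", .id = "outcome"),
      sensitivity = purrr::map_dfr(per_outcome, ~ select(.x$ranks, -rank), .id = "outcome"),
      ranks = purrr::map_dfr(per_outcome, "ranks", .id = "outcome"),
      optima = purrr::map_dfr(per_outcome, "optima", .id = "outcome"),
      factors = factors,
      outcomes = outcomes,
      floor = floor
    ),
    class = "taguchi_analysis"
  )
}

#' @export
print.taguchi_analysis <- function(x, ...) {
  cat("Taguchi larger-the-better S/N analysis\n")
  cat("  runs:", nrow(x$sn), "  factors:", paste(x$factors, collapse = ", "), "\n")
  cat("  outcomes:", paste(x$outcomes, collapse = ", "), "\n")
  cat("  measurement floor:", x$floor, "\n\n")
  cat("Factor ranking (1 = largest sensitivity):\n")
  print(tidyr::pivot_wider(
    select(x$ranks, outcome, factor_name, rank),
    names_from = factor_name, values_from = rank
  ))
  invisible(x)
}

#' @rdname taguchi_analysis
#' @param x a `taguchi_analysis` object.
#' @param ... unused.
#' @method tidy taguchi_analysis
#' @export
tidy.taguchi_analysis <- function(x, ...) {
  x$ranks %>%
    left_join(select(x$optima, outcome, factor_name, optimum_level),
      by = c("outcome", "factor_name")
    ) %>%
    arrange(outcome, rank)
}

#' @rdname taguchi_analysis
#' @method glance taguchi_analysis
#' @export
glance.taguchi_analysis <- function(x, ...) {
  x$ranks %>%
    group_by(outcome) %>%
    summarise(
      n_factors = dplyr::n(),
      top_factor = factor_name[rank == 1],
      max_delta = max(delta),
      .groups = "drop"
    )
}

#' @rdname taguchi_analysis
#' @param object a `taguchi_analysis` object.
#' @method autoplot taguchi_analysis
#' @export
autoplot.taguchi_analysis <- function(object, ...) {
  ggplot2::ggplot(
    object$level_averages,
    ggplot2::aes(x = level, y = mean_r, group = outcome, colour = outcome)
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~factor_name, scales = "free_x") +
    ggplot2::labs(
      x = "factor level", y = "mean S/N ratio (dB)",
      title = "Main-effect profiles of per-level average S/N ratios"
    )
}
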