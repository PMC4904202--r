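# run code with a local RNG state so generators are pure in (spec, seed)
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Default planted main effects for simulated DOE tables
#'
#' Per-factor, per-level outcome multipliers emulating the qualitative
#' structure of the hydrolysis experiment: acid dominates (non-monotone,
#' peaking at the 2% level), solid load comes second, time and temperature
#' are weak. On the packaged mixed-level 16-run array these defaults give
#' deterministic realized sensitivities of roughly 31 (acid), 15 (solid),
#' 9 (time) and 5 (temperature) dB, so the planted importance ordering is
#' acid > solid > time > temperature with comfortable margins over
#' replicate noise.
#'
#' @return Named list of named multiplier vectors keyed by factor column.
#' @export
doe_effects <- function() {
  list(
    temperature_c = c("100" = 1, "121" = 1.05, "134" = 1.1),
    time_min = c("30" = 1.3, "45" = 1.15, "60" = 1),
    acid_pct = c("0" = 1, "0.5" = 3, "2" = 30, "5" = 20),
    solid_pct = c("5" = 1, "15" = 2.5, "25" = 5)
  )
}

#' Simulate a replicated DOE outcome table with planted effects
#'
#' Generates duplicate (or `n_rep`-fold) outcome measurements on a factorial
#' design: `outcome = baseline * prod(level multipliers) * noise`, with
#' multiplicative log-normal replicate noise by default (hydrolysate
#' concentrations span four orders of magnitude, so noise proportional to
#' the signal is the realistic choice); additive gaussian noise is available
#' via `noise = "gaussian"` (truncated at zero). The planted ground truth is
#' attached as the `effects` attribute for recovery tests.
#'
#' @param design factor table, one row per run (default the packaged 16-run
#'   array [ulva_design()]).
#' @param effects named list of per-level multiplier vectors, as
#'   [doe_effects()].
#' @param baseline outcome value when every multiplier is 1.
#' @param noise_sd relative noise level (sdlog of the log-normal, or sd as a
#'   fraction of the true mean for gaussian noise).
#' @param noise `"lognormal"` or `"gaussian"`.
#' @param n_rep replicates per run (default 2).
#' @param seed integer seed; fixed seed gives identical tables.
#' @return The design tibble with `response_rep1..n_rep` columns added and
#'   attributes `effects` and `truth` (noise-free per-run means); feed to
#'   [sn_table()]/[taguchi_analysis()] with `outcomes = "response"`.
#' @examples
#' d <- simulate_doe(noise_sd = 0, seed = 1)
#' taguchi_analysis(d, outcomes = "response")$ranks
#' @export
simulate_doe <- function(design = ulva_design(), effects = doe_effects(),
                         baseline = 1000, noise_sd = 0.05,
                         noise = c("lognormal", "gaussian"),
                         n_rep = 2, seed = NULL) {
  noise <- arg_match(noise)
  if (noise_sd < 0) abort("`noise_sd` must be non-negative")
  design <- as_tibble(design)
  mult <- rep(1, nrow(design))
  for (f in names(effects)) {
    if (!f %in% names(design)) abort(sprintf("effect factor '%s' not in design", f))
    lev <- as.character(design[[f]])
    if (!all(lev %in% names(effects[[f]]))) {
      abort(sprintf("design uses level(s) of '%s' missing from `effects`", f))
    }
    mult <- mult * unname(effects[[f]][lev])
  }
  mu <- baseline * mult
  out <- design
  with_seed(seed, {
    for (k in seq_len(n_rep)) {
      reps <- switch(noise,
        lognormal = mu * exp(rnorm(length(mu), mean = 0, sd = noise_sd)),
        gaussian = pmax(mu + rnorm(length(mu), mean = 0, sd = noise_sd * mu), 0)
      )
      out[[paste0("response_rep", k)]] <- reps
    }
  })
  attr(out, "effects") <- effects
  attr(out, "truth") <- mu
  out
}

#' Toy metabolic models with known optima
#'
#' Small stoichiometric networks whose flux balance solutions are known in
#' closed form, used to test the LP machinery:
#' * `toy_chain_model()`: uptake -> A -> growth; maximal growth equals the
#'   uptake cap.
#' * `toy_branch_model()`: growth and a secreted product compete for one
#'   precursor. With `cofactor_uptake = NULL` growth consumes the entire
#'   precursor supply at its optimum and the product range at maximal growth
#'   is (0, 0); with a finite cofactor cap growth is limited by the
#'   cofactor, leaving `uptake - cofactor_uptake` precursor for the product,
#'   whose range becomes (0, uptake - cofactor_uptake).
#' * `toy_fermenter_model()`: glucose -> 2 ethanol + 2 ATP, growth on ATP;
#'   on a glucose-only medium at 1 g/gDW/h the ethanol yield is the
#'   stoichiometric maximum 2 * (46.07 / 180.16) * 1000 = 511.4 g per kg.
#'
#' The analytically expected values are attached as the `expected`
#' attribute.
#'
#' @param uptake precursor uptake cap in mmol/gDW/h.
#' @param cofactor_uptake optional cofactor uptake cap (see above).
#' @return A [metabolic_model()] with an `expected` attribute.
#' @examples
#' max_growth(toy_chain_model(10))$growth # 10
#' @export
toy_chain_model <- function(uptake = 10) {
  m <- metabolic_model(
    metabolites = c("A"),
    reactions = tibble(
      id = c("EX_A", "GROWTH"),
      lb = c(-uptake, 0),
      ub = c(Inf, Inf)
    ),
    stoichiometry = tibble(
      reaction = c("EX_A", "GROWTH"),
      metabolite = c("A", "A"),
      coef = c(-1, -1)
    ),
    growth_reaction = "GROWTH"
  )
  attr(m, "expected") <- list(max_growth = uptake)
  m
}

#' @rdname toy_chain_model
#' @export
toy_branch_model <- function(uptake = 10, cofactor_uptake = NULL) {
  coupled <- is.null(cofactor_uptake)
  mets <- c("A", "P", if (!coupled) "N")
  reactions <- tibble(
    id = c("EX_A", "PROD", "EX_P", "GROWTH", if (!coupled) "EX_N"),
    lb = c(-uptake, 0, 0, 0, if (!coupled) -cofactor_uptake),
    ub = rep(Inf, if (coupled) 4 else 5)
  )
  stoich <- bind_rows(
    tibble(reaction = "EX_A", metabolite = "A", coef = -1),
    tibble(reaction = "PROD", metabolite = c("A", "P"), coef = c(-1, 1)),
    tibble(reaction = "EX_P", metabolite = "P", coef = -1),
    tibble(reaction = "GROWTH", metabolite = "A", coef = -1),
    if (!coupled) tibble(reaction = "GROWTH", metabolite = "N", coef = -1),
    if (!coupled) tibble(reaction = "EX_N", metabolite = "N", coef = -1)
  )
  m <- metabolic_model(
    metabolites = mets,
    reactions = reactions,
    stoichiometry = stoich,
    growth_reaction = "GROWTH",
    targets = tibble(product = "P", reaction = "EX_P", mw = 46.07)
  )
  attr(m, "expected") <- if (coupled) {
    list(max_growth = uptake, fva = c(0, 0))
  } else {
    list(
      max_growth = min(uptake, cofactor_uptake),
      fva = c(0, max(uptake - cofactor_uptake, 0))
    )
  }
  m
}

#' @rdname toy_chain_model
#' @export
toy_fermenter_model <- function() {
  m <- metabolic_model(
    metabolites = c("glc", "eth", "atp"),
    reactions = tibble(
      id = c("EX_GLC", "FERM", "GROWTH", "EX_ETH"),
      lb = c(0, 0, 0, 0), # uptake opened by apply_media()
      ub = rep(Inf, 4)
    ),
    stoichiometry = bind_rows(
      tibble(reaction = "EX_GLC", metabolite = "glc", coef = -1),
      tibble(
        reaction = "FERM", metabolite = c("glc", "eth", "atp"),
        coef = c(-1, 2, 2)
      ),
      tibble(reaction = "GROWTH", metabolite = "atp", coef = -1),
      tibble(reaction = "EX_ETH", metabolite = "eth", coef = -1)
    ),
    growth_reaction = "GROWTH",
    exchanges = tibble(reaction = "EX_GLC", component = "glucose", mw = 180.16),
    targets = tibble(product = "ethanol", reaction = "EX_ETH", mw = 46.07)
  )
  attr(m, "expected") <- list(
    ethanol_yield_g_kg = 2 * 46.07 / 180.16 * 1000
  )
  m
}

#' Toy fermenter matched to the Ulva feedstock composition
#'
#' A deliberately small fermentation network whose transporters use the
#' component names of [ulva_composition()], so it can run a full
#' [ferment_panel()] over the packaged hydrolysis runs. Glucose and xylose
#' are fermented to ethanol with ATP gain; rhamnose and glucuronic acid
#' yield ethanol but no ATP; amino acids supply a lumped biomass precursor;
#' growth consumes 1000 ATP (a growth-associated maintenance-scale demand)
#' plus one precursor unit. Because only the sugar fluxes generate ATP,
#' runs whose hydrolysates contain almost no glucose/xylose fall below the
#' 1e-5 viability gate and produce all-zero yield rows, mirroring the
#' qualitative structure of genome-scale fermentation panels on the same
#' media. This is a synthetic stand-in for a genome-scale model, not a
#' reduction of one.
#'
#' @return A [metabolic_model()] with exchanges for the four sugars and the
#'   seventeen amino acids, and ethanol as target product.
#' @export
toy_ulva_fermenter <- function() {
  aa <- c(
    "L-Aspartic acid" = 133.10, "L-Threonine" = 119.12, "L-Serine" = 105.09,
    "L-Glutamic acid" = 147.13, "L-Proline" = 115.13, "Glycine" = 75.07,
    "L-Alanine" = 89.09, "L-Valine" = 117.15, "L-Methionine" = 149.21,
    "Cystine" = 240.30, "L-Isoleucine" = 131.17, "L-Leucine" = 131.17,
    "L-Tyrosine" = 181.19, "L-Phenylalanine" = 165.19, "L-Histidine" = 155.15,
    "L-Lysine" = 146.19, "L-Arginine" = 174.20
  )
  aa_rids <- sprintf("EX_AA%02d", seq_along(aa))
  sugar <- tibble(
    rid = c("EX_GLC", "EX_XYL", "EX_RHA", "EX_UA"),
    met = c("glc", "xyl", "rha", "ua"),
    component = c("D-Glucose", "D-Xylose", "L-Rhamnose", "Glucuronic Acid"),
    mw = c(180.16, 150.13, 164.16, 194.14),
    eth = c(2, 5 / 3, 1.5, 1),
    atp = c(2, 5 / 3, 0, 0)
  )
  ferm_ids <- paste0("FERM_", toupper(sugar$met))
  reactions <- tibble(
    id = c(sugar$rid, aa_rids, ferm_ids, "GROWTH", "EX_ETH"),
    lb = 0, # uptakes opened by apply_media()
    ub = Inf
  )
  stoich <- bind_rows(
    tibble(reaction = sugar$rid, metabolite = sugar$met, coef = -1),
    tibble(reaction = aa_rids, metabolite = "aa", coef = -1),
    purrr::map_dfr(seq_len(nrow(sugar)), function(i) {
      tibble(
        reaction = ferm_ids[i],
        metabolite = c(sugar$met[i], "eth", "atp"),
        coef = c(-1, sugar$eth[i], sugar$atp[i])
      ) %>% filter(coef != 0)
    }),
    tibble(
      reaction = "GROWTH", metabolite = c("atp", "aa"),
      coef = c(-1000, -1)
    ),
    tibble(reaction = "EX_ETH", metabolite = "eth", coef = -1)
  )
  metabolic_model(
    metabolites = c("glc", "xyl", "rha", "ua", "aa", "eth", "atp"),
    reactions = reactions,
    stoichiometry = stoich,
    growth_reaction = "GROWTH",
    exchanges = bind_rows(
      select(sugar, reaction = rid, component, mw),
      tibble(reaction = aa_rids, component = names(aa), mw = unname(aa))
    ),
    targets = tibble(product = "ethanol", reaction = "EX_ETH", mw = 46.07)
  )
}

#' Random small metabolic network
#'
#' Draws a random sparse stoichiometric network with finite flux bounds
#' (zero flux always feasible, so the growth LP is feasible and bounded) for
#' stress-testing the LP solver against exhaustive vertex enumeration. The
#' last reaction is designated the growth reaction.
#'
#' @param n_metabolites,n_reactions network size (reactions >= metabolites).
#' @param seed integer seed.
#' @param max_bound largest flux bound magnitude.
#' @return A [metabolic_model()].
#' @export
random_toy_network <- function(n_metabolites = 3, n_reactions = 6,
                               seed = NULL, max_bound = 10) {
  if (n_reactions < n_metabolites) abort("need at least as many reactions as metabolites")
  with_seed(seed, {
    mets <- paste0("M", seq_len(n_metabolites))
    rids <- paste0("R", seq_len(n_reactions))
    stoich <- purrr::map_dfr(seq_len(n_reactions), function(j) {
      k <- sample(1:min(2, n_metabolites), 1)
      who <- sample(n_metabolites, k)
      tibble(
        reaction = rids[j],
        metabolite = mets[who],
        coef = sample(c(-2, -1, 1, 2), k, replace = TRUE)
      )
    })
    u <- sample(seq_len(max_bound), n_reactions, replace = TRUE)
    rev <- runif(n_reactions) < 0.4
    reactions <- tibble(
      id = rids,
      lb = ifelse(rev, -u, 0),
      ub = u
    )
    metabolic_model(
      metabolites = mets,
      reactions = reactions,
      stoichiometry = stoich,
      growth_reaction = rids[n_reactions]
    )
  })
}

#' Simulate resonator mode observations for a droplet load
#'
#' Evaluates the droplet forward model for every mode of the membrane spec
#' and adds multiplicative gaussian noise to the frequency shifts:
#' `f_wet = f_dry - shift * (1 + N(0, noise_sd))`.
#'
#' @param load a [droplet_load()].
#' @param spec a [membrane_spec()].
#' @param noise_sd relative noise on the shifts (e.g. 0.001 for 0.1%).
#' @param seed integer seed.
#' @return Observation tibble for [invert_load()] with columns `m`, `n`,
#'   `f_dry_hz`, `f_wet_hz`.
#' @examples
#' simulate_resonator(droplet_load(1004.2, 0.3), membrane_spec())
#' @export
simulate_resonator <- function(load, spec = membrane_spec(),
                               noise_sd = 0, seed = NULL) {
  shifts <- purrr::map_dbl(
    seq_len(nrow(spec$modes)),
    function(i) frequency_shift(spec, c(spec$modes$m[i], spec$modes$n[i]), load)
  )
  with_seed(seed, {
    noisy <- shifts * (1 + rnorm(length(shifts), sd = noise_sd))
  })
  tibble(
    m = spec$modes$m,
    n = spec$modes$n,
    f_dry_hz = spec$modes$f_dry_hz,
    f_wet_hz = pmin(spec$modes$f_dry_hz - noisy, spec$modes$f_dry_hz)
  )
}

#' Simulate a linear process-outcome dataset for PLS
#'
#' `y = intercept + X %*% coefficients + N(0, noise_sd)` with predictors
#' taken from the packaged 16-run design grid (`design = "grid"`, resampled
#' with replacement if `n` exceeds 16) or drawn uniformly over the factor
#' ranges. Defaults plant the percent-yield process model (intercept 6.44;
#' temperature 0.04, time -0.004, acid 0.7, solid -0.60) with noise sd 2.
#'
#' @param n number of samples (>= 5).
#' @param coefficients named numeric vector of raw-scale coefficients.
#' @param intercept intercept.
#' @param noise_sd gaussian noise sd.
#' @param design `"grid"` or `"uniform"`.
#' @param seed integer seed.
#' @return Tibble with the factor columns and response `y`; attributes
#'   `coefficients` and `intercept` carry the ground truth.
#' @export
simulate_pls_data <- function(n = 16,
                              coefficients = c(
                                temperature_c = 0.04, time_min = -0.004,
                                acid_pct = 0.7, solid_pct = -0.60
                              ),
                              intercept = 6.44, noise_sd = 2,
                              design = c("grid", "uniform"), seed = NULL) {
  design <- arg_match(design)
  if (n < 5) abort("need at least 5 samples")
  with_seed(seed, {
    x <- if (design == "grid") {
      g <- ulva_design()[, names(coefficients), drop = FALSE]
      if (n <= nrow(g)) g[seq_len(n), ] else g[sample(nrow(g), n, replace = TRUE), ]
    } else {
      ranges <- list(
        temperature_c = c(100, 134), time_min = c(30, 60),
        acid_pct = c(0, 5), solid_pct = c(5, 25)
      )
      as_tibble(purrr::map(
        ranges[names(coefficients)],
        ~ runif(n, .x[1], .x[2])
      ))
    }
    y <- intercept + drop(as.matrix(x) %*% coefficients) + rnorm(n, sd = noise_sd)
    out <- bind_cols(x, tibble(y = y))
  })
  attr(out, "coefficients") <- coefficients
  attr(out, "intercept") <- intercept
  out
}
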