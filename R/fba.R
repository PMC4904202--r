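# flux cap substituted for infinite bounds; fluxes are mmol/gDW/h and media
# uptake is normalised to 1 g/gDW/h, so |v| << 1000 in any sensible model
FLUX_CAP <- 1000

#' Construct a stoichiometric metabolic model
#'
#' A lightweight constraint-based model: metabolite ids, reactions with flux
#' bounds (mmol/gDW/h; `[-Inf, Inf]` for bidirectional and `[0, Inf]` for
#' unidirectional reactions when nothing more is known), a sparse
#' stoichiometry table, a designated growth reaction, media exchange
#' reactions (uptake is the negative flux direction of an exchange) with the
#' component each transports and its molecular mass, and target product
#' transporters with product molecular masses.
#'
#' @param metabolites character vector of metabolite ids.
#' @param reactions tibble with columns `id`, `lb`, `ub`.
#' @param stoichiometry tibble with columns `reaction`, `metabolite`, `coef`
#'   (negative = consumed).
#' @param growth_reaction id of the biomass/growth reaction.
#' @param exchanges tibble with columns `reaction`, `component`, `mw`
#'   (g/mol) mapping media components to their transporters.
#' @param targets tibble with columns `product`, `reaction`, `mw` (g/mol).
#' @return An object of class `metabolic_model`.
#' @export
metabolic_model <- function(metabolites, reactions, stoichiometry,
                            growth_reaction, exchanges = NULL, targets = NULL) {
  reactions <- as_tibble(reactions)
  stoichiometry <- as_tibble(stoichiometry)
  if (!all(c("id", "lb", "ub") %in% names(reactions))) {
    abort("`reactions` needs columns id, lb, ub")
  }
  if (!all(c("reaction", "metabolite", "coef") %in% names(stoichiometry))) {
    abort("`stoichiometry` needs columns reaction, metabolite, coef")
  }
  if (anyDuplicated(reactions$id)) abort("duplicated reaction ids")
  if (anyDuplicated(metabolites)) abort("duplicated metabolite ids")
  bad_r <- setdiff(stoichiometry$reaction, reactions$id)
  bad_m <- setdiff(stoichiometry$metabolite, metabolites)
  if (length(bad_r) > 0) abort(paste("stoichiometry references unknown reaction(s):", paste(bad_r, collapse = ", ")))
  if (length(bad_m) > 0) abort(paste("stoichiometry references unknown metabolite(s):", paste(bad_m, collapse = ", ")))
  if (any(reactions$lb > reactions$ub)) abort("reaction bounds must satisfy lb <= ub")
  if (!growth_reaction %in% reactions$id) abort("growth reaction not in model")
  if (!is.null(exchanges)) {
    exchanges <- as_tibble(exchanges)
    if (!all(exchanges$reaction %in% reactions$id)) abort("exchange reaction not in model")
    if (any(exchanges$mw <= 0)) abort("molecular masses must be positive")
  }
  if (!is.null(targets)) {
    targets <- as_tibble(targets)
    if (!all(targets$reaction %in% reactions$id)) abort("target reaction not in model")
    if (any(targets$mw <= 0)) abort("molecular masses must be positive")
  }
  structure(
    list(
      metabolites = metabolites,
      reactions = reactions,
      stoichiometry = stoichiometry,
      growth_reaction = growth_reaction,
      exchanges = exchanges,
      targets = targets
    ),
    class = "metabolic_model"
  )
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat(sprintf(
    "Metabolic model: %d metabolites, %d reactions (growth: %s)\n",
    length(x$metabolites), nrow(x$reactions), x$growth_reaction
  ))
  if (!is.null(x$exchanges)) {
    cat("  media exchanges:", paste(x$exchanges$component, collapse = ", "), "\n")
  }
  if (!is.null(x$targets)) {
    cat("  targets:", paste(x$targets$product, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Dense stoichiometric matrix of a model
#'
#' @param model a [metabolic_model()].
#' @return Metabolites-by-reactions numeric matrix.
#' @export
stoich_matrix <- function(model) {
  S <- matrix(0, length(model$metabolites), nrow(model$reactions),
    dimnames = list(model$metabolites, model$reactions$id)
  )
  S[cbind(
    match(model$stoichiometry$metabolite, model$metabolites),
    match(model$stoichiometry$reaction, model$reactions$id)
  )] <- model$stoichiometry$coef
  S
}

#' Read or write a metabolic model as JSON
#'
#' Schema: `metabolites` (array of ids), `reactions` (array of objects with
#' `id`, `stoichiometry` map, `lb`, `ub`; missing bounds default to
#' unbounded), `growth_reaction`, optional `exchanges` and `targets` arrays.
#'
#' @param path file path.
#' @param model a [metabolic_model()].
#' @return `read_metabolic_model()` returns a [metabolic_model()];
#'   `write_metabolic_model()` the path, invisibly.
#' @export
read_metabolic_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  reactions <- purrr::map_dfr(j$reactions, function(r) {
    tibble(
      id = r$id,
      lb = if (is.null(r$lb)) -Inf else as_bound(r$lb),
      ub = if (is.null(r$ub)) Inf else as_bound(r$ub)
    )
  })
  stoich <- purrr::map_dfr(j$reactions, function(r) {
    if (length(r$stoichiometry) == 0) {
      return(tibble())
    }
    tibble(
      reaction = r$id,
      metabolite = names(r$stoichiometry),
      coef = as.numeric(unlist(r$stoichiometry))
    )
  })
  metabolic_model(
    metabolites = unlist(j$metabolites),
    reactions = reactions,
    stoichiometry = stoich,
    growth_reaction = j$growth_reaction,
    exchanges = if (!is.null(j$exchanges)) purrr::map_dfr(j$exchanges, as_tibble),
    targets = if (!is.null(j$targets)) purrr::map_dfr(j$targets, as_tibble)
  )
}

as_bound <- function(x) {
  if (is.character(x)) {
    return(switch(x, "Inf" = Inf, "-Inf" = -Inf, as.numeric(x)))
  }
  as.numeric(x)
}

#' @rdname read_metabolic_model
#' @export
write_metabolic_model <- function(model, path) {
  stoich_by_r <- split(model$stoichiometry, model$stoichiometry$reaction)
  reactions <- purrr::map(seq_len(nrow(model$reactions)), function(i) {
    r <- model$reactions[i, ]
    st <- stoich_by_r[[r$id]]
    list(
      id = r$id,
      stoichiometry = if (is.null(st)) list() else as.list(setNames(st$coef, st$metabolite)),
      lb = if (is.finite(r$lb)) r$lb else "-Inf",
      ub = if (is.finite(r$ub)) r$ub else "Inf"
    )
  })
  jsonlite::write_json(
    list(
      metabolites = model$metabolites,
      reactions = reactions,
      growth_reaction = model$growth_reaction,
      exchanges = model$exchanges,
      targets = model$targets
    ),
    path,
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(path)
}

#' Media uptake bounds from a feedstock composition
#'
#' Converts mass fractions (g per kg feedstock) of media components into
#' molar uptake caps on the model's exchange reactions, normalised so that
#' the total permitted mass-uptake rate is 1 g/gDW/h: each component's mass
#' allowance is proportional to its share of the usable media mass, and the
#' molar cap is `mass_allowance / MW * 1000` mmol/gDW/h. Components without
#' a matching transporter in the model are dropped with a message.
#'
#' @param model a [metabolic_model()] with `exchanges`.
#' @param media tibble with columns `component`, `g_per_kg`.
#' @return A tibble with columns `reaction`, `component`, `g_per_kg`,
#'   `mass_cap_g` (summing to 1 over usable components) and `uptake_mmol`.
#' @examples
#' m <- toy_fermenter_model()
#' media_uptake_bounds(m, tibble::tibble(component = "glucose", g_per_kg = 1000))
#' @export
media_uptake_bounds <- function(model, media) {
  if (is.null(model$exchanges)) abort("model has no media exchange reactions")
  media <- as_tibble(media)
  if (any(media$g_per_kg < 0)) abort("media mass fractions must be non-negative")
  usable <- media %>%
    filter(g_per_kg > 0) %>%
    dplyr::inner_join(model$exchanges, by = "component")
  dropped <- setdiff(media$component[media$g_per_kg > 0], usable$component)
  if (length(dropped) > 0) {
    inform(paste(
      "media component(s) without a model transporter dropped:",
      paste(dropped, collapse = ", ")
    ))
  }
  if (nrow(usable) == 0) abort("no consumable components")
  usable %>%
    mutate(
      mass_cap_g = g_per_kg / sum(g_per_kg),
      uptake_mmol = mass_cap_g / mw * 1000
    ) %>%
    select(reaction, component, g_per_kg, mass_cap_g, uptake_mmol)
}

#' Constrain a model to a medium
#'
#' Sets every exchange reaction's uptake bound (its negative lower bound)
#' from [media_uptake_bounds()]; exchanges whose component is absent from
#' the medium are closed for uptake (lower bound 0). Secretion bounds are
#' untouched.
#'
#' @param model a [metabolic_model()].
#' @param bounds output of [media_uptake_bounds()].
#' @return The constrained model.
#' @export
apply_media <- function(model, bounds) {
  if (is.null(model$exchanges)) abort("model has no media exchange reactions")
  for (rid in model$exchanges$reaction) {
    i <- match(rid, model$reactions$id)
    j <- match(rid, bounds$reaction)
    model$reactions$lb[i] <- if (is.na(j)) 0 else -bounds$uptake_mmol[j]
  }
  model
}

# core bounded-variable LP: optimise c'v s.t. S v = 0, lb <= v <= ub.
# Infinite bounds are capped at +/- FLUX_CAP. Returns list(value, flux,
# solved) with solved 1 (optimal) or -1 (infeasible).
fba_lp <- function(model, objective, maximize = TRUE) {
  S <- stoich_matrix(model)
  lb <- pmax(model$reactions$lb, -FLUX_CAP)
  ub <- pmin(model$reactions$ub, FLUX_CAP)
  obj_i <- match(objective, model$reactions$id)
  if (is.na(obj_i)) abort(sprintf("unknown reaction '%s'", objective))

  cc <- rep(0, ncol(S))
  cc[obj_i] <- 1
  res <- solve_bounded_lp(S, rep(0, nrow(S)), lb, ub, cc, maximize = maximize)
  if (res$status != "optimal") {
    return(list(value = NA_real_, flux = NULL, solved = -1L))
  }
  list(
    value = res$flux[obj_i],
    flux = setNames(res$flux, model$reactions$id),
    solved = 1L
  )
}

#' Maximal growth rate of a model (flux balance analysis)
#'
#' Solves the linear programme: maximise the growth-reaction flux subject to
#' steady-state mass balance `S v = 0` and the flux bounds (including any
#' media uptake caps set with [apply_media()]).
#'
#' @param model a [metabolic_model()].
#' @return A list with `growth` (h^-1), the optimal `flux` vector (one of
#'   possibly many alternate optima; only the objective value is a contract
#'   output), and `solved`.
#' @export
max_growth <- function(model) {
  res <- fba_lp(model, model$growth_reaction, maximize = TRUE)
  if (res$solved == -1) {
    abort("growth LP infeasible: check mass balance and bounds")
  }
  if (res$solved != 1) {
    abort("growth LP not solved within the iteration limit")
  }
  if (res$value >= FLUX_CAP * (1 - 1e-9)) {
    abort("model leak: growth unbounded up to the flux cap")
  }
  list(growth = res$value, flux = res$flux, solved = res$solved)
}

#' Flux range of a target reaction at maximal growth (FVA)
#'
#' Two linear programmes minimising and maximising the target flux with the
#' growth flux fixed at `growth`. If fixing growth exactly makes the
#' programme infeasible (degenerate optimum at a numerical boundary), the
#' fixation is relaxed to `growth * (1 - 1e-6)` as a lower bound and the
#' relaxation reported with a message.
#'
#' @param model a [metabolic_model()].
#' @param target target reaction id.
#' @param growth growth flux at which to evaluate the range; defaults to
#'   [max_growth()] of the model.
#' @return A tibble with columns `min_flux`, `max_flux` (`min <= max`).
#' @export
target_flux_range <- function(model, target, growth = NULL) {
  if (is.null(growth)) growth <- max_growth(model)$growth
  gi <- match(model$growth_reaction, model$reactions$id)
  fixed <- model
  # fix growth within a 1e-9 absolute tolerance band: the LP optimum carries
  # float error, and an exact equality at a slightly-off value is infeasible
  fixed$reactions$lb[gi] <- growth - 1e-9
  fixed$reactions$ub[gi] <- min(growth + 1e-9, model$reactions$ub[gi])
  lo <- fba_lp(fixed, target, maximize = FALSE)
  hi <- fba_lp(fixed, target, maximize = TRUE)
  if (lo$solved != 1 || hi$solved != 1) {
    inform("growth fixation infeasible; relaxed to a (1 - 1e-6) lower bound")
    relaxed <- model
    relaxed$reactions$lb[gi] <- growth * (1 - 1e-6)
    lo <- fba_lp(relaxed, target, maximize = FALSE)
    hi <- fba_lp(relaxed, target, maximize = TRUE)
    if (lo$solved != 1 || hi$solved != 1) {
      abort("target flux LP infeasible even after relaxed growth fixation")
    }
  }
  tibble(min_flux = lo$value, max_flux = hi$value)
}

#' Product yield in g per kg feedstock
#'
#' Unit bridge from a transporter flux to a mass yield: with media uptake
#' normalised to 1 g/gDW/h, a product flux of `v` mmol/gDW/h carries
#' `v * MW` mg product per g of consumed medium, i.e. `v * MW` g product per
#' kg feedstock.
#'
#' @param flux flux in mmol/gDW/h.
#' @param mw product molecular mass in g/mol.
#' @return Yield in g product per kg feedstock.
#' @examples
#' yield_g_per_kg(1, 46.07) # ethanol, 46.07 g/kg
#' @export
yield_g_per_kg <- function(flux, mw) {
  if (any(mw <= 0)) abort("molecular mass must be positive")
  flux * mw
}

#' Fermentation yield panel over hydrolysis experiments
#'
#' For each run: overwrites the carbohydrate rows of the base feedstock
#' composition with the run's measured values, rebuilds the media uptake
#' bounds, maximises growth, applies the viability gate (growth below
#' `epsilon` means non-viable and zero product yields), and otherwise runs
#' flux variability analysis for each target product, reporting minimal and
#' maximal yields in g product per kg feedstock.
#'
#' @param model a [metabolic_model()] with `exchanges` and `targets`.
#' @param base_media tibble with columns `component`, `g_per_kg` (e.g. the
#'   non-inert rows of [ulva_composition()]).
#' @param run_media tibble with columns `run`, `component`, `g_per_kg`:
#'   per-run overrides of the base composition (see [run_sugar_g_per_kg()]).
#' @param epsilon viability threshold on the growth rate (default 1e-5
#'   h^-1).
#' @return A tibble with one row per run and target product: `run`,
#'   `growth`, `viable`, `product`, `min_flux`, `max_flux`,
#'   `min_yield_g_kg`, `max_yield_g_kg`, `status`.
#' @export
ferment_panel <- function(model, base_media, run_media, epsilon = 1e-5) {
  if (is.null(model$targets)) abort("model has no target products")
  base_media <- as_tibble(base_media)
  run_media <- as_tibble(run_media)
  runs <- unique(run_media$run)
  purrr::map_dfr(runs, function(rn) {
    over <- filter(run_media, run == rn)
    media <- base_media %>%
      filter(!component %in% over$component) %>%
      bind_rows(select(over, component, g_per_kg))
    result <- tryCatch(
      {
        bounds <- suppressMessages(media_uptake_bounds(model, media))
        constrained <- apply_media(model, bounds)
        mg <- max_growth(constrained)
        viable <- mg$growth >= epsilon
        per_target <- purrr::map_dfr(seq_len(nrow(model$targets)), function(k) {
          tg <- model$targets[k, ]
          if (!viable) {
            return(tibble(
              product = tg$product, min_flux = 0, max_flux = 0
            ))
          }
          rng <- target_flux_range(constrained, tg$reaction, growth = mg$growth)
          tibble(product = tg$product, min_flux = rng$min_flux, max_flux = rng$max_flux)
        })
        per_target %>%
          mutate(
            run = rn, growth = mg$growth, viable = viable,
            min_yield_g_kg = yield_g_per_kg(min_flux, model$targets$mw[match(product, model$targets$product)]),
            max_yield_g_kg = yield_g_per_kg(max_flux, model$targets$mw[match(product, model$targets$product)]),
            status = "ok"
          )
      },
      error = function(e) {
        tibble(
          product = model$targets$product, min_flux = NA_real_, max_flux = NA_real_,
          run = rn, growth = NA_real_, viable = NA,
          min_yield_g_kg = NA_real_, max_yield_g_kg = NA_real_,
          status = conditionMessage(e)
        )
      }
    )
    select(
      result, run, growth, viable, product,
      min_flux, max_flux, min_yield_g_kg, max_yield_g_kg, status
    )
  })
}

#' Per-run sugar content of the feedstock in g per kg dry weight
#'
#' Converts the measured hydrolysate concentrations (ug/ml) of a run table
#' into released sugar mass per kg of dry biomass:
#' `g/kg = conc * volume * dilution / dry_weight`, the same mass bridge as
#' [hydrolysate_yield()] applied per sugar. The result is formatted as the
#' per-run media override table consumed by [ferment_panel()], with sugars
#' mapped to feedstock component names.
#'
#' @param runs run table such as [ulva_runs()].
#' @param sugar_components named character vector mapping `<sugar>` column
#'   prefixes to media component names.
#' @inheritParams hydrolysate_yield
#' @return A tibble with columns `run`, `component`, `g_per_kg`.
#' @examples
#' run_sugar_g_per_kg(ulva_runs())
#' @export
run_sugar_g_per_kg <- function(runs,
                               sugar_components = c(
                                 rhamnose = "L-Rhamnose",
                                 glucose = "D-Glucose",
                                 xylose = "D-Xylose",
                                 glucuronic_acid = "Glucuronic Acid"
                               ),
                               volume_ml = 1, dilution = 2.7) {
  runs <- as_tibble(runs)
  dw <- dry_weight(runs$solid_pct, volume_ml = volume_ml)
  purrr::map_dfr(names(sugar_components), function(sg) {
    conc <- runs[[paste0(sg, "_mean")]]
    tibble(
      run = runs$run,
      component = unname(sugar_components[sg]),
      g_per_kg = conc * volume_ml * dilution / dw
    )
  }) %>% arrange(run)
}
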