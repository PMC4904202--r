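test_that("model construction validates structure", {
  expect_error(
    metabolic_model(
      metabolites = "A",
      reactions = tibble::tibble(id = "R1", lb = 0, ub = 1),
      stoichiometry = tibble::tibble(reaction = "R2", metabolite = "A", coef = 1),
      growth_reaction = "R1"
    ),
    "unknown reaction"
  )
  expect_error(
    metabolic_model(
      metabolites = "A",
      reactions = tibble::tibble(id = "R1", lb = 1, ub = 0),
      stoichiometry = tibble::tibble(reaction = "R1", metabolite = "A", coef = 1),
      growth_reaction = "R1"
    ),
    "lb <= ub"
  )
})

test_that("maximal growth matches hand solutions on toy networks", {
  expect_equal(max_growth(toy_chain_model(10))$growth, 10)
  expect_equal(max_growth(toy_chain_model(3.5))$growth, 3.5)
  # closed uptake, no internal source: zero growth
  expect_equal(max_growth(toy_chain_model(0))$growth, 0)
})

test_that("unbounded growth is reported as a model leak", {
  leaky <- metabolic_model(
    metabolites = "A",
    reactions = tibble::tibble(id = c("SRC", "GROWTH"), lb = c(-Inf, 0), ub = c(Inf, Inf)),
    stoichiometry = tibble::tibble(
      reaction = c("SRC", "GROWTH"), metabolite = "A", coef = c(-1, -1)
    ),
    growth_reaction = "GROWTH"
  )
  expect_error(max_growth(leaky), "model leak")
})

test_that("flux variability reflects precursor competition with growth", {
  # fully coupled: biomass consumes the entire precursor supply at optimum
  coupled <- toy_branch_model(10)
  expect_equal(max_growth(coupled)$growth, 10)
  rng <- target_flux_range(coupled, "EX_P")
  expect_equal(c(rng$min_flux, rng$max_flux), c(0, 0), tolerance = 1e-8)
  # cofactor-limited: half the precursor is left over for the product
  half <- toy_branch_model(10, cofactor_uptake = 5)
  expect_equal(max_growth(half)$growth, 5)
  rng2 <- target_flux_range(half, "EX_P")
  expect_equal(c(rng2$min_flux, rng2$max_flux), c(0, 5), tolerance = 1e-8)
  # the FVA interval contains the FBA optimum's target flux
  opt_flux <- max_growth(half)$flux[["EX_P"]]
  expect_gte(opt_flux, rng2$min_flux - 1e-9)
  expect_lte(opt_flux, rng2$max_flux + 1e-9)
})

test_that("media bounds scale uptake to a 1 g/gDW/h mass budget", {
  fm <- toy_fermenter_model()
  b <- media_uptake_bounds(fm, tibble::tibble(component = "glucose", g_per_kg = 1000))
  expect_equal(b$uptake_mmol, 1 / 180.16 * 1000, tolerance = 1e-12)
  expect_equal(sum(b$mass_cap_g), 1, tolerance = 1e-12)
  # two components at equal mass: equal mass caps, molar bounds inverse to MW
  m2 <- toy_ulva_fermenter()
  b2 <- media_uptake_bounds(m2, tibble::tibble(
    component = c("D-Glucose", "D-Xylose"), g_per_kg = c(100, 100)
  ))
  expect_equal(b2$mass_cap_g, c(0.5, 0.5))
  expect_equal(
    b2$uptake_mmol[b2$component == "D-Glucose"] /
      b2$uptake_mmol[b2$component == "D-Xylose"],
    150.13 / 180.16
  )
  # realistic media: total permitted mass flux sums to exactly 1 g
  media <- dplyr::bind_rows(
    dplyr::filter(ulva_composition(), class %in% c("amino_acid")),
    tibble::tibble(component = c("D-Glucose", "D-Xylose", "L-Rhamnose", "Glucuronic Acid"),
      g_per_kg = c(93.53, 12.2, 67.3, 51.6), class = "carbohydrate", note = NA
    )
  )[, c("component", "g_per_kg")]
  b3 <- media_uptake_bounds(m2, media)
  expect_equal(sum(b3$mass_cap_g), 1, tolerance = 1e-9)
  expect_error(
    suppressMessages(media_uptake_bounds(m2, tibble::tibble(component = "unobtainium", g_per_kg = 10))),
    "no consumable components"
  )
})

test_that("the glucose-only fermenter reaches the stoichiometric ethanol maximum", {
  fm <- toy_fermenter_model()
  cm <- apply_media(fm, media_uptake_bounds(
    fm, tibble::tibble(component = "glucose", g_per_kg = 1000)
  ))
  mg <- max_growth(cm)
  rng <- target_flux_range(cm, "EX_ETH", growth = mg$growth)
  yield <- yield_g_per_kg(rng$max_flux, 46.07)
  expect_equal(yield, 2 * 46.07 / 180.16 * 1000, tolerance = 1e-6)
  expect_equal(yield_g_per_kg(0, 46.07), 0)
  expect_equal(yield_g_per_kg(1, 46.07), 46.07)
  expect_error(yield_g_per_kg(1, 0), "positive")
})

test_that("solutions satisfy mass balance and LP optima match vertex enumeration", {
  n_nets <- 30
  for (s in seq_len(n_nets)) {
    m <- random_toy_network(
      n_metabolites = 2 + (s %% 3), n_reactions = 4 + (s %% 5),
      seed = 6000 + s
    )
    got <- max_growth(m)
    expect_lt(max(abs(stoich_matrix(m) %*% got$flux)), 1e-8)
    want <- oracle_max_growth(m)
    expect_equal(got$growth, want, tolerance = 1e-7)
  }
})

test_that("tightening media never increases growth", {
  m <- toy_ulva_fermenter()
  media <- dplyr::bind_rows(
    dplyr::filter(ulva_composition(), class == "amino_acid")[, c("component", "g_per_kg")],
    tibble::tibble(
      component = c("D-Glucose", "D-Xylose"),
      g_per_kg = c(90, 12)
    )
  )
  g_full <- max_growth(apply_media(m, media_uptake_bounds(m, media)))$growth
  no_glc <- dplyr::filter(media, component != "D-Glucose")
  g_less <- max_growth(apply_media(m, media_uptake_bounds(m, no_glc)))$growth
  expect_lte(g_less, g_full + 1e-12)
})

test_that("the fermentation panel is deterministic and applies the viability gate", {
  m <- toy_ulva_fermenter()
  base <- dplyr::filter(ulva_composition(), class != "inert")[, c("component", "g_per_kg")]
  runs <- tibble::tibble(
    run = c(1, 1, 1, 1, 2, 2, 2, 2, 3, 3, 3, 3),
    component = rep(c("D-Glucose", "D-Xylose", "L-Rhamnose", "Glucuronic Acid"), 3),
    g_per_kg = c(90, 12, 60, 50, 90, 12, 60, 50, 0, 0, 0, 0)
  )
  panel <- suppressMessages(ferment_panel(m, base, runs))
  expect_equal(nrow(panel), 3)
  # identical media give identical rows
  expect_equal(
    panel[panel$run == 1, -1],
    panel[panel$run == 2, -1]
  )
  # carbohydrate-free media: no ATP source, non-viable, zero yields
  r3 <- panel[panel$run == 3, ]
  expect_false(r3$viable)
  expect_equal(c(r3$min_yield_g_kg, r3$max_yield_g_kg), c(0, 0))
  # viable rows have min <= max
  expect_true(all(panel$min_yield_g_kg <= panel$max_yield_g_kg + 1e-9))
})

test_that("doubling the sugar content never decreases growth in the panel", {
  m <- toy_ulva_fermenter()
  base <- dplyr::filter(ulva_composition(), class != "inert")[, c("component", "g_per_kg")]
  sugars <- run_sugar_g_per_kg(ulva_runs())
  r8 <- dplyr::filter(sugars, run == 8)
  r8x2 <- dplyr::mutate(r8, run = 99, g_per_kg = 2 * g_per_kg)
  panel <- suppressMessages(ferment_panel(m, base, dplyr::bind_rows(r8, r8x2)))
  expect_gte(
    panel$growth[panel$run == 99][1],
    panel$growth[panel$run == 8][1] - 1e-12
  )
})

test_that("model JSON round trip preserves structure and solutions", {
  m <- toy_ulva_fermenter()
  path <- withr::local_tempfile(fileext = ".json")
  write_metabolic_model(m, path)
  m2 <- read_metabolic_model(path)
  expect_equal(sort(m2$metabolites), sort(m$metabolites))
  expect_equal(m2$reactions, m$reactions)
  expect_equal(m2$growth_reaction, m$growth_reaction)
  expect_equal(m2$exchanges, m$exchanges)
  expect_equal(m2$targets, m$targets)
  b <- media_uptake_bounds(m, tibble::tibble(component = "D-Glucose", g_per_kg = 500))
  expect_equal(
    max_growth(apply_media(m2, b))$growth,
    max_growth(apply_media(m, b))$growth
  )
})
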