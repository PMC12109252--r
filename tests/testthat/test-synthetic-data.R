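test_that("generators are bit-identical under a fixed seed", {
  cfg <- small_scenario(seed = 42)
  a <- generate_landscape(cfg)
  b <- generate_landscape(cfg)
  expect_identical(a$land_use$labels, b$land_use$labels)
  expect_identical(a$admin$labels, b$admin$labels)
  expect_identical(lapply(a$drivers, `[[`, "values"),
                   lapply(b$drivers, `[[`, "values"))

  s1 <- simulate_spread(cfg, a$land_use, a$admin, a$drivers)
  s2 <- simulate_spread(cfg, a$land_use, a$admin, a$drivers)
  expect_identical(s1$schedule, s2$schedule)
  expect_identical(s1$occurrences, s2$occurrences)

  p1 <- generate_panel(cfg, s1$schedule, a$admin, a$land_use)
  p2 <- generate_panel(cfg, s1$schedule, a$admin, a$land_use)
  expect_identical(p1$panel, p2$panel)
  expect_identical(p1$truth, p2$truth)

  expect_identical(generate_suitability(cfg, a$land_use, a$drivers)$values,
                   generate_suitability(cfg, a$land_use, a$drivers)$values)
})

test_that("realized land-class shares match configured proportions", {
  cfg <- scenario_config(seed = 5, grid = grid_spec(200, 200, 1000),
                         n_units = 20)
  land <- generate_landscape(cfg)
  shares <- table(land$land_use$labels) / (200 * 200)
  legend <- land_use_legend()
  for (cls in names(cfg$land_proportions))
    expect_lt(abs(shares[[as.character(legend[[cls]])]] -
                    cfg$land_proportions[[cls]]), 0.02)
  # arable + forest shares dominate, as configured
  expect_equal(unname(shares[[as.character(legend[["arable"]])]]), 0.45,
               tolerance = 0.02)
})

test_that("degenerate tiling: n_units equal to cell count gives one cell each", {
  cfg <- scenario_config(seed = 2, grid = grid_spec(5, 5, 1000), n_units = 25,
                         years = 2011:2012)
  land <- generate_landscape(cfg)
  expect_equal(sort(as.vector(table(land$admin$labels))), rep(1L, 25))
  expect_error(scenario_config(grid = grid_spec(4, 4), n_units = 17),
               "exceeds")
})

test_that("isotropic spread is monotone in distance from the origin", {
  cfg <- small_scenario(seed = 9, corridor_strength = 0)
  land <- generate_landscape(cfg)
  sp <- simulate_spread(cfg, land$land_use, land$admin, land$drivers)
  sev <- sp$severity_by_year[["2016"]]$values
  # octile (8-neighbor shortest-path) distance from the origin cell
  rows <- row(sev) - cfg$spread_origin[["row"]]
  cols <- col(sev) - cfg$spread_origin[["col"]]
  oct <- pmax(abs(rows), abs(cols)) +
    (sqrt(2) - 1) * pmin(abs(rows), abs(cols))
  # compare on host cells only (host multiplier is constant = 1 there)
  host <- land$land_use$labels %in%
    land_use_legend()[cfg$host_classes]
  o <- order(oct[host])
  expect_true(all(diff(sev[host][o]) <= 1e-9))
})

test_that("zero spread rate confines infestation to the origin unit", {
  cfg <- small_scenario(seed = 7, spread_rate = 0)
  land <- generate_landscape(cfg)
  sp <- simulate_spread(cfg, land$land_use, land$admin, land$drivers)
  origin_unit <- land$admin$labels[cfg$spread_origin[["row"]],
                                   cfg$spread_origin[["col"]]]
  infested <- sp$schedule$unit[!is.na(sp$schedule$first_year)]
  expect_true(all(infested %in% origin_unit))
})

test_that("severity stays within [0, 1] for any seed", {
  for (seed in c(1, 17, 99)) {
    cfg <- small_scenario(seed = seed, corridor_strength = 3)
    land <- generate_landscape(cfg)
    sp <- simulate_spread(cfg, land$land_use, land$admin, land$drivers)
    for (sev in sp$severity_by_year) {
      expect_gte(min(sev$values, na.rm = TRUE), 0)
      expect_lte(max(sev$values, na.rm = TRUE), 1)
    }
  }
})

test_that("unit first-infestation year matches the severity exceedance rule", {
  cfg <- small_scenario(seed = 4)
  land <- generate_landscape(cfg)
  sp <- simulate_spread(cfg, land$land_use, land$admin, land$drivers)
  for (u in sp$schedule$unit) {
    cells <- land$admin$labels == u
    exceed <- vapply(cfg$years, function(t)
      any(sp$severity_by_year[[as.character(t)]]$values[cells] > 0.5,
          na.rm = TRUE), logical(1))
    first <- if (any(exceed)) cfg$years[which(exceed)[1]] else NA_integer_
    expect_identical(sp$schedule$first_year[sp$schedule$unit == u],
                     as.integer(first))
  }
})

test_that("noiseless, effect-free panels differ only by fixed effects", {
  cfg <- small_scenario(seed = 3, sigma_noise = 0,
                        beta_true = c(forestry = 0), theta_true = 0)
  land <- generate_landscape(cfg)
  sched <- random_schedule(cfg$n_units, cfg$years, seed = 3)
  pt <- generate_panel(cfg, sched, land$admin, land$land_use)
  p <- pt$panel
  implied <- pt$truth$alpha + pt$truth$mu[as.character(p$unit)] +
    pt$truth$gamma[as.character(p$year)]
  expect_equal(p$Y, unname(implied), tolerance = 1e-12)
})

test_that("random schedules always keep a never-treated control unit", {
  for (seed in 1:5) {
    sched <- random_schedule(30, 2011:2022, frac_never = 0.05, seed = seed)
    expect_gte(sum(is.na(sched$first_year)), 1)
    expect_true(all(sched$first_year[!is.na(sched$first_year)] > 2011))
  }
})

test_that("suitability is in [0, 1], host-driven, and zero without hosts", {
  cfg <- small_scenario(seed = 6)
  land <- generate_landscape(cfg)
  suit <- generate_suitability(cfg, land$land_use, land$drivers)
  expect_gte(min(suit$values), 0)
  expect_lte(max(suit$values), 1)
  host <- land$land_use$labels %in% land_use_legend()[cfg$host_classes]
  expect_gt(mean(suit$values[host]), mean(suit$values[!host]))

  water <- uniform_land_use("water", 30, 30)
  suit0 <- generate_suitability(cfg, water, land$drivers)
  expect_true(all(suit0$values == 0))
})
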