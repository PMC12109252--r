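test_that("allocation weights are provincial output intensities", {
  areas <- c(arable = 50, broadleaf_forest = 20, other_forest = 10,
             grassland = 5, water = 4, urban = 3, bare = 1)
  w <- derive_allocation_weights(c(cultivation = 100, forestry = 60,
                                   husbandry = 0, fishery = 8), areas)
  expect_equal(w["cultivation", "arable"], 100 / 50)
  expect_equal(w["forestry", "broadleaf_forest"], 60 / 30)
  expect_equal(w["forestry", "other_forest"], 60 / 30)
  expect_true(all(w["husbandry", ] == 0))  # zero output -> zero weights
  expect_equal(w["fishery", "water"], 2)
  # urban/bare masking holds regardless of inputs
  expect_true(all(w[, c("urban", "bare")] == 0))
  expect_error(
    derive_allocation_weights(c(fishery = 5), c(arable = 1, water = 0)),
    "zero linked-class area")
})

test_that("disaggregation splits unit totals by allocation shares", {
  areas <- c(arable = 1, broadleaf_forest = 1, other_forest = 1,
             grassland = 1, water = 1, urban = 1, bare = 1)
  w <- derive_allocation_weights(
    c(cultivation = 10, forestry = 10, husbandry = 10, fishery = 10), areas)

  # single unit, uniform arable, total 100 over 4 cells -> 25 each
  admin <- strip_admin(1, 2, 2)
  lu <- uniform_land_use("arable", 2, 2)
  tab <- data.frame(unit = 1, year = 2020, sector = "cultivation", value = 100)
  out <- disaggregate_outputs(tab, admin, lu, w)
  expect_equal(out$cultivation[["2020"]]$values, matrix(25, 2, 2))

  # 3 arable + 1 urban cell, total 90 -> 30/30/30/0
  lu$labels[2, 2] <- land_use_legend()[["urban"]]
  tab$value <- 90
  out <- disaggregate_outputs(tab, admin, lu, w)
  expect_equal(sort(as.vector(out$cultivation[["2020"]]$values)),
               c(0, 30, 30, 30))

  # all-urban unit cannot absorb forestry output: nodata + warning
  lu_urban <- uniform_land_use("urban", 2, 2)
  tabf <- data.frame(unit = 1, year = 2020, sector = "forestry", value = 5)
  expect_warning(outf <- disaggregate_outputs(tabf, admin, lu_urban, w),
                 "unallocated")
  expect_true(all(is.na(outf$forestry[["2020"]]$values)))

  expect_error(disaggregate_outputs(
    data.frame(unit = 9, year = 2020, sector = "cultivation", value = 1),
    admin, lu, w), "absent")
  expect_error(disaggregate_outputs(rbind(tab, tab), admin, lu, w),
               "duplicate")
})

test_that("disaggregate-then-aggregate conserves district totals", {
  cfg <- small_scenario(seed = 21)
  land <- generate_landscape(cfg)
  set.seed(99)
  tab <- expand.grid(unit = 1:8, year = 2015:2016,
                     sector = c("cultivation", "forestry", "husbandry",
                                "fishery"), stringsAsFactors = FALSE)
  tab$value <- runif(nrow(tab), 50, 500)
  areas <- table(factor(names(land_use_legend())[land$land_use$labels],
                        levels = names(land_use_legend())))
  w <- derive_allocation_weights(
    c(cultivation = 1000, forestry = 700, husbandry = 200, fishery = 150),
    stats::setNames(as.numeric(areas), names(areas)))
  out <- suppressWarnings(disaggregate_outputs(tab, land$admin, land$land_use, w))
  rec <- suppressWarnings(validate_reconstruction(out, tab, land$admin))
  # conservation holds wherever the unit has positive allocation mass
  linkage <- default_sector_linkage()
  legend <- land_use_legend()
  has_mass <- mapply(function(u, s)
    any(land$admin$labels == u &
          land$land_use$labels %in% legend[linkage[[s]]]),
    rec$unit, rec$sector)
  expect_true(any(has_mass))
  expect_true(all(rec$ape[has_mass] < 1e-9))
  # urban and bare cells carry exactly zero in every sector raster
  nonprod <- land$land_use$labels %in%
    land_use_legend()[non_productive_classes()]
  for (s in names(out)) for (yr in names(out[[s]])) {
    v <- out[[s]][[yr]]$values[nonprod]
    expect_true(all(v[!is.na(v)] == 0))
  }
})

test_that("monotonicity: scaling a unit total scales its cells", {
  admin <- strip_admin(2, 3, 4)
  lu <- uniform_land_use("arable", 3, 4)
  w <- derive_allocation_weights(c(cultivation = 10),
                                 c(arable = 5, broadleaf_forest = 1,
                                   other_forest = 1, grassland = 1,
                                   water = 1, urban = 1, bare = 1))
  tab1 <- data.frame(unit = c(1, 2), year = 2020, sector = "cultivation",
                     value = c(60, 30))
  tab2 <- tab1; tab2$value[1] <- 120
  o1 <- disaggregate_outputs(tab1, admin, lu, w)$cultivation[["2020"]]$values
  o2 <- disaggregate_outputs(tab2, admin, lu, w)$cultivation[["2020"]]$values
  u1 <- admin$labels == 1
  expect_equal(o2[u1], 2 * o1[u1])
  expect_equal(o2[!u1], o1[!u1])
})

test_that("reconstruction reports percentage errors and edge cases", {
  admin <- strip_admin(1, 2, 2)
  lu <- uniform_land_use("arable", 2, 2)
  w <- derive_allocation_weights(c(cultivation = 10), c(arable = 10,
    broadleaf_forest = 1, other_forest = 1, grassland = 1, water = 1,
    urban = 1, bare = 1))
  tab <- data.frame(unit = 1, year = 2020, sector = "cultivation", value = 100)
  out <- disaggregate_outputs(tab, admin, lu, w)
  rec0 <- validate_reconstruction(out, tab, admin)
  expect_equal(rec0$ape, 0, tolerance = 1e-12)

  # perturb one cell by +10% of the unit total -> 10% error
  out$cultivation[["2020"]]$values[1, 1] <-
    out$cultivation[["2020"]]$values[1, 1] + 10
  rec <- validate_reconstruction(out, tab, admin)
  expect_equal(rec$ape, 0.1, tolerance = 1e-12)
  expect_equal(attr(rec, "max_ape"), 0.1, tolerance = 1e-12)

  # zero table value with nonzero mass -> infinite error flag
  tab0 <- data.frame(unit = 1, year = 2020, sector = "cultivation", value = 0)
  expect_true(is.infinite(validate_reconstruction(out, tab0, admin)$ape))

  empty <- validate_reconstruction(out,
    data.frame(unit = integer(), year = integer(), sector = character(),
               value = numeric()), admin)
  expect_equal(nrow(empty), 0)
})
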