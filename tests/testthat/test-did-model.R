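test_that("2x2 panel reproduces the hand-computed difference-in-differences", {
  p <- data.frame(unit = c(1, 1, 2, 2), year = c(2011, 2012, 2011, 2012),
                  Y = c(10, 10, 10, 7), D = c(0, 0, 0, 1))
  fit <- fit_staggered_did(p, treatment = "D")
  expect_equal(fit$beta, -3, tolerance = 1e-12)  # (7-10) - (10-10)
  cp <- counterfactual_outputs(fit, p)
  expect_equal(cp$counterfactual, c(10, 10, 10, 10), tolerance = 1e-10)
})

test_that("noiseless staggered panels recover planted beta, mu, gamma exactly", {
  cfg <- small_scenario(seed = 12, sigma_noise = 0)
  land <- generate_landscape(cfg)
  sched <- random_schedule(cfg$n_units, cfg$years, seed = 12)
  pt <- generate_panel(cfg, sched, land$admin, land$land_use)
  for (s in names(cfg$beta_true)) {
    sub <- pt$panel[pt$panel$sector == s, ]
    if (all(sub$X == 0)) next
    fit <- suppressWarnings(  # noiseless data: summary.lm flags a perfect fit
      fit_staggered_did(sub, treatment = "X", controls = "w1"))
    expect_equal(fit$beta, unname(cfg$beta_true[[s]]), tolerance = 1e-8)
    expect_equal(unname(fit$theta["w1"]), cfg$theta_true, tolerance = 1e-8)
    # fixed effects identified up to a constant: compare centered versions
    expect_equal(unname(fit$mu - mean(fit$mu)),
                 unname(pt$truth$mu - mean(pt$truth$mu)), tolerance = 1e-8)
    expect_equal(unname(fit$gamma - mean(fit$gamma)),
                 unname(pt$truth$gamma - mean(pt$truth$gamma)),
                 tolerance = 1e-8)
  }
})

test_that("zero planted effect is recovered as zero", {
  cfg <- small_scenario(seed = 14, sigma_noise = 0,
                        beta_true = c(forestry = 0))
  land <- generate_landscape(cfg)
  sched <- random_schedule(cfg$n_units, cfg$years, seed = 14)
  pt <- generate_panel(cfg, sched, land$admin, land$land_use)
  fit <- suppressWarnings(
    fit_staggered_did(pt$panel, treatment = "X", controls = "w1"))
  expect_lt(abs(fit$beta), 1e-10)
})

test_that("dummy-variable OLS agrees with the within-demeaning estimator", {
  set.seed(55)
  for (k in 1:5) {
    units <- 1:12; yrs <- 2011:2018
    sched <- random_schedule(12, yrs, seed = 100 + k)
    p <- expand.grid(unit = units, year = yrs)
    first <- sched$first_year[match(p$unit, sched$unit)]
    p$D <- as.integer(!is.na(first) & p$year >= first)
    p$X <- p$D * rep(sample(5:30, 12), length(yrs))
    p$Y <- rnorm(12) [p$unit] + 0.8 * match(p$year, yrs) - 0.2 * p$X +
      rnorm(nrow(p), 0, 0.7)
    if (all(p$X == 0) || all(p$X != 0)) next
    fit <- fit_staggered_did(p, treatment = "X")
    expect_equal(fit$beta, oracle_twfe(p, "X"), tolerance = 1e-8)
  }
})

test_that("degenerate and unidentified panels are rejected", {
  p <- data.frame(unit = c(1, 1, 2, 2), year = c(1, 2, 1, 2),
                  Y = rnorm(4), D = c(0, 0, 0, 1))
  expect_error(fit_staggered_did(p[p$unit == 1, ], treatment = "D"),
               "degenerate")
  expect_error(fit_staggered_did(transform(p, D = 1), treatment = "D"),
               "identified")
  expect_error(fit_staggered_did(transform(p, D = 0), treatment = "D"),
               "identified")
  expect_error(fit_staggered_did(rbind(p, p), treatment = "D"), "duplicate")
  # treated-everywhere-once-treated collinear with unit effects
  p2 <- data.frame(unit = c(1, 1, 2, 2), year = c(1, 2, 1, 2),
                   Y = rnorm(4), D = c(0, 0, 1, 1))
  expect_error(suppressWarnings(fit_staggered_did(p2, treatment = "D")),
               "collinear")
})

test_that("build_panel applies the absorbing threshold rule", {
  out <- expand.grid(unit = c("a", "b"), year = 2011:2016,
                     sector = "forestry", stringsAsFactors = FALSE)
  out$value <- 1
  sched <- data.frame(unit = c("a", "b"), first_year = c(2014, NA))
  p <- build_panel(out, sched)
  expect_equal(p$D[p$unit == "a"][order(p$year[p$unit == "a"])],
               c(0L, 0L, 0L, 1L, 1L, 1L))
  expect_true(all(p$D[p$unit == "b"] == 0L))
  expect_error(build_panel(transform(out, unit = "c"), sched), "absent")
  # without a cells column no intensity regressor is created
  expect_false("X" %in% names(p))
})

test_that("counterfactuals and annual losses follow the accounting identities", {
  p <- data.frame(unit = c(1, 1, 2, 2), year = c(2011, 2012, 2011, 2012),
                  sector = "forestry", Y = c(10, 10, 10, 7),
                  D = c(0, 0, 0, 1))
  fit <- fit_staggered_did(p, treatment = "D")
  cp <- counterfactual_outputs(fit, p)
  # untreated observations unchanged
  expect_equal(cp$counterfactual[cp$D == 0], cp$Y[cp$D == 0])

  # deflator of 1.5 on a gap of 3 -> real loss 2
  losses <- annual_losses(cp, deflator = c("2011" = 1, "2012" = 1.5))
  expect_equal(losses$loss[losses$year == 2011], 0, tolerance = 1e-10)
  expect_equal(losses$loss[losses$year == 2012], 2, tolerance = 1e-10)
  expect_equal(unname(attr(losses, "cumulative")["forestry"]), 2,
               tolerance = 1e-10)

  # nominal when the deflator is 1 everywhere
  nom <- annual_losses(cp)
  expect_equal(nom$loss[nom$year == 2012], 3, tolerance = 1e-10)

  # zero treatment effect -> identically zero loss series
  fit0 <- fit
  fit0$beta <- 0
  z <- annual_losses(counterfactual_outputs(fit0, p))
  expect_true(all(z$loss == 0))

  expect_error(annual_losses(cp, deflator = c("2011" = 1)), "missing")
  expect_error(annual_losses(cp, deflator = c("2011" = 1, "2012" = -1)),
               "positive")
})

test_that("cluster-robust and HC1 standard errors are both available", {
  cfg <- small_scenario(seed = 19)
  land <- generate_landscape(cfg)
  sched <- random_schedule(cfg$n_units, cfg$years, seed = 19)
  pt <- generate_panel(cfg, sched, land$admin, land$land_use)
  sub <- pt$panel[pt$panel$sector == "forestry", ]
  f1 <- fit_staggered_did(sub, treatment = "X", se = "cluster")
  f2 <- fit_staggered_did(sub, treatment = "X", se = "HC1")
  expect_equal(f1$beta, f2$beta)
  expect_gt(f1$se, 0)
  expect_gt(f2$se, 0)
  expect_false(isTRUE(all.equal(f1$se, f2$se)))
  expect_equal(f1$t, f1$beta / f1$se)
  # residuals of the dummy regression sum to ~0
  expect_lt(abs(sum(f1$residuals)), 1e-8)
})
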