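# Staggered two-way fixed-effects DID estimation, counterfactual
# construction and annual loss accounting.
#
# Y_it = alpha + beta * D_it + theta' W_it + mu_i + gamma_t + eps_it
#
# Estimated as OLS with unit and year dummies; cluster-robust (by unit)
# standard errors by default. The treatment regressor may be the binary
# infestation indicator D, or the treatment intensity X = exposed cells x D,
# in which case beta is a per-cell effect.

#' Build a DID panel from a sector table and an infestation schedule
#'
#' `D_it = 1` iff `t >= first_infestation_year(i)` (absorbing treatment);
#' when a `cells` column is present, the intensity regressor
#' `X_it = cells_i * D_it` is also constructed. Control covariates, if
#' given, are merged on (unit, year).
#'
#' @param outputs Data frame `unit`, `year`, `sector`, `value` (and
#'   optionally `cells`, the unit's exposed cell count).
#' @param schedule Data frame `unit`, `first_year` (NA = never treated).
#' @param controls Optional data frame keyed by `unit`, `year` with control
#'   columns.
#' @return Data frame `unit`, `year`, `sector`, `Y`, `D` (+ `cells`, `X`,
#'   controls).
#' @export
build_panel <- function(outputs, schedule, controls = NULL) {
  need <- c("unit", "year", "sector", "value")
  if (!all(need %in% names(outputs)))
    stop("outputs needs columns ", paste(need, collapse = ", "))
  if (!all(c("unit", "first_year") %in% names(schedule)))
    stop("schedule needs columns unit, first_year")
  miss <- setdiff(unique(outputs$unit), schedule$unit)
  if (length(miss))
    stop("unit(s) present in outputs but absent from the schedule: ",
         paste(miss, collapse = ", "))
  first <- schedule$first_year[match(outputs$unit, schedule$unit)]
  panel <- data.frame(unit = outputs$unit, year = outputs$year,
                      sector = outputs$sector, Y = outputs$value,
                      D = as.integer(!is.na(first) & outputs$year >= first))
  if ("cells" %in% names(outputs)) {
    panel$cells <- outputs$cells
    panel$X <- panel$cells * panel$D
  }
  if (!is.null(controls)) {
    key <- paste(panel$unit, panel$year)
    ckey <- paste(controls$unit, controls$year)
    for (col in setdiff(names(controls), c("unit", "year")))
      panel[[col]] <- controls[[col]][match(key, ckey)]
  }
  panel
}

#' Fit the staggered two-way fixed-effects DID model
#'
#' Least squares with unit and year dummies (equivalent to the two-way
#' within transformation). Standard errors are cluster-robust by unit
#' (default) or heteroskedasticity-robust (`se = "HC1"`); p-values use
#' `G - 1` degrees of freedom under clustering (G = number of units).
#' Collinear controls are dropped with a warning. Panels with a single unit
#' or year, or without both treated and untreated observations, are
#' rejected.
#'
#' @param panel Data frame with columns `unit`, `year`, `Y`, and the
#'   treatment column. If a `sector` column with several sectors is present,
#'   pass each sector separately (see [fit_did_by_sector()]).
#' @param treatment Name of the treatment regressor: `"X"` (intensity;
#'   per-cell beta) when available, else `"D"` (binary).
#' @param controls Character vector of control-covariate columns.
#' @param se `"cluster"` (by unit) or `"HC1"`.
#' @return Object of class `did_fit`: `alpha`, `beta`, `se`, `t`, `p`,
#'   `ci` (95%), `theta`, `mu` (unit effects, reference unit 0), `gamma`
#'   (year effects, reference year 0), `residuals`, `n_obs`, `n_units`,
#'   `n_years`, `treatment`, `vcov_type`.
#' @examples
#' # 2x2 textbook case: treated unit drops by 3 -> beta = -3 exactly
#' p <- data.frame(unit = c(1, 1, 2, 2), year = c(1, 2, 1, 2),
#'                 Y = c(10, 10, 10, 7), D = c(0, 0, 0, 1))
#' fit_staggered_did(p, treatment = "D")$beta
#' @export
fit_staggered_did <- function(panel, treatment = if ("X" %in% names(panel)) "X" else "D",
                              controls = character(),
                              se = c("cluster", "HC1")) {
  se <- match.arg(se)
  need <- c("unit", "year", "Y", treatment)
  if (!all(need %in% names(panel)))
    stop("panel needs columns ", paste(need, collapse = ", "))
  if ("sector" %in% names(panel) && length(unique(panel$sector)) > 1)
    stop("panel contains multiple sectors; fit each separately ",
         "(see fit_did_by_sector)")
  if (anyDuplicated(paste(panel$unit, panel$year)))
    stop("duplicate (unit, year) observations")
  units <- sort(unique(panel$unit)); yrs <- sort(unique(panel$year))
  if (length(units) < 2L || length(yrs) < 2L)
    stop("degenerate panel: need at least 2 units and 2 years")
  tr <- panel[[treatment]]
  if (all(tr != 0) || all(tr == 0))
    stop("treatment effect not identified: need both treated and ",
         "untreated observations")
  varies_within <- tapply(tr, panel$unit, function(v) length(unique(v)) > 1)
  if (!any(varies_within))
    stop("treatment effect not identified: treatment is collinear with the ",
         "unit fixed effects (no unit switches status)")

  dat <- data.frame(.Y = panel$Y, .D = tr,
                    .unit = factor(panel$unit, levels = units),
                    .year = factor(panel$year, levels = yrs))
  for (col in controls) dat[[col]] <- panel[[col]]
  rhs <- paste(c(".D", controls, ".unit", ".year"), collapse = " + ")
  fit <- stats::lm(stats::as.formula(paste(".Y ~", rhs)), data = dat)

  cf <- stats::coef(fit)
  dropped <- names(cf)[is.na(cf)]
  if (length(dropped)) {
    warning("collinear term(s) dropped: ", paste(dropped, collapse = ", "))
    if (".D" %in% dropped)
      stop("treatment regressor is collinear with the fixed effects")
  }
  vc <- if (se == "cluster")
    sandwich::vcovCL(fit, cluster = panel$unit, type = "HC1")
  else sandwich::vcovHC(fit, type = "HC1")
  beta <- unname(cf[".D"])
  beta_se <- sqrt(vc[".D", ".D"])
  df <- if (se == "cluster") length(units) - 1L else fit$df.residual
  tval <- beta / beta_se
  pval <- 2 * stats::pt(-abs(tval), df)
  crit <- stats::qt(0.975, df)

  mu <- c(0, unname(cf[paste0(".unit", units[-1])]))
  gamma <- c(0, unname(cf[paste0(".year", yrs[-1])]))
  theta <- if (length(controls)) cf[controls] else numeric(0)
  structure(list(alpha = unname(cf["(Intercept)"]),
                 beta = beta, se = beta_se, t = tval, p = pval,
                 ci = c(lower = beta - crit * beta_se,
                        upper = beta + crit * beta_se),
                 theta = theta,
                 mu = stats::setNames(mu, units),
                 gamma = stats::setNames(gamma, yrs),
                 residuals = unname(stats::residuals(fit)),
                 n_obs = nrow(panel), n_units = length(units),
                 n_years = length(yrs), treatment = treatment,
                 vcov_type = se),
            class = "did_fit")
}

#' @export
print.did_fit <- function(x, ...) {
  cat(sprintf("<did_fit> beta = %.4f (SE %.4f, t = %.2f, p = %.3g) [%s, %s SE]\n",
              x$beta, x$se, x$t, x$p, x$treatment, x$vcov_type))
  cat(sprintf("  %d obs, %d units, %d years\n", x$n_obs, x$n_units, x$n_years))
  invisible(x)
}

#' Fit one DID model per sector
#'
#' @param panel Long panel with a `sector` column.
#' @param ... Passed to [fit_staggered_did()].
#' @return Named list of `did_fit` objects.
#' @export
fit_did_by_sector <- function(panel, ...) {
  sectors <- unique(panel$sector)
  fits <- lapply(sectors, function(s)
    fit_staggered_did(panel[panel$sector == s, , drop = FALSE], ...))
  stats::setNames(fits, sectors)
}

#' Summary table of sectoral DID fits
#'
#' @param fits Named list of `did_fit`s (from [fit_did_by_sector()]).
#' @return Data frame with columns `sector`, `estimate`, `std_error`,
#'   `t_value`, `p_value`.
#' @export
did_summary_table <- function(fits) {
  data.frame(sector = names(fits),
             estimate = vapply(fits, `[[`, numeric(1), "beta"),
             std_error = vapply(fits, `[[`, numeric(1), "se"),
             t_value = vapply(fits, `[[`, numeric(1), "t"),
             p_value = vapply(fits, `[[`, numeric(1), "p"),
             row.names = NULL)
}

#' Counterfactual (no-infestation) outputs
#'
#' Removes the estimated treatment term from each observation:
#' `Yhat_it(D = 0) = Y_it - beta * D_it`, all other terms held at their
#' observed values. Untreated observations are unchanged.
#'
#' @param fit A `did_fit`.
#' @param panel The panel the fit came from.
#' @return `panel` with an added `counterfactual` column.
#' @export
counterfactual_outputs <- function(fit, panel) {
  stopifnot(inherits(fit, "did_fit"))
  tr <- panel[[fit$treatment]]
  if (is.null(tr)) stop("panel lacks the fitted treatment column ", fit$treatment)
  panel$counterfactual <- panel$Y - fit$beta * tr
  panel
}

#' Annual deflator-adjusted loss series
#'
#' Loss in year t is `sum_i (Yhat_it - Y_it) / deflator(t)` per sector: the
#' gap between counterfactual and observed output, converted to real terms
#' with a GDP deflator (base-year index 1).
#'
#' @param counterfactual_panel Output of [counterfactual_outputs()].
#' @param deflator Named numeric, year -> index (default 1 for all years).
#' @return Data frame `year`, `sector`, `observed`, `counterfactual`,
#'   `loss` (real terms), with attribute `cumulative` (named by sector).
#' @export
annual_losses <- function(counterfactual_panel, deflator = NULL) {
  p <- counterfactual_panel
  if (!"counterfactual" %in% names(p))
    stop("run counterfactual_outputs() first")
  if (!"sector" %in% names(p)) p$sector <- "all"
  yrs <- sort(unique(p$year))
  if (is.null(deflator)) deflator <- stats::setNames(rep(1, length(yrs)), yrs)
  if (any(deflator <= 0)) stop("deflator indices must be positive")
  miss <- setdiff(as.character(yrs), names(deflator))
  if (length(miss)) stop("deflator missing for year(s): ",
                         paste(miss, collapse = ", "))
  agg <- stats::aggregate(cbind(observed = p$Y, counterfactual = p$counterfactual),
                          by = list(year = p$year, sector = p$sector), FUN = sum)
  idx <- deflator[as.character(agg$year)]
  agg$observed <- agg$observed / idx
  agg$counterfactual <- agg$counterfactual / idx
  agg$loss <- agg$counterfactual - agg$observed
  agg <- agg[order(agg$sector, agg$year), ]
  rownames(agg) <- NULL
  structure(agg, cumulative = tapply(agg$loss, agg$sector, sum))
}
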