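# Synthetic scenario generator: landscapes, staggered infestation spread,
# occurrence points, driver stacks, suitability surfaces and economic panels
# with machine-readable ground truth, so every pipeline stage is testable
# without external administrative data.

# one pseudo-random stream per generator, all derived from the master seed
stream_seed <- function(seed, stage) {
  offsets <- c(landscape = 11L, spread = 23L, panel = 37L, suitability = 41L,
               schedule = 53L, pipeline = 67L)
  if (!stage %in% names(offsets)) stop("unknown rng stream: ", stage)
  (abs(as.integer(seed)) %% 2000000L) * 1000L + offsets[[stage]]
}

#' Configure a synthetic invasion scenario
#'
#' Bundles every parameter of the synthetic data-generating process. The
#' defaults describe the study conditions the package is exercised under: a
#' 100 x 100 grid of 1-km cells, 50 administrative units observed over
#' 2011-2022, land-class shares dominated by arable (45%) and forest (32%)
#' cover, per-cell annual sectoral treatment effects matching the magnitudes
#' estimated for a defoliating forest pest (forestry -0.163, cultivation
#' -0.021, husbandry +0.005, fishery -0.034 output units per infested cell and
#' year), and unit-year noise with s.d. 0.5.
#'
#' @param seed Master seed; every generator stream is derived from it.
#' @param grid A [grid_spec()].
#' @param n_units Number of contiguous administrative units (>= 2).
#' @param years Inclusive vector of panel years.
#' @param beta_true Named per-cell annual treatment effect by sector.
#' @param sigma_noise Panel noise standard deviation.
#' @param spread_origin `c(row, col)` cell where the invasion starts.
#' @param spread_rate Base wavefront speed in cells/year.
#' @param corridor_strength Non-negative multiplier of road density on spread
#'   speed: local speed is `spread_rate * (1 + corridor_strength * road)`.
#' @param host_classes Land-use classes attractive to the pest.
#' @param land_proportions Named class shares, summing to 1.
#' @param theta_true Coefficient of the single time-varying control covariate.
#' @param occ_rate Expected occurrence points per unit of summed severity.
#' @param frac_never Fraction of units kept as never-treated controls when a
#'   schedule is drawn at random (see [random_schedule()]).
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(seed = 1L,
                            grid = grid_spec(100, 100, 1000),
                            n_units = 50L,
                            years = 2011:2022,
                            beta_true = c(cultivation = -0.021,
                                          forestry = -0.163,
                                          husbandry = 0.005,
                                          fishery = -0.034),
                            sigma_noise = 0.5,
                            spread_origin = c(row = 10L, col = 10L),
                            spread_rate = 4,
                            corridor_strength = 1.5,
                            host_classes = c("arable", "broadleaf_forest",
                                             "other_forest"),
                            land_proportions = c(arable = 0.45,
                                                 broadleaf_forest = 0.20,
                                                 other_forest = 0.12,
                                                 grassland = 0.10,
                                                 water = 0.06,
                                                 urban = 0.05,
                                                 bare = 0.02),
                            theta_true = 0.5,
                            occ_rate = 0.02,
                            frac_never = 0.3) {
  stopifnot(inherits(grid, "grid_spec"))
  n_units <- as.integer(n_units)
  if (n_units < 2L) stop("n_units must be >= 2")
  if (n_units > grid$n_rows * grid$n_cols)
    stop("n_units exceeds the number of grid cells")
  if (abs(sum(land_proportions) - 1) > 1e-8)
    stop("land_proportions must sum to 1")
  if (!all(names(land_proportions) %in% names(land_use_legend())))
    stop("unknown land-use class in land_proportions")
  if (corridor_strength < 0) stop("corridor_strength must be >= 0")
  structure(list(seed = as.integer(seed), grid = grid, n_units = n_units,
                 years = as.integer(years), beta_true = beta_true,
                 sigma_noise = sigma_noise, spread_origin = spread_origin,
                 spread_rate = spread_rate,
                 corridor_strength = corridor_strength,
                 host_classes = host_classes,
                 land_proportions = land_proportions,
                 theta_true = theta_true, occ_rate = occ_rate,
                 frac_never = frac_never),
            class = "scenario_config")
}

# Gaussian-blur a white-noise field; edge-normalized separable kernel.
smooth_field <- function(n_rows, n_cols, radius = 6) {
  z <- matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols)
  k <- stats::dnorm(seq(-2.5, 2.5, length.out = 2 * radius + 1))
  blur1 <- function(m, along_rows) {
    acc <- matrix(0, nrow(m), ncol(m))
    mass <- matrix(0, nrow(m), ncol(m))
    for (j in seq_along(k)) {
      off <- j - radius - 1L
      if (along_rows) {
        src <- seq_len(nrow(m)) + off
        ok <- src >= 1 & src <= nrow(m)
        acc[ok, ] <- acc[ok, ] + k[j] * m[src[ok], ]
        mass[ok, ] <- mass[ok, ] + k[j]
      } else {
        src <- seq_len(ncol(m)) + off
        ok <- src >= 1 & src <= ncol(m)
        acc[, ok] <- acc[, ok] + k[j] * m[, src[ok]]
        mass[, ok] <- mass[, ok] + k[j]
      }
    }
    acc / mass
  }
  blur1(blur1(z, TRUE), FALSE)
}

# carve a continuous field into classes with exact target shares
classify_by_quantiles <- function(field, proportions) {
  legend <- land_use_legend()
  v <- as.vector(field)
  ord <- order(v, sample.int(length(v)))  # random tie-break, seeded stream
  n <- length(v)
  counts <- floor(proportions * n)
  counts[length(counts)] <- counts[length(counts)] + (n - sum(counts))
  labels <- integer(n)
  labels[ord] <- rep(legend[names(proportions)], times = counts)
  matrix(labels, nrow(field), ncol(field))
}

#' Generate a synthetic landscape
#'
#' Produces contiguous administrative units (nearest-seed tessellation), a
#' categorical land-use map whose realized class shares match
#' `config$land_proportions` exactly (quantile slicing of a smooth Gaussian
#' field), and a stack of driver rasters in `[0, 1]`: a corridor-like road
#' density, smooth population density, nighttime lights, built environment,
#' waterway proximity, a rainfall gradient, slope, altitude and wind.
#'
#' @param config A [scenario_config()].
#' @return List with `land_use` (`label_raster`), `admin` (`label_raster`,
#'   codes `1:n_units`) and `drivers` (named list of `raster_layer`s).
#' @export
generate_landscape <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  g <- config$grid
  nr <- g$n_rows; nc <- g$n_cols; n <- nr * nc
  set.seed(stream_seed(config$seed, "landscape"))

  # admin units: nearest-seed (Voronoi) tessellation -> contiguous regions
  seeds <- sample.int(n, config$n_units)
  sr <- (seeds - 1L) %% nr + 1L
  sc <- (seeds - 1L) %/% nr + 1L
  rows <- rep(seq_len(nr), times = nc)
  cols <- rep(seq_len(nc), each = nr)
  best <- rep(Inf, n); lab <- integer(n)
  for (u in seq_len(config$n_units)) {
    d2 <- (rows - sr[u])^2 + (cols - sc[u])^2
    take <- d2 < best
    best[take] <- d2[take]
    lab[take] <- u
  }
  admin <- label_raster(matrix(lab, nr, nc), g,
                        legend = stats::setNames(seq_len(config$n_units),
                                                 paste0("unit_", seq_len(config$n_units))))

  lu_field <- smooth_field(nr, nc, radius = max(3, round(min(nr, nc) / 15)))
  land_use <- label_raster(classify_by_quantiles(lu_field, config$land_proportions),
                           g, legend = land_use_legend())

  # corridor through the spread origin, oriented NW-SE
  orow <- config$spread_origin[["row"]]; ocol <- config$spread_origin[["col"]]
  t_par <- (rows - orow) + (cols - ocol)
  d_perp <- abs((rows - orow) - (cols - ocol)) / sqrt(2)
  road <- exp(-(d_perp / 4)^2) +
    0.5 * exp(-((abs(t_par) / sqrt(2) - min(nr, nc) / 3) / 4)^2) +
    0.15 * abs(smooth_field(nr, nc, 4))
  road <- normalize01(matrix(road, nr, nc))

  pop <- normalize01(0.6 * smooth_field(nr, nc, 10) + 0.4 * road)
  lights <- normalize01(0.7 * pop + 0.3 * smooth_field(nr, nc, 6))
  water_mask <- land_use$labels == land_use_legend()[["water"]]
  ww <- normalize01(smooth_mask(water_mask, radius = 5))
  built <- normalize01(smooth_mask(land_use$labels == land_use_legend()[["urban"]],
                                   radius = 4) + 0.3 * pop)
  rain <- normalize01(outer(seq_len(nr), rep(1, nc)) / nr +
                        0.3 * smooth_field(nr, nc, 8))
  alt <- normalize01(smooth_field(nr, nc, 12))
  slope <- normalize01(abs(rbind(alt[-1, , drop = FALSE], alt[nr, , drop = FALSE]) - alt) +
                         abs(cbind(alt[, -1, drop = FALSE], alt[, nc, drop = FALSE]) - alt))
  wind <- normalize01(outer(rep(1, nr), seq_len(nc)) / nc +
                        0.4 * smooth_field(nr, nc, 9))

  drivers <- lapply(list(road_density = road, population_density = pop,
                         nighttime_lights = lights, built_environment = built,
                         waterways = ww, rainfall = rain, slope = slope,
                         altitude = alt, wind = wind),
                    raster_layer, grid = g)
  list(land_use = land_use, admin = admin, drivers = drivers)
}

# smoothed density of a logical mask
smooth_mask <- function(mask, radius) {
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  k <- rep(1, 2 * radius + 1)
  acc <- matrix(0, nrow(m), ncol(m)); cnt <- acc
  for (off in -radius:radius) {
    src <- seq_len(nrow(m)) + off
    ok <- src >= 1 & src <= nrow(m)
    acc[ok, ] <- acc[ok, ] + m[src[ok], ]
    cnt[ok, ] <- cnt[ok, ] + 1
  }
  m <- acc / cnt
  acc <- matrix(0, nrow(m), ncol(m)); cnt <- acc
  for (off in -radius:radius) {
    src <- seq_len(ncol(m)) + off
    ok <- src >= 1 & src <= ncol(m)
    acc[, ok] <- acc[, ok] + m[, src[ok]]
    cnt[, ok] <- cnt[, ok] + 1
  }
  acc / cnt
}

#' Simulate staggered infestation spread
#'
#' A deterministic wavefront expands from `spread_origin` over the 8-neighbor
#' cell graph; local speed is `spread_rate * (1 + corridor_strength * road)`,
#' so spread is faster along the road corridor. Cell severity after arrival
#' follows a saturating ramp `1 - exp(-(t - arrival + 0.5))`, scaled by a host
#' multiplier (1 on host classes, 0.6 on other land, 0 on water), and is
#' always within `[0, 1]`. A unit's first infestation year is the first year
#' any of its cells exceeds severity 0.5. Occurrence points are sampled with
#' probability proportional to severity (Poisson count with mean
#' `occ_rate * sum(severity)` per year, uniform jitter within the cell).
#'
#' @param config A [scenario_config()].
#' @param land_use,admin,drivers Landscape from [generate_landscape()].
#' @return List with `schedule` (data frame `unit`, `first_year`, NA = never),
#'   `severity_by_year` (named list of `raster_layer`, one per year) and
#'   `occurrences` (data frame `x`, `y`, `year`).
#' @export
simulate_spread <- function(config, land_use, admin, drivers) {
  stopifnot(inherits(config, "scenario_config"))
  g <- config$grid
  nr <- g$n_rows; nc <- g$n_cols; n <- nr * nc
  set.seed(stream_seed(config$seed, "spread"))

  road <- drivers$road_density$values
  speed <- config$spread_rate * (1 + config$corridor_strength * road)
  origin <- (config$spread_origin[["col"]] - 1L) * nr +
    config$spread_origin[["row"]]

  if (config$spread_rate <= 0) {
    arrival <- rep(Inf, n); arrival[origin] <- 0
  } else {
    edges <- neighbor_edges(nr, nc)
    w <- edges$dist * 2 / (speed[edges$from] + speed[edges$to])
    ggr <- igraph::graph_from_data_frame(
      data.frame(from = edges$from, to = edges$to, weight = w),
      directed = FALSE,
      vertices = data.frame(name = seq_len(n)))
    arrival <- as.numeric(igraph::distances(ggr, v = as.character(origin),
                                            weights = igraph::E(ggr)$weight))
    arrival <- arrival[order(as.integer(igraph::V(ggr)$name))]
  }
  arrival_mat <- matrix(arrival, nr, nc)

  host_codes <- land_use_legend()[config$host_classes]
  host_mult <- matrix(0.6, nr, nc)
  host_mult[land_use$labels %in% host_codes] <- 1
  host_mult[land_use$labels == land_use_legend()[["water"]]] <- 0

  years <- config$years
  y0 <- years[1] - 1L  # origin cell arrives just before the first panel year
  severity_by_year <- list()
  first_year <- rep(NA_integer_, config$n_units)
  occ <- list()
  for (t in years) {
    age <- (t - y0) - arrival_mat
    sev <- ifelse(age >= 0, 1 - exp(-(age + 0.5)), 0) * host_mult
    sev <- pmin(pmax(sev, 0), 1)
    sev[is.na(land_use$labels)] <- NA
    severity_by_year[[as.character(t)]] <- raster_layer(sev, g)

    hit <- !is.na(sev) & sev > 0.5
    if (any(hit)) {
      units_hit <- unique(admin$labels[hit])
      newly <- units_hit[is.na(first_year[units_hit])]
      first_year[newly] <- t
    }
    tot <- sum(sev, na.rm = TRUE)
    n_pts <- stats::rpois(1, config$occ_rate * tot)
    if (n_pts > 0) {
      p <- as.vector(ifelse(is.na(sev), 0, sev))
      cells <- sample.int(n, n_pts, replace = TRUE, prob = p)
      r <- (cells - 1L) %% nr + 1L
      cl <- (cells - 1L) %/% nr + 1L
      occ[[as.character(t)]] <- data.frame(
        x = g$origin_x + (cl - 1 + stats::runif(n_pts)) * g$cell_size,
        y = g$origin_y - (r - 1 + stats::runif(n_pts)) * g$cell_size,
        year = t)
    }
  }
  list(schedule = data.frame(unit = seq_len(config$n_units),
                             first_year = first_year),
       severity_by_year = severity_by_year,
       occurrences = if (length(occ)) do.call(rbind, c(occ, make.row.names = FALSE))
                     else data.frame(x = numeric(), y = numeric(),
                                     year = integer()))
}

# undirected 8-neighbor edge list for an nr x nc lattice (column-major ids)
neighbor_edges <- function(nr, nc) {
  id <- function(r, c) (c - 1L) * nr + r
  from <- integer(0); to <- integer(0); dist <- numeric(0)
  shifts <- list(c(1L, 0L, 1), c(0L, 1L, 1), c(1L, 1L, sqrt(2)),
                 c(1L, -1L, sqrt(2)))
  for (s in shifts) {
    dr <- s[1]; dc <- s[2]
    r <- rep(seq_len(nr), times = nc); c <- rep(seq_len(nc), each = nr)
    ok <- r + dr >= 1 & r + dr <= nr & c + dc >= 1 & c + dc <= nc
    from <- c(from, id(r[ok], c[ok]))
    to <- c(to, id(r[ok] + dr, c[ok] + dc))
    dist <- c(dist, rep(s[3], sum(ok)))
  }
  list(from = from, to = to, dist = dist)
}

#' Draw a random staggered infestation schedule
#'
#' Convenience generator for panel-only experiments: each unit is either
#' never treated (probability `frac_never`) or receives a first infestation
#' year uniform over the interior of the panel window, guaranteeing at least
#' one never-treated unit.
#'
#' @param n_units Number of units.
#' @param years Panel years.
#' @param frac_never Expected fraction of never-treated units.
#' @param seed RNG seed.
#' @return Data frame `unit`, `first_year` (NA = never treated).
#' @export
random_schedule <- function(n_units, years, frac_never = 0.3, seed = 1L) {
  set.seed(stream_seed(seed, "schedule"))
  candidate <- years[-1]  # treatment switches on strictly inside the window
  first <- sample(candidate, n_units, replace = TRUE)
  never <- stats::runif(n_units) < frac_never
  if (!any(never)) never[sample.int(n_units, 1)] <- TRUE
  first[never] <- NA_integer_
  data.frame(unit = seq_len(n_units), first_year = as.integer(first))
}

#' Generate a sectoral economic panel with planted ground truth
#'
#' For each unit i, year t and sector s the outcome is
#' `Y = alpha + mu_i + gamma_t + theta * W_it + beta_s * A_is * D_it + eps`,
#' with `A_is` the number of the unit's cells in the sector's linked land-use
#' classes (the exposed production area), `D_it` the absorbing binary
#' infestation indicator from the schedule, one time-varying control `W`, and
#' `eps ~ N(0, sigma_noise)`. The planted `alpha`, `mu_i`, `gamma_t`,
#' `theta` and `beta` are returned as machine-readable ground truth.
#'
#' @param config A [scenario_config()].
#' @param schedule Data frame `unit`, `first_year` (NA = never).
#' @param admin,land_use Landscape layers on the scenario grid.
#' @return Object of class `panel_truth`: list with `panel` (data frame
#'   `unit`, `year`, `sector`, `Y`, `D`, `cells`, `X`, `w1`) and `truth`
#'   (list `alpha`, `beta`, `theta`, `mu`, `gamma`).
#' @export
generate_panel <- function(config, schedule, admin, land_use) {
  stopifnot(inherits(config, "scenario_config"))
  if (!all(c("unit", "first_year") %in% names(schedule)))
    stop("schedule must have columns unit, first_year")
  units <- sort(unique(schedule$unit))
  years <- config$years
  sectors <- names(config$beta_true)
  set.seed(stream_seed(config$seed, "panel"))

  linkage <- default_sector_linkage()[sectors]
  legend <- land_use_legend()
  cells_us <- sapply(sectors, function(s) {
    codes <- legend[linkage[[s]]]
    vapply(units, function(u)
      sum(admin$labels == u & land_use$labels %in% codes, na.rm = TRUE),
      numeric(1))
  })  # units x sectors

  alpha <- 50
  mu <- stats::rnorm(length(units), 0, 10)
  gamma <- 2 * seq_along(years) + stats::rnorm(length(years), 0, 1)
  z_unit <- stats::rnorm(length(units))
  first <- schedule$first_year[match(units, schedule$unit)]

  rows <- expand.grid(unit = units, year = years, sector = sectors,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  ui <- match(rows$unit, units)
  ti <- match(rows$year, years)
  si <- match(rows$sector, sectors)
  D <- as.integer(!is.na(first[ui]) & rows$year >= first[ui])
  cells <- cells_us[cbind(ui, si)]
  w1 <- 0.4 * z_unit[ui] + 0.2 * scale(ti)[, 1] +
    stats::rnorm(nrow(rows), 0, 0.5)
  eps <- stats::rnorm(nrow(rows), 0, config$sigma_noise)
  beta <- config$beta_true[rows$sector]
  Y <- alpha + mu[ui] + gamma[ti] + config$theta_true * w1 +
    beta * cells * D + eps
  panel <- data.frame(unit = rows$unit, year = rows$year,
                      sector = rows$sector, Y = Y, D = D, cells = cells,
                      X = cells * D, w1 = w1)
  structure(list(panel = panel,
                 truth = list(alpha = alpha,
                              beta = config$beta_true,
                              theta = config$theta_true,
                              mu = stats::setNames(mu, units),
                              gamma = stats::setNames(gamma, years))),
            class = "panel_truth")
}

#' Generate a synthetic habitat-suitability surface
#'
#' Suitability is a smooth field in `[0, 1]` positively associated with the
#' density of host land-use classes, modulated mildly by rainfall. A
#' landscape without host cells (e.g., all water) yields zero suitability
#' everywhere. This emulates the output of an external species distribution
#' model; no niche model is fitted here.
#'
#' @param config A [scenario_config()].
#' @param land_use Land-use `label_raster`.
#' @param drivers Optional driver list (uses `rainfall` if present).
#' @return A `raster_layer` with values in `[0, 1]`.
#' @export
generate_suitability <- function(config, land_use, drivers = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(stream_seed(config$seed, "suitability"))
  host_codes <- land_use_legend()[config$host_classes]
  host_mask <- matrix(land_use$labels %in% host_codes,
                      nrow(land_use$labels), ncol(land_use$labels))
  host <- smooth_mask(host_mask,
                      radius = max(3, round(min(dim(land_use$labels)) / 20)))
  climate <- if (!is.null(drivers$rainfall))
    0.75 + 0.25 * drivers$rainfall$values else 1
  suit <- pmin(pmax(host * climate, 0), 1)
  raster_layer(suit, config$grid)
}
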