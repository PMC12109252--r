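# End-to-end orchestration of the synthetic pipeline from one config:
# simulate -> spatialize -> disaggregate -> geodetect -> did -> project.
# Every stage reads/writes plain files under the run directory, so stages
# can be re-run individually; all randomness flows from one master seed.

#' Default pipeline configuration
#'
#' A plain named list covering every tunable parameter of the pipeline; any
#' entry can be overridden before passing the list to [run_pipeline()], or
#' the whole structure can be stored as a YAML file. Defaults match
#' [scenario_config()] plus the matching/weighting parameters: equal
#' severity-overlay weights (0.5, 0.5), IDW power 2, 5 quantile strata for
#' the GeoDetector, cluster-robust SEs, suitability thresholds
#' (0.25, 0.5, 0.75) and area scaling 1.
#'
#' @param seed Master seed.
#' @return Named list (class `pipeline_config`).
#' @export
default_pipeline_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    grid = list(n_rows = 100L, n_cols = 100L, cell_size = 1000),
    n_units = 50L,
    years = c(2011L, 2022L),
    beta_true = list(cultivation = -0.021, forestry = -0.163,
                     husbandry = 0.005, fishery = -0.034),
    sigma_noise = 0.5,
    spread_origin = c(row = 10L, col = 10L),
    spread_rate = 4,
    corridor_strength = 1.5,
    host_weights = as.list(default_host_weights()),
    overlay_weights = c(0.5, 0.5),
    idw_power = 2,
    classes = 5L,
    discretize_method = "quantile",
    se = "cluster",
    suit_thresholds = c(0.25, 0.5, 0.75),
    area_scaling = 1,
    deflator = NULL,
    severity_threshold = 0.75
  ), class = "pipeline_config")
}

config_to_scenario <- function(cfg) {
  scenario_config(
    seed = cfg$seed,
    grid = grid_spec(cfg$grid$n_rows, cfg$grid$n_cols, cfg$grid$cell_size),
    n_units = cfg$n_units,
    years = seq(cfg$years[1], cfg$years[2]),
    beta_true = unlist(cfg$beta_true),
    sigma_noise = cfg$sigma_noise,
    spread_origin = c(row = as.integer(cfg$spread_origin[["row"]]),
                      col = as.integer(cfg$spread_origin[["col"]])),
    spread_rate = cfg$spread_rate,
    corridor_strength = cfg$corridor_strength)
}

#' Read a pipeline configuration from YAML
#'
#' Unspecified entries fall back to [default_pipeline_config()] so every run
#' manifest echoes a complete parameter set.
#'
#' @param path YAML file.
#' @return A `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_pipeline_config(seed = user$seed %||% 1L)
  for (nm in names(user)) cfg[[nm]] <- user[[nm]]
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_csv_stable <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Run the synthetic assessment pipeline end to end
#'
#' Executes, in order, the requested stages: `simulate` (landscape, spread,
#' panel, suitability with ground truth), `spatialize` (presence-absence
#' rasterization, IDW occurrence surface, severity overlay and severe-grid
#' counts per year), `disaggregate` (allocation weights, per-cell sector
#' output, reconstruction report), `geodetect` (factor q and interactions of
#' the driver stack against disaggregated output; diagnostic, not on the
#' critical path), `did` (per-sector staggered DID fits, counterfactuals,
#' annual losses) and `project` (suitability-classified potential losses).
#' All intermediate rasters (`.asc`) and tables (`.csv`), the ground truth
#' and a complete parameter manifest (`manifest.yml`) are written under
#' `out_dir`. Stages not requested are read back from a previous run in the
#' same directory when needed.
#'
#' @param config A `pipeline_config` list (or path to a YAML file).
#' @param out_dir Run directory (created if missing).
#' @param stages Character subset of
#'   `c("simulate", "spatialize", "disaggregate", "geodetect", "did",
#'   "project")`.
#' @return Invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(config = default_pipeline_config(), out_dir,
                         stages = c("simulate", "spatialize", "disaggregate",
                                    "geodetect", "did", "project")) {
  if (is.character(config)) config <- read_pipeline_config(config)
  all_stages <- c("simulate", "spatialize", "disaggregate", "geodetect",
                  "did", "project")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  scen <- config_to_scenario(config)
  res <- list(config = config)
  msg <- function(...) message("[invadeloss] ", sprintf(...))

  lu_legend <- land_use_legend()
  unit_legend <- stats::setNames(seq_len(scen$n_units),
                                 paste0("unit_", seq_len(scen$n_units)))

  if ("simulate" %in% stages) {
    msg("simulate: landscape, spread, panel, suitability (seed %d)", scen$seed)
    land <- generate_landscape(scen)
    spread <- simulate_spread(scen, land$land_use, land$admin, land$drivers)
    pt <- generate_panel(scen, spread$schedule, land$admin, land$land_use)
    suit <- generate_suitability(scen, land$land_use, land$drivers)
    res$simulate <- list(land = land, spread = spread, panel = pt,
                         suitability = suit)
    write_ascii_grid(land$land_use, file.path(out_dir, "land_use.asc"))
    write_ascii_grid(land$admin, file.path(out_dir, "admin.asc"))
    for (nm in names(land$drivers))
      write_ascii_grid(land$drivers[[nm]],
                       file.path(out_dir, paste0("driver_", nm, ".asc")))
    for (yr in names(spread$severity_by_year))
      write_ascii_grid(spread$severity_by_year[[yr]],
                       file.path(out_dir, paste0("severity_sim_", yr, ".asc")))
    write_csv_stable(spread$occurrences, file.path(out_dir, "occurrences.csv"))
    write_csv_stable(spread$schedule, file.path(out_dir, "schedule.csv"))
    write_csv_stable(pt$panel, file.path(out_dir, "panel.csv"))
    yaml::write_yaml(lapply(pt$truth, as.list),
                     file.path(out_dir, "ground_truth.yml"))
    write_ascii_grid(suit, file.path(out_dir, "suitability.asc"))
  } else {
    msg("loading prior simulate outputs from %s", out_dir)
    land <- list(
      land_use = read_ascii_grid(file.path(out_dir, "land_use.asc"),
                                 legend = lu_legend),
      admin = read_ascii_grid(file.path(out_dir, "admin.asc"),
                              legend = unit_legend),
      drivers = NULL)
    drv_files <- list.files(out_dir, pattern = "^driver_.*\\.asc$")
    land$drivers <- stats::setNames(
      lapply(drv_files, function(f) read_ascii_grid(file.path(out_dir, f))),
      sub("^driver_(.*)\\.asc$", "\\1", drv_files))
    spread <- list(
      schedule = utils::read.csv(file.path(out_dir, "schedule.csv")),
      occurrences = utils::read.csv(file.path(out_dir, "occurrences.csv")))
    pt <- list(panel = utils::read.csv(file.path(out_dir, "panel.csv")))
    suit <- read_ascii_grid(file.path(out_dir, "suitability.asc"))
  }
  panel <- pt$panel
  years <- seq(config$years[1], config$years[2])

  if ("spatialize" %in% stages) {
    msg("spatialize: severity coefficient per year")
    hw <- unlist(config$host_weights)
    counts <- list()
    sev_final <- NULL
    for (yr in years) {
      infested <- spread$schedule$unit[!is.na(spread$schedule$first_year) &
                                         spread$schedule$first_year <= yr]
      pa <- rasterize_presence_absence(land$admin, infested, land$land_use,
                                       host_weights = hw)
      pts <- spread$occurrences[spread$occurrences$year == yr, , drop = FALSE]
      po <- if (nrow(pts)) idw_surface(pts, scen$grid, power = config$idw_power)
      else raster_layer(matrix(0, scen$grid$n_rows, scen$grid$n_cols),
                        scen$grid)
      sev <- severity_overlay(pa, po, weights = config$overlay_weights)
      write_ascii_grid(sev, file.path(out_dir,
                                      paste0("severity_matched_", yr, ".asc")))
      cnt <- count_severity_grids(sev, threshold = config$severity_threshold)
      counts[[as.character(yr)]] <- data.frame(year = yr,
                                               n_cells = cnt$n_cells,
                                               area_ha = cnt$area_ha)
      sev_final <- sev
    }
    counts <- do.call(rbind, counts)
    write_csv_stable(counts, file.path(out_dir, "severity_counts.csv"))
    res$spatialize <- list(counts = counts, severity_final = sev_final)
  }

  if ("disaggregate" %in% stages) {
    msg("disaggregate: sector outputs onto the grid")
    final_year <- max(years)
    tab <- panel[panel$year == final_year,
                 c("unit", "year", "sector", "Y")]
    names(tab)[4] <- "value"
    tab$value <- pmax(tab$value, 0)
    prov_out <- tapply(tab$value, tab$sector, sum)
    cls_counts <- table(factor(names(lu_legend)[land$land_use$labels],
                               levels = names(lu_legend)))
    prov_area <- as.numeric(cls_counts) * cell_area_ha(scen$grid)
    names(prov_area) <- names(cls_counts)
    weights <- derive_allocation_weights(as.list(prov_out), prov_area)
    rasters <- disaggregate_outputs(tab, land$admin, land$land_use, weights)
    recon <- validate_reconstruction(rasters, tab, land$admin)
    write_csv_stable(as.data.frame.table(unclass(weights),
                                         responseName = "weight"),
                     file.path(out_dir, "allocation_weights.csv"))
    write_csv_stable(recon, file.path(out_dir, "reconstruction.csv"))
    for (s in names(rasters))
      write_ascii_grid(rasters[[s]][[as.character(final_year)]],
                       file.path(out_dir, paste0("output_", s, "_",
                                                 final_year, ".asc")))
    res$disaggregate <- list(weights = weights, rasters = rasters,
                             reconstruction = recon)
  }

  if ("geodetect" %in% stages) {
    msg("geodetect: driver screening")
    if (is.null(res$disaggregate))
      stop("stage 'geodetect' needs 'disaggregate' in the same run")
    final_year <- max(years)
    sector_rasters <- lapply(res$disaggregate$rasters,
                             function(r) r[[as.character(final_year)]])
    outcome <- hadamard_overlay(unname(sector_rasters),
                                rep(1, length(sector_rasters)))
    outcome$values[is.na(outcome$values)] <- 0
    sev_file <- file.path(out_dir, paste0("severity_matched_", final_year,
                                          ".asc"))
    factors <- land$drivers
    if (file.exists(sev_file)) factors$infestation <- read_ascii_grid(sev_file)
    gd <- geodetect(outcome, factors, n_classes = config$classes,
                    method = config$discretize_method, interactions = TRUE)
    write_csv_stable(gd$factors, file.path(out_dir, "geodetector_q.csv"))
    write_csv_stable(gd$interactions,
                     file.path(out_dir, "geodetector_interactions.csv"))
    res$geodetect <- gd
  }

  if ("did" %in% stages) {
    msg("did: staggered two-way FE estimation per sector")
    fits <- fit_did_by_sector(panel, treatment = "X", controls = "w1",
                              se = config$se)
    tabfit <- did_summary_table(fits)
    write_csv_stable(tabfit, file.path(out_dir, "did_fits.csv"))
    losses <- do.call(rbind, lapply(names(fits), function(s) {
      cp <- counterfactual_outputs(fits[[s]],
                                   panel[panel$sector == s, , drop = FALSE])
      dfl <- if (!is.null(config$deflator)) unlist(config$deflator) else NULL
      annual_losses(cp, deflator = dfl)
    }))
    write_csv_stable(losses, file.path(out_dir, "annual_losses.csv"))
    res$did <- list(fits = fits, table = tabfit, losses = losses)
  }

  if ("project" %in% stages) {
    msg("project: potential losses over suitable habitat")
    if (is.null(res$did))
      stop("stage 'project' needs 'did' in the same run")
    cls <- classify_suitability(suit, thresholds = config$suit_thresholds)
    proj <- project_losses(cls, land$land_use, res$did$fits,
                           area_scaling = config$area_scaling)
    write_csv_stable(as.data.frame(proj), file.path(out_dir, "projection.csv"))
    res$project <- proj
  }

  manifest <- list(package = "invadeloss",
                   version = as.character(utils::packageVersion("invadeloss")),
                   stages = stages,
                   config = rapply(unclass(config), as.vector, how = "replace"))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yml"))
  invisible(res)
}
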