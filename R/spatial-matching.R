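# Spatial matching: convert coarse administrative presence-absence records
# and presence-only occurrence points into one per-cell severity coefficient.

#' Default host-preference weights by land-use class
#'
#' Weight in `[0, 1]` that an infested unit's cell receives per land-use
#' class, reflecting the pest's host preference for broadleaf forests and
#' croplands. Non-host classes carry weight 0.
#'
#' @return Named numeric vector over the [land_use_legend()] classes.
#' @export
default_host_weights <- function() {
  c(arable = 0.8, broadleaf_forest = 1.0, other_forest = 0.6,
    grassland = 0.2, water = 0, urban = 0, bare = 0)
}

#' Rasterize administrative presence-absence records
#'
#' Each cell of an infested administrative unit receives the host weight of
#' its land-use class; cells of uninfested units receive 0. This converts
#' coarse unit-level bulletins into a biologically informed `[0, 1]` layer.
#'
#' @param admin Administrative-unit `label_raster`.
#' @param infested_units Vector of unit codes (or legend names) currently
#'   infested; may be empty.
#' @param land_use Land-use `label_raster` on the same grid.
#' @param host_weights Named weights in `[0, 1]` per land-use class.
#' @return A `raster_layer` with values in `[0, 1]`.
#' @export
rasterize_presence_absence <- function(admin, infested_units, land_use,
                                       host_weights = default_host_weights()) {
  stopifnot(inherits(admin, "label_raster"), inherits(land_use, "label_raster"))
  if (!grids_equal(admin$grid, land_use$grid))
    stop("admin and land_use are not on the same grid")
  if (any(host_weights < 0 | host_weights > 1))
    stop("host weights must be in [0, 1]")
  if (is.character(infested_units))
    infested_units <- admin$legend[infested_units]
  infested_units <- as.integer(infested_units)
  if (length(infested_units) && !all(infested_units %in% admin$legend))
    stop("infested unit label(s) absent from the admin legend: ",
         paste(setdiff(infested_units, admin$legend), collapse = ", "))

  w_by_code <- rep(0, max(land_use$legend))
  w_by_code[land_use$legend[names(host_weights)]] <- host_weights
  vals <- matrix(0, admin$grid$n_rows, admin$grid$n_cols)
  inf <- !is.na(admin$labels) & admin$labels %in% infested_units
  vals[inf] <- w_by_code[land_use$labels[inf]]
  vals[is.na(admin$labels) | is.na(land_use$labels)] <- NA
  raster_layer(vals, admin$grid)
}

#' Inverse-distance-weighted occurrence surface
#'
#' Raw influence at a cell center is `sum_p 1 / d(c, p)^power` over all
#' occurrence points. A cell that contains a point is assigned the largest
#' finite influence observed on the raster (the `d -> 0` cap), and the
#' surface is then min-max normalized to `[0, 1]` so the source cells sit at
#' 1. Points outside the grid extent are dropped with a warning.
#'
#' @param points Data frame with columns `x`, `y` (meters; a `year` column is
#'   ignored here).
#' @param grid A [grid_spec()].
#' @param power IDW exponent (default 2: influence decays as `1/d^2`).
#' @param normalize Min-max normalize to `[0, 1]` (default). With
#'   `FALSE` the raw influence surface is returned (source cells capped).
#' @return A `raster_layer`.
#' @export
idw_surface <- function(points, grid, power = 2, normalize = TRUE) {
  stopifnot(inherits(grid, "grid_spec"))
  if (!all(c("x", "y") %in% names(points)))
    stop("points must have columns x and y")
  if (nrow(points) == 0) stop("no occurrence points supplied")
  loc <- point_to_cell(grid, points$x, points$y)
  if (any(!loc$inside)) {
    warning(sum(!loc$inside), " occurrence point(s) outside the grid extent dropped")
    points <- points[loc$inside, , drop = FALSE]
    loc <- loc[loc$inside, , drop = FALSE]
  }
  if (nrow(points) == 0) stop("no occurrence points inside the grid extent")

  cc <- cell_centers(grid)
  raw <- matrix(0, grid$n_rows, grid$n_cols)
  for (p in seq_len(nrow(points))) {
    d2 <- outer((cc$y - points$y[p])^2, (cc$x - points$x[p])^2, "+")
    raw <- raw + 1 / sqrt(d2)^power
  }
  src <- unique(cbind(loc$row, loc$col))
  src_idx <- (src[, 2] - 1L) * grid$n_rows + src[, 1]
  finite <- raw[is.finite(raw)]
  cap <- if (length(finite)) max(finite) else 1
  raw[!is.finite(raw)] <- cap
  raw[src_idx] <- cap
  if (!normalize) return(raster_layer(raw, grid))
  raster_layer(normalize01(raw), grid)
}

#' Overlay presence-absence and presence-only layers into a severity raster
#'
#' `severity = clip(w_pa * pa + w_po * po, 0, 1)` via [hadamard_overlay()].
#' The default equal weights (0.5, 0.5) give both evidence sources the same
#' influence.
#'
#' @param pa,po `raster_layer`s in `[0, 1]` on one grid.
#' @param weights Length-2 non-negative weights `(w_pa, w_po)`.
#' @return A `raster_layer` (severity coefficient) with values in `[0, 1]`.
#' @export
severity_overlay <- function(pa, po, weights = c(0.5, 0.5)) {
  if (length(weights) != 2 || any(weights < 0))
    stop("weights must be two non-negative numbers")
  out <- hadamard_overlay(list(pa, po), weights)
  out$values <- pmin(pmax(out$values, 0), 1)
  out
}

#' Count severely infested grid cells
#'
#' @param severity Severity `raster_layer` in `[0, 1]`.
#' @param threshold Severity cut-off in `[0, 1]`; cells strictly greater than
#'   the threshold are counted (default 0.75, the severe-infestation cut-off).
#' @return List with `n_cells` and `area_ha` (`n_cells` times the cell area).
#' @export
count_severity_grids <- function(severity, threshold = 0.75) {
  stopifnot(inherits(severity, "raster_layer"))
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
  n <- sum(severity$values > threshold, na.rm = TRUE)
  list(n_cells = n, area_ha = n * cell_area_ha(severity$grid))
}
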