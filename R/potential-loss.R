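# Potential-loss projection: combine habitat-suitability surfaces with land
# use and the fitted DID loss coefficients.

#' Classify a suitability raster into ordinal zones
#'
#' Half-open interval membership over `[0, 1]`:
#' `[0, t1)` unsuitable, `[t1, t2)` low, `[t2, t3)` medium-high and
#' `[t3, 1]` high (upper class closed, so a value exactly at `t3` is high).
#'
#' @param suitability `raster_layer` with values in `[0, 1]`.
#' @param thresholds Strictly increasing triple inside (0, 1); default
#'   `c(0.25, 0.5, 0.75)`.
#' @return A `label_raster` with legend `unsuitable = 1`, `low = 2`,
#'   `medium_high = 3`, `high = 4`; the thresholds are attached as attribute
#'   `thresholds`.
#' @export
classify_suitability <- function(suitability, thresholds = c(0.25, 0.5, 0.75)) {
  stopifnot(inherits(suitability, "raster_layer"))
  t <- thresholds
  if (length(t) != 3 || any(diff(t) <= 0) || t[1] <= 0 || t[3] >= 1)
    stop("thresholds must be a strictly increasing triple inside (0, 1)")
  v <- suitability$values
  if (any(v < 0 | v > 1, na.rm = TRUE))
    stop("suitability values must lie in [0, 1]")
  cls <- matrix(NA_integer_, nrow(v), ncol(v))
  ok <- !is.na(v)
  cls[ok] <- 1L + (v[ok] >= t[1]) + (v[ok] >= t[2]) + (v[ok] >= t[3])
  out <- label_raster(cls, suitability$grid,
                      legend = c(unsuitable = 1L, low = 2L,
                                 medium_high = 3L, high = 4L))
  attr(out, "thresholds") <- t
  out
}

#' Project sectoral potential losses over suitable habitat
#'
#' For each sector with an estimated loss coefficient, the projected annual
#' loss is `|beta| * area_scaling * A`, where `A` counts the medium-high and
#' high suitability cells whose land-use class is linked to the sector. The
#' 95% interval maps `beta -/+ 1.96 * SE` through the same linear function
#' (delta method), so the interval width is exactly
#' `2 * 1.96 * SE * A * area_scaling`. Sectors whose coefficient is not
#' significant at `alpha` are excluded by default. The `total` row sums the
#' sectoral points and bounds exactly.
#'
#' @param classes Suitability `label_raster` from [classify_suitability()].
#' @param land_use Land-use `label_raster` on the same grid.
#' @param fits Named list of `did_fit`s by sector.
#' @param area_scaling Cells-to-target-area conversion constant multiplying
#'   every estimate. The per-cell coefficient may be expressed on a finer
#'   reference cell than the analysis grid (e.g. a 30 m coefficient applied
#'   on a 1-km grid needs `(1000/30)^2`); the default 1 leaves beta on the
#'   analysis cell.
#' @param linkage Sector -> land-use classes, see [default_sector_linkage()].
#' @param alpha Significance level for sector inclusion (default 0.05).
#' @param include_nonsignificant Keep sectors with `p >= alpha`?
#' @param scenario Free-text scenario tag (e.g. an SSP label) echoed in the
#'   output.
#' @return Object of class `loss_projection`: data frame `scenario`,
#'   `sector`, `eligible_cells`, `point`, `lower95`, `upper95` with a final
#'   `total` row.
#' @export
project_losses <- function(classes, land_use, fits, area_scaling = 1,
                           linkage = default_sector_linkage(),
                           alpha = 0.05, include_nonsignificant = FALSE,
                           scenario = "baseline") {
  stopifnot(inherits(classes, "label_raster"),
            inherits(land_use, "label_raster"))
  if (!grids_equal(classes$grid, land_use$grid))
    stop("classes and land_use are not on the same grid")
  eligible_zone <- !is.na(classes$labels) &
    classes$labels %in% classes$legend[c("medium_high", "high")]
  legend <- land_use_legend()

  rows <- list()
  for (s in names(fits)) {
    fit <- fits[[s]]
    if (is.null(fit$beta) || is.null(fit$se))
      stop("missing coefficient or SE for sector ", s)
    if (!include_nonsignificant && fit$p >= alpha) next
    codes <- legend[linkage[[s]]]
    A <- sum(eligible_zone & land_use$labels %in% codes, na.rm = TRUE)
    k <- A * area_scaling
    point <- abs(fit$beta) * k
    lo <- (abs(fit$beta) - 1.96 * fit$se) * k
    hi <- (abs(fit$beta) + 1.96 * fit$se) * k
    rows[[s]] <- data.frame(scenario = scenario, sector = s,
                            eligible_cells = A, point = point,
                            lower95 = lo, upper95 = hi)
  }
  res <- if (length(rows)) do.call(rbind, rows)
  else data.frame(scenario = character(), sector = character(),
                  eligible_cells = integer(), point = numeric(),
                  lower95 = numeric(), upper95 = numeric())
  total <- data.frame(scenario = scenario, sector = "total",
                      eligible_cells = sum(res$eligible_cells),
                      point = sum(res$point), lower95 = sum(res$lower95),
                      upper95 = sum(res$upper95))
  out <- rbind(res, total)
  rownames(out) <- NULL
  class(out) <- c("loss_projection", "data.frame")
  out
}
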