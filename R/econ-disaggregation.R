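# Dasymetric disaggregation of district-level sectoral gross output onto the
# analysis grid using land-use allocation weights, plus reconstruction checks.
# Currency convention: values are stored in ten-thousand CNY.

#' Sector to land-use linkage
#'
#' Each primary-industry sector draws its allocation weight exclusively from
#' its linked land-use class(es): cultivation from arable land, forestry from
#' forest cover, animal husbandry from grassland and fishery from water
#' bodies. Urban and bare land never receive weight.
#'
#' @return Named list: sector -> character vector of land-use classes.
#' @export
default_sector_linkage <- function() {
  list(cultivation = "arable",
       forestry = c("broadleaf_forest", "other_forest"),
       husbandry = "grassland",
       fishery = "water")
}

#' Derive sectoral allocation weights from provincial aggregates
#'
#' The weight of a (sector, class) pair is the provincial output intensity of
#' the sector on its linked class(es): provincial sectoral output divided by
#' the total provincial area of the linked classes. Non-linked classes, and
#' the non-productive classes urban and bare, are exactly 0.
#'
#' @param provincial_outputs Named numeric: sector -> provincial output.
#' @param provincial_areas Named numeric: land-use class -> provincial area
#'   (any consistent unit).
#' @param linkage Sector -> class linkage, see [default_sector_linkage()].
#' @return An `allocation_weights` matrix (sectors x land-use classes).
#' @export
derive_allocation_weights <- function(provincial_outputs, provincial_areas,
                                      linkage = default_sector_linkage()) {
  sectors <- names(provincial_outputs)
  if (is.null(sectors)) stop("provincial_outputs must be named by sector")
  classes <- names(land_use_legend())
  w <- matrix(0, length(sectors), length(classes),
              dimnames = list(sectors, classes))
  for (s in sectors) {
    linked <- linkage[[s]]
    if (is.null(linked)) stop("no land-use linkage defined for sector ", s)
    area <- sum(provincial_areas[linked], na.rm = TRUE)
    out <- provincial_outputs[[s]]
    if (out == 0) next
    if (!is.finite(area) || area <= 0)
      stop("sector ", s, " has nonzero output but zero linked-class area")
    w[s, linked] <- out / area
  }
  w[, non_productive_classes()] <- 0  # zero-weight masking, always
  structure(w, class = c("allocation_weights", "matrix", "array"))
}

validate_sector_table <- function(table) {
  need <- c("unit", "year", "sector", "value")
  if (!all(need %in% names(table)))
    stop("sector output table needs columns ", paste(need, collapse = ", "))
  if (any(table$value < 0, na.rm = TRUE)) stop("sector outputs must be >= 0")
  key <- paste(table$unit, table$year, table$sector)
  if (anyDuplicated(key))
    stop("duplicate (unit, year, sector) rows in the sector output table")
  invisible(table)
}

#' Disaggregate district sector outputs onto the grid
#'
#' Within each administrative unit, a cell's share of the unit's sectoral
#' total is its allocation weight (by land-use class) divided by the unit's
#' total weight; cell value = unit total x share. Units whose cells carry
#' zero total weight for a sector cannot absorb that sector's output: their
#' cells become nodata and a warning names the units.
#'
#' @param table Data frame `unit`, `year`, `sector`, `value` (>= 0, no
#'   duplicate keys).
#' @param admin,land_use `label_raster`s on one grid.
#' @param weights An `allocation_weights` matrix from
#'   [derive_allocation_weights()].
#' @return Nested named list: `sector -> year -> raster_layer`.
#' @export
disaggregate_outputs <- function(table, admin, land_use, weights) {
  validate_sector_table(table)
  if (!grids_equal(admin$grid, land_use$grid))
    stop("admin and land_use are not on the same grid")
  missing_units <- setdiff(unique(table$unit), admin$legend)
  if (length(missing_units))
    stop("table unit(s) absent from the admin raster: ",
         paste(missing_units, collapse = ", "))
  g <- admin$grid
  cells_by_unit <- split(seq_along(admin$labels), admin$labels)

  out <- list()
  starved <- character(0)
  for (s in unique(table$sector)) {
    if (!s %in% rownames(weights)) stop("no allocation weights for sector ", s)
    w_by_code <- rep(0, max(land_use$legend))
    present <- intersect(names(land_use$legend), colnames(weights))
    w_by_code[land_use$legend[present]] <- weights[s, present]
    w_cell <- w_by_code[land_use$labels]
    w_cell[is.na(w_cell)] <- 0
    out[[s]] <- list()
    tab_s <- table[table$sector == s, , drop = FALSE]
    for (yr in sort(unique(tab_s$year))) {
      tab_sy <- tab_s[tab_s$year == yr, , drop = FALSE]
      m <- matrix(NA_real_, g$n_rows, g$n_cols)
      for (k in seq_len(nrow(tab_sy))) {
        u <- tab_sy$unit[k]
        idx <- cells_by_unit[[as.character(u)]]
        wu <- w_cell[idx]
        tot_w <- sum(wu)
        if (tot_w <= 0) {
          if (tab_sy$value[k] > 0)
            starved <- c(starved, paste0(s, ":", yr, ":", u))
          else m[idx] <- 0
          next
        }
        m[idx] <- tab_sy$value[k] * wu / tot_w
      }
      out[[s]][[as.character(yr)]] <- raster_layer(m, g)
    }
  }
  if (length(starved))
    warning("unallocated output (zero allocation mass) for ",
            length(starved), " unit-year-sector combination(s): ",
            paste(utils::head(starved, 5), collapse = ", "))
  out
}

#' Validate disaggregation by reconstructing unit totals
#'
#' Sums each sector raster back over administrative units and reports the
#' absolute percentage error against the input table: `|sum(cells) - value|
#' / value`. A zero table value with nonzero cell mass is flagged as
#' infinite error.
#'
#' @param cell_rasters Output of [disaggregate_outputs()].
#' @param table The original sector output table.
#' @param admin Administrative `label_raster`.
#' @return Data frame `unit`, `year`, `sector`, `reconstructed`, `value`,
#'   `ape`, with attributes `max_ape` and `mean_ape`.
#' @export
validate_reconstruction <- function(cell_rasters, table, admin) {
  validate_sector_table(table)
  if (nrow(table) == 0)
    return(structure(data.frame(unit = integer(), year = integer(),
                                sector = character(),
                                reconstructed = numeric(), value = numeric(),
                                ape = numeric()),
                     max_ape = NA_real_, mean_ape = NA_real_))
  cells_by_unit <- split(seq_along(admin$labels), admin$labels)
  rec <- numeric(nrow(table))
  for (k in seq_len(nrow(table))) {
    r <- cell_rasters[[table$sector[k]]][[as.character(table$year[k])]]
    if (is.null(r)) { rec[k] <- NA_real_; next }
    rec[k] <- sum(r$values[cells_by_unit[[as.character(table$unit[k])]]],
                  na.rm = TRUE)
  }
  ape <- ifelse(table$value > 0, abs(rec - table$value) / table$value,
                ifelse(abs(rec) > 0, Inf, 0))
  res <- data.frame(unit = table$unit, year = table$year,
                    sector = table$sector, reconstructed = rec,
                    value = table$value, ape = ape)
  structure(res, max_ape = max(ape, na.rm = TRUE),
            mean_ape = mean(ape, na.rm = TRUE))
}
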