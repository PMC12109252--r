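# Shared raster data model: one planar GridSpec that every layer in the
# pipeline shares, plus plain-text raster I/O, resampling and weighted overlay.

#' Define the shared analysis grid
#'
#' All layers in a run live on a single planar grid. The grid is addressed with
#' 0-based row-major conventions internally exposed as ordinary R matrices
#' (row 1 = northernmost row); the origin is the *top-left corner* of the
#' top-left cell, cell centers sit at `origin + (index - 0.5) * cell_size`,
#' and point-to-cell mapping uses half-open cell intervals.
#'
#' @param n_rows,n_cols Grid dimensions (positive integers).
#' @param cell_size Cell edge length in meters. The default 1000 m corresponds
#'   to the 1 km^2 analysis resolution used throughout the package.
#' @param origin_x,origin_y Planar coordinates (m) of the top-left corner.
#'   `origin_y` defaults to `n_rows * cell_size` so the lower-left corner is
#'   at (0, 0).
#' @return An object of class `grid_spec`.
#' @examples
#' g <- grid_spec(10, 20)
#' cell_area_ha(g)  # 100 ha per 1-km cell
#' @export
grid_spec <- function(n_rows, n_cols, cell_size = 1000,
                      origin_x = 0, origin_y = NULL) {
  n_rows <- as.integer(n_rows)
  n_cols <- as.integer(n_cols)
  if (is.na(n_rows) || is.na(n_cols) || n_rows < 1L || n_cols < 1L)
    stop("n_rows and n_cols must be integers >= 1")
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("cell_size must be a single positive number")
  if (is.null(origin_y)) origin_y <- n_rows * cell_size
  structure(
    list(n_rows = n_rows, n_cols = n_cols, cell_size = as.numeric(cell_size),
         origin_x = as.numeric(origin_x), origin_y = as.numeric(origin_y)),
    class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d cells, %.6g m resolution, origin (%.6g, %.6g)\n",
              x$n_rows, x$n_cols, x$cell_size, x$origin_x, x$origin_y))
  invisible(x)
}

#' Cell area of a grid in hectares
#'
#' @param grid A [grid_spec()].
#' @return Area of one cell in hectares: `(cell_size / 100)^2`.
#' @export
cell_area_ha <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  (grid$cell_size / 100)^2
}

grids_equal <- function(a, b, tol = 1e-9) {
  a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    abs(a$cell_size - b$cell_size) <= tol * max(1, abs(a$cell_size)) &&
    abs(a$origin_x - b$origin_x) <= tol * max(1, a$cell_size) &&
    abs(a$origin_y - b$origin_y) <= tol * max(1, a$cell_size)
}

#' Cell-center coordinates
#'
#' @param grid A [grid_spec()].
#' @return List with vectors `x` (length `n_cols`, west to east) and `y`
#'   (length `n_rows`, north to south).
#' @export
cell_centers <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  list(x = grid$origin_x + (seq_len(grid$n_cols) - 0.5) * grid$cell_size,
       y = grid$origin_y - (seq_len(grid$n_rows) - 0.5) * grid$cell_size)
}

#' Map planar points to grid cells
#'
#' Half-open cell intervals: a point on the shared edge of two cells belongs
#' to the cell to its east/south.
#'
#' @param grid A [grid_spec()].
#' @param x,y Coordinate vectors (meters).
#' @return Data frame with columns `row`, `col` (NA outside the grid extent)
#'   and logical `inside`.
#' @export
point_to_cell <- function(grid, x, y) {
  stopifnot(inherits(grid, "grid_spec"), length(x) == length(y))
  col <- floor((x - grid$origin_x) / grid$cell_size) + 1
  row <- floor((grid$origin_y - y) / grid$cell_size) + 1
  inside <- col >= 1 & col <= grid$n_cols & row >= 1 & row <= grid$n_rows &
    is.finite(x) & is.finite(y)
  row[!inside] <- NA_integer_
  col[!inside] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col), inside = inside)
}

#' Construct a numeric raster layer
#'
#' A raster couples a numeric matrix with the grid it lives on. Missing cells
#' are `NA` in memory; `nodata` is only the sentinel used on disk.
#'
#' @param values Numeric matrix of dimension `n_rows x n_cols` (row 1 = north).
#' @param grid A [grid_spec()]. Defaults to a grid matching `values` with
#'   1000 m cells.
#' @param nodata Sentinel written to / masked from disk files.
#' @return An object of class `raster_layer`.
#' @export
raster_layer <- function(values, grid = NULL, nodata = -9999) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(grid)) grid <- grid_spec(nrow(values), ncol(values))
  stopifnot(inherits(grid, "grid_spec"))
  if (nrow(values) != grid$n_rows || ncol(values) != grid$n_cols)
    stop("values shape (", nrow(values), "x", ncol(values),
         ") does not match grid (", grid$n_rows, "x", grid$n_cols, ")")
  structure(list(grid = grid, values = values, nodata = nodata),
            class = "raster_layer")
}

#' @export
print.raster_layer <- function(x, ...) {
  v <- x$values
  cat(sprintf("<raster_layer> %d x %d, range [%.4g, %.4g], %d NA cells\n",
              nrow(v), ncol(v),
              suppressWarnings(min(v, na.rm = TRUE)),
              suppressWarnings(max(v, na.rm = TRUE)), sum(is.na(v))))
  invisible(x)
}

#' Construct a categorical (label) raster
#'
#' @param labels Integer matrix of class codes; `NA` marks nodata.
#' @param grid A [grid_spec()].
#' @param legend Named integer vector mapping class name -> code. Every
#'   non-NA code present in `labels` must appear in the legend.
#' @param nodata Integer sentinel used on disk (default 255).
#' @return An object of class `label_raster`.
#' @export
label_raster <- function(labels, grid = NULL, legend, nodata = 255L) {
  labels <- as.matrix(labels)
  storage.mode(labels) <- "integer"
  if (is.null(grid)) grid <- grid_spec(nrow(labels), ncol(labels))
  stopifnot(inherits(grid, "grid_spec"))
  if (nrow(labels) != grid$n_rows || ncol(labels) != grid$n_cols)
    stop("labels shape does not match grid")
  if (is.null(names(legend)) || anyNA(names(legend)))
    stop("legend must be a named integer vector (name -> code)")
  present <- unique(labels[!is.na(labels)])
  if (!all(present %in% legend))
    stop("labels contain codes absent from the legend: ",
         paste(setdiff(present, legend), collapse = ", "))
  structure(list(grid = grid, labels = labels,
                 legend = as.integer(legend) |> stats::setNames(names(legend)),
                 nodata = as.integer(nodata)),
            class = "label_raster")
}

#' @export
print.label_raster <- function(x, ...) {
  cat(sprintf("<label_raster> %d x %d, %d classes (%s)\n",
              nrow(x$labels), ncol(x$labels), length(x$legend),
              paste(utils::head(names(x$legend), 5), collapse = ", ")))
  invisible(x)
}

#' Land-use legend used throughout the pipeline
#'
#' Seven classes; `urban` and `bare` are flagged non-productive and always
#' receive zero economic allocation weight.
#'
#' @return Named integer vector (class name -> code).
#' @seealso [non_productive_classes()]
#' @export
land_use_legend <- function() {
  c(arable = 1L, broadleaf_forest = 2L, other_forest = 3L, grassland = 4L,
    water = 5L, urban = 6L, bare = 7L)
}

#' @rdname land_use_legend
#' @export
non_productive_classes <- function() c("urban", "bare")

# ---- plain-text raster I/O (ESRI ASCII grid) --------------------------------

#' Read / write rasters as ESRI ASCII grids
#'
#' Rasters are stored in the ESRI ASCII grid format (`.asc`): a six-line
#' header (`ncols`, `nrows`, `xllcorner`, `yllcorner`, `cellsize`,
#' `NODATA_value`) followed by rows of values from north to south. The format
#' is plain text, carries the full grid specification, and is understood by
#' every mainstream GIS.
#'
#' @param path File path.
#' @param legend If supplied, the file is read as a [label_raster()] with this
#'   legend; otherwise a numeric [raster_layer()] is returned.
#' @return `read_ascii_grid()` returns a `raster_layer` or `label_raster`;
#'   `write_ascii_grid()` returns `path` invisibly.
#' @export
read_ascii_grid <- function(path, legend = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 7L) stop("malformed ASCII grid (too short): ", path)
  hdr <- list()
  for (i in 1:6) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(parts) != 2L)
      stop("malformed ASCII grid header line: '", lines[i], "'")
    hdr[[tolower(parts[1])]] <- suppressWarnings(as.numeric(parts[2]))
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
            "nodata_value")
  if (!all(need %in% names(hdr)) || anyNA(unlist(hdr[need])))
    stop("malformed ASCII grid header in ", path)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  vals <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  if (length(vals) != nr * nc)
    stop("ASCII grid body has ", length(vals), " values, expected ", nr * nc)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == hdr$nodata_value] <- NA
  g <- grid_spec(nr, nc, cell_size = hdr$cellsize, origin_x = hdr$xllcorner,
                 origin_y = hdr$yllcorner + nr * hdr$cellsize)
  if (is.null(legend)) raster_layer(m, g, nodata = hdr$nodata_value)
  else label_raster(m, g, legend = legend, nodata = as.integer(hdr$nodata_value))
}

#' @param x A `raster_layer` or `label_raster`.
#' @rdname read_ascii_grid
#' @export
write_ascii_grid <- function(x, path) {
  if (inherits(x, "label_raster")) {
    m <- x$labels; nodata <- x$nodata
    fmt <- function(row) paste(ifelse(is.na(row), nodata, row), collapse = " ")
  } else if (inherits(x, "raster_layer")) {
    m <- x$values; nodata <- x$nodata
    fmt <- function(row) paste(ifelse(is.na(row), as.character(nodata),
                                      formatC(row, digits = 15, format = "g")),
                               collapse = " ")
  } else stop("x must be a raster_layer or label_raster")
  g <- x$grid
  hdr <- c(paste("ncols", g$n_cols),
           paste("nrows", g$n_rows),
           paste("xllcorner", formatC(g$origin_x, digits = 15, format = "g")),
           paste("yllcorner",
                 formatC(g$origin_y - g$n_rows * g$cell_size,
                         digits = 15, format = "g")),
           paste("cellsize", formatC(g$cell_size, digits = 15, format = "g")),
           paste("NODATA_value", nodata))
  body <- vapply(seq_len(g$n_rows), function(i) fmt(m[i, ]), character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}

# ---- resampling -------------------------------------------------------------

#' Resample a raster onto a target grid
#'
#' `nearest` samples the source at each target cell center (mandatory, and the
#' only legal method, for label rasters). `mean` and `sum` aggregate all
#' source cells whose centers fall inside a target cell; `sum` conserves the
#' global total when the target extent covers the source.
#'
#' @param source A `raster_layer` or `label_raster`.
#' @param target A [grid_spec()] sharing the source's planar frame.
#' @param method One of `"nearest"`, `"mean"`, `"sum"`.
#' @return A raster on `target`.
#' @export
resample_to_grid <- function(source, target,
                             method = c("nearest", "mean", "sum")) {
  method <- match.arg(method)
  stopifnot(inherits(target, "grid_spec"))
  is_label <- inherits(source, "label_raster")
  if (!is_label && !inherits(source, "raster_layer"))
    stop("source must be a raster_layer or label_raster")
  if (is_label && method != "nearest")
    stop("label rasters must be resampled with method = 'nearest'")
  vals <- if (is_label) source$labels else source$values
  sg <- source$grid

  if (method == "nearest") {
    cc <- cell_centers(target)
    src_col <- floor((cc$x - sg$origin_x) / sg$cell_size) + 1
    src_row <- floor((sg$origin_y - cc$y) / sg$cell_size) + 1
    src_col[src_col < 1 | src_col > sg$n_cols] <- NA
    src_row[src_row < 1 | src_row > sg$n_rows] <- NA
    out <- matrix(vals[cbind(rep(src_row, times = target$n_cols),
                             rep(src_col, each = target$n_rows))],
                  nrow = target$n_rows, ncol = target$n_cols)
    if (is_label)
      return(label_raster(out, target, legend = source$legend,
                          nodata = source$nodata))
    return(raster_layer(out, target, nodata = source$nodata))
  }

  cc <- cell_centers(sg)
  tc <- floor((rep(cc$x, each = sg$n_rows) - target$origin_x) /
                target$cell_size) + 1
  tr <- floor((target$origin_y - rep(cc$y, times = sg$n_cols)) /
                target$cell_size) + 1
  keep <- tc >= 1 & tc <= target$n_cols & tr >= 1 & tr <= target$n_rows &
    !is.na(as.vector(vals))
  idx <- (tc[keep] - 1L) * target$n_rows + tr[keep]
  v <- as.vector(vals)[keep]
  out <- matrix(NA_real_, target$n_rows, target$n_cols)
  if (length(idx)) {
    sums <- rowsum(v, idx)
    if (method == "mean") sums <- sums / rowsum(rep(1, length(idx)), idx)
    out[as.integer(rownames(sums))] <- sums[, 1]
  }
  raster_layer(out, target, nodata = source$nodata)
}

# ---- weighted overlay -------------------------------------------------------

#' Weighted cell-wise overlay of aligned rasters
#'
#' Combines layers on one shared grid as `sum_k w_k * L_k` (the Hadamard-style
#' element-wise operation used to homogenize multi-source layers onto the
#' common grid). A nodata cell in any input yields nodata in the output.
#'
#' @param layers List of `raster_layer`s on one common grid.
#' @param weights Numeric vector, one weight per layer.
#' @return A `raster_layer` on the shared grid.
#' @examples
#' a <- raster_layer(matrix(2, 3, 3)); b <- raster_layer(matrix(3, 3, 3))
#' hadamard_overlay(list(a, b), c(1, 2))$values[1, 1]  # 8
#' @export
hadamard_overlay <- function(layers, weights) {
  if (!length(layers)) stop("need at least one layer")
  if (length(weights) != length(layers))
    stop("weights must have one entry per layer")
  if (!all(vapply(layers, inherits, logical(1), "raster_layer")))
    stop("all layers must be raster_layer objects")
  g <- layers[[1]]$grid
  for (l in layers[-1])
    if (!grids_equal(g, l$grid)) stop("layers are not on the same grid")
  acc <- matrix(0, g$n_rows, g$n_cols)
  for (k in seq_along(layers)) acc <- acc + weights[k] * layers[[k]]$values
  raster_layer(acc, g, nodata = layers[[1]]$nodata)
}

# internal: rescale a matrix to [0, 1]; constant input maps to 0
normalize01 <- function(m) {
  rng <- range(m, na.rm = TRUE)
  if (!is.finite(rng[1]) || rng[2] == rng[1]) {
    m[!is.na(m)] <- 0
    return(m)
  }
  (m - rng[1]) / (rng[2] - rng[1])
}
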