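# Spatial diagnostics: global Moran's I on raster fields and Gaussian
# kernel-density surfaces for occurrence points.

neighbor_offsets <- function(scheme) {
  rook <- list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  if (scheme == "rook") return(rook)
  c(rook, list(c(-1L, -1L), c(-1L, 1L), c(1L, -1L), c(1L, 1L)))
}

# sum of z over each cell's neighbors, plus neighbor counts; NA cells excluded
neighbor_sums <- function(z, ok, scheme) {
  nr <- nrow(z); nc <- ncol(z)
  zz <- z; zz[!ok] <- 0
  Wz <- matrix(0, nr, nc); deg <- matrix(0, nr, nc)
  for (off in neighbor_offsets(scheme)) {
    dr <- off[1]; dc <- off[2]
    r_dst <- max(1, 1 - dr):min(nr, nr - dr)
    c_dst <- max(1, 1 - dc):min(nc, nc - dc)
    r_src <- r_dst + dr; c_src <- c_dst + dc
    Wz[r_dst, c_dst] <- Wz[r_dst, c_dst] + zz[r_src, c_src]
    deg[r_dst, c_dst] <- deg[r_dst, c_dst] + ok[r_src, c_src]
  }
  list(Wz = Wz, deg = deg)
}

#' Global Moran's I on a raster
#'
#' `I = (n / S0) * sum_ij w_ij z_i z_j / sum_i z_i^2` with `z` the deviations
#' from the mean, contiguity weights on the cell lattice (queen by default,
#' truncated at edges, zero diagonal) and optional row standardization.
#' Positive I indicates clustering; the permutation-null expectation is
#' `-1/(n-1)`; a perfectly alternating field under rook weights gives -1.
#'
#' @param raster Numeric `raster_layer` (>= 2 non-nodata cells, positive
#'   variance).
#' @param scheme `"queen"` (default) or `"rook"` contiguity.
#' @param row_standardized Row-standardize the weights (default TRUE)?
#' @param permutations If > 0, a permutation p-value (two-sided on the rank
#'   of observed I) is attached as attribute `p_value`.
#' @return Moran's I as a numeric scalar with attributes `expectation`
#'   (`-1/(n-1)`) and optionally `p_value`.
#' @export
morans_i <- function(raster, scheme = c("queen", "rook"),
                     row_standardized = TRUE, permutations = 0) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(raster, "raster_layer"))
  v <- raster$values
  ok <- !is.na(v)
  n <- sum(ok)
  if (n < 2L) stop("need at least two non-nodata cells")
  if (pop_var(v[ok]) <= 0) stop("constant field; Moran's I is undefined")

  compute_i <- function(vals) {
    z <- vals - mean(vals[ok]); z[!ok] <- 0
    ns <- neighbor_sums(z, ok, scheme)
    if (row_standardized) {
      has <- ok & ns$deg > 0
      num <- sum(z[has] * ns$Wz[has] / ns$deg[has])
      s0 <- sum(has)
    } else {
      num <- sum(z[ok] * ns$Wz[ok])
      s0 <- sum(ns$deg[ok])
    }
    (n / s0) * num / sum(z[ok]^2)
  }
  I <- compute_i(v)
  out <- I
  attr(out, "expectation") <- -1 / (n - 1)
  if (permutations > 0) {
    sims <- vapply(seq_len(permutations), function(k) {
      vv <- v
      vv[ok] <- sample(v[ok])
      compute_i(vv)
    }, numeric(1))
    r <- sum(sims >= I)
    attr(out, "p_value") <- 2 * min(r + 1, permutations - r + 1) /
      (permutations + 1)
  }
  out
}

#' Gaussian kernel-density surface for occurrence points
#'
#' Evaluates `sum_p (2 pi h^2)^-1 exp(-d(c, p)^2 / (2 h^2))` at every cell
#' center (points per m^2). Multiplying by the cell area and summing
#' approximates the point count when the bandwidth is small relative to the
#' extent; the surface is linear in the point set and translation
#' equivariant.
#'
#' @param points Data frame with columns `x`, `y`.
#' @param grid A [grid_spec()].
#' @param bandwidth Gaussian kernel bandwidth in meters (> 0).
#' @return A `raster_layer` of densities.
#' @export
kernel_density <- function(points, grid, bandwidth) {
  stopifnot(inherits(grid, "grid_spec"))
  if (!all(c("x", "y") %in% names(points)))
    stop("points must have columns x and y")
  if (nrow(points) == 0) stop("no points supplied")
  if (!is.numeric(bandwidth) || bandwidth <= 0)
    stop("bandwidth must be a positive length in meters")
  cc <- cell_centers(grid)
  h2 <- bandwidth^2
  dens <- matrix(0, grid$n_rows, grid$n_cols)
  norm <- 1 / (2 * pi * h2)
  for (p in seq_len(nrow(points))) {
    gy <- exp(-(cc$y - points$y[p])^2 / (2 * h2))
    gx <- exp(-(cc$x - points$x[p])^2 / (2 * h2))
    dens <- dens + norm * outer(gy, gx)
  }
  raster_layer(dens, grid)
}
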