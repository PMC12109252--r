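# Independent brute-force oracles and small fixtures used across tests.
# Each oracle is written from the statistic's definition, not from the
# package implementation it checks.

# population variance
pvar <- function(x) mean((x - mean(x))^2)

# grouped-variance q-statistic by explicit grouping
oracle_q <- function(y, strata) {
  ok <- !is.na(y) & !is.na(strata)
  y <- y[ok]; s <- strata[ok]
  within <- sum(tapply(y, s, function(g) length(g) * pvar(g)))
  1 - within / (length(y) * pvar(y))
}

# global Moran's I by explicit O(n^2) pairwise weights
oracle_moran <- function(m, scheme = c("queen", "rook"),
                         row_standardized = TRUE) {
  scheme <- match.arg(scheme)
  idx <- which(!is.na(m), arr.ind = TRUE)
  n <- nrow(idx)
  z <- m[idx] - mean(m[idx])
  dr <- abs(outer(idx[, 1], idx[, 1], "-"))
  dc <- abs(outer(idx[, 2], idx[, 2], "-"))
  W <- if (scheme == "rook") (dr + dc == 1) * 1 else (dr <= 1 & dc <= 1) * 1
  diag(W) <- 0
  if (row_standardized) {
    rs <- rowSums(W)
    W[rs > 0, ] <- W[rs > 0, ] / rs[rs > 0]
  }
  (n / sum(W)) * sum(W * outer(z, z)) / sum(z^2)
}

# raw IDW influence by explicit per-cell / per-point loops, with the same
# published post-conditions (source-cell cap, min-max normalization)
oracle_idw <- function(points, grid, power = 2, normalize = TRUE) {
  raw <- matrix(0, grid$n_rows, grid$n_cols)
  for (r in seq_len(grid$n_rows)) for (cl in seq_len(grid$n_cols)) {
    cx <- grid$origin_x + (cl - 0.5) * grid$cell_size
    cy <- grid$origin_y - (r - 0.5) * grid$cell_size
    acc <- 0
    for (p in seq_len(nrow(points)))
      acc <- acc + 1 / sqrt((cx - points$x[p])^2 + (cy - points$y[p])^2)^power
    raw[r, cl] <- acc
  }
  cap <- max(raw[is.finite(raw)])
  raw[!is.finite(raw)] <- cap
  for (p in seq_len(nrow(points))) {
    cl <- floor((points$x[p] - grid$origin_x) / grid$cell_size) + 1
    r <- floor((grid$origin_y - points$y[p]) / grid$cell_size) + 1
    raw[r, cl] <- cap
  }
  if (!normalize) return(raw)
  (raw - min(raw)) / (max(raw) - min(raw))
}

# two-way within-demeaning estimator (balanced panels, no controls)
oracle_twfe <- function(panel, treatment = "X") {
  dd <- function(v) v - stats::ave(v, panel$unit) - stats::ave(v, panel$year) +
    mean(v)
  sum(dd(panel[[treatment]]) * dd(panel$Y)) / sum(dd(panel[[treatment]])^2)
}

# compact scenario for fast tests
small_scenario <- function(seed = 1, spread_rate = 2, ...) {
  scenario_config(seed = seed, grid = grid_spec(30, 30, 1000), n_units = 8,
                  years = 2011:2016, spread_rate = spread_rate, ...)
}

# uniform land-use raster of one class
uniform_land_use <- function(class, n_rows, n_cols, cell_size = 1000) {
  code <- land_use_legend()[[class]]
  label_raster(matrix(code, n_rows, n_cols),
               grid_spec(n_rows, n_cols, cell_size),
               legend = land_use_legend())
}

# admin raster splitting an n_rows x n_cols grid into vertical strips
strip_admin <- function(n_units, n_rows, n_cols, cell_size = 1000) {
  strip <- rep(seq_len(n_units), each = ceiling(n_cols / n_units),
               length.out = n_cols)
  label_raster(matrix(strip, n_rows, n_cols, byrow = TRUE),
               grid_spec(n_rows, n_cols, cell_size),
               legend = stats::setNames(seq_len(n_units),
                                        paste0("unit_", seq_len(n_units))))
}

# minimal did_fit stub for projection tests
fake_fit <- function(beta, se, p = 1e-6) {
  structure(list(beta = beta, se = se, p = p, treatment = "D"),
            class = "did_fit")
}
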