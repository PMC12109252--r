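# GeoDetector: factor detector q-statistic and the interaction detector with
# its five-category classification.
#
# q = 1 - (sum_h n_h * sigma_h^2) / (n * sigma^2), with *population*
# variances throughout; the law of total variance then pins q to [0, 1]
# exactly, which sample variances would not.

pop_var <- function(x) {
  m <- mean(x)
  mean((x - m)^2)
}

#' Discretize a continuous raster into strata
#'
#' Stratification methods: `quantile` (near-equal stratum sizes),
#' `equal_interval` (equal-width bins over the value range) and
#' `natural_breaks` (1-D k-means with quantile-seeded centers, a
#' deterministic approximation to Jenks breaks).
#'
#' @param raster A numeric `raster_layer`.
#' @param n_classes Number of strata (>= 2).
#' @param method Discretization method.
#' @param name Factor identifier carried into results.
#' @return An object of class `factor_layer` with fields `grid`, `strata`
#'   (integer matrix, labels `1:L`), `L`, `name`.
#' @export
discretize_factor <- function(raster, n_classes = 5,
                              method = c("quantile", "equal_interval",
                                         "natural_breaks"),
                              name = deparse(substitute(raster))) {
  method <- match.arg(method)
  stopifnot(inherits(raster, "raster_layer"))
  n_classes <- as.integer(n_classes)
  if (n_classes < 2L) stop("n_classes must be >= 2")
  v <- raster$values
  ok <- !is.na(v)
  uv <- unique(v[ok])
  if (length(uv) < 2L) stop("cannot discretize a constant raster")
  breaks <- switch(method,
    quantile = unique(stats::quantile(v[ok], probs = seq(0, 1, length.out = n_classes + 1))),
    equal_interval = seq(min(v[ok]), max(v[ok]), length.out = n_classes + 1),
    natural_breaks = {
      centers <- stats::quantile(v[ok], probs = seq(0.5, n_classes - 0.5) / n_classes)
      km <- stats::kmeans(v[ok], centers = matrix(sort(unique(centers))),
                          iter.max = 50)
      cs <- sort(km$centers[, 1])
      c(min(v[ok]), (cs[-1] + cs[-length(cs)]) / 2, max(v[ok]))
    })
  if (length(breaks) < 3L)
    stop("cannot form >= 2 strata; raster has too few distinct values")
  strata <- matrix(NA_integer_, nrow(v), ncol(v))
  strata[ok] <- as.integer(cut(v[ok], breaks = breaks, include.lowest = TRUE,
                               labels = FALSE))
  structure(list(grid = raster$grid, strata = strata,
                 L = length(breaks) - 1L, name = name),
            class = "factor_layer")
}

#' Use a categorical raster directly as a stratification
#'
#' Bypass for already-categorical inputs: existing codes are relabeled
#' `1:L` in sorted order, preserving the partition.
#'
#' @param x A `label_raster`, or an integer matrix/`raster_layer` of codes.
#' @param grid Grid (taken from `x` when available).
#' @param name Factor identifier.
#' @return A `factor_layer`.
#' @export
as_factor_layer <- function(x, grid = NULL, name = deparse(substitute(x))) {
  if (inherits(x, "factor_layer")) return(x)
  if (inherits(x, "label_raster")) { m <- x$labels; grid <- x$grid }
  else if (inherits(x, "raster_layer")) { m <- x$values; grid <- x$grid }
  else m <- as.matrix(x)
  if (is.null(grid)) grid <- grid_spec(nrow(m), ncol(m))
  codes <- sort(unique(m[!is.na(m)]))
  strata <- matrix(match(m, codes), nrow(m), ncol(m))
  structure(list(grid = grid, strata = strata, L = length(codes), name = name),
            class = "factor_layer")
}

#' Factor detector q-statistic
#'
#' Quantifies how much of the spatial variance of `outcome` the
#' stratification explains:
#' `q = 1 - (sum_h n_h sigma_h^2) / (n sigma^2)` over the strata `h = 1..L`,
#' with population variances. `q = 0` means the factor has no explanatory
#' power; `q = 1` means it completely controls the spatial variation.
#' Single-cell strata contribute zero within-stratum variance and are kept.
#'
#' @param outcome Numeric `raster_layer`.
#' @param factor_layer A `factor_layer` on the same grid.
#' @param min_stratum_size Drop strata smaller than this before computing q
#'   (default 1 = keep all).
#' @return Object of class `factor_result`: list with `q`, `n`, `sigma2`,
#'   `strata` (data frame `stratum`, `n_h`, `sigma2_h`), `name`.
#' @export
factor_q <- function(outcome, factor_layer, min_stratum_size = 1L) {
  stopifnot(inherits(outcome, "raster_layer"),
            inherits(factor_layer, "factor_layer"))
  if (!grids_equal(outcome$grid, factor_layer$grid))
    stop("outcome and factor are not on the same grid")
  ok <- !is.na(outcome$values) & !is.na(factor_layer$strata)
  y <- outcome$values[ok]
  h <- factor_layer$strata[ok]
  if (min_stratum_size > 1L) {
    sizes <- table(h)
    keep <- h %in% as.integer(names(sizes)[sizes >= min_stratum_size])
    y <- y[keep]; h <- h[keep]
  }
  n <- length(y)
  if (n < 2L) stop("need at least two non-nodata cells")
  sigma2 <- pop_var(y)
  if (sigma2 <= 0) stop("outcome has zero variance; q is undefined")
  groups <- split(y, h)
  n_h <- vapply(groups, length, numeric(1))
  s2_h <- vapply(groups, pop_var, numeric(1))
  q <- 1 - sum(n_h * s2_h) / (n * sigma2)
  structure(list(q = q, n = n, sigma2 = sigma2,
                 strata = data.frame(stratum = as.integer(names(groups)),
                                     n_h = as.integer(n_h), sigma2_h = s2_h),
                 name = factor_layer$name),
            class = "factor_result")
}

#' @export
print.factor_result <- function(x, ...) {
  cat(sprintf("<factor_result> %s: q = %.4f (n = %d, L = %d)\n",
              x$name, x$q, x$n, nrow(x$strata)))
  invisible(x)
}

#' Interaction detector: q of a factor-pair cross-classification
#'
#' The interaction stratification is the set of nonempty `(h1, h2)` pairs;
#' its q measures the joint explanatory power of the two factors.
#'
#' @param outcome Numeric `raster_layer`.
#' @param f1,f2 `factor_layer`s on the outcome's grid.
#' @return The interaction q (numeric scalar).
#' @export
interaction_q <- function(outcome, f1, f2) {
  stopifnot(inherits(f1, "factor_layer"), inherits(f2, "factor_layer"))
  if (!grids_equal(f1$grid, f2$grid))
    stop("factors are not on the same grid")
  cross <- f1$strata * (max(f2$strata, na.rm = TRUE) + 1L) + f2$strata
  codes <- sort(unique(cross[!is.na(cross)]))
  combined <- structure(list(grid = f1$grid,
                             strata = matrix(match(cross, codes),
                                             nrow(cross), ncol(cross)),
                             L = length(codes),
                             name = paste(f1$name, f2$name, sep = ":")),
                        class = "factor_layer")
  factor_q(outcome, combined)$q
}

#' Classify a factor interaction
#'
#' Compares the interaction q with the single-factor q values and assigns one
#' of the five categories: `q12 < min(q1, q2)` nonlinear weakening;
#' `min < q12 < max` single-factor nonlinear weakening; `q12 > max(q1, q2)`
#' bi-factor enhancement; `q12 = q1 + q2` (within tolerance `tau`)
#' independent; `q12 > q1 + q2` nonlinear enhancement.
#'
#' @param q1,q2,q12 q values in `[0, 1]`.
#' @param tau Equality tolerance for the independent category.
#' @return One of `"nonlinear_weakening"`, `"single_factor_nonlinear_weakening"`,
#'   `"bifactor_enhancement"`, `"independent"`, `"nonlinear_enhancement"`.
#' @export
classify_interaction <- function(q1, q2, q12, tau = 1e-9) {
  stopifnot(all(c(q1, q2, q12) >= -tau), all(c(q1, q2, q12) <= 1 + tau))
  if (abs(q12 - (q1 + q2)) <= tau) return("independent")
  if (q12 > q1 + q2) return("nonlinear_enhancement")
  if (q12 > max(q1, q2)) return("bifactor_enhancement")
  if (q12 < min(q1, q2)) return("nonlinear_weakening")
  "single_factor_nonlinear_weakening"
}

#' Run the factor and interaction detectors over a set of drivers
#'
#' @param outcome Numeric `raster_layer`.
#' @param factors Named list of `factor_layer`s (or rasters, discretized with
#'   `n_classes`/`method`).
#' @param n_classes,method Passed to [discretize_factor()] for continuous
#'   inputs.
#' @param interactions Also compute all pairwise interactions?
#' @return List with `factors` (data frame `name`, `q`) and, when requested,
#'   `interactions` (data frame `f1`, `f2`, `q1`, `q2`, `q12`, `category`).
#' @export
geodetect <- function(outcome, factors, n_classes = 5, method = "quantile",
                      interactions = FALSE) {
  fl <- lapply(names(factors), function(nm) {
    f <- factors[[nm]]
    if (inherits(f, "factor_layer")) f
    else if (inherits(f, "label_raster")) as_factor_layer(f, name = nm)
    else discretize_factor(f, n_classes = n_classes, method = method,
                           name = nm)
  })
  names(fl) <- names(factors)
  qs <- vapply(fl, function(f) factor_q(outcome, f)$q, numeric(1))
  res <- list(factors = data.frame(name = names(fl), q = unname(qs)))
  if (interactions && length(fl) >= 2) {
    pairs <- utils::combn(names(fl), 2)
    rows <- apply(pairs, 2, function(p) {
      q12 <- interaction_q(outcome, fl[[p[1]]], fl[[p[2]]])
      data.frame(f1 = p[1], f2 = p[2], q1 = qs[[p[1]]], q2 = qs[[p[2]]],
                 q12 = q12,
                 category = classify_interaction(qs[[p[1]]], qs[[p[2]]], q12))
    })
    res$interactions <- do.call(rbind, rows)
  }
  res
}
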