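make_outcome <- function(m) raster_layer(m)

test_that("q endpoints: perfect stratification gives 1, single stratum gives 0", {
  strata <- matrix(rep(1:4, each = 25), 10, 10)
  fl <- as_factor_layer(strata)
  # outcome constant within strata, distinct across: full control
  out <- make_outcome(matrix(c(5, 9, 2, 7)[strata], 10, 10))
  expect_equal(factor_q(out, fl)$q, 1)

  one <- as_factor_layer(matrix(1L, 10, 10))
  set.seed(1)
  noisy <- make_outcome(matrix(rnorm(100), 10, 10))
  expect_equal(factor_q(noisy, one)$q, 0)
})

test_that("q matches the grouped-variance hand computation", {
  # outcome (1,2,3,4), strata (A,A,B,B): q = 1 - (2*.25 + 2*.25)/(4*1.25)
  out <- make_outcome(matrix(1:4, 2, 2))
  fl <- as_factor_layer(matrix(c(1L, 1L, 2L, 2L), 2, 2))
  res <- factor_q(out, fl)
  expect_equal(res$q, 0.8)
  expect_equal(sum(res$strata$n_h), res$n)
})

test_that("q equals a brute-force oracle and stays in [0, 1]", {
  set.seed(202)
  for (k in 1:50) {
    y <- matrix(rnorm(400), 20, 20)
    L <- sample(2:8, 1)
    strata <- matrix(sample.int(L, 400, replace = TRUE), 20, 20)
    q <- factor_q(make_outcome(y), as_factor_layer(strata))$q
    expect_equal(q, oracle_q(y, strata), tolerance = 1e-12)
    expect_gte(q, 0)
    expect_lte(q, 1)
  }
})

test_that("refining a stratification never decreases q", {
  set.seed(77)
  for (k in 1:10) {
    y <- matrix(rnorm(225), 15, 15)
    strata <- matrix(sample.int(4, 225, replace = TRUE), 15, 15)
    q0 <- factor_q(make_outcome(y), as_factor_layer(strata))$q
    # split stratum 1 into two arbitrary halves
    refined <- strata
    ones <- which(refined == 1)
    refined[sample(ones, length(ones) %/% 2)] <- 5L
    q1 <- factor_q(make_outcome(y), as_factor_layer(refined))$q
    expect_gte(q1, q0 - 1e-12)
  }
})

test_that("q is invariant under affine transforms of the outcome", {
  set.seed(13)
  y <- matrix(rnorm(100), 10, 10)
  fl <- as_factor_layer(matrix(sample.int(3, 100, replace = TRUE), 10, 10))
  q0 <- factor_q(make_outcome(y), fl)$q
  expect_equal(factor_q(make_outcome(-2.5 * y + 7), fl)$q, q0,
               tolerance = 1e-12)
})

test_that("degenerate inputs are rejected", {
  expect_error(factor_q(make_outcome(matrix(3, 5, 5)),
                        as_factor_layer(matrix(1:25, 5, 5))),
               "zero variance")
  expect_error(discretize_factor(raster_layer(matrix(1, 5, 5))), "constant")
})

test_that("interaction q collapses and separates correctly", {
  set.seed(5)
  y <- matrix(rnorm(144), 12, 12)
  out <- make_outcome(y)
  f1 <- as_factor_layer(matrix(sample.int(3, 144, replace = TRUE), 12, 12))
  q1 <- factor_q(out, f1)$q
  # identical second factor: cross-classification collapses
  expect_equal(interaction_q(out, f1, f1), q1, tolerance = 1e-12)
  # constant second factor: no extra information
  const <- as_factor_layer(matrix(1L, 12, 12))
  expect_equal(interaction_q(out, f1, const), q1, tolerance = 1e-12)
  # a pair that fully separates all cells explains everything
  f2 <- as_factor_layer(matrix(rep(1:48, each = 3), 12, 12))
  f3 <- as_factor_layer(matrix(rep(1:3, 48), 12, 12))
  expect_equal(interaction_q(out, f2, f3), 1)
})

test_that("interaction categories follow the printed inequalities", {
  expect_equal(classify_interaction(0.3, 0.4, 0.7), "independent")
  expect_equal(classify_interaction(0.3, 0.4, 0.9), "nonlinear_enhancement")
  expect_equal(classify_interaction(0.3, 0.4, 0.35),
               "single_factor_nonlinear_weakening")
  expect_equal(classify_interaction(0.3, 0.4, 0.2), "nonlinear_weakening")
  expect_equal(classify_interaction(0.3, 0.4, 0.5), "bifactor_enhancement")
  # tolerance on the equality branch
  expect_equal(classify_interaction(0.3, 0.4, 0.7 + 1e-12), "independent")
})

test_that("discretization methods produce the expected strata", {
  g <- grid_spec(10, 10)
  vals <- raster_layer(matrix(1:100, 10, 10), g)
  fq <- discretize_factor(vals, 5, "quantile")
  expect_equal(unname(table(fq$strata)), rep(20L, 5),
               ignore_attr = TRUE)

  ei <- discretize_factor(raster_layer(matrix(seq(0, 10, length.out = 100),
                                              10, 10), g),
                          2, "equal_interval")
  v <- matrix(seq(0, 10, length.out = 100), 10, 10)
  expect_true(all(ei$strata[v <= 5] == 1L))
  expect_true(all(ei$strata[v > 5] == 2L))

  nb <- discretize_factor(vals, 4, "natural_breaks")
  expect_equal(nb$L, 4L)
  # categorical bypass keeps the partition intact
  lab <- label_raster(matrix(c(3L, 7L, 3L, 7L), 2, 2), grid_spec(2, 2),
                      legend = c(a = 3L, b = 7L))
  fl <- as_factor_layer(lab)
  expect_equal(fl$L, 2L)
  expect_equal(fl$strata, matrix(c(1L, 2L, 1L, 2L), 2, 2))
})
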