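lin_sf <- function(w) toy_scorer("linear", list(weights = w))

test_that("raw gradients recover closed-form derivatives", {
  set.seed(1)
  w <- matrix(runif(16, -1, 1), 4, 4)
  x <- matrix(runif(16), 4, 4)
  expect_equal(gradients(lin_sf(w), x)$values, w)

  const_sf <- score_function(function(x) 3, grad = function(x) x * 0)
  expect_equal(gradients(const_sf, x)$values, matrix(0, 4, 4))

  quad <- toy_scorer("quadratic")
  expect_equal(gradients(quad, x)$values, 2 * x)
  expect_equal(gradients(quad, x)$values,
               finite_difference_grad(quad$f, x), tolerance = 1e-4)
})

test_that("finite-difference provider agrees with analytic gradients", {
  set.seed(2)
  x <- matrix(runif(9, 0.2, 0.8), 3, 3)
  # smooth nonlinear scorer: f = sum(sin(x)) + sum(x^3)
  f <- function(z) sum(sin(z)) + sum(z^3)
  sf_fd <- score_function(f) # finite-difference fallback
  analytic <- cos(x) + 3 * x^2
  expect_equal(sf_fd$grad(x), analytic, tolerance = 1e-4)
})

test_that("input x gradient is the elementwise product of its factors", {
  set.seed(3)
  w <- matrix(runif(16, -1, 1), 4, 4)
  x <- matrix(runif(16), 4, 4)
  expect_equal(input_times_gradient(lin_sf(w), x)$values, w * x)
  expect_equal(input_times_gradient(lin_sf(w), x * 0)$values, matrix(0, 4, 4))
  quad <- toy_scorer("quadratic")
  expect_equal(input_times_gradient(quad, x)$values,
               x * gradients(quad, x)$values)
})

test_that("integrated gradients is exact for linear scorers and complete", {
  set.seed(4)
  w <- matrix(runif(16, -1, 1), 4, 4)
  x <- matrix(runif(16), 4, 4)
  sf <- lin_sf(w)
  for (steps in c(1, 8, 64)) {
    expect_equal(integrated_gradients(sf, x, steps = steps)$values, w * x)
  }
  expect_equal(integrated_gradients(sf, x, baseline = x)$values,
               matrix(0, 4, 4))

  # completeness on a smooth nonlinear scorer
  f <- function(z) sum(z^2) + sum(sin(z))
  g <- function(z) 2 * z + cos(z)
  sf2 <- score_function(f, g)
  baseline <- x * 0
  ig <- integrated_gradients(sf2, x, baseline = baseline, steps = 256)
  expect_equal(sum(ig$values), f(x) - f(baseline), tolerance = 1e-3)

  expect_error(integrated_gradients(sf, x, steps = 0), class = "ecs_param_error")
  expect_error(integrated_gradients(sf, x, baseline = matrix(0, 2, 2)),
               class = "ecs_shape_error")
})

test_that("smoothgrad degenerates to gradients at sigma 0 and is seeded", {
  set.seed(5)
  w <- matrix(runif(16, -1, 1), 4, 4)
  x <- matrix(runif(16), 4, 4)
  sf <- lin_sf(w)
  expect_identical(smoothgrad(sf, x, sigma = 0, n_samples = 7)$values,
                   gradients(sf, x)$values)

  a <- smoothgrad(sf, x, sigma = 0.2, n_samples = 10, seed = 11)$values
  b <- smoothgrad(sf, x, sigma = 0.2, n_samples = 10, seed = 11)$values
  expect_identical(a, b)

  # linear score: sample mean concentrates on w (gradient is constant)
  expect_equal(a, w)
})

test_that("smoothgrad sample mean approaches the expected gradient", {
  # quadratic f: grad(x + eps) = 2(x + eps), E = 2x, each pixel mean has
  # sd = 2 sigma / sqrt(n); assert within 4 sd elementwise
  set.seed(6)
  x <- matrix(runif(25), 5, 5)
  sigma <- 0.1
  n <- 400
  sg <- smoothgrad(toy_scorer("quadratic"), x, sigma = sigma, n_samples = n,
                   seed = 2)$values
  bound <- 4 * 2 * sigma / sqrt(n)
  expect_true(all(abs(sg - 2 * x) < bound))
})

test_that("smoothgrad-squared averages squared gradients", {
  set.seed(7)
  x <- matrix(runif(16), 4, 4)
  quad <- toy_scorer("quadratic")
  expect_equal(smoothgrad_squared(quad, x, sigma = 0, n_samples = 3)$values,
               (2 * x)^2)
  sg2 <- smoothgrad_squared(quad, x, sigma = 0.3, n_samples = 50, seed = 1)$values
  expect_true(all(sg2 >= 0))
  # E[(2(x+eps))^2] = 4x^2 + 4 sigma^2
  expect_equal(mean(sg2 - 4 * x^2), 4 * 0.09, tolerance = 0.05)
})

test_that("vargrad is the population variance of the noisy gradients", {
  set.seed(8)
  w <- matrix(runif(16, -1, 1), 4, 4)
  x <- matrix(runif(16), 4, 4)
  quad <- toy_scorer("quadratic")

  expect_equal(vargrad(quad, x, sigma = 0, n_samples = 5)$values,
               matrix(0, 4, 4))
  # linear scorer: constant gradient, zero variance at any sigma
  expect_equal(vargrad(lin_sf(w), x, sigma = 0.5, n_samples = 20, seed = 3)$values,
               matrix(0, 4, 4))

  # variance identity on the same seeded sample set
  args <- list(quad, x, sigma = 0.25, n_samples = 30, seed = 99)
  vg <- do.call(vargrad, args)$values
  sg <- do.call(smoothgrad, args)$values
  sg2 <- do.call(smoothgrad_squared, args)$values
  expect_equal(vg, sg2 - sg * sg)
})

test_that("stochastic methods are bit-reproducible under a fixed seed", {
  set.seed(9)
  x <- matrix(runif(36), 6, 6)
  quad <- toy_scorer("quadratic")
  for (fn in list(smoothgrad, smoothgrad_squared, vargrad)) {
    a <- fn(quad, x, sigma = 0.2, n_samples = 8, seed = 5)$values
    b <- fn(quad, x, sigma = 0.2, n_samples = 8, seed = 5)$values
    expect_identical(a, b)
  }
})

test_that("non-finite gradients and unknown scorers raise typed errors", {
  bad <- score_function(function(x) sum(x), grad = function(x) x * NaN)
  expect_error(gradients(bad, matrix(1, 2, 2)), class = "ecs_value_error")
  expect_error(toy_scorer("mystery"), class = "ecs_param_error")
})

test_that("disk-sum scorer gradient is the disk indicator", {
  sf <- toy_scorer("disk-sum", list(center = c(5, 5), radius = 2.5))
  x <- matrix(runif(81), 9, 9)
  g <- gradients(sf, x)$values
  expect_true(all(g %in% c(0, 1)))
  expect_equal(g[5, 5], 1)
  expect_equal(g[1, 1], 0)
  d2 <- outer((1:9 - 5)^2, (1:9 - 5)^2, `+`)
  expect_equal(g, (d2 <= 2.5^2) + 0)
  # scorer value equals masked intensity sum
  expect_equal(sf$f(x), sum(x[d2 <= 2.5^2]))
})
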