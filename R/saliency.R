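#' Scalar score function with gradient provider
#'
#' The attribution methods in this package are architecture-independent: they
#' only need a scalar score `f(image)` and its per-pixel gradient. Any model
#' — a closed-form scorer, a wrapped neural network, or a finite-difference
#' approximation — can stand behind this contract. When `grad` is omitted, a
#' central finite-difference provider is constructed from `f`.
#'
#' @param f Function mapping an image (numeric matrix or array) to a scalar.
#' @param grad Optional function mapping the image to the per-pixel partial
#'   derivatives of `f` (same shape as the image).
#' @param eps Step size for the finite-difference fallback.
#' @return An object of class `score_fn` with elements `f` and `grad`.
#' @export
score_function <- function(f, grad = NULL, eps = 1e-5) {
  stopifnot(is.function(f))
  if (is.null(grad)) {
    grad <- function(x) finite_difference_grad(f, x, eps = eps)
  }
  stopifnot(is.function(grad))
  structure(list(f = f, grad = grad), class = "score_fn")
}

#' Central finite-difference gradient
#'
#' @param f Scalar-valued function of an image.
#' @param x Image (numeric matrix or array).
#' @param eps Half step size.
#' @return Array of partial derivatives, same shape as `x`.
#' @export
finite_difference_grad <- function(f, x, eps = 1e-5) {
  g <- x
  g[] <- 0
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

.new_attribution <- function(values, method, params = list()) {
  if (!all(is.finite(values))) {
    .stop_with_class(
      sprintf("%s produced non-finite attribution values", method),
      "ecs_value_error"
    )
  }
  structure(list(values = values, method = method, params = params),
            class = "attribution_map")
}

#' @export
print.attribution_map <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "<attribution_map> method '%s', %s, range [%.4g, %.4g]\n",
    x$method, paste(d, collapse = " x "), min(x$values), max(x$values)
  ))
  invisible(x)
}

#' Raw gradients attribution
#'
#' The per-pixel partial derivatives of the score at the input: the simplest
#' saliency map.
#'
#' @param sf A [score_function()].
#' @param x Input image.
#' @return An `attribution_map`.
#' @export
gradients <- function(sf, x) {
  stopifnot(inherits(sf, "score_fn"))
  .new_attribution(sf$grad(x), "gradients")
}

#' Input x Gradient attribution
#'
#' Elementwise product of the input with the gradient at the input.
#'
#' @inheritParams gradients
#' @export
input_times_gradient <- function(sf, x) {
  stopifnot(inherits(sf, "score_fn"))
  .new_attribution(x * sf$grad(x), "input_times_gradient")
}

#' Integrated Gradients attribution
#'
#' Path integral of the gradient along the straight line from `baseline` to
#' `x`, scaled elementwise by `(x - baseline)`. Approximated by a midpoint
#' Riemann sum over `steps` points:
#' `(x - b) * mean_k grad(b + ((k - 1/2)/steps) (x - b))`, `k = 1..steps`.
#' The midpoint rule has `O(1/steps^2)` quadrature error (an endpoint rule
#' would only reach `O(1/steps)`), so the completeness axiom — the map sums
#' to `f(x) - f(baseline)` — holds tightly at moderate step counts; it is
#' exact for linear scorers at any number of steps.
#'
#' @inheritParams gradients
#' @param baseline Baseline image, same shape as `x` (default all zeros).
#' @param steps Number of Riemann steps (default 64).
#' @export
integrated_gradients <- function(sf, x, baseline = NULL, steps = 64L) {
  stopifnot(inherits(sf, "score_fn"))
  if (!.is_count(steps)) {
    .stop_with_class("steps must be a positive integer", "ecs_param_error")
  }
  if (is.null(baseline)) {
    baseline <- x
    baseline[] <- 0
  }
  if (!identical(dim(baseline), dim(x)) || length(baseline) != length(x)) {
    .stop_with_class("baseline must have the same shape as x",
                     "ecs_shape_error")
  }
  diff <- x - baseline
  acc <- x
  acc[] <- 0
  for (k in seq_len(steps)) {
    acc <- acc + sf$grad(baseline + ((k - 0.5) / steps) * diff)
  }
  .new_attribution(
    diff * acc / steps, "integrated_gradients",
    params = list(steps = as.integer(steps))
  )
}

# Draw n_samples noisy gradients and fold them with `combine`; shared by the
# SmoothGrad family so that same-seed runs see identical noise sequences.
.noisy_gradient_stack <- function(sf, x, sigma, n_samples, seed, combine) {
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma < 0) {
    .stop_with_class("sigma must be a nonnegative number", "ecs_param_error")
  }
  if (!.is_count(n_samples)) {
    .stop_with_class("n_samples must be a positive integer", "ecs_param_error")
  }
  with_seed(seed, {
    grads <- vector("list", n_samples)
    for (i in seq_len(n_samples)) {
      noise <- x
      noise[] <- stats::rnorm(length(x), mean = 0, sd = sigma)
      grads[[i]] <- sf$grad(x + noise)
    }
    combine(grads)
  })
}

.default_sigma <- function(x) 0.15 * (max(x) - min(x))

#' SmoothGrad attribution
#'
#' Mean gradient over `n_samples` Gaussian-perturbed copies of the input:
#' `mean_i grad(x + eps_i)`, `eps_i ~ N(0, sigma^2)` iid per pixel. Averaging
#' suppresses high-frequency gradient noise. With `sigma = 0` it equals
#' [gradients()] exactly.
#'
#' @inheritParams gradients
#' @param sigma Noise standard deviation; default `0.15 * (max(x) - min(x))`.
#' @param n_samples Number of noisy samples (default 25).
#' @param seed Optional seed; same seed, same inputs give a bit-identical map.
#' @export
smoothgrad <- function(sf, x, sigma = NULL, n_samples = 25L, seed = NULL) {
  stopifnot(inherits(sf, "score_fn"))
  if (is.null(sigma)) sigma <- .default_sigma(x)
  # sigma = 0: all samples coincide with the plain gradient
  vals <- if (sigma == 0) {
    sf$grad(x)
  } else .noisy_gradient_stack(sf, x, sigma, n_samples, seed, function(gs) {
    Reduce(`+`, gs) / length(gs)
  })
  .new_attribution(vals, "smoothgrad",
                   params = list(sigma = sigma, n_samples = as.integer(n_samples),
                                 seed = seed))
}

#' SmoothGrad-Squared attribution
#'
#' Mean of the elementwise-squared noisy gradients:
#' `mean_i grad(x + eps_i)^2`. Nonnegative by construction.
#'
#' @inheritParams smoothgrad
#' @export
smoothgrad_squared <- function(sf, x, sigma = NULL, n_samples = 25L,
                               seed = NULL) {
  stopifnot(inherits(sf, "score_fn"))
  if (is.null(sigma)) sigma <- .default_sigma(x)
  vals <- if (sigma == 0) {
    g <- sf$grad(x)
    g * g
  } else .noisy_gradient_stack(sf, x, sigma, n_samples, seed, function(gs) {
    Reduce(`+`, lapply(gs, function(g) g * g)) / length(gs)
  })
  .new_attribution(vals, "smoothgrad_squared",
                   params = list(sigma = sigma, n_samples = as.integer(n_samples),
                                 seed = seed))
}

#' VarGrad attribution
#'
#' Elementwise variance of the noisy gradients across samples (population
#' variance, divisor `n`): high where the gradient is unstable under input
#' perturbation. Identically zero for linear score functions, whose gradient
#' is constant.
#'
#' @inheritParams smoothgrad
#' @export
vargrad <- function(sf, x, sigma = NULL, n_samples = 25L, seed = NULL) {
  stopifnot(inherits(sf, "score_fn"))
  if (is.null(sigma)) sigma <- .default_sigma(x)
  vals <- if (sigma == 0) {
    z <- x
    z[] <- 0
    z
  } else .noisy_gradient_stack(sf, x, sigma, n_samples, seed, function(gs) {
    n <- length(gs)
    m <- Reduce(`+`, gs) / n
    m2 <- Reduce(`+`, lapply(gs, function(g) g * g)) / n
    m2 - m * m
  })
  .new_attribution(vals, "vargrad",
                   params = list(sigma = sigma, n_samples = as.integer(n_samples),
                                 seed = seed))
}
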