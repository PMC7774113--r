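#' Parameters for synthetic lesion-mask fixtures
#'
#' Describes a generator of IDRiD-style per-image lesion annotations: filled
#' axis-aligned ellipses for hemorrhages (HE), hard exudates (EX) and soft
#' exudates (SE), and 1-4 pixel dots for microaneurysms (MA). The default
#' geometry is chosen so that, over a corpus, the expected share of lesion
#' pixels per type matches the severely imbalanced profile observed in real
#' expert segmentations: about 47% HE, 44% EX, 8% SE and 1% MA.
#'
#' Severity grades are sampled from `grade_probs`, which defaults to the
#' empirical grade distribution of an 54-image DR-positive tuning set
#' (one grade-1 image, 18 grade-2, 16 grade-3, 19 grade-4).
#'
#' @param image_size Image side length in pixels (square), `>= 32`.
#' @param he_n,ex_n,se_n,ma_n Number of lesions per type per image.
#' @param he_axes,ex_axes,se_axes Semi-axis range (pixels) for the ellipse
#'   types; each semi-axis is drawn uniformly from the range.
#' @param ma_size Range of microaneurysm dot sizes in pixels (1-4).
#' @param target_profile Named fractions of corpus lesion pixels per type
#'   (documentation of the generator's target; not used at draw time).
#' @param grade_probs Named probabilities over grades "1".."4".
#' @return An object of class `fixture_params`.
#' @export
fixture_params <- function(image_size = 100L,
                           he_n = 3L, he_axes = c(3.5, 6.5),
                           ex_n = 6L, ex_axes = c(2.5, 4.5),
                           se_n = 1L, se_axes = c(3.0, 4.5),
                           ma_n = 2L, ma_size = c(1L, 4L),
                           target_profile = c(he = 0.47, ex = 0.44,
                                              se = 0.08, ma = 0.01),
                           grade_probs = c("1" = 1, "2" = 18, "3" = 16,
                                           "4" = 19) / 54) {
  image_size <- as.integer(image_size)
  if (image_size < 32L) {
    .stop_with_class("image_size must be at least 32", "ecs_param_error")
  }
  counts <- c(he = he_n, ex = ex_n, se = se_n, ma = ma_n)
  if (any(counts < 0)) {
    .stop_with_class("lesion counts must be nonnegative", "ecs_param_error")
  }
  max_axis <- max(he_axes, ex_axes, se_axes)
  if (2 * ceiling(max_axis) + 2 >= image_size) {
    .stop_with_class("lesions cannot fit: largest semi-axis too big for image",
                     "ecs_geometry_error")
  }
  stopifnot(all(ma_size >= 1), all(ma_size <= 4))
  structure(
    list(
      image_size = image_size,
      he_n = as.integer(he_n), he_axes = he_axes,
      ex_n = as.integer(ex_n), ex_axes = ex_axes,
      se_n = as.integer(se_n), se_axes = se_axes,
      ma_n = as.integer(ma_n), ma_size = as.integer(ma_size),
      target_profile = target_profile,
      grade_probs = grade_probs
    ),
    class = "fixture_params"
  )
}

# Rasterize a filled axis-aligned ellipse into a binary matrix (in place).
.paint_ellipse <- function(mask, cy, cx, ay, ax) {
  r0 <- max(1L, floor(cy - ay)); r1 <- min(nrow(mask), ceiling(cy + ay))
  c0 <- max(1L, floor(cx - ax)); c1 <- min(ncol(mask), ceiling(cx + ax))
  rows <- r0:r1
  cols <- c0:c1
  inside <- outer(((rows - cy) / ay)^2, ((cols - cx) / ax)^2, `+`) <= 1
  mask[rows, cols][inside] <- 1L
  mask
}

# Microaneurysm dots: 1-4 pixel clusters grown in a fixed pattern.
.paint_dot <- function(mask, r, c, size) {
  offs <- list(c(0L, 0L), c(0L, 1L), c(1L, 0L), c(1L, 1L))[seq_len(size)]
  for (o in offs) {
    rr <- min(nrow(mask), r + o[1L])
    cc <- min(ncol(mask), c + o[2L])
    mask[rr, cc] <- 1L
  }
  mask
}

.draw_ellipse_mask <- function(n_px, count, axes) {
  mask <- matrix(0L, n_px, n_px)
  if (count == 0L) return(mask)
  for (i in seq_len(count)) {
    ay <- stats::runif(1L, axes[1L], axes[2L])
    ax <- stats::runif(1L, axes[1L], axes[2L])
    cy <- stats::runif(1L, ceiling(ay) + 1, n_px - ceiling(ay))
    cx <- stats::runif(1L, ceiling(ax) + 1, n_px - ceiling(ax))
    mask <- .paint_ellipse(mask, cy, cx, ay, ax)
  }
  mask
}

#' Generate one synthetic lesion mask set
#'
#' Draws lesion positions and sizes per [fixture_params()] and returns four
#' binary masks plus a sampled severity grade. Reproducible per seed.
#'
#' @param params A [fixture_params()].
#' @param seed Optional seed.
#' @return A [lesion_mask_set()].
#' @examples
#' m <- generate_mask_set(fixture_params(), seed = 1)
#' sum(m$ma) # a handful of microaneurysm pixels
#' @export
generate_mask_set <- function(params = fixture_params(), seed = NULL) {
  stopifnot(inherits(params, "fixture_params"))
  n <- params$image_size
  with_seed(seed, {
    he <- .draw_ellipse_mask(n, params$he_n, params$he_axes)
    ex <- .draw_ellipse_mask(n, params$ex_n, params$ex_axes)
    se <- .draw_ellipse_mask(n, params$se_n, params$se_axes)
    ma <- matrix(0L, n, n)
    if (params$ma_n > 0L) {
      for (i in seq_len(params$ma_n)) {
        size <- sample(seq(params$ma_size[1L], params$ma_size[2L]), 1L)
        r <- sample.int(n - 1L, 1L)
        c <- sample.int(n - 1L, 1L)
        ma <- .paint_dot(ma, r, c, size)
      }
    }
    total <- sum(he) + sum(ma) + sum(se) + sum(ex)
    grade <- if (total == 0L) {
      0L
    } else {
      as.integer(sample(names(params$grade_probs), 1L,
                        prob = params$grade_probs))
    }
    lesion_mask_set(he = he, ma = ma, se = se, ex = ex, grade = grade)
  })
}

#' Construct a heatmap with an exact target top-K overlap
#'
#' Builds a heatmap whose ECS against the given expert annotation is exactly
#' `round(q * k) / k` by construction: `round(q * k)` of the expert's top-K
#' cells receive high heatmap mass, the remaining `k - round(q * k)` high
#' cells are placed outside the expert top-K, and all other cells get zero.
#' Cell values are painted as constants over the cell's pixels, so
#' discretization recovers them exactly. This enables parameter-recovery
#' testing of the scoring pipeline.
#'
#' @param masks A [lesion_mask_set()].
#' @param grid A [grid_spec()] matching the mask shape.
#' @param k Top-cell count the overlap is targeted at.
#' @param q Target overlap fraction in `[0, 1]`.
#' @param weights A [weight_set()] used to discretize the expert annotation.
#' @param seed Optional seed (placement of non-overlap cells and choice of
#'   overlap cells).
#' @return A nonnegative heatmap matrix of the grid's image size.
#' @export
generate_heatmap_with_overlap <- function(masks, grid, k = 15L, q,
                                          weights = lesion_weights_preset("idrid-paper"),
                                          seed = NULL) {
  stopifnot(inherits(masks, "lesion_mask_set"), inherits(grid, "grid_spec"))
  if (!is.numeric(q) || length(q) != 1L || q < 0 || q > 1) {
    .stop_with_class("q must be a fraction in [0, 1]", "ecs_param_error")
  }
  if (!.is_count(k)) {
    .stop_with_class("k must be a positive integer", "ecs_param_error")
  }
  de <- discretize_expert(masks, weights, grid)
  s <- grid$s
  et <- top_k_cells(de, k)
  n_expert <- nrow(et)
  if (n_expert < k && q < 1) {
    .stop_with_class(
      sprintf("expert discretization has only %d positive cells (< k = %d); cannot target overlap q = %g",
              n_expert, k, q),
      "ecs_geometry_error"
    )
  }
  m <- as.integer(round(q * k))
  et_ids <- .cell_ids(et, s)
  other_ids <- setdiff(seq_len(s * s), et_ids)
  if (length(other_ids) < k - m) {
    .stop_with_class("grid too small to place non-overlapping top cells",
                     "ecs_geometry_error")
  }
  chosen <- with_seed(seed, {
    n_keep <- min(m, length(et_ids))
    keep <- et_ids[sample.int(length(et_ids), n_keep)]
    fill <- other_ids[sample.int(length(other_ids), k - m)]
    c(keep, fill)
  })
  # descending distinct cell masses, painted as per-pixel constants
  cell_vals <- numeric(s * s)
  cell_vals[chosen] <- seq(from = length(chosen), to = 1L)
  h <- matrix(0, grid$nrow, grid$ncol)
  rb <- .cell_bins(grid$nrow, s)
  cb <- .cell_bins(grid$ncol, s)
  npx <- tabulate(rb, s) %o% tabulate(cb, s)
  for (id in chosen) {
    i <- (id - 1L) %/% s + 1L
    j <- (id - 1L) %% s + 1L
    h[rb == i, cb == j] <- cell_vals[id] / npx[i, j]
  }
  h
}

#' Closed-form score functions for saliency testing
#'
#' Returns a [score_function()] with analytic gradient:
#' * `"linear"`: `f(x) = sum(w * x)`; gradient is `w` everywhere
#'   (`params$weights`, an image-shaped matrix).
#' * `"disk-sum"`: total intensity inside a disk of `params$radius` centred
#'   at `params$center = c(row, col)`; gradient is the disk indicator.
#' * `"quadratic"`: `f(x) = sum(x^2)`; gradient `2 x`.
#'
#' @param kind One of `"linear"`, `"disk-sum"`, `"quadratic"`.
#' @param params List of parameters for the chosen kind.
#' @return A [score_function()].
#' @export
toy_scorer <- function(kind = c("linear", "disk-sum", "quadratic"),
                       params = list()) {
  kind <- tryCatch(match.arg(kind), error = function(e) {
    .stop_with_class(sprintf("unknown scorer kind '%s'", kind[1L]),
                     "ecs_param_error")
  })
  switch(kind,
    "linear" = {
      w <- params$weights
      stopifnot(is.numeric(w))
      score_function(
        f = function(x) sum(w * x),
        grad = function(x) {
          g <- x; g[] <- w; g
        }
      )
    },
    "disk-sum" = {
      ctr <- params$center
      rad <- params$radius
      stopifnot(length(ctr) == 2L, is.numeric(rad), rad > 0)
      indicator <- function(x) {
        d2 <- outer((seq_len(nrow(x)) - ctr[1L])^2,
                    (seq_len(ncol(x)) - ctr[2L])^2, `+`)
        (d2 <= rad^2) + 0
      }
      score_function(
        f = function(x) sum(x * indicator(x)),
        grad = indicator
      )
    },
    "quadratic" = score_function(
      f = function(x) sum(x^2),
      grad = function(x) 2 * x
    )
  )
}
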