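#' Grid specification for discretization
#'
#' Describes the S x S grid overlaid on an image. Cell `(i, j)` (1-based,
#' row-major) covers pixel rows `[(i-1)*dy + 1, i*dy]` and columns
#' `[(j-1)*dx + 1, j*dx]`, where `dy = floor(nrow/S)` and
#' `dx = floor(ncol/S)`. When the image size is not divisible by `S`, the
#' trailing `nrow %% S` rows (and `ncol %% S` columns) join the last cell
#' row/column, so no annotated pixel is ever dropped. Rectangular images use
#' independent cell widths per axis.
#'
#' @param image_size Image size in pixels: a single number for square images
#'   or `c(nrow, ncol)`.
#' @param grid_size Number of grid cells per side, `S`.
#' @return An object of class `grid_spec` with fields `nrow`, `ncol`, `s`,
#'   `dy`, `dx`.
#' @examples
#' grid_spec(100, 10)
#' @export
grid_spec <- function(image_size, grid_size = 10L) {
  stopifnot(is.numeric(image_size), length(image_size) %in% c(1L, 2L))
  if (length(image_size) == 1L) image_size <- c(image_size, image_size)
  image_size <- as.integer(image_size)
  s <- as.integer(grid_size)
  if (!.is_count(s)) {
    .stop_with_class("grid_size must be a positive integer", "ecs_param_error")
  }
  if (any(image_size < s)) {
    .stop_with_class(
      sprintf(
        "image size (%d x %d) must be at least grid_size (%d) on each axis",
        image_size[1L], image_size[2L], s
      ),
      "ecs_param_error"
    )
  }
  structure(
    list(
      nrow = image_size[1L], ncol = image_size[2L], s = s,
      dy = image_size[1L] %/% s, dx = image_size[2L] %/% s
    ),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf(
    "<grid_spec> %d x %d image, %d x %d grid (cells %d x %d px%s)\n",
    x$nrow, x$ncol, x$s, x$s, x$dy, x$dx,
    if (x$nrow %% x$s || x$ncol %% x$s) ", boundary cells enlarged" else ""
  ))
  invisible(x)
}

# Map pixel indices 1..n to cell indices 1..s; trailing remainder pixels
# are absorbed by the last cell.
.cell_bins <- function(n, s) {
  d <- n %/% s
  pmin.int((seq_len(n) - 1L) %/% d + 1L, s)
}

#' Reduce a three-channel attribution map to one channel
#'
#' Gradient-type attribution maps have one value per colour channel; the ECS
#' pipeline consumes a single-channel map obtained by taking the maximum over
#' channels. The default `"abs-max"` mode takes absolute values per channel
#' first, so strong negative evidence is kept; the literal `"max"` mode takes
#' the signed per-channel maximum and clips negatives to zero.
#'
#' @param raw A numeric array of dimension `nrow x ncol x 3`.
#' @param mode `"abs-max"` (default) or `"max"`.
#' @return A nonnegative matrix (class `matrix`), same spatial size as `raw`.
#' @examples
#' a <- array(c(1, -5, 2), dim = c(1, 1, 3))
#' reduce_channels(a)              # 5
#' reduce_channels(a, mode = "max") # 2
#' @export
reduce_channels <- function(raw, mode = c("abs-max", "max")) {
  mode <- match.arg(mode)
  if (!is.array(raw) || length(dim(raw)) != 3L || dim(raw)[3L] != 3L) {
    .stop_with_class(
      "raw must be an nrow x ncol x 3 array (three channels)",
      "ecs_shape_error"
    )
  }
  if (!all(is.finite(raw))) {
    .stop_with_class("raw contains non-finite values", "ecs_value_error")
  }
  if (mode == "abs-max") raw <- abs(raw)
  out <- pmax(raw[, , 1L], raw[, , 2L], raw[, , 3L])
  if (mode == "max") out <- pmax(out, 0)
  dim(out) <- dim(raw)[1:2] # 1 x n slices drop dims under pmax
  out
}

#' Construct a lesion mask set
#'
#' Bundles the four aligned binary lesion masks annotated for one fundus
#' image: hemorrhages (HE), microaneurysms (MA), soft exudates (SE) and hard
#' exudates (EX). Masks may overlap. An optional ordinal diabetic-retinopathy
#' severity grade (0-4) can be attached for stratified reporting.
#'
#' @param he,ma,se,ex Binary matrices (values 0/1) of identical shape.
#' @param grade Optional integer severity grade in 0..4.
#' @return An object of class `lesion_mask_set`.
#' @export
lesion_mask_set <- function(he, ma, se, ex, grade = NULL) {
  masks <- list(he = he, ma = ma, se = se, ex = ex)
  dims <- lapply(masks, dim)
  if (any(vapply(masks, function(m) !is.matrix(m), logical(1L)))) {
    .stop_with_class("all four masks must be matrices", "ecs_shape_error")
  }
  if (!all(vapply(dims, identical, logical(1L), dims[[1L]]))) {
    .stop_with_class("all four masks must share one shape", "ecs_shape_error")
  }
  for (nm in names(masks)) {
    v <- masks[[nm]]
    if (!all(v %in% c(0, 1))) {
      .stop_with_class(
        sprintf("mask '%s' must be strictly binary (0/1)", toupper(nm)),
        "ecs_value_error"
      )
    }
    storage.mode(masks[[nm]]) <- "integer"
  }
  if (!is.null(grade)) {
    stopifnot(is.numeric(grade), length(grade) == 1L, grade %in% 0:4)
    grade <- as.integer(grade)
  }
  structure(c(masks, list(grade = grade)), class = "lesion_mask_set")
}

#' @export
print.lesion_mask_set <- function(x, ...) {
  px <- vapply(.lesion_types, function(t) sum(x[[t]]), numeric(1L))
  cat(sprintf(
    "<lesion_mask_set> %d x %d; lesion pixels HE=%d MA=%d SE=%d EX=%d%s\n",
    nrow(x$he), ncol(x$he), px["he"], px["ma"], px["se"], px["ex"],
    if (is.null(x$grade)) "" else sprintf("; grade %d", x$grade)
  ))
  invisible(x)
}

.new_discretized_map <- function(cells, kind, grid) {
  structure(
    list(cells = cells, kind = kind, grid = grid),
    class = "discretized_map"
  )
}

#' @export
print.discretized_map <- function(x, ...) {
  cat(sprintf(
    "<discretized_map> kind '%s', %d x %d cells, total mass %.6g, nnz %d\n",
    x$kind, x$grid$s, x$grid$s, sum(x$cells), sum(x$cells > 0)
  ))
  invisible(x)
}

# Block-sum a pixel matrix onto the grid. Two nested rowsum() calls: one over
# pixel rows, one over pixel columns.
.block_sum <- function(m, grid) {
  rb <- .cell_bins(nrow(m), grid$s)
  cb <- .cell_bins(ncol(m), grid$s)
  by_row <- rowsum(m, rb, reorder = TRUE)
  out <- t(rowsum(t(by_row), cb, reorder = TRUE))
  dimnames(out) <- NULL
  out
}

#' Discretize a heatmap onto a grid
#'
#' Sums heatmap values inside each grid cell (no weighting: heatmaps do not
#' distinguish lesion types). Total mass is conserved.
#'
#' @param h Nonnegative numeric matrix, same size as the grid's image.
#' @param grid A [grid_spec()].
#' @return A `discretized_map` of kind `"heatmap"`.
#' @export
discretize_heatmap <- function(h, grid) {
  if (!is.matrix(h) || !is.numeric(h)) {
    .stop_with_class("h must be a numeric matrix", "ecs_shape_error")
  }
  if (nrow(h) != grid$nrow || ncol(h) != grid$ncol) {
    .stop_with_class(
      sprintf(
        "heatmap shape (%d x %d) does not match grid image size (%d x %d)",
        nrow(h), ncol(h), grid$nrow, grid$ncol
      ),
      "ecs_shape_error"
    )
  }
  if (!all(is.finite(h))) {
    .stop_with_class("heatmap contains non-finite values", "ecs_value_error")
  }
  if (any(h < 0)) {
    .stop_with_class(
      "heatmap contains negative values; apply reduce_channels() or abs() first",
      "ecs_value_error"
    )
  }
  .new_discretized_map(.block_sum(h, grid), "heatmap", grid)
}

#' Discretize an expert segmentation onto a grid, with lesion weighting
#'
#' Counts lesion pixels of each type inside each grid cell and combines the
#' four per-type counts with the lesion-type weights:
#' `DE[i,j] = w_HE * n_HE + w_MA * n_MA + w_SE * n_SE + w_EX * n_EX`.
#' Weighting compensates the severe pixel-count imbalance between lesion
#' types, so that rare microaneurysms still influence the top-K cells.
#'
#' @param masks A [lesion_mask_set()].
#' @param weights A [weight_set()] of strictly positive lesion weights.
#' @param grid A [grid_spec()].
#' @return A `discretized_map` of kind `"expert"`.
#' @export
discretize_expert <- function(masks, weights, grid) {
  stopifnot(inherits(masks, "lesion_mask_set"), inherits(weights, "weight_set"))
  if (nrow(masks$he) != grid$nrow || ncol(masks$he) != grid$ncol) {
    .stop_with_class(
      sprintf(
        "mask shape (%d x %d) does not match grid image size (%d x %d)",
        nrow(masks$he), ncol(masks$he), grid$nrow, grid$ncol
      ),
      "ecs_shape_error"
    )
  }
  cells <- matrix(0, grid$s, grid$s)
  for (t in .lesion_types) {
    w <- weights[[paste0("w_", t)]]
    m <- masks[[t]]
    if (any(m > 0L)) cells <- cells + w * .block_sum(m, grid)
  }
  .new_discretized_map(cells, "expert", grid)
}
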