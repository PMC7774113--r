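#' Top-K cells of a discretized map
#'
#' Returns the grid cells with the K highest values. Only strictly positive
#' cells are eligible, so sparse maps with fewer than K positive cells return
#' fewer than K cells and a score of 0 remains attainable. Ties are broken
#' deterministically: by value descending, then row-major cell index
#' ascending. A `"random"` tie mode (seeded) is available for sensitivity
#' checks.
#'
#' @param d A `discretized_map` (from [discretize_heatmap()] /
#'   [discretize_expert()]) or a plain numeric matrix.
#' @param k Number of cells to select, `k >= 1`.
#' @param ties `"row-major"` (default, deterministic) or `"random"`.
#' @param seed Seed for the `"random"` tie mode.
#' @return Integer matrix with columns `row`, `col` (1-based), at most `k`
#'   rows, ordered by decreasing cell value.
#' @export
top_k_cells <- function(d, k, ties = c("row-major", "random"), seed = NULL) {
  ties <- match.arg(ties)
  cells <- if (inherits(d, "discretized_map")) d$cells else d
  stopifnot(is.matrix(cells), is.numeric(cells))
  if (!.is_count(k)) {
    .stop_with_class("k must be a positive integer", "ecs_param_error")
  }
  nr <- nrow(cells)
  nc <- ncol(cells)
  v <- as.vector(t(cells)) # row-major order
  tie_key <- switch(ties,
    "row-major" = seq_along(v),
    "random" = with_seed(seed, sample.int(length(v)))
  )
  ord <- order(-v, tie_key)
  ord <- ord[v[ord] > 0]
  ord <- ord[seq_len(min(k, length(ord)))]
  cbind(
    row = (ord - 1L) %/% nc + 1L,
    col = (ord - 1L) %% nc + 1L
  )
}

# Row-major linear ids for a cell matrix (row, col) on an s x s grid.
.cell_ids <- function(cells, s) {
  if (nrow(cells) == 0L) return(integer(0L))
  (cells[, "row"] - 1L) * s + cells[, "col"]
}

#' Explainability Consistency Score
#'
#' Computes the agreement between a discretized expert segmentation `DE` and
#' a discretized heatmap `DH` as the number of shared top-K cells divided by
#' `min(K, nnz(DE))`, where `nnz` is the number of nonzero expert cells. The
#' score always lies in `[0, 1]` and can be read as the fraction of the
#' expert's most lesion-dense regions that the heatmap also ranks highest.
#'
#' Images with an empty expert map (no annotated lesion) have no defined
#' score; an error of class `ecs_empty_expert` is raised so that callers can
#' skip such images explicitly.
#'
#' @param de Discretized expert map (kind `"expert"`).
#' @param dh Discretized heatmap (kind `"heatmap"`).
#' @param k Number of top cells compared (default 15).
#' @return An object of class `ecs_result` with fields `score`, `k`,
#'   `expert_top_cells`, `heatmap_top_cells`, `overlap`, `denominator`.
#' @examples
#' g <- grid_spec(4, 2)
#' de <- discretize_heatmap(diag(4), g)
#' ecs_score(de, de, k = 2)$score # 1
#' @export
ecs_score <- function(de, dh, k = 15L) {
  stopifnot(inherits(de, "discretized_map"), inherits(dh, "discretized_map"))
  if (de$grid$s != dh$grid$s) {
    .stop_with_class("de and dh must share one grid", "ecs_shape_error")
  }
  if (!.is_count(k)) {
    .stop_with_class("k must be a positive integer", "ecs_param_error")
  }
  nnz <- sum(de$cells > 0)
  if (nnz == 0L) {
    .stop_with_class(
      "expert map has no nonzero cell (image has no annotated lesion); score undefined",
      "ecs_empty_expert"
    )
  }
  s <- de$grid$s
  et <- top_k_cells(de, k)
  ht <- top_k_cells(dh, k)
  overlap <- length(intersect(.cell_ids(et, s), .cell_ids(ht, s)))
  denominator <- min(k, nnz)
  structure(
    list(
      score = overlap / denominator, k = as.integer(k),
      expert_top_cells = et, heatmap_top_cells = ht,
      overlap = overlap, denominator = as.integer(denominator)
    ),
    class = "ecs_result"
  )
}

#' @export
print.ecs_result <- function(x, ...) {
  cat(sprintf(
    "<ecs_result> ECS = %.4f (overlap %d / denominator %d, K = %d)\n",
    x$score, x$overlap, x$denominator, x$k
  ))
  invisible(x)
}

#' Per-lesion ECS (unweighted)
#'
#' Computes the ECS between the heatmap and the segmentation of a single
#' lesion type. No lesion weighting is applied: the single mask is
#' discretized by plain pixel counting. Images whose selected mask is empty
#' raise an `ecs_empty_expert` error (callers skip them, with a log record).
#'
#' @param masks A [lesion_mask_set()].
#' @param dh Discretized heatmap on `grid`.
#' @param k Number of top cells compared.
#' @param lesion One of `"he"`, `"ma"`, `"se"`, `"ex"`.
#' @param grid A [grid_spec()].
#' @return An `ecs_result`.
#' @export
ecs_per_lesion <- function(masks, dh, k, lesion = c("he", "ma", "se", "ex"),
                           grid) {
  lesion <- match.arg(lesion)
  stopifnot(inherits(masks, "lesion_mask_set"))
  m <- masks[[lesion]]
  if (sum(m) == 0L) {
    .stop_with_class(
      sprintf("mask '%s' is empty; per-lesion score undefined", toupper(lesion)),
      "ecs_empty_expert"
    )
  }
  de <- discretize_heatmap(m + 0, grid)
  de$kind <- "expert"
  ecs_score(de, dh, k)
}

#' Random-importance baseline
#'
#' Expected ECS of a heatmap that attributes importance randomly: cell values
#' are drawn iid uniform(0, 1), which induces a uniformly random cell
#' ranking. This is the chance floor every attribution method should beat.
#' Randomization happens at cell level, not pixel level: summing iid pixel
#' noise into cells would concentrate cell sums near equality and not emulate
#' random importance rankings.
#'
#' @param de Discretized expert map.
#' @param k Number of top cells compared.
#' @param n_draws Number of random heatmaps scored (default 10000).
#' @param seed Optional seed for reproducibility.
#' @return List with `mean`, `se` (standard error of the mean), `n_draws`.
#' @export
random_baseline <- function(de, k = 15L, n_draws = 10000L, seed = NULL) {
  stopifnot(inherits(de, "discretized_map"))
  if (!.is_count(n_draws)) {
    .stop_with_class("n_draws must be a positive integer", "ecs_param_error")
  }
  s <- de$grid$s
  scores <- with_seed(seed, {
    vapply(seq_len(n_draws), function(i) {
      rh <- .new_discretized_map(matrix(stats::runif(s * s), s, s),
                                 "heatmap", de$grid)
      ecs_score(de, rh, k)$score
    }, numeric(1L))
  })
  list(
    mean = mean(scores),
    se = stats::sd(scores) / sqrt(n_draws),
    n_draws = as.integer(n_draws)
  )
}
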