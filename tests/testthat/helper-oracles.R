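# Independent brute-force oracles. These deliberately avoid the package's
# vectorized code paths: block sums by explicit double loops, top-K selection
# by repeated row-major scanning.

# Block sum of pixel matrix m onto an s x s grid, trailing remainder pixels
# absorbed by the last cell row/column.
oracle_block_sum <- function(m, s) {
  dy <- nrow(m) %/% s
  dx <- ncol(m) %/% s
  out <- matrix(0, s, s)
  for (p in seq_len(nrow(m))) {
    for (q in seq_len(ncol(m))) {
      i <- min((p - 1) %/% dy + 1, s)
      j <- min((q - 1) %/% dx + 1, s)
      out[i, j] <- out[i, j] + m[p, q]
    }
  }
  out
}

# Top-k positive cells by repeated scanning: at each round pick the cell with
# the largest value, preferring the smallest row-major index among ties.
oracle_top_k <- function(cells, k) {
  remaining <- cells
  picked <- integer(0)
  nc <- ncol(cells)
  for (round in seq_len(k)) {
    best_val <- 0
    best_id <- NA_integer_
    # scanning in ascending row-major id and replacing only on strictly
    # greater value keeps the earliest id among ties
    for (i in seq_len(nrow(cells))) {
      for (j in seq_len(nc)) {
        v <- remaining[i, j]
        if (v > 0 && (is.na(best_id) || v > best_val)) {
          best_val <- v
          best_id <- (i - 1) * nc + j
        }
      }
    }
    if (is.na(best_id)) break
    picked <- c(picked, best_id)
    remaining[(best_id - 1) %/% nc + 1, (best_id - 1) %% nc + 1] <- -Inf
  }
  picked
}

# ECS by explicit sorted enumeration, from raw cell matrices.
oracle_ecs <- function(de_cells, dh_cells, k) {
  et <- oracle_top_k(de_cells, k)
  ht <- oracle_top_k(dh_cells, k)
  nnz <- sum(de_cells > 0)
  length(intersect(et, ht)) / min(k, nnz)
}

# Wrap a plain nonnegative cell matrix as a discretized map on a 1 px/cell
# grid (S = N discretization is the identity), for tests in cell space.
as_cell_map <- function(cells, kind = "expert") {
  g <- ecscore::grid_spec(dim(cells), nrow(cells))
  d <- ecscore::discretize_heatmap(cells, g)
  d$kind <- kind
  d
}

random_cells <- function(s, sparsity = 0.3, max_val = 5L) {
  m <- matrix(sample(0:max_val, s * s, replace = TRUE,
                     prob = c(sparsity, rep((1 - sparsity) / max_val, max_val))),
              s, s)
  m + 0
}
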