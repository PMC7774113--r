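test_that("top-k selection orders by value with row-major tie-break", {
  m <- matrix(c(3, 2, 1, 0), 2, 2) # row-major: [[3,1],[2,0]]
  tk <- top_k_cells(m, 2)
  expect_equal(tk, cbind(row = c(1L, 2L), col = c(1L, 1L)))

  expect_equal(nrow(top_k_cells(matrix(0, 3, 3), 5)), 0L)

  # five equal positive cells, k = 3: earliest in row-major order win
  m2 <- matrix(0, 3, 3)
  m2[1, 2] <- m2[2, 1] <- m2[2, 3] <- m2[3, 1] <- m2[3, 3] <- 4
  tk3 <- top_k_cells(m2, 3)
  expect_equal(tk3, cbind(row = c(1L, 2L, 2L), col = c(2L, 1L, 3L)))

  # fewer positive cells than k
  expect_equal(nrow(top_k_cells(m2, 10)), 5L)
  expect_error(top_k_cells(m2, 0), class = "ecs_param_error")
})

test_that("randomized tie mode is seeded and permutes only ties", {
  m <- matrix(1, 4, 4)
  a <- top_k_cells(m, 5, ties = "random", seed = 42)
  b <- top_k_cells(m, 5, ties = "random", seed = 42)
  expect_identical(a, b)
  # values distinct: tie mode irrelevant
  m2 <- matrix(1:16, 4, 4)
  expect_equal(top_k_cells(m2, 4, ties = "random", seed = 1),
               top_k_cells(m2, 4))
})

test_that("ecs_score matches the published formula on canonical cases", {
  set.seed(2)
  de_cells <- matrix(runif(25) + 0.1, 5, 5)
  de <- as_cell_map(de_cells)
  dh <- as_cell_map(de_cells, kind = "heatmap")
  expect_equal(ecs_score(de, dh, 4)$score, 1)

  # disjoint top-k sets
  a <- matrix(0, 4, 4); a[1, 1:2] <- c(5, 4)
  b <- matrix(0, 4, 4); b[4, 3:4] <- c(5, 4)
  expect_equal(ecs_score(as_cell_map(a), as_cell_map(b, "heatmap"), 2)$score, 0)

  # 11 of the top 15 expert cells found, nnz >= 15 -> 11/15
  s <- 10
  de15 <- matrix(0, s, s)
  de15[1:3, 1:7] <- matrix(100 - seq_len(21), 3, 7) # 21 positive cells
  et <- top_k_cells(de15, 15)
  hcells <- matrix(0, s, s)
  keep <- et[1:11, , drop = FALSE]
  hcells[cbind(keep[, "row"], keep[, "col"])] <- 50
  hcells[8:9, 9:10] <- 60 # 4 cells far from the expert top block
  r <- ecs_score(as_cell_map(de15), as_cell_map(hcells, "heatmap"), 15)
  expect_equal(r$overlap, 11L)
  expect_equal(r$score, 11 / 15)

  # denominator capped by nnz: 4 expert cells, k = 15
  de4 <- matrix(0, s, s)
  de4[2, 2:5] <- 7
  h4 <- de4 + matrix(runif(s * s) * 0.01, s, s)
  r4 <- ecs_score(as_cell_map(de4), as_cell_map(h4, "heatmap"), 15)
  expect_equal(r4$denominator, 4L)
  expect_equal(r4$score, 1)
})

test_that("empty expert maps raise a typed undefined-score error", {
  de0 <- as_cell_map(matrix(0, 3, 3))
  dh <- as_cell_map(matrix(1, 3, 3), "heatmap")
  expect_error(ecs_score(de0, dh, 2), class = "ecs_empty_expert")
})

test_that("ecs_score equals the brute-force enumeration oracle", {
  set.seed(77)
  for (i in 1:200) {
    s <- sample(2:5, 1)
    k <- sample(1:4, 1)
    de_cells <- random_cells(s)
    dh_cells <- random_cells(s)
    if (sum(de_cells > 0) == 0) next
    got <- ecs_score(as_cell_map(de_cells), as_cell_map(dh_cells, "heatmap"), k)
    expect_identical(got$score, oracle_ecs(de_cells, dh_cells, k))
  }
})

test_that("score is invariant under monotone rescaling of the heatmap", {
  set.seed(13)
  for (i in 1:25) {
    s <- sample(3:8, 1)
    de <- as_cell_map(random_cells(s) + 0.01)
    dh_cells <- matrix(runif(s * s), s, s)
    k <- sample(1:6, 1)
    base <- ecs_score(de, as_cell_map(dh_cells, "heatmap"), k)$score
    expect_equal(ecs_score(de, as_cell_map(3.7 * dh_cells, "heatmap"), k)$score, base)
    expect_equal(ecs_score(de, as_cell_map(dh_cells^2, "heatmap"), k)$score, base)
  }
})

test_that("swapping in one expert top cell raises the score by 1/denominator", {
  set.seed(31)
  s <- 6
  de_cells <- matrix(runif(s * s) + 0.5, s, s)
  de <- as_cell_map(de_cells)
  k <- 5
  et_ids <- (top_k_cells(de, k)[, "row"] - 1) * s + top_k_cells(de, k)[, "col"]
  # heatmap top-k: 2 expert cells + 3 elsewhere
  dh_cells <- matrix(0, s, s)
  ids_all <- seq_len(s * s)
  outside <- setdiff(ids_all, et_ids)
  pick <- c(et_ids[1:2], outside[1:3])
  dh_cells[cbind((pick - 1) %/% s + 1, (pick - 1) %% s + 1)] <- 10:6
  before <- ecs_score(de, as_cell_map(dh_cells, "heatmap"), k)
  # swap one non-overlapping heatmap top cell for an expert top cell
  dh_swapped <- dh_cells
  drop_id <- pick[5]
  dh_swapped[(drop_id - 1) %/% s + 1, (drop_id - 1) %% s + 1] <- 0
  add_id <- et_ids[3]
  dh_swapped[(add_id - 1) %/% s + 1, (add_id - 1) %% s + 1] <- 6
  after <- ecs_score(de, as_cell_map(dh_swapped, "heatmap"), k)
  expect_equal(after$score - before$score, 1 / before$denominator)
})

test_that("per-lesion score equals ecs_score on the single unweighted mask", {
  set.seed(17)
  n <- 40
  g <- grid_spec(n, 10)
  params <- fixture_params(image_size = n, he_n = 2, ex_n = 2, se_n = 1,
                           ma_n = 2)
  masks <- generate_mask_set(params, seed = 4)
  dh <- discretize_heatmap(matrix(runif(n * n), n, n), g)
  for (t in c("he", "ma", "se", "ex")) {
    if (sum(masks[[t]]) == 0) next
    got <- ecs_per_lesion(masks, dh, 15, lesion = t, grid = g)
    de1 <- discretize_heatmap(masks[[t]] + 0, g)
    de1$kind <- "expert"
    expect_equal(got$score, ecs_score(de1, dh, 15)$score)
  }

  # heatmap built from the MA mask alone gives MA-ECS 1
  ma_h <- masks$ma + 0
  got <- ecs_per_lesion(masks, discretize_heatmap(ma_h, g), 15, "ma", g)
  expect_equal(got$score, 1)

  empty <- lesion_mask_set(matrix(0L, n, n), matrix(0L, n, n),
                           matrix(0L, n, n), matrix(0L, n, n))
  expect_error(ecs_per_lesion(empty, dh, 15, "se", g),
               class = "ecs_empty_expert")
})

test_that("random baseline is seeded and matches forced-overlap cases", {
  s <- 4
  # expert positive on all 16 cells and k = 16: every draw overlaps fully
  de_full <- as_cell_map(matrix(1:16 + 0, s, s))
  rb <- random_baseline(de_full, k = 16, n_draws = 50, seed = 1)
  expect_equal(rb$mean, 1)
  expect_equal(rb$se, 0)

  de <- as_cell_map(matrix(runif(16), 4, 4))
  a <- random_baseline(de, k = 3, n_draws = 200, seed = 99)
  b <- random_baseline(de, k = 3, n_draws = 200, seed = 99)
  expect_identical(a, b)
})
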