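#' Grouped mean ECS
#'
#' Arithmetic mean of per-image scores within groups of a score table (for
#' instance per model x heatmapping-method combination).
#'
#' @param table Data frame with a numeric `score` column in `[0, 1]` and the
#'   grouping columns.
#' @param group_keys Character vector of column names to group by; `NULL`
#'   returns the overall mean.
#' @return Data frame with the group columns, `mean_score` and `n`.
#' @export
mean_ecs <- function(table, group_keys = c("model", "method")) {
  if (!is.data.frame(table) || nrow(table) == 0L) {
    .stop_with_class("table must be a nonempty data frame", "ecs_param_error")
  }
  stopifnot("score" %in% names(table))
  if (is.null(group_keys) || length(group_keys) == 0L) {
    return(data.frame(mean_score = mean(table$score), n = nrow(table)))
  }
  missing_keys <- setdiff(group_keys, names(table))
  if (length(missing_keys)) {
    .stop_with_class(
      paste0("grouping column(s) not in table: ",
             paste(missing_keys, collapse = ", ")),
      "ecs_param_error"
    )
  }
  agg <- stats::aggregate(
    table$score, by = table[group_keys], FUN = mean, drop = TRUE
  )
  names(agg)[ncol(agg)] <- "mean_score"
  cnt <- stats::aggregate(
    table$score, by = table[group_keys], FUN = length, drop = TRUE
  )
  agg$n <- cnt$x
  agg[do.call(order, unname(agg[group_keys])), , drop = FALSE]
}

#' Percentile-bootstrap confidence interval for a mean score
#'
#' Nonparametric percentile bootstrap over images: resamples the per-image
#' scores with replacement `n_boot` times, takes the mean of each resample,
#' and reports the `(1 - level)/2` and `1 - (1 - level)/2` quantiles.
#'
#' @param scores Numeric vector of per-image scores, length >= 2.
#' @param level Confidence level (default 0.95).
#' @param n_boot Number of bootstrap resamples (default 10000).
#' @param seed Optional seed.
#' @return Named numeric vector `c(low, high)`.
#' @export
bootstrap_ci <- function(scores, level = 0.95, n_boot = 10000L, seed = NULL) {
  if (!is.numeric(scores) || length(scores) < 2L) {
    .stop_with_class("need at least 2 scores for a confidence interval",
                     "ecs_param_error")
  }
  stopifnot(level > 0, level < 1, .is_count(n_boot))
  n <- length(scores)
  boot_means <- with_seed(seed, {
    idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n_boot)
    rowMeans(matrix(scores[idx], nrow = n_boot))
  })
  alpha <- (1 - level) / 2
  q <- stats::quantile(boot_means, c(alpha, 1 - alpha), names = FALSE)
  c(low = q[1L], high = q[2L])
}

#' Stratify scores by severity grade
#'
#' Per-grade mean ECS with bootstrap confidence intervals. Strata with a
#' single image report the mean only; their CI is marked unavailable (`NA`),
#' since a one-image stratum carries no resampling information.
#'
#' @param table Data frame with `score` and `grade` columns.
#' @param level,n_boot,seed Passed to [bootstrap_ci()].
#' @return Data frame with `grade`, `n`, `mean_score`, `ci_low`, `ci_high`.
#' @export
stratify_by_grade <- function(table, level = 0.95, n_boot = 10000L,
                              seed = NULL) {
  if (!is.data.frame(table) || !all(c("score", "grade") %in% names(table))) {
    .stop_with_class("table must have 'score' and 'grade' columns",
                     "ecs_param_error")
  }
  tab <- table[!is.na(table$grade), , drop = FALSE]
  grades <- sort(unique(tab$grade))
  out <- lapply(grades, function(g) {
    sc <- tab$score[tab$grade == g]
    ci <- if (length(sc) >= 2L) {
      bootstrap_ci(sc, level = level, n_boot = n_boot, seed = seed)
    } else {
      c(low = NA_real_, high = NA_real_)
    }
    data.frame(
      grade = g, n = length(sc), mean_score = mean(sc),
      ci_low = ci[["low"]], ci_high = ci[["high"]]
    )
  })
  do.call(rbind, out)
}

#' Grid-size / K sensitivity sweep
#'
#' Recomputes the ECS for every image and every combination of grid size `S`
#' and top-cell count `K`, so that the stability of method rankings under
#' these tuning parameters can be inspected. Images whose expert annotation
#' is empty are skipped with a warning and recorded in the `skipped`
#' attribute.
#'
#' @param dataset List of entries, each a list with `image_id`, `masks` (a
#'   [lesion_mask_set()]), `heatmap` (nonnegative matrix), and optional
#'   `model` / `method` tags.
#' @param s_values Integer vector of grid sizes.
#' @param k_values Integer vector of K values.
#' @param weights A [weight_set()] (default the published preset).
#' @return Data frame (score table) with columns `image_id`, `model`,
#'   `method`, `s`, `k`, `score`, `grade`; skipped images in
#'   `attr(, "skipped")`.
#' @export
sensitivity_sweep <- function(dataset, s_values = c(10L), k_values = c(10L, 15L, 20L),
                              weights = lesion_weights_preset("idrid-paper")) {
  stopifnot(is.list(dataset), length(dataset) >= 1L)
  if (any(s_values < 1L) || any(k_values < 1L)) {
    .stop_with_class("s_values and k_values must be >= 1", "ecs_param_error")
  }
  rows <- list()
  skipped <- character(0L)
  for (s in s_values) {
    for (entry in dataset) {
      g <- grid_spec(dim(entry$heatmap), s)
      de <- discretize_expert(entry$masks, weights, g)
      if (sum(de$cells > 0) == 0L) {
        warning(sprintf("image '%s' skipped: empty expert annotation",
                        entry$image_id), call. = FALSE)
        skipped <- c(skipped, entry$image_id)
        next
      }
      dh <- discretize_heatmap(entry$heatmap, g)
      for (k in k_values) {
        res <- ecs_score(de, dh, k)
        rows[[length(rows) + 1L]] <- data.frame(
          image_id = entry$image_id,
          model = if (is.null(entry$model)) "model" else entry$model,
          method = if (is.null(entry$method)) "method" else entry$method,
          s = as.integer(s), k = as.integer(k), score = res$score,
          grade = if (is.null(entry$masks$grade)) NA_integer_ else entry$masks$grade
        )
      }
    }
  }
  if (length(rows) == 0L) {
    .stop_with_class("no scorable images in dataset", "ecs_param_error")
  }
  out <- do.call(rbind, rows)
  attr(out, "skipped") <- unique(skipped)
  out
}

#' Method ranking per (S, K) combination
#'
#' Orders the (model, method) combinations by mean score within each grid
#' size / K combination of a score table.
#'
#' @param table Score table as produced by [sensitivity_sweep()] or
#'   [run_evaluate()].
#' @return Data frame with `s`, `k`, `model`, `method`, `mean_score`, `rank`
#'   (1 = highest mean score).
#' @export
method_ranking <- function(table) {
  m <- mean_ecs(table, group_keys = c("s", "k", "model", "method"))
  parts <- split(m, interaction(m$s, m$k, drop = TRUE))
  out <- lapply(parts, function(p) {
    p <- p[order(-p$mean_score, p$model, p$method), , drop = FALSE]
    p$rank <- seq_len(nrow(p))
    p
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$s, res$k, res$rank), , drop = FALSE]
}
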