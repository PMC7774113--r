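#' Evaluation configuration
#'
#' Bundles the tuning parameters of an ECS evaluation run: grid size `S`
#' (default 10), top-cell count `K` (default 15, with a conventional sweep
#' over 10/15/20), the lesion weights, channel-reduction mode, bootstrap
#' settings and seed. Serializable to/from JSON.
#'
#' @param s Grid size.
#' @param k Top-cell count.
#' @param k_sweep K values for sensitivity sweeps.
#' @param weights A [weight_set()] or a preset name for
#'   [lesion_weights_preset()].
#' @param channel_mode Passed to [reduce_channels()].
#' @param level Confidence level for intervals.
#' @param n_boot Bootstrap resamples.
#' @param seed Seed for bootstrap and any randomized step.
#' @return An object of class `ecs_config`.
#' @export
ecs_config <- function(s = 10L, k = 15L, k_sweep = c(10L, 15L, 20L),
                       weights = "idrid-paper",
                       channel_mode = c("abs-max", "max"),
                       level = 0.95, n_boot = 10000L, seed = 1L) {
  channel_mode <- match.arg(channel_mode)
  if (is.character(weights)) weights <- lesion_weights_preset(weights)
  stopifnot(inherits(weights, "weight_set"))
  structure(
    list(
      s = as.integer(s), k = as.integer(k), k_sweep = as.integer(k_sweep),
      weights = weights, channel_mode = channel_mode,
      level = level, n_boot = as.integer(n_boot), seed = as.integer(seed)
    ),
    class = "ecs_config"
  )
}

#' @rdname ecs_config
#' @param path JSON file path.
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  w <- if (is.character(x$weights)) {
    x$weights
  } else {
    weight_set(w_he = x$weights$w_he, w_ma = x$weights$w_ma,
               w_se = x$weights$w_se, w_ex = x$weights$w_ex)
  }
  ecs_config(
    s = x$s %||% 10L, k = x$k %||% 15L,
    k_sweep = x$k_sweep %||% c(10L, 15L, 20L),
    weights = w %||% "idrid-paper",
    channel_mode = x$channel_mode %||% "abs-max",
    level = x$level %||% 0.95, n_boot = x$n_boot %||% 10000L,
    seed = x$seed %||% 1L
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Prepare a single-channel nonnegative heatmap from whatever was on disk.
.prepare_heatmap <- function(raw, channel_mode) {
  if (length(dim(raw)) == 3L) {
    raw <- reduce_channels(raw, mode = channel_mode)
  }
  if (any(raw < 0)) {
    # single-channel signed map (raw gradients): magnitude carries importance
    raw <- abs(raw)
  }
  raw
}

#' Evaluate a dataset manifest
#'
#' The main evaluation loop: for every manifest row, reads the four lesion
#' masks and the heatmap, discretizes both (expert side weighted), and
#' computes the ECS at the configured `S` and `K`. Produces per-image scores
#' plus the aggregate tables used for reporting: mean with bootstrap CI per
#' (model, method), per-lesion means (unweighted single-lesion ECS), and
#' per-grade strata. Images with an empty expert annotation are skipped with
#' a warning and listed in the result; a missing heatmap file is reported
#' the same way, not fatal.
#'
#' @param manifest Path to a manifest CSV or a data frame from
#'   [read_manifest()].
#' @param config An [ecs_config()].
#' @param verbose Emit per-skip messages.
#' @return List of class `ecs_evaluation` with elements `scores` (score
#'   table), `summary` (per model/method mean, CI, n), `per_lesion`,
#'   `per_grade`, `skipped`.
#' @export
run_evaluate <- function(manifest, config = ecs_config(), verbose = FALSE) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  stopifnot(is.data.frame(manifest), inherits(config, "ecs_config"))
  if (nrow(manifest) == 0L) {
    .stop_with_class("manifest is empty", "ecs_io_error")
  }
  rows <- list()
  lesion_rows <- list()
  skipped <- data.frame(image_id = character(0L), reason = character(0L))
  for (r in seq_len(nrow(manifest))) {
    mrow <- manifest[r, ]
    h <- tryCatch(read_heatmap(mrow$heatmap), error = function(e) e)
    if (inherits(h, "error")) {
      if (verbose) message(sprintf("skip %s: %s", mrow$image_id, conditionMessage(h)))
      skipped <- rbind(skipped, data.frame(
        image_id = mrow$image_id, reason = "missing or unreadable heatmap"
      ))
      next
    }
    masks <- lesion_mask_set(
      he = read_mask(mrow$he), ma = read_mask(mrow$ma),
      se = read_mask(mrow$se), ex = read_mask(mrow$ex),
      grade = if (is.na(mrow$grade)) NULL else mrow$grade
    )
    grid <- grid_spec(dim(masks$he), config$s)
    h <- .prepare_heatmap(h, config$channel_mode)
    de <- discretize_expert(masks, config$weights, grid)
    if (sum(de$cells > 0) == 0L) {
      warning(sprintf("image '%s' skipped: empty expert annotation",
                      mrow$image_id), call. = FALSE)
      skipped <- rbind(skipped, data.frame(
        image_id = mrow$image_id, reason = "empty expert annotation"
      ))
      next
    }
    dh <- discretize_heatmap(h, grid)
    res <- ecs_score(de, dh, config$k)
    rows[[length(rows) + 1L]] <- data.frame(
      image_id = mrow$image_id, model = mrow$model, method = mrow$method,
      s = config$s, k = config$k, score = res$score,
      overlap = res$overlap, denominator = res$denominator,
      grade = if (is.na(mrow$grade)) NA_integer_ else as.integer(mrow$grade)
    )
    for (t in .lesion_types) {
      pl <- tryCatch(
        ecs_per_lesion(masks, dh, config$k, lesion = t, grid = grid),
        ecs_empty_expert = function(e) NULL
      )
      if (is.null(pl)) {
        if (verbose) message(sprintf("image '%s': no %s annotation, lesion skipped",
                                     mrow$image_id, toupper(t)))
        next
      }
      lesion_rows[[length(lesion_rows) + 1L]] <- data.frame(
        image_id = mrow$image_id, model = mrow$model, method = mrow$method,
        lesion = toupper(t), score = pl$score
      )
    }
  }
  if (length(rows) == 0L) {
    .stop_with_class("no scorable images in manifest", "ecs_io_error")
  }
  scores <- do.call(rbind, rows)
  summary <- mean_ecs(scores, group_keys = c("model", "method"))
  cis <- t(vapply(seq_len(nrow(summary)), function(i) {
    sel <- scores$model == summary$model[i] & scores$method == summary$method[i]
    sc <- scores$score[sel]
    if (length(sc) >= 2L) {
      bootstrap_ci(sc, level = config$level, n_boot = config$n_boot,
                   seed = config$seed)
    } else {
      c(low = NA_real_, high = NA_real_)
    }
  }, numeric(2L)))
  summary$ci_low <- cis[, 1L]
  summary$ci_high <- cis[, 2L]
  per_lesion <- if (length(lesion_rows)) {
    mean_ecs(do.call(rbind, lesion_rows),
             group_keys = c("model", "method", "lesion"))
  } else {
    NULL
  }
  per_grade <- if (!all(is.na(scores$grade))) {
    stratify_by_grade(scores, level = config$level, n_boot = config$n_boot,
                      seed = config$seed)
  } else {
    NULL
  }
  structure(
    list(scores = scores, summary = summary, per_lesion = per_lesion,
         per_grade = per_grade, skipped = skipped, config = config),
    class = "ecs_evaluation"
  )
}

#' @export
print.ecs_evaluation <- function(x, ...) {
  cat(sprintf("<ecs_evaluation> %d scored image-method rows, %d skipped (S=%d, K=%d)\n",
              nrow(x$scores), nrow(x$skipped), x$config$s, x$config$k))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Write evaluation reports to disk
#'
#' Writes `scores.csv` (per-image rows), `summary.csv`, and when available
#' `per_lesion.csv` / `per_grade.csv`, plus a `report.json` combining all
#' tables. Output is deterministic for a fixed config seed; no timestamps.
#'
#' @param evaluation An `ecs_evaluation` from [run_evaluate()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_evaluation <- function(evaluation, dir) {
  stopifnot(inherits(evaluation, "ecs_evaluation"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(evaluation$scores, file.path(dir, "scores.csv"),
                   row.names = FALSE)
  utils::write.csv(evaluation$summary, file.path(dir, "summary.csv"),
                   row.names = FALSE)
  if (!is.null(evaluation$per_lesion)) {
    utils::write.csv(evaluation$per_lesion, file.path(dir, "per_lesion.csv"),
                     row.names = FALSE)
  }
  if (!is.null(evaluation$per_grade)) {
    utils::write.csv(evaluation$per_grade, file.path(dir, "per_grade.csv"),
                     row.names = FALSE)
  }
  jsonlite::write_json(
    list(
      summary = evaluation$summary, per_lesion = evaluation$per_lesion,
      per_grade = evaluation$per_grade, skipped = evaluation$skipped
    ),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows"
  )
  invisible(dir)
}
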