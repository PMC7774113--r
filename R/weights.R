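#' Lesion-type weight set
#'
#' Weights applied to lesion pixel counts when discretizing the expert
#' segmentation. By construction (see [derive_weights()]) the most frequent
#' lesion type has weight 1 and all weights are >= 1.
#'
#' @param w_he,w_ma,w_se,w_ex Strictly positive weights for hemorrhages,
#'   microaneurysms, soft exudates and hard exudates.
#' @return An object of class `weight_set`.
#' @seealso [derive_weights()], [lesion_weights_preset()]
#' @export
weight_set <- function(w_he, w_ma, w_se, w_ex) {
  w <- c(w_he = w_he, w_ma = w_ma, w_se = w_se, w_ex = w_ex)
  if (!all(is.finite(w)) || any(w <= 0)) {
    .stop_with_class("all weights must be strictly positive and finite",
                     "ecs_param_error")
  }
  structure(as.list(w), class = "weight_set")
}

#' @export
print.weight_set <- function(x, ...) {
  cat(sprintf(
    "<weight_set> w_HE=%.4g  w_MA=%.4g  w_SE=%.4g  w_EX=%.4g\n",
    x$w_he, x$w_ma, x$w_se, x$w_ex
  ))
  invisible(x)
}

#' Derive lesion weights from corpus pixel counts
#'
#' Implements the inverse-frequency rule: each lesion type's weight is the
#' pixel count of the most frequent lesion type divided by that type's own
#' pixel count, `w_t = max_count / count_t`. The most frequent type gets
#' weight 1; rarer types get proportionally larger weights.
#'
#' A lesion type with zero pixels in the corpus has no defined weight; the
#' function stops with guidance rather than producing an infinite weight.
#'
#' @param pixel_counts Named numeric vector or list with entries `he`, `ma`,
#'   `se`, `ex`: total lesion pixel counts over the corpus.
#' @return A [weight_set()].
#' @examples
#' derive_weights(c(he = 4700, ma = 100, se = 800, ex = 4400))
#' @export
derive_weights <- function(pixel_counts) {
  pc <- unlist(pixel_counts)[.lesion_types]
  if (anyNA(pc)) {
    .stop_with_class(
      "pixel_counts must contain entries named he, ma, se, ex",
      "ecs_param_error"
    )
  }
  if (any(pc < 0) || !any(pc > 0)) {
    .stop_with_class("pixel counts must be nonnegative with at least one > 0",
                     "ecs_param_error")
  }
  if (any(pc == 0)) {
    .stop_with_class(
      paste0(
        "lesion type(s) with zero corpus pixels: ",
        paste(toupper(.lesion_types[pc == 0]), collapse = ", "),
        ". Inverse-frequency weight is undefined; exclude the type or ",
        "supply a preset via lesion_weights_preset()."
      ),
      "ecs_zero_count_error"
    )
  }
  mx <- max(pc)
  weight_set(
    w_he = mx / pc[["he"]], w_ma = mx / pc[["ma"]],
    w_se = mx / pc[["se"]], w_ex = mx / pc[["ex"]]
  )
}

#' Published lesion-weight presets
#'
#' `"idrid-paper"` returns the constants published for the IDRiD expert
#' segmentations: `w_HE = 1, w_EX = 1.05, w_SE = 5.77, w_MA = 46.97`. These
#' are stored verbatim; they are close to, but not exactly, the ratios of the
#' rounded corpus percentages (47/44/8/1), so the preset and
#' [derive_weights()] are never mixed silently.
#'
#' `"uniform"` returns all-ones weights (raw pixel counts, no rebalancing).
#'
#' @param name Preset name.
#' @return A [weight_set()].
#' @export
lesion_weights_preset <- function(name = c("idrid-paper", "uniform")) {
  name <- match.arg(name)
  switch(name,
    "idrid-paper" = weight_set(w_he = 1, w_ma = 46.97, w_se = 5.77, w_ex = 1.05),
    "uniform" = weight_set(w_he = 1, w_ma = 1, w_se = 1, w_ex = 1)
  )
}

#' Count lesion pixels over a corpus of mask sets
#'
#' @param mask_sets A list of [lesion_mask_set()] objects.
#' @return Named numeric vector with per-type pixel totals (`he`, `ma`,
#'   `se`, `ex`).
#' @export
count_lesion_pixels <- function(mask_sets) {
  if (!is.list(mask_sets) || length(mask_sets) == 0L) {
    .stop_with_class("mask_sets must be a nonempty list", "ecs_param_error")
  }
  stopifnot(all(vapply(mask_sets, inherits, logical(1L), "lesion_mask_set")))
  counts <- vapply(
    .lesion_types,
    function(t) sum(vapply(mask_sets, function(m) sum(m[[t]]), numeric(1L))),
    numeric(1L)
  )
  counts
}

#' Write / read a weight set as JSON
#'
#' @param w A [weight_set()].
#' @param path File path.
#' @return `read_weights` returns a [weight_set()]; `write_weights` returns
#'   `path` invisibly.
#' @export
write_weights <- function(w, path) {
  stopifnot(inherits(w, "weight_set"))
  jsonlite::write_json(unclass(w), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_weights
#' @export
read_weights <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  weight_set(w_he = x$w_he, w_ma = x$w_ma, w_se = x$w_se, w_ex = x$w_ex)
}
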