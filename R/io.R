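.file_ext <- function(path) tolower(tools::file_ext(path))

.read_image_array <- function(path) {
  if (!file.exists(path)) {
    .stop_with_class(sprintf("file not found: %s", path), "ecs_io_error")
  }
  ext <- .file_ext(path)
  img <- switch(ext,
    "png" = png::readPNG(path),
    "tif" = ,
    "tiff" = {
      x <- tiff::readTIFF(path, info = TRUE)
      bps <- attr(x, "bits.per.sample")
      # 8/16-bit integer images: return raw integer sample values;
      # 32-bit images: keep the [0,1] decoded scale
      if (!is.null(bps) && bps <= 16L) {
        x <- tiff::readTIFF(path, as.is = TRUE)
      }
      attributes(x)[setdiff(names(attributes(x)), "dim")] <- NULL
      x
    },
    .stop_with_class(
      sprintf("unsupported image format '.%s' for %s", ext, path),
      "ecs_io_error"
    )
  )
  if (length(img) == 0L) {
    .stop_with_class(sprintf("empty image file: %s", path), "ecs_io_error")
  }
  img
}

#' Read a binary lesion mask from an image file
#'
#' Any nonzero pixel is treated as lesion. Grayscale, paletted and RGB(A)
#' inputs are accepted; multi-channel images are collapsed with "any channel
#' nonzero".
#'
#' @param path PNG or TIFF file.
#' @return Integer 0/1 matrix.
#' @export
read_mask <- function(path) {
  img <- .read_image_array(path)
  if (length(dim(img)) == 3L) {
    img <- apply(img != 0, c(1L, 2L), any)
  }
  out <- (img != 0) + 0L
  storage.mode(out) <- "integer"
  out
}

#' Write a binary mask as a PNG file
#'
#' @param mask 0/1 matrix.
#' @param path Output path (`.png`).
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(is.matrix(mask), all(mask %in% c(0, 1)))
  png::writePNG(mask + 0, path)
  invisible(path)
}

#' Read a heatmap (raw importance values)
#'
#' Supported formats: float or integer TIFF (single- or three-channel), PNG,
#' and plain-text matrices (`.csv` / `.tsv` / `.txt`, no header). Channel
#' count is preserved so that three-channel maps can be reduced with
#' [reduce_channels()]; PNG alpha channels are dropped. More than three
#' colour channels is a format error.
#'
#' @param path Input file.
#' @return Numeric matrix (single channel) or `nrow x ncol x 3` array.
#' @export
read_heatmap <- function(path) {
  ext <- .file_ext(path)
  if (ext %in% c("csv", "tsv", "txt")) {
    if (!file.exists(path)) {
      .stop_with_class(sprintf("file not found: %s", path), "ecs_io_error")
    }
    sep <- if (ext == "csv") "," else "\t"
    m <- as.matrix(utils::read.table(path, sep = sep, header = FALSE))
    dimnames(m) <- NULL
    storage.mode(m) <- "double"
    return(m)
  }
  img <- .read_image_array(path)
  if (length(dim(img)) == 3L) {
    nchan <- dim(img)[3L]
    if (nchan == 4L && ext == "png") {
      img <- img[, , 1:3, drop = FALSE] # drop alpha
    } else if (nchan > 3L) {
      .stop_with_class(
        sprintf("heatmap has %d channels (max 3): %s", nchan, path),
        "ecs_io_error"
      )
    } else if (nchan == 1L) {
      img <- img[, , 1L]
    }
  }
  storage.mode(img) <- "double"
  img
}

#' Write a heatmap
#'
#' Plain-text matrices (`.tsv`/`.csv`/`.txt`) are written at 17 significant
#' digits, which round-trips IEEE doubles exactly. TIFF output
#' (`.tif`/`.tiff`, 32-bit) requires values in `[0, 1]`; since the ECS is
#' invariant to positive rescaling, rescale before writing if needed.
#'
#' @param h Numeric matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_heatmap <- function(h, path) {
  stopifnot(is.matrix(h), all(is.finite(h)))
  ext <- .file_ext(path)
  if (ext %in% c("tif", "tiff")) {
    if (min(h) < 0 || max(h) > 1) {
      .stop_with_class(
        "TIFF output requires values in [0, 1]; rescale the heatmap or use .tsv",
        "ecs_io_error"
      )
    }
    tiff::writeTIFF(h, path, bits.per.sample = 32L, reduce = FALSE)
  } else if (ext %in% c("csv", "tsv", "txt")) {
    sep <- if (ext == "csv") "," else "\t"
    txt <- formatC(h, digits = 17L, format = "g")
    utils::write.table(txt, path, sep = sep, row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
  } else {
    .stop_with_class(sprintf("unsupported heatmap format '.%s'", ext),
                     "ecs_io_error")
  }
  invisible(path)
}

#' Read a dataset manifest
#'
#' A manifest is a CSV with one row per (image, model, method) combination
#' and columns `image_id`, `he`, `ma`, `se`, `ex` (mask paths), `heatmap`
#' (heatmap path), optional `model`, `method`, `grade`, `split`. Relative
#' paths are resolved against the manifest's directory. Referenced files
#' must exist; image/model/method combinations must be unique.
#'
#' @param path Manifest CSV path.
#' @return Data frame with resolved paths.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) {
    .stop_with_class(sprintf("manifest not found: %s", path), "ecs_io_error")
  }
  mf <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("image_id", "he", "ma", "se", "ex", "heatmap")
  missing_cols <- setdiff(required, names(mf))
  if (length(missing_cols)) {
    .stop_with_class(
      paste0("manifest missing column(s): ",
             paste(missing_cols, collapse = ", ")),
      "ecs_io_error"
    )
  }
  if (nrow(mf) == 0L) {
    .stop_with_class("manifest is empty", "ecs_io_error")
  }
  if (!"model" %in% names(mf)) mf$model <- "model"
  if (!"method" %in% names(mf)) mf$method <- "method"
  if (!"grade" %in% names(mf)) mf$grade <- NA_integer_
  key <- paste(mf$image_id, mf$model, mf$method)
  if (anyDuplicated(key)) {
    .stop_with_class("duplicate (image_id, model, method) rows in manifest",
                     "ecs_io_error")
  }
  base <- dirname(normalizePath(path))
  for (col in c("he", "ma", "se", "ex", "heatmap")) {
    rel <- !grepl("^(/|[A-Za-z]:)", mf[[col]])
    mf[[col]][rel] <- file.path(base, mf[[col]][rel])
    gone <- !file.exists(mf[[col]])
    if (any(gone)) {
      .stop_with_class(
        sprintf("manifest references missing file(s), e.g. %s",
                mf[[col]][gone][1L]),
        "ecs_io_error"
      )
    }
  }
  mf
}

#' Write a synthetic fixture dataset to disk
#'
#' Materializes a corpus from the synthetic generator in the on-disk layout
#' the evaluator consumes: per-image binary mask PNGs (one per lesion type),
#' one plain-text heatmap per image, and a `manifest.csv` with grades and
#' generator parameters. Heatmaps are built with
#' [generate_heatmap_with_overlap()] at overlap fraction `q`.
#'
#' @param dir Output directory (created if needed).
#' @param n_images Number of images.
#' @param params A [fixture_params()].
#' @param grid_size Grid size S used for the overlap construction.
#' @param k Top-cell count for the overlap construction.
#' @param q Target overlap fraction.
#' @param weights A [weight_set()].
#' @param seed Seed; image `i` uses `seed + i`.
#' @param method Method tag recorded in the manifest.
#' @return Path of the written manifest, invisibly.
#' @export
write_fixture_dataset <- function(dir, n_images = 10L,
                                  params = fixture_params(),
                                  grid_size = 10L, k = 15L, q = 0.6,
                                  weights = lesion_weights_preset("idrid-paper"),
                                  seed = 1L, method = "synthetic") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  grid <- grid_spec(params$image_size, grid_size)
  rows <- vector("list", n_images)
  for (i in seq_len(n_images)) {
    id <- sprintf("img%03d", i)
    masks <- generate_mask_set(params, seed = seed + i)
    h <- generate_heatmap_with_overlap(masks, grid, k = k, q = q,
                                       weights = weights, seed = seed + i)
    paths <- vapply(.lesion_types, function(t) {
      p <- file.path(dir, sprintf("%s_%s.png", id, toupper(t)))
      write_mask(masks[[t]], p)
      basename(p)
    }, character(1L))
    hp <- file.path(dir, sprintf("%s_heatmap.tsv", id))
    write_heatmap(h, hp)
    rows[[i]] <- data.frame(
      image_id = id, he = paths[["he"]], ma = paths[["ma"]],
      se = paths[["se"]], ex = paths[["ex"]], heatmap = basename(hp),
      model = "synthetic", method = method, grade = masks$grade,
      split = if (i <= ceiling(2 * n_images / 3)) "tuning" else "test"
    )
  }
  manifest <- do.call(rbind, rows)
  mp <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mp, row.names = FALSE)
  jsonlite::write_json(
    list(n_images = n_images, grid_size = grid_size, k = k, q = q,
         image_size = params$image_size, seed = seed),
    file.path(dir, "generator.json"), auto_unbox = TRUE
  )
  invisible(mp)
}
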