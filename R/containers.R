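#' @importFrom stats approx coef kmeans lm median predict quantile rnorm runif sd
#' @importFrom utils head tail write.csv read.csv
NULL

# Shared coordinate convention: pixel grids are numeric matrices indexed
# [row, col], 1-based, row index increasing downward (towards the deep
# aponeurosis). Curves are stored per-column as row positions.

#' Grayscale ultrasound image
#'
#' A minimal container for a 2-D grayscale pixel grid with physical pixel
#' spacing and a muscle tag. Pixels are stored as a numeric matrix in
#' `[0, 255]`, row index increasing downward.
#'
#' @param pixels numeric matrix (rows x cols), values in `[0, 255]`.
#' @param spacing_mm isotropic pixel spacing in mm/px, or `NA` if unknown.
#' @param muscle one of `"BB"`, `"GCM"`, `"TA"`, or `NA`.
#' @return an object of class `us_image`.
#' @export
us_image <- function(pixels, spacing_mm = NA_real_, muscle = NA_character_) {
  stopifnot(is.matrix(pixels))
  if (length(spacing_mm) > 1L)
    stop("anisotropic pixel spacing is not supported; supply a single mm/px value")
  if (!is.na(muscle)) muscle <- match.arg(muscle, c("BB", "GCM", "TA"))
  structure(list(pixels = pixels, spacing_mm = spacing_mm, muscle = muscle),
            class = "us_image")
}

#' @export
print.us_image <- function(x, ...) {
  cat(sprintf("<us_image> %d x %d px, spacing %s mm/px, muscle %s\n",
              nrow(x$pixels), ncol(x$pixels),
              format(x$spacing_mm), ifelse(is.na(x$muscle), "?", x$muscle)))
  invisible(x)
}

#' Integer label mask
#'
#' Integer-valued matrix aligned to a [us_image]: 0 background, 1 aponeurosis,
#' 2 central fascia (tibialis anterior only).
#'
#' @param labels integer matrix.
#' @return an object of class `label_mask`.
#' @export
label_mask <- function(labels) {
  stopifnot(is.matrix(labels))
  storage.mode(labels) <- "integer"
  if (any(labels < 0L, na.rm = TRUE)) stop("labels must be non-negative")
  structure(list(labels = labels), class = "label_mask")
}

#' @export
print.label_mask <- function(x, ...) {
  tab <- table(x$labels)
  cat(sprintf("<label_mask> %d x %d px, labels: %s\n",
              nrow(x$labels), ncol(x$labels),
              paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = " ")))
  invisible(x)
}

as_binary <- function(mask, label = 1L) {
  m <- if (inherits(mask, "label_mask")) mask$labels else mask
  m == label
}

#' Superficial/deep aponeurosis pair
#'
#' Per-column row positions of the two aponeurosis curves. Each curve is a
#' numeric vector of length `width`, `NA` where the curve is absent; the
#' superficial curve lies strictly above (smaller row than) the deep curve at
#' every shared column.
#'
#' @param superficial,deep numeric vectors of per-column rows (length = width).
#' @param width,height dimensions of the source image.
#' @param fascia optional central-fascia curve (tibialis anterior).
#' @param flags character vector of processing flags.
#' @return an object of class `apo_pair`.
#' @export
apo_pair <- function(superficial, deep, width, height, fascia = NULL,
                     flags = character()) {
  stopifnot(length(superficial) == width, length(deep) == width)
  shared <- which(!is.na(superficial) & !is.na(deep))
  if (length(shared) && any(superficial[shared] >= deep[shared]))
    stop("aponeurosis geometry error: superficial curve must lie strictly above the deep curve")
  structure(list(superficial = superficial, deep = deep, width = width,
                 height = height, fascia = fascia, flags = flags),
            class = "apo_pair")
}

#' @export
print.apo_pair <- function(x, ...) {
  sh <- which(!is.na(x$superficial) & !is.na(x$deep))
  cat(sprintf("<apo_pair> image %d x %d, shared columns %d-%d (%d), flags: %s\n",
              x$height, x$width,
              if (length(sh)) min(sh) else NA, if (length(sh)) max(sh) else NA,
              length(sh),
              if (length(x$flags)) paste(x$flags, collapse = ",") else "none"))
  invisible(x)
}

shared_columns <- function(pair) {
  which(!is.na(pair$superficial) & !is.na(pair$deep))
}

#' Read a grayscale image from PNG or TIFF
#'
#' @param path file path (`.png`, `.tif`/`.tiff`).
#' @param spacing_mm pixel spacing in mm/px; required for physical-unit
#'   measurements downstream.
#' @param muscle optional muscle tag.
#' @return a [us_image].
#' @export
read_us_image <- function(path, spacing_mm = NA_real_, muscle = NA_character_) {
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("package 'tiff' is required to read TIFF images")
      tiff::readTIFF(path)
    },
    stop("unsupported image format: ", ext))
  if (length(dim(arr)) == 3L) arr <- arr[, , 1L]  # take first channel
  us_image(round(arr * 255), spacing_mm = spacing_mm, muscle = muscle)
}

#' Write a grayscale image or mask to PNG
#'
#' Images are written as 8-bit grayscale; masks keep their integer labels as
#' raw 8-bit values (0, 1, 2), readable back with [read_mask()].
#'
#' @param x a [us_image] or [label_mask].
#' @param path output `.png` path.
#' @export
write_png <- function(x, path) {
  m <- if (inherits(x, "us_image")) x$pixels else x$labels
  png::writePNG(pmin(pmax(m, 0), 255) / 255, path)
  invisible(path)
}

#' Read an integer label mask from PNG
#'
#' @param path `.png` path written by [write_png()] (labels stored as raw
#'   8-bit values).
#' @return a [label_mask].
#' @export
read_mask <- function(path) {
  arr <- png::readPNG(path)
  if (length(dim(arr)) == 3L) arr <- arr[, , 1L]
  label_mask(matrix(as.integer(round(arr * 255)), nrow(arr), ncol(arr)))
}

#' Export aponeurosis curves as CSV
#'
#' One row per (curve, column): columns `curve` (superficial/deep/fascia),
#' `col`, `row`.
#'
#' @param pair an [apo_pair].
#' @param path output `.csv` path.
#' @export
write_curves_csv <- function(pair, path) {
  rows <- list()
  for (nm in c("superficial", "deep", "fascia")) {
    v <- pair[[nm]]
    if (is.null(v)) next
    ok <- which(!is.na(v))
    if (length(ok))
      rows[[nm]] <- data.frame(curve = nm, col = ok, row = v[ok])
  }
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read aponeurosis curves from CSV
#'
#' @param path CSV written by [write_curves_csv()].
#' @param width,height image dimensions the curves refer to.
#' @return an [apo_pair].
#' @export
read_curves_csv <- function(path, width, height) {
  df <- read.csv(path)
  get <- function(nm) {
    v <- rep(NA_real_, width)
    sub <- df[df$curve == nm, ]
    v[sub$col] <- sub$row
    v
  }
  fa <- if ("fascia" %in% df$curve) get("fascia") else NULL
  apo_pair(get("superficial"), get("deep"), width, height, fascia = fa)
}

# Clamp helper shared across modules.
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Fold an angle (degrees) into [0, 180).
fold180 <- function(a) {
  a <- a %% 180
  a[a < 0] <- a[a < 0] + 180
  a
}

# Acute difference between two orientations in degrees, result in [0, 90].
angle_diff <- function(a, b) {
  d <- abs(fold180(a) - fold180(b))
  pmin(d, 180 - d)
}
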