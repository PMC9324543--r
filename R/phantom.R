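# Synthetic phantom generator: ultrasound-like images with exactly known
# aponeurosis geometry, fascicle orientation and pixel spacing, used as the
# ground-truth oracle for every downstream stage.

#' Specify a synthetic muscle phantom
#'
#' Defines the exact geometry of a phantom image: two bright aponeurosis
#' bands whose medial axes follow polynomials of degree <= 2 (row as a
#' function of column), oblique bright fascicle stripes between them at a
#' known pennation angle relative to the deep curve's local tangent, optional
#' blanked column intervals (simulating segmentation gaps), and multiplicative
#' speckle-like noise.
#'
#' @param width_px,height_px image size in pixels.
#' @param pixel_spacing_mm isotropic pixel spacing (mm/px), > 0.
#' @param superficial_curve,deep_curve polynomial coefficients
#'   `c(c0, c1, c2)` giving row `c0 + c1*x + c2*x^2` at column `x`; the deep
#'   curve must lie strictly below the superficial one at every column.
#' @param fascicle_angle_deg true pennation angle in degrees, in `(0, 90]`,
#'   measured against the deep curve's local tangent.
#' @param fascicle_spacing_px perpendicular separation between consecutive
#'   stripes (px).
#' @param aponeurosis_gap_columns list of integer column intervals
#'   `c(from, to)` blanked out of both bands and the mask (may be empty); a
#'   third element restricts the gap to one band (`1` superficial, `2` deep).
#' @param noise_level multiplicative speckle level (>= 0); each pixel is
#'   scaled by `1 + noise_level * N(0,1)` and clipped to `[0, 255]`.
#' @param band_px aponeurosis band thickness in px (3-7 typical).
#' @param seed integer RNG seed; identical spec + seed gives bit-identical
#'   output.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(width_px = 256L, height_px = 256L,
                         pixel_spacing_mm = 0.1,
                         superficial_curve = c(60, 0, 0),
                         deep_curve = c(180, 0, 0),
                         fascicle_angle_deg = 20,
                         fascicle_spacing_px = 14L,
                         aponeurosis_gap_columns = list(),
                         noise_level = 0,
                         band_px = 5L,
                         seed = 1L) {
  stopifnot(width_px >= 16, height_px >= 16, pixel_spacing_mm > 0,
            fascicle_angle_deg > 0, fascicle_angle_deg <= 90,
            fascicle_spacing_px >= 2, noise_level >= 0,
            band_px >= 1)
  spec <- structure(list(
    width_px = as.integer(width_px), height_px = as.integer(height_px),
    pixel_spacing_mm = pixel_spacing_mm,
    superficial_curve = as.numeric(superficial_curve),
    deep_curve = as.numeric(deep_curve),
    fascicle_angle_deg = fascicle_angle_deg,
    fascicle_spacing_px = as.integer(fascicle_spacing_px),
    aponeurosis_gap_columns = aponeurosis_gap_columns,
    noise_level = noise_level, band_px = as.integer(band_px),
    seed = as.integer(seed)), class = "phantom_spec")
  x <- seq_len(spec$width_px)
  su <- poly_eval(spec$superficial_curve, x)
  de <- poly_eval(spec$deep_curve, x)
  if (any(de <= su + spec$band_px))
    stop("phantom geometry error: deep curve must lie strictly below the superficial curve at every column")
  if (any(su < 1) || any(de > spec$height_px))
    stop("phantom geometry error: curves leave the image")
  spec
}

poly_eval <- function(coefs, x) {
  y <- 0
  for (k in seq_along(coefs)) y <- y + coefs[k] * x^(k - 1)
  y
}

poly_deriv <- function(coefs, x) {
  d <- 0
  if (length(coefs) >= 2) for (k in 2:length(coefs))
    d <- d + (k - 1) * coefs[k] * x^(k - 2)
  d
}

# Mean perpendicular distance (px) from curve a to curve b: for every column,
# nearest distance from the point on a to a densely resampled polyline of b.
# Symmetrised to remove the direction dependence on curved geometry.
curve_mean_distance <- function(coef_a, coef_b, width, step = 0.1) {
  xs <- seq(1, width, by = step)
  one_way <- function(ca, cb) {
    bx <- xs; by <- poly_eval(cb, bx)
    x <- seq_len(width); y <- poly_eval(ca, x)
    vapply(seq_along(x), function(i)
      sqrt(min((bx - x[i])^2 + (by - y[i])^2)), numeric(1))
  }
  (mean(one_way(coef_a, coef_b)) + mean(one_way(coef_b, coef_a))) / 2
}

# Rasterise a polynomial band of given thickness into a logical matrix.
raster_band <- function(coefs, width, height, band_px) {
  m <- matrix(FALSE, height, width)
  half <- (band_px - 1) / 2
  x <- seq_len(width)
  y <- poly_eval(coefs, x)
  for (off in seq(-half, half, by = 1)) {
    r <- clamp(round(y + off), 1, height)
    m[cbind(r, x)] <- TRUE
  }
  m
}

# Draw a straight stripe through (x0, y0) with direction angle alpha
# (radians, image coords: row increases downward), clipped between curves.
raster_stripe <- function(m, x0, y0, alpha, sup_y, deep_y, thick = 2) {
  h <- nrow(m); w <- ncol(m)
  tmax <- sqrt(h^2 + w^2)
  ts <- seq(-tmax, tmax, by = 0.5)
  xs <- x0 + ts * cos(alpha)
  ys <- y0 + ts * sin(alpha)
  ok <- xs >= 1 & xs <= w
  xs <- xs[ok]; ys <- ys[ok]
  xi <- round(xs)
  inside <- ys >= sup_y[xi] + 1 & ys <= deep_y[xi] - 1
  xs <- xs[inside]; ys <- ys[inside]
  if (!length(xs)) return(m)
  for (off in seq(0, thick - 1)) {
    r <- clamp(round(ys) + off, 1, h)
    m[cbind(r, round(xs))] <- TRUE
  }
  m
}

#' Generate a phantom image, mask and ground truth
#'
#' Renders the phantom described by a [phantom_spec()]: bright bands along
#' both aponeurosis curves (blanked over the requested gap intervals), bright
#' oblique fascicle stripes at the true pennation angle, and multiplicative
#' speckle noise. The returned truth holds the exact thickness (mean
#' perpendicular inter-curve distance, mm), the true pennation angle and the
#' implied fascicle length `thickness / sin(pennation)`.
#'
#' @param spec a [phantom_spec()].
#' @return a list with elements `image` ([us_image]), `mask` ([label_mask],
#'   gapped), and `truth` (list: `thickness_mm`, `pennation_deg`,
#'   `fascicle_length_mm`, `mask` — the ideal ungapped [label_mask],
#'   `stripes` — logical matrix of noise-free stripe pixels).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  w <- spec$width_px; h <- spec$height_px
  x <- seq_len(w)
  sup_y <- poly_eval(spec$superficial_curve, x)
  deep_y <- poly_eval(spec$deep_curve, x)

  band_sup <- raster_band(spec$superficial_curve, w, h, spec$band_px)
  band_deep <- raster_band(spec$deep_curve, w, h, spec$band_px)
  ideal_mask <- band_sup | band_deep

  gap_sup <- band_sup; gap_deep <- band_deep
  for (iv in spec$aponeurosis_gap_columns) {
    cols <- seq(max(1, iv[1]), min(w, iv[2]))
    which_band <- if (length(iv) >= 3) iv[3] else 0
    if (which_band != 2) gap_sup[, cols] <- FALSE
    if (which_band != 1) gap_deep[, cols] <- FALSE
  }
  gapped <- gap_sup | gap_deep

  # Fascicle stripes anchored on the deep curve, at the true pennation angle
  # relative to its local tangent; canonical direction descends to the right
  # (superficial top-left towards deep bottom-right), the frame the
  # downstream collinearity criteria assume (BB images get flipped into it).
  stripes <- matrix(FALSE, h, w)
  theta <- spec$fascicle_angle_deg * pi / 180
  # fascicle_spacing_px is the perpendicular separation between stripes, so
  # anchors on the deep curve advance by spacing / sin(theta) columns
  step <- spec$fascicle_spacing_px / sin(theta)
  anchors <- seq(1 - h / max(tan(theta), 0.05), w + h, by = step)
  for (x0 in anchors) {
    tang <- atan(poly_deriv(spec$deep_curve, x0))
    alpha <- tang + theta   # row grows along +x: stripe descends to the right
    y0 <- poly_eval(spec$deep_curve, x0)
    stripes <- raster_stripe(stripes, x0, y0, alpha, sup_y, deep_y)
  }

  img <- matrix(30, h, w)                   # background echo level
  img[stripes] <- 160                       # fascicle stripes
  img[gapped] <- 230                        # aponeurosis bands (gapped)

  if (spec$noise_level > 0) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv), add = TRUE)
    set.seed(spec$seed)
    img <- img * (1 + spec$noise_level * matrix(rnorm(h * w), h, w))
  }
  img <- clamp(round(img), 0, 255)

  thick_px <- curve_mean_distance(spec$superficial_curve, spec$deep_curve, w)
  thickness_mm <- thick_px * spec$pixel_spacing_mm
  truth <- list(
    thickness_mm = thickness_mm,
    pennation_deg = spec$fascicle_angle_deg,
    fascicle_length_mm = thickness_mm / sin(theta),
    mask = label_mask(ideal_mask * 1L),
    stripes = stripes,
    superficial = sup_y, deep = deep_y)

  list(image = us_image(img, spec$pixel_spacing_mm, NA_character_),
       mask = label_mask(gapped * 1L),
       truth = truth)
}

#' Write a phantom to disk
#'
#' Writes the image and (gapped) mask as 8-bit PNG and the ground truth as a
#' JSON sidecar.
#'
#' @param ph output of [generate_phantom()].
#' @param stem path stem; files `<stem>.png`, `<stem>_mask.png`,
#'   `<stem>_truth.json` are produced.
#' @export
write_phantom <- function(ph, stem) {
  write_png(ph$image, paste0(stem, ".png"))
  write_png(ph$mask, paste0(stem, "_mask.png"))
  tr <- ph$truth[c("thickness_mm", "pennation_deg", "fascicle_length_mm")]
  tr$pixel_spacing_mm <- ph$image$spacing_mm
  jsonlite::write_json(tr, paste0(stem, "_truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(stem)
}

#' Fixed phantom suite for thickness validation
#'
#' Builds the standard validation suite: `n` phantoms with thickness ramped
#' over 5-35 mm, curve shapes cycling flat / linear / quadratic, moderate
#' speckle noise, and gap intervals punched into the aponeurosis bands so the
#' refinement stage is exercised.
#'
#' @param seeds integer vector of phantom seeds (default `0:49`).
#' @param noise_level speckle level (default 0.2, moderate).
#' @return list of lists: `spec`, plus `gaps` applied.
#' @export
phantom_suite_thickness <- function(seeds = 0:49, noise_level = 0.2) {
  n <- length(seeds)
  lapply(seq_len(n), function(i) {
    seed <- seeds[i]
    w <- 480L; h <- 460L; sp <- 0.1
    thick_mm <- 5 + 30 * (i - 1) / max(1, n - 1)
    gap_px <- thick_mm / sp
    shape <- (i - 1) %% 3  # 0 flat, 1 linear, 2 quadratic
    slope <- c(0, 0.06, -0.05)[shape + 1]
    quad <- c(0, 0, 6e-5)[shape + 1]
    ysup <- 40 + 10 * ((seed %% 5) / 5)
    sup <- c(ysup, slope, quad)
    dee <- c(ysup + gap_px, slope, quad)
    # keep curves inside the frame
    ys <- poly_eval(sup, c(1, w)); yd <- poly_eval(dee, c(1, w))
    shift <- 0
    if (min(ys) < 12) shift <- 12 - min(ys)
    if (max(yd) + shift > h - 12) sup[1] <- sup[1] - (max(yd) + shift - (h - 12))
    sup[1] <- sup[1] + shift; dee[1] <- sup[1] + gap_px
    band <- (seed %% 2) + 1L  # gaps afflict one boundary per phantom
    gaps <- list(c(120L + 10L * (seed %% 4), 160L + 10L * (seed %% 4), band),
                 c(300L, 330L, band))
    phantom_spec(width_px = w, height_px = h, pixel_spacing_mm = sp,
                 superficial_curve = sup, deep_curve = dee,
                 fascicle_angle_deg = 15 + (seed %% 10),
                 fascicle_spacing_px = 16L,
                 aponeurosis_gap_columns = gaps,
                 noise_level = noise_level, band_px = 5L, seed = seed)
  })
}

#' Fixed phantom suite for pennation-angle validation
#'
#' `n` phantoms with true pennation angle ramped over 8-35 degrees, thickness
#' in a mid range, flat-to-quadratic curves and moderate noise.
#'
#' @inheritParams phantom_suite_thickness
#' @return list of [phantom_spec()] objects.
#' @export
phantom_suite_pennation <- function(seeds = 0:49, noise_level = 0.2) {
  n <- length(seeds)
  lapply(seq_len(n), function(i) {
    seed <- seeds[i]
    w <- 480L; h <- 420L; sp <- 0.1
    angle <- 8 + 27 * (i - 1) / max(1, n - 1)
    thick_mm <- 15 + 10 * ((seed %% 7) / 7)
    shape <- (i - 1) %% 3
    slope <- c(0, 0.05, -0.04)[shape + 1]
    quad <- c(0, 0, 5e-5)[shape + 1]
    ysup <- 50
    sup <- c(ysup, slope, quad)
    dee <- c(ysup + thick_mm / sp, slope, quad)
    phantom_spec(width_px = w, height_px = h, pixel_spacing_mm = sp,
                 superficial_curve = sup, deep_curve = dee,
                 fascicle_angle_deg = angle,
                 fascicle_spacing_px = 18L,
                 aponeurosis_gap_columns = list(),
                 noise_level = noise_level, band_px = 5L, seed = seed)
  })
}
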