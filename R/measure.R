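# Pennation angle and fascicle length: each extended fascicle line is
# intersected with the deep aponeurosis (linearly extended beyond the image
# when needed), the pennation angle is the acute angle between the fascicle
# and the local deep tangent, and fascicle length follows from LF = d / sin(theta).

# Linear fit over the trailing/leading fraction of the deep curve, for
# extending it beyond the image.
deep_extension_fit <- function(pair, side = c("right", "left"),
                               fraction = 0.25) {
  side <- match.arg(side)
  ok <- which(!is.na(pair$deep))
  nfit <- max(2L, ceiling(length(ok) * fraction))
  sel <- if (side == "right") tail(ok, nfit) else head(ok, nfit)
  fit <- lm(y ~ x, data = data.frame(x = sel, y = pair$deep[sel]))
  coef(fit)  # intercept, slope
}

# Intersection of the infinite line through a segment with the deep curve:
# marches the polyline; if no crossing inside the image, intersects the
# linear extension on the side the line exits. Returns x, tangent slope and
# whether the extension was used, or NULL for a parallel/no-crossing case.
fascicle_deep_intersection <- function(seg, pair, fraction = 0.25) {
  ok <- which(!is.na(pair$deep))
  dx <- seg$x2 - seg$x1; dy <- seg$y2 - seg$y1
  for (i in seq_len(length(ok) - 1)) {
    b <- list(x1 = ok[i], y1 = pair$deep[ok[i]],
              x2 = ok[i + 1], y2 = pair$deep[ok[i + 1]])
    pt <- line_intersection(seg, b)
    if (!is.null(pt) && pt$s >= 0 && pt$s <= 1) {
      j <- clamp(round(pt$x), min(ok) + 1, max(ok) - 1)
      slope <- (pair$deep[j + 1] - pair$deep[j - 1]) / 2
      return(list(x = pt$x, y = pt$y, slope = slope, extended = FALSE))
    }
  }
  # no crossing inside the image: extend linearly on the exit side
  for (side in c("right", "left")) {
    cf <- deep_extension_fit(pair, side, fraction)
    # line: y = cf1 + cf2 * x; fascicle param: (x1 + t dx, y1 + t dy)
    den <- dy - cf[2] * dx
    if (abs(den) < 1e-12) next
    t <- (cf[1] + cf[2] * seg$x1 - seg$y1) / den
    x <- seg$x1 + t * dx
    if ((side == "right" && x >= max(ok)) || (side == "left" && x <= min(ok)))
      return(list(x = x, y = seg$y1 + t * dy, slope = cf[2], extended = TRUE))
  }
  NULL
}

#' Pennation angle of extracted fascicles
#'
#' For every extended fascicle line, the acute angle between the line and the
#' deep aponeurosis' local tangent at their intersection; when a line meets
#' the deep curve outside the image, the curve is extended linearly (fit to
#' its last 25% of columns) and the intersection taken on the extension
#' (flagged). The reported angle is the median over non-parallel fascicles.
#'
#' @param fascicles a `fascicle_set` from [extract_fascicles()].
#' @param pair an [apo_pair].
#' @param parallel_tol angles below this (deg) are flagged parallel and
#'   excluded from the median (default 0.5).
#' @return list: `theta_deg` (reported median), `per_fascicle` (data frame:
#'   theta_deg, extended, parallel), `flags`.
#' @export
pennation_angle <- function(fascicles, pair, parallel_tol = 0.5) {
  lines <- fascicles$lines
  if (is.null(lines) || !nrow(lines))
    stop("measurement error: no fascicle lines available")
  theta <- rep(NA_real_, nrow(lines))
  extended <- logical(nrow(lines))
  for (i in seq_len(nrow(lines))) {
    hit <- fascicle_deep_intersection(lines[i, ], pair)
    if (is.null(hit)) next
    tang_deg <- atan2(hit$slope, 1) * 180 / pi  # same convention as segments
    theta[i] <- angle_diff(lines$orientation[i], tang_deg)
    extended[i] <- hit$extended
  }
  par_flag <- !is.na(theta) & theta < parallel_tol
  use <- !is.na(theta) & !par_flag
  if (!any(use))
    stop("measurement error: all fascicles parallel to the deep aponeurosis")
  flags <- character()
  if (any(extended[use])) flags <- c(flags, "aponeurosis_extended")
  if (any(par_flag)) flags <- c(flags, "parallel_fascicle")
  list(theta_deg = median(theta[use]),
       per_fascicle = data.frame(theta_deg = theta, extended = extended,
                                 parallel = par_flag),
       flags = flags)
}

#' Fascicle length from thickness and pennation angle
#'
#' `LF = d / sin(theta)`.
#'
#' @param d_mm muscle thickness in mm (> 0).
#' @param theta_deg pennation angle in degrees, in `(0, 90]`.
#' @return fascicle length in mm.
#' @export
fascicle_length <- function(d_mm, theta_deg) {
  if (is.na(theta_deg) || theta_deg <= 0)
    stop("undefined-length error: pennation angle must be > 0 (parallel fascicle)")
  if (theta_deg > 90) stop("pennation angle must be <= 90 degrees")
  if (d_mm <= 0) stop("thickness must be > 0")
  d_mm / sin(theta_deg * pi / 180)
}

#' Measure one image end-to-end
#'
#' Runs the full chain: segmentation (a supplied mask bypasses the model) ->
#' refinement -> thickness -> fascicle extraction -> pennation angle ->
#' fascicle length. Every fallback taken along the way is recorded in
#' `flags`.
#'
#' @param image a [us_image].
#' @param mask optional [label_mask]; if `NULL`, `model` must be a trained
#'   [train_segnet()] model used to predict one.
#' @param model optional segmentation model (ignored when `mask` given).
#' @param muscle muscle tag (default: the image's).
#' @param pixel_spacing_mm spacing override (default: the image's); an
#'   unresolvable spacing is a unit error — never silently assumed.
#' @param image_id identifier recorded in the report.
#' @param params fascicle parameters, see `default_fascicle_params()`.
#' @return object of class `measurement_report`: `image_id`, `muscle`,
#'   `d_mm`, `sector_means_mm`, `theta_deg`, `theta_per_fascicle`, `lf_mm`,
#'   `flags`.
#' @export
measure_image <- function(image, mask = NULL, model = NULL,
                          muscle = image$muscle,
                          pixel_spacing_mm = image$spacing_mm,
                          image_id = "image",
                          params = default_fascicle_params()) {
  if (length(pixel_spacing_mm) != 1L || is.na(pixel_spacing_mm))
    stop("unit error: pixel spacing is missing; supply pixel_spacing_mm")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  if (is.null(mask)) {
    if (is.null(model)) stop("[segment] neither mask nor model supplied")
    mask <- stage("segment", predict_segnet(model, image))
  }
  pair <- stage("refine", refine(mask))
  th <- stage("thickness", muscle_thickness(pair, pixel_spacing_mm))
  fs <- stage("fascicle", extract_fascicles(image, pair, muscle = muscle,
                                            params = params))
  flags <- c(pair$flags, fs$flags)
  theta <- NA_real_; lf <- NA_real_; per <- NULL
  if (fs$status == "ok") {
    pa <- stage("pennation", pennation_angle(fs, pair))
    theta <- pa$theta_deg
    per <- pa$per_fascicle
    flags <- c(flags, pa$flags)
    lf <- stage("length", fascicle_length(th$overall, theta))
  } else {
    flags <- c(flags, "no_fascicles")
  }
  structure(list(image_id = image_id,
                 muscle = if (is.null(muscle) || is.na(muscle)) "GCM" else muscle,
                 d_mm = th$overall,
                 sector_means_mm = th$sector_means,
                 theta_deg = theta,
                 theta_per_fascicle = per,
                 lf_mm = lf,
                 flags = unique(flags)),
            class = "measurement_report")
}

#' @export
print.measurement_report <- function(x, ...) {
  cat(sprintf("<measurement_report> %s [%s]: d = %.2f mm, theta = %.2f deg, LF = %.2f mm\n",
              x$image_id, x$muscle, x$d_mm, x$theta_deg, x$lf_mm))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Write a measurement report as JSON
#'
#' @param report a `measurement_report`.
#' @param path output `.json`.
#' @export
write_report_json <- function(report, path) {
  out <- report[c("image_id", "muscle", "d_mm", "sector_means_mm",
                  "theta_deg", "lf_mm", "flags")]
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Aggregate measurement reports into a CSV table
#'
#' @param reports list of `measurement_report`s.
#' @param path output `.csv`.
#' @return the data frame written, invisibly.
#' @export
reports_to_csv <- function(reports, path) {
  df <- do.call(rbind, lapply(reports, function(r)
    data.frame(image_id = r$image_id, muscle = r$muscle, d_mm = r$d_mm,
               theta_deg = r$theta_deg, lf_mm = r$lf_mm,
               flags = paste(r$flags, collapse = ";"))))
  write.csv(df, path, row.names = FALSE)
  invisible(df)
}
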