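# Muscle thickness via centerline and perpendicular chords: a centerline is
# drawn midway between the two aponeurosis curves, a chord perpendicular to
# the local centerline tangent is cast at each sample, chord lengths are
# averaged within five equal-arc-length sectors, and the sector means are
# averaged into the reported thickness.

#' Centerline between the two aponeuroses
#'
#' For each column shared by both curves, the midpoint of their rows;
#' restricted to the shared column range.
#'
#' @param pair an [apo_pair].
#' @return object of class `centerline`: list with `x` (columns), `y` (rows),
#'   `arc` (cumulative arc length, px).
#' @export
centerline <- function(pair) {
  sh <- shared_columns(pair)
  if (length(sh) < 10)
    stop("geometry error: aponeurosis curves overlap over fewer than 10 columns")
  x <- sh
  y <- (pair$superficial[sh] + pair$deep[sh]) / 2
  arc <- c(0, cumsum(sqrt(diff(x)^2 + diff(y)^2)))
  structure(list(x = x, y = y, arc = arc), class = "centerline")
}

# First intersection of the ray p + t*dir (t > 0) with the polyline
# (px_, py_): returns smallest positive t, or NA if the ray exits the span.
ray_polyline_t <- function(p, dir, px_, py_) {
  n <- length(px_)
  dx <- px_[-1] - px_[-n]; dy <- py_[-1] - py_[-n]
  qx <- p[1] - px_[-n];    qy <- p[2] - py_[-n]
  det <- dx * dir[2] - dy * dir[1]
  t <- (qx * dy - qy * dx) / det
  s <- (qx * dir[2] - qy * dir[1]) / det
  ok <- is.finite(t) & t > 1e-9 & s >= -1e-9 & s <= 1 + 1e-9
  if (!any(ok)) return(NA_real_)
  min(t[ok])
}

#' Perpendicular chord lengths along the centerline
#'
#' At each centerline sample the local tangent is estimated by central
#' differences; a chord perpendicular to it is cast in both directions until
#' it meets each aponeurosis curve (sub-pixel, by linear interpolation between
#' curve samples). Chords that exit the shared column range are dropped. The
#' centerline is split into `n_sectors` equal-arc-length sectors; the result
#' holds per-sector mean chord lengths and their mean as the overall
#' thickness, in pixel units.
#'
#' @param pair an [apo_pair].
#' @param cl optional precomputed [centerline()].
#' @param n_sectors number of sectors (5, following the centerline-distance
#'   protocol).
#' @return object of class `thickness_result`: `sector_means`, `overall`,
#'   `chords` (data frame: x, y, nx, ny, length), `unit` (`"px"`),
#'   `n_sectors`.
#' @export
chord_lengths <- function(pair, cl = centerline(pair), n_sectors = 5) {
  x <- cl$x; y <- cl$y
  n <- length(x)
  if (!n) stop("empty centerline")
  # central-difference tangents (one-sided at the ends)
  ip <- pmin(seq_len(n) + 1, n); im <- pmax(seq_len(n) - 1, 1)
  tx <- x[ip] - x[im]; ty <- y[ip] - y[im]
  nt <- sqrt(tx^2 + ty^2)
  nx <- -ty / nt; ny <- tx / nt          # normal; ny > 0 points to deep
  flipit <- ny < 0
  nx[flipit] <- -nx[flipit]; ny[flipit] <- -ny[flipit]

  sh <- shared_columns(pair)
  sx <- sh; sy <- pair$superficial[sh]
  dxp <- sh; dyp <- pair$deep[sh]
  len <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    p <- c(x[i], y[i])
    t_deep <- ray_polyline_t(p, c(nx[i], ny[i]), dxp, dyp)
    t_sup <- ray_polyline_t(p, c(-nx[i], -ny[i]), sx, sy)
    if (!is.na(t_deep) && !is.na(t_sup)) len[i] <- t_deep + t_sup
  }
  valid <- which(!is.na(len))
  if (!length(valid)) stop("measurement error: no valid perpendicular chords")

  total <- cl$arc[n]
  sector <- pmin(floor(cl$arc / total * n_sectors) + 1, n_sectors)
  sector_means <- rep(NA_real_, n_sectors)
  for (s in seq_len(n_sectors)) {
    sel <- valid[sector[valid] == s]
    if (!length(sel))
      stop("measurement error: sector ", s, " has no valid chords")
    sector_means[s] <- mean(len[sel])
  }
  structure(list(
    sector_means = sector_means,
    overall = mean(sector_means),
    chords = data.frame(x = x[valid], y = y[valid],
                        nx = nx[valid], ny = ny[valid],
                        length = len[valid]),
    unit = "px", n_sectors = n_sectors),
    class = "thickness_result")
}

#' @export
print.thickness_result <- function(x, ...) {
  cat(sprintf("<thickness_result> overall %.3f %s (sectors: %s)\n",
              x$overall, x$unit,
              paste(sprintf("%.2f", x$sector_means), collapse = ", ")))
  invisible(x)
}

#' Convert a thickness result to millimetres
#'
#' Multiplies all lengths by the isotropic pixel spacing. Refuses silently
#' assumed or anisotropic spacings: spacing must be a single positive number.
#'
#' @param result a [chord_lengths()] result in px.
#' @param pixel_spacing_mm isotropic spacing in mm/px.
#' @return the result with all lengths in mm and `unit = "mm"`.
#' @export
to_mm <- function(result, pixel_spacing_mm) {
  if (length(pixel_spacing_mm) != 1L)
    stop("unit error: anisotropic pixel spacing is not supported (isotropic assumed)")
  if (is.na(pixel_spacing_mm))
    stop("unit error: pixel spacing is missing; supply spacing_mm explicitly")
  if (pixel_spacing_mm <= 0) stop("unit error: pixel spacing must be > 0")
  if (result$unit == "mm") return(result)
  result$sector_means <- result$sector_means * pixel_spacing_mm
  result$overall <- result$overall * pixel_spacing_mm
  result$chords$length <- result$chords$length * pixel_spacing_mm
  result$unit <- "mm"
  result
}

#' Muscle thickness in mm from an aponeurosis pair
#'
#' Convenience wrapper: [centerline()] + [chord_lengths()] + [to_mm()].
#'
#' @param pair an [apo_pair].
#' @param pixel_spacing_mm isotropic spacing in mm/px.
#' @param n_sectors number of sectors (default 5).
#' @return a `thickness_result` in mm.
#' @export
muscle_thickness <- function(pair, pixel_spacing_mm, n_sectors = 5) {
  to_mm(chord_lengths(pair, n_sectors = n_sectors), pixel_spacing_mm)
}
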