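# Unsupervised fascicle extraction inside the aponeurosis-bounded region:
# CLAHE contrast enhancement, multiscale ridge (vesselness) filtering,
# k-means binarisation, small-structure pruning, skeleton line fitting,
# collinearity merging, dominant-orientation selection and extension of the
# retained lines across the muscle with anatomical intersection pruning.

#' Muscle region between the two aponeuroses
#'
#' The region polygon bounded above/below by the curves over their shared
#' columns, optionally inset vertically to exclude the bright aponeurosis
#' bands themselves.
#'
#' @param pair an [apo_pair].
#' @param inset_px rows to shave off each curve (default 4).
#' @return list: `cols`, `sup`, `deep` (per shared column, inset applied).
#' @export
muscle_region <- function(pair, inset_px = 4) {
  sh <- shared_columns(pair)
  sup <- pair$superficial[sh] + inset_px
  deep <- pair$deep[sh] - inset_px
  ok <- deep > sup
  list(cols = sh[ok], sup = sup[ok], deep = deep[ok])
}

region_mask <- function(region, h, w) {
  m <- matrix(FALSE, h, w)
  for (i in seq_along(region$cols)) {
    r <- seq(max(1, ceiling(region$sup[i])), min(h, floor(region$deep[i])))
    if (length(r)) m[r, region$cols[i]] <- TRUE
  }
  m
}

# Linear interpolation of the region bounds at arbitrary x; NA outside.
region_bounds_at <- function(region, x) {
  sup <- approx(region$cols, region$sup, xout = x, rule = 1)$y
  deep <- approx(region$cols, region$deep, xout = x, rule = 1)$y
  list(sup = sup, deep = deep)
}

#' Contrast-limited adaptive histogram equalisation inside the muscle region
#'
#' Applies CLAHE to the bounding box of the region and writes back only the
#' pixels inside it; everything outside is untouched. Falls back to a single
#' tile when the region is smaller than one tile.
#'
#' @param image a [us_image].
#' @param region a [muscle_region()] (or `NULL` for the whole image).
#' @param clip_limit CLAHE clip limit (> 0, default 2).
#' @param tiles tile grid (default 8, i.e. 8 x 8).
#' @return a [us_image] with enhanced region.
#' @export
enhance <- function(image, region = NULL, clip_limit = 2, tiles = 8) {
  if (clip_limit <= 0) stop("parameter error: clip_limit must be > 0")
  px <- image$pixels
  h <- nrow(px); w <- ncol(px)
  if (is.null(region)) {
    rm_ <- matrix(TRUE, h, w); rows <- 1:h; cols <- 1:w
  } else {
    rm_ <- region_mask(region, h, w)
    if (!any(rm_)) stop("empty muscle region")
    rows <- range(which(rowSums(rm_) > 0)); rows <- rows[1]:rows[2]
    cols <- range(which(colSums(rm_) > 0)); cols <- cols[1]:cols[2]
  }
  sub <- px[rows, cols, drop = FALSE]
  nx <- if (ncol(sub) < 2 * tiles) 1 else tiles
  ny <- if (nrow(sub) < 2 * tiles) 1 else tiles
  # pad to tile multiples by edge replication (CLAHE needs full tiles)
  padr <- (ny - nrow(sub) %% ny) %% ny
  padc <- (nx - ncol(sub) %% nx) %% nx
  subp <- rbind(sub, sub[rep(nrow(sub), padr), , drop = FALSE])
  subp <- cbind(subp, subp[, rep(ncol(subp), padc), drop = FALSE])
  eq <- EBImage::clahe(EBImage::Image(subp / 255), nx = nx, ny = ny,
                       limit = clip_limit)
  eq <- EBImage::imageData(eq)[seq_len(nrow(sub)), seq_len(ncol(sub)),
                               drop = FALSE] * 255
  out <- px
  sel <- rm_[rows, cols, drop = FALSE]
  out[rows, cols][sel] <- eq[sel]
  us_image(out, image$spacing_mm, image$muscle)
}

gauss_deriv_kernels <- function(sigma) {
  r <- ceiling(3 * sigma)
  t <- seq(-r, r)
  g <- exp(-t^2 / (2 * sigma^2)); g <- g / sum(g)
  g1 <- -t / sigma^2 * g
  g2 <- (t^2 - sigma^2) / sigma^4 * g
  list(g = g, g1 = g1, g2 = g2)
}

conv_sep <- function(m, krow, kcol) {
  k <- outer(krow, kcol)
  EBImage::imageData(EBImage::filter2(EBImage::Image(m), k,
                                      boundary = "replicate"))
}

#' Multiscale ridge (vesselness) filter for bright elongated structures
#'
#' Hessian-based tubularity response: at each scale the Gaussian-smoothed
#' Hessian eigenvalues are combined into a vesselness measure that is large
#' on bright ridges and suppressed on blobs and background; the response is
#' the maximum over scales, normalised to `[0, 1]`.
#'
#' @param image a [us_image] or numeric matrix.
#' @param scales Gaussian scales in px (default `c(1.5, 2.5, 3.5)`,
#'   bracketing typical fascicle stripe widths).
#' @param beta blob-suppression parameter (default 0.5).
#' @param normalize divide by the maximum response (default `TRUE`); turn off
#'   to compare absolute tubularity across images.
#' @return numeric matrix in `[0, 1]` (raw response if `normalize = FALSE`).
#' @export
ridge_filter <- function(image, scales = c(1.5, 2.5, 3.5), beta = 0.5,
                         normalize = TRUE) {
  m <- if (inherits(image, "us_image")) image$pixels else image
  m <- m / 255
  best <- matrix(0, nrow(m), ncol(m))
  for (s in scales) {
    kk <- gauss_deriv_kernels(s)
    lrr <- s^2 * conv_sep(m, kk$g2, kk$g)   # d2 / d row2
    lcc <- s^2 * conv_sep(m, kk$g, kk$g2)   # d2 / d col2
    lrc <- s^2 * conv_sep(m, kk$g1, kk$g1)
    tmp <- sqrt(((lrr - lcc) / 2)^2 + lrc^2)
    mu1 <- (lrr + lcc) / 2 + tmp
    mu2 <- (lrr + lcc) / 2 - tmp
    # order by magnitude: l1 small, l2 large
    swap <- abs(mu1) > abs(mu2)
    l1 <- ifelse(swap, mu2, mu1)
    l2 <- ifelse(swap, mu1, mu2)
    S <- sqrt(l1^2 + l2^2)
    smax <- max(S)
    if (smax == 0) next
    rb <- ifelse(l2 != 0, l1 / l2, 0)
    v <- exp(-rb^2 / (2 * beta^2)) * (1 - exp(-S^2 / (2 * (smax / 2)^2)))
    v[l2 > 0] <- 0                          # bright ridges only
    best <- pmax(best, v)
  }
  if (normalize) {
    mx <- max(best)
    if (mx > 0) best <- best / mx
  }
  best
}

# Deterministic 1-D Lloyd k-means: centers initialised at spread quantiles
# of the unique values (k collapses to the number of distinct values when
# smaller). Returns integer cluster assignment and the final centers.
kmeans1d <- function(v, k, iter_max = 100) {
  uq <- sort(unique(v))
  k <- min(k, length(uq))
  centers <- if (k == 1) mean(uq) else
    quantile(uq, (seq_len(k) - 0.5) / k, names = FALSE, type = 7)
  centers <- sort(unique(centers))
  k <- length(centers)
  cl <- rep(1L, length(v))
  for (it in seq_len(iter_max)) {
    d <- abs(outer(v, centers, "-"))
    newcl <- max.col(-d, ties.method = "first")
    if (all(newcl == cl) && it > 1) break
    cl <- newcl
    for (j in seq_len(k))
      if (any(cl == j)) centers[j] <- mean(v[cl == j])
  }
  list(cluster = cl, centers = centers)
}

#' Binarise a ridge response by 2-means clustering
#'
#' Clusters response values into `k = 2` groups with deterministic
#' quantile-based initial centers; the cluster with the higher mean response
#' becomes foreground.
#'
#' @param response numeric matrix (ridge response).
#' @param k number of clusters (2).
#' @return a binary [label_mask]; constant response gives an empty foreground
#'   with a warning.
#' @export
binarize_kmeans <- function(response, k = 2) {
  v <- as.numeric(response)
  if (max(v) - min(v) < .Machine$double.eps * 10) {
    warning("constant response: empty foreground")
    return(label_mask(matrix(0L, nrow(response), ncol(response))))
  }
  km <- kmeans1d(v, 2)
  fg <- which.max(km$centers)
  label_mask(matrix(as.integer(km$cluster == fg), nrow(response),
                    ncol(response)))
}

#' Remove small connected structures
#'
#' @param mask binary [label_mask].
#' @param min_area_px minimum surviving component area (px).
#' @return pruned [label_mask].
#' @export
prune_small <- function(mask, min_area_px = 30) {
  cs <- connected_components(mask, connectivity = 8)
  m <- matrix(0L, cs$height, cs$width)
  for (co in cs$components)
    if (co$area >= min_area_px) m[co$pixels] <- 1L
  label_mask(m)
}

# Orientation convention shared by all modules: angle of the line against
# the +column axis with rows increasing downward, folded to [0, 180); a
# fascicle descending to the right has a small positive orientation.
seg_orientation <- function(x1, y1, x2, y2) {
  fold180(atan2(y2 - y1, x2 - x1) * 180 / pi)
}

make_segments <- function(x1, y1, x2, y2) {
  data.frame(x1 = x1, y1 = y1, x2 = x2, y2 = y2,
             orientation = seg_orientation(x1, y1, x2, y2),
             length = sqrt((x2 - x1)^2 + (y2 - y1)^2))
}

#' Fit a line segment to each structure's skeleton
#'
#' Each connected structure is skeletonised and its skeleton points fitted by
#' a total-least-squares line (principal axis), with segment endpoints at the
#' projections of the extreme skeleton points. Orientation is the line angle
#' against the +column axis, counter-clockwise positive in the displayed image
#' (rows increase downward), folded to `[0, 180)`.
#'
#' @param mask binary [label_mask].
#' @return data frame of segments: `x1, y1, x2, y2, orientation, length`.
#' @export
fit_segments <- function(mask) {
  cs <- connected_components(mask, connectivity = 8)
  h <- cs$height; w <- cs$width
  out <- list()
  for (co in cs$components) {
    sk <- component_skeleton(co$pixels, h, w)
    if (nrow(sk) < 2) next
    x <- sk[, "col"]; y <- sk[, "row"]
    cx <- mean(x); cy <- mean(y)
    cv <- cbind(x - cx, y - cy)
    ei <- eigen(crossprod(cv) / nrow(cv), symmetric = TRUE)
    v <- ei$vectors[, 1]
    t <- cv %*% v
    t1 <- min(t); t2 <- max(t)
    if (t2 - t1 < 1e-9) next
    out[[length(out) + 1L]] <- make_segments(
      cx + t1 * v[1], cy + t1 * v[2], cx + t2 * v[1], cy + t2 * v[2])
  }
  if (!length(out)) return(make_segments(numeric(0), numeric(0), numeric(0), numeric(0)))
  do.call(rbind, out)
}

# Intersection of the infinite lines through two segments; NULL if parallel.
line_intersection <- function(a, b) {
  d1 <- c(a$x2 - a$x1, a$y2 - a$y1)
  d2 <- c(b$x2 - b$x1, b$y2 - b$y1)
  det <- d1[1] * d2[2] - d1[2] * d2[1]
  if (abs(det) < 1e-12) return(NULL)
  q <- c(b$x1 - a$x1, b$y1 - a$y1)
  t <- (q[1] * d2[2] - q[2] * d2[1]) / det
  s <- (q[1] * d1[2] - q[2] * d1[1]) / det
  list(x = a$x1 + t * d1[1], y = a$y1 + t * d1[2], t = t, s = s)
}

# Perpendicular distance from a point to the infinite line through a segment.
point_line_distance <- function(px, py, seg) {
  dx <- seg$x2 - seg$x1; dy <- seg$y2 - seg$y1
  abs(dy * (px - seg$x1) - dx * (py - seg$y1)) / sqrt(dx^2 + dy^2)
}

#' Merge collinear segment pairs
#'
#' Two segments are merged when at least two of the three collinearity
#' criteria hold: (1) their line extensions intersect inside the image
#' bounds (parallel lines qualify only when coincident, i.e. their
#' perpendicular offset is below `coll_tol`, in which case the extensions
#' overlap inside the image); (2) one segment's midpoint lies upper-left of
#' the other's — both smaller column and smaller row, by more than `pos_tol`
#' to keep sub-pixel fitting jitter from ordering midpoints spuriously;
#' (3) their orientations differ by strictly less than `max_angle` degrees.
#' Merging replaces the pair by the principal-axis segment spanning the union
#' of their endpoints, iterated to a fixed point.
#'
#' @param segments segment data frame (see [fit_segments()]).
#' @param width,height image bounds for criterion (1).
#' @param max_angle orientation-difference threshold in degrees (strict; 5).
#' @param coll_tol perpendicular offset (px) under which parallel lines count
#'   as coincident for criterion (1).
#' @param pos_tol margin (px) for the upper-left relation of criterion (2).
#' @return merged segment data frame.
#' @export
merge_collinear <- function(segments, width, height, max_angle = 5,
                            coll_tol = 2, pos_tol = 2) {
  repeat {
    n <- nrow(segments)
    if (n < 2) return(segments)
    merged <- FALSE
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        a <- segments[i, ]; b <- segments[j, ]
        crit <- 0L
        pt <- line_intersection(a, b)
        if (is.null(pt)) {
          mb <- c((b$x1 + b$x2) / 2, (b$y1 + b$y2) / 2)
          if (point_line_distance(mb[1], mb[2], a) < coll_tol) crit <- crit + 1L
        } else if (pt$x >= 1 && pt$x <= width &&
                   pt$y >= 1 && pt$y <= height) crit <- crit + 1L
        ma <- c((a$x1 + a$x2) / 2, (a$y1 + a$y2) / 2)
        mb <- c((b$x1 + b$x2) / 2, (b$y1 + b$y2) / 2)
        if ((ma[1] < mb[1] - pos_tol && ma[2] < mb[2] - pos_tol) ||
            (mb[1] < ma[1] - pos_tol && mb[2] < ma[2] - pos_tol)) crit <- crit + 1L
        if (angle_diff(a$orientation, b$orientation) < max_angle)
          crit <- crit + 1L
        if (crit >= 2L) {
          px <- c(a$x1, a$x2, b$x1, b$x2)
          py <- c(a$y1, a$y2, b$y1, b$y2)
          cx <- mean(px); cy <- mean(py)
          cv <- cbind(px - cx, py - cy)
          v <- eigen(crossprod(cv), symmetric = TRUE)$vectors[, 1]
          t <- cv %*% v
          newseg <- make_segments(cx + min(t) * v[1], cy + min(t) * v[2],
                                  cx + max(t) * v[1], cy + max(t) * v[2])
          # consistency guard: connecting pieces of one line must not change
          # the orientation; otherwise the pair is not the same fascicle
          if (angle_diff(newseg$orientation, a$orientation) >= max_angle ||
              angle_diff(newseg$orientation, b$orientation) >= max_angle)
            next
          segments <- rbind(segments[-c(i, j), ], newseg)
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) return(segments)
  }
}

#' Dominant orientation by 1-D k-means
#'
#' Clusters segment orientations and keeps the cluster with the largest total
#' segment length (not count); the dominant orientation is that cluster's
#' length-weighted mean.
#'
#' @param segments segment data frame.
#' @param k_orient number of orientation clusters (reduced to the segment
#'   count when fewer segments are available).
#' @return list: `dominant_deg`, `segments` (the winning cluster's members).
#' @export
dominant_orientation <- function(segments, k_orient = 3) {
  n <- nrow(segments)
  if (!n) stop("no segments: cannot select a dominant orientation")
  k <- min(k_orient, n)
  if (k == 1) {
    dom <- sum(segments$orientation * segments$length) / sum(segments$length)
    return(list(dominant_deg = dom, segments = segments))
  }
  km <- kmeans1d(segments$orientation, k)
  tot <- tapply(segments$length, km$cluster, sum)
  win <- as.integer(names(tot))[which.max(tot)]
  sel <- segments[km$cluster == win, , drop = FALSE]
  dom <- sum(sel$orientation * sel$length) / sum(sel$length)
  list(dominant_deg = dom, segments = sel)
}

# Extend a segment along its line to the muscle region boundary: dense
# samples along the line, the contiguous inside-run containing the segment
# midpoint becomes the extended chord.
extend_segment <- function(seg, region, step = 0.25) {
  dx <- seg$x2 - seg$x1; dy <- seg$y2 - seg$y1
  L <- sqrt(dx^2 + dy^2)
  ux <- dx / L; uy <- dy / L
  mx <- (seg$x1 + seg$x2) / 2; my <- (seg$y1 + seg$y2) / 2
  span <- max(region$cols) - min(region$cols) +
    max(region$deep) - min(region$sup)
  ts <- seq(-span, span, by = step)
  xs <- mx + ts * ux; ys <- my + ts * uy
  b <- region_bounds_at(region, xs)
  inside <- !is.na(b$sup) & ys >= b$sup & ys <= b$deep
  if (!any(inside)) return(NULL)
  mid <- which.min(abs(ts))
  if (!inside[mid]) {
    cand <- which(inside)
    mid <- cand[which.min(abs(ts[cand]))]
  }
  runs <- rle(inside)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  ri <- which(runs$values & starts <= mid & ends >= mid)
  if (!length(ri)) return(NULL)
  i1 <- starts[ri]; i2 <- ends[ri]
  make_segments(xs[i1], ys[i1], xs[i2], ys[i2])
}

seg_interior_intersection <- function(a, b, region, eps = 1e-6) {
  pt <- line_intersection(a, b)
  if (is.null(pt)) return(FALSE)
  if (pt$t <= eps || pt$t >= 1 - eps || pt$s <= eps || pt$s >= 1 - eps)
    return(FALSE)
  bnd <- region_bounds_at(region, pt$x)
  !is.na(bnd$sup) && pt$y > bnd$sup + eps && pt$y < bnd$deep - eps
}

#' Extend segments across the muscle and prune intersecting lines
#'
#' Each retained segment is extended along its own line to the muscle region
#' boundary (the two aponeurosis curves and the image sides). Anatomically,
#' two fascicles cannot intersect inside the muscle: while any two extended
#' lines intersect strictly inside the region, the line whose orientation
#' deviates most from the median orientation of all current lines is deleted
#' (median recomputed after each deletion; deviation ties drop the shorter
#' line).
#'
#' @param segments segment data frame (the dominant cluster).
#' @param region a [muscle_region()].
#' @return list: `lines` (extended, pairwise non-intersecting), `dropped`
#'   (number of pruned lines).
#' @export
extend_and_prune <- function(segments, region) {
  ext <- list()
  for (i in seq_len(nrow(segments))) {
    e <- extend_segment(segments[i, ], region)
    if (!is.null(e)) ext[[length(ext) + 1L]] <- e
  }
  if (!length(ext))
    return(list(lines = make_segments(numeric(0), numeric(0), numeric(0),
                                      numeric(0)), dropped = 0L))
  lines <- do.call(rbind, ext)
  dropped <- 0L
  repeat {
    n <- nrow(lines)
    bad <- FALSE
    for (i in seq_len(max(0, n - 1))) {
      for (j in seq(i + 1, n)) {
        if (seg_interior_intersection(lines[i, ], lines[j, ], region)) {
          med <- median(lines$orientation)
          dev <- angle_diff(lines$orientation, med)
          pairdev <- dev[c(i, j)]
          if (abs(diff(pairdev)) < 1e-12) {
            del <- if (lines$length[i] <= lines$length[j]) i else j
          } else {
            del <- c(i, j)[which.max(pairdev)]
          }
          lines <- lines[-del, , drop = FALSE]
          dropped <- dropped + 1L
          bad <- TRUE
          break
        }
      }
      if (bad) break
    }
    if (!bad) break
  }
  list(lines = lines, dropped = dropped)
}

flip_image_h <- function(image) {
  us_image(image$pixels[, rev(seq_len(ncol(image$pixels))), drop = FALSE],
           image$spacing_mm, image$muscle)
}

flip_pair_h <- function(pair) {
  apo_pair(rev(pair$superficial), rev(pair$deep), pair$width, pair$height,
           fascia = if (is.null(pair$fascia)) NULL else rev(pair$fascia),
           flags = pair$flags)
}

flip_segments_h <- function(segments, width) {
  if (!nrow(segments)) return(segments)
  make_segments(width + 1 - segments$x1, segments$y1,
                width + 1 - segments$x2, segments$y2)
}

# Core steps (a)-(g) on one region of one (already flipped, if needed) image.
extract_core <- function(image, region, params) {
  h <- nrow(image$pixels); w <- ncol(image$pixels)
  enh <- enhance(image, region, clip_limit = params$clip_limit,
                 tiles = params$tiles)
  resp <- ridge_filter(enh, scales = params$scales, beta = params$beta,
                       normalize = FALSE)
  # keep only response clear of the region boundary: the bright aponeurosis
  # bands just outside bleed into the Hessian over the Gaussian support
  margin <- ceiling(3 * max(params$scales))
  inner <- list(cols = region$cols, sup = region$sup + margin,
                deep = region$deep - margin)
  rm_ <- region_mask(inner, h, w)
  resp[!rm_] <- 0
  # an absolute tubularity floor separates real stripes (O(0.1) and above)
  # from numerical dust left by contrast enhancement at the region edge
  if (max(resp) >= params$response_floor) resp <- resp / max(resp)
  else resp[] <- 0
  if (max(resp) == 0)
    return(list(segments = make_segments(numeric(0), numeric(0), numeric(0),
                                         numeric(0)),
                lines = NULL, dominant = NA_real_, status = "no_fascicles"))
  bin <- suppressWarnings(binarize_kmeans(resp))
  bin <- prune_small(bin, params$min_area_px)
  segs <- fit_segments(bin)
  if (!nrow(segs))
    return(list(segments = segs, lines = NULL, dominant = NA_real_,
                status = "no_fascicles"))
  segs <- merge_collinear(segs, width = w, height = h,
                          max_angle = params$merge_angle)
  domr <- dominant_orientation(segs, k_orient = params$k_orient)
  ep <- extend_and_prune(domr$segments, region)
  list(segments = domr$segments, lines = ep$lines,
       dominant = domr$dominant_deg, dropped = ep$dropped, status = "ok")
}

default_fascicle_params <- function() {
  list(clip_limit = 2, tiles = 8, scales = c(1.5, 2.5, 3.5), beta = 0.5,
       min_area_px = 30, merge_angle = 5, k_orient = 3, inset_px = 4,
       response_floor = 1e-3)
}

#' Extract fascicles from a muscle image
#'
#' Runs the full unsupervised extraction inside the aponeurosis-bounded
#' region: CLAHE, ridge filtering, 2-means binarisation, small-structure
#' pruning, per-structure skeleton line fitting, collinearity merging,
#' dominant-orientation selection and extension with intersection pruning.
#' Muscle-specific preprocessing: BB images are flipped horizontally first
#' (results are mapped back); TA is split at the central fascia and the two
#' compartments processed separately, the lower one flipped.
#'
#' @param image a [us_image].
#' @param pair an [apo_pair] from [refine()].
#' @param muscle `"BB"`, `"GCM"` or `"TA"` (default from the image tag, else
#'   GCM-like processing).
#' @param params parameter list, see `default_fascicle_params()`.
#' @return object of class `fascicle_set`: `segments` (dominant cluster,
#'   original frame), `lines` (extended lines), `dominant_orientation_deg`,
#'   `region`, `status`, `flags`.
#' @export
extract_fascicles <- function(image, pair, muscle = image$muscle,
                              params = default_fascicle_params()) {
  w <- ncol(image$pixels)
  flags <- character()
  if (is.na(muscle) || is.null(muscle)) muscle <- "GCM"
  if (muscle == "TA" && is.null(pair$fascia)) {
    flags <- c(flags, "ta_no_fascia_whole_region")
    muscle <- "GCM"
  }
  if (muscle == "BB") {
    res <- extract_core(flip_image_h(image),
                        muscle_region(flip_pair_h(pair), params$inset_px),
                        params)
    res$segments <- flip_segments_h(res$segments, w)
    if (!is.null(res$lines)) res$lines <- flip_segments_h(res$lines, w)
    if (!is.na(res$dominant)) res$dominant <- fold180(180 - res$dominant)
  } else if (muscle == "TA") {
    p1 <- apo_pair(pair$superficial, pair$fascia, pair$width, pair$height)
    p2 <- apo_pair(pair$fascia, pair$deep, pair$width, pair$height)
    r1 <- extract_core(image, muscle_region(p1, params$inset_px), params)
    r2 <- extract_core(flip_image_h(image),
                       muscle_region(flip_pair_h(p2), params$inset_px), params)
    r2$segments <- flip_segments_h(r2$segments, w)
    if (!is.null(r2$lines)) r2$lines <- flip_segments_h(r2$lines, w)
    if (!is.na(r2$dominant)) r2$dominant <- fold180(180 - r2$dominant)
    doms <- c(r1$dominant, r2$dominant)
    lens <- c(if (nrow(r1$segments)) sum(r1$segments$length) else 0,
              if (nrow(r2$segments)) sum(r2$segments$length) else 0)
    ok <- !is.na(doms) & lens > 0
    dom <- if (any(ok))
      sum(pmin(doms[ok], 180 - doms[ok]) * lens[ok]) / sum(lens[ok])
      else NA_real_
    res <- list(segments = rbind(r1$segments, r2$segments),
                lines = rbind(r1$lines, r2$lines),
                dominant = dom,
                status = if (r1$status == "ok" || r2$status == "ok") "ok"
                         else "no_fascicles")
    flags <- c(flags, "ta_compartments")
  } else {
    res <- extract_core(image, muscle_region(pair, params$inset_px), params)
  }
  structure(list(segments = res$segments, lines = res$lines,
                 dominant_orientation_deg = res$dominant,
                 region = muscle_region(pair, params$inset_px),
                 status = res$status, flags = flags),
            class = "fascicle_set")
}

#' @export
print.fascicle_set <- function(x, ...) {
  cat(sprintf("<fascicle_set> status %s, %d segments, %d extended lines, dominant %.2f deg\n",
              x$status, nrow(x$segments),
              if (is.null(x$lines)) 0L else nrow(x$lines),
              x$dominant_orientation_deg))
  invisible(x)
}

draw_segment_rgb <- function(rgb, seg, channel_on, channel_off) {
  h <- dim(rgb)[1]; w <- dim(rgb)[2]
  n <- max(2L, ceiling(seg$length * 2))
  xs <- clamp(round(seq(seg$x1, seg$x2, length.out = n)), 1, w)
  ys <- clamp(round(seq(seg$y1, seg$y2, length.out = n)), 1, h)
  for (ch in channel_on) rgb[cbind(ys, xs, ch)] <- 1
  for (ch in channel_off) rgb[cbind(ys, xs, ch)] <- 0
  rgb
}

#' Write a fascicle overlay PNG
#'
#' The grayscale image with the pre-extension segments drawn in green and
#' the extended fascicle lines in yellow.
#'
#' @param image a [us_image].
#' @param fs a `fascicle_set`.
#' @param path output `.png`.
#' @export
write_overlay_png <- function(image, fs, path) {
  g <- image$pixels / 255
  rgb <- array(rep(g, 3), c(nrow(g), ncol(g), 3))
  if (!is.null(fs$lines) && nrow(fs$lines))
    for (i in seq_len(nrow(fs$lines)))
      rgb <- draw_segment_rgb(rgb, fs$lines[i, ], c(1, 2), 3)   # yellow
  if (nrow(fs$segments))
    for (i in seq_len(nrow(fs$segments)))
      rgb <- draw_segment_rgb(rgb, fs$segments[i, ], 2, c(1, 3)) # green
  png::writePNG(rgb, path)
  invisible(path)
}

#' Export a fascicle set as CSV
#'
#' One row per extended line: id, endpoint coordinates, orientation (deg) and
#' length (px).
#'
#' @param fs a `fascicle_set`.
#' @param path output `.csv`.
#' @export
write_fascicles_csv <- function(fs, path) {
  ln <- fs$lines
  if (is.null(ln)) ln <- make_segments(numeric(0), numeric(0), numeric(0), numeric(0))
  df <- cbind(id = seq_len(nrow(ln)), ln)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
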