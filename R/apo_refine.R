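# Aponeurosis mask refinement: connected-component analysis, morphological
# skeletonization, and quadratic bridging of gaps — keeps the two largest
# components as aponeurosis candidates, absorbs fragments lying along their
# x-axis band, and discards everything else as artifact.

shift_mat <- function(m, dr, dc) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(FALSE, h, w)
  rs <- seq_len(h) - dr; cs <- seq_len(w) - dc
  rok <- rs >= 1 & rs <= h; cok <- cs >= 1 & cs <= w
  out[rok, cok] <- m[rs[rok], cs[cok]]
  out
}

#' Connected components of a binary mask
#'
#' Labels maximal connected foreground regions (8- or 4-connectivity) and
#' reports, per component, its pixel set, area and bounding extents.
#'
#' @param mask a [label_mask], or a logical/0-1 matrix; non-zero is foreground
#'   (select a single label upstream with [as_binary]).
#' @param connectivity 8 (default) or 4.
#' @return an object of class `component_set`: list with `components` (each a
#'   list `pixels` (n x 2 matrix of row, col), `area`, `xrange`, `yrange`),
#'   `connectivity`, and the mask dimensions.
#' @export
connected_components <- function(mask, connectivity = 8) {
  stopifnot(connectivity %in% c(4, 8))
  m <- if (inherits(mask, "label_mask")) mask$labels != 0L else mask != 0
  h <- nrow(m); w <- ncol(m)
  idx <- which(m)
  comps <- list()
  if (length(idx)) {
    id <- matrix(0L, h, w)
    id[idx] <- seq_along(idx)
    offs <- list(c(0, 1), c(1, 0))
    if (connectivity == 8) offs <- c(offs, list(c(1, 1), c(1, -1)))
    edges <- NULL
    rr <- ((idx - 1) %% h) + 1
    cc <- ((idx - 1) %/% h) + 1
    for (o in offs) {
      r2 <- rr + o[1]; c2 <- cc + o[2]
      ok <- r2 >= 1 & r2 <= h & c2 >= 1 & c2 <= w
      ok[ok] <- m[cbind(r2[ok], c2[ok])]
      if (any(ok))
        edges <- rbind(edges, cbind(id[idx[ok]], id[cbind(r2[ok], c2[ok])]))
    }
    g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
    if (!is.null(edges)) g <- igraph::add_edges(g, t(edges))
    memb <- igraph::components(g)$membership
    for (k in sort(unique(memb))) {
      sel <- idx[memb == k]
      pr <- ((sel - 1) %% h) + 1
      pc <- ((sel - 1) %/% h) + 1
      comps[[length(comps) + 1L]] <- list(
        pixels = cbind(row = pr, col = pc),
        area = length(sel),
        xrange = range(pc), yrange = range(pr))
    }
  }
  structure(list(components = comps, connectivity = connectivity,
                 height = h, width = w),
            class = "component_set")
}

#' @export
print.component_set <- function(x, ...) {
  cat(sprintf("<component_set> %d components (%d-connected), %d x %d grid\n",
              length(x$components), x$connectivity, x$height, x$width))
  invisible(x)
}

#' Morphological skeleton (Zhang-Suen thinning)
#'
#' Thins a binary region to a one-pixel-wide medial path. For an elongated
#' horizontal band the result is single-valued per column at the medial row.
#'
#' @param m logical (or 0-1) matrix; foreground is thinned.
#' @return logical matrix of the same size containing the skeleton.
#' @export
skeletonize <- function(m) {
  m <- m != 0
  if (!any(m)) return(m)
  repeat {
    changed <- FALSE
    for (pass in 1:2) {
      p2 <- shift_mat(m, -1, 0); p3 <- shift_mat(m, -1, 1)
      p4 <- shift_mat(m, 0, 1);  p5 <- shift_mat(m, 1, 1)
      p6 <- shift_mat(m, 1, 0);  p7 <- shift_mat(m, 1, -1)
      p8 <- shift_mat(m, 0, -1); p9 <- shift_mat(m, -1, -1)
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      a <- (!p2 & p3) + (!p3 & p4) + (!p4 & p5) + (!p5 & p6) +
           (!p6 & p7) + (!p7 & p8) + (!p8 & p9) + (!p9 & p2)
      if (pass == 1) {
        cond <- m & b >= 2 & b <= 6 & a == 1 &
          !(p2 & p4 & p6) & !(p4 & p6 & p8)
      } else {
        cond <- m & b >= 2 & b <= 6 & a == 1 &
          !(p2 & p4 & p8) & !(p2 & p6 & p8)
      }
      if (any(cond)) { m[cond] <- FALSE; changed <- TRUE }
    }
    if (!changed) break
  }
  m
}

# Skeleton points (col, row) of a component's pixel set within an h x w grid;
# thinning runs on the component's padded bounding box, not the full grid.
component_skeleton <- function(pixels, h, w) {
  r0 <- min(pixels[, "row"]); c0 <- min(pixels[, "col"])
  hh <- max(pixels[, "row"]) - r0 + 3L
  ww <- max(pixels[, "col"]) - c0 + 3L
  m <- matrix(FALSE, hh, ww)
  m[cbind(pixels[, "row"] - r0 + 2L, pixels[, "col"] - c0 + 2L)] <- TRUE
  sk <- skeletonize(m)
  sel <- which(sk)
  cbind(col = ((sel - 1) %/% hh) + c0 - 1L,
        row = ((sel - 1) %% hh) + r0 - 1L)
}

#' Bridge a candidate skeleton across gaps by polynomial fitting
#'
#' Fits a degree-2 polynomial jointly to the candidate's skeleton points and
#' those of the accepted fragments, fills every missing column in the union
#' x-span by evaluating the fit, keeps existing skeleton columns, and replaces
#' spikes deviating from the fit by more than `spike_tol` px.
#'
#' @param cand_pts matrix with columns `col`, `row` — candidate skeleton.
#' @param frag_pts_list list of matrices like `cand_pts` — fragment skeletons.
#' @param width image width (curve is reported over `1:width`, `NA` outside
#'   the union span).
#' @param spike_tol residual (px) beyond which an existing point is replaced
#'   by the fitted value.
#' @return list: `curve` (numeric length `width`), `flag` (`""`, `"linear"`,
#'   or `"nofill"`).
#' @export
bridge_fit <- function(cand_pts, frag_pts_list = list(), width,
                       spike_tol = 3) {
  pts <- rbind(cand_pts, do.call(rbind, frag_pts_list))
  # single-valued per column: average rows
  rowmean <- tapply(pts[, "row"], pts[, "col"], mean)
  xs <- as.integer(names(rowmean))
  ys <- as.numeric(rowmean)
  curve <- rep(NA_real_, width)
  nx <- length(unique(xs))
  flag <- ""
  if (nx < 2) {
    curve[xs] <- ys
    return(list(curve = curve, flag = "nofill"))
  }
  deg <- if (nx < 3) { flag <- "linear"; 1 } else 2
  fit <- lm(y ~ poly(x, degree = deg, raw = TRUE),
            data = data.frame(x = xs, y = ys))
  span <- seq(min(xs), max(xs))
  pred_span <- as.numeric(predict(fit, newdata = data.frame(x = span)))
  curve[span] <- pred_span
  # keep existing skeleton columns unless they spike off the fit
  pred_at <- pred_span[xs - min(xs) + 1]
  keep <- abs(ys - pred_at) <= spike_tol
  curve[xs[keep]] <- ys[keep]
  list(curve = curve, flag = flag)
}

# Columns covered by a component (from its pixel set).
covered_columns <- function(pixels) sort(unique(pixels[, "col"]))

# Order components by decreasing area; ties broken by smaller mean row
# (superficial first), then leftmost pixel — deterministic top-2 selection.
order_components <- function(comps) {
  area <- vapply(comps, `[[`, numeric(1), "area")
  mrow <- vapply(comps, function(co) mean(co$pixels[, "row"]), numeric(1))
  minc <- vapply(comps, function(co) min(co$pixels[, "col"]), numeric(1))
  order(-area, mrow, minc)
}

# Complete one candidate using fragments assigned to it.
complete_candidate <- function(cand, frags, h, w, spike_tol = 3) {
  cand_sk <- component_skeleton(cand$pixels, h, w)
  frag_sk <- lapply(frags, function(f) component_skeleton(f$pixels, h, w))
  bridge_fit(cand_sk, frag_sk, width = w, spike_tol = spike_tol)
}

# Quadratic fit through a candidate's skeleton, for extrapolating its row at
# fragment positions (the vertical-band membership test).
candidate_row_at <- function(cand_sk, x) {
  nx <- length(unique(cand_sk[, "col"]))
  deg <- min(2, nx - 1)
  if (deg < 1) return(rep(mean(cand_sk[, "row"]), length(x)))
  fit <- lm(y ~ poly(x, degree = deg, raw = TRUE),
            data = data.frame(x = cand_sk[, "col"], y = cand_sk[, "row"]))
  as.numeric(predict(fit, newdata = data.frame(x = x)))
}

#' Refine a predicted aponeurosis mask into a curve pair
#'
#' Implements the post-processing refinement: connected-component analysis,
#' selection of the two largest components as aponeurosis candidates,
#' completion of each candidate by skeletonizing it together with the
#' remainder fragments that lie along its x-axis band and fitting a degree-2
#' polynomial across the gaps, and removal of all unused fragments as
#' artifacts. Candidates are labelled superficial/deep by mean row.
#'
#' A fragment is accepted by a candidate when its column interval intersects
#' columns missing from the candidate and its mean row lies within
#' `height / 8` px of the candidate's extrapolated row there; a fragment
#' acceptable to both candidates goes to the vertically closer one.
#'
#' @param mask a [label_mask] (label 1 = aponeurosis; label 2, if present and
#'   `fascia = TRUE`, is refined separately as the single central fascia).
#' @param min_area_px components smaller than this are never candidates
#'   (but may still be fragments).
#' @param spike_tol spike-smoothing tolerance passed to [bridge_fit()].
#' @param fascia refine label 2 into a central-fascia curve when present.
#' @return an [apo_pair].
#' @export
refine <- function(mask, min_area_px = 20, spike_tol = 3, fascia = TRUE) {
  stopifnot(inherits(mask, "label_mask"))
  h <- nrow(mask$labels); w <- ncol(mask$labels)
  cs <- connected_components(as_binary(mask, 1L), connectivity = 8)
  comps <- cs$components
  if (length(comps) < 2)
    stop("single aponeurosis: need two aponeurosis components, found ",
         length(comps))
  ord <- order_components(comps)
  # candidates must have non-trivial area; fall back to plain top-2 otherwise
  big <- ord[vapply(ord, function(i) comps[[i]]$area >= min_area_px, logical(1))]
  if (length(big) >= 2) ord <- c(big, setdiff(ord, big))
  cand_idx <- ord[1:2]
  frag_idx <- setdiff(seq_along(comps), cand_idx)

  cand_sks <- lapply(cand_idx, function(i)
    component_skeleton(comps[[i]]$pixels, h, w))
  cand_cols <- lapply(cand_idx, function(i)
    covered_columns(comps[[i]]$pixels))

  # assign each fragment to at most one candidate
  assign_to <- rep(0L, length(frag_idx))
  offsets <- rep(Inf, length(frag_idx))
  for (j in seq_along(frag_idx)) {
    f <- comps[[frag_idx[j]]]
    fcols <- covered_columns(f$pixels)
    frow <- mean(f$pixels[, "row"])
    fx <- mean(f$pixels[, "col"])
    for (k in 1:2) {
      missing <- setdiff(seq_len(w), cand_cols[[k]])
      if (!length(intersect(fcols, missing))) next
      off <- abs(frow - candidate_row_at(cand_sks[[k]], fx))
      if (off <= h / 8 && off < offsets[j]) {
        offsets[j] <- off; assign_to[j] <- k
      }
    }
  }

  curves <- vector("list", 2)
  flags <- character()
  for (k in 1:2) {
    frags <- comps[frag_idx[assign_to == k]]
    res <- complete_candidate(comps[[cand_idx[k]]], frags, h, w, spike_tol)
    curves[[k]] <- res$curve
    if (nzchar(res$flag)) flags <- c(flags, paste0("cand", k, ":", res$flag))
  }

  mr <- vapply(curves, function(cv) mean(cv, na.rm = TRUE), numeric(1))
  sup <- curves[[which.min(mr)]]
  dee <- curves[[which.max(mr)]]
  shared <- which(!is.na(sup) & !is.na(dee))
  if (length(shared) && any(sup[shared] >= dee[shared]))
    stop("aponeurosis geometry error: refined curves cross or touch")

  fa <- NULL
  if (fascia && any(mask$labels == 2L)) {
    fa <- tryCatch(refine_single(label_mask((mask$labels == 2L) * 1L),
                                 spike_tol = spike_tol)$curve,
                   error = function(e) { flags <<- c(flags, "fascia:failed"); NULL })
  }
  apo_pair(sup, dee, width = w, height = h, fascia = fa, flags = flags)
}

#' Refine a single-curve mask (central fascia variant)
#'
#' Same completion procedure as [refine()] but for a single candidate: the
#' largest component is the candidate and every other component in its
#' x-axis band is a bridging fragment.
#'
#' @param mask binary [label_mask] containing the single curve.
#' @param spike_tol see [bridge_fit()].
#' @return list: `curve`, `flag`.
#' @export
refine_single <- function(mask, spike_tol = 3) {
  h <- nrow(mask$labels); w <- ncol(mask$labels)
  cs <- connected_components(as_binary(mask, 1L), connectivity = 8)
  comps <- cs$components
  if (!length(comps)) stop("empty mask: no curve component")
  ord <- order_components(comps)
  cand <- comps[[ord[1]]]
  cand_sk <- component_skeleton(cand$pixels, h, w)
  ccols <- covered_columns(cand$pixels)
  frags <- list()
  for (i in ord[-1]) {
    f <- comps[[i]]
    fcols <- covered_columns(f$pixels)
    if (!length(intersect(fcols, setdiff(seq_len(w), ccols)))) next
    off <- abs(mean(f$pixels[, "row"]) -
                 candidate_row_at(cand_sk, mean(f$pixels[, "col"])))
    if (off <= h / 8) frags <- c(frags, list(f))
  }
  complete_candidate(cand, frags, h, w, spike_tol)
}

#' Render an aponeurosis pair back into a label mask
#'
#' Draws each curve as a band of the given thickness; used for idempotence
#' checks and for exporting refined masks.
#'
#' @param pair an [apo_pair].
#' @param band_px band thickness in px.
#' @return a [label_mask] (curves as label 1, fascia as label 2).
#' @export
render_pair <- function(pair, band_px = 3) {
  m <- matrix(0L, pair$height, pair$width)
  half <- (band_px - 1) / 2
  draw <- function(m, v, lab) {
    ok <- which(!is.na(v))
    for (off in seq(-half, half, by = 1)) {
      r <- clamp(round(v[ok] + off), 1, pair$height)
      m[cbind(r, ok)] <- lab
    }
    m
  }
  m <- draw(m, pair$superficial, 1L)
  m <- draw(m, pair$deep, 1L)
  if (!is.null(pair$fascia)) m <- draw(m, pair$fascia, 2L)
  label_mask(m)
}
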