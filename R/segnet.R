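# Aponeurosis segmentation: a compact attention U-Net (encoder-decoder with
# an attention gate on the skip connection) trained with a weighted soft-Dice
# loss and Adam with stepwise learning-rate decay. Forward and backward
# passes are written directly on BLAS matrix operations (im2col convolution),
# which keeps smoke-scale training deterministic and CPU-friendly; the stage
# is fully bypassable by supplying a label mask downstream.

# ---- array helpers ---------------------------------------------------------

# Nearest / bilinear resize of a matrix to (h2, w2).
resize_matrix <- function(m, h2, w2, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  h <- nrow(m); w <- ncol(m)
  if (h == h2 && w == w2) return(m)
  rs <- (seq_len(h2) - 0.5) * h / h2 + 0.5
  cs <- (seq_len(w2) - 0.5) * w / w2 + 0.5
  if (method == "nearest") {
    return(m[clamp(round(rs), 1, h), clamp(round(cs), 1, w), drop = FALSE])
  }
  r0 <- clamp(floor(rs), 1, h); r1 <- clamp(r0 + 1, 1, h); fr <- clamp(rs - r0, 0, 1)
  c0 <- clamp(floor(cs), 1, w); c1 <- clamp(c0 + 1, 1, w); fc <- clamp(cs - c0, 0, 1)
  a <- m[r0, c0, drop = FALSE] * (1 - fr) + m[r1, c0, drop = FALSE] * fr
  b <- m[r0, c1, drop = FALSE] * (1 - fr) + m[r1, c1, drop = FALSE] * fr
  fcm <- matrix(fc, h2, w2, byrow = TRUE)
  a * (1 - fcm) + b * fcm
}

# im2col index table for a 3x3, pad-1 convolution on an h x w grid:
# (h*w) x 9 matrix of linear input indices, 0 where the tap falls outside.
im2col_index <- function(h, w) {
  rr <- rep(seq_len(h), w)
  cc <- rep(seq_len(w), each = h)
  idx <- matrix(0L, h * w, 9L)
  k <- 0L
  for (dc in -1:1) for (dr in -1:1) {
    k <- k + 1L
    r2 <- rr + dr; c2 <- cc + dc
    ok <- r2 >= 1 & r2 <= h & c2 >= 1 & c2 <= w
    idx[ok, k] <- (c2[ok] - 1L) * h + r2[ok]
  }
  idx
}

# x: (h*w) x Cin matrix -> patches (h*w) x (9*Cin)
im2col <- function(x, idx) {
  n <- nrow(idx); cin <- ncol(x)
  p <- matrix(0, n, 9L * cin)
  for (k in 1:9) {
    ok <- idx[, k] > 0L
    p[ok, ((k - 1L) * cin + 1L):(k * cin)] <- x[idx[ok, k], , drop = FALSE]
  }
  p
}

# scatter-add of patch gradients back onto the input grid
col2im <- function(dp, idx, cin) {
  dx <- matrix(0, nrow(idx), cin)
  for (k in 1:9) {
    ok <- idx[, k] > 0L
    if (!any(ok)) next
    blk <- dp[ok, ((k - 1L) * cin + 1L):(k * cin), drop = FALSE]
    acc <- rowsum(blk, idx[ok, k])
    tgt <- as.integer(rownames(acc))
    dx[tgt, ] <- dx[tgt, , drop = FALSE] + acc
  }
  dx
}

conv3_fwd <- function(x, W, b, idx) {
  p <- im2col(x, idx)
  list(y = sweep(p %*% W, 2, b, "+"), p = p)
}

conv3_bwd <- function(dy, p, W, idx, cin) {
  list(dW = crossprod(p, dy), db = colSums(dy),
       dx = col2im(dy %*% t(W), idx, cin))
}

# 2x2 max pool on channel matrices; x is (h*w) x C for an h x w grid.
pool_fwd <- function(x, h, w) {
  h2 <- h %/% 2L; w2 <- w %/% 2L
  rr <- rep(seq_len(h2), w2) * 2L - 1L
  cc <- rep(seq_len(w2), each = h2) * 2L - 1L
  base <- (cc - 1L) * h + rr
  cand <- cbind(base, base + 1L, base + h, base + h + 1L)
  y <- matrix(0, h2 * w2, ncol(x))
  amax <- matrix(0L, h2 * w2, ncol(x))
  for (ch in seq_len(ncol(x))) {
    vals <- matrix(x[cand, ch], ncol = 4L)
    wmax <- max.col(vals, ties.method = "first")
    amax[, ch] <- cand[cbind(seq_len(nrow(cand)), wmax)]
    y[, ch] <- vals[cbind(seq_len(nrow(vals)), wmax)]
  }
  list(y = y, amax = amax)
}

pool_bwd <- function(dy, amax, n_in) {
  dx <- matrix(0, n_in, ncol(dy))
  for (ch in seq_len(ncol(dy))) {
    acc <- rowsum(dy[, ch], amax[, ch])
    dx[as.integer(rownames(acc)), ch] <- acc
  }
  dx
}

# nearest x2 upsampling index: maps fine pixels to coarse parents
upsample_index <- function(h, w) {
  h2 <- h %/% 2L; w2 <- w %/% 2L
  rr <- rep(seq_len(h), w)
  cc <- rep(seq_len(w), each = h)
  (pmin((cc + 1L) %/% 2L, w2) - 1L) * h2 + pmin((rr + 1L) %/% 2L, h2)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# ---- loss ------------------------------------------------------------------

#' Weighted soft-Dice loss
#'
#' `1 -` the weighted mean over classes of the soft Dice coefficient
#' `(2 sum(p*t) + eps) / (sum(p) + sum(t) + eps)`. Classes with zero mass in
#' both prediction and target are vacuous and excluded from the mean, so the
#' loss is 0 exactly at the one-hot target and 1 when the prediction is
#' one-hot on the wrong class everywhere.
#'
#' @param pred numeric array `(h, w, C)` of per-class probabilities (summing
#'   to 1 per pixel).
#' @param target a [label_mask] (labels `0 .. C-1`) of the same spatial
#'   shape.
#' @param weights positive, finite per-class weights (length `C`).
#' @param eps smoothing term (default `1e-6`).
#' @return non-negative scalar loss.
#' @export
weighted_dice_loss <- function(pred, target, weights = rep(1, dim(pred)[3]),
                               eps = 1e-6) {
  tg <- if (inherits(target, "label_mask")) target$labels else target
  if (!all(dim(pred)[1:2] == dim(tg)))
    stop("dimension error: prediction and target shapes differ")
  nc <- dim(pred)[3]
  if (length(weights) != nc || any(!is.finite(weights)) || any(weights <= 0))
    stop("class weights must be positive and finite")
  num <- den <- wsum <- 0
  for (c in seq_len(nc)) {
    p <- pred[, , c]
    t <- (tg == c - 1L) * 1
    sp <- sum(p); st <- sum(t)
    if (sp == 0 && st == 0) next  # vacuous class
    d <- (2 * sum(p * t) + eps) / (sp + st + eps)
    num <- num + weights[c] * d
    wsum <- wsum + weights[c]
  }
  if (wsum == 0) return(0)
  1 - num / wsum
}

# loss + gradient wrt probabilities, on (n x C) matrices (training internal)
dice_loss_grad <- function(probs, tonehot, weights, eps = 1e-6) {
  nc <- ncol(probs)
  loss_terms <- numeric(0); wuse <- numeric(0)
  grad <- matrix(0, nrow(probs), nc)
  active <- integer(0)
  for (c in seq_len(nc)) {
    sp <- sum(probs[, c]); st <- sum(tonehot[, c])
    if (sp == 0 && st == 0) next
    active <- c(active, c)
  }
  wsum <- sum(weights[active])
  loss <- 1
  if (wsum > 0) {
    acc <- 0
    for (c in active) {
      p <- probs[, c]; t <- tonehot[, c]
      sp <- sum(p); st <- sum(t); spt <- sum(p * t)
      den <- sp + st + eps
      d <- (2 * spt + eps) / den
      acc <- acc + weights[c] * d
      # d d/dp_i = (2 t_i * den - (2 spt + eps)) / den^2
      grad[, c] <- -(weights[c] / wsum) * (2 * t * den - (2 * spt + eps)) / den^2
    }
    loss <- 1 - acc / wsum
  }
  list(loss = loss, grad = grad)
}

# ---- augmentations ---------------------------------------------------------

#' Boundary-aware random erasing
#'
#' Erases rectangular patches (filled with the image's background level,
#' taken as its 10th-percentile intensity) whose centres are sampled
#' preferentially from aponeurosis (label-1) pixels, emulating the
#' band gaps the refinement stage must repair; labels under the erased
#' patches are cleared too. Deterministic under `seed`.
#'
#' @param image a [us_image].
#' @param mask a [label_mask] aligned to it.
#' @param rate erasing intensity in `[0, 1]`: `ceiling(rate * 4)` patches;
#'   0 is a no-op.
#' @param seed integer RNG seed.
#' @param patch_range patch side range in px (default `c(4, 32)`).
#' @return list: `image`, `mask`.
#' @export
boundary_aware_random_erasing <- function(image, mask, rate, seed = 1L,
                                          patch_range = c(4, 32)) {
  if (rate < 0 || rate > 1) stop("parameter error: rate must be in [0, 1]")
  if (rate == 0) return(list(image = image, mask = mask))
  px <- image$pixels; lb <- mask$labels
  h <- nrow(px); w <- ncol(px)
  bg <- quantile(px, 0.1, names = FALSE)
  band <- which(lb == 1L)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv), add = TRUE)
  set.seed(seed)
  n_patch <- ceiling(rate * 4)
  for (i in seq_len(n_patch)) {
    on_band <- length(band) > 0 && (i == 1L || runif(1) < 0.8)
    ctr <- if (on_band) band[sample.int(length(band), 1L)]
           else sample.int(h * w, 1L)
    cr <- ((ctr - 1L) %% h) + 1L
    cc <- ((ctr - 1L) %/% h) + 1L
    sh <- sample(patch_range[1]:patch_range[2], 1L)
    sw <- sample(patch_range[1]:patch_range[2], 1L)
    rr <- clamp(seq(cr - sh %/% 2, length.out = sh), 1, h)
    cc2 <- clamp(seq(cc - sw %/% 2, length.out = sw), 1, w)
    px[rr, cc2] <- bg
    lb[rr, cc2] <- 0L
  }
  list(image = us_image(px, image$spacing_mm, image$muscle),
       mask = label_mask(lb))
}

# joint geometric transforms used during training (same op on image + mask)
flip_vertical <- function(m) m[rev(seq_len(nrow(m))), , drop = FALSE]

rotate_nearest <- function(m, angle_deg, fill = 0) {
  h <- nrow(m); w <- ncol(m)
  th <- angle_deg * pi / 180
  cr <- (h + 1) / 2; cc <- (w + 1) / 2
  rr <- rep(seq_len(h), w) - cr
  cc2 <- rep(seq_len(w), each = h) - cc
  sr <- round(cos(th) * rr - sin(th) * cc2 + cr)
  sc <- round(sin(th) * rr + cos(th) * cc2 + cc)
  out <- matrix(fill, h, w)
  ok <- sr >= 1 & sr <= h & sc >= 1 & sc <= w
  out[cbind(rep(seq_len(h), w)[ok], rep(seq_len(w), each = h)[ok])] <-
    m[cbind(sr[ok], sc[ok])]
  out
}

scale_nearest <- function(m, factor, fill = 0) {
  h <- nrow(m); w <- ncol(m)
  cr <- (h + 1) / 2; cc <- (w + 1) / 2
  sr <- round((seq_len(h) - cr) / factor + cr)
  sc <- round((seq_len(w) - cc) / factor + cc)
  out <- matrix(fill, h, w)
  rok <- sr >= 1 & sr <= h; cok <- sc >= 1 & sc <= w
  out[rok, cok] <- m[sr[rok], sc[cok], drop = FALSE]
  out
}

# ---- model -----------------------------------------------------------------

#' Training configuration for the attention U-Net
#'
#' Defaults follow the published recipe (256 x 256 inputs, 300 epochs, batch
#' size 8, Adam with stepwise learning-rate decay, weighted Dice loss);
#' `width` and `input_size` are deliberately configurable so smoke-scale
#' training runs on CPU.
#'
#' @param input_size square input side in px (default 256).
#' @param epochs training epochs (default 300).
#' @param batch_size minibatch size (default 8).
#' @param lr initial Adam learning rate.
#' @param lr_decay_at fractions of `epochs` at which the learning rate drops
#'   by `lr_decay_factor` (default 60% and 85%).
#' @param lr_decay_factor stepwise decay factor (default 0.1).
#' @param width base channel width of the network (default 8; reduced-width).
#' @param n_classes output classes (3: background, aponeurosis, fascia).
#' @param class_weights Dice-loss class weights; `NULL` = inverse class pixel
#'   frequency computed on the training set.
#' @param augment list of augmentation settings:
#'   `vertical_flip` (logical), `rotation` (max degrees, 0 = off), `scaling`
#'   (max relative deviation, 0 = off), `erasing_rate` (0 = off).
#' @param seed RNG seed; training is deterministic given the seed.
#' @return a `train_config` list.
#' @export
train_config <- function(input_size = 256L, epochs = 300L, batch_size = 8L,
                         lr = 5e-3, lr_decay_at = c(0.6, 0.85),
                         lr_decay_factor = 0.1, width = 8L, n_classes = 3L,
                         class_weights = NULL,
                         augment = list(vertical_flip = FALSE, rotation = 0,
                                        scaling = 0, erasing_rate = 0),
                         seed = 1L) {
  if (!is.null(class_weights) &&
      (any(!is.finite(class_weights)) || any(class_weights <= 0)))
    stop("class weights must be positive and finite")
  structure(list(input_size = as.integer(input_size),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 lr_decay_at = lr_decay_at,
                 lr_decay_factor = lr_decay_factor,
                 width = as.integer(width), n_classes = as.integer(n_classes),
                 class_weights = class_weights, augment = augment,
                 seed = as.integer(seed)),
            class = "train_config")
}

init_params <- function(width, n_classes) {
  c1 <- width
  he <- function(fanin, nout) matrix(rnorm(fanin * nout, sd = sqrt(2 / fanin)),
                                     fanin, nout)
  list(W1 = he(9, c1), b1 = rep(0, c1),
       W2 = he(9 * c1, c1), b2 = rep(0, c1),
       W3 = he(9 * c1, 2 * c1), b3 = rep(0, 2 * c1),
       W4 = he(18 * c1, 2 * c1), b4 = rep(0, 2 * c1),
       Wg = he(2 * c1, c1), Wx = he(c1, c1), bg = rep(0, c1),
       Wpsi = he(c1, 1), bpsi = 0,
       W5 = he(27 * c1, c1), b5 = rep(0, c1),
       W6 = he(9 * c1, c1), b6 = rep(0, c1),
       Wo = he(c1, n_classes), bo = rep(0, n_classes))
}

# Full forward pass; x is (h*w) x 1, grids precomputed in `gr`.
unet_forward <- function(x, pm, gr) {
  s <- list(x = x)
  o1 <- conv3_fwd(x, pm$W1, pm$b1, gr$idx1); s$p1 <- o1$p
  s$a1 <- pmax(o1$y, 0)
  o2 <- conv3_fwd(s$a1, pm$W2, pm$b2, gr$idx1); s$p2 <- o2$p
  s$e1 <- pmax(o2$y, 0)
  pl <- pool_fwd(s$e1, gr$h, gr$w); s$pool <- pl$y; s$amax <- pl$amax
  o3 <- conv3_fwd(s$pool, pm$W3, pm$b3, gr$idx2); s$p3 <- o3$p
  s$a3 <- pmax(o3$y, 0)
  o4 <- conv3_fwd(s$a3, pm$W4, pm$b4, gr$idx2); s$p4 <- o4$p
  s$e2 <- pmax(o4$y, 0)
  s$g <- s$e2[gr$upidx, , drop = FALSE]
  s$agpre <- sweep(s$g %*% pm$Wg + s$e1 %*% pm$Wx, 2, pm$bg, "+")
  s$q <- pmax(s$agpre, 0)
  s$psi <- s$q %*% pm$Wpsi + pm$bpsi
  s$att <- sigmoid(s$psi)
  s$xatt <- s$e1 * as.numeric(s$att)
  s$cat <- cbind(s$g, s$xatt)
  o5 <- conv3_fwd(s$cat, pm$W5, pm$b5, gr$idx1); s$p5 <- o5$p
  s$a5 <- pmax(o5$y, 0)
  o6 <- conv3_fwd(s$a5, pm$W6, pm$b6, gr$idx1); s$p6 <- o6$p
  s$d1 <- pmax(o6$y, 0)
  s$logits <- sweep(s$d1 %*% pm$Wo, 2, pm$bo, "+")
  zmax <- apply(s$logits, 1, max)
  ez <- exp(s$logits - zmax)
  s$probs <- ez / rowSums(ez)
  s
}

unet_backward <- function(s, pm, gr, dprobs) {
  c1 <- ncol(pm$W1)
  # softmax
  dlog <- s$probs * (dprobs - rowSums(dprobs * s$probs))
  g <- list()
  g$Wo <- crossprod(s$d1, dlog); g$bo <- colSums(dlog)
  dd1 <- dlog %*% t(pm$Wo)
  dd1[s$d1 <= 0] <- 0
  b6 <- conv3_bwd(dd1, s$p6, pm$W6, gr$idx1, c1)
  g$W6 <- b6$dW; g$b6 <- b6$db
  da5 <- b6$dx; da5[s$a5 <= 0] <- 0
  b5 <- conv3_bwd(da5, s$p5, pm$W5, gr$idx1, 3L * c1)
  g$W5 <- b5$dW; g$b5 <- b5$db
  dcat <- b5$dx
  dg <- dcat[, 1:(2 * c1), drop = FALSE]
  dxatt <- dcat[, (2 * c1 + 1):(3 * c1), drop = FALSE]
  de1 <- dxatt * as.numeric(s$att)
  datt <- rowSums(dxatt * s$e1)
  dpsi <- datt * as.numeric(s$att) * (1 - as.numeric(s$att))
  g$Wpsi <- crossprod(s$q, dpsi); g$bpsi <- sum(dpsi)
  dq <- dpsi %*% t(pm$Wpsi)
  dq[s$agpre <= 0] <- 0
  g$Wg <- crossprod(s$g, dq); g$Wx <- crossprod(s$e1, dq); g$bg <- colSums(dq)
  dg <- dg + dq %*% t(pm$Wg)
  de1 <- de1 + dq %*% t(pm$Wx)
  # upsample backward: scatter-add fine grads to coarse
  de2 <- rowsum(dg, gr$upidx)
  de2 <- de2[order(as.integer(rownames(de2))), , drop = FALSE]
  de2[s$e2 <= 0] <- 0
  b4 <- conv3_bwd(de2, s$p4, pm$W4, gr$idx2, 2L * c1)
  g$W4 <- b4$dW; g$b4 <- b4$db
  da3 <- b4$dx; da3[s$a3 <= 0] <- 0
  b3 <- conv3_bwd(da3, s$p3, pm$W3, gr$idx2, c1)
  g$W3 <- b3$dW; g$b3 <- b3$db
  de1 <- de1 + pool_bwd(b3$dx, s$amax, gr$h * gr$w)
  de1[s$e1 <= 0] <- 0
  b2 <- conv3_bwd(de1, s$p2, pm$W2, gr$idx1, c1)
  g$W2 <- b2$dW; g$b2 <- b2$db
  da1 <- b2$dx; da1[s$a1 <= 0] <- 0
  b1 <- conv3_bwd(da1, s$p1, pm$W1, gr$idx1, 1L)
  g$W1 <- b1$dW; g$b1 <- b1$db
  g
}

make_grids <- function(n) {
  list(h = n, w = n, idx1 = im2col_index(n, n),
       idx2 = im2col_index(n %/% 2L, n %/% 2L),
       upidx = upsample_index(n, n))
}

#' Train the attention U-Net
#'
#' Trains on image/mask pairs with the weighted soft-Dice loss and Adam;
#' the learning rate drops stepwise at the configured fractions of the epoch
#' budget. Images are resized to `input_size` (bilinear; masks nearest) and
#' intensities scaled to `[0, 1]`. Class weights default to inverse class
#' pixel frequency on the training set. The per-epoch mean loss is logged in
#' the returned model.
#'
#' @param images list of [us_image]s (>= 1).
#' @param masks list of aligned [label_mask]s.
#' @param config a [train_config()].
#' @return object of class `attention_unet`: `params`, `config`,
#'   `loss_log` (per-epoch mean loss).
#' @export
train_segnet <- function(images, masks, config = train_config()) {
  if (!length(images) || length(images) != length(masks))
    stop("data error: need a non-empty matched set of images and masks")
  n <- config$input_size
  gr <- make_grids(n)
  nc <- config$n_classes
  xs <- lapply(images, function(im)
    resize_matrix(im$pixels, n, n, "bilinear") / 255)
  ys <- lapply(masks, function(mk) {
    lb <- resize_matrix(mk$labels, n, n, "nearest")
    oh <- matrix(0, n * n, nc)
    oh[cbind(seq_len(n * n), as.integer(lb) + 1L)] <- 1
    oh
  })
  wts <- config$class_weights
  if (is.null(wts)) {
    freq <- Reduce(`+`, lapply(ys, colSums))
    wts <- ifelse(freq > 0, 1 / pmax(freq, 1), 0)
    if (all(wts == 0)) wts <- rep(1, nc)
    wts <- wts / sum(wts[wts > 0]) * sum(wts > 0)
    wts[wts == 0] <- min(wts[wts > 0]) * 1e-3  # keep weights positive/finite
  }

  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv), add = TRUE)
  set.seed(config$seed)
  pm <- init_params(config$width, nc)
  mstate <- lapply(pm, function(p) p * 0)
  vstate <- lapply(pm, function(p) p * 0)
  beta1 <- 0.9; beta2 <- 0.999; epsA <- 1e-8
  step <- 0L
  drop_epochs <- ceiling(config$lr_decay_at * config$epochs)
  loss_log <- numeric(config$epochs)

  for (ep in seq_len(config$epochs)) {
    lr <- config$lr * config$lr_decay_factor ^ sum(ep > drop_epochs)
    ord <- sample.int(length(xs))
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    eploss <- 0
    for (bt in batches) {
      grads <- NULL
      bloss <- 0
      for (i in bt) {
        xi <- xs[[i]]; yi <- ys[[i]]
        ag <- config$augment
        if (isTRUE(ag$vertical_flip) && runif(1) < 0.5) {
          xi <- flip_vertical(xi)
          yi <- apply(yi, 2, function(col)
            as.numeric(flip_vertical(matrix(col, n, n))))
        }
        if (!is.null(ag$rotation) && ag$rotation > 0) {
          angle <- runif(1, -ag$rotation, ag$rotation)
          xi <- rotate_nearest(xi, angle)
          yi <- apply(yi, 2, function(col)
            as.numeric(rotate_nearest(matrix(col, n, n))))
          yi[rowSums(yi) == 0, 1] <- 1  # rotated-in corners are background
        }
        if (!is.null(ag$erasing_rate) && ag$erasing_rate > 0) {
          lb <- max.col(yi, ties.method = "first") - 1L
          er <- boundary_aware_random_erasing(
            us_image(matrix(xi * 255, n, n)),
            label_mask(matrix(as.integer(lb), n, n)),
            rate = ag$erasing_rate,
            seed = sample.int(.Machine$integer.max, 1L))
          xi <- er$image$pixels / 255
          lb2 <- er$mask$labels
          yi <- matrix(0, n * n, nc)
          yi[cbind(seq_len(n * n), as.integer(lb2) + 1L)] <- 1
        }
        st <- unet_forward(matrix(as.numeric(xi), ncol = 1), pm, gr)
        lg <- dice_loss_grad(st$probs, yi, wts)
        bloss <- bloss + lg$loss
        gi <- unet_backward(st, pm, gr, lg$grad)
        grads <- if (is.null(grads)) gi
                 else Map(`+`, grads, gi)
      }
      grads <- lapply(grads, function(g) g / length(bt))
      step <- step + 1L
      for (nm in names(pm)) {
        mstate[[nm]] <- beta1 * mstate[[nm]] + (1 - beta1) * grads[[nm]]
        vstate[[nm]] <- beta2 * vstate[[nm]] + (1 - beta2) * grads[[nm]]^2
        mh <- mstate[[nm]] / (1 - beta1^step)
        vh <- vstate[[nm]] / (1 - beta2^step)
        pm[[nm]] <- pm[[nm]] - lr * mh / (sqrt(vh) + epsA)
      }
      eploss <- eploss + bloss / length(bt)
    }
    loss_log[ep] <- eploss / length(batches)
  }
  structure(list(params = pm, config = config, loss_log = loss_log),
            class = "attention_unet")
}

#' @export
print.attention_unet <- function(x, ...) {
  cat(sprintf("<attention_unet> width %d, input %d px, %d epochs trained, final loss %.4f\n",
              x$config$width, x$config$input_size, length(x$loss_log),
              tail(x$loss_log, 1)))
  invisible(x)
}

#' Per-class probability grid for one image
#'
#' @param model a trained `attention_unet`.
#' @param image a [us_image].
#' @return numeric array `(input_size, input_size, n_classes)`.
#' @export
predict_probs <- function(model, image) {
  if (!inherits(model, "attention_unet")) stop("state error: model not trained/loaded")
  n <- model$config$input_size
  gr <- make_grids(n)
  x <- matrix(as.numeric(resize_matrix(image$pixels, n, n, "bilinear") / 255),
              ncol = 1)
  st <- unet_forward(x, model$params, gr)
  array(st$probs, c(n, n, model$config$n_classes))
}

#' Segment an image with a trained model
#'
#' Argmax over the per-class probabilities (ties resolved to the lowest class
#' index), resized back to the image's native resolution (nearest
#' neighbour).
#'
#' @param model a trained `attention_unet`.
#' @param image a [us_image].
#' @return a [label_mask] at native resolution.
#' @export
predict_segnet <- function(model, image) {
  pr <- predict_probs(model, image)
  n <- dim(pr)[1]
  flat <- matrix(pr, n * n, dim(pr)[3])
  lab <- max.col(flat, ties.method = "first") - 1L
  lab <- matrix(as.integer(lab), n, n)
  h <- nrow(image$pixels); w <- ncol(image$pixels)
  label_mask(resize_matrix(lab, h, w, "nearest"))
}

#' Save / load a trained model
#'
#' Single-file checkpoint (RDS).
#'
#' @param model an `attention_unet`.
#' @param path checkpoint path.
#' @export
save_segnet <- function(model, path) { saveRDS(model, path); invisible(path) }

#' @rdname save_segnet
#' @export
load_segnet <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "attention_unet")) stop("state error: not a model checkpoint")
  m
}
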