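blank_segments <- function() musarch:::make_segments(numeric(0), numeric(0),
                                                     numeric(0), numeric(0))

test_that("CLAHE leaves constant regions constant and flattens stripe histograms", {
  const <- us_image(matrix(128, 120, 160))
  out <- enhance(const)
  expect_true(all(abs(out$pixels - out$pixels[1, 1]) < 1e-6))

  ph <- gcm_phantom(noise = 0.15, seed = 5)
  pair <- refine(ph$mask)
  region <- muscle_region(pair)
  enh <- enhance(ph$image, region)
  rm_ <- musarch:::region_mask(region, nrow(ph$image$pixels),
                               ncol(ph$image$pixels))
  expect_gte(hist_entropy(enh$pixels[rm_]), hist_entropy(ph$image$pixels[rm_]))
  # pixels outside the region untouched
  expect_identical(enh$pixels[!rm_], ph$image$pixels[!rm_])
  expect_error(enhance(ph$image, region, clip_limit = 0), "parameter")
})

test_that("ridge filter responds to lines, not blobs or blank fields", {
  blank <- matrix(0, 80, 80)
  expect_true(all(ridge_filter(blank) == 0))

  line <- matrix(0, 81, 81); line[40:41, 10:70] <- 200
  resp <- ridge_filter(line)
  on_line <- max(resp[40:41, 20:60])
  off_line <- max(resp[c(1:25, 56:81), ])
  expect_gt(on_line / max(off_line, 1e-12), 10)

  blob <- matrix(0, 81, 81)
  rr <- row(blob) - 41; cc <- col(blob) - 41
  blob[rr^2 + cc^2 <= 16] <- 200
  expect_gt(max(ridge_filter(line, normalize = FALSE)),
            max(ridge_filter(blob, normalize = FALSE)))
})

test_that("2-means binarisation splits bimodal responses deterministically", {
  resp <- matrix(0.1, 40, 40); resp[15:25, ] <- 0.9
  bin <- binarize_kmeans(resp)
  expect_identical(bin$labels == 1L, resp == 0.9)
  expect_identical(binarize_kmeans(resp)$labels, bin$labels)
  expect_warning(b0 <- binarize_kmeans(matrix(0.5, 10, 10)), "constant")
  expect_equal(sum(b0$labels), 0)
})

test_that("binarised phantom stripes recall the true stripe pixels", {
  ph <- gcm_phantom(noise = 0.1, seed = 11)
  pair <- refine(ph$mask)
  region <- muscle_region(pair)
  enh <- enhance(ph$image, region)
  resp <- ridge_filter(enh)
  rm_ <- musarch:::region_mask(region, nrow(resp), ncol(resp))
  resp[!rm_] <- 0
  bin <- binarize_kmeans(resp)
  truth <- ph$truth$stripes & rm_
  recall <- sum(bin$labels == 1L & truth) / sum(truth)
  expect_gte(recall, 0.8)
})

test_that("small-structure pruning matches a flood-fill census", {
  m <- matrix(0L, 40, 60)
  m[5:6, 5:6] <- 1L          # 4 px
  m[15:17, 10:20] <- 1L      # 33 px
  m[30:30, 40:44] <- 1L      # 5 px
  m[25:28, 50:58] <- 1L      # 36 px
  expect_identical(prune_small(label_mask(m), 1)$labels, m)
  pruned <- prune_small(label_mask(m), 10)
  cs <- connected_components(pruned)
  expect_length(cs$components, 2)
  expect_true(all(vapply(cs$components, `[[`, numeric(1), "area") >= 10))
  expect_equal(sum(prune_small(label_mask(m), 100)$labels), 0)
})

test_that("segment fitting recovers orientations of staircases and stripes", {
  # exact 45-degree staircase (descending to the right)
  st <- matrix(0L, 40, 40)
  for (i in 1:30) st[5 + i, 5 + i] <- 1L
  seg <- fit_segments(label_mask(st))
  expect_equal(nrow(seg), 1)
  expect_lt(abs(seg$orientation - 45), 0.5)

  # horizontal 1-px line, length 30
  hl <- matrix(0L, 20, 40); hl[10, 6:35] <- 1L
  seg2 <- fit_segments(label_mask(hl))
  expect_equal(seg2$orientation, 0, tolerance = 1e-6)
  expect_lt(abs(seg2$length - 29), 1.5)

  # phantom stripes at a known angle, after the real preprocessing chain
  ph <- gcm_phantom(angle = 22, noise = 0.1, seed = 2)
  pair <- refine(ph$mask)
  region <- muscle_region(pair)
  resp <- ridge_filter(enhance(ph$image, region))
  rm_ <- musarch:::region_mask(region, nrow(resp), ncol(resp))
  resp[!rm_] <- 0
  segs <- fit_segments(prune_small(binarize_kmeans(resp), 30))
  main <- segs[segs$length > 50, ]
  expect_gt(nrow(main), 3)
  expect_true(all(abs(main$orientation - 22) < 2))
})

test_that("merge criteria counting follows the two-of-three rule", {
  # collinear gently descending pieces, left one upper-left: merged
  a <- musarch:::make_segments(10, 40, 60, 43)
  b <- musarch:::make_segments(80, 44.2, 130, 47.2)
  m <- merge_collinear(rbind(a, b), width = 200, height = 100)
  expect_equal(nrow(m), 1)
  expect_gt(m$length, 100)

  # parallel segments 50 px apart vertically, same orientation, same
  # columns: only the orientation criterion holds -> not merged
  c1 <- musarch:::make_segments(10, 20, 60, 20)
  c2 <- musarch:::make_segments(10, 70, 60, 70)
  expect_equal(nrow(merge_collinear(rbind(c1, c2), 200, 100)), 2)

  # orientation difference exactly 5 degrees (strict) and intersection
  # outside the image: not merged
  d1 <- musarch:::make_segments(10, 50, 60, 50)
  ang <- 5 * pi / 180
  d2 <- musarch:::make_segments(10, 20, 10 + 50 * cos(ang), 20 - 50 * sin(ang))
  expect_equal(musarch:::angle_diff(d1$orientation, d2$orientation), 5,
               tolerance = 1e-9)
  mm <- merge_collinear(rbind(d1, d2), width = 80, height = 100)
  expect_equal(nrow(mm), 2)
})

test_that("dominant orientation picks the largest total length, not count", {
  many_short <- do.call(rbind, lapply(1:3, function(i)
    musarch:::make_segments(10 * i, 100, 10 * i + 10 * cos(25 * pi / 180),
                            100 + 10 * sin(25 * pi / 180))))
  one_long <- musarch:::make_segments(50, 20, 50 + 100 * cos(70 * pi / 180),
                                      20 + 100 * sin(70 * pi / 180))
  segs <- rbind(many_short, one_long)
  dom <- dominant_orientation(segs, k_orient = 2)
  expect_equal(dom$dominant_deg, 70, tolerance = 0.5)
  expect_equal(nrow(dom$segments), 1)

  allsame <- do.call(rbind, lapply(1:4, function(i)
    musarch:::make_segments(5 * i, 50, 5 * i + 20 * cos(30 * pi / 180),
                            50 + 20 * sin(30 * pi / 180))))
  dom2 <- dominant_orientation(allsame, k_orient = 3)
  expect_equal(dom2$dominant_deg, 30, tolerance = 0.5)

  dom3 <- dominant_orientation(segs, k_orient = 1)
  expect_equal(nrow(dom3$segments), 4)
  expect_equal(dom3$dominant_deg,
               sum(segs$orientation * segs$length) / sum(segs$length),
               tolerance = 1e-9)
})

test_that("extension clips to the region and pruning removes the outlier line", {
  region <- list(cols = 1:200, sup = rep(20, 200), deep = rep(120, 200))
  # parallel lines: all retained
  par <- do.call(rbind, lapply(c(40, 90, 140), function(x0)
    musarch:::make_segments(x0, 60, x0 + 30 * cos(20 * pi / 180),
                            60 + 30 * sin(20 * pi / 180))))
  ep <- extend_and_prune(par, region)
  expect_equal(nrow(ep$lines), 3)
  expect_equal(ep$dropped, 0)
  # every extended endpoint sits on the region boundary (a curve or a side)
  on_boundary <- function(x, y)
    abs(y - 20) < 1 || abs(y - 120) < 1 || x < 2 || x > 199
  for (i in 1:3) {
    expect_true(on_boundary(ep$lines$x1[i], ep$lines$y1[i]))
    expect_true(on_boundary(ep$lines$x2[i], ep$lines$y2[i]))
  }

  # 30, 31, 80 degrees; the 80-degree line crosses both -> deleted
  mk <- function(x0, y0, ang, len = 40)
    musarch:::make_segments(x0, y0, x0 + len * cos(ang * pi / 180),
                            y0 + len * sin(ang * pi / 180))
  trio <- rbind(mk(40, 40, 30), mk(110, 40, 31), mk(95, 30, 80))
  ep2 <- extend_and_prune(trio, region)
  expect_equal(nrow(ep2$lines), 2)
  expect_equal(ep2$dropped, 1)
  expect_true(all(ep2$lines$orientation < 40))
})

test_that("extracted fascicle lines never intersect inside the muscle", {
  ph <- gcm_phantom(angle = 26, noise = 0.2, seed = 17)
  pair <- refine(ph$mask)
  fs <- extract_fascicles(ph$image, pair, muscle = "GCM")
  expect_equal(fs$status, "ok")
  ln <- fs$lines
  if (nrow(ln) >= 2) {
    for (i in 1:(nrow(ln) - 1)) for (j in (i + 1):nrow(ln))
      expect_false(musarch:::seg_interior_intersection(ln[i, ], ln[j, ],
                                                       fs$region))
  }
})

test_that("BB extraction round-trips through the horizontal flip", {
  # BB-style phantom: fascicles ascend to the right in the original frame,
  # i.e. the mirrored image of the canonical descending pattern
  ph <- gcm_phantom(angle = 20, noise = 0.1, seed = 9)
  flip_px <- ph$image$pixels[, rev(seq_len(ncol(ph$image$pixels)))]
  img_bb <- us_image(flip_px, 0.1, "BB")
  mask_bb <- label_mask(ph$mask$labels[, rev(seq_len(ncol(ph$mask$labels)))])
  pair_bb <- refine(mask_bb)
  fs <- extract_fascicles(img_bb, pair_bb, muscle = "BB")
  expect_equal(fs$status, "ok")
  # output coordinates are in the unflipped (original BB) frame:
  # orientations are mirrored, around 180 - 20
  expect_lt(abs(fs$dominant_orientation_deg - 160), 2)
  w <- ncol(flip_px)
  expect_true(all(fs$lines$x1 >= 1 & fs$lines$x1 <= w))
  # pennation angle agrees with the unflipped run
  # pixel-level mirror equivariance: thinning asymmetry bounds agreement at
  # a few hundredths of a degree, not floating-point accuracy
  pa_bb <- pennation_angle(fs, pair_bb)
  pair0 <- refine(ph$mask)
  fs0 <- extract_fascicles(ph$image, pair0, muscle = "GCM")
  pa0 <- pennation_angle(fs0, pair0)
  expect_lt(abs(pa_bb$theta_deg - pa0$theta_deg), 0.05)
})

test_that("blank inner regions yield an empty set with no-fascicles status", {
  w <- 256L; h <- 200L
  img <- matrix(30, h, w)
  img[38:42, ] <- 230; img[118:122, ] <- 230
  mask <- matrix(0L, h, w); mask[38:42, ] <- 1L; mask[118:122, ] <- 1L
  pair <- refine(label_mask(mask))
  fs <- extract_fascicles(us_image(img, 0.1), pair, muscle = "GCM")
  expect_equal(fs$status, "no_fascicles")
  expect_equal(nrow(fs$segments), 0)
})

test_that("fascicle sets export to CSV and overlay PNG", {
  ph <- gcm_phantom(angle = 22, noise = 0.15, seed = 2, width = 300L,
                    height = 280L)
  pair <- refine(ph$mask)
  fs <- extract_fascicles(ph$image, pair, muscle = "GCM")
  cp <- file.path(tempdir(), "fs.csv")
  write_fascicles_csv(fs, cp)
  df <- read.csv(cp)
  expect_equal(nrow(df), nrow(fs$lines))
  expect_true(all(c("orientation", "length") %in% names(df)))
  op <- file.path(tempdir(), "fs.png")
  write_overlay_png(ph$image, fs, op)
  arr <- png::readPNG(op)
  expect_equal(dim(arr)[3], 3)
  # yellow pixels (R = G = 1, B = 0) from the extended lines are present
  expect_gt(sum(arr[, , 1] == 1 & arr[, , 2] == 1 & arr[, , 3] == 0), 50)
  unlink(c(cp, op))
})

test_that("angle recovery RMSE over the 50-phantom suite is at most 2.22 degrees", {
  specs <- phantom_suite_pennation(0:49)
  err <- vapply(specs, function(sp) {
    ph <- generate_phantom(sp)
    pair <- refine(ph$mask)
    fs <- extract_fascicles(ph$image, pair, muscle = "GCM")
    if (fs$status != "ok") return(NA_real_)
    pennation_angle(fs, pair)$theta_deg - sp$fascicle_angle_deg
  }, numeric(1))
  expect_false(anyNA(err))
  expect_lte(sqrt(mean(err^2)), 2.22)
})
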