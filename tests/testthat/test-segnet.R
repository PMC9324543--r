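test_that("weighted dice loss matches hand expansions at its extremes", {
  # perfect one-hot prediction
  tg <- label_mask(matrix(c(0L, 1L, 1L, 0L), 2, 2))
  pred <- array(0, c(2, 2, 3))
  pred[, , 1] <- (tg$labels == 0L) * 1
  pred[, , 2] <- (tg$labels == 1L) * 1
  expect_equal(weighted_dice_loss(pred, tg), 0, tolerance = 1e-5)

  # one-hot on the wrong class everywhere
  wrong <- array(0, c(2, 2, 3))
  wrong[, , 1] <- (tg$labels == 1L) * 1
  wrong[, , 2] <- (tg$labels == 0L) * 1
  expect_equal(weighted_dice_loss(wrong, tg), 1, tolerance = 1e-5)

  # 2x2 single-class toy, one pixel wrong: hand-expanded soft Dice
  tg2 <- label_mask(matrix(1L, 2, 2))
  p2 <- array(0, c(2, 2, 2))
  p2[, , 2] <- 1; p2[1, 1, 2] <- 0; p2[1, 1, 1] <- 1
  eps <- 1e-6
  d1 <- (2 * 3 + eps) / (3 + 4 + eps)   # class 1 overlap
  d0 <- (2 * 0 + eps) / (1 + 0 + eps)   # class 0: predicted only
  expect_equal(weighted_dice_loss(p2, tg2), 1 - (d0 + d1) / 2,
               tolerance = 1e-12)

  expect_error(weighted_dice_loss(array(0.5, c(3, 3, 2)),
                                  label_mask(matrix(0L, 2, 2))),
               "dimension")
  expect_error(weighted_dice_loss(p2, tg2, weights = c(1, -1)), "positive")
})

test_that("dice loss stays within [0, 1] for normalised probability grids", {
  set.seed(5)
  for (i in 1:10) {
    z <- array(rexp(4 * 4 * 3), c(4, 4, 3))
    s <- z[, , 1] + z[, , 2] + z[, , 3]
    for (c in 1:3) z[, , c] <- z[, , c] / s
    tg <- label_mask(matrix(sample(0:2, 16, replace = TRUE), 4, 4))
    l <- weighted_dice_loss(z, tg, weights = runif(3, 0.5, 2))
    expect_gte(l, 0); expect_lte(l, 1)
  }
})

test_that("boundary-aware random erasing honours its contracts", {
  ph <- flat_phantom(noise = 0.1, seed = 2)
  # rate 0: exact no-op
  e0 <- boundary_aware_random_erasing(ph$image, ph$mask, rate = 0)
  expect_identical(e0$image$pixels, ph$image$pixels)
  expect_identical(e0$mask$labels, ph$mask$labels)

  # rate 1: at least one erased patch intersects the aponeurosis band
  e1 <- boundary_aware_random_erasing(ph$image, ph$mask, rate = 1, seed = 4)
  cleared <- ph$mask$labels == 1L & e1$mask$labels == 0L
  expect_gt(sum(cleared), 0)

  # determinism under a fixed seed
  e2 <- boundary_aware_random_erasing(ph$image, ph$mask, rate = 0.5, seed = 9)
  e3 <- boundary_aware_random_erasing(ph$image, ph$mask, rate = 0.5, seed = 9)
  expect_identical(e2$image$pixels, e3$image$pixels)
  expect_identical(e2$mask$labels, e3$mask$labels)

  expect_error(boundary_aware_random_erasing(ph$image, ph$mask, rate = 1.2),
               "parameter")
})

test_that("geometric augmentations keep image and mask aligned", {
  # a phantom flipped vertically equals the phantom built with mirrored
  # geometry: the aponeurosis masks must agree exactly (Dice 1)
  h <- 161L
  mk <- function(sup_row, deep_row) generate_phantom(phantom_spec(
    width_px = 120L, height_px = h, pixel_spacing_mm = 0.1,
    superficial_curve = c(sup_row, 0, 0), deep_curve = c(deep_row, 0, 0),
    fascicle_angle_deg = 20))
  a <- mk(40, 120)
  b <- mk(h + 1 - 120, h + 1 - 40)
  flipped <- musarch:::flip_vertical(a$mask$labels)
  expect_equal(dice_iou(label_mask(flipped), b$mask)[["dice"]], 1)

  # the same nearest-neighbour rotation applied to image and mask moves
  # foreground pixels to identical places
  rotm <- musarch:::rotate_nearest(a$mask$labels, 7)
  roti <- musarch:::rotate_nearest(a$image$pixels, 7)
  expect_true(all(roti[rotm == 1L] == 230))
})

test_that("a zero-weight model predicts background everywhere (tie-break contract)", {
  cfg <- train_config(input_size = 32L, width = 4L, epochs = 1L)
  set.seed(1)
  pm <- musarch:::init_params(cfg$width, cfg$n_classes)
  for (nm in names(pm)) pm[[nm]] <- pm[[nm]] * 0
  model <- structure(list(params = pm, config = cfg, loss_log = 0),
                     class = "attention_unet")
  img <- us_image(matrix(runif(48 * 40, 0, 255), 48, 40))
  pr <- predict_probs(model, img)
  expect_true(all(abs(pr - 1 / 3) < 1e-12))  # exact three-way tie
  mask <- predict_segnet(model, img)
  expect_true(all(mask$labels == 0L))        # lowest class index wins
  expect_equal(dim(mask$labels), dim(img$pixels))
  expect_error(predict_probs(list(), img), "state error")
})

test_that("short training runs reduce the loss and are seed-deterministic", {
  phs <- lapply(1:2, function(s) generate_phantom(phantom_spec(
    width_px = 48L, height_px = 48L, pixel_spacing_mm = 0.3,
    superficial_curve = c(12, 0, 0), deep_curve = c(36, 0, 0),
    fascicle_angle_deg = 20 + 5 * s, band_px = 5L, noise_level = 0.1,
    seed = s)))
  imgs <- lapply(phs, `[[`, "image")
  msks <- lapply(phs, `[[`, "mask")
  cfg <- train_config(input_size = 48L, epochs = 30L, batch_size = 2L,
                      width = 4L, lr = 5e-3, seed = 11L)
  m1 <- train_segnet(imgs, msks, cfg)
  expect_lt(tail(m1$loss_log, 1), m1$loss_log[1])
  m2 <- train_segnet(imgs, msks, cfg)
  expect_identical(m1$loss_log, m2$loss_log)
  expect_identical(m1$params, m2$params)

  expect_error(train_segnet(list(), list(), cfg), "data error")

  # checkpoint round trip
  path <- file.path(tempdir(), "net.rds")
  save_segnet(m1, path)
  m3 <- load_segnet(path)
  expect_identical(m3$params, m1$params)
  unlink(path)
})
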