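fs_with_lines <- function(lines) {
  structure(list(lines = lines, segments = lines,
                 dominant_orientation_deg = NA_real_, status = "ok",
                 flags = character()), class = "fascicle_set")
}

line_at <- function(x0, y0, ang_deg, len = 60)
  musarch:::make_segments(x0, y0, x0 + len * cos(ang_deg * pi / 180),
                          y0 + len * sin(ang_deg * pi / 180))

test_that("pennation angle against flat and sloped deep curves is analytic", {
  w <- 300
  pair <- apo_pair(rep(40, w), rep(200, w), width = w, height = 300)
  # fascicle descending at 20 degrees onto a horizontal deep curve
  pa <- pennation_angle(fs_with_lines(line_at(50, 100, 20, 120)), pair)
  expect_equal(pa$theta_deg, 20, tolerance = 1e-6)

  # deep curve at 10 degrees, fascicle at 35 (same sense): difference 25
  x <- 1:w
  pair2 <- apo_pair(rep(20, w), 150 + x * tan(10 * pi / 180), width = w,
                    height = 400)
  pa2 <- pennation_angle(fs_with_lines(line_at(50, 120, 35, 100)), pair2)
  expect_equal(pa2$theta_deg, 25, tolerance = 0.05)

  # fascicle at 170 degrees vs horizontal: acute folding gives 10
  pa3 <- pennation_angle(fs_with_lines(line_at(250, 100, 170, 120)), pair)
  expect_equal(pa3$theta_deg, 10, tolerance = 1e-6)
})

test_that("fascicles meeting the deep curve off-image use its linear extension", {
  w <- 200
  pair <- apo_pair(rep(30, w), rep(120, w), width = w, height = 200)
  # shallow fascicle leaving the image right edge before reaching the curve
  ln <- line_at(150, 60, 8, 45)
  pa <- pennation_angle(fs_with_lines(ln), pair)
  expect_true("aponeurosis_extended" %in% pa$flags)
  expect_equal(pa$theta_deg, 8, tolerance = 0.1)
})

test_that("parallel fascicles are flagged and excluded; all-parallel errors", {
  w <- 300
  pair <- apo_pair(rep(40, w), rep(200, w), width = w, height = 300)
  lines <- rbind(line_at(50, 100, 20, 100), line_at(120, 100, 0.1, 100))
  pa <- pennation_angle(fs_with_lines(lines), pair)
  expect_true("parallel_fascicle" %in% pa$flags)
  expect_equal(pa$theta_deg, 20, tolerance = 1e-6)
  expect_error(pennation_angle(fs_with_lines(line_at(50, 100, 0.1, 100)),
                               pair),
               "parallel")
})

test_that("fascicle length follows LF = d / sin(theta) with its contracts", {
  expect_equal(fascicle_length(10, 30), 20, tolerance = 1e-12)
  expect_equal(fascicle_length(7.3, 90), 7.3, tolerance = 1e-12)
  expect_equal(fascicle_length(8, 23), 8 / sin(23 * pi / 180),
               tolerance = 1e-12)
  expect_error(fascicle_length(10, 0), "undefined-length")
  expect_error(fascicle_length(10, -5), "undefined-length")
  expect_error(fascicle_length(-1, 20), "thickness")
})

test_that("end-to-end phantom report recovers truth within the error budgets", {
  ph <- gcm_phantom(angle = 20, thickness_px = 180, noise = 0.2, seed = 23)
  rep <- measure_image(ph$image, mask = ph$mask, muscle = "GCM",
                       pixel_spacing_mm = 0.1, image_id = "gcm_demo")
  expect_lte(abs(rep$theta_deg - 20), 2.22)
  expect_lte(abs(rep$d_mm - ph$truth$thickness_mm), 0.4)
  # internal consistency of the emitted report
  expect_equal(rep$lf_mm * sin(rep$theta_deg * pi / 180), rep$d_mm,
               tolerance = 1e-9)
})

test_that("a supplied mask bypasses the model with identical results", {
  ph <- gcm_phantom(angle = 24, noise = 0.1, seed = 31)
  r1 <- measure_image(ph$image, mask = ph$mask, muscle = "GCM",
                      pixel_spacing_mm = 0.1)
  r2 <- measure_image(ph$image, mask = ph$mask, muscle = "GCM",
                      pixel_spacing_mm = 0.1)
  expect_identical(r1$d_mm, r2$d_mm)
  expect_identical(r1$theta_deg, r2$theta_deg)
  expect_error(measure_image(ph$image, mask = NULL, model = NULL,
                             pixel_spacing_mm = 0.1),
               "segment")
})

test_that("missing pixel spacing is a unit error and no report is emitted", {
  ph <- flat_phantom()
  img <- us_image(ph$image$pixels)  # spacing stripped
  expect_error(measure_image(img, mask = ph$mask, muscle = "GCM"),
               "unit error")
})

test_that("theta sensitivity bounds the fascicle-length error near small angles", {
  # dLF/dtheta = -d cos(theta) / sin^2(theta): the measured LF error must be
  # within this sensitivity times the theta error (plus the thickness term)
  for (seed in c(3, 13)) {
    ph <- gcm_phantom(angle = 10, thickness_px = 160, noise = 0.2, seed = seed)
    rep <- measure_image(ph$image, mask = ph$mask, muscle = "GCM",
                         pixel_spacing_mm = 0.1)
    tr <- ph$truth
    th_err <- abs(rep$theta_deg - tr$pennation_deg) * pi / 180
    d_err <- abs(rep$d_mm - tr$thickness_mm)
    th_rad <- tr$pennation_deg * pi / 180
    bound <- tr$thickness_mm * cos(th_rad) / sin(th_rad)^2 * th_err +
      d_err / sin(th_rad) + 1e-6
    expect_lte(abs(rep$lf_mm - tr$fascicle_length_mm), bound * 1.25)
  }
})

test_that("reports serialise to JSON and aggregate to CSV", {
  ph <- gcm_phantom(angle = 18, noise = 0.1, seed = 41)
  rep <- measure_image(ph$image, mask = ph$mask, muscle = "GCM",
                       pixel_spacing_mm = 0.1, image_id = "p41")
  jp <- file.path(tempdir(), "rep.json")
  write_report_json(rep, jp)
  back <- jsonlite::read_json(jp)
  expect_equal(back$d_mm, rep$d_mm, tolerance = 1e-12)
  expect_equal(back$image_id, "p41")
  cp <- file.path(tempdir(), "reps.csv")
  df <- reports_to_csv(list(rep, rep), cp)
  expect_equal(nrow(read.csv(cp)), 2)
  unlink(c(jp, cp))
})
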