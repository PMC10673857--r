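test_that("disc visibility follows the ON/OFF isoluminance band", {
  # inside the band a green disc on UV background has no motion contrast
  expect_equal(predict_visibility("green_on_UV", 7, 4.5, 9.2), "invisible")
  expect_equal(predict_visibility("UV_on_green", 7, 4.5, 9.2), "visible")
  expect_equal(predict_visibility("green_on_UV", 0, 4.5, 9.2), "visible")
  expect_equal(predict_visibility("green_on_UV", c(0, 5, 9, 15), 4.5, 9.2),
               c("visible", "invisible", "invisible", "visible"))
  # UV discs on green are visible at every level (the bands overlap)
  expect_true(all(predict_visibility("UV_on_green", 0:15, 4.5, 9.2) ==
                    "visible"))
  expect_error(predict_visibility("green_on_UV", 5, 9, 4), "unsupported regime")
})

test_that("noiseless behavioral simulations have exact zero structure", {
  gt <- ground_truth(i_on = 5, i_off = 9, noise_sd = 0, seed = 3)
  on <- simulate_behavior(gt, "edges_on", uv_levels = c(3, 5, 7))
  sel <- on$meta$uv_level == 5
  expect_true(all(on$traces[sel, ] == 0))  # sigmoid zero at i_on
  # green discs strictly inside the visibility band give zero response
  disc <- simulate_behavior(gt, "disc_green", uv_levels = c(6, 7, 8))
  expect_true(all(abs(disc$traces) < 1e-12))
  # CCW/left trials are sign-inverted copies in the noiseless limit
  off <- simulate_behavior(gt, "edges_off", uv_levels = c(4, 12))
  for (lv in c(4, 12)) {
    cw <- off$traces[off$meta$uv_level == lv & off$meta$rotation == "CW", ]
    ccw <- off$traces[off$meta$uv_level == lv & off$meta$rotation == "CCW", ]
    expect_equal(ccw, -cw)
  }
  expect_error(simulate_behavior(gt, "edges_on", uv_levels = numeric()),
               "empty")
})

test_that("behavioral simulations are bit-identical under a fixed seed", {
  gt <- ground_truth(noise_sd = 0.2, seed = 99)
  a <- simulate_behavior(gt, "edges_compact")
  b <- simulate_behavior(gt, "edges_compact")
  expect_identical(a$traces, b$traces)
  expect_identical(a$meta, b$meta)
})

test_that("the downstream estimator recovers noiseless behavioral truth", {
  gt <- ground_truth(i_on = 4.5, i_off = 9.2, noise_sd = 0, seed = 8)
  on <- fly_isoluminance(simulate_behavior(gt, "edges_on"))
  expect_equal(on$value, 4.5, tolerance = 1e-12)  # symmetric levels 4 and 5
  off <- fly_isoluminance(simulate_behavior(gt, "edges_off"))
  # interpolation through the sigmoid between levels 9 and 10
  expect_equal(off$value, 9.2, tolerance = 0.05)
})

test_that("synthetic movies are reproducible, non-negative and validated", {
  rois <- data.frame(x = c(18, 45), y = c(20, 44),
                     polarity = c("ON", "OFF"), isoluminance = c(5, 8))
  a <- small_movie(rois, jitter_sd = 1.5, noise_sd = 0.02)
  b <- small_movie(rois, jitter_sd = 1.5, noise_sd = 0.02)
  expect_identical(a$frames, b$frames)
  expect_identical(a$jitter, b$jitter)
  expect_true(all(a$frames >= 0))
  expect_true(any(a$jitter$dx != 0))
  # planting blobs closer than a column spacing is refused
  close <- data.frame(x = c(20, 25), y = c(20, 22),
                      polarity = "ON", isoluminance = 5)
  expect_error(small_movie(close), "overlapping blobs")
})

test_that("planted movie isoluminances are recovered by the pipeline", {
  # one ON and one OFF blob, noiseless: recovery to < 0.1 UV levels
  on_mv <- small_movie(data.frame(x = 22, y = 24, polarity = "ON",
                                  isoluminance = 5))
  on_res <- analyze_movie(on_mv, "ON", min_separation = 16)
  expect_equal(nrow(on_res$rois), 1)
  expect_lt(abs(on_res$rois$isoluminance - 5), 0.1)
  off_mv <- small_movie(data.frame(x = 40, y = 30, polarity = "OFF",
                                   isoluminance = 8))
  off_res <- analyze_movie(off_mv, "OFF", min_separation = 16)
  expect_lt(abs(off_res$rois$isoluminance - 8), 0.1)
})

test_that("test images put the requested colors inside the disc", {
  img <- make_test_image(c(120, 160), disc_center = c(80, 60),
                         disc_radius = 30)
  inside <- img[60, 80, ]; outside <- img[10, 10, ]
  expect_gt(inside[1], outside[1])  # warm disc: brighter R channel
  expect_lt(inside[3], outside[3])
  flat <- make_test_image(c(50, 50), disc_center = c(25, 25),
                          disc_radius = 10, disc_rgb = c(9, 9, 9),
                          background_rgb = c(9, 9, 9))
  expect_true(all(flat == 9))
  expect_error(make_test_image(c(50, 50), disc_center = c(45, 25),
                               disc_radius = 10), "fit")
})

test_that("recordings and movies round-trip through their file formats", {
  gt <- ground_truth(n_trials = 2, noise_sd = 0.1, seed = 21)
  rec <- simulate_behavior(gt, "edges_on", uv_levels = c(0, 8, 15))
  csv <- withr::local_tempfile(fileext = ".csv")
  write_wba_csv(rec, csv)
  back <- read_wba_csv(csv)
  expect_equal(back$traces, rec$traces, tolerance = 1e-12)
  expect_equal(back$meta$uv_level, rec$meta$uv_level)
  expect_equal(back$fs, rec$fs)

  mv <- small_movie(data.frame(x = 20, y = 20, polarity = "ON",
                               isoluminance = 5),
                    uv_levels = c(0, 15), image_size = 32,
                    column_spacing = 10, noise_sd = 0.01)
  tif <- withr::local_tempfile(fileext = ".tif")
  write_movie_tiff(mv, tif)
  back <- read_movie_tiff(tif)
  expect_equal(back$frames, mv$frames, tolerance = 1e-6)
  expect_equal(back$trials$uv_level, mv$trials$uv_level)
  expect_equal(back$frame_rate, mv$frame_rate)
})
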