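test_that("the 120 x 104 rasterization puts exactly 9360 pixels per hexagon", {
  img <- make_test_image(c(620, 720), disc_center = c(360, 310),
                         disc_radius = 150)
  lat <- hex_sample(img)
  inner <- lat$sites[lat$sites$interior, ]
  expect_gt(nrow(inner), 0)
  expect_true(all(inner$n_pixels == 9360))  # 0.75 * 120 * 104
  # exhaustive partition: every pixel belongs to exactly one site
  expect_equal(sum(lat$sites$n_pixels), 620 * 720)
  expect_false(any(is.na(lat$assignment)))
})

test_that("site means reproduce constant images and channel structure", {
  flat <- array(42, dim = c(250, 300, 3))
  lat <- hex_sample(flat, hex_width = 60, hex_height = 52)
  expect_true(all(lat$sites$meanR == 42))
  expect_true(all(lat$sites$meanG == 42))
  img <- make_test_image(c(250, 300), disc_center = c(150, 125),
                         disc_radius = 60)
  lat2 <- hex_sample(img, hex_width = 60, hex_height = 52)
  central <- which.min((lat2$sites$x - 150)^2 + (lat2$sites$y - 125)^2)
  far <- which.max((lat2$sites$x - 150)^2 + (lat2$sites$y - 125)^2)
  expect_gt(lat2$sites$meanR[central], lat2$sites$meanR[far])
})

test_that("Weber contrast has the defining values and guards", {
  expect_equal(weber_contrast(100, 100), 0)
  expect_equal(weber_contrast(150, 100), 0.5)
  expect_equal(weber_contrast(50, 100), -0.5)
  expect_error(weber_contrast(50, 0), "undefined contrast")
})

test_that("directional contrasts are zero on flat input and signed at edges", {
  flat <- array(10, dim = c(300, 400, 3))
  lat <- hex_sample(flat, hex_width = 40, hex_height = 34)
  cc <- directional_contrasts(lat)
  vals <- unlist(cc[, c("c_left", "c_up", "c_right", "c_down")])
  expect_true(all(vals[!is.na(vals)] == 0))
  # vertical step edge, bright right half
  step <- array(10, dim = c(300, 400, 3)); step[, 201:400, ] <- 100
  lat2 <- hex_sample(step, hex_width = 40, hex_height = 34)
  c2 <- directional_contrasts(lat2)
  # looking left is toward the dark side (positive contrast somewhere),
  # looking right toward the bright side (negative), never the reverse
  expect_gt(max(c2$c_left, na.rm = TRUE), 0)
  expect_lt(min(c2$c_right, na.rm = TRUE), 0)
  expect_true(all(c2$c_left >= 0, na.rm = TRUE))
  expect_true(all(c2$c_right <= 0, na.rm = TRUE))
  # hand computation at one interior site away from the edge
  s <- lat2$sites
  cand <- which(!is.na(c2$c_right))
  k <- cand[which.min(abs(s$x[cand] - 100) + abs(s$y[cand] - 150))]
  px <- 0.75 * 40; h <- 34
  grab <- function(dx, dy) {
    j <- which(abs(s$x - (s$x[k] + dx)) < 1e-6 &
                 abs(s$y - (s$y[k] + dy)) < 1e-6)
    (s$meanR[j] + s$meanG[j] + s$meanB[j]) / 3
  }
  home <- mean(c(grab(0, 0), grab(0, -h), grab(0, h), grab(px, -h / 2),
                 grab(px, h / 2), grab(-px, -h / 2), grab(-px, h / 2)))
  bg <- mean(c(grab(2 * px, 0), grab(2 * px, -h), grab(2 * px, h)))
  expect_equal(c2$c_right[k], (home - bg) / bg, tolerance = 1e-12)
  expect_equal(directional_contrast(lat2, s$site[k], "right"),
               c2$c_right[k])
})

test_that("radial motion matches the brute-force oracle on toy lattices", {
  set.seed(17)
  img <- array(runif(220 * 260 * 3, 20, 230), dim = c(220, 260, 3))
  lat <- hex_sample(img, hex_width = 28, hex_height = 24)
  for (mode in c("approach", "recede")) {
    est <- radial_motion(lat, c(130, 110), mode,
                         on_weights = c(1, 0, 0), off_weights = c(0, 0, 1))
    orc <- oracle_radial_motion(lat, c(130, 110), mode,
                                c(1, 0, 0), c(0, 0, 1))
    ok <- !is.na(est$combined)
    expect_gt(sum(ok), 20)
    expect_equal(est$combined[ok], orc$combined[ok], tolerance = 1e-10)
    expect_equal(est$on[ok], orc$on[ok], tolerance = 1e-10)
    expect_equal(est$off[ok], orc$off[ok], tolerance = 1e-10)
  }
  # equal weights: the second contrast pass is the shared one
  est_sym <- radial_motion(lat, c(130, 110), "approach")
  orc_sym <- oracle_radial_motion(lat, c(130, 110), "approach",
                                  rep(1, 3) / 3, rep(1, 3) / 3)
  ok <- !is.na(est_sym$combined)
  expect_equal(est_sym$combined[ok], orc_sym$combined[ok], tolerance = 1e-10)
})

test_that("zero-contrast images give exactly zero motion estimates", {
  flat <- array(77, dim = c(300, 400, 3))
  lat <- hex_sample(flat, hex_width = 40, hex_height = 34)
  est <- radial_motion(lat, c(200, 150), "approach",
                       on_weights = c(1, 0, 0), off_weights = c(0, 0, 1))
  ok <- !is.na(est$combined)
  expect_gt(sum(ok), 0)
  expect_true(all(est$combined[ok] == 0))
  expect_true(all(est$on[ok] == 0) && all(est$off[ok] == 0))
})

test_that("a bright rim drives positive approach motion at the boundary", {
  img <- make_test_image(c(300, 400), disc_center = c(200, 150),
                         disc_radius = 90, disc_rgb = c(200, 200, 200),
                         background_rgb = c(20, 20, 20))
  lat <- hex_sample(img, hex_width = 40, hex_height = 34)
  est <- radial_motion(lat, c(200, 150), "approach")
  s <- lat$sites
  r <- sqrt((s$x - 200)^2 + (s$y - 150)^2)
  rim <- which(!is.na(est$combined) & abs(r - 90) < 40)
  expect_gt(length(rim), 3)
  expect_gt(max(est$on[rim]), 0)  # outward ON contrast at the rim
})

test_that("identical estimates compare as indistinguishable", {
  flat <- array(50, dim = c(250, 300, 3))
  lat <- hex_sample(flat, hex_width = 40, hex_height = 34)
  a <- radial_motion(lat, c(150, 125), "approach")
  b <- radial_motion(lat, c(150, 125), "approach")
  cmp <- compare_modes(a, b)
  expect_equal(cmp$test$p_value, 1)
  expect_true(all(cmp$differences$difference == 0))
})

test_that("lattices and estimates export to CSV", {
  flat <- array(50, dim = c(250, 300, 3))
  lat <- hex_sample(flat, hex_width = 40, hex_height = 34)
  p1 <- withr::local_tempfile(fileext = ".csv")
  write_lattice_csv(lat, p1)
  back <- utils::read.csv(p1)
  expect_equal(nrow(back), nrow(lat$sites))
  est <- radial_motion(lat, c(150, 125), "approach")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_motion_csv(est, p2)
  expect_equal(nrow(utils::read.csv(p2)), nrow(est))
})
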