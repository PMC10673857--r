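test_that("alignment recovers planted rigid shifts and is idempotent", {
  mv <- small_movie(data.frame(x = 25, y = 30, polarity = "ON",
                               isoluminance = 5),
                    uv_levels = c(0, 5, 15), noise_sd = 0.01)
  al <- align_movie(mv, 15)
  expect_true(all(al$shifts$dx == 0) && all(al$shifts$dy == 0))
  expect_false(al$rejected)
  # plant a rigid (+3, -2) (columns, rows) shift on the non-template
  # trials; the template trials define the reference frame
  shifted <- mv
  planted <- which(mv$trials$uv_level != 15)
  moved <- unlist(lapply(planted, function(tr) {
    mv$trials$start_frame[tr] + seq_len(mv$trials$n_frames[tr]) - 1L
  }))
  for (k in moved)
    shifted$frames[, , k] <- translate_px(mv$frames[, , k], -2, 3,
                                          fill = 0.2)
  al2 <- align_movie(shifted, 15)
  expect_true(all(al2$shifts$dx[moved] == 3))
  expect_true(all(al2$shifts$dy[moved] == -2))
  expect_false(al2$rejected)
  # aligning the aligned movie yields zero shifts
  al3 <- align_movie(al2$movie, 15)
  expect_true(all(al3$shifts$dx == 0) && all(al3$shifts$dy == 0))
})

test_that("a >25 px excursion triggers recording rejection", {
  mv <- small_movie(data.frame(x = 40, y = 40, polarity = "ON",
                               isoluminance = 5),
                    uv_levels = c(0, 15), image_size = 96,
                    noise_sd = 0.01)
  mv$frames[, , 5] <- translate_px(mv$frames[, , 5], 0, 30, fill = 0.2)
  al <- align_movie(mv, 15)
  expect_true(al$rejected)
  expect_equal(max(abs(al$shifts$dx)), 30)
  # analyze_movie propagates the rejection and returns no ROIs
  res <- analyze_movie(mv, "ON", min_separation = 16)
  expect_true(res$rejected)
  expect_equal(nrow(res$rois), 0)
})

test_that("ROI detection finds planted blobs and merges close peaks", {
  sigma <- 16 / (2 * sqrt(2 * log(2)))
  blob <- function(x0, y0, amp = 2) {
    outer(seq_len(96), seq_len(96), function(r, cc)
      amp * exp(-((cc - x0)^2 + (r - y0)^2) / (2 * sigma^2)))
  }
  one <- 0.2 + blob(40, 50)
  d1 <- detect_rois(one, fwhm = 11, min_separation = 16)
  expect_equal(nrow(d1$peaks), 1)
  expect_true(d1$masks[[1]][50, 40])
  # three well-separated blobs: three ROIs with centers within 2 px
  truth <- cbind(x = c(20, 66, 36), y = c(24, 30, 72))
  three <- 0.2 + blob(20, 24) + blob(66, 30) + blob(36, 72)
  d3 <- detect_rois(three, fwhm = 11, min_separation = 16)
  expect_equal(nrow(d3$peaks), 3)
  for (k in seq_len(3)) {
    err <- sqrt((d3$peaks$col - truth[k, "x"])^2 +
                  (d3$peaks$row - truth[k, "y"])^2)
    expect_lte(min(err), 2)
  }
  # masks are pairwise disjoint and connected
  expect_true(all(rowSums(sapply(d3$masks, as.vector)) <= 1))
  for (m in d3$masks) expect_true(mask_connected(m))
  # two blobs closer than the separation merge into one ROI
  two_close <- 0.2 + blob(40, 40) + blob(48, 44)
  d2 <- detect_rois(two_close, fwhm = 11, min_separation = 16)
  expect_equal(nrow(d2$peaks), 1)
  # a featureless image yields no ROIs, not an error
  d0 <- detect_rois(matrix(0.2, 96, 96), fwhm = 11, min_separation = 16)
  expect_equal(length(d0$masks), 0)
})

test_that("dF/F0 uses the 1.5 s pre-stimulus baseline per trial", {
  mv <- small_movie(data.frame(x = 20, y = 20, polarity = "ON",
                               isoluminance = 5),
                    uv_levels = c(0, 15), image_size = 32,
                    column_spacing = 10)
  mask <- matrix(FALSE, 32, 32); mask[18:22, 18:22] <- TRUE
  # constant-fluorescence movie: all-zero traces
  flat <- mv; flat$frames[] <- 0.7
  tr0 <- roi_dff(flat, mask)
  expect_true(all(abs(tr0$dff) < 1e-12))
  expect_true(tr0$valid)
  # doubling fluorescence after onset gives dF/F0 = 1
  doubled <- flat
  resp <- which(flat$time >= flat$params$onset)
  for (g in seq_len(nrow(flat$trials))) {
    cols <- flat$trials$start_frame[g] + resp - 1L
    doubled$frames[, , cols] <- 1.4
  }
  tr1 <- roi_dff(doubled, mask)
  expect_equal(max(tr1$dff), 1, tolerance = 1e-12)
  # closed-form check against the generator's planted response
  tr <- roi_dff(mv, mask)
  expect_true(tr$valid)
  base_idx <- which(mv$time >= mv$params$onset - 1.5 &
                      mv$time < mv$params$onset)
  for (g in seq_len(nrow(mv$trials))) {
    cols <- mv$trials$start_frame[g] + seq_along(mv$time) - 1L
    f <- sapply(cols, function(cc) mean(mv$frames[, , cc][mask]))
    f0 <- mean(f[base_idx])
    expect_equal(tr$dff[g, ], (f - f0) / f0, tolerance = 1e-12)
  }
})

test_that("the two-frame metric matches its window and hand averages", {
  mv <- small_movie(data.frame(x = 20, y = 20, polarity = "ON",
                               isoluminance = 5),
                    uv_levels = c(0, 10, 15), image_size = 32,
                    column_spacing = 10)
  # the two frames after full expansion at 6.83 Hz are ~150 ms apart
  idx <- which(mv$time >= mv$params$expansion_end)[1:2]
  expect_lt(abs(diff(mv$time[idx]) - 0.150), 0.005)
  dff <- matrix(0, nrow(mv$trials), length(mv$time))
  dff[, idx] <- rep(c(0.2, 0.6), each = nrow(mv$trials))
  cv <- roi_metric_curve(dff, mv)
  expect_true(all(cv$mean_response == 0.4))  # (a + b) / 2
  # constant post-expansion response returns that constant
  dff2 <- matrix(0, nrow(mv$trials), length(mv$time))
  dff2[, mv$time >= mv$params$expansion_end] <- 0.9
  expect_true(all(roi_metric_curve(dff2, mv)$mean_response == 0.9))
})

test_that("ROI isoluminance scans by polarity with the minimum fallback", {
  off <- tuning_curve(c(7, 8), c(0.1, -0.1))
  expect_equal(roi_isoluminance(off, "OFF")$value, 7.5)
  on <- tuning_curve(c(5, 6), c(-0.2, 0.2))
  expect_equal(roi_isoluminance(on, "ON")$value, 5.5)  # scans down from 15
  # strictly positive OFF curve: level of the minimum, no crossing
  pos <- tuning_curve(c(0, 3, 6, 9, 12, 15), c(5, 4, 3, 1, 2, 3))
  est <- roi_isoluminance(pos, "OFF")
  expect_equal(est$value, 9)
  expect_false(est$crossing_found)
  # exactness on linear ROI tuning, both polarities
  set.seed(9)
  for (i in 1:15) {
    truth <- runif(1, 1, 14)
    lv <- 0:15
    on_cv <- tuning_curve(lv, 0.4 * (lv - truth))
    expect_equal(roi_isoluminance(on_cv, "ON")$value, truth,
                 tolerance = 1e-12)
    off_cv <- tuning_curve(lv, 0.4 * (truth - lv))
    expect_equal(roi_isoluminance(off_cv, "OFF")$value, truth,
                 tolerance = 1e-12)
  }
})

test_that("responsiveness thresholding removes flat ROIs and is stable", {
  rois <- data.frame(x = c(18, 46), y = c(20, 44), polarity = "ON",
                     isoluminance = c(5, 5))
  mv <- small_movie(rois, noise_sd = 0.01, seed = 31)
  res <- analyze_movie(mv, "ON", min_separation = 16)
  expect_equal(nrow(res$rois), 2)
  expect_equal(nrow(threshold_responsive(res$rois, 0)), 2)
  # a planted flat (unresponsive) ROI row is removed at any positive threshold
  flat_row <- res$rois[1, ]
  flat_row$ref_response <- 0
  tab <- rbind(res$rois, flat_row)
  expect_equal(nrow(threshold_responsive(tab, 1e-6)), 2)
  # sweep: estimate stable while ROIs survive
  sw <- threshold_sweep(res$rois, c(0, 0.05, 0.1))
  kept <- sw[sw$n_rois > 0, ]
  expect_lt(max(kept$mean_iso) - min(kept$mean_iso), 0.2)
  expect_true(all(diff(sw$n_rois) <= 0))
})

test_that("aggregation weights flies equally, not ROIs", {
  tab <- data.frame(fly_id = c("A", "A", "B"), isoluminance = c(4, 6, 8))
  agg <- aggregate_isoluminance(tab)
  expect_equal(agg$grand_mean, 6.5)  # (5 + 8) / 2, not pooled 6
  expect_equal(agg$n_flies, 2)
  one <- aggregate_isoluminance(data.frame(fly_id = "A", isoluminance = 7.3))
  expect_equal(one$grand_mean, 7.3)
})

test_that("population isoluminance applies the scan to the mean curve", {
  a <- tuning_curve(0:15, 0.3 * (0:15 - 4))
  b <- tuning_curve(0:15, 0.3 * (0:15 - 6))
  expect_equal(population_isoluminance(list(a, b), "ON")$value, 5)
})

test_that("ON and OFF cohorts recover distinct planted isoluminances", {
  # T4-like (5.2) vs T5-like (7.8) population truths, small noiseless cohort
  iso <- c(ON = 5.2, OFF = 7.8)
  grand <- sapply(names(iso), function(pol) {
    tabs <- lapply(1:2, function(f) {
      mv <- small_movie(data.frame(x = c(20, 46), y = c(22, 44),
                                   polarity = pol, isoluminance = iso[[pol]]),
                        seed = 500 + f)
      res <- analyze_movie(mv, pol, fly_id = paste0("fly", f),
                           min_separation = 16)
      res$rois
    })
    aggregate_isoluminance(do.call(rbind, tabs))$grand_mean
  })
  expect_lt(abs(grand[["ON"]] - 5.2), 0.1)
  expect_lt(abs(grand[["OFF"]] - 7.8), 0.1)
  expect_lt(grand[["ON"]], grand[["OFF"]])
})
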