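# Synthetic calcium movies with planted column-scale ROIs, rigid frame
# jitter and additive noise, plus colored-disc test images for the
# hexagonal-lattice motion model.

#' Simulate a trial-structured calcium-imaging movie
#'
#' Plants isotropic Gaussian blobs (FWHM of about one neural-column spacing)
#' on a uniform baseline. Each trial presents one expanding-disc UV level;
#' a blob's noiseless response is linear in the UV level with its zero
#' crossing at the blob's true isoluminance (increasing for ON polarity,
#' decreasing for OFF), low-pass filtered by a first-order exponential
#' kernel emulating calcium-indicator kinetics. Whole-frame rigid jitter
#' (rounded Gaussian, recorded in the output) and additive Gaussian pixel
#' noise are then applied.
#'
#' Trials follow the imaging protocol: `pre_stim` seconds of background,
#' 1 s disc expansion, 1 s hold of the full disc, return to background,
#' with `record_duration` seconds of frames per trial.
#'
#' @param rois data frame with columns `x`, `y` (blob centers, pixels),
#'   `polarity` (`"ON"`/`"OFF"`) and `isoluminance` (true zero crossing,
#'   UV levels). Centers closer than `column_spacing` are rejected.
#' @param uv_levels UV levels presented, one per trial repetition block.
#' @param n_reps trials per UV level.
#' @param frame_rate Hz; 6.83 is the two-photon rate for T4/T5 recordings.
#' @param image_size frame side length in pixels (256 by default).
#' @param kinetics_tau indicator time constant, seconds.
#' @param jitter_sd SD of the per-frame rigid shift, pixels (rounded to
#'   integers); 0 disables jitter.
#' @param noise_sd additive Gaussian pixel noise SD (fluorescence units).
#' @param column_spacing minimum blob separation and blob FWHM, pixels.
#'   Default scales the 5 um medulla column (38 px at 256 px / 34 um) to
#'   `image_size`.
#' @param gain response slope per UV level (dF/F-like units).
#' @param baseline background fluorescence level (dim, as in a dark-field
#'   two-photon recording, so flood-fill floors sit above it).
#' @param blob_amplitude peak blob fluorescence above baseline.
#' @param pre_stim seconds of background before stimulus onset.
#' @param expansion_duration,hold_duration disc timing, seconds.
#' @param record_duration recorded seconds per trial (7.6; the trailing
#'   0.4 s of the 8 s trial is the unrecorded save gap).
#' @param seed RNG seed.
#' @return object of class `cm_movie`: `frames` (H x W x T array),
#'   `frame_rate`, `trials` (trial, uv_level, start frame), `time`
#'   (within-trial frame times), `rois` (planted truth), `jitter`
#'   (per-frame `dx` = columns, `dy` = rows), and `params` timing metadata.
#' @export
simulate_movie <- function(rois, uv_levels = .standard_uv_levels, n_reps = 5,
                           frame_rate = 6.83, image_size = 256,
                           kinetics_tau = 0.3, jitter_sd = 0, noise_sd = 0.02,
                           column_spacing = round(38 * image_size / 256),
                           gain = 0.08, baseline = 0.2, blob_amplitude = 2,
                           pre_stim = 3, expansion_duration = 1,
                           hold_duration = 1, record_duration = 7.6,
                           seed = NULL) {
  .check(is.data.frame(rois) &&
           all(c("x", "y", "polarity", "isoluminance") %in% names(rois)),
         "'rois' needs columns x, y, polarity, isoluminance")
  .check(all(rois$polarity %in% c("ON", "OFF")), "polarity must be ON or OFF")
  .check(all(rois$isoluminance >= 0 & rois$isoluminance <= 15),
         "isoluminance must be in [0, 15]")
  .check(length(uv_levels) >= 1 && all(uv_levels >= 0 & uv_levels <= 15),
         "uv_levels must be in [0, 15]")
  .check(all(c(kinetics_tau, jitter_sd, noise_sd) >= 0),
         "kinetics/jitter/noise parameters must be non-negative")
  n_roi <- nrow(rois)
  if (n_roi > 1) {
    dmin <- min(stats::dist(rois[, c("x", "y")]))
    .check(dmin >= column_spacing,
           sprintf("overlapping blobs: centers %.1f px apart, need >= %d",
                   dmin, column_spacing))
  }
  uv_levels <- as.integer(uv_levels)
  H <- W <- as.integer(image_size)
  nf <- floor(record_duration * frame_rate)
  tf <- (seq_len(nf) - 1) / frame_rate
  onset <- pre_stim
  expansion_end <- pre_stim + expansion_duration
  return_green <- expansion_end + hold_duration

  # static blob images
  sigma <- column_spacing / (2 * sqrt(2 * log(2)))
  xs <- matrix(rep(seq_len(W), each = H), H, W)   # column index
  ys <- matrix(rep(seq_len(H), times = W), H, W)  # row index
  blobs <- lapply(seq_len(n_roi), function(b) {
    blob_amplitude *
      exp(-((xs - rois$x[b])^2 + (ys - rois$y[b])^2) / (2 * sigma^2))
  })

  # exponential kinetics as a first-order recursive filter
  a <- if (kinetics_tau > 0) exp(-1 / (frame_rate * kinetics_tau)) else 0
  drive <- as.numeric(tf >= expansion_end & tf < return_green)
  kernel_resp <- as.numeric(stats::filter((1 - a) * drive, a,
                                          method = "recursive"))

  trials <- expand.grid(rep = seq_len(n_reps), uv_level = uv_levels)
  n_tr <- nrow(trials)
  trials <- data.frame(trial = seq_len(n_tr), uv_level = trials$uv_level,
                       start_frame = (seq_len(n_tr) - 1L) * nf + 1L,
                       n_frames = nf)
  total <- n_tr * nf

  with_seed(seed, {
    jit <- matrix(0L, total, 2)
    if (jitter_sd > 0)
      jit <- matrix(as.integer(pmax(pmin(
        round(stats::rnorm(2 * total, 0, jitter_sd)), 12), -12)), total, 2)
    frames <- array(0, dim = c(H, W, total))
    for (tr in seq_len(n_tr)) {
      uv <- trials$uv_level[tr]
      resp <- lapply(seq_len(n_roi), function(b) {
        sgn <- if (rois$polarity[b] == "ON") 1 else -1
        sgn * gain * (uv - rois$isoluminance[b]) * kernel_resp
      })
      for (k in seq_len(nf)) {
        f <- matrix(baseline, H, W)
        for (b in seq_len(n_roi))
          f <- f + blobs[[b]] * (1 + resp[[b]][k])
        g <- trials$start_frame[tr] + k - 1L
        if (jit[g, 1] != 0 || jit[g, 2] != 0)
          f <- shift_matrix(f, drow = jit[g, 2], dcol = jit[g, 1],
                            fill = baseline)
        if (noise_sd > 0)
          f <- f + stats::rnorm(H * W, 0, noise_sd)
        frames[, , g] <- pmax(f, 0)  # fluorescence is non-negative
      }
    }
    structure(list(frames = frames, frame_rate = frame_rate, trials = trials,
                   time = tf, rois = rois,
                   jitter = data.frame(frame = seq_len(total),
                                       dx = jit[, 1], dy = jit[, 2]),
                   params = list(onset = onset,
                                 expansion_end = expansion_end,
                                 return_green = return_green,
                                 baseline = baseline,
                                 column_spacing = column_spacing)),
              class = "cm_movie")
  })
}

#' @export
print.cm_movie <- function(x, ...) {
  cat(sprintf("<cm_movie> %d x %d px, %d frames (%d trials) at %g Hz\n",
              dim(x$frames)[1], dim(x$frames)[2], dim(x$frames)[3],
              nrow(x$trials), x$frame_rate))
  invisible(x)
}

#' Synthetic colored-disc test image
#'
#' A flat colored disc on a flat colored background, with optional iid
#' Gaussian pixel noise: the controlled stand-in for a photograph of a
#' warm-colored object against cool foliage used to exercise the
#' hexagonal-lattice motion model.
#'
#' @param image_size height/width in pixels (length 1 or 2, rows x columns).
#' @param disc_center `(x, y)` pixel coordinates (x = column, y = row).
#' @param disc_radius pixels; the disc must fit inside the image.
#' @param disc_rgb,background_rgb length-3 RGB values (0-255 scale).
#' @param noise_sd per-pixel Gaussian noise SD, applied independently per
#'   channel; 0 for a noiseless image.
#' @param seed RNG seed.
#' @return numeric array `H x W x 3`, clipped to `[0, 255]`.
#' @export
make_test_image <- function(image_size = c(900, 1500),
                            disc_center = NULL, disc_radius = 300,
                            disc_rgb = c(200, 120, 40),
                            background_rgb = c(40, 120, 200),
                            noise_sd = 0, seed = NULL) {
  if (length(image_size) == 1) image_size <- rep(image_size, 2)
  H <- image_size[1]; W <- image_size[2]
  if (is.null(disc_center)) disc_center <- c(W / 2, H / 2)
  .check(length(disc_rgb) == 3 && length(background_rgb) == 3,
         "RGB values must have length 3")
  .check(disc_center[1] - disc_radius >= 0 &&
           disc_center[1] + disc_radius <= W + 1 &&
           disc_center[2] - disc_radius >= 0 &&
           disc_center[2] + disc_radius <= H + 1,
         "disc does not fit in the image")
  xs <- matrix(rep(seq_len(W), each = H), H, W)
  ys <- matrix(rep(seq_len(H), times = W), H, W)
  inside <- (xs - disc_center[1])^2 + (ys - disc_center[2])^2 <= disc_radius^2
  img <- array(0, dim = c(H, W, 3))
  with_seed(seed, {
    for (ch in 1:3) {
      m <- matrix(background_rgb[ch], H, W)
      m[inside] <- disc_rgb[ch]
      if (noise_sd > 0) m <- m + stats::rnorm(H * W, 0, noise_sd)
      img[, , ch] <- pmin(pmax(m, 0), 255)
    }
    img
  })
}

#' Write or read a movie as multi-page TIFF with a JSON sidecar
#'
#' Frames are stored as 32-bit float TIFF pages scaled to `[0, 1]`; the
#' sidecar records the scale factor, frame rate, trial table, planted ROI
#' truth and jitter so the movie round-trips exactly.
#'
#' @param movie a `cm_movie`.
#' @param path TIFF path; the sidecar defaults to `<path>.json`.
#' @param sidecar JSON sidecar path.
#' @return `read_movie_tiff` returns a `cm_movie`.
#' @export
write_movie_tiff <- function(movie, path, sidecar = paste0(path, ".json")) {
  .check(inherits(movie, "cm_movie"), "'movie' must be a cm_movie")
  mx <- max(movie$frames)
  scale <- if (mx > 0) mx else 1
  pages <- lapply(seq_len(dim(movie$frames)[3]),
                  function(k) movie$frames[, , k] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32, reduce = FALSE)
  meta <- list(scale = scale, frame_rate = movie$frame_rate,
               trials = movie$trials, time = movie$time,
               rois = movie$rois, jitter = movie$jitter,
               params = movie$params)
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_movie_tiff
#' @export
read_movie_tiff <- function(path, sidecar = paste0(path, ".json")) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  frames <- array(0, dim = c(dim(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) frames[, , k] <- pages[[k]] * meta$scale
  structure(list(frames = frames, frame_rate = meta$frame_rate,
                 trials = as.data.frame(meta$trials),
                 time = meta$time,
                 rois = if (!is.null(meta$rois)) as.data.frame(meta$rois),
                 jitter = if (!is.null(meta$jitter)) as.data.frame(meta$jitter),
                 params = meta$params),
            class = "cm_movie")
}
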