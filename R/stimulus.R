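# Stimulus generation: looming (constant-velocity expanding) discs and
# competing UV/green edge stimuli on an angular azimuth x elevation grid,
# plus the UV/green display calibration mask.

#' Angular display grid
#'
#' Frames are stored on a regular azimuth x elevation grid of bin centers.
#' The default spans -20 to 100 degrees azimuth and -50 to 50 degrees
#' elevation (the imaging display span) at 1 degree per bin.
#'
#' @param az_range,el_range numeric length-2, degrees.
#' @param bin bin width in degrees.
#' @return list with `az`, `el` (bin-center vectors) and `bin`.
#' @export
angular_grid <- function(az_range = c(-20, 100), el_range = c(-50, 50), bin = 1) {
  .check(.is_number(bin) && bin > 0, "'bin' must be a positive number")
  .check(diff(az_range) > 0 && diff(el_range) > 0, "degenerate angular range")
  list(az = seq(az_range[1] + bin / 2, az_range[2] - bin / 2, by = bin),
       el = seq(el_range[1] + bin / 2, el_range[2] - bin / 2, by = bin),
       bin = bin)
}

#' Half-angle of a disc approaching at constant velocity
#'
#' An object of radius `r` approaching at speed `v` subtends the half-angle
#' `atan(r / (v * t))` when `t` seconds remain before collision, so the
#' expansion profile is fully parameterized by the ratio `r/v`. At collision
#' (`time_to_collision = 0`) the half-angle is 90 degrees.
#'
#' @param r_over_v ratio of radius to approach speed, seconds (> 0).
#' @param time_to_collision seconds remaining before collision (>= 0);
#'   vectorized.
#' @return half-angle in degrees.
#' @examples
#' disc_half_angle(0.120, 1.0)  # 6.84 deg, the standard start size
#' disc_half_angle(0.120, 0)    # 90 deg at collision
#' @export
disc_half_angle <- function(r_over_v, time_to_collision) {
  .check(.is_number(r_over_v) && r_over_v > 0, "'r_over_v' must be a positive number")
  .check(is.numeric(time_to_collision) && all(is.finite(time_to_collision)) &&
           all(time_to_collision >= 0),
         "'time_to_collision' must be non-negative")
  ifelse(time_to_collision == 0, 90,
         atan(r_over_v / time_to_collision) * 180 / pi)
}

#' Expanding-disc stimulus specification
#'
#' @param r_over_v radius/speed ratio in seconds; 0.120 throughout the
#'   standard protocols.
#' @param center_azimuth,center_elevation disc center, degrees.
#' @param start_half_angle initial half-angle in degrees (6.8 by default).
#' @param disc_channel `"UV_on_green"` (UV disc, calibrated green background)
#'   or `"green_on_UV"` (calibrated green disc, uniform UV background).
#' @param disc_uv_level UV intensity 0-15 of the disc (`UV_on_green`).
#' @param background_uv_level UV intensity 0-15 of the background
#'   (`green_on_UV`).
#' @param expansion_duration,hold_duration seconds; the disc reaches full
#'   expansion (90 degrees) at `expansion_duration` and the final frame is
#'   then held for `hold_duration`.
#' @return object of class `cm_disc_spec`.
#' @export
disc_spec <- function(r_over_v = 0.120, center_azimuth = 60,
                      center_elevation = 0, start_half_angle = 6.8,
                      disc_channel = c("UV_on_green", "green_on_UV"),
                      disc_uv_level = 15, background_uv_level = 7,
                      expansion_duration = 1, hold_duration = 1) {
  disc_channel <- match.arg(disc_channel)
  .check(.is_number(r_over_v) && r_over_v > 0, "'r_over_v' must be > 0")
  .check(.is_number(expansion_duration) && expansion_duration > 0,
         "'expansion_duration' must be > 0")
  .check(.is_number(hold_duration) && hold_duration >= 0,
         "'hold_duration' must be >= 0")
  for (lv in c(disc_uv_level, background_uv_level))
    .check(.is_number(lv) && lv >= 0 && lv <= 15 && lv == round(lv),
           "UV levels must be integers in 0-15")
  .check(.is_number(start_half_angle) && start_half_angle > 0 &&
           start_half_angle < 90, "'start_half_angle' must be in (0, 90)")
  structure(list(r_over_v = r_over_v, center_azimuth = center_azimuth,
                 center_elevation = center_elevation,
                 start_half_angle = start_half_angle,
                 disc_channel = disc_channel,
                 disc_uv_level = as.integer(disc_uv_level),
                 background_uv_level = as.integer(background_uv_level),
                 expansion_duration = expansion_duration,
                 hold_duration = hold_duration),
            class = "cm_disc_spec")
}

#' Competing-edge stimulus specification
#'
#' The display is split into `n_windows` perspective-corrected windows of
#' `window_width` degrees. In every window a green edge and a UV edge advance
#' in opposite directions, each filling the window in one `cycle_period`;
#' the sequence repeats for `duration` seconds. The OFF stimulus is the ON
#' stimulus with frame order reversed within each cycle; counterclockwise
#' stimuli are the clockwise frames mirrored about the vertical axis.
#'
#' @param window_width degrees per window (30).
#' @param n_windows number of windows (8).
#' @param cycle_period seconds per fill cycle (0.25).
#' @param duration total stimulus seconds (2); must be an integer multiple of
#'   `cycle_period`.
#' @param polarity `"ON"` or `"OFF"`.
#' @param rotation `"CW"` or `"CCW"`.
#' @param uv_level UV intensity 0-15 of the UV edge.
#' @return object of class `cm_edge_spec`.
#' @export
edge_spec <- function(window_width = 30, n_windows = 8, cycle_period = 0.25,
                      duration = 2, polarity = c("ON", "OFF"),
                      rotation = c("CW", "CCW"), uv_level = 7) {
  polarity <- match.arg(polarity); rotation <- match.arg(rotation)
  .check(.is_number(window_width) && window_width > 0, "'window_width' must be > 0")
  .check(.is_number(n_windows) && n_windows >= 1 && n_windows == round(n_windows),
         "'n_windows' must be a positive integer")
  .check(.is_number(cycle_period) && cycle_period > 0, "'cycle_period' must be > 0")
  .check(.is_number(duration) && duration > 0, "'duration' must be > 0")
  n_cycles <- duration / cycle_period
  .check(abs(n_cycles - round(n_cycles)) < 1e-9,
         "'duration' must be an integer multiple of 'cycle_period'")
  .check(.is_number(uv_level) && uv_level >= 0 && uv_level <= 15 &&
           uv_level == round(uv_level), "'uv_level' must be an integer in 0-15")
  structure(list(window_width = window_width, n_windows = as.integer(n_windows),
                 cycle_period = cycle_period, duration = duration,
                 polarity = polarity, rotation = rotation,
                 uv_level = as.integer(uv_level)),
            class = "cm_edge_spec")
}

#' Edge speed and cycle frequency of a competing-edge stimulus
#'
#' @param spec a [edge_spec()].
#' @return degrees per second (`edge_speed`) or Hz (`cycle_frequency`).
#' @export
edge_speed <- function(spec) {
  .check(inherits(spec, "cm_edge_spec"), "'spec' must be an edge_spec")
  spec$window_width / spec$cycle_period
}

#' @rdname edge_speed
#' @export
cycle_frequency <- function(spec) {
  .check(inherits(spec, "cm_edge_spec"), "'spec' must be an edge_spec")
  1 / spec$cycle_period
}

#' Build the green-channel luminance mask from a UV irradiance grid
#'
#' The UV and green primaries scatter differently through the projection
#' screen, so the green intensity must be adjusted site by site so that,
#' under a linear display model (irradiance proportional to intensity), the
#' green irradiance is `scale` times the UV irradiance everywhere. The
#' standard scaling factor is 2.3, chosen so the isoluminant UV intensity
#' falls mid-range.
#'
#' @param uv_irradiance data frame with columns `azimuth`, `elevation`,
#'   `uv_irradiance` (all irradiances > 0), or a numeric matrix of
#'   irradiances sampled on a 10-degree grid.
#' @param scale dimensionless linear factor (default 2.3).
#' @return object of class `cm_calibration`: `sites` data frame with the
#'   mask and the achieved green/UV `ratio`, the `scale`, and a `residual`
#'   column (`ratio - scale`) for QC.
#' @export
build_green_mask <- function(uv_irradiance, scale = 2.3) {
  if (is.matrix(uv_irradiance)) {
    uv_irradiance <- data.frame(
      azimuth = rep(10 * (seq_len(ncol(uv_irradiance)) - 1),
                    each = nrow(uv_irradiance)),
      elevation = rep(10 * (seq_len(nrow(uv_irradiance)) - 1),
                      times = ncol(uv_irradiance)),
      uv_irradiance = as.vector(uv_irradiance))
  }
  .check(is.data.frame(uv_irradiance) &&
           all(c("azimuth", "elevation", "uv_irradiance") %in% names(uv_irradiance)),
         "'uv_irradiance' must have columns azimuth, elevation, uv_irradiance")
  .check(.is_number(scale) && scale > 0, "'scale' must be a positive number")
  .check(all(uv_irradiance$uv_irradiance > 0), "irradiance values must be > 0")
  sites <- uv_irradiance
  sites$green_mask <- scale * sites$uv_irradiance
  sites$ratio <- sites$green_mask / sites$uv_irradiance  # linear display model
  structure(list(sites = sites, scale = scale,
                 residual = sites$ratio - scale),
            class = "cm_calibration")
}

# green intensity at arbitrary grid points: nearest calibration site value
# (a uniform unit mask when no calibration is supplied)
.green_at <- function(calib, az, el, multiplier = 1) {
  if (is.null(calib)) return(matrix(multiplier, length(az), length(el)))
  .check(inherits(calib, "cm_calibration"), "'calib' must be a cm_calibration")
  s <- calib$sites
  g <- outer(az, el, Vectorize(function(a, e) {
    s$green_mask[which.min((s$azimuth - a)^2 + (s$elevation - e)^2)]
  }))
  g * multiplier
}

.new_frameset <- function(uv, green, time, grid, frame_rate, spec) {
  structure(list(uv = uv, green = green, time = time,
                 az = grid$az, el = grid$el,
                 frame_rate = frame_rate, spec = spec),
            class = "cm_frameset")
}

#' @export
print.cm_frameset <- function(x, ...) {
  cat(sprintf("<cm_frameset> %d frames at %g Hz, %d x %d bins (az x el)\n",
              length(x$time), x$frame_rate, length(x$az), length(x$el)))
  invisible(x)
}

# great-circle angular distance (degrees) from each grid bin to a point
.angular_distance <- function(grid, az0, el0) {
  d2r <- pi / 180
  cosd <- outer(grid$az, grid$el, function(a, e) {
    sin(el0 * d2r) * sin(e * d2r) +
      cos(el0 * d2r) * cos(e * d2r) * cos((a - az0) * d2r)
  })
  acos(pmin(pmax(cosd, -1), 1)) / d2r
}

#' Render an expanding-disc stimulus
#'
#' A grid bin is disc-colored iff its great-circle angular distance to the
#' disc center is at most the current half-angle; the half-angle time course
#' is [disc_half_angle()] with collision at the end of the expansion. Frames
#' are sampled at `k / frame_rate` for `k = 1..n`, so the final expansion
#' frame is at full expansion (90 degrees); it is then held for
#' `hold_duration`. For `green_on_UV` specs the background is uniform UV at
#' `background_uv_level` and the disc is calibrated green.
#'
#' @param spec a [disc_spec()].
#' @param calib optional [build_green_mask()] calibration; `NULL` means a
#'   uniform unit green mask.
#' @param frame_rate display update rate, Hz (60).
#' @param grid an [angular_grid()].
#' @param green_multiplier scalar applied to the green mask (the doubled-green
#'   manipulation); default 1.
#' @return a `cm_frameset`: `uv` and `green` arrays of dimension
#'   time x azimuth x elevation, plus `time`, `az`, `el`, `frame_rate` and
#'   the per-frame `half_angle` sequence.
#' @export
render_disc <- function(spec, calib = NULL, frame_rate = 60,
                        grid = angular_grid(), green_multiplier = 1) {
  .check(inherits(spec, "cm_disc_spec"), "'spec' must be a disc_spec")
  .check(.is_number(frame_rate) && frame_rate > 0, "'frame_rate' must be > 0")
  naz <- length(grid$az); nel <- length(grid$el)
  dist <- .angular_distance(grid, spec$center_azimuth, spec$center_elevation)
  .check(any(dist <= spec$start_half_angle),
         "frame grid too coarse to represent start_half_angle")
  n_exp <- round(spec$expansion_duration * frame_rate)
  n_hold <- round(spec$hold_duration * frame_rate)
  t_exp <- seq_len(n_exp) / frame_rate
  theta <- disc_half_angle(spec$r_over_v,
                           pmax(spec$expansion_duration - t_exp, 0))
  time <- c(t_exp, spec$expansion_duration + seq_len(n_hold) / frame_rate)
  nt <- length(time)
  gmask <- .green_at(calib, grid$az, grid$el, green_multiplier)
  uv <- array(0, dim = c(nt, naz, nel))
  green <- array(0, dim = c(nt, naz, nel))
  for (k in seq_len(nt)) {
    th <- if (k <= n_exp) theta[k] else 90
    inside <- dist <= th + 1e-9
    if (spec$disc_channel == "UV_on_green") {
      fuv <- matrix(0, naz, nel); fuv[inside] <- spec$disc_uv_level
      fgr <- gmask; fgr[inside] <- 0
    } else {
      fuv <- matrix(spec$background_uv_level, naz, nel); fuv[inside] <- 0
      fgr <- matrix(0, naz, nel); fgr[inside] <- gmask[inside]
    }
    uv[k, , ] <- fuv; green[k, , ] <- fgr
  }
  out <- .new_frameset(uv, green, time, grid, frame_rate, spec)
  out$half_angle <- c(theta, rep(90, n_hold))
  out
}

#' Render a competing UV/green edge stimulus
#'
#' In every window a green edge advances from the left at
#' `window_width / cycle_period` degrees per second while a UV edge advances
#' from the right, both filling the window by the end of each cycle; the
#' pattern repeats for `duration / cycle_period` cycles. OFF frames are the
#' ON frames in reverse temporal order within each cycle (bit-exact), and
#' CCW frames are the CW frames mirrored in azimuth.
#'
#' @inheritParams render_disc
#' @param spec an [edge_spec()].
#' @param grid an [angular_grid()]; must span at least
#'   `window_width * n_windows` degrees of azimuth. The default covers the
#'   eight standard 30-degree windows.
#' @return a `cm_frameset` (see [render_disc()]).
#' @export
render_competing_edges <- function(spec, calib = NULL, frame_rate = 60,
                                   grid = angular_grid(az_range = c(-120, 120)),
                                   green_multiplier = 1) {
  .check(inherits(spec, "cm_edge_spec"), "'spec' must be an edge_spec")
  .check(.is_number(frame_rate) && frame_rate > 0, "'frame_rate' must be > 0")
  span <- spec$window_width * spec$n_windows
  az_lo <- min(grid$az) - grid$bin / 2; az_hi <- max(grid$az) + grid$bin / 2
  .check(span <= az_hi - az_lo + 1e-9,
         "window_width * n_windows exceeds the grid's azimuth span")
  n_cyc <- spec$cycle_period * frame_rate
  .check(abs(n_cyc - round(n_cyc)) < 1e-9,
         "cycle_period must be an integer number of frames")
  n_cyc <- as.integer(round(n_cyc))
  n_cycles <- as.integer(round(spec$duration / spec$cycle_period))
  naz <- length(grid$az); nel <- length(grid$el)
  start <- (az_lo + az_hi) / 2 - span / 2  # windows centered on the grid
  w_idx <- floor((grid$az - start) / spec$window_width)
  pos <- grid$az - (start + w_idx * spec$window_width)
  in_win <- w_idx >= 0 & w_idx < spec$n_windows
  gmask <- .green_at(calib, grid$az, grid$el, green_multiplier)

  cyc_uv <- array(0, dim = c(n_cyc, naz, nel))
  cyc_gr <- array(0, dim = c(n_cyc, naz, nel))
  for (k in seq_len(n_cyc)) {
    phase <- k / n_cyc
    adv <- phase * spec$window_width
    green_cols <- in_win & pos < adv                      # edge from the left
    uv_cols <- in_win & pos > spec$window_width - adv     # edge from the right
    fgr <- matrix(0, naz, nel); fgr[green_cols, ] <- gmask[green_cols, ]
    fuv <- matrix(0, naz, nel); fuv[uv_cols, ] <- spec$uv_level
    cyc_gr[k, , ] <- fgr; cyc_uv[k, , ] <- fuv
  }
  if (spec$polarity == "OFF") {  # same frames, reverse order within a cycle
    cyc_uv <- cyc_uv[rev(seq_len(n_cyc)), , , drop = FALSE]
    cyc_gr <- cyc_gr[rev(seq_len(n_cyc)), , , drop = FALSE]
  }
  rep_idx <- rep(seq_len(n_cyc), n_cycles)
  uv <- cyc_uv[rep_idx, , , drop = FALSE]
  green <- cyc_gr[rep_idx, , , drop = FALSE]
  if (spec$rotation == "CCW") {  # reflect along the vertical axis
    uv <- uv[, rev(seq_len(naz)), , drop = FALSE]
    green <- green[, rev(seq_len(naz)), , drop = FALSE]
  }
  time <- seq_len(n_cyc * n_cycles) / frame_rate
  .new_frameset(uv, green, time, grid, frame_rate, spec)
}

#' Read or write a calibration map as CSV
#'
#' @param calib a `cm_calibration`.
#' @param path CSV path (columns azimuth, elevation, uv_irradiance,
#'   green_mask).
#' @return `read_calibration_csv` returns a `cm_calibration` (the scale is
#'   recovered as the mean green/UV ratio).
#' @export
write_calibration_csv <- function(calib, path) {
  .check(inherits(calib, "cm_calibration"), "'calib' must be a cm_calibration")
  utils::write.csv(calib$sites[, c("azimuth", "elevation", "uv_irradiance",
                                   "green_mask")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_calibration_csv
#' @export
read_calibration_csv <- function(path) {
  s <- utils::read.csv(path)
  build_green_mask(s[, c("azimuth", "elevation", "uv_irradiance")],
                   scale = mean(s$green_mask / s$uv_irradiance))
}
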