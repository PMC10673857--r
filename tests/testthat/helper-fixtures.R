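# Shared fixtures and independent oracle implementations.

# small standard movie configuration used by several imaging tests
small_movie <- function(rois, uv_levels = c(0, 3, 5, 6, 8, 10, 12, 15),
                        n_reps = 1, image_size = 64, jitter_sd = 0,
                        noise_sd = 0, column_spacing = 16, seed = 11, ...) {
  simulate_movie(rois, uv_levels = uv_levels, n_reps = n_reps,
                 image_size = image_size, jitter_sd = jitter_sd,
                 noise_sd = noise_sd, column_spacing = column_spacing,
                 seed = seed, ...)
}

# independent integer translation (down `drow` rows, right `dcol` columns)
translate_px <- function(m, drow, dcol, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    sr <- r - drow; sc <- cc - dcol
    if (sr >= 1 && sr <= nr && sc >= 1 && sc <= nc) out[r, cc] <- m[sr, sc]
  }
  out
}

# is a logical mask 4/8-connected? (breadth-first flood from one pixel)
mask_connected <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) <= 1) return(TRUE)
  seen <- matrix(FALSE, nrow(mask), ncol(mask))
  queue <- list(idx[1, ])
  seen[idx[1, 1], idx[1, 2]] <- TRUE
  while (length(queue) > 0) {
    p <- queue[[1]]; queue <- queue[-1]
    for (dr in -1:1) for (dc in -1:1) {
      r <- p[1] + dr; cc <- p[2] + dc
      if (r < 1 || r > nrow(mask) || cc < 1 || cc > ncol(mask)) next
      if (mask[r, cc] && !seen[r, cc]) {
        seen[r, cc] <- TRUE
        queue[[length(queue) + 1]] <- c(r, cc)
      }
    }
  }
  sum(seen) == sum(mask)
}

# Brute-force radial motion oracle: plain per-site loops, neighbor search by
# center distance, no shared code with the package implementation.
oracle_radial_motion <- function(lattice, focus, mode, on_w, off_w) {
  s <- lattice$sites
  w <- lattice$hex_width; h <- lattice$hex_height
  px <- 0.75 * w
  inten <- function(wts) wts[1] * s$meanR + wts[2] * s$meanG + wts[3] * s$meanB
  find_site <- function(x, y) {
    d2 <- (s$x - x)^2 + (s$y - y)^2
    k <- which.min(d2)
    if (d2[k] < 1e-6) k else NA_integer_
  }
  ring_off <- list(c(0, -h), c(0, h), c(px, -h / 2), c(px, h / 2),
                   c(-px, -h / 2), c(-px, h / 2))
  bg_off <- list(
    left  = list(c(-2 * px, 0), c(-2 * px, -h), c(-2 * px, h)),
    up    = list(c(0, -2 * h), c(px, -1.5 * h), c(-px, -1.5 * h)),
    right = list(c(2 * px, 0), c(2 * px, -h), c(2 * px, h)),
    down  = list(c(0, 2 * h), c(px, 1.5 * h), c(-px, 1.5 * h)))
  units <- list(left = c(-1, 0), up = c(0, -1), right = c(1, 0),
                down = c(0, 1))
  ion <- inten(on_w); ioff <- inten(off_w)
  out <- data.frame(site = s$site, on = NA_real_, off = NA_real_,
                    combined = NA_real_)
  for (k in seq_len(nrow(s))) {
    ring <- vapply(ring_off, function(o) find_site(s$x[k] + o[1],
                                                   s$y[k] + o[2]),
                   integer(1))
    if (anyNA(ring)) next
    rvec <- c(s$x[k] - focus[1], s$y[k] - focus[2])
    rl <- sqrt(sum(rvec^2))
    if (rl == 0) next
    rhat <- rvec / rl
    if (mode == "recede") rhat <- -rhat
    on_vec <- c(0, 0); off_vec <- c(0, 0)
    bad <- FALSE
    for (d in names(bg_off)) {
      bg <- vapply(bg_off[[d]], function(o) find_site(s$x[k] + o[1],
                                                      s$y[k] + o[2]),
                   integer(1))
      if (anyNA(bg)) { bad <- TRUE; break }
      ih_on <- mean(ion[c(k, ring)]); ib_on <- mean(ion[bg])
      ih_off <- mean(ioff[c(k, ring)]); ib_off <- mean(ioff[bg])
      c_on <- (ih_on - ib_on) / ib_on
      c_off <- (ih_off - ib_off) / ib_off
      if (c_on > 0) on_vec <- on_vec + units[[d]] * c_on
      if (c_off < 0) off_vec <- off_vec + units[[d]] * (-c_off)
    }
    if (bad) next
    out$on[k] <- sum(on_vec * rhat)
    out$off[k] <- sum(off_vec * rhat)
    out$combined[k] <- out$on[k] + out$off[k]
  }
  out
}
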