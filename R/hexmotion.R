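# Hexagonal-lattice chromatic motion model: sample an RGB image on a
# compound-eye-like hexagonal lattice, compute directional Weber contrasts
# from home/background facet groups, and form radial ON/OFF vector sums
# with channel-asymmetric spectral weights for approach-vs-recede
# comparisons.

#' Sample an RGB image on a hexagonal lattice
#'
#' Flat-topped hexagons of `hex_width` (point-to-point, horizontal) by
#' `hex_height` (flat-to-flat, vertical): centers sit at horizontal pitch
#' `0.75 * hex_width` with alternate columns offset by half a height. Every
#' pixel is assigned to its nearest center (lexicographic tie-break), which
#' tiles the plane with hexagonal cells; for the standard 120 x 104 cell
#' each interior hexagon contains exactly 9360 pixels
#' (`0.75 * 120 * 104`). Site values are the mean R, G, B over member
#' pixels.
#'
#' @param image numeric array `H x W x 3` (or a matrix, replicated to three
#'   identical channels). Pixel `(row, col)` has coordinates
#'   `x = col, y = row`.
#' @param hex_width,hex_height hexagon extent in pixels.
#' @return object of class `cm_hexlattice`: `sites` data frame (`site`,
#'   column/row indices `i`/`j`, center `x`/`y`, `n_pixels`, `meanR/G/B`,
#'   `interior` flag), `assignment` (H x W site-id matrix), and the
#'   lattice geometry.
#' @export
hex_sample <- function(image, hex_width = 120, hex_height = 104) {
  .check(.is_number(hex_width) && hex_width > 0 &&
           .is_number(hex_height) && hex_height > 0,
         "hexagon dimensions must be positive")
  if (is.matrix(image)) image <- array(rep(image, 3),
                                       dim = c(dim(image), 3))
  .check(length(dim(image)) == 3 && dim(image)[3] == 3,
         "'image' must be an H x W x 3 array")
  H <- dim(image)[1]; W <- dim(image)[2]
  .check(W >= hex_width && H >= hex_height,
         "image smaller than one hexagon")
  px <- 0.75 * hex_width  # horizontal pitch
  x <- rep(seq_len(W), each = H)
  y <- rep(seq_len(H), times = W)

  best_d2 <- rep(Inf, length(x))
  best_i <- integer(length(x)); best_j <- integer(length(x))
  best_cx <- numeric(length(x)); best_cy <- numeric(length(x))
  i0 <- round(x / px)
  for (di in -1:1) for (dj in -1:1) {
    ci <- i0 + di
    cx <- px * ci
    off <- (hex_height / 2) * (ci %% 2)
    cj <- round((y - off) / hex_height) + dj
    cy <- hex_height * cj + off
    d2 <- (x - cx)^2 + (y - cy)^2
    better <- d2 < best_d2 |
      (d2 == best_d2 & (cx < best_cx | (cx == best_cx & cy < best_cy)))
    best_d2[better] <- d2[better]
    best_i[better] <- ci[better]; best_j[better] <- cj[better]
    best_cx[better] <- cx[better]; best_cy[better] <- cy[better]
  }

  key <- paste(best_i, best_j)
  uk <- unique(key)
  site_of <- match(key, uk)
  n_sites <- length(uk)
  n_pix <- tabulate(site_of, n_sites)
  sums <- vapply(1:3, function(ch) {
    v <- as.vector(image[, , ch])
    as.vector(rowsum(v, site_of))
  }, numeric(n_sites))
  ij <- do.call(rbind, strsplit(uk, " "))
  si <- as.integer(ij[, 1]); sj <- as.integer(ij[, 2])
  scx <- px * si
  scy <- hex_height * sj + (hex_height / 2) * (si %% 2)
  border <- as.vector(rowsum(as.numeric(x == 1 | x == W | y == 1 | y == H),
                             site_of)) > 0
  sites <- data.frame(site = seq_len(n_sites), i = si, j = sj,
                      x = scx, y = scy, n_pixels = n_pix,
                      meanR = sums[, 1] / n_pix,
                      meanG = sums[, 2] / n_pix,
                      meanB = sums[, 3] / n_pix,
                      interior = !border)
  assignment <- matrix(site_of, H, W)
  structure(list(sites = sites, assignment = assignment,
                 hex_width = hex_width, hex_height = hex_height,
                 dim = c(H, W)),
            class = "cm_hexlattice")
}

#' @export
print.cm_hexlattice <- function(x, ...) {
  cat(sprintf("<cm_hexlattice> %d sites (%d interior), %g x %g px hexagons on %d x %d image\n",
              nrow(x$sites), sum(x$sites$interior),
              x$hex_width, x$hex_height, x$dim[1], x$dim[2]))
  invisible(x)
}

#' Weber contrast
#'
#' `C = (i_h - i_b) / i_b`: the contrast of a home intensity relative to a
#' background intensity.
#'
#' @param i_h,i_b home and background intensities; `i_b` must be positive.
#' @return dimensionless contrast.
#' @examples
#' weber_contrast(150, 100)  # 0.5
#' @export
weber_contrast <- function(i_h, i_b) {
  .check(is.numeric(i_h) && is.numeric(i_b), "intensities must be numeric")
  if (any(i_b <= 0))
    stop("undefined contrast: background intensity must be > 0",
         call. = FALSE)
  (i_h - i_b) / i_b
}

# site-id lookup by center coordinates (rounded key; pitches are far larger
# than float error)
.site_lookup <- function(lattice) {
  s <- lattice$sites
  stats::setNames(s$site, sprintf("%.3f_%.3f", s$x, s$y))
}

.site_at <- function(lookup, x, y) {
  id <- lookup[sprintf("%.3f_%.3f", x, y)]
  ifelse(is.na(id), NA_integer_, id)
}

# offsets (pixels) of the home ring and of the 3-facet background group
# leading the home group in each direction of motion; up is -y
.hex_groups <- function(w, h) {
  px <- 0.75 * w
  ring <- rbind(c(0, -h), c(0, h), c(px, -h / 2), c(px, h / 2),
                c(-px, -h / 2), c(-px, h / 2))
  bg <- list(
    right = rbind(c(2 * px, 0), c(2 * px, -h), c(2 * px, h)),
    left  = rbind(c(-2 * px, 0), c(-2 * px, -h), c(-2 * px, h)),
    up    = rbind(c(0, -2 * h), c(px, -1.5 * h), c(-px, -1.5 * h)),
    down  = rbind(c(0, 2 * h), c(px, 1.5 * h), c(-px, 1.5 * h)))
  list(ring = ring, bg = bg)
}

.unit_vectors <- list(left = c(-1, 0), up = c(0, -1),
                      right = c(1, 0), down = c(0, 1))

#' Directional Weber contrast at a lattice site
#'
#' The home intensity `I_h` is the mean channel-weighted intensity of the
#' site and its six adjacent facets; the background intensity `I_b` is the
#' mean over the three facets adjacent to the home group's leading edge
#' along the direction of motion. Sites lacking any required facet (at the
#' lattice border) are not computed (`NA`).
#'
#' @param lattice a [hex_sample()] lattice.
#' @param site site id.
#' @param direction `"left"`, `"up"`, `"right"` or `"down"` (up is -y).
#' @param channel_weights length-3 RGB weights, summing to 1.
#' @return Weber contrast, or `NA` if the site lacks neighbors.
#' @export
directional_contrast <- function(lattice, site,
                                 direction = c("left", "up", "right", "down"),
                                 channel_weights = c(1, 1, 1) / 3) {
  direction <- match.arg(direction)
  cm <- directional_contrasts(lattice, channel_weights)
  cm[cm$site == site, paste0("c_", direction)]
}

#' Directional Weber contrasts for every site
#'
#' Vectorized form of [directional_contrast()] over all sites and the four
#' cardinal directions.
#'
#' @inheritParams directional_contrast
#' @return data frame: `site`, `x`, `y`, `c_left`, `c_up`, `c_right`,
#'   `c_down` (`NA` where facet groups are incomplete).
#' @export
directional_contrasts <- function(lattice, channel_weights = c(1, 1, 1) / 3) {
  .check(inherits(lattice, "cm_hexlattice"), "'lattice' must be a cm_hexlattice")
  .check(length(channel_weights) == 3 && abs(sum(channel_weights) - 1) < 1e-9,
         "'channel_weights' must be 3 weights summing to 1")
  s <- lattice$sites
  inten <- channel_weights[1] * s$meanR + channel_weights[2] * s$meanG +
    channel_weights[3] * s$meanB
  lookup <- .site_lookup(lattice)
  grp <- .hex_groups(lattice$hex_width, lattice$hex_height)
  ring_ids <- sapply(seq_len(nrow(grp$ring)), function(k)
    .site_at(lookup, s$x + grp$ring[k, 1], s$y + grp$ring[k, 2]))
  ring_ids <- matrix(ring_ids, nrow = nrow(s))
  home_ok <- rowSums(is.na(ring_ids)) == 0
  i_h <- rep(NA_real_, nrow(s))
  hv <- inten[ring_ids[home_ok, , drop = FALSE]]
  hv <- matrix(hv, nrow = sum(home_ok))
  i_h[home_ok] <- (inten[home_ok] + rowSums(hv)) / 7

  out <- data.frame(site = s$site, x = s$x, y = s$y)
  for (d in names(grp$bg)) {
    off <- grp$bg[[d]]
    bg_ids <- sapply(1:3, function(k)
      .site_at(lookup, s$x + off[k, 1], s$y + off[k, 2]))
    bg_ids <- matrix(bg_ids, nrow = nrow(s))
    ok <- home_ok & rowSums(is.na(bg_ids)) == 0
    i_b <- rep(NA_real_, nrow(s))
    bv <- matrix(inten[bg_ids[ok, , drop = FALSE]], nrow = sum(ok))
    i_b[ok] <- rowMeans(bv)
    cc <- rep(NA_real_, nrow(s))
    pos <- ok & !is.na(i_b) & i_b > 0
    if (any(ok & i_b <= 0, na.rm = TRUE))
      warning("sites with non-positive background intensity excluded",
              call. = FALSE)
    cc[pos] <- (i_h[pos] - i_b[pos]) / i_b[pos]
    out[[paste0("c_", d)]] <- cc
  }
  out
}

#' Radial ON/OFF motion estimate per lattice site
#'
#' For every site the four directional contrasts are computed twice, with
#' the ON and the OFF spectral weights. The ON vector is the sum of the
#' cardinal unit vectors weighted by the positive contrasts; the OFF vector
#' uses the magnitudes of the negative contrasts. Both vectors are
#' projected onto the site's radial unit vector pointing away from the
#' expansion focus (`approach`) or toward it (`recede`);
#' `combined = on + off`.
#'
#' @param lattice a [hex_sample()] lattice.
#' @param focus `(x, y)` pixel coordinates of the expansion/contraction
#'   point.
#' @param mode `"approach"` or `"recede"`.
#' @param on_weights,off_weights length-3 RGB weights for the ON and OFF
#'   channels; `(1,0,0)` / `(0,0,1)` implement the red-ON/blue-OFF
#'   configuration.
#' @return object of class `cm_motion`: data frame `site`, `x`, `y`,
#'   `on`, `off`, `combined` (`NA` for border sites), with `mode`, `focus`
#'   and the weights as attributes.
#' @export
radial_motion <- function(lattice, focus, mode = c("approach", "recede"),
                          on_weights = c(1, 1, 1) / 3,
                          off_weights = on_weights) {
  mode <- match.arg(mode)
  .check(length(focus) == 2 && all(is.finite(focus)),
         "'focus' must be (x, y) pixel coordinates")
  .check(focus[1] >= 1 && focus[1] <= lattice$dim[2] &&
           focus[2] >= 1 && focus[2] <= lattice$dim[1],
         "'focus' must lie inside the image")
  con <- directional_contrasts(lattice, on_weights)
  coff <- if (identical(on_weights, off_weights)) con
          else directional_contrasts(lattice, off_weights)
  dirs <- names(.unit_vectors)
  rx <- con$x - focus[1]; ry <- con$y - focus[2]
  rn <- sqrt(rx^2 + ry^2)
  rx <- rx / rn; ry <- ry / rn
  if (mode == "recede") { rx <- -rx; ry <- -ry }
  on_x <- on_y <- off_x <- off_y <- rep(0, nrow(con))
  bad <- rn == 0
  for (d in dirs) {
    u <- .unit_vectors[[d]]
    cvon <- con[[paste0("c_", d)]]
    cvoff <- coff[[paste0("c_", d)]]
    bad <- bad | is.na(cvon) | is.na(cvoff)
    pon <- pmax(cvon, 0); poff <- pmax(-cvoff, 0)
    pon[is.na(pon)] <- 0; poff[is.na(poff)] <- 0
    on_x <- on_x + u[1] * pon; on_y <- on_y + u[2] * pon
    off_x <- off_x + u[1] * poff; off_y <- off_y + u[2] * poff
  }
  on <- on_x * rx + on_y * ry
  off <- off_x * rx + off_y * ry
  on[bad] <- NA; off[bad] <- NA
  out <- data.frame(site = con$site, x = con$x, y = con$y,
                    on = on, off = off, combined = on + off)
  structure(out, mode = mode, focus = focus,
            on_weights = on_weights, off_weights = off_weights,
            class = c("cm_motion", "data.frame"))
}

#' Compare motion estimates between two modes
#'
#' Rank-orders the per-site combined estimates, forms per-site paired
#' differences, and compares the two sets of combined values across
#' hexagonal pixels with a two-sided Wilcoxon rank-sum test (sites with
#' incomplete neighborhoods are dropped from both sets).
#'
#' @param est_a,est_b `cm_motion` estimates over the same lattice sites
#'   (e.g. approach vs recede).
#' @return list: `test` (a `cm_test`), `n_sites`, `median_difference`
#'   (median of a - b), `differences` data frame, and the rank-ordered
#'   `sorted_a`, `sorted_b` values.
#' @export
compare_modes <- function(est_a, est_b) {
  .check(inherits(est_a, "cm_motion") && inherits(est_b, "cm_motion"),
         "inputs must be cm_motion estimates")
  .check(identical(est_a$site, est_b$site), "mismatched site sets")
  ok <- !is.na(est_a$combined) & !is.na(est_b$combined)
  a <- est_a$combined[ok]; b <- est_b$combined[ok]
  .check(length(a) >= 1, "no sites with complete neighborhoods")
  if (all(a == b)) {
    test <- structure(list(kind = "rank_sum", statistic = NA_real_,
                           p_value = 1, sidedness = "two.sided",
                           n = c(n_x = length(a), n_y = length(b)),
                           adjusted_p = NA_real_),
                      class = "cm_test")
  } else {
    test <- run_test("rank_sum", a, b)
  }
  list(test = test, n_sites = length(a),
       median_difference = stats::median(a - b),
       differences = data.frame(site = est_a$site[ok], difference = a - b),
       sorted_a = sort(a), sorted_b = sort(b))
}

#' Export a lattice or motion estimate as CSV
#'
#' @param lattice a `cm_hexlattice`.
#' @param est a `cm_motion`.
#' @param path CSV path.
#' @export
write_lattice_csv <- function(lattice, path) {
  .check(inherits(lattice, "cm_hexlattice"), "'lattice' must be a cm_hexlattice")
  utils::write.csv(lattice$sites, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_lattice_csv
#' @export
write_motion_csv <- function(est, path) {
  .check(inherits(est, "cm_motion"), "'est' must be a cm_motion")
  utils::write.csv(as.data.frame(est), path, row.names = FALSE)
  invisible(path)
}
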