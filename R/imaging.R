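# Calcium-imaging analysis: rigid binary-template alignment, flood-fill ROI
# segmentation, dF/F0, polarity-specific response metrics, responsiveness
# thresholds and ROI/fly/population isoluminance.

# mean image over the frames of all trials at one UV level
.mean_stimulus_image <- function(movie, uv_level) {
  sel <- movie$trials$uv_level == uv_level
  .check(any(sel), sprintf("no trials at UV level %s", uv_level))
  idx <- unlist(lapply(which(sel), function(tr) {
    movie$trials$start_frame[tr] + seq_len(movie$trials$n_frames[tr]) - 1L
  }))
  apply(movie$frames[, , idx, drop = FALSE], c(1, 2), mean)
}

#' Rigidly align a calcium movie to a binary stimulus template
#'
#' The template is the binarized (Otsu) mean fluorescence image over the
#' trials of one designated stimulus - UV = 0 for OFF cells, UV = 15 for ON
#' cells, whose discs drive the strongest responses. Each frame is
#' binarized and its integer shift estimated as the argmax of the spatial
#' cross-correlation with the template (searched within `search` pixels);
#' frames are translated back by the recovered shift. Recordings in which
#' any shift component exceeds `max_shift` (25 px) are flagged for
#' rejection.
#'
#' @param movie a `cm_movie`.
#' @param template_uv UV level whose trials define the template.
#' @param max_shift rejection threshold, pixels.
#' @param search half-width of the shift search, pixels.
#' @return list: `movie` (aligned), `shifts` (frame, `dx` columns, `dy`
#'   rows), `rejected` flag, `template` (binary matrix).
#' @export
align_movie <- function(movie, template_uv, max_shift = 25, search = 32) {
  .check(inherits(movie, "cm_movie"), "'movie' must be a cm_movie")
  nT <- dim(movie$frames)[3]
  .check(nT >= 1, "empty movie")
  tmpl_mean <- .mean_stimulus_image(movie, template_uv)
  tmpl <- (tmpl_mean > otsu_threshold(tmpl_mean)) * 1
  ft <- Conj(stats::fft(tmpl))
  H <- nrow(tmpl); W <- ncol(tmpl)
  ok_r <- c(seq_len(search + 1), H - seq_len(search) + 1)  # wrapped window
  ok_c <- c(seq_len(search + 1), W - seq_len(search) + 1)
  shifts <- matrix(0L, nT, 2)
  fill <- stats::median(movie$frames[, , 1])
  aligned <- movie$frames
  for (k in seq_len(nT)) {
    fr <- movie$frames[, , k]
    frb <- (fr > otsu_threshold(fr)) * 1
    cc <- Re(stats::fft(stats::fft(frb) * ft, inverse = TRUE))
    cc_win <- cc[ok_r, ok_c]
    idx <- which(cc_win == max(cc_win), arr.ind = TRUE)[1, ]
    dr <- ok_r[idx[1]] - 1L; dc <- ok_c[idx[2]] - 1L
    if (dr > H / 2) dr <- dr - H
    if (dc > W / 2) dc <- dc - W
    shifts[k, ] <- c(dc, dr)  # (dx = columns, dy = rows)
    if (dr != 0 || dc != 0)
      aligned[, , k] <- shift_matrix(fr, drow = -dr, dcol = -dc, fill = fill)
  }
  rejected <- any(abs(shifts) > max_shift)
  out <- movie
  out$frames <- aligned
  list(movie = out,
       shifts = data.frame(frame = seq_len(nT),
                           dx = shifts[, 1], dy = shifts[, 2]),
       rejected = rejected, template = tmpl)
}

#' Detect ROIs by smoothing, peak finding and flood filling
#'
#' The mean stimulus image is smoothed with a Gaussian filter of the given
#' full width at half maximum (11 px for the standard recordings), local
#' maxima above a floor (mean + 1 SD of the smoothed image by default)
#' become seeds, peaks closer than `min_separation` are merged into the
#' stronger seed, and a flood fill grows each seed downhill - pixels join
#' the brightest neighbouring territory in order of decreasing intensity -
#' until territories meet or intensity falls below `fill_floor_frac` of the
#' seed's peak. `min_separation` defaults to the 5 um medulla column
#' spacing at the standard 256 px / 34 um field of view; use ~60 px for
#' the 17 um lobula fields.
#'
#' @param mean_image numeric matrix (mean fluorescence over one stimulus).
#' @param fwhm Gaussian smoothing FWHM, pixels.
#' @param min_separation minimum peak separation, pixels.
#' @param peak_floor seed threshold on the smoothed image; default
#'   `mean + sd`.
#' @param fill_floor_frac stop growing below this fraction of the seed peak.
#' @return list: `labels` (integer matrix, 0 = unassigned), `peaks`
#'   (data frame roi, row, col, value), `masks` (list of logical matrices,
#'   disjoint and connected).
#' @export
detect_rois <- function(mean_image, fwhm = 11, min_separation = 38,
                        peak_floor = NULL, fill_floor_frac = 0.2) {
  .check(is.matrix(mean_image) && all(is.finite(mean_image)),
         "'mean_image' must be a finite numeric matrix")
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  sm <- EBImage::gblur(mean_image, sigma = sigma)
  H <- nrow(sm); W <- ncol(sm)
  if (is.null(peak_floor)) peak_floor <- mean(sm) + stats::sd(sm)

  # strict local maxima over the 8-neighbourhood
  pad <- matrix(-Inf, H + 2, W + 2)
  pad[2:(H + 1), 2:(W + 1)] <- sm
  is_max <- matrix(TRUE, H, W)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    is_max <- is_max & (sm > pad[2:(H + 1) + dr, 2:(W + 1) + dc])
  }
  cand <- which(is_max & sm > peak_floor, arr.ind = TRUE)
  if (nrow(cand) == 0)
    return(list(labels = matrix(0L, H, W),
                peaks = data.frame(roi = integer(), row = integer(),
                                   col = integer(), value = numeric()),
                masks = list()))
  vals <- sm[cand]
  ord <- order(vals, decreasing = TRUE)
  cand <- cand[ord, , drop = FALSE]; vals <- vals[ord]
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!any(keep)) { keep[i] <- TRUE; next }
    d2 <- (cand[keep, 1] - cand[i, 1])^2 + (cand[keep, 2] - cand[i, 2])^2
    if (all(d2 >= min_separation^2)) keep[i] <- TRUE
  }
  peaks <- cand[keep, , drop = FALSE]; pv <- vals[keep]
  n_roi <- nrow(peaks)

  labels <- matrix(0L, H, W)
  labels[peaks] <- seq_len(n_roi)
  floor_k <- fill_floor_frac * pv
  # grow in order of decreasing smoothed intensity: each pixel joins the
  # brightest already-labelled neighbour, if above its seed's floor
  todo <- which(sm >= min(floor_k) & labels == 0)
  todo <- todo[order(sm[todo], decreasing = TRUE)]
  for (px in todo) {
    r <- ((px - 1) %% H) + 1; cc <- ((px - 1) %/% H) + 1
    best_lab <- 0L; best_val <- -Inf
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rr <- r + dr; ccc <- cc + dc
      if (rr < 1 || rr > H || ccc < 1 || ccc > W) next
      lab <- labels[rr, ccc]
      if (lab > 0 && sm[rr, ccc] > best_val) {
        best_val <- sm[rr, ccc]; best_lab <- lab
      }
    }
    if (best_lab > 0 && sm[px] >= floor_k[best_lab]) labels[px] <- best_lab
  }
  masks <- lapply(seq_len(n_roi), function(k) labels == k)
  list(labels = labels,
       peaks = data.frame(roi = seq_len(n_roi), row = peaks[, 1],
                          col = peaks[, 2], value = pv),
       masks = masks)
}

#' Per-trial dF/F0 traces for one ROI
#'
#' F0 is the mean mask fluorescence over the `baseline_window` seconds
#' before stimulus onset, computed per trial; the trace is `(F - F0) / F0`.
#' ROIs whose F0 is not positive are flagged invalid.
#'
#' @param movie an (aligned) `cm_movie`.
#' @param mask logical matrix selecting the ROI pixels.
#' @param baseline_window seconds before onset (1.5).
#' @return list: `dff` (trials x frames matrix), `f0` per trial, `valid`.
#' @export
roi_dff <- function(movie, mask, baseline_window = 1.5) {
  .check(inherits(movie, "cm_movie"), "'movie' must be a cm_movie")
  .check(is.logical(mask) && any(mask), "'mask' must select at least one pixel")
  onset <- movie$params$onset
  .check(onset >= baseline_window - 1e-9,
         "trial has less pre-stimulus time than the baseline window")
  base_idx <- which(movie$time >= onset - baseline_window & movie$time < onset)
  .check(length(base_idx) >= 1, "no frames in the baseline window")
  n_tr <- nrow(movie$trials); nf <- movie$trials$n_frames[1]
  flat <- matrix(movie$frames, nrow = prod(dim(movie$frames)[1:2]))
  midx <- which(as.vector(mask))
  dff <- matrix(NA_real_, n_tr, nf)
  f0 <- numeric(n_tr)
  for (tr in seq_len(n_tr)) {
    cols <- movie$trials$start_frame[tr] + seq_len(nf) - 1L
    trace <- colMeans(flat[midx, cols, drop = FALSE])
    f0[tr] <- mean(trace[base_idx])
    dff[tr, ] <- if (f0[tr] > 0) (trace - f0[tr]) / f0[tr] else NA_real_
  }
  list(dff = dff, f0 = f0, valid = all(f0 > 0))
}

#' Two-frame response metric and tuning curve for one ROI
#'
#' The response to each trial is the mean dF/F0 of the two imaging frames
#' immediately after the designated event - full disc expansion for most
#' cell classes (a 150 ms interval at the 6.83 Hz T4/T5 frame rate), or the
#' return to green for Dm9-style cells.
#'
#' @param dff trials x frames dF/F0 matrix from [roi_dff()].
#' @param movie the `cm_movie` the traces came from.
#' @param event `"expansion_end"` or `"return_green"`.
#' @param n_frames frames in the response window (2).
#' @param polarity curve tag, `"roi_on"` or `"roi_off"`.
#' @return a [tuning_curve()] over the movie's UV levels.
#' @export
roi_metric_curve <- function(dff, movie, event = c("expansion_end",
                                                   "return_green"),
                             n_frames = 2, polarity = "roi_on") {
  event <- match.arg(event)
  t_event <- movie$params[[event]]
  idx <- which(movie$time >= t_event - 1e-9)
  .check(length(idx) >= n_frames, "response window lies outside the trial")
  idx <- idx[seq_len(n_frames)]
  vals <- rowMeans(dff[, idx, drop = FALSE])
  tuning_curve(movie$trials$uv_level, vals, polarity = polarity)
}

#' ROI isoluminance: polarity-specific zero-crossing scan
#'
#' OFF-sensitive ROIs respond positively at low UV; scanning upward from
#' UV = 0, the first adjacent pair crossing from `>= 0` to `< 0` is linearly
#' interpolated. ON-sensitive ROIs are scanned downward from UV = 15
#' symmetrically. When the response never goes negative, the level of the
#' curve's minimum response is returned with `crossing_found = FALSE`; when
#' the first scanned level is already negative, that boundary level is
#' returned capped.
#'
#' @param curve a [tuning_curve()].
#' @param polarity `"ON"` or `"OFF"`.
#' @return a `cm_iso` (see [estimate_isoluminance()]), `method` `"roi_on"`
#'   or `"roi_off"`.
#' @examples
#' off <- tuning_curve(c(7, 8), c(0.1, -0.1))
#' roi_isoluminance(off, "OFF")$value  # 7.5
#' @export
roi_isoluminance <- function(curve, polarity = c("ON", "OFF")) {
  .check(inherits(curve, "cm_tuning"), "'curve' must be a cm_tuning")
  polarity <- match.arg(polarity)
  u <- curve$uv_levels; m <- curve$mean_response
  .check(length(u) >= 2, "need at least 2 levels to estimate isoluminance")
  if (polarity == "ON") { u <- rev(u); m <- rev(m) }  # scan down from 15
  value <- NA_real_; capped <- FALSE; crossing <- FALSE
  if (m[1] < 0) {
    value <- u[1]; capped <- TRUE
  } else {
    for (i in seq_len(length(u) - 1)) {
      if (m[i] >= 0 && m[i + 1] < 0) {
        value <- u[i] + (u[i + 1] - u[i]) * (0 - m[i]) / (m[i + 1] - m[i])
        crossing <- TRUE
        break
      }
    }
    if (!crossing) value <- u[which.min(m)]  # no zero crossing: the minimum
  }
  structure(list(value = value, capped = capped, crossing_found = crossing,
                 method = paste0("roi_", tolower(polarity))),
            class = "cm_iso")
}

#' Mean response over the polarity's reference levels
#'
#' The responsiveness statistic thresholded by [threshold_responsive()]:
#' mean tuning-curve response over UV 12-15 for ON-sensitive cells, UV 0-3
#' for OFF-sensitive cells (UV 0-1 for Dm9-style cells via
#' `reference_levels`).
#'
#' @param curve a [tuning_curve()].
#' @param polarity `"ON"` or `"OFF"`.
#' @param reference_levels override of the reference UV levels.
#' @return mean response over the reference levels present in the curve.
#' @export
responsiveness <- function(curve, polarity = c("ON", "OFF"),
                           reference_levels = NULL) {
  polarity <- match.arg(polarity)
  if (is.null(reference_levels))
    reference_levels <- if (polarity == "ON") 12:15 else 0:3
  sel <- curve$uv_levels %in% reference_levels
  .check(any(sel), "no reference levels present in the curve")
  mean(curve$mean_response[sel])
}

#' Keep ROIs whose reference response clears a threshold
#'
#' @param rois data frame of per-ROI results containing a `ref_response`
#'   column (see [analyze_movie()]).
#' @param threshold minimum reference response; 0 keeps every ROI.
#' @return the filtered data frame.
#' @export
threshold_responsive <- function(rois, threshold) {
  .check(is.data.frame(rois) && "ref_response" %in% names(rois),
         "'rois' must contain a ref_response column")
  rois[rois$ref_response >= threshold, , drop = FALSE]
}

#' Sweep the responsiveness threshold
#'
#' Recomputes the two-level (ROI to fly, fly to grand mean) isoluminance
#' aggregate at each threshold, reporting how the estimate and the number
#' of contributing flies evolve as weakly responding ROIs are removed.
#'
#' @param rois per-ROI results with columns `fly_id`, `isoluminance`,
#'   `ref_response`.
#' @param thresholds numeric vector of thresholds.
#' @return data frame: `threshold`, `mean_iso` (grand mean), `sem` (across
#'   flies), `n_flies`, `n_rois`.
#' @export
threshold_sweep <- function(rois, thresholds) {
  out <- lapply(thresholds, function(th) {
    kept <- threshold_responsive(rois, th)
    if (nrow(kept) == 0)
      return(data.frame(threshold = th, mean_iso = NA_real_, sem = NA_real_,
                        n_flies = 0L, n_rois = 0L))
    agg <- aggregate_isoluminance(kept)
    data.frame(threshold = th, mean_iso = agg$grand_mean,
               sem = stats::sd(agg$per_fly$mean_iso) /
                 sqrt(nrow(agg$per_fly)),
               n_flies = nrow(agg$per_fly), n_rois = nrow(kept))
  })
  do.call(rbind, out)
}

#' Two-level aggregation of ROI isoluminance estimates
#'
#' ROIs are averaged within each fly, then flies averaged with equal
#' weight, so flies with many ROIs do not dominate the population value.
#'
#' @param rois data frame with columns `fly_id` and `isoluminance`.
#' @return list: `per_fly` (fly_id, mean_iso, n_rois), `grand_mean`,
#'   `n_flies`.
#' @export
aggregate_isoluminance <- function(rois) {
  .check(is.data.frame(rois) &&
           all(c("fly_id", "isoluminance") %in% names(rois)),
         "'rois' needs fly_id and isoluminance columns")
  .check(nrow(rois) >= 1, "no ROIs to aggregate")
  per_fly <- stats::aggregate(isoluminance ~ fly_id, data = rois, FUN = mean)
  names(per_fly)[2] <- "mean_iso"
  per_fly$n_rois <- as.vector(table(rois$fly_id)[per_fly$fly_id])
  list(per_fly = per_fly, grand_mean = mean(per_fly$mean_iso),
       n_flies = nrow(per_fly))
}

#' Population isoluminance from per-fly tuning curves
#'
#' Averages the curves across flies (equal weight) and applies the
#' polarity-specific zero-crossing scan to the mean curve.
#'
#' @param curves list of per-fly [tuning_curve()]s on identical levels.
#' @param polarity `"ON"` or `"OFF"`.
#' @return a `cm_iso`.
#' @export
population_isoluminance <- function(curves, polarity) {
  roi_isoluminance(population_curve(curves), polarity)
}

#' Full imaging pipeline for one fly's movie
#'
#' Runs alignment, ROI detection on the mean template-stimulus image,
#' dF/F0 extraction, the two-frame response metric, responsiveness scoring
#' and the polarity-specific isoluminance estimate for every detected ROI.
#'
#' @param movie a `cm_movie`.
#' @param polarity `"ON"` or `"OFF"`; also selects the default template
#'   stimulus (UV = 15 for ON cells, UV = 0 for OFF).
#' @param fly_id identifier copied into the result rows.
#' @param template_uv override of the template stimulus level.
#' @param fwhm,min_separation,peak_floor,fill_floor_frac see
#'   [detect_rois()].
#' @param metric_event,n_metric_frames see [roi_metric_curve()].
#' @param threshold responsiveness threshold applied to the result (0 keeps
#'   all ROIs).
#' @param reference_levels see [responsiveness()].
#' @param max_shift,search see [align_movie()].
#' @param baseline_window see [roi_dff()].
#' @return list: `rois` (per-ROI data frame: fly_id, roi, polarity,
#'   isoluminance, capped, crossing_found, ref_response, peak coordinates),
#'   `curves` (per-ROI tuning curves), `peaks`, `labels`, `shifts`,
#'   `rejected`. When the recording is rejected for excessive motion the
#'   ROI table is empty.
#' @export
analyze_movie <- function(movie, polarity = c("ON", "OFF"), fly_id = "fly1",
                          template_uv = NULL, fwhm = 11,
                          min_separation = 38, peak_floor = NULL,
                          fill_floor_frac = 0.2,
                          metric_event = "expansion_end",
                          n_metric_frames = 2, threshold = 0,
                          reference_levels = NULL, max_shift = 25,
                          search = 32, baseline_window = 1.5) {
  polarity <- match.arg(polarity)
  if (is.null(template_uv))
    template_uv <- if (polarity == "ON") max(movie$trials$uv_level)
                   else min(movie$trials$uv_level)
  al <- align_movie(movie, template_uv, max_shift = max_shift,
                    search = search)
  empty <- data.frame(fly_id = character(), roi = integer(),
                      polarity = character(), isoluminance = numeric(),
                      capped = logical(), crossing_found = logical(),
                      ref_response = numeric(), peak_row = integer(),
                      peak_col = integer(), stringsAsFactors = FALSE)
  if (al$rejected)
    return(list(rois = empty, curves = list(), peaks = NULL, labels = NULL,
                shifts = al$shifts, rejected = TRUE))
  mean_img <- .mean_stimulus_image(al$movie, template_uv)
  det <- detect_rois(mean_img, fwhm = fwhm, min_separation = min_separation,
                     peak_floor = peak_floor,
                     fill_floor_frac = fill_floor_frac)
  rows <- list(); curves <- list()
  for (k in seq_along(det$masks)) {
    tr <- roi_dff(al$movie, det$masks[[k]], baseline_window = baseline_window)
    if (!tr$valid) next
    cv <- roi_metric_curve(tr$dff, al$movie, event = metric_event,
                           n_frames = n_metric_frames,
                           polarity = paste0("roi_", tolower(polarity)))
    est <- roi_isoluminance(cv, polarity)
    curves[[length(curves) + 1L]] <- cv
    rows[[length(rows) + 1L]] <- data.frame(
      fly_id = fly_id, roi = k, polarity = polarity,
      isoluminance = est$value, capped = est$capped,
      crossing_found = est$crossing_found,
      ref_response = responsiveness(cv, polarity, reference_levels),
      peak_row = det$peaks$row[k], peak_col = det$peaks$col[k],
      stringsAsFactors = FALSE)
  }
  rois <- if (length(rows)) do.call(rbind, rows) else empty
  rois <- threshold_responsive(rois, threshold)
  list(rois = rois, curves = curves, peaks = det$peaks,
       labels = det$labels, shifts = al$shifts, rejected = FALSE)
}
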