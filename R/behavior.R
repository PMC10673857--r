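# Behavioral analysis: trial folding, response metrics, tuning curves and
# the zero-crossing isoluminance estimator for wingbeat recordings.

#' Fold clockwise/counterclockwise (or right/left) trials
#'
#' Counterclockwise and left-side responses are sign-inverted and pooled
#' with their clockwise/right counterparts, doubling the per-stimulus trial
#' count. Every `(protocol, uv_level)` stimulus must have equally many
#' trials of each rotation; unmatched trials raise an error naming them.
#'
#' @param rec a `cm_wba` recording.
#' @return a `cm_wba` with inverted-and-pooled traces (`rotation` set to
#'   `"folded"`).
#' @export
fold_trials <- function(rec) {
  .check(inherits(rec, "cm_wba"), "'rec' must be a cm_wba")
  inv <- rec$meta$rotation %in% c("CCW", "left")
  .check(any(inv) && any(!inv), "recording lacks one of the two rotations")
  key <- interaction(rec$meta$protocol, rec$meta$uv_level, drop = TRUE)
  n_pos <- tapply(!inv, key, sum)
  n_inv <- tapply(inv, key, sum)
  bad <- names(n_pos)[n_pos != n_inv]
  if (length(bad) > 0) {
    orphans <- rec$meta$trial[key %in% bad]
    stop("unmatched rotation trials for stimulus ", paste(bad, collapse = ", "),
         " (trials ", paste(orphans, collapse = ", "), ")", call. = FALSE)
  }
  out <- rec
  out$traces[inv, ] <- -out$traces[inv, , drop = FALSE]
  out$meta$rotation <- "folded"
  out
}

#' Disc response metric: mean dWBA just after full expansion
#'
#' The mean of the samples in the 100 ms half-open window
#' `[expansion_end, expansion_end + 0.1)` (50 samples at 500 Hz).
#'
#' @param trace numeric dWBA trace; sample `i` is at time `(i - 1) / fs`.
#' @param expansion_end_time seconds from trace start.
#' @param fs sampling rate, Hz.
#' @return mean response over the window.
#' @export
disc_metric <- function(trace, expansion_end_time, fs = 500) {
  .window_mean(trace, expansion_end_time, 0.1, fs)
}

#' Edge response metric: mean dWBA over the stimulus
#'
#' The mean over the half-open window `[stim_start, stim_start + duration)`;
#' the competing-edge stimuli last 2 s.
#'
#' @inheritParams disc_metric
#' @param stim_start stimulus onset, seconds from trace start.
#' @param stim_duration seconds (2).
#' @export
edge_metric <- function(trace, stim_start = 0, stim_duration = 2, fs = 500) {
  .window_mean(trace, stim_start, stim_duration, fs)
}

.window_mean <- function(trace, t0, dur, fs) {
  .check(is.numeric(trace) && length(trace) >= 1, "'trace' must be numeric")
  times <- (seq_along(trace) - 1) / fs
  .check(t0 >= 0 && t0 + dur <= length(trace) / fs + 1e-9,
         "response window lies outside the trace")
  mean(trace[times >= t0 - 1e-9 & times < t0 + dur - 1e-9])
}

#' Build a tuning curve from per-trial response values
#'
#' @param uv_level integer UV level per trial value.
#' @param value per-trial response metric.
#' @param polarity tag (`"behavior_on"`, `"behavior_off"`, `"roi_on"`, ...).
#' @param cap optional `c(lo, hi)` level-range cap (the compact 3-9 protocol
#'   caps estimates at its range boundaries).
#' @return object of class `cm_tuning`: sorted `uv_levels`, `mean_response`,
#'   `per_trial` values per level, `polarity`, `cap`.
#' @export
tuning_curve <- function(uv_level, value, polarity = "behavior", cap = NULL) {
  .check(length(uv_level) == length(value) && length(value) >= 1,
         "uv_level and value must be non-empty and matched")
  .check(!anyNA(value), "response values contain NA")
  lv <- sort(unique(uv_level))
  per_trial <- lapply(lv, function(l) value[uv_level == l])
  structure(list(uv_levels = lv,
                 mean_response = vapply(per_trial, mean, numeric(1)),
                 per_trial = per_trial, polarity = polarity, cap = cap),
            class = "cm_tuning")
}

#' @export
print.cm_tuning <- function(x, ...) {
  cat(sprintf("<cm_tuning> %s: %d levels (%s), mean response %s\n",
              x$polarity, length(x$uv_levels),
              paste(x$uv_levels, collapse = ","),
              paste(sprintf("%.3g", x$mean_response), collapse = ", ")))
  invisible(x)
}

#' Behavioral isoluminance: first upward zero crossing from UV = 0
#'
#' Scanning the levels in increasing order, finds the first adjacent pair
#' with `mean(u1) <= 0 < mean(u2)` and linearly interpolates to the zero.
#' If the first level's mean is already positive the first level is returned
#' (capped); with no crossing the last level is returned (capped). A curve
#' `cap` range additionally clamps the value to its bounds.
#'
#' @param curve a [tuning_curve()] with at least two levels.
#' @return object of class `cm_iso`: `value`, `capped`, `crossing_found`,
#'   `method`.
#' @examples
#' cv <- tuning_curve(c(4, 4, 5, 5), c(-0.5, -0.5, 0.5, 0.5))
#' estimate_isoluminance(cv)$value  # 4.5
#' @export
estimate_isoluminance <- function(curve) {
  .check(inherits(curve, "cm_tuning"), "'curve' must be a cm_tuning")
  u <- curve$uv_levels; m <- curve$mean_response
  .check(length(u) >= 2, "need at least 2 levels to estimate isoluminance")
  value <- NA_real_; capped <- FALSE; crossing <- FALSE
  if (m[1] > 0) {
    value <- u[1]; capped <- TRUE
  } else {
    for (i in seq_len(length(u) - 1)) {
      if (m[i] <= 0 && m[i + 1] > 0) {
        value <- u[i] + (u[i + 1] - u[i]) * (0 - m[i]) / (m[i + 1] - m[i])
        crossing <- TRUE
        break
      }
    }
    if (!crossing) { value <- u[length(u)]; capped <- TRUE }
  }
  if (!is.null(curve$cap)) {
    clamped <- min(max(value, curve$cap[1]), curve$cap[2])
    if (clamped != value) capped <- TRUE
    value <- clamped
  }
  structure(list(value = value, capped = capped, crossing_found = crossing,
                 method = "behavior_increasing"),
            class = "cm_iso")
}

#' @export
print.cm_iso <- function(x, ...) {
  cat(sprintf("<cm_iso> %s: %.3f%s%s\n", x$method, x$value,
              if (x$capped) " [capped]" else "",
              if (!x$crossing_found) " [no crossing]" else ""))
  invisible(x)
}

#' Average tuning curves across flies
#'
#' Per-level mean across flies with every fly weighted equally; applying the
#' isoluminance estimator to the result gives the population isoluminance.
#'
#' @param curves list of [tuning_curve()]s sharing identical `uv_levels`.
#' @return a `cm_tuning` whose `per_trial` entries are the per-fly means.
#' @export
population_curve <- function(curves) {
  .check(is.list(curves) && length(curves) >= 1 &&
           all(vapply(curves, inherits, logical(1), "cm_tuning")),
         "'curves' must be a list of cm_tuning objects")
  lv <- curves[[1]]$uv_levels
  for (cv in curves)
    .check(identical(cv$uv_levels, lv), "curves have mismatched uv_levels")
  fly_means <- vapply(curves, function(cv) cv$mean_response,
                      numeric(length(lv)))
  fly_means <- matrix(fly_means, nrow = length(lv))
  structure(list(uv_levels = lv,
                 mean_response = rowMeans(fly_means),
                 per_trial = lapply(seq_along(lv),
                                    function(i) fly_means[i, ]),
                 polarity = curves[[1]]$polarity,
                 cap = curves[[1]]$cap),
            class = "cm_tuning")
}

#' Per-fly isoluminance estimates from a wingbeat recording
#'
#' Folds rotations, computes the protocol-appropriate response metric per
#' trial (100 ms post-expansion window for discs, 2 s stimulus mean for
#' edges), builds one tuning curve per protocol and applies
#' [estimate_isoluminance()]. Compact-protocol recordings are capped at
#' their level range.
#'
#' @param rec a `cm_wba` recording.
#' @return data frame with one row per protocol: `fly_id`, `protocol`,
#'   `value`, `capped`, `crossing_found`; tuning curves attached as the
#'   `"curves"` attribute.
#' @export
fly_isoluminance <- function(rec) {
  folded <- fold_trials(rec)
  cap <- if (isTRUE(folded$compact))
    range(folded$meta$uv_level) else NULL
  protos <- unique(folded$meta$protocol)
  curves <- list(); rows <- list()
  for (p in protos) {
    sel <- folded$meta$protocol == p
    vals <- vapply(which(sel), function(k) {
      if (startsWith(p, "disc"))
        disc_metric(folded$traces[k, ], folded$stim$expansion_end, folded$fs)
      else
        edge_metric(folded$traces[k, ], 0, folded$stim$edge_duration,
                    folded$fs)
    }, numeric(1))
    cv <- tuning_curve(folded$meta$uv_level[sel], vals,
                       polarity = p, cap = cap)
    est <- estimate_isoluminance(cv)
    curves[[p]] <- cv
    rows[[p]] <- data.frame(fly_id = rec$fly_id, protocol = p,
                            value = est$value, capped = est$capped,
                            crossing_found = est$crossing_found,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "curves") <- curves
  out
}
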