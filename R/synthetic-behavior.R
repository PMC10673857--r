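# Synthetic ground truth and behavioral (wingbeat) data generation. The
# generators exist so that every analysis stage can be validated against
# known ground truth: tuning curves cross zero at configurable UV levels,
# separately for the ON- and OFF-motion protocols.

#' Ground truth for a synthetic fly
#'
#' @param i_on,i_off true ON- and OFF-motion isoluminance levels, UV-level
#'   units in `[0, 15]`. The biological regime has `i_on < i_off` (the ON
#'   pathway is more UV-sensitive).
#' @param amplitude response amplitude (dWBA units).
#' @param noise_sd per-trial Gaussian noise SD (dWBA units).
#' @param n_trials trials per stimulus per rotation/side.
#' @param seed integer RNG seed, or `NULL`.
#' @return object of class `cm_ground_truth`.
#' @export
ground_truth <- function(i_on = 4.5, i_off = 9.2, amplitude = 1,
                         noise_sd = 0.05, n_trials = 5, seed = NULL) {
  .check(.is_number(i_on) && i_on >= 0 && i_on <= 15, "'i_on' must be in [0, 15]")
  .check(.is_number(i_off) && i_off >= 0 && i_off <= 15, "'i_off' must be in [0, 15]")
  .check(.is_number(amplitude) && amplitude > 0, "'amplitude' must be > 0")
  .check(.is_number(noise_sd) && noise_sd >= 0, "'noise_sd' must be >= 0")
  .check(.is_number(n_trials) && n_trials >= 1 && n_trials == round(n_trials),
         "'n_trials' must be a positive integer")
  structure(list(i_on = i_on, i_off = i_off, amplitude = amplitude,
                 noise_sd = noise_sd, n_trials = as.integer(n_trials),
                 seed = seed),
            class = "cm_ground_truth")
}

#' Predict whether an expanding disc is visible to the motion pathways
#'
#' A UV disc on a calibrated green background always has motion contrast for
#' at least one pathway: OFF contrast below the OFF isoluminance, ON contrast
#' above the ON isoluminance, and the two bands overlap when
#' `i_on < i_off`. A green disc on a UV background is invisible exactly when
#' the background UV level lies strictly inside `(i_on, i_off)`: there the
#' disc is isoluminant-or-worse for both pathways and generates no motion
#' contrast.
#'
#' @param disc_channel `"UV_on_green"` or `"green_on_UV"`.
#' @param uv_level UV intensity 0-15 of the disc (`UV_on_green`) or of the
#'   background (`green_on_UV`); vectorized.
#' @param i_on,i_off pathway isoluminance levels; requires `i_on <= i_off`.
#' @return character vector, `"visible"` or `"invisible"`.
#' @examples
#' predict_visibility("green_on_UV", 7, 4.5, 9.2)   # invisible
#' predict_visibility("UV_on_green", 7, 4.5, 9.2)   # visible
#' @export
predict_visibility <- function(disc_channel = c("UV_on_green", "green_on_UV"),
                               uv_level, i_on, i_off) {
  disc_channel <- match.arg(disc_channel)
  .check(is.numeric(uv_level) && all(uv_level >= 0 & uv_level <= 15),
         "'uv_level' must be in [0, 15]")
  .check(.is_number(i_on) && .is_number(i_off), "'i_on'/'i_off' must be numbers")
  if (i_on > i_off)
    stop("unsupported regime: i_on > i_off", call. = FALSE)
  if (disc_channel == "UV_on_green") {
    rep("visible", length(uv_level))
  } else {
    ifelse(uv_level > i_on & uv_level < i_off, "invisible", "visible")
  }
}

# contrast margin driving the synthetic disc response: distance to the
# nearer visibility boundary (0 when the disc is invisible)
.disc_margin <- function(disc_channel, uv_level, i_on, i_off) {
  if (disc_channel == "UV_on_green") {
    pmax(uv_level - i_on, i_off - uv_level)   # overlapping ON/OFF bands
  } else {
    pmax(i_on - uv_level, uv_level - i_off, 0)
  }
}

.standard_uv_levels <- c(0, 2, 4, 5, 6, 7, 8, 9, 10, 12, 15)

#' Simulate a tethered-flight wingbeat recording
#'
#' Generates per-trial dWBA traces whose analysis metrics have a known
#' structure. Competing-edge trials carry a constant signal
#' `amplitude * tanh((uv - I) / sigmoid_slope)` over the 2 s stimulus, with
#' `I = i_on` for the ON protocol and `i_off` for OFF, so the mean response
#' crosses zero exactly at the true isoluminance. Expanding-disc trials are
#' flat until full expansion, then carry
#' `amplitude * tanh(margin / sigmoid_slope)` where the margin is the
#' distance of the UV level to the nearer visibility boundary (zero for
#' invisible green-on-UV discs, see [predict_visibility()]).
#' Counterclockwise (or left-side) trials are sign-inverted copies, matching
#' the mirror symmetry of the display. Per-trial Gaussian offsets of SD
#' `noise_sd` plus per-sample white noise of the same SD are added.
#'
#' @param gt a [ground_truth()].
#' @param protocol one of `"disc_uv"`, `"disc_green"`, `"edges_on"`,
#'   `"edges_off"`, `"edges_compact"` (the 3-9 protocol measuring ON and OFF
#'   in the same fly).
#' @param uv_levels UV levels to present; defaults to the standard set
#'   `{0,2,4,5,6,7,8,9,10,12,15}`, restricted to `3:9` for the compact
#'   protocol.
#' @param fs sampling rate, Hz (500).
#' @param fly_id identifier stored with the recording.
#' @param sigmoid_slope softness of the response nonlinearity, UV-level units.
#' @return object of class `cm_wba`: `traces` (trials x samples matrix over
#'   the 2 s stimulus window), `meta` (trial, protocol, uv_level, rotation),
#'   `fs`, `fly_id`, `compact` flag and `stim` timing (`expansion_end`,
#'   `edge_duration`).
#' @export
simulate_behavior <- function(gt, protocol = c("disc_uv", "disc_green",
                                               "edges_on", "edges_off",
                                               "edges_compact"),
                              uv_levels = NULL, fs = 500, fly_id = "fly1",
                              sigmoid_slope = 2) {
  .check(inherits(gt, "cm_ground_truth"), "'gt' must be a ground_truth object")
  protocol <- match.arg(protocol)
  if (is.null(uv_levels))
    uv_levels <- if (protocol == "edges_compact") 3:9 else .standard_uv_levels
  .check(length(uv_levels) >= 1, "empty uv_levels")
  .check(all(uv_levels >= 0 & uv_levels <= 15 & uv_levels == round(uv_levels)),
         "uv_levels must be integers in 0-15")
  uv_levels <- sort(unique(as.integer(uv_levels)))
  if (protocol == "edges_compact")
    .check(all(uv_levels >= 3 & uv_levels <= 9),
           "compact protocol uses UV levels 3-9 only")

  dur <- 2; n_samp <- round(dur * fs)
  t_samp <- (seq_len(n_samp) - 1) / fs
  expansion_end <- 1  # discs: 1 s expansion then 1 s hold within the window

  sub_protocols <- switch(protocol,
                          edges_compact = c("edges_on", "edges_off"),
                          protocol)
  is_disc <- startsWith(protocol, "disc")
  rotations <- if (is_disc) c("right", "left") else c("CW", "CCW")

  grid <- expand.grid(rep = seq_len(gt$n_trials), rotation = rotations,
                      uv_level = uv_levels, protocol = sub_protocols,
                      stringsAsFactors = FALSE)
  n_tr <- nrow(grid)

  with_seed(gt$seed, {
    traces <- matrix(0, n_tr, n_samp)
    for (k in seq_len(n_tr)) {
      uv <- grid$uv_level[k]
      if (is_disc) {
        channel <- if (protocol == "disc_uv") "UV_on_green" else "green_on_UV"
        d <- .disc_margin(channel, uv, gt$i_on, gt$i_off)
        mu <- gt$amplitude * tanh(d / sigmoid_slope)
        signal <- ifelse(t_samp >= expansion_end, mu, 0)
      } else {
        iso <- if (grid$protocol[k] == "edges_on") gt$i_on else gt$i_off
        signal <- rep(gt$amplitude * tanh((uv - iso) / sigmoid_slope), n_samp)
      }
      if (grid$rotation[k] %in% c("CCW", "left")) signal <- -signal
      traces[k, ] <- signal + stats::rnorm(1, 0, gt$noise_sd) +
        stats::rnorm(n_samp, 0, gt$noise_sd)
    }
    structure(list(traces = traces,
                   meta = data.frame(trial = seq_len(n_tr),
                                     protocol = grid$protocol,
                                     uv_level = grid$uv_level,
                                     rotation = grid$rotation,
                                     stringsAsFactors = FALSE),
                   fs = fs, fly_id = fly_id,
                   compact = protocol == "edges_compact",
                   stim = list(expansion_end = expansion_end,
                               edge_duration = dur)),
              class = "cm_wba")
  })
}

#' @export
print.cm_wba <- function(x, ...) {
  cat(sprintf("<cm_wba> fly %s: %d trials x %d samples at %g Hz (%s)\n",
              x$fly_id, nrow(x$traces), ncol(x$traces), x$fs,
              paste(unique(x$meta$protocol), collapse = ", ")))
  invisible(x)
}

#' Read or write a wingbeat recording as long-format CSV
#'
#' Columns: `fly_id, trial, protocol, uv_level, rotation, t, dwba`.
#'
#' @param rec a `cm_wba` recording.
#' @param path CSV path.
#' @return `read_wba_csv` returns a `cm_wba`.
#' @export
write_wba_csv <- function(rec, path) {
  .check(inherits(rec, "cm_wba"), "'rec' must be a cm_wba")
  n_samp <- ncol(rec$traces)
  t_samp <- (seq_len(n_samp) - 1) / rec$fs
  long <- data.frame(fly_id = rec$fly_id,
                     trial = rep(rec$meta$trial, each = n_samp),
                     protocol = rep(rec$meta$protocol, each = n_samp),
                     uv_level = rep(rec$meta$uv_level, each = n_samp),
                     rotation = rep(rec$meta$rotation, each = n_samp),
                     t = rep(t_samp, times = nrow(rec$traces)),
                     dwba = as.vector(t(rec$traces)))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_wba_csv
#' @export
read_wba_csv <- function(path) {
  long <- utils::read.csv(path)
  trials <- unique(long$trial)
  n_samp <- sum(long$trial == trials[1])
  fs <- 1 / diff(long$t[1:2])
  traces <- matrix(long$dwba, length(trials), n_samp, byrow = TRUE)
  meta <- long[!duplicated(long$trial),
               c("trial", "protocol", "uv_level", "rotation")]
  rownames(meta) <- NULL
  structure(list(traces = traces, meta = meta, fs = fs,
                 fly_id = long$fly_id[1],
                 compact = all(long$uv_level >= 3 & long$uv_level <= 9) &&
                   all(c("edges_on", "edges_off") %in% long$protocol),
                 stim = list(expansion_end = 1, edge_duration = 2)),
            class = "cm_wba")
}
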