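# Seeded synthetic two-view hand-washing sessions with frame-level ground
# truth. Each action is rendered by a deterministic motion program: frames
# are pure functions of (view, action, time-in-segment, appearance mode), so
# identical scripts and seeds give bit-identical videos. Wall view shows
# torso-scale silhouette motion near a sink; chest view shows close-up
# hand-region motion. In `motion_only` mode all classes share one palette
# and geometry and differ ONLY by the temporal frequency of one oscillating
# hand pair, so a single static frame carries no class information.

#' Per-action duration model (truncated normal, floored)
#'
#' Rubbing durations are calibrated to statistics measured on real
#' hand-washing sessions (rub without water 16.40 +/- 11.83 s, rub with
#' water 13.72 +/- 7.93 s); the remaining actions use shorter defaults
#' typical of a washing session.
#' Durations are sampled from a normal and resampled until they exceed
#' `min_s` (the std of the rubbing actions exceeds half their mean, so a
#' naive normal can go negative).
#'
#' @param means,stds,mins named numeric vectors over [standard7] (seconds).
#' @return list of class `duration_model`.
#' @export
duration_model <- function(
    means = c(faucet_elbow = 3, faucet_hand = 3, rub_water = 13.72,
              rub_nowater = 16.40, soap = 4, dry_hands = 8,
              non_hygiene = 8),
    stds = c(faucet_elbow = 1, faucet_hand = 1, rub_water = 7.93,
             rub_nowater = 11.83, soap = 1.5, dry_hands = 2.5,
             non_hygiene = 3),
    mins = c(faucet_elbow = 1, faucet_hand = 1, rub_water = 1,
             rub_nowater = 1, soap = 1, dry_hands = 1, non_hygiene = 1)) {
  stopifnot(all(standard7 %in% names(means)), all(means > 0),
            all(stds[standard7] >= 0), all(mins[standard7] > 0))
  structure(list(means = means, stds = stds, mins = mins),
            class = "duration_model")
}

sample_duration <- function(model, action) {
  m <- model$means[[action]]; s <- model$stds[[action]]
  lo <- model$mins[[action]]
  repeat {
    d <- stats::rnorm(1, m, s)
    if (d >= lo) return(d)
  }
}

#' The scripted session timeline
#'
#' A session runs pre-hygiene walking, then the hand-hygiene block (wet
#' hands, rub with water, soap, rub without water, rinse, close the faucet
#' with the elbow), then the post-hygiene block (walk to the towel, dry
#' hands, walk away). `NA` durations are sampled from the duration model
#' with the script's seed.
#'
#' @param segments data.frame with columns `action`, `duration` (seconds or
#'   NA); default is the canonical timeline above.
#' @param fps frames per second.
#' @param participant_id opaque identifier.
#' @param seed integer seed used for any NA duration sampling.
#' @return list of class `session_script` with resolved durations.
#' @export
session_script <- function(segments = default_timeline(), fps = 30,
                           participant_id = "p0", seed = 1L) {
  stopifnot(nrow(segments) >= 1, fps > 0)
  check_actions(segments$action)
  if (anyNA(segments$duration)) {
    set.seed(as.integer(seed))
    model <- duration_model()
    for (i in which(is.na(segments$duration))) {
      segments$duration[i] <- sample_duration(model, segments$action[i])
    }
  }
  if (any(segments$duration <= 0)) stop("durations must be positive")
  structure(list(segments = segments, fps = fps,
                 participant_id = participant_id, seed = as.integer(seed)),
            class = "session_script")
}

#' @rdname session_script
#' @export
default_timeline <- function() {
  data.frame(
    action = c("non_hygiene", "faucet_hand", "rub_water", "soap",
               "rub_nowater", "rub_water", "faucet_elbow", "non_hygiene",
               "dry_hands", "non_hygiene"),
    duration = NA_real_)
}

# frame-boundary arithmetic: cumulative rounding so that the total frame
# count equals round(fps * total duration) exactly
script_frames <- function(script) {
  bounds <- round(script$fps * cumsum(script$segments$duration))
  n <- bounds[length(bounds)]
  labels <- character(n)
  prev <- 0
  for (i in seq_len(nrow(script$segments))) {
    if (bounds[i] > prev) {
      labels[(prev + 1):bounds[i]] <- script$segments$action[i]
    }
    prev <- bounds[i]
  }
  list(n_frames = as.integer(n), labels = labels,
       bounds = as.integer(bounds))
}

# oscillation frequencies (Hz) keyed by action for motion_only mode: the
# ONLY thing that differs between classes there
motion_only_freq <- c(faucet_elbow = 0.2, faucet_hand = 0.45,
                      rub_water = 0.8, rub_nowater = 1.8, soap = 4,
                      dry_hands = 2.8, non_hygiene = 0)

# ---- deterministic renderers ------------------------------------------------

scene_grid <- local({
  cache <- list()
  function(res) {
    key <- as.character(res)
    if (is.null(cache[[key]])) {
      u <- (seq_len(res) - 0.5) / res
      cache[[key]] <<- list(
        yg = matrix(u, res, res), xg = matrix(u, res, res, byrow = TRUE))
    }
    cache[[key]]
  }
})

paint <- function(canvas, mask, col) {
  idx <- which(mask)
  if (length(idx)) {
    n <- dim(canvas)[1] * dim(canvas)[2]
    canvas[idx] <- col[1]
    canvas[idx + n] <- col[2]
    canvas[idx + 2L * n] <- col[3]
  }
  canvas
}

# bounding-box-restricted painters for the per-frame hot path
axis_u <- local({
  cache <- list()
  function(res) {
    key <- as.character(res)
    if (is.null(cache[[key]])) cache[[key]] <<- (seq_len(res) - 0.5) / res
    cache[[key]]
  }
})

paint_sub <- function(cv, ys, xs, m, col) {
  for (ch in 1:3) {
    blk <- cv[ys, xs, ch]
    blk[m] <- col[ch]
    cv[ys, xs, ch] <- blk
  }
  cv
}

paint_ellipse <- function(cv, res, cx, cy, rx, ry, col) {
  u <- axis_u(res)
  ys <- which(abs(u - cy) <= ry); xs <- which(abs(u - cx) <= rx)
  if (!length(ys) || !length(xs)) return(cv)
  m <- outer(((u[ys] - cy) / ry)^2, ((u[xs] - cx) / rx)^2, "+") <= 1
  paint_sub(cv, ys, xs, m, col)
}

paint_rect <- function(cv, res, x0, x1, y0, y1, col) {
  u <- axis_u(res)
  ys <- which(u >= y0 & u <= y1); xs <- which(u >= x0 & u <= x1)
  if (!length(ys) || !length(xs)) return(cv)
  for (ch in 1:3) cv[ys, xs, ch] <- col[ch]
  cv
}

paint_rot_rect <- function(cv, res, cx, cy, ang, half_len, half_wid, col) {
  u <- axis_u(res)
  r <- sqrt(half_len^2 + half_wid^2)
  ys <- which(abs(u - cy) <= r); xs <- which(abs(u - cx) <= r)
  if (!length(ys) || !length(xs)) return(cv)
  dy <- u[ys] - cy; dx <- u[xs] - cx
  a <- outer(sin(ang) * dy, cos(ang) * dx, "+")
  b <- outer(cos(ang) * dy, -sin(ang) * dx, "+")
  m <- abs(a) <= half_len & abs(b) <= half_wid
  paint_sub(cv, ys, xs, m, col)
}

ellipse_mask <- function(g, cx, cy, rx, ry) {
  ((g$xg - cx) / rx)^2 + ((g$yg - cy) / ry)^2 <= 1
}

rect_mask <- function(g, x0, x1, y0, y1) {
  g$xg >= x0 & g$xg <= x1 & g$yg >= y0 & g$yg <= y1
}

rot_rect_mask <- function(g, cx, cy, ang, half_len, half_wid) {
  dx <- g$xg - cx; dy <- g$yg - cy
  a <- cos(ang) * dx + sin(ang) * dy
  b <- -sin(ang) * dx + cos(ang) * dy
  abs(a) <= half_len & abs(b) <= half_wid
}

wall_background <- local({
  cache <- list()
  function(res) {
    key <- as.character(res)
    if (is.null(cache[[key]])) {
      g <- scene_grid(res)
      base <- 170 + 12 * sin(18 * pi * g$xg) * sin(18 * pi * g$yg) +
        20 * (1 - g$yg)
      cv <- array(0, c(res, res, 3))
      cv[, , 1] <- base; cv[, , 2] <- base; cv[, , 3] <- base + 6
      cv <- paint(cv, rect_mask(g, 0.33, 0.67, 0.74, 0.86), c(120, 122, 132))
      cv <- paint(cv, rect_mask(g, 0.47, 0.53, 0.66, 0.75), c(90, 92, 96))
      cache[[key]] <<- round(cv)
    }
    cache[[key]]
  }
})

chest_background <- local({
  cache <- list()
  function(res) {
    key <- as.character(res)
    if (is.null(cache[[key]])) {
      g <- scene_grid(res)
      base <- 140 + 50 * g$yg + 8 * sin(10 * pi * g$xg)
      cv <- array(0, c(res, res, 3))
      cv[, , 1] <- base; cv[, , 2] <- base + 4; cv[, , 3] <- base + 8
      cv <- paint(cv, ellipse_mask(g, 0.5, 0.48, 0.38, 0.28),
                  c(192, 196, 202))
      cache[[key]] <<- round(cv)
    }
    cache[[key]]
  }
})

skin <- c(226, 188, 158)
body_col <- c(58, 62, 94)

render_wall_frame <- function(action, t_seg, fps, res) {
  cv <- wall_background(res)
  ph <- function(f) 2 * pi * f * t_seg / fps
  bx <- switch(action,
               non_hygiene = 0.5 + 0.28 * sin(ph(0.2)),
               dry_hands = 0.5 + 0.22 * sin(ph(0.3)),
               0.5 + 0.01 * sin(ph(0.3)))
  if (action == "faucet_elbow") bx <- bx - 0.05
  cv <- paint_ellipse(cv, res, bx, 0.62, 0.13, 0.23, body_col)
  cv <- paint_ellipse(cv, res, bx, 0.33, 0.06, 0.07, skin)
  hands_at <- function(cv, dxl, dxr, cy = 0.72) {
    cv <- paint_ellipse(cv, res, 0.5 + dxl, cy, 0.04, 0.035, skin)
    paint_ellipse(cv, res, 0.5 + dxr, cy, 0.04, 0.035, skin)
  }
  if (action == "rub_water") {
    cv <- paint_rect(cv, res, 0.47, 0.53, 0.68, 0.80, c(80, 140, 230))
    o <- 0.030 + 0.022 * sin(ph(2.2))
    cv <- hands_at(cv, -o, o)
  } else if (action == "rub_nowater") {
    o <- 0.040 + 0.030 * sin(ph(1.1))
    cv <- hands_at(cv, -o, o)
  } else if (action == "soap") {
    cv <- paint_ellipse(cv, res, 0.5, 0.69, 0.035, 0.03, c(90, 210, 90))
    cv <- hands_at(cv, -0.05 - 0.02 * cos(ph(1.6)),
                   0.05 + 0.02 * sin(ph(1.6)))
  } else if (action == "faucet_hand") {
    cv <- paint_rect(cv, res, 0.47, 0.53, 0.68, 0.80, c(80, 140, 230))
    cv <- paint_ellipse(cv, res, 0.5 + 0.015 * sin(ph(1.0)), 0.68,
                        0.04, 0.035, skin)
  } else if (action == "faucet_elbow") {
    a <- -0.2 - 0.55 * (0.5 + 0.5 * sin(ph(0.8)))
    cv <- paint_rot_rect(cv, res, bx + 0.16, 0.55, a, 0.14, 0.035,
                         c(205, 165, 135))
  } else if (action == "dry_hands") {
    cv <- paint_ellipse(cv, res, bx + 0.02 * sin(ph(1.8)), 0.55,
                        0.06, 0.05, c(246, 246, 246))
  }
  cv
}

render_chest_frame <- function(action, t_seg, fps, res) {
  ph <- function(f) 2 * pi * f * t_seg / fps
  if (action == "non_hygiene") {
    # away from the sink: drifting corridor, no hands in view
    g <- scene_grid(res)
    drift <- 0.15 * sin(ph(0.25))
    base <- 130 + 40 * g$yg + 25 * sin(6 * pi * (g$xg - drift))
    cv <- array(0, c(res, res, 3))
    cv[, , 1] <- base + 10; cv[, , 2] <- base; cv[, , 3] <- base - 5
    return(round(cv))
  }
  cv <- chest_background(res)
  hands <- function(cv, dxl, dxr, cy = 0.56) {
    cv <- paint_ellipse(cv, res, 0.5 + dxl, cy, 0.13, 0.09, skin)
    paint_ellipse(cv, res, 0.5 + dxr, cy, 0.13, 0.09, skin)
  }
  if (action == "rub_water") {
    cv <- paint_rect(cv, res, 0.44, 0.56, 0.0, 0.5, c(80, 140, 230))
    o <- 0.06 + 0.05 * sin(ph(2.2))
    cv <- hands(cv, -o, o)
  } else if (action == "rub_nowater") {
    o <- 0.09 + 0.06 * sin(ph(1.1))
    cv <- hands(cv, -o, o)
  } else if (action == "soap") {
    cv <- paint_ellipse(cv, res, 0.5, 0.52, 0.06, 0.05, c(90, 210, 90))
    cv <- hands(cv, -0.10 - 0.03 * cos(ph(1.6)),
                0.10 + 0.03 * sin(ph(1.6)),
                cy = 0.56 + 0.03 * sin(ph(1.6)))
  } else if (action == "faucet_hand") {
    cv <- paint_ellipse(cv, res, 0.75, 0.18, 0.06, 0.05, c(150, 25, 25))
    cv <- paint_rect(cv, res, 0.44, 0.56, 0.0, 0.5, c(80, 140, 230))
    u <- 0.5 + 0.5 * sin(ph(0.9))
    cv <- paint_ellipse(cv, res, 0.5 + 0.25 * u, 0.56 - 0.34 * u,
                        0.13, 0.09, skin)
  } else if (action == "faucet_elbow") {
    a <- 0.3 + 0.5 * sin(ph(0.8))
    cv <- paint_rot_rect(cv, res, 0.5, 0.35, a, 0.42, 0.10, c(70, 52, 100))
  } else if (action == "dry_hands") {
    o <- 0.10 * sin(ph(1.8))
    cv <- hands(cv, -0.16 + o, 0.16 + o)
    cv <- paint_rect(cv, res, 0.36 + o, 0.64 + o, 0.48, 0.64,
                     c(246, 246, 246))
  }
  cv
}

render_motion_only_frame <- function(action, t_seg, fps, res, view,
                                     phase0 = 0) {
  cv <- array(140, c(res, res, 3))
  f <- motion_only_freq[[action]]
  o <- 0.05 + 0.10 * sin(2 * pi * (f * t_seg / fps + phase0))
  s <- if (view == "wall") 0.6 else 1   # same palette, per-view geometry
  cv <- paint_ellipse(cv, res, 0.5 - s * o, 0.55, s * 0.10, s * 0.07,
                      c(205, 205, 205))
  paint_ellipse(cv, res, 0.5 + s * o, 0.55, s * 0.10, s * 0.07,
                c(205, 205, 205))
}

render_frame <- function(view, mode, action, t_seg, fps, res,
                         phase0 = 0) {
  # backgrounds are pre-rounded and painted colours are integer constants,
  # so frames are integer-valued 0..255 without a final rounding pass
  if (mode == "motion_only") {
    render_motion_only_frame(action, t_seg, fps, res, view, phase0)
  } else if (view == "wall") {
    render_wall_frame(action, t_seg, fps, res)
  } else {
    render_chest_frame(action, t_seg, fps, res)
  }
}

# ---- session / dataset generation ------------------------------------------

#' Generate one paired two-view synthetic session
#'
#' Both views are rendered lazily (frames on demand) from the same script,
#' so they share one label track frame for frame.
#'
#' @param script a [session_script()].
#' @param appearance_mode `"distinct"` (classes differ in appearance and
#'   motion) or `"motion_only"` (classes differ only by motion frequency).
#' @param resolution square frame size in pixels (default 224).
#' @return list with `wall` and `chest` `labeled_video`s.
#' @export
generate_session <- function(script, appearance_mode = c("distinct",
                                                         "motion_only"),
                             resolution = 224L) {
  appearance_mode <- match.arg(appearance_mode)
  sf <- script_frames(script)
  bounds <- sf$bounds
  # in motion_only mode each segment's oscillation starts at a seeded
  # random phase, so a class can never be read off a single frame via the
  # discrete set of positions its frequency visits at this frame rate
  seg_phase <- rep(0, nrow(script$segments))
  if (appearance_mode == "motion_only") {
    set.seed(script$seed)
    seg_phase <- stats::runif(nrow(script$segments))
  }
  seg_of <- function(i) findInterval(i - 1L, bounds) + 1L  # i is 1-based
  mk_view <- function(view) {
    force(view)
    labeled_video(
      frame_fn = function(i) {
        s <- seg_of(i)
        t_seg <- (i - 1L) - c(0L, bounds)[s]
        render_frame(view, appearance_mode, script$segments$action[s],
                     t_seg, script$fps, resolution, seg_phase[s])
      },
      n_frames = sf$n_frames, fps = script$fps, labels = sf$labels,
      view = view)
  }
  list(wall = mk_view("wall"), chest = mk_view("chest"))
}

#' Generate a participant-level split dataset manifest
#'
#' Participants are partitioned (never shared) across train/validation/test
#' in the given proportions; each participant contributes
#' `sessions_per_participant` scripted sessions whose segment durations are
#' sampled per-session from the duration model.
#'
#' @param n_participants number of participants.
#' @param sessions_per_participant sessions recorded per participant.
#' @param split_proportions length-3 numeric: participant counts summing to
#'   `n_participants`, or fractions summing to 1. Default mirrors the
#'   66/12/22 protocol.
#' @param seed integer master seed.
#' @return data.frame manifest: `participant`, `session`, `split`,
#'   `session_seed`.
#' @export
generate_dataset <- function(n_participants, sessions_per_participant = 1L,
                             split_proportions = c(66, 12, 22),
                             seed = 1L) {
  stopifnot(length(split_proportions) == 3)
  if (n_participants < 3) {
    stop("need at least as many participants (", n_participants,
         ") as splits (3)")
  }
  p <- split_proportions
  if (abs(sum(p) - 1) < 1e-9) {
    # largest-remainder rounding with at least one participant per split
    counts <- floor(p * n_participants)
    while (sum(counts) < n_participants) {
      rem <- p * n_participants - counts
      i <- which.max(rem)
      counts[i] <- counts[i] + 1L
    }
    while (any(counts < 1)) {
      counts[which.min(counts)] <- counts[which.min(counts)] + 1L
      counts[which.max(counts)] <- counts[which.max(counts)] - 1L
    }
  } else {
    if (sum(p) != n_participants) {
      stop("split proportions must sum to 1 or to n_participants")
    }
    counts <- p
  }
  if (any(counts < 1)) stop("every split needs at least one participant")
  set.seed(as.integer(seed))
  perm <- sample(n_participants)
  split <- rep(c("train", "val", "test"), times = counts)
  assign <- split[order(perm)]  # participant i -> split
  out <- do.call(rbind, lapply(seq_len(n_participants), function(pid) {
    do.call(rbind, lapply(seq_len(sessions_per_participant), function(s) {
      data.frame(participant = sprintf("p%03d", pid), session = s,
                 split = assign[pid],
                 session_seed = (as.integer(seed) %% 10000L) * 100000L +
                   pid * 100L + s)
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Materialise the session for one manifest row
#'
#' @param row one row of a [generate_dataset()] manifest.
#' @param appearance_mode,resolution passed to [generate_session()].
#' @param fps frames per second of the rendered session.
#' @return list with `wall`, `chest` and the resolved `script`.
#' @export
session_from_manifest <- function(row, appearance_mode = "distinct",
                                  resolution = 224L, fps = 30) {
  script <- session_script(fps = fps, participant_id = row$participant,
                           seed = row$session_seed)
  c(generate_session(script, appearance_mode, resolution),
    list(script = script))
}
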