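# Shared fixtures: tiny in-memory videos and deterministic stubs.

# a video built from explicit frames (list of H x W x 3 arrays, 0..255)
video_from_frames <- function(frames, labels = NULL, fps = 30,
                              view = "wall") {
  labeled_video(frames = frames, fps = fps, labels = labels, view = view)
}

# random small video for MHI oracle tests
random_video <- function(n_frames = 20, size = 16, seed = 1) {
  set.seed(seed)
  frames <- lapply(seq_len(n_frames), function(i) {
    array(sample(0:255, size * size * 3, replace = TRUE),
          c(size, size, 3))
  })
  video_from_frames(frames)
}

# uniform-colour frame
flat_frame <- function(col, size = 16) {
  f <- array(0, c(size, size, 3))
  for (c in 1:3) f[, , c] <- col[c]
  f
}

# video with per-frame labels over tiny flat frames (fast pipeline fuel)
labeled_flat_video <- function(frame_labels, size = 8, view = "chest") {
  frames <- lapply(seq_along(frame_labels), function(i) flat_frame(c(i %% 7,
    100, 200), size))
  video_from_frames(frames, labels = frame_labels, view = view)
}

# deterministic 7-class stub used for expansion tests: unit index -> label
cycling_stub <- function(u) standard7[(u * 3L) %% 7L + 1L]

oracle_models <- function() {
  list(wall_coarse = oracle_classifier("coarse3"),
       chest_dry = oracle_classifier("dry"),
       wall_refine = oracle_classifier("standard7"),
       chest_refine = oracle_classifier("standard7"))
}

# independent BT.601 luminance for oracles (scalar, per pixel)
lum_px <- function(px) 0.299 * px[1] + 0.587 * px[2] + 0.114 * px[3]
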