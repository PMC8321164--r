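# Motion history image (MHI) and the hand-crafted descriptors used by the
# dry-hands baselines (HSV colour histogram, HOG, LBP, random forest).

#' MHI parameters
#'
#' @param tau motion history duration in frames: the value written where
#'   motion is detected. Default 5.
#' @param delta per-frame decay subtracted where no motion is detected.
#'   Default 1.
#' @param xi frame-difference threshold on the 0..255 luminance scale;
#'   a pixel is "moving" iff |lum_t - lum_prev| > xi (strict). Default 20.
#' @return list of class `mhi_params`.
#' @export
mhi_params <- function(tau = 5, delta = 1, xi = 20) {
  stopifnot(tau > 0, delta > 0, xi >= 0)
  structure(list(tau = tau, delta = delta, xi = xi), class = "mhi_params")
}

# ITU-R BT.601 luminance from an H x W x 3 array on the 0..255 scale
luminance <- function(img) {
  d <- dim(img)
  luminance_cpp(img, d[1], d[2])
}

#' Binary motion mask between two frames
#'
#' Frames are converted to BT.601 luminance; a pixel is marked as moving iff
#' the absolute luminance difference strictly exceeds `xi`.
#'
#' @param frame_t,frame_prev H x W x 3 arrays (0..255) of identical shape.
#' @param params an [mhi_params()] object.
#' @return H x W 0/1 matrix.
#' @export
motion_mask <- function(frame_t, frame_prev, params = mhi_params()) {
  if (!identical(dim(frame_t), dim(frame_prev))) {
    stop("frame shapes differ: ", paste(dim(frame_t), collapse = "x"),
         " vs ", paste(dim(frame_prev), collapse = "x"))
  }
  (abs(luminance(frame_t) - luminance(frame_prev)) > params$xi) * 1
}

#' Motion history image sequence for a video
#'
#' Classical frame-count decay recurrence, per pixel:
#' `H_t = tau` where motion is detected at frame t, else
#' `max(0, H_(t-1) - delta)`; `H` at the first frame is all zeros. The MHI is
#' computed at the source resolution and each one is then down-sampled to
#' `out_size` by area averaging (values stay in \[0, tau\]).
#'
#' @param video a `labeled_video` with at least 2 frames.
#' @param params an [mhi_params()] object.
#' @param out_size target (h, w); `NULL` keeps source resolution.
#' @param frame_range optional 1-based inclusive range `c(from, to)` to
#'   restrict the output (history is still causal from the clip start or
#'   from the exact decay window, whichever is shorter).
#' @return array (h, w, n) of MHIs, one slice per frame in range.
#' @export
mhi_sequence <- function(video, params = mhi_params(), out_size = c(32, 32),
                         frame_range = NULL) {
  if (video$n_frames < 2) stop("need at least 2 frames to compute an MHI")
  if (is.null(frame_range)) frame_range <- c(1L, video$n_frames)
  from <- frame_range[1]; to <- frame_range[2]
  # the recurrence forgets anything older than ceiling(tau/delta) steps,
  # so starting from zeros that many frames early is exact
  window <- as.integer(ceiling(params$tau / params$delta))
  start <- max(1L, from - window)
  prev_lum <- luminance(get_frame(video, start))
  h <- matrix(0, nrow(prev_lum), ncol(prev_lum))
  d <- if (is.null(out_size)) dim(h) else out_size
  out <- array(0, c(d[1], d[2], to - from + 1L))
  if (start == from) {
    out[, , 1] <- resize_image(h, d[1], d[2])
  }
  t <- start + 1L
  while (t <= to) {
    cur_lum <- luminance(get_frame(video, t))
    h <- pmax(h - params$delta, 0)
    h[abs(cur_lum - prev_lum) > params$xi] <- params$tau
    prev_lum <- cur_lum
    if (t >= from) out[, , t - from + 1L] <- resize_image(h, d[1], d[2])
    t <- t + 1L
  }
  out
}

#' HSV colour histogram feature (288 dimensions)
#'
#' The image is resized to 224 x 224 if needed and split into a 2 x 2 grid
#' of non-overlapping regions. Per region a joint HSV histogram is taken
#' with 8 evenly spaced value bins and 3 bins each for hue and saturation
#' (8 x 3 x 3 = 72 joint bins), normalised to sum 1 over the region. The
#' four region histograms are concatenated in row-major region order with
#' value-major bin order inside each, for 4 x 72 = 288 dimensions.
#'
#' @param image H x W x 3 array (0..255).
#' @return numeric vector of length 288.
#' @export
hsv_color_histogram <- function(image) {
  if (length(dim(image)) != 3 || dim(image)[3] != 3) {
    stop("need a 3-channel colour image")
  }
  image <- resize_image(image, 224, 224)
  hsv <- grDevices::rgb2hsv(r = as.vector(image[, , 1]),
                            g = as.vector(image[, , 2]),
                            b = as.vector(image[, , 3]),
                            maxColorValue = 255)
  bin_of <- function(x, k) pmin(floor(x * k) + 1L, k)
  hb <- bin_of(hsv["h", ], 3L)
  sb <- bin_of(hsv["s", ], 3L)
  vb <- bin_of(hsv["v", ], 8L)
  # value-major joint bin: value slowest, then hue, then saturation
  joint <- (vb - 1L) * 9L + (hb - 1L) * 3L + sb
  ys <- rep(seq_len(224), times = 224)
  xs <- rep(seq_len(224), each = 224)
  region <- (ys > 112) * 2L + (xs > 112) + 1L       # row-major 2x2 regions
  out <- numeric(288)
  for (r in 1:4) {
    cnt <- tabulate(joint[region == r], nbins = 72L)
    out[(r - 1L) * 72L + seq_len(72L)] <- cnt / sum(cnt)
  }
  out
}

#' HOG and LBP texture descriptors
#'
#' Fixed published defaults on the 224 x 224 BT.601 luminance: HOG with 9
#' unsigned orientation bins, 8 x 8 pixel cells and 2 x 2-cell blocks
#' (L2-normalised, block stride one cell), and LBP with uniform 8-neighbour
#' radius-1 codes histogrammed over the whole image (59 bins, normalised).
#'
#' @param image H x W x 3 array (0..255).
#' @return list with `hog` (length 26244) and `lbp_histogram` (length 59).
#' @export
texture_descriptors <- function(image) {
  d <- dim(image)
  if (is.null(d) || d[1] <= 1 || d[2] <= 1) stop("degenerate image")
  image <- resize_image(image, 224, 224)
  lum <- luminance(image)
  list(hog = hog_descriptor(lum), lbp_histogram = lbp_histogram(lum))
}

hog_descriptor <- function(lum, cell = 8L, bins = 9L) {
  n <- nrow(lum)
  gx <- matrix(0, n, n); gy <- matrix(0, n, n)
  gx[, 2:(n - 1)] <- (lum[, 3:n] - lum[, 1:(n - 2)]) / 2
  gy[2:(n - 1), ] <- (lum[3:n, ] - lum[1:(n - 2), ]) / 2
  mag <- sqrt(gx^2 + gy^2)
  ang <- atan2(gy, gx) %% pi                      # unsigned, [0, pi)
  ob <- pmin(floor(as.vector(ang) / pi * bins) + 1L, bins)
  ncell <- n %/% cell
  cy <- (rep(seq_len(n), times = n) - 1L) %/% cell
  cx <- (rep(seq_len(n), each = n) - 1L) %/% cell
  cid <- cy + ncell * cx                          # 0-based cell id
  grp <- cid * bins + ob                          # 1..ncell^2 * bins
  hist <- numeric(ncell * ncell * bins)
  agg <- rowsum(as.vector(mag), grp)
  hist[as.integer(rownames(agg))] <- agg
  cells <- array(hist, c(bins, ncell, ncell))     # [bin, cy, cx]
  nb <- ncell - 1L
  out <- numeric(nb * nb * 4L * bins)
  k <- 1L
  for (bx in seq_len(nb)) {
    for (by in seq_len(nb)) {
      v <- c(cells[, by, bx], cells[, by + 1L, bx],
             cells[, by, bx + 1L], cells[, by + 1L, bx + 1L])
      v <- v / sqrt(sum(v^2) + 1e-12)             # safe L2: zero stays zero
      out[k:(k + 4L * bins - 1L)] <- v
      k <- k + 4L * bins
    }
  }
  out
}

# uniform LBP lookup: code -> 1..59 (58 uniform patterns + 1 catch-all)
lbp_uniform_table <- function() {
  tab <- integer(256)
  nxt <- 1L
  for (code in 0:255) {
    bits <- as.integer(intToBits(code))[1:8]
    trans <- sum(bits != c(bits[-1], bits[1]))
    if (trans <= 2L) {
      tab[code + 1L] <- nxt
      nxt <- nxt + 1L
    } else {
      tab[code + 1L] <- 59L
    }
  }
  tab
}
.lbp_tab <- lbp_uniform_table()

lbp_histogram <- function(lum) {
  n <- nrow(lum); m <- ncol(lum)
  ctr <- lum[2:(n - 1), 2:(m - 1)]
  sh <- function(dy, dx) lum[2:(n - 1) + dy, 2:(m - 1) + dx]
  offs <- list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, 1),
               c(1, 1), c(1, 0), c(1, -1), c(0, -1))
  code <- matrix(0L, n - 2, m - 2)
  for (k in seq_len(8)) {
    code <- code + as.integer(sh(offs[[k]][1], offs[[k]][2]) >= ctr) * 2L^(k - 1L)
  }
  cnt <- tabulate(.lbp_tab[code + 1L], nbins = 59L)
  cnt / sum(cnt)
}

#' Random-forest dry-hands baseline on hand-crafted features
#'
#' Trains a seeded random forest to separate `dry_hands` (positive) from
#' `non_hygiene` (negative) frames given any fixed feature vector (HSV
#' histogram, HOG or LBP).
#'
#' @param features numeric matrix, one row per frame.
#' @param labels character vector in `{dry_hands, non_hygiene}`.
#' @param seed RNG seed.
#' @param ntree forest size.
#' @return object of class `dry_hands_forest`.
#' @export
train_dry_hands_forest <- function(features, labels, seed = 1L,
                                   ntree = 100L) {
  labels <- factor(labels, levels = c("non_hygiene", "dry_hands"))
  if (any(is.na(labels))) stop("labels must be dry_hands or non_hygiene")
  if (any(table(labels) < 2)) {
    stop("need at least 2 samples in each class; got counts ",
         paste(table(labels), collapse = "/"))
  }
  set.seed(seed)
  fit <- randomForest::randomForest(x = as.matrix(features), y = labels,
                                    ntree = ntree)
  structure(list(fit = fit, seed = seed), class = "dry_hands_forest")
}

#' @rdname train_dry_hands_forest
#' @param object trained `dry_hands_forest`.
#' @param feature numeric vector or matrix of row features.
#' @return score(s) in \[0, 1\]: probability of `dry_hands`; class decision
#'   at the 0.5 threshold.
#' @export
predict_frame <- function(object, feature) {
  if (is.null(dim(feature))) feature <- matrix(feature, nrow = 1)
  p <- stats::predict(object$fit, feature, type = "prob")
  unname(p[, "dry_hands"])
}
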