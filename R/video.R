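# LabeledVideo: the carrier between all stages. Frames are H x W x 3 arrays
# with intensities 0..255. Frames may be held in memory or produced lazily by
# a renderer/reader closure, so hour-scale sessions never need to be fully
# materialised.

#' Construct a labeled video
#'
#' @param frames list of H x W x 3 numeric arrays (0..255), or `NULL` when
#'   `frame_fn` is given.
#' @param frame_fn function(i) returning frame i (1-based) on demand.
#' @param n_frames frame count (required with `frame_fn`).
#' @param fps frames per second (default 30).
#' @param labels optional per-frame action labels, length `n_frames`.
#' @param view `"wall"` (third-person) or `"chest"` (egocentric).
#' @return object of class `labeled_video`.
#' @export
labeled_video <- function(frames = NULL, frame_fn = NULL, n_frames = NULL,
                          fps = 30, labels = NULL,
                          view = c("wall", "chest")) {
  view <- match.arg(view)
  if (is.null(frames) == is.null(frame_fn)) {
    stop("give exactly one of `frames` or `frame_fn`")
  }
  if (!is.null(frames)) {
    n_frames <- length(frames)
    d <- dim(frames[[1]])
    for (f in frames) {
      if (!identical(dim(f), d)) stop("all frames must share one shape")
    }
  } else if (is.null(n_frames)) {
    stop("`n_frames` is required with `frame_fn`")
  }
  if (!is.null(labels)) {
    if (length(labels) != n_frames) {
      stop("labels length (", length(labels),
           ") must equal frame count (", n_frames, ")")
    }
    check_actions(labels)
  }
  structure(list(frames = frames, frame_fn = frame_fn,
                 n_frames = as.integer(n_frames), fps = fps,
                 labels = labels, view = view),
            class = "labeled_video")
}

#' Number of frames in a video
#' @param x a `labeled_video`.
#' @export
n_frames <- function(x) x$n_frames

#' Fetch one frame (1-based index) as an H x W x 3 array
#' @param video a `labeled_video`.
#' @param i frame index, 1-based.
#' @export
get_frame <- function(video, i) {
  stopifnot(i >= 1, i <= video$n_frames)
  if (!is.null(video$frames)) video$frames[[i]] else video$frame_fn(i)
}

#' @export
print.labeled_video <- function(x, ...) {
  d <- dim(get_frame(x, 1L))
  cat(sprintf("<labeled_video: %s view, %d frames @ %g FPS, %dx%d, %s>\n",
              x$view, x$n_frames, x$fps, d[1], d[2],
              if (is.null(x$labels)) "unlabeled" else "frame-labeled"))
  invisible(x)
}

#' Read a video from a directory of PNG frames
#'
#' Frames are read lazily in lexicographic file order; `labels.csv` and
#' `meta.json` in the directory (as written by [write_fixture()]) are picked
#' up automatically when present.
#'
#' @param path directory containing `*.png` frames.
#' @param fps frames per second override (default: from meta.json, else 30).
#' @param view view override.
#' @return a `labeled_video`.
#' @export
read_video <- function(path, fps = NULL, view = NULL) {
  if (!dir.exists(path)) stop("not a readable frame directory: ", path)
  files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
  if (length(files) == 0) stop("no PNG frames found under ", path)
  meta_path <- file.path(path, "meta.json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else list()
  if (is.null(fps)) fps <- meta$fps %||% 30
  if (is.null(view)) view <- meta$view %||% "wall"
  labels <- NULL
  lab_path <- file.path(path, "labels.csv")
  if (file.exists(lab_path)) labels <- read_labels(lab_path)
  labeled_video(
    frame_fn = function(i) {
      img <- png::readPNG(files[i])
      if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
      round(img[, , 1:3] * 255)
    },
    n_frames = length(files), fps = fps, labels = labels, view = view)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a video as a lossless PNG frame directory fixture
#'
#' Creates `frame_<i>.png` (0-based, zero-padded), a `labels.csv` with one
#' row per frame when labels are present, and a `meta.json` carrying fps and
#' view. Reading the directory back with [read_video()] reproduces the
#' frames and labels exactly.
#'
#' @param video a `labeled_video`.
#' @param path output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_fixture <- function(video, path) {
  ok <- dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop("cannot create directory: ", path)
  n <- video$n_frames
  width <- max(6L, nchar(as.character(n - 1L)))
  for (i in seq_len(n)) {
    f <- get_frame(video, i)
    png::writePNG(f / 255,
                  file.path(path, sprintf(paste0("frame_%0", width, "d.png"),
                                          i - 1L)))
  }
  if (!is.null(video$labels)) {
    write_labels(video$labels, file.path(path, "labels.csv"))
  }
  jsonlite::write_json(list(fps = video$fps, view = video$view,
                            n_frames = n),
                       file.path(path, "meta.json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read / write per-frame label CSV
#'
#' Format: header `frame_index,action`, 0-based contiguous frame indices.
#' Unknown action tokens, duplicate indices and index gaps are rejected with
#' the offending rows named.
#'
#' @param path CSV path.
#' @return character vector of per-frame labels (index 1 = frame 0).
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("label file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("frame_index", "action") %in% names(df))) {
    stop("label CSV must have header `frame_index,action`: ", path)
  }
  dup <- duplicated(df$frame_index)
  if (any(dup)) {
    stop("duplicate frame_index at line(s) ",
         paste(which(dup) + 1L, collapse = ", "))
  }
  bad <- !(df$action %in% standard7)
  if (any(bad)) {
    stop("unknown action token(s) at line(s) ",
         paste(which(bad) + 1L, collapse = ", "), ": ",
         paste(unique(df$action[bad]), collapse = ", "))
  }
  df <- df[order(df$frame_index), ]
  expect <- seq(0L, max(df$frame_index))
  missing <- setdiff(expect, df$frame_index)
  if (length(missing) > 0 || df$frame_index[1] != 0L) {
    stop("frame_index gaps; missing indices: ",
         paste(utils::head(c(setdiff(0:max(df$frame_index), df$frame_index)),
                           20), collapse = ", "))
  }
  df$action
}

#' @rdname read_labels
#' @param labels character vector of per-frame labels.
#' @export
write_labels <- function(labels, path) {
  check_actions(labels)
  utils::write.csv(
    data.frame(frame_index = seq_along(labels) - 1L, action = labels),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Resize an image or matrix
#'
#' Area (block-mean) resampling when the source size is an integer multiple
#' of the target (the antialiased, monotone path used for MHI and coarse-net
#' inputs); bilinear interpolation otherwise.
#'
#' @param img H x W matrix or H x W x C array.
#' @param h,w target size.
#' @export
resize_image <- function(img, h, w) {
  d <- dim(img)
  if (length(d) == 3) {
    out <- array(0, c(h, w, d[3]))
    for (c in seq_len(d[3])) out[, , c] <- resize_image(img[, , c], h, w)
    return(out)
  }
  if (d[1] == h && d[2] == w) return(img)
  if (d[1] %% h == 0 && d[2] %% w == 0) {
    block_mean(img, d[1] %/% h, d[2] %/% w)
  } else {
    yi <- (seq_len(h) - 0.5) * d[1] / h + 0.5
    xi <- (seq_len(w) - 0.5) * d[2] / w + 0.5
    y0 <- pmin(pmax(floor(yi), 1), d[1]); y1 <- pmin(y0 + 1, d[1])
    x0 <- pmin(pmax(floor(xi), 1), d[2]); x1 <- pmin(x0 + 1, d[2])
    wy <- pmin(pmax(yi - y0, 0), 1); wx <- pmin(pmax(xi - x0, 0), 1)
    a <- img[y0, x0, drop = FALSE] * outer(1 - wy, 1 - wx) +
      img[y1, x0, drop = FALSE] * outer(wy, 1 - wx) +
      img[y0, x1, drop = FALSE] * outer(1 - wy, wx) +
      img[y1, x1, drop = FALSE] * outer(wy, wx)
    a
  }
}
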