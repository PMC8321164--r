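# CNN classifiers: the three 32x32 coarse variants, the dual-stream RGB+MHI
# fusion net, the binary dry-hands net, and the pluggable refinement
# classifier.

#' Specification of a low-complexity coarse classifier
#'
#' The coarse nets take 32 x 32 inputs and follow a VGG-style layout: 3 x 3
#' convolutions, 2 x 2 stride-2 max pooling, batch normalisation after every
#' convolution and before the ReLU.
#'
#' * `conv5_fc1`: five conv/BN/ReLU/pool groups then one fully connected
#'   head (spatial trace 32-16-8-4-2-1).
#' * `conv4_fc2`: four conv groups; the fifth group is replaced by a fully
#'   connected layer with 512 outputs, followed by the class head.
#' * `dwconv4_fc2`: as `conv4_fc2` with the 4th group depthwise separable.
#'
#' @param variant one of `conv5_fc1`, `conv4_fc2`, `dwconv4_fc2`.
#' @param streams `"rgb"` or `"rgb_mhi"` (dual stream).
#' @param n_classes output classes (>= 1); 1 means a single sigmoid score.
#' @param input_size square input side, default 32.
#' @param channel_widths 5 output widths, default `c(32, 64, 128, 256, 512)`.
#' @return list of class `coarse_net_spec`.
#' @export
coarse_net_spec <- function(variant = c("conv5_fc1", "conv4_fc2",
                                        "dwconv4_fc2"),
                            streams = c("rgb", "rgb_mhi"),
                            n_classes = 3L, input_size = 32L,
                            channel_widths = c(32L, 64L, 128L, 256L, 512L)) {
  variant <- match.arg(variant)
  streams <- match.arg(streams)
  stopifnot(n_classes >= 1, length(channel_widths) == 5)
  n_pools <- if (variant == "conv5_fc1") 5L else 4L
  if (input_size %% 2L^n_pools != 0L) {
    trace <- paste(input_size / 2L^(0:n_pools), collapse = " -> ")
    stop("input size ", input_size, " is not divisible by 2^", n_pools,
         " poolings (trace ", trace, ")")
  }
  structure(list(variant = variant, streams = streams,
                 n_classes = as.integer(n_classes),
                 input_size = as.integer(input_size),
                 channel_widths = as.integer(channel_widths)),
            class = "coarse_net_spec")
}

# one tower of conv groups; returns list(layers, feat_dim)
coarse_tower <- function(spec, in_channels) {
  w <- spec$channel_widths
  s <- spec$input_size
  cin <- in_channels
  layers <- list()
  n_groups <- if (spec$variant == "conv5_fc1") 5L else 4L
  for (g in seq_len(n_groups)) {
    conv <- if (spec$variant == "dwconv4_fc2" && g == 4L) {
      nn_dwsep(cin, w[g], s, s)
    } else {
      nn_conv(cin, w[g], s, s)
    }
    layers <- c(layers, list(conv, nn_bn(w[g]), nn_relu(),
                             nn_maxpool(w[g], s, s)))
    cin <- w[g]
    s <- s %/% 2L
  }
  list(layers = layers, feat_dim = cin * s * s)
}

coarse_head <- function(spec, feat_dim) {
  if (spec$variant == "conv5_fc1") {
    list(nn_linear(feat_dim, spec$n_classes))
  } else {
    # the 5th conv group is traded for a 512-output fully connected layer
    list(nn_linear(feat_dim, spec$channel_widths[5]), nn_relu(),
         nn_linear(spec$channel_widths[5], spec$n_classes))
  }
}

new_frame_classifier <- function(net, vocab, preprocessing, spec = NULL,
                                 binary = FALSE) {
  structure(list(net = net, vocab = vocab, preprocessing = preprocessing,
                 spec = spec, binary = binary, trained = FALSE,
                 history = NULL),
            class = "frame_classifier")
}

#' Build an untrained coarse classifier
#'
#' @param spec a [coarse_net_spec()]; `streams = "rgb_mhi"` builds the
#'   dual-stream fusion net (see [build_dual_stream_net()]).
#' @param vocab label vocabulary; defaults to [coarse3].
#' @param flip flip wall-view frames horizontally at prediction time.
#' @return untrained `frame_classifier`.
#' @export
build_coarse_net <- function(spec = coarse_net_spec(), vocab = coarse3,
                             flip = FALSE) {
  stopifnot(length(vocab) == spec$n_classes || spec$n_classes == 1L)
  if (spec$streams == "rgb_mhi") return(build_dual_stream_net(spec, vocab,
                                                              flip))
  tower <- coarse_tower(spec, 3L)
  net <- list(type = "seq",
              layers = c(tower$layers, coarse_head(spec, tower$feat_dim)))
  new_frame_classifier(
    net, vocab,
    preprocessing = list(input_size = spec$input_size, streams = "rgb",
                         flip = flip, norm = NULL),
    spec = spec, binary = spec$n_classes == 1L)
}

#' Build the dual-stream RGB + MHI coarse classifier
#'
#' Both streams use the same per-stream architecture (the MHI stream takes
#' the single-channel 32 x 32 down-sampled MHI); the feature maps after the
#' last convolutional group are concatenated and passed into the final
#' fully connected head, whose input dimensionality is twice the last
#' channel width.
#'
#' @inheritParams build_coarse_net
#' @param mhi_pars [mhi_params()] used to compute the MHI stream input.
#' @export
build_dual_stream_net <- function(spec = coarse_net_spec(streams = "rgb_mhi"),
                                  vocab = coarse3, flip = FALSE,
                                  mhi_pars = mhi_params()) {
  stopifnot(spec$streams == "rgb_mhi")
  t_rgb <- coarse_tower(spec, 3L)
  t_mhi <- coarse_tower(spec, 1L)
  if (t_rgb$feat_dim != t_mhi$feat_dim) {
    stop("streams have mismatched feature sizes: ", t_rgb$feat_dim, " vs ",
         t_mhi$feat_dim)
  }
  net <- list(type = "dual", rgb_tower = t_rgb$layers,
              mhi_tower = t_mhi$layers,
              head = coarse_head(spec, 2L * t_rgb$feat_dim))
  new_frame_classifier(
    net, vocab,
    preprocessing = list(input_size = spec$input_size,
                         streams = c("rgb", "mhi"), flip = flip,
                         mhi_params = mhi_pars, norm = NULL),
    spec = spec, binary = spec$n_classes == 1L)
}

#' Build the binary dry-hands chest classifier
#'
#' Same five-group architecture as the wall coarse classifier, with the head
#' reduced to a single sigmoid confidence score and binary cross-entropy
#' loss; scores above 0.5 mean "dry hands".
#'
#' @param channel_widths per-group widths.
#' @export
build_dry_hands_net <- function(channel_widths = c(32L, 64L, 128L, 256L,
                                                   512L)) {
  spec <- coarse_net_spec("conv5_fc1", "rgb", n_classes = 1L,
                          channel_widths = channel_widths)
  build_coarse_net(spec, vocab = "dry_hands")
}

#' Build the refinement classifier (pluggable backbone)
#'
#' The refinement classifier labels 224 x 224 frames with the seven
#' standard-level actions.
#'
#' * `vgg11_style`: the VGG11 convolutional configuration
#'   (64, 128, 256x2, 512x2, 512x2 with five poolings) with a
#'   global-average-pooled 7-class head, trainable from scratch.
#' * `small_backbone`: area-downsamples the input to 32 x 32 and applies the
#'   five-group coarse architecture with reduced widths; the desk-scale
#'   default.
#' * `external`: any user function `f(matrix)` returning class scores, e.g.
#'   an adapter around externally pre-trained weights.
#'
#' @param backbone backbone token.
#' @param n_classes output classes (default 7).
#' @param vocab label vocabulary.
#' @param channel_widths widths for `small_backbone`.
#' @param external prediction function for `backbone = "external"`.
#' @param flip flip wall-view frames horizontally at prediction time.
#' @export
build_refinement_net <- function(backbone = c("vgg11_style",
                                              "small_backbone", "external"),
                                 n_classes = 7L, vocab = standard7,
                                 channel_widths = c(16L, 32L, 32L, 64L,
                                                    64L),
                                 external = NULL, flip = FALSE) {
  backbone <- tryCatch(match.arg(backbone),
                       error = function(e) stop("unknown backbone token: ",
                                                backbone[1]))
  if (backbone == "small_backbone") {
    spec <- coarse_net_spec("conv5_fc1", "rgb", n_classes = n_classes,
                            channel_widths = channel_widths)
    m <- build_coarse_net(spec, vocab = vocab, flip = flip)
    m$backbone <- "small_backbone"
    return(m)
  }
  if (backbone == "external") {
    if (!is.function(external)) {
      stop("backbone = 'external' needs an `external` prediction function")
    }
    m <- new_frame_classifier(NULL, vocab,
                              preprocessing = list(input_size = 224L,
                                                   streams = "rgb",
                                                   flip = flip, norm = NULL))
    m$external <- external
    m$backbone <- "external"
    m$trained <- TRUE
    return(m)
  }
  cfgs <- list(c(64L), c(128L), c(256L, 256L), c(512L, 512L), c(512L, 512L))
  s <- 224L; cin <- 3L
  layers <- list()
  for (g in seq_along(cfgs)) {
    for (w in cfgs[[g]]) {
      layers <- c(layers, list(nn_conv(cin, w, s, s), nn_bn(w), nn_relu()))
      cin <- w
    }
    layers <- c(layers, list(nn_maxpool(cin, s, s)))
    s <- s %/% 2L
  }
  layers <- c(layers, list(nn_gap(cin, s * s),
                           nn_linear(cin, n_classes)))
  m <- new_frame_classifier(list(type = "seq", layers = layers), vocab,
                            preprocessing = list(input_size = 224L,
                                                 streams = "rgb",
                                                 flip = flip, norm = NULL))
  m$backbone <- "vgg11_style"
  m
}

#' Training configuration presets
#'
#' The full-scale presets are: `coarse` (250 epochs, SGD, lr 0.001
#' decayed by 10 at epochs 100 and 200, batch 128, cross-entropy),
#' `refinement` (same with batch 25) and `dry_hands` (batch 128, binary
#' cross-entropy). The `desk` preset is the package's reduced setting for
#' small synthetic problems: 30 epochs, milestones 12/24, batch 128,
#' lr 0.01.
#'
#' @param preset preset name.
#' @param ... overrides for any field (`epochs`, `batch_size`, `lr`,
#'   `lr_milestones`, `lr_factor`, `loss`, `samples_per_clip`, `seed`).
#' @return list of class `train_config`.
#' @export
train_config <- function(preset = c("coarse", "refinement", "dry_hands",
                                    "desk"), ...) {
  preset <- match.arg(preset)
  cfg <- switch(preset,
    coarse = list(epochs = 250L, batch_size = 128L, lr = 0.001,
                  lr_milestones = c(100L, 200L), lr_factor = 0.1,
                  loss = "cross_entropy"),
    refinement = list(epochs = 250L, batch_size = 25L, lr = 0.001,
                      lr_milestones = c(100L, 200L), lr_factor = 0.1,
                      loss = "cross_entropy"),
    dry_hands = list(epochs = 250L, batch_size = 128L, lr = 0.001,
                     lr_milestones = c(100L, 200L), lr_factor = 0.1,
                     loss = "binary_cross_entropy"),
    desk = list(epochs = 30L, batch_size = 128L, lr = 0.01,
                lr_milestones = c(12L, 24L), lr_factor = 0.1,
                loss = "cross_entropy"))
  cfg$samples_per_clip <- 3L
  cfg$seed <- 1L
  over <- list(...)
  cfg[names(over)] <- over
  cfg$preset <- preset
  structure(cfg, class = "train_config")
}

#' Learning rate at a given epoch under the milestone schedule
#'
#' @param cfg a [train_config()].
#' @param epoch 1-based epoch number.
#' @export
lr_at_epoch <- function(cfg, epoch) {
  cfg$lr * cfg$lr_factor^sum(epoch > cfg$lr_milestones)
}

#' Split a frame-labeled video into trimmed clips
#'
#' A trimmed clip is a maximal run of frames sharing one action label.
#'
#' @param video a frame-labeled `labeled_video`.
#' @return list of clips: `list(video, frames, label)`.
#' @export
clips_from_video <- function(video) {
  if (is.null(video$labels)) stop("video carries no frame labels")
  r <- rle(video$labels)
  ends <- cumsum(r$lengths)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  lapply(seq_along(r$values), function(i) {
    list(video = video, frames = starts[i]:ends[i], label = r$values[i])
  })
}

# convert one frame to the flattened channel-first input column
frame_to_input <- function(frame, input_size, flip = FALSE) {
  if (flip) frame <- frame[, rev(seq_len(ncol(frame))), , drop = FALSE]
  f <- resize_image(frame, input_size, input_size)
  as.vector(aperm(f, c(3, 1, 2)))
}

mhi_to_input <- function(video, t, input_size, pars, flip = FALSE) {
  v <- if (flip) flip_video(video) else video
  m <- mhi_sequence(v, pars, out_size = c(input_size, input_size),
                    frame_range = c(t, t))
  as.vector(m[, , 1])
}

#' Horizontally flip a video (lazily)
#' @param video a `labeled_video`.
#' @export
flip_video <- function(video) {
  labeled_video(
    frame_fn = function(i) {
      f <- get_frame(video, i)
      f[, rev(seq_len(ncol(f))), , drop = FALSE]
    },
    n_frames = video$n_frames, fps = video$fps, labels = video$labels,
    view = video$view)
}

use_flip <- function(model, video) {
  isTRUE(model$preprocessing$flip) && identical(video$view, "wall")
}

# build the training sample pool: random frames (with MHIs when needed)
# drawn per clip
build_pool <- function(model, clips, cfg) {
  pp <- model$preprocessing
  ns <- cfg$samples_per_clip
  want_mhi <- "mhi" %in% pp$streams
  cols_rgb <- list(); cols_mhi <- list(); labs <- character(0)
  for (cl in clips) {
    flip <- use_flip(model, cl$video)
    pick <- if (length(cl$frames) <= ns) {
      sample(cl$frames, ns, replace = TRUE)
    } else {
      sample(cl$frames, ns)
    }
    for (t in pick) {
      cols_rgb[[length(cols_rgb) + 1L]] <-
        frame_to_input(get_frame(cl$video, t), pp$input_size, flip)
      if (want_mhi) {
        cols_mhi[[length(cols_mhi) + 1L]] <-
          mhi_to_input(cl$video, t, pp$input_size, pp$mhi_params, flip)
      }
      labs <- c(labs, cl$label)
    }
  }
  list(rgb = do.call(cbind, cols_rgb),
       mhi = if (want_mhi) do.call(cbind, cols_mhi) else NULL,
       labels = labs)
}

channel_stats <- function(X, C) {
  ch <- ((seq_len(nrow(X)) - 1L) %% C) + 1L
  mean_c <- vapply(seq_len(C), function(c) mean(X[ch == c, ]), numeric(1))
  sd_c <- vapply(seq_len(C), function(c) stats::sd(X[ch == c, ]), numeric(1))
  list(mean = mean_c, sd = pmax(sd_c, 1e-6))
}

normalize_stream <- function(X, st) (X - st$mean) / st$sd

#' Train a frame classifier on trimmed clips
#'
#' Each training sample is a randomly selected frame from a trimmed clip
#' (MHIs are computed from the causal in-clip history for dual-stream
#' models). Optimisation is SGD with cross-entropy (or binary cross-entropy
#' for the sigmoid dry-hands net) and the milestone learning-rate schedule.
#' Input normalisation constants are channel-wise statistics of the
#' training pool, stored in the model's preprocessing spec. Fully seeded:
#' the same clips, config and seed reproduce the same model.
#'
#' @param model untrained `frame_classifier`.
#' @param clips list of trimmed clips (see [clips_from_video()]), each with
#'   exactly one action label.
#' @param cfg a [train_config()].
#' @return trained `frame_classifier` with a `history` data.frame
#'   (epoch, lr, loss, accuracy).
#' @export
train_frame_classifier <- function(model, clips, cfg = train_config()) {
  stopifnot(inherits(model, "frame_classifier"))
  if (!is.null(model$external)) stop("external backbones are not trainable")
  labs <- vapply(clips, `[[`, character(1), "label")
  if (model$binary) {
    missing_cls <- setdiff(c("dry_hands", "non_hygiene"), unique(labs))
  } else {
    check_actions(labs, model$vocab)
    missing_cls <- setdiff(model$vocab, unique(labs))
  }
  if (length(missing_cls) > 0) {
    stop("no training clips for class(es): ",
         paste(missing_cls, collapse = ", "))
  }
  set.seed(cfg$seed)
  pool <- build_pool(model, clips, cfg)
  norm <- list(rgb = channel_stats(pool$rgb, 3L))
  Xr <- normalize_stream(pool$rgb, norm$rgb)
  Xm <- NULL
  if (!is.null(pool$mhi)) {
    norm$mhi <- channel_stats(pool$mhi, 1L)
    Xm <- normalize_stream(pool$mhi, norm$mhi)
  }
  model$preprocessing$norm <- norm
  y <- if (model$binary) {
    as.numeric(pool$labels == "dry_hands")
  } else {
    match(pool$labels, model$vocab)
  }
  n <- length(y)
  hist <- data.frame(epoch = integer(0), lr = numeric(0), loss = numeric(0),
                     accuracy = numeric(0))
  net <- model$net
  for (ep in seq_len(cfg$epochs)) {
    lr <- lr_at_epoch(cfg, ep)
    perm <- sample(n)
    losses <- c(); hits <- 0L
    for (bs in split(perm, ceiling(seq_along(perm) / cfg$batch_size))) {
      xb <- if (is.null(Xm)) {
        Xr[, bs, drop = FALSE]
      } else {
        list(rgb = Xr[, bs, drop = FALSE], mhi = Xm[, bs, drop = FALSE])
      }
      fw <- net_forward(net, xb, train = TRUE)
      if (model$binary) {
        l <- sigmoid_bce(fw$out, y[bs])
        hits <- hits + sum((l$p > 0.5) == (y[bs] > 0.5))
      } else {
        l <- softmax_ce(fw$out, y[bs])
        hits <- hits + sum(apply(fw$out, 2, which.max) == y[bs])
      }
      net_backward(net, fw$caches, l$dz)
      sgd_step(net, lr)
      losses <- c(losses, l$loss)
    }
    hist <- rbind(hist, data.frame(epoch = ep, lr = lr,
                                   loss = mean(losses),
                                   accuracy = hits / n))
  }
  model$history <- hist
  model$trained <- TRUE
  model
}

#' Per-frame class probabilities over a frame range
#'
#' Applies the classifier's preprocessing (resize, optional wall-view flip,
#' normalisation; causal MHI for dual-stream models) to every frame in the
#' range and returns one probability vector per frame (softmax over the
#' vocabulary, or a single sigmoid score for binary models). An empty range
#' yields a 0-row matrix.
#'
#' @param model a `frame_classifier` (or oracle stub).
#' @param video a `labeled_video`.
#' @param frame_range 1-based inclusive `c(from, to)`, or `NULL` for all.
#' @param batch frames per forward batch.
#' @return matrix n x K, columns named by the vocabulary (K = 1 for binary).
#' @export
predict_frames <- function(model, video, frame_range = NULL, batch = 256L) {
  UseMethod("predict_frames")
}

#' @export
predict_frames.frame_classifier <- function(model, video, frame_range = NULL,
                                            batch = 256L) {
  if (is.null(frame_range)) frame_range <- c(1L, video$n_frames)
  k <- if (model$binary) 1L else length(model$vocab)
  empty <- matrix(0, 0, k, dimnames = list(NULL, if (model$binary)
    "dry_hands" else model$vocab))
  if (length(frame_range) == 0 || frame_range[2] < frame_range[1]) {
    return(empty)
  }
  if (!is.null(model$external)) {
    idx <- frame_range[1]:frame_range[2]
    X <- vapply(idx, function(t) frame_to_input(get_frame(video, t),
                                                model$preprocessing$input_size),
                numeric(3 * model$preprocessing$input_size^2))
    out <- t(model$external(X))
    colnames(out) <- model$vocab
    return(out)
  }
  if (!model$trained) warning("predicting with an untrained classifier")
  pp <- model$preprocessing
  flip <- use_flip(model, video)
  want_mhi <- "mhi" %in% pp$streams
  idx <- frame_range[1]:frame_range[2]
  out <- matrix(0, length(idx), k)
  isz <- pp$input_size
  forward_batch <- function(Xr, Xm, bs) {
    xb <- if (want_mhi) {
      list(rgb = normalize_stream(Xr, pp$norm$rgb),
           mhi = normalize_stream(Xm, pp$norm$mhi))
    } else {
      normalize_stream(Xr, pp$norm$rgb)
    }
    z <- net_forward(model$net, xb, train = FALSE)$out
    out[bs, ] <<- if (model$binary) {
      1 / (1 + exp(-t(z)))
    } else {
      t(softmax_cols(z))
    }
  }
  if (!want_mhi) {
    for (bs in split(seq_along(idx), ceiling(seq_along(idx) / batch))) {
      Xr <- vapply(idx[bs], function(t) {
        frame_to_input(get_frame(video, t), isz, flip)
      }, numeric(3 * isz^2))
      forward_batch(Xr, NULL, bs)
    }
    colnames(out) <- if (model$binary) "dry_hands" else model$vocab
    return(out)
  }
  # dual stream: one pass over the frames, sharing each rendered frame
  # between the RGB input and the causal MHI recurrence
  mp <- pp$mhi_params
  window <- as.integer(ceiling(mp$tau / mp$delta))
  start <- max(1L, frame_range[1] - window)
  prep <- function(t) {
    f <- get_frame(video, t)
    if (flip) f <- f[, rev(seq_len(ncol(f))), , drop = FALSE]
    f
  }
  f <- prep(start)
  prev_lum <- luminance(f)
  h <- matrix(0, nrow(prev_lum), ncol(prev_lum))
  # warm the recurrence up to just before the output range
  t <- start + 1L
  while (t < frame_range[1]) {
    cur_lum <- luminance(prep(t))
    h <- pmax(h - mp$delta, 0)
    h[abs(cur_lum - prev_lum) > mp$xi] <- mp$tau
    prev_lum <- cur_lum
    t <- t + 1L
  }
  chunks <- split(seq_along(idx), ceiling(seq_along(idx) / batch))
  for (bs in chunks) {
    n <- length(bs)
    Xr <- matrix(0, 3 * isz^2, n)
    Xm <- matrix(0, isz^2, n)
    for (j in seq_len(n)) {
      t <- idx[bs[j]]
      if (t > start) {         # first frame of the video has H = 0
        f <- prep(t)
        cur_lum <- luminance(f)
        h <- pmax(h - mp$delta, 0)
        h[abs(cur_lum - prev_lum) > mp$xi] <- mp$tau
        prev_lum <- cur_lum
      }
      Xr[, j] <- as.vector(aperm(resize_image(f, isz, isz), c(3, 1, 2)))
      Xm[, j] <- as.vector(resize_image(h, isz, isz))
    }
    forward_batch(Xr, Xm, bs)
  }
  colnames(out) <- if (model$binary) "dry_hands" else model$vocab
  out
}

#' Clip-level prediction: average of per-frame scores
#'
#' The trained model is applied to every frame of a trimmed clip and the
#' per-frame probability vectors are averaged; the argmax of the average is
#' the clip prediction.
#'
#' @inheritParams predict_frames
#' @param frames frame indices of the clip.
#' @export
predict_clip <- function(model, video, frames) {
  p <- predict_frames(model, video, c(min(frames), max(frames)))
  conf <- colMeans(p)
  list(label = names(conf)[which.max(conf)], conf = conf)
}

#' Save / load a trained classifier
#'
#' Weights go to an RDS file with a JSON sidecar describing the
#' architecture, vocabulary, preprocessing and training history.
#'
#' @param model a `frame_classifier`.
#' @param path file stem; writes `<path>.rds` and `<path>.json`.
#' @export
save_classifier <- function(model, path) {
  if (!is.null(model$external)) stop("external backbones cannot be saved")
  state <- list(weights = net_state(model$net), vocab = model$vocab,
                spec = model$spec, backbone = model$backbone,
                preprocessing = model$preprocessing, binary = model$binary,
                trained = model$trained)
  saveRDS(state, paste0(path, ".rds"))
  side <- list(vocab = model$vocab, binary = model$binary,
               backbone = model$backbone,
               spec = if (!is.null(model$spec)) unclass(model$spec),
               input_size = model$preprocessing$input_size,
               streams = model$preprocessing$streams,
               trained = model$trained)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  st <- readRDS(paste0(path, ".rds"))
  model <- if (!is.null(st$spec)) {
    sp <- structure(st$spec, class = "coarse_net_spec")
    build_coarse_net(sp, vocab = st$vocab)
  } else {
    build_refinement_net(st$backbone, n_classes = length(st$vocab),
                         vocab = st$vocab)
  }
  net_load_state(model$net, st$weights)
  model$preprocessing <- st$preprocessing
  model$binary <- st$binary
  model$trained <- st$trained
  model
}
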