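layer_types <- function(layers) vapply(layers, function(l) l$type,
                                       character(1))

test_that("conv5_fc1 has five conv groups, one head, and the 32->1 trace", {
  m <- build_coarse_net(coarse_net_spec("conv5_fc1", "rgb"))
  tys <- layer_types(m$net$layers)
  expect_equal(tys, c(rep(c("conv", "bn", "relu", "maxpool"), 5), "linear"))
  convs <- Filter(function(l) l$type == "conv", m$net$layers)
  expect_equal(vapply(convs, function(l) l$H, integer(1)),
               c(32L, 16L, 8L, 4L, 2L))
  expect_equal(vapply(convs, function(l) l$Cout, integer(1)),
               c(32L, 64L, 128L, 256L, 512L))
  # head sees 512 x 1 x 1 features
  head <- m$net$layers[[21]]
  expect_equal(head$Fin, 512L)
  expect_equal(head$Fout, 3L)
})

test_that("conv4_fc2 trades the 5th group for a 512-wide fc layer", {
  m <- build_coarse_net(coarse_net_spec("conv4_fc2", "rgb"))
  tys <- layer_types(m$net$layers)
  expect_equal(tys, c(rep(c("conv", "bn", "relu", "maxpool"), 4),
                      "linear", "relu", "linear"))
  fc1 <- m$net$layers[[17]]
  expect_equal(fc1$Fin, 256L * 4L)  # 2x2 spatial x 256 channels
  expect_equal(fc1$Fout, 512L)
})

test_that("depthwise-separable variant has strictly fewer parameters", {
  env <- asNamespace("hygiene2stage")
  dw <- build_coarse_net(coarse_net_spec("dwconv4_fc2", "rgb"))
  full <- build_coarse_net(coarse_net_spec("conv4_fc2", "rgb"))
  expect_equal(layer_types(dw$net$layers)[13], "dwsep")
  expect_lt(env$net_param_count(dw$net), env$net_param_count(full$net))
  # closed-form parameter difference in the 4th group:
  # full 3x3 conv: 9*128*256 + 256; depthwise separable: 9*128 + 128*256 + 256
  diff <- (9 * 128 * 256 + 256) - (9 * 128 + 128 * 256 + 256)
  expect_equal(env$net_param_count(full$net) - env$net_param_count(dw$net),
               diff)
})

test_that("incompatible input sizes are rejected with the trace", {
  expect_error(coarse_net_spec("conv5_fc1", input_size = 48L),
               "not divisible")
})

test_that("dual-stream head concatenates both towers (1024 features)", {
  m <- build_dual_stream_net(coarse_net_spec(streams = "rgb_mhi"))
  expect_equal(m$net$type, "dual")
  expect_equal(m$net$head[[1]]$Fin, 1024L)
  expect_equal(m$net$rgb_tower[[1]]$Cin, 3L)
  expect_equal(m$net$mhi_tower[[1]]$Cin, 1L)
})

test_that("dual-stream output is a probability vector per frame pair", {
  set.seed(31)
  spec <- coarse_net_spec(streams = "rgb_mhi",
                          channel_widths = c(4L, 8L, 8L, 8L, 8L))
  m <- build_dual_stream_net(spec)
  m$preprocessing$norm <- list(rgb = list(mean = rep(0, 3), sd = rep(1, 3)),
                               mhi = list(mean = 0, sd = 1))
  m$trained <- TRUE
  frames <- lapply(1:35, function(i) {
    flat_frame(c((i * 40) %% 256, 10, 10), 32)
  })
  v <- video_from_frames(frames)
  # MHI input comes from the 32x32 video itself here (exercises the plumbing)
  p <- predict_frames(m, v, c(2, 6))
  expect_equal(dim(p), c(5L, 3L))
  expect_equal(rowSums(p), rep(1, 5), tolerance = 1e-6)
  expect_identical(p, predict_frames(m, v, c(2, 6)))
  # zeroing the MHI tower's head weights makes output a function of RGB
  # alone: constant-rgb frames then all score identically even though their
  # MHI histories differ
  nf <- m$net$head[[1]]$Fin
  head_w <- m$net$head[[1]]$Wt
  m$net$head[[1]]$Wt[, (nf / 2 + 1):nf] <- 0
  same_rgb <- video_from_frames(lapply(1:35, function(i) {
    f <- flat_frame(c(100, 10, 10), 32)
    f[(i %% 30) + 1, , ] <- 250   # moving line: motion without rgb change?
    f
  }))
  p_rgb_only <- predict_frames(m, v, c(10, 14))
  m$net$head[[1]]$Wt <- head_w
  p_full <- predict_frames(m, v, c(10, 14))
  expect_false(isTRUE(all.equal(p_rgb_only, p_full)))
})

test_that("refinement backbones emit 7 classes and reject unknown tokens", {
  m <- build_refinement_net("small_backbone",
                            channel_widths = c(4L, 8L, 8L, 8L, 8L))
  expect_length(m$vocab, 7)
  expect_error(build_refinement_net("resnet152"), "unknown backbone")
  ext <- build_refinement_net("external",
                              external = function(X) {
                                matrix(1 / 7, 7, ncol(X))
                              })
  v <- video_from_frames(lapply(1:3, function(i) flat_frame(c(5, 5, 5))))
  p <- predict_frames(ext, v, c(1, 2))
  expect_equal(dim(p), c(2L, 7L))
  expect_error(build_refinement_net("external"), "external")
  # small backbone forward is fast on a single CPU (informational)
  m$preprocessing$norm <- list(rgb = list(mean = rep(0, 3), sd = rep(1, 3)))
  m$trained <- TRUE
  big <- video_from_frames(list(flat_frame(c(9, 9, 9), 224)))
  t0 <- proc.time()
  p1 <- predict_frames(m, big, c(1, 1))
  dt <- (proc.time() - t0)[3]
  message(sprintf("small_backbone single-frame forward: %.0f ms", dt * 1000))
  expect_equal(sum(p1), 1, tolerance = 1e-6)
})

test_that("vgg11-style builds its conv configuration", {
  m <- build_refinement_net("vgg11_style", n_classes = 7L)
  tys <- layer_types(m$net$layers)
  convs <- Filter(function(l) l$type == "conv", m$net$layers)
  expect_equal(vapply(convs, function(l) l$Cout, integer(1)),
               c(64L, 128L, 256L, 256L, 512L, 512L, 512L, 512L))
  expect_equal(sum(tys == "maxpool"), 5)
  expect_equal(tys[length(tys)], "linear")
  expect_equal(m$net$layers[[length(tys)]]$Fout, 7L)
})

test_that("the learning-rate schedule decays by 10 at 100 and 200", {
  cfg <- train_config("coarse")
  expect_equal(cfg$epochs, 250L)
  expect_equal(cfg$batch_size, 128L)
  expect_equal(lr_at_epoch(cfg, 50), 0.001)
  expect_equal(lr_at_epoch(cfg, 150), 1e-4)
  expect_equal(lr_at_epoch(cfg, 201), 1e-5)
  expect_equal(train_config("refinement")$batch_size, 25L)
  expect_equal(train_config("dry_hands")$loss, "binary_cross_entropy")
})

test_that("training rejects clip sets with an empty class", {
  m <- build_coarse_net(coarse_net_spec(
    "conv5_fc1", "rgb", channel_widths = c(4L, 4L, 4L, 4L, 4L)))
  v <- labeled_flat_video(rep("soap", 10))
  clips <- list(list(video = v, frames = 1:10, label = "hand_hygiene"))
  expect_error(train_frame_classifier(m, clips, train_config("desk")),
               "faucet_elbow")
})

test_that("a seeded two-class toy trains to perfect held-out accuracy", {
  mk_clip <- function(col, label, n = 12) {
    frames <- lapply(seq_len(n), function(i) {
      f <- flat_frame(col, 32)
      f[((i - 1) %% 32) + 1, , ] <- 255 - col  # a moving line: some texture
      f
    })
    list(video = video_from_frames(frames,
                                   labels = rep(label, n), view = "chest"),
         frames = 1:n, label = label)
  }
  clips <- c(lapply(1:6, function(i) mk_clip(c(240, 240, 240),
                                             "non_hygiene")),
             lapply(1:6, function(i) mk_clip(c(15, 15, 15), "dry_hands")))
  set.seed(77)  # weight initialisation draws from the session RNG
  m <- build_dry_hands_net(channel_widths = c(4L, 8L, 8L, 8L, 8L))
  cfg <- train_config("desk", epochs = 5L, batch_size = 16L,
                      samples_per_clip = 4L, seed = 2L,
                      loss = "binary_cross_entropy")
  m <- train_frame_classifier(m, clips, cfg)
  expect_true(m$trained)
  expect_equal(nrow(m$history), 5)
  # held-out frames of each colour family
  held_pos <- video_from_frames(list(flat_frame(c(10, 10, 10), 32)))
  held_neg <- video_from_frames(list(flat_frame(c(245, 245, 245), 32)))
  expect_gt(predict_frames(m, held_pos, c(1, 1))[1, 1], 0.5)
  expect_lt(predict_frames(m, held_neg, c(1, 1))[1, 1], 0.5)
  # seeded determinism (same init seed, same training seed)
  set.seed(77)
  m2 <- build_dry_hands_net(channel_widths = c(4L, 8L, 8L, 8L, 8L))
  m2 <- train_frame_classifier(m2, clips, cfg)
  expect_equal(m$history$loss, m2$history$loss, tolerance = 1e-12)
})

test_that("classifiers round-trip through checkpoints", {
  set.seed(41)
  m <- build_coarse_net(coarse_net_spec(
    "conv5_fc1", "rgb", channel_widths = c(4L, 4L, 4L, 4L, 4L)))
  m$preprocessing$norm <- list(rgb = list(mean = rep(0, 3),
                                          sd = rep(1, 3)))
  m$trained <- TRUE
  stem <- tempfile()
  save_classifier(m, stem)
  expect_true(file.exists(paste0(stem, ".rds")))
  expect_true(file.exists(paste0(stem, ".json")))
  m2 <- load_classifier(stem)
  v <- video_from_frames(list(flat_frame(c(77, 10, 200), 32)))
  expect_equal(predict_frames(m, v, c(1, 1)),
               predict_frames(m2, v, c(1, 1)))
})

test_that("clip-level prediction averages the per-frame scores", {
  v <- labeled_flat_video(rep("soap", 8))
  o <- oracle_classifier("standard7")
  p <- predict_frames(o, v, c(1, 8))
  cl <- predict_clip(o, v, 1:8)
  expect_equal(unname(cl$conf), colMeans(p), ignore_attr = TRUE)
  expect_equal(cl$label, "soap")
})
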