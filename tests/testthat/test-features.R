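test_that("motion mask thresholds the luminance difference strictly", {
  a <- flat_frame(c(100, 100, 100))
  expect_equal(motion_mask(a, a), matrix(0, 16, 16))
  b <- flat_frame(c(255, 255, 255))
  z <- flat_frame(c(0, 0, 0))
  expect_equal(motion_mask(b, z), matrix(1, 16, 16))
  # single pixel difference of 25 fires with xi = 20; exactly 20 does not
  c1 <- a
  c1[3, 5, ] <- 125  # luminance difference exactly 25
  m <- motion_mask(c1, a)
  expect_equal(sum(m), 1)
  expect_equal(m[3, 5], 1)
  c2 <- a
  c2[3, 5, ] <- 120  # difference exactly 20: strict inequality
  expect_equal(sum(motion_mask(c2, a)), 0)
  expect_error(motion_mask(a, flat_frame(c(1, 1, 1), size = 8)),
               "shapes differ")
})

test_that("MHI follows the decay recurrence on a single-pixel activation", {
  # pixel active only between frames 1 and 2, tau = 5, delta = 1:
  # values afterwards decay 5, 4, 3, 2, 1, 0
  base <- flat_frame(c(50, 50, 50), size = 4)
  hot <- base
  hot[2, 2, ] <- 200
  frames <- c(list(base, hot), lapply(1:6, function(i) hot))
  v <- video_from_frames(frames)
  m <- mhi_sequence(v, out_size = NULL)
  expect_equal(m[2, 2, 1], 0)
  expect_equal(m[2, 2, 2:7], c(5, 4, 3, 2, 1, 0))
  expect_true(all(m[1, 1, ] == 0))
})

test_that("static clips give all-zero MHIs and constant motion saturates", {
  v <- video_from_frames(lapply(1:6, function(i) flat_frame(c(9, 9, 9))))
  expect_true(all(mhi_sequence(v, out_size = NULL) == 0))
  # alternate black/white: every pixel active at every step
  v2 <- video_from_frames(lapply(1:6, function(i) {
    flat_frame(if (i %% 2) c(0, 0, 0) else c(255, 255, 255))
  }))
  m <- mhi_sequence(v2, out_size = NULL)
  expect_true(all(m[, , 2:6] == 5))
  expect_error(mhi_sequence(video_from_frames(list(flat_frame(c(1, 1, 1))))),
               "at least 2 frames")
})

test_that("windowed MHI at a frame equals the full causal recurrence", {
  v <- random_video(n_frames = 25, seed = 42)
  full <- mhi_sequence(v, out_size = NULL)
  for (t in c(7, 15, 25)) {
    one <- mhi_sequence(v, out_size = NULL, frame_range = c(t, t))
    expect_equal(one[, , 1], full[, , t])
  }
})

test_that("HSV colour histogram has 288 dimensions and unit region mass", {
  set.seed(3)
  img <- array(sample(0:255, 224 * 224 * 3, replace = TRUE),
               c(224, 224, 3))
  h <- hsv_color_histogram(img)
  expect_length(h, 288)
  for (r in 1:4) {
    expect_equal(sum(h[(r - 1) * 72 + 1:72]), 1, tolerance = 1e-9)
  }
  expect_true(all(h >= 0))
  expect_error(hsv_color_histogram(matrix(0, 10, 10)), "3-channel")
})

test_that("uniform-colour image concentrates each region in one bin", {
  img <- flat_frame(c(200, 30, 30), size = 224)
  h <- hsv_color_histogram(img)
  for (r in 1:4) {
    reg <- h[(r - 1) * 72 + 1:72]
    expect_equal(sum(reg > 0), 1)
    expect_equal(max(reg), 1)
  }
})

test_that("half-and-half image separates mass by region column", {
  img <- array(0, c(224, 224, 3))
  img[, 1:112, 1] <- 250                       # left half: red
  img[, 113:224, 3] <- 250                     # right half: blue
  h <- hsv_color_histogram(img)
  # regions in row-major order: TL, TR, BL, BR; compute the expected joint
  # bin per colour with an independent per-pixel assignment
  bin_for <- function(px) {
    hsv <- grDevices::rgb2hsv(px[1], px[2], px[3], maxColorValue = 255)
    vb <- min(floor(hsv["v", 1] * 8) + 1, 8)
    hb <- min(floor(hsv["h", 1] * 3) + 1, 3)
    sb <- min(floor(hsv["s", 1] * 3) + 1, 3)
    (vb - 1) * 9 + (hb - 1) * 3 + sb
  }
  red_bin <- bin_for(c(250, 0, 0)); blue_bin <- bin_for(c(0, 0, 250))
  for (r in c(1, 3)) {  # left-column regions
    expect_equal(h[(r - 1) * 72 + red_bin], 1)
  }
  for (r in c(2, 4)) {  # right-column regions
    expect_equal(h[(r - 1) * 72 + blue_bin], 1)
  }
})

test_that("texture descriptors have the closed-form lengths", {
  set.seed(4)
  img <- array(sample(0:255, 224 * 224 * 3, replace = TRUE),
               c(224, 224, 3))
  d <- texture_descriptors(img)
  # HOG: (224/8 - 1)^2 blocks x 4 cells x 9 orientations
  expect_length(d$hog, 27^2 * 4 * 9)
  expect_length(d$lbp_histogram, 59)
  expect_equal(sum(d$lbp_histogram), 1, tolerance = 1e-9)
  expect_error(texture_descriptors(array(0, c(1, 1, 3))), "degenerate")
})

test_that("constant image yields an all-zero HOG", {
  d <- texture_descriptors(flat_frame(c(120, 120, 120), 224))
  expect_true(all(d$hog == 0))
})

test_that("a vertical step edge loads the horizontal-gradient HOG bin", {
  img <- array(0, c(224, 224, 3))
  img[, 113:224, ] <- 255
  d <- texture_descriptors(img)
  hog <- array(d$hog, c(9, 4, 27 * 27))
  by_bin <- apply(hog, 1, sum)
  # horizontal gradient (angle 0) lands in orientation bin 1
  expect_equal(which.max(by_bin), 1)
  expect_gt(by_bin[1], 0.99 * sum(by_bin))
})

test_that("descriptors are deterministic", {
  set.seed(5)
  img <- array(sample(0:255, 224 * 224 * 3, replace = TRUE),
               c(224, 224, 3))
  expect_identical(hsv_color_histogram(img), hsv_color_histogram(img))
  expect_identical(texture_descriptors(img), texture_descriptors(img))
})

test_that("dry-hands random forest separates a toy problem", {
  set.seed(9)
  pos <- matrix(rnorm(40 * 5, mean = 3), 40, 5)
  neg <- matrix(rnorm(40 * 5, mean = -3), 40, 5)
  X <- rbind(pos, neg)
  y <- rep(c("dry_hands", "non_hygiene"), each = 40)
  clf <- train_dry_hands_forest(X, y, seed = 2)
  expect_true(all(predict_frame(clf, pos) > 0.5))
  expect_true(all(predict_frame(clf, neg) < 0.5))
  # deterministic given the seed
  clf2 <- train_dry_hands_forest(X, y, seed = 2)
  expect_identical(predict_frame(clf, X), predict_frame(clf2, X))
  expect_error(train_dry_hands_forest(pos, rep("dry_hands", 40)),
               "at least 2 samples")
})
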