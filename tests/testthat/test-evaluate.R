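test_that("Jaccard index follows the set definition and conventions", {
  expect_equal(jaccard_index(1:5, 1:5), 1)
  expect_equal(jaccard_index(1:3, 7:9), 0)
  expect_equal(jaccard_index(2:9, 5:14), 5 / 13)
  expect_equal(jaccard_index(integer(0), integer(0)), 1)
  expect_equal(jaccard_index(integer(0), 1:2), 0)
  expect_equal(jaccard_index(1:2, integer(0)), 0)
  # symmetric; equals 1 iff equal sets (both nonempty)
  expect_equal(jaccard_index(2:9, 5:14), jaccard_index(5:14, 2:9))
  expect_lt(jaccard_index(1:4, 1:5), 1)
})

test_that("duration error is the absolute unit-count difference", {
  expect_equal(duration_error(1:16, 1:14), 2)
  expect_equal(duration_error(1:5, 11:15), 0)
  expect_equal(duration_error(1:16, 1:14), duration_error(1:14, 1:16))
})

test_that("existence accuracy counts matches over total", {
  expect_equal(existence_accuracy(rep(TRUE, 5), rep(TRUE, 5)), 1)
  pred <- c(rep(TRUE, 19), rep(FALSE, 3))
  gt <- rep(TRUE, 22)
  expect_equal(existence_accuracy(pred, gt), 19 / 22)
  expect_error(existence_accuracy(logical(0), logical(0)), "empty")
  expect_error(existence_accuracy(c(TRUE), c(TRUE, FALSE)), "length")
})

test_that("level accuracy counts correct labels at the given granularity", {
  set.seed(21)
  gt <- sample(standard7, 90, replace = TRUE)
  pred <- gt
  flip <- sample(90, 9)
  pred[flip] <- vapply(pred[flip], function(a) {
    setdiff(standard7, a)[1]
  }, character(1))
  expect_equal(level_accuracy(pred, gt, "frame"), 81 / 90)
  expect_equal(level_accuracy(rep("soap", 5), rep("rub_water", 5)), 0)
  expect_error(level_accuracy(gt[1:10], gt), "length")
})

test_that("dry-hands precision/recall handles the no-positive case", {
  # TP = 3, FP = 1, FN = 2
  pred <- c(rep(TRUE, 4), rep(FALSE, 4))
  gt <- c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, FALSE, FALSE)
  pr <- dry_hands_pr(pred, gt)
  expect_equal(pr$precision, 0.75)
  expect_equal(pr$recall, 0.6)
  perfect <- dry_hands_pr(gt, gt)
  expect_equal(unlist(perfect), c(precision = 1, recall = 1, accuracy = 1))
  expect_warning(pr0 <- dry_hands_pr(rep(FALSE, 4),
                                     c(TRUE, TRUE, FALSE, FALSE)),
                 "undefined")
  expect_true(is.na(pr0$precision))
  expect_equal(pr0$recall, 0)
})

test_that("metrics match brute-force recomputation on random tracks", {
  set.seed(22)
  for (i in 1:100) {
    n <- sample(5:40, 1)
    gt <- sample(0:(n - 1), sample(0:n, 1))
    pred <- sample(0:(n - 1), sample(0:n, 1))
    # brute force over the universe of units
    inter <- 0; uni <- 0
    for (u in 0:(n - 1)) {
      ing <- u %in% gt; inp <- u %in% pred
      inter <- inter + (ing && inp)
      uni <- uni + (ing || inp)
    }
    jexp <- if (uni == 0) 1 else inter / uni
    expect_equal(jaccard_index(gt, pred), jexp)
    expect_equal(duration_error(gt, pred), abs(length(gt) - length(pred)))
  }
})

test_that("track evaluation summarises per-action sets", {
  gt <- data.frame(unit = 0:5,
                   label = c("non_hygiene", "rub_water", "rub_water",
                             "soap", "dry_hands", "non_hygiene"))
  pred <- data.frame(unit = 0:5,
                     label = c("non_hygiene", "rub_water", "soap", "soap",
                               "non_hygiene", "non_hygiene"))
  ev <- evaluate_unit_track(pred, gt)
  pa <- ev$per_action
  expect_equal(pa$jaccard[pa$action == "rub_water"], 0.5)
  expect_equal(pa$duration_error_s[pa$action == "rub_water"], 1)
  expect_equal(pa$jaccard[pa$action == "soap"], 0.5)
  expect_false(pa$pred_present[pa$action == "dry_hands"])
  expect_equal(ev$unit_accuracy, 4 / 6)
})
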