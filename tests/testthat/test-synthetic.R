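test_that("identical script and seed give bit-identical sessions", {
  s1 <- generate_session(session_script(seed = 3), resolution = 64)
  s2 <- generate_session(session_script(seed = 3), resolution = 64)
  expect_identical(s1$wall$labels, s2$wall$labels)
  for (i in c(1, 50, 200)) {
    expect_identical(get_frame(s1$wall, i), get_frame(s2$wall, i))
    expect_identical(get_frame(s1$chest, i), get_frame(s2$chest, i))
  }
})

test_that("frame counts and labels follow the script arithmetic", {
  sc <- session_script(data.frame(
    action = c("non_hygiene", "rub_water"), duration = c(2, 3)))
  ses <- generate_session(sc, resolution = 32)
  expect_equal(n_frames(ses$wall), 150)
  expect_equal(ses$wall$labels[1:60], rep("non_hygiene", 60))
  expect_equal(ses$wall$labels[61:150], rep("rub_water", 90))
  # label conservation: per-label counts equal segment frame counts
  expect_equal(unname(table(ses$wall$labels)["rub_water"]), 90,
               ignore_attr = TRUE)
  # view consistency
  expect_identical(ses$wall$labels, ses$chest$labels)
})

test_that("unknown actions are rejected with the token named", {
  expect_error(session_script(data.frame(action = "rinse", duration = 1)),
               "rinse")
})

test_that("sampled durations respect the truncation floor", {
  for (seed in 1:5) {
    sc <- session_script(seed = seed)
    expect_true(all(sc$segments$duration >= 1))
  }
})

test_that("motion_only classes are pixel-identical at matched phase", {
  # classes differ only in oscillation frequency f: a frame at time t
  # depends on the phase f * t only, so times with equal phase (mod 1)
  # give identical frames across classes
  mk <- function(action, dur) {
    generate_session(session_script(data.frame(action = action,
                                               duration = dur)),
                     appearance_mode = "motion_only", resolution = 64)
  }
  a <- mk("rub_water", 4)    # f = 0.8 Hz
  b <- mk("rub_nowater", 4)  # f = 1.8 Hz
  # phase 0 at segment start for both
  expect_identical(get_frame(a$wall, 1), get_frame(b$wall, 1))
  # rub_water at t = 75 frames: phase 0.8*75/30 = 2.0; rub_nowater at
  # t = 100: phase 1.8*100/30 = 6.0 -> equal mod 1
  expect_identical(get_frame(a$wall, 76), get_frame(b$wall, 101))
  # and the time-averaged histograms over full cycles agree
  hist_of <- function(ses, frames) {
    h <- 0
    for (i in frames) h <- h + tabulate(get_frame(ses$wall, i)[, , 1] + 1,
                                        256)
    h / length(frames)
  }
  ha <- hist_of(a, 1:75)     # 2 full cycles of f = 0.8 at 30 fps
  hb <- hist_of(b, 1:50)     # 3 full cycles of f = 1.8
  expect_lt(max(abs(ha - hb)) / max(ha), 0.02)
})

test_that("dataset manifest splits participants 66/12/22 and is disjoint", {
  man <- generate_dataset(100, 2, split_proportions = c(66, 12, 22),
                          seed = 4)
  by_split <- split(unique(man$participant[order(man$participant)]),
                    man$split[man$session == 1][order(man$participant[man$session == 1])])
  counts <- table(man$split[man$session == 1])
  expect_equal(unname(counts[c("train", "val", "test")]), c(66, 12, 22),
               ignore_attr = TRUE)
  # participant-level: both sessions of one participant share a split
  agg <- tapply(man$split, man$participant,
                function(s) length(unique(s)))
  expect_true(all(agg == 1))
  # pairwise disjoint and union = all participants
  expect_equal(length(unique(man$participant)), 100)
  # fixed seed reproduces the manifest
  expect_identical(man, generate_dataset(100, 2, c(66, 12, 22), seed = 4))
  # fractions are accepted too
  man2 <- generate_dataset(10, 1, c(0.6, 0.2, 0.2), seed = 1)
  expect_equal(unname(table(man2$split)[c("train", "val", "test")]),
               c(6, 2, 2), ignore_attr = TRUE)
  expect_error(generate_dataset(2, 1), "at least")
})

test_that("fixtures round-trip losslessly through PNG directories", {
  sc <- session_script(data.frame(action = c("soap", "dry_hands"),
                                  duration = c(1, 1)))
  ses <- generate_session(sc, resolution = 32)
  d <- file.path(tempdir(), "fix_test")
  on.exit(unlink(d, recursive = TRUE))
  write_fixture(ses$chest, d)
  expect_length(list.files(d, pattern = "\\.png$"), 60)
  lab <- utils::read.csv(file.path(d, "labels.csv"))
  expect_equal(nrow(lab), 60)
  back <- read_video(d)
  expect_equal(back$n_frames, 60)
  expect_identical(back$labels, ses$chest$labels)
  for (i in c(1, 31, 60)) {
    expect_equal(get_frame(back, i), get_frame(ses$chest, i))
  }
  expect_equal(back$fps, 30)
  expect_equal(back$view, "chest")
})
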