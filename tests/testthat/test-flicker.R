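cfg <- flicker_config()

test_that("the three buffer states are recognized", {
  cases <- list(
    list(c(1, 1, 1, 1, 1, 1), "UNIFORM"),      # one label, no variation
    list(c(1, 1, 1, 2, 2, 2), "TRANSITION"),   # ascending two-label blocks
    list(c(2, 3, 1, 1, 2, 4), "FLICKER"),      # many labels, unsorted
    list(c(2, 2, 2, 1, 1, 1), "FLICKER"),      # backward jump
    list(c(1, 2, 1, 2, 1, 2), "FLICKER"),      # two labels, interleaved
    list(c(1, 1, 1, 3, 3, 3), "TRANSITION"),   # non-adjacent phases allowed
    list(c(1, 1, 2, 2, 3, 3), "FLICKER")       # three labels even if sorted
  )
  for (case in cases) {
    expect_equal(classify_window(case[[1]], cfg), case[[2]],
                 info = paste(case[[1]], collapse = ","))
  }
  expect_error(classify_window(c(1, 1, 1), cfg), "buffer width")
})

test_that("classifier agrees with the literal rule text (randomized windows)", {
  set.seed(7)
  for (i in 1:500) {
    w <- sample(0:7, 6, replace = TRUE)
    expect_equal(classify_window(w, cfg), oracle_classify(w),
                 info = paste(w, collapse = ","))
  }
})

test_that("window permutation and sorting behave as the states demand", {
  set.seed(11)
  for (i in 1:100) {
    w <- sample(0:7, 6, replace = TRUE)
    p <- sample(w)
    # permuting never changes UNIFORM status
    expect_equal(classify_window(w, cfg) == "UNIFORM",
                 classify_window(p, cfg) == "UNIFORM")
    # sorting any two-label window always yields TRANSITION
    if (length(unique(w)) == 2L) {
      expect_equal(classify_window(sort(w), cfg), "TRANSITION")
    }
  }
})

test_that("scanning slides the buffer with stride 1", {
  s <- annotation_sequence(rep(4, 10))
  expect_equal(scan_sequence(s, cfg), rep("UNIFORM", 5))

  s <- annotation_sequence(c(1, 1, 1, 2, 2, 2))
  expect_equal(scan_sequence(s, cfg), "TRANSITION")

  expect_error(scan_sequence(annotation_sequence(rep(1, 5)), cfg),
               "shorter")

  # window-by-window agreement with the per-window classifier
  set.seed(3)
  labels <- sample(0:7, 200, replace = TRUE, prob = c(8, 8, 1, 1, 1, 1, 1, 1))
  s <- annotation_sequence(labels)
  states <- scan_sequence(s, cfg)
  expect_length(states, 195)
  for (i in seq_along(states)) {
    expect_equal(states[i], classify_window(labels[i:(i + 5)], cfg))
  }
})

test_that("an isolated stray frame is classified per window along the scan", {
  labels <- c(1, 1, 1, 1, 3, 1, 1, 1, 1)
  states <- scan_sequence(annotation_sequence(labels), cfg)
  expected <- vapply(1:4, function(i) oracle_classify(labels[i:(i + 5)]),
                     character(1))
  expect_equal(states, expected)
  expect_true(all(states == "FLICKER"))  # 3 then back to 1 is never sorted
})

test_that("active frames are the union of non-uniform window spans", {
  # all uniform -> nothing active
  expect_equal(mark_active_frames(rep("UNIFORM", 5), cfg, 10),
               rep(FALSE, 10))
  # one transition window at the first position covers frames 1..6
  st <- c("TRANSITION", rep("UNIFORM", 4))
  expect_equal(which(mark_active_frames(st, cfg, 10)), 1:6)
  # two flicker windows at positions 1 and 4 cover the union 1..9
  st <- c("FLICKER", "UNIFORM", "UNIFORM", "FLICKER", rep("UNIFORM", 3))
  expect_equal(which(mark_active_frames(st, cfg, 12)), 1:9)
  expect_error(mark_active_frames(rep("UNIFORM", 4), cfg, 10), "geometry")
})

test_that("a clean 8-phase course yields exactly 7 transition-only groups", {
  s <- clean_course()
  g <- extract_ft_groups(s, cfg)
  expect_equal(nrow(g), 7L)
  expect_false(any(g$contains_flicker))
  # each single-step boundary is covered by width-1 transition windows,
  # touching 2 * width - 2 frames
  expect_equal(g$n_frames, rep(10L, 7))

  p <- flicker_profile(s, cfg)
  expect_equal(p$n_ft_groups, 7L)
  expect_equal(p$n_ft_frames, 70L)
  expect_equal(p$n_flicker_frames, 0L)
})

test_that("a constant sequence profiles to zero", {
  p <- flicker_profile(annotation_sequence(rep(5, 50)), cfg)
  expect_equal(p$n_ft_groups, 0L)
  expect_equal(p$n_ft_frames, 0L)
  expect_equal(p$n_flicker_frames, 0L)
})

test_that("active runs merge at the 10 s gap boundary and not beyond", {
  # two single-step boundaries; the inactive gap between their active spans
  # is (middle run length - 10) frames
  two_boundary <- function(mid) {
    annotation_sequence(c(rep(1, 30), rep(2, mid), rep(3, 30)), fps = 2)
  }
  g20 <- extract_ft_groups(two_boundary(30), cfg)  # gap of 20 frames = 10 s
  g21 <- extract_ft_groups(two_boundary(31), cfg)  # gap of 21 frames
  expect_equal(nrow(g20), 1L)
  expect_equal(nrow(g21), 2L)
  # merged group spans first to last active frame across both runs
  expect_equal(g20$n_frames, g21$n_frames[1] + g21$n_frames[2] + 21L - 1L)
})

test_that("merge gap scales with the frame rate", {
  mk <- function(mid, fps) {
    annotation_sequence(c(rep(1, 30), rep(2, mid), rep(3, 30)), fps = fps)
  }
  # at 1 fps the limit is 10 inactive frames
  expect_equal(nrow(extract_ft_groups(mk(20, 1), cfg)), 1L)
  expect_equal(nrow(extract_ft_groups(mk(21, 1), cfg)), 2L)
})

test_that("a group touching one flicker window counts all its frames", {
  # burst of disorder right next to a regular transition: they merge and the
  # whole group counts as flicker-affected
  labels <- c(rep(1, 30), c(3, 1, 3), rep(1, 5), rep(2, 30))
  s <- annotation_sequence(labels, fps = 2)
  g <- extract_ft_groups(s, cfg)
  expect_equal(nrow(g), 1L)
  expect_true(g$contains_flicker)
  p <- flicker_profile(s, cfg)
  expect_equal(p$n_flicker_frames, p$n_ft_frames)
})

test_that("well-separated bursts add one group each to a clean course", {
  s <- clean_course(frames_per_phase = rep(100L, 8L))
  labels <- s$labels
  # 5 bursts in the interiors of phases 1..5, far from every boundary
  for (ph in 1:5) {
    at <- (ph * 100L) + 50L
    labels[at:(at + 3L)] <- sample(setdiff(0:7, ph), 4L, replace = TRUE)
  }
  p <- flicker_profile(annotation_sequence(labels), cfg)
  expect_equal(p$n_ft_groups, 12L)  # 7 transitions + 5 bursts
})

test_that("corrupting any single frame of a clean course never shrinks FT coverage", {
  s <- clean_course(frames_per_phase = rep(40L, 8L))
  base <- flicker_profile(s, cfg)$n_ft_frames
  set.seed(19)
  for (i in 1:60) {
    at <- sample(length(s$labels), 1L)
    new_label <- sample(setdiff(0:7, s$labels[at]), 1L)
    labels <- s$labels
    labels[at] <- new_label
    expect_gte(flicker_profile(annotation_sequence(labels), cfg)$n_ft_frames,
               base)
  }
})

test_that("groups are disjoint, sorted, and account for every counted frame", {
  set.seed(23)
  for (i in 1:20) {
    labels <- sample(0:7, 300, replace = TRUE,
                     prob = c(20, 20, 20, 1, 1, 1, 1, 1))
    g <- extract_ft_groups(annotation_sequence(labels), cfg)
    if (nrow(g) > 1L) {
      expect_true(all(diff(g$start_frame) > 0))
      expect_true(all(g$start_frame[-1L] > g$end_frame[-nrow(g)]))
    }
    expect_equal(g$n_frames, g$end_frame - g$start_frame + 1L)
    p <- flicker_profile(annotation_sequence(labels), cfg)
    expect_equal(p$n_ft_frames, sum(g$n_frames))
    expect_lte(p$n_flicker_frames, p$n_ft_frames)
  }
})

test_that("configuration bounds are enforced", {
  expect_error(flicker_config(buffer_width = 1), "buffer_width")
  expect_error(flicker_config(merge_gap_seconds = -1), "merge_gap")
  # a zero merge gap keeps adjacent runs separate
  c0 <- flicker_config(merge_gap_seconds = 0)
  s <- annotation_sequence(c(rep(1, 30), rep(2, 12), rep(3, 30)))
  expect_equal(nrow(extract_ft_groups(s, c0)), 2L)
})
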