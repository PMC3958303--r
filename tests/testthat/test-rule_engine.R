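test_that("eval_rows matches the worked single-stance example", {
  th <- TH600
  # left foot loaded above stance threshold, right foot in the air, flexed
  # legs, strong GRF asymmetry -> the left-stance row fires
  frame <- data.frame(t = 0, grfL = 500, grfR = 10, copyL = 100,
                      copyR = NA_real_, hipL = 10, hipR = 10, kneeL = 5,
                      kneeR = 5, gyroL = 0, gyroR = 2)
  expect_true(11L %in% eval_rows(frame, grfDiff = 490, th = th))
  # an all-quiet zero frame fires (at least) quiet standing
  zero <- data.frame(t = 0, grfL = 0, grfR = 0, copyL = NA_real_,
                     copyR = NA_real_, hipL = 0, hipR = 0, kneeL = 0,
                     kneeR = 0, gyroL = 0, gyroR = 0)
  expect_identical(eval_rows(zero, grfDiff = 0, th = th), 5L)
})

test_that("eval_rows agrees with the independently coded rule table", {
  th <- TH600
  set.seed(42)
  for (i in 1:4000) {
    rf <- random_frame()
    got <- eval_rows(rf$frame, grfDiff = rf$sig$grfDiff, th = th)
    expect_identical(got, oracle_rule_flags(rf$sig, th),
                     label = paste("frame", i))
  }
})

test_that("detector_step retains the flag when no row fires", {
  th <- TH600
  det <- new_detector(th, current = 11L)
  # both feet barely off the thresholds, moderate flexion: nothing fires
  idle <- data.frame(t = 0, grfL = 10, grfR = 10, copyL = NA_real_,
                     copyR = NA_real_, hipL = 4.5, hipR = 4.5, kneeL = 4.5,
                     kneeR = 4.5, gyroL = 1, gyroR = 1)
  expect_identical(
    eval_rows(idle, grfDiff = 0, th = th), integer(0))
  expect_identical(detector_step(det, idle)$flag, 11L)
})

test_that("initiation is entered from quiet standing", {
  th <- TH600
  det <- new_detector(th, current = 5L)
  expect_identical(detector_step(det, make_snapshot(6, th))$flag, 6L)
})

test_that("strict mode only accepts transitions legal in the state diagram", {
  th <- TH600
  term <- make_snapshot(4, th)
  # termination is reachable from a double stance but not from single stance
  expect_identical(
    detector_step(new_detector(th, "strict", current = 12L), term)$flag, 4L)
  expect_identical(
    detector_step(new_detector(th, "strict", current = 11L), term)$flag, 11L)
  expect_identical(
    detector_step(new_detector(th, "free", current = 11L), term)$flag, 4L)
})

test_that("batch detection equals streaming and is causal and deterministic", {
  th <- TH600
  tr <- simulate_trial(gait_params(n_strides = 3, seed = 21, sigma_grf = 10,
                                   sigma_cop = 4, sigma_ang = 1.5,
                                   sigma_gyro = 0.05))
  for (mode in c("free", "strict")) {
    batch <- detect_trial(tr, th, mode = mode)
    det <- new_detector(th, mode)
    stream <- integer(nrow(tr))
    for (i in seq_len(nrow(tr))) {
      st <- detector_step(det, tr[i, ])
      stream[i] <- st$flag
      det <- st$detector
    }
    expect_identical(batch, stream, label = mode)
    # causality: truncation preserves the common prefix
    k <- 400
    expect_identical(detect_trial(tr[seq_len(k), ], th, mode = mode),
                     batch[seq_len(k)])
    # determinism and closed output
    expect_identical(detect_trial(tr, th, mode = mode), batch)
    expect_true(all(batch %in% phase_flags()))
  }
  expect_identical(detect_trial(tr[0, ], th), integer(0))
})

test_that("a noise-free steady walk cycles through exactly the four phases", {
  th <- TH600
  tr <- clean_trial(n_strides = 6, seed = 8)
  flags <- detect_trial(tr, th)
  seg <- segment_phases(flags)
  # restrict to complete strides (drop the entry into and exit from walking)
  first11 <- which(seg$flag == 11L)[1]
  core <- seg[first11:(first11 + 4 * 4 - 1), ]
  expect_identical(core$flag,
                   rep(c(11L, 12L, 13L, 14L), 4))
  # each stride yields each walking flag exactly once
  expect_true(all(table(core$flag) == 4))
})

test_that("noise-free detection matches labels on walking samples", {
  th <- TH600
  tr <- clean_trial(n_strides = 8, seed = 13)
  flags <- detect_trial(tr, th)
  truth <- tr$label
  # exclude a +/-3 sample tolerance band around every label transition
  trans <- which(diff(truth) != 0)
  band <- unique(unlist(lapply(trans, function(i) (i - 2):(i + 3))))
  keep <- setdiff(which(truth %in% walking_flags()), band)
  expect_gt(mean(flags[keep] == truth[keep]), 0.99)
})
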