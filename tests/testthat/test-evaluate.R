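test_that("segmentation run-length encodes walking flags", {
  expect_identical(nrow(segment_phases(rep(5L, 20))), 0L)
  seg <- segment_phases(rep(11L, 15))
  expect_identical(seg, data.frame(flag = 11L, start = 1L, end = 16L))
  flags <- rep(rep(c(11L, 12L, 13L, 14L), 3), each = 20)
  seg <- segment_phases(flags)
  expect_identical(nrow(seg), 12L)
  expect_identical(seg$flag, rep(c(11L, 12L, 13L, 14L), 3))
  expect_identical(seg$end - seg$start, rep(20L, 12))
  # short jitter runs are absorbed by their neighbours
  jit <- c(rep(11L, 20), 13L, 13L, rep(12L, 20))
  seg <- segment_phases(jit, debounce = 3)
  expect_identical(seg$flag, c(11L, 12L))
  expect_identical(seg$end[1], 23L)
  # debounce = 1 keeps them
  expect_identical(segment_phases(jit, debounce = 1)$flag,
                   c(11L, 13L, 12L))
})

test_that("segmentation concatenation matches re-encoding the whole", {
  set.seed(12)
  for (i in 1:20) {
    a <- sample(c(5L, 11L, 12L, 13L, 14L), 60, TRUE, c(.1, rep(.225, 4)))
    b <- sample(c(5L, 11L, 12L, 13L, 14L), 60, TRUE, c(.1, rep(.225, 4)))
    whole <- segment_phases(c(a, b), debounce = 1)
    # independent brute-force re-encoding of the concatenation
    x <- c(a, b)
    ref <- list()
    j <- 1
    while (j <= length(x)) {
      if (!x[j] %in% walking_flags()) { j <- j + 1; next }
      k <- j
      while (k < length(x) && x[k + 1] == x[j]) k <- k + 1
      ref[[length(ref) + 1]] <- data.frame(flag = x[j],
                                           start = as.integer(j),
                                           end = as.integer(k + 1))
      j <- k + 1
    }
    ref <- do.call(rbind, ref)
    rownames(ref) <- NULL
    expect_identical(whole, ref)
  }
})

test_that("success ratios are exact on identity and simple arithmetic", {
  tr <- clean_trial(n_strides = 5, seed = 3)
  rep0 <- success_ratio(tr$label, tr$label)
  expect_identical(rep0$phases$ratio, rep(100, 4))
  expect_identical(rep0$mean_phase, 100)
  # 10 truth phases of one type, 9 matched -> 90%
  truth <- rep(rep(c(11L, 12L, 13L, 14L), 10), each = 10)
  detected <- truth
  detected[1:10] <- 5L  # wipe the first left stance entirely
  r <- success_ratio(detected, truth)
  expect_identical(r$phases$ratio[r$phases$flag == 11L], 90)
  expect_identical(r$phases$ratio[r$phases$flag == 12L], 100)
  expect_error(success_ratio(detected, rep(5L, 50)), "no walking phases")
})

test_that("success matching agrees with the brute-force interval matcher", {
  set.seed(19)
  for (i in 1:25) {
    truth <- rep(rep(c(11L, 12L, 13L, 14L), 6),
                 times = rep(sample(8:20, 24, TRUE)))
    detected <- truth
    # random perturbations: shifts, wipes, and relabels
    n <- length(detected)
    shift <- sample(-4:4, 1)
    if (shift != 0) {
      detected <- if (shift > 0) c(rep(5L, shift), detected[1:(n - shift)])
      else c(detected[(1 - shift):n], rep(5L, -shift))
    }
    wipe <- sample(n, sample(0:30, 1))
    detected[wipe] <- 5L
    flip <- sample(n, sample(0:10, 1))
    detected[flip] <- sample(c(11L, 12L, 13L, 14L), length(flip), TRUE)
    got <- success_ratio(detected, truth, debounce = 1)
    ref <- oracle_success_counts(detected, truth)
    expect_identical(got$phases$n_true, unname(ref$n_true))
    expect_identical(got$phases$n_correct, unname(ref$n_correct))
  }
})

test_that("side mapping is the documented bijection and its mirror", {
  expect_identical(map_to_side(c(11, 12, 13, 14), "right"),
                   c("SS_s", "DS_sp", "SS_p", "DS_ps"))
  expect_identical(map_to_side(c(11, 12, 13, 14), "left"),
                   c("SS_p", "DS_ps", "SS_s", "DS_sp"))
  for (side in c("left", "right")) {
    expect_identical(anyDuplicated(map_to_side(walking_flags(), side)), 0L)
  }
  expect_error(map_to_side(5, "right"), "walking flags")
})

test_that("sequence checking follows the topology with a skip-one allowance", {
  tr <- clean_trial(n_strides = 4, seed = 6)
  expect_identical(nrow(sequence_check(tr$label)), 0L)
  skip <- rep(c(11L, 13L, 14L), each = 10)  # 12 skipped
  expect_identical(nrow(sequence_check(skip)), 0L)
  v <- sequence_check(skip, strict = TRUE)
  expect_identical(nrow(v), 1L)
  expect_identical(c(v$from, v$to), c(11L, 13L))
  # a transition outside the diagram is always flagged
  bad <- rep(c(5L, 11L), each = 10)
  expect_identical(nrow(sequence_check(bad)), 1L)
  backwards <- rep(c(12L, 11L), each = 10)
  expect_gt(nrow(sequence_check(backwards)), 0L)
})

test_that("pooled reports aggregate counts, invariant to trial order", {
  trials <- lapply(c(2, 4, 6), function(s) {
    simulate_trial(gait_params(n_strides = 4, seed = s, sigma_grf = 12,
                               sigma_cop = 5, sigma_ang = 2,
                               sigma_gyro = 0.05))
  })
  reps <- lapply(trials, function(tr) {
    success_ratio(detect_trial(tr, TH600), tr$label, "right")
  })
  pooled <- pool_reports(reps)
  shuffled <- pool_reports(reps[c(3, 1, 2)])
  expect_identical(pooled$phases, shuffled$phases)
  expect_identical(sum(pooled$phases$n_true),
                   sum(vapply(reps, function(r) sum(r$phases$n_true), 1)))
  # the phase mean is the arithmetic mean of the four per-phase ratios
  expect_equal(pooled$mean_phase, mean(pooled$phases$ratio))
  # the weighted mean pools counts
  expect_equal(pooled$mean_weighted,
               100 * sum(pooled$phases$n_correct) /
                 sum(pooled$phases$n_true))
})
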