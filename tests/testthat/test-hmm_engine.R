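# a small trained bank shared by several tests
bank_fixture <- local({
  train <- lapply(1:3, function(i) clean_trial(n_strides = 5, seed = 100 + i))
  list(train = train, bank = train_hmm_bank(train, seed = 1))
})

test_that("feature extraction follows the documented order and mapping", {
  tr <- clean_trial(n_strides = 2, seed = 1)
  f <- extract_features(tr)
  expect_identical(colnames(f),
                   c("grfL", "grfR", "grfDiff", "copyL", "copyR", "sumAng",
                     "gyroL", "gyroR", "loadedL", "loadedR"))
  expect_identical(nrow(f), nrow(tr))
  # sentinel COP maps to mid-insole with the loaded flag cleared
  swing <- which(is.na(tr$copyR))[1]
  expect_equal(unname(f[swing, "copyR"]), 130)
  expect_equal(unname(f[swing, "loadedR"]), 0)
  loadedi <- which(!is.na(tr$copyR))[1]
  expect_equal(unname(f[loadedi, "copyR"]), tr$copyR[loadedi])
  expect_equal(unname(f[loadedi, "loadedR"]), 1)
  expect_equal(unname(f[, "grfDiff"]),
               rolling_grf_diff(tr$grfL, tr$grfR))
})

test_that("normalisation round-trips exactly", {
  set.seed(6)
  x <- matrix(rnorm(60, 10, 4), 6, 10)
  center <- rnorm(10)
  scale <- runif(10, 0.5, 3)
  expect_equal(denormalize_features(normalize_features(x, center, scale),
                                    center, scale), x)
})

test_that("EM training is monotone, stochastic and seed-deterministic", {
  # segments sampled from a known 3-state Gaussian HMM
  sample_hmm <- function(Tn) {
    A <- matrix(c(.8, .2, 0, 0, .8, .2, .1, 0, .9), 3, byrow = TRUE)
    mu <- matrix(c(0, 0, 4, 0, 0, 4), 3, 2)
    s <- integer(Tn)
    s[1] <- 1
    for (t in 2:Tn) s[t] <- sample(1:3, 1, prob = A[s[t - 1], ])
    cbind(rnorm(Tn, mu[s, 1], .5), rnorm(Tn, mu[s, 2], .5))
  }
  set.seed(9)
  segs <- lapply(rep(30, 8), sample_hmm)
  m <- train_phase_hmm(segs, n_states = 3, phase = 11L, seed = 2)
  trace <- attr(m, "loglik_trace")
  expect_gt(length(trace), 1)
  expect_true(all(diff(trace) >= -1e-8))
  expect_gt(trace[length(trace)], trace[1])
  # stochasticity invariants
  expect_equal(rowSums(m$trans), rep(1, 3), tolerance = 1e-9)
  expect_equal(sum(m$init), 1, tolerance = 1e-9)
  expect_true(all(m$vars >= 1e-2))
  # same data and seed give the identical model
  m2 <- train_phase_hmm(segs, n_states = 3, phase = 11L, seed = 2)
  expect_identical(m[c("init", "trans", "means", "vars")],
                   m2[c("init", "trans", "means", "vars")])
  # degenerate constant segments train without failure
  const <- lapply(1:3, function(i) matrix(1, 10, 2))
  mc <- train_phase_hmm(const, n_states = 3, seed = 1)
  expect_true(all(is.finite(mc$means)))
  expect_error(train_phase_hmm(list(matrix(0, 2, 2)), n_states = 3),
               "at least")
})

test_that("forward log-likelihood equals exhaustive path enumeration", {
  set.seed(15)
  # 2-state toy model, windows up to length 8 (2^8 paths)
  init2 <- c(.7, .3)
  A2 <- matrix(c(.9, .1, .3, .7), 2, byrow = TRUE)
  mu2 <- matrix(c(-1, 2, 0, 1), 2, 2)
  v2 <- matrix(c(.5, .8, 1.2, .4), 2, 2)
  m2 <- structure(list(phase = 11L, n_states = 2L, init = init2, trans = A2,
                       means = mu2, vars = v2), class = "gait_hmm")
  for (Tn in c(1, 3, 8)) {
    obs <- matrix(rnorm(2 * Tn), Tn, 2)
    expect_equal(hmm_loglik(m2, obs),
                 oracle_enum_loglik(init2, A2, mu2, v2, obs),
                 tolerance = 1e-8)
  }
  # 3-state model with a structural zero in the transitions, length 6
  init3 <- c(.6, .3, .1)
  A3 <- matrix(c(.8, .2, 0, 0, .7, .3, .2, .1, .7), 3, byrow = TRUE)
  mu3 <- matrix(rnorm(6), 3, 2)
  v3 <- matrix(runif(6, .3, 1.5), 3, 2)
  m3 <- structure(list(phase = 12L, n_states = 3L, init = init3, trans = A3,
                       means = mu3, vars = v3), class = "gait_hmm")
  obs <- matrix(rnorm(12), 6, 2)
  expect_equal(hmm_loglik(m3, obs),
               oracle_enum_loglik(init3, A3, mu3, v3, obs),
               tolerance = 1e-8)
})

test_that("windows drawn from a phase are classified as that phase", {
  bank <- bank_fixture$bank
  held_out <- clean_trial(n_strides = 5, seed = 222)
  feats <- extract_features(held_out)
  r <- rle(held_out$label)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (f in walking_flags()) {
    runs <- which(r$values == f & r$lengths >= 10)
    run <- runs[length(runs) %/% 2 + 1]  # a mid-trial occurrence
    i <- starts[run] + (r$lengths[run] %/% 2)
    win <- feats[(i - 9):i, , drop = FALSE]
    expect_identical(classify_window(win, bank), f,
                     label = paste("phase", f))
  }
})

test_that("exact likelihood ties break by ascending flag order", {
  bank <- bank_fixture$bank
  m <- bank$models[["13"]]
  tied <- bank
  tied$models <- stats::setNames(
    lapply(c(11L, 12L, 13L, 14L), function(f) { m$phase <- f; m }),
    c("11", "12", "13", "14"))
  win <- matrix(rnorm(100), 10, 10,
                dimnames = list(NULL, bank$features))
  expect_identical(classify_window(win, tied), 11L)
})

test_that("classification is invariant to affine feature rescaling", {
  bank <- bank_fixture$bank
  a <- runif(10, 0.5, 4)
  b <- rnorm(10, 0, 20)
  bank2 <- bank
  bank2$center <- bank$center * a + b
  bank2$scale <- bank$scale * a
  tr <- clean_trial(n_strides = 4, seed = 333)
  feats <- extract_features(tr)
  feats2 <- sweep(sweep(feats, 2, a, "*"), 2, b, "+")
  for (i in seq(20, nrow(feats), by = 97)) {
    w <- (i - 9):i
    expect_identical(classify_window(feats[w, ], bank),
                     classify_window(feats2[w, ], bank2))
  }
})

test_that("HMM trial detection is causal and pads the first window", {
  bank <- bank_fixture$bank
  tr <- clean_trial(n_strides = 3, seed = 55)
  fl <- detect_trial_hmm(tr, bank)
  expect_identical(length(fl), nrow(tr))
  expect_identical(fl[1:9], rep(0L, 9))
  expect_true(all(fl[-(1:9)] %in% walking_flags()))
  k <- 500
  expect_identical(detect_trial_hmm(tr[seq_len(k), ], bank), fl[seq_len(k)])
  expect_identical(detect_trial_hmm(tr[0, ], bank), integer(0))
})

test_that("the model bank serialises to JSON and back without loss", {
  bank <- bank_fixture$bank
  path <- withr::local_tempfile(fileext = ".json")
  write_hmm_bank(bank, path)
  b2 <- read_hmm_bank(path)
  expect_identical(names(b2$models), names(bank$models))
  win <- extract_features(clean_trial(n_strides = 2, seed = 5))[31:40, ]
  expect_identical(classify_window(win, bank), classify_window(win, b2))
  for (f in names(bank$models)) {
    expect_equal(b2$models[[f]]$trans, bank$models[[f]]$trans)
    expect_equal(b2$models[[f]]$means, bank$models[[f]]$means)
  }
})

test_that("training-set construction honours the three schemes", {
  trials <- as.list(1:9)  # placeholders; splitting only uses the ids
  ids <- rep(c("A", "B", "C"), each = 3)
  for (scheme in c("intra", "inter", "pooled")) {
    sp <- build_training_sets(trials, ids, scheme = scheme, n_train = 2)
    expect_identical(vapply(sp, `[[`, "", "subject"), c("A", "B", "C"))
    for (s in sp) {
      expect_identical(length(intersect(s$train, s$test)), 0L)
      expect_true(all(ids[s$test] == s$subject))
    }
  }
  inter <- build_training_sets(trials, ids, scheme = "inter", n_train = 2)
  expect_false("A" %in% ids[inter[[1]]$train])
  expect_identical(sort(unique(ids[inter[[1]]$train])), c("B", "C"))
  pooled <- build_training_sets(trials, ids, scheme = "pooled", n_train = 2)
  expect_identical(sort(unique(ids[pooled[[1]]$train])), c("A", "B", "C"))
  expect_error(build_training_sets(trials, ids, "intra", n_train = 3),
               "needs more than")
  expect_error(build_training_sets(trials[1:3], ids[1:3], "inter"),
               "two subjects")
})
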