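# Independent oracles, written as plain re-implementations of the documented
# definitions. They deliberately share no code with the package internals.

# mean |grfL - grfR| over the most recent min(window, n) samples, by loop
oracle_grf_diff <- function(grfL, grfR, window = 50) {
  n <- length(grfL)
  k <- min(window, n)
  acc <- 0
  for (i in (n - k + 1):n) acc <- acc + abs(grfL[i] - grfR[i])
  acc / k
}

# The condition table, row by row, coded directly from its published form
# (with the two typo corrections). `sig` is a list of scalar signals; COP
# may be NA (comparison false). Returns the set of firing flags.
oracle_rule_flags <- function(sig, th) {
  flags <- integer(0)
  cop_ok <- function(x, op, thr) !is.na(x) && op(x, thr)
  # quiet standing from initiation (b)
  if (sig$grfDiff < th[["init2"]] && sig$sumAng < th[["sumQS"]]) {
    flags <- c(flags, 5L)
  }
  # quiet standing from termination (j)
  if (sig$grfDiff < th[["init2"]] && sig$sumAng < th[["sumQS"]] &&
      abs(sig$gyroL) < th[["minG"]] && abs(sig$gyroR) < th[["minG"]]) {
    flags <- c(flags, 5L)
  }
  # initiation (a)
  if (sig$grfDiff > th[["init1"]] &&
      (sig$grfL < th[["QSgrf"]] || sig$grfR < th[["QSgrf"]]) &&
      sig$sumAng > th[["sumAngInit"]]) {
    flags <- c(flags, 6L)
  }
  # termination (h, i)
  if (sig$grfDiff < th[["init1"]] && sig$grfL > th[["QSgrf"]] &&
      sig$grfR > th[["QSgrf"]] && sig$sumAng < th[["sumAngTerm"]] &&
      abs(sig$gyroL) < th[["termG"]] && abs(sig$gyroR) < th[["termG"]]) {
    flags <- c(flags, 4L)
  }
  # left stance (c, d)
  if (sig$grfDiff > th[["init1"]] && sig$sumAng > th[["sumAngInit"]] &&
      sig$grfL > th[["stanceL"]] && sig$grfR < th[["stanceR"]]) {
    flags <- c(flags, 11L)
  }
  # left-right double stance (e)
  if (sig$grfR > th[["stanceR"]] && sig$grfL > th[["stanceL"]] &&
      cop_ok(sig$copyL, `<`, th[["midCOP"]]) &&
      cop_ok(sig$copyR, `>`, th[["toeCOP"]]) &&
      sig$sumAng > th[["minAng"]]) {
    flags <- c(flags, 12L)
  }
  # right stance (c, f)
  if (sig$grfDiff > th[["init1"]] && sig$sumAng > th[["sumAngInit"]] &&
      sig$grfL < th[["stanceL"]] && sig$grfR > th[["stanceR"]]) {
    flags <- c(flags, 13L)
  }
  # right-left double stance (g); flexion condition mirrors the L-R row
  if (sig$grfR > th[["stanceR"]] && sig$grfL > th[["stanceL"]] &&
      cop_ok(sig$copyL, `>`, th[["toeCOP"]]) &&
      cop_ok(sig$copyR, `<`, th[["midCOP"]]) &&
      sig$sumAng > th[["minAng"]]) {
    flags <- c(flags, 14L)
  }
  sort(unique(flags))
}

# Random sensor frame spanning realistic and edge-case signal values, as a
# one-row trial data.frame plus the signal list the oracle consumes.
random_frame <- function(W = 600, L = 260) {
  grfL <- sample(c(0, runif(1, 0, 1.3 * W)), 1)
  grfR <- sample(c(0, runif(1, 0, 1.3 * W)), 1)
  copyL <- if (grfL < 5 || runif(1) < 0.2) NA_real_ else runif(1, 0, L)
  copyR <- if (grfR < 5 || runif(1) < 0.2) NA_real_ else runif(1, 0, L)
  sumAng <- runif(1, -5, 90)
  gyroL <- runif(1, -4, 4)
  gyroR <- runif(1, -4, 4)
  grfDiff <- runif(1, 0, W)
  frame <- data.frame(t = 0, grfL = grfL, grfR = grfR,
                      copyL = copyL, copyR = copyR,
                      hipL = sumAng / 4, hipR = sumAng / 4,
                      kneeL = sumAng / 4, kneeR = sumAng / 4,
                      gyroL = gyroL, gyroR = gyroR)
  list(frame = frame,
       sig = list(grfL = grfL, grfR = grfR, copyL = copyL, copyR = copyR,
                  sumAng = sumAng, gyroL = gyroL, gyroR = gyroR,
                  grfDiff = grfDiff))
}

# Exhaustive-path log-likelihood of an observation sequence under a
# diagonal-Gaussian HMM: direct summation over all k^T hidden paths.
oracle_enum_loglik <- function(init, trans, means, vars, obs) {
  k <- length(init)
  Tn <- nrow(obs)
  dens <- function(x, j) prod(stats::dnorm(x, means[j, ], sqrt(vars[j, ])))
  paths <- as.matrix(expand.grid(rep(list(seq_len(k)), Tn)))
  total <- 0
  for (r in seq_len(nrow(paths))) {
    p <- paths[r, ]
    pr <- init[p[1]] * dens(obs[1, ], p[1])
    if (Tn > 1) for (tt in 2:Tn) {
      pr <- pr * trans[p[tt - 1], p[tt]] * dens(obs[tt, ], p[tt])
    }
    total <- total + pr
  }
  log(total)
}

# Independent success-ratio matcher: plain RLE over walking flags (no
# debounce), overlap + cyclic-neighbour consistency with one allowed skip.
oracle_success_counts <- function(detected, truth) {
  walking <- c(11L, 12L, 13L, 14L)
  segs <- function(x) {
    x <- ifelse(x %in% walking, x, NA_integer_)
    out <- list()
    i <- 1
    n <- length(x)
    while (i <= n) {
      if (is.na(x[i])) { i <- i + 1; next }
      j <- i
      while (j < n && !is.na(x[j + 1]) && x[j + 1] == x[i]) j <- j + 1
      out[[length(out) + 1]] <- c(flag = x[i], start = i, end = j + 1)
      i <- j + 1
    }
    if (length(out)) do.call(rbind, out) else
      matrix(integer(0), 0, 3, dimnames = list(NULL, c("flag", "start", "end")))
  }
  step_fwd <- function(a, b) (match(b, walking) - match(a, walking)) %% 4
  det <- segs(detected)
  tru <- segs(truth)
  consistent <- function(j) {
    if (j > 1) {
      s <- step_fwd(det[j - 1, "flag"], det[j, "flag"])
      if (!(s %in% c(1, 2))) return(FALSE)
    }
    if (j < nrow(det)) {
      s <- step_fwd(det[j, "flag"], det[j + 1, "flag"])
      if (!(s %in% c(1, 2))) return(FALSE)
    }
    TRUE
  }
  n_true <- n_correct <- stats::setNames(integer(4), walking)
  for (i in seq_len(nrow(tru))) {
    f <- as.character(tru[i, "flag"])
    n_true[f] <- n_true[f] + 1L
    hit <- FALSE
    for (j in seq_len(nrow(det))) {
      if (det[j, "flag"] == tru[i, "flag"] &&
          det[j, "start"] < tru[i, "end"] &&
          det[j, "end"] > tru[i, "start"] && consistent(j)) {
        hit <- TRUE
        break
      }
    }
    if (hit) n_correct[f] <- n_correct[f] + 1L
  }
  list(n_true = n_true, n_correct = n_correct)
}

# shared fixtures (built once per test run)
TH600 <- default_thresholds(600)
clean_trial <- function(n_strides = 6, seed = 11, ...) {
  simulate_trial(gait_params(n_strides = n_strides, seed = seed, ...))
}
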