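# Transition-rule table. Each row is a conjunction of threshold comparisons
# on one sensor frame plus the windowed GRF asymmetry (grfDiff). Two
# documented typo corrections relative to the published condition table are
# applied: the initiation unload condition reads (grfL < QSgrf) OR
# (grfR < QSgrf) (the prose lists grfL twice), and the right-left
# double-stance flexion condition reads (sumAng > minAng), mirroring the
# left-right row ("midAng" appears in no threshold table and is treated as a
# typo for minAng).
#
# COP comparisons are defined false when the unloaded sentinel (NA) is
# present.
RULE_ROWS <- data.frame(
  row = c("qs_from_init", "qs_from_term", "initiation", "termination",
          "left_stance", "lr_double", "right_stance", "rl_double"),
  flag = c(5L, 5L, 6L, 4L, 11L, 12L, 13L, 14L),
  designator = c("b", "j", "a", "h/i", "c/d", "e", "c/f", "g"),
  stringsAsFactors = FALSE
)

# Source states from which each rule row is a legal transition in the state
# diagram (used by strict mode; free mode ignores this).
RULE_FROM <- list(
  qs_from_init = 6L,
  qs_from_term = 4L,
  initiation   = 5L,
  termination  = c(12L, 14L),
  left_stance  = c(6L, 14L),
  lr_double    = 11L,
  right_stance = c(6L, 12L),
  rl_double    = 13L
)

# Tie-break priority when several rows fire on the same sample: double
# stance over single stance (double-stance conditions are strict supersets
# of the foot-contact conditions and would otherwise be unreachable), then
# initiation, then quiet standing, then termination. Quiet standing is
# ordered above termination because a subject standing relaxed with both
# feet loaded above QSgrf satisfies the termination row and both
# quiet-standing rows simultaneously and indefinitely; the reverse order
# would make quiet standing unreachable in free mode. Quiet standing and
# initiation are mutually exclusive (init2 <= init1).
RULE_PRIORITY <- c("lr_double", "rl_double", "left_stance", "right_stance",
                   "initiation", "qs_from_init", "qs_from_term",
                   "termination")

# Vectorised evaluation of all eight rule rows. Arguments are equal-length
# numeric vectors; returns an n x 8 logical matrix (columns in RULE_ROWS
# order). NA COP comparisons evaluate to FALSE.
eval_rule_matrix <- function(grfL, grfR, copyL, copyR, sumAng,
                             gyroL, gyroR, grfDiff, th) {
  lt <- function(x, t) !is.na(x) & x < t
  gt <- function(x, t) !is.na(x) & x > t
  cbind(
    qs_from_init = grfDiff < th["init2"] & sumAng < th["sumQS"],
    qs_from_term = grfDiff < th["init2"] & sumAng < th["sumQS"] &
      abs(gyroL) < th["minG"] & abs(gyroR) < th["minG"],
    initiation = grfDiff > th["init1"] &
      (grfL < th["QSgrf"] | grfR < th["QSgrf"]) &
      sumAng > th["sumAngInit"],
    termination = grfDiff < th["init1"] & grfL > th["QSgrf"] &
      grfR > th["QSgrf"] & sumAng < th["sumAngTerm"] &
      abs(gyroL) < th["termG"] & abs(gyroR) < th["termG"],
    left_stance = grfDiff > th["init1"] & sumAng > th["sumAngInit"] &
      grfL > th["stanceL"] & grfR < th["stanceR"],
    lr_double = grfL > th["stanceL"] & grfR > th["stanceR"] &
      lt(copyL, th["midCOP"]) & gt(copyR, th["toeCOP"]) &
      sumAng > th["minAng"],
    right_stance = grfDiff > th["init1"] & sumAng > th["sumAngInit"] &
      grfL < th["stanceL"] & grfR > th["stanceR"],
    rl_double = grfL > th["stanceL"] & grfR > th["stanceR"] &
      gt(copyL, th["toeCOP"]) & lt(copyR, th["midCOP"]) &
      sumAng > th["minAng"]
  )
}

frame_signals <- function(frame) {
  list(grfL = frame$grfL, grfR = frame$grfR,
       copyL = frame$copyL, copyR = frame$copyR,
       sumAng = sum_ang(frame$hipL, frame$hipR, frame$kneeL, frame$kneeR),
       gyroL = frame$gyroL, gyroR = frame$gyroR)
}

#' Evaluate the transition-rule table on one frame
#'
#' Returns the set of phase flags whose full conjunctive condition row is
#' satisfied by the given frame and derived signals. This is the stateless
#' layer of the detector; [detector_step()] adds retention and tie-breaking.
#'
#' @param frame a one-row trial data.frame (see [gait_trial()]).
#' @param grfDiff windowed GRF asymmetry for this frame in N (see
#'   [grf_diff()]).
#' @param th a [threshold_set()].
#' @return sorted integer vector of distinct firing flags (possibly empty).
#' @examples
#' th <- default_thresholds(600)
#' eval_rows(make_snapshot(11, th), grfDiff = 108, th = th)
#' @export
eval_rows <- function(frame, grfDiff, th) {
  stopifnot(inherits(th, "threshold_set"), nrow(frame) == 1L)
  s <- frame_signals(frame)
  fired <- eval_rule_matrix(s$grfL, s$grfR, s$copyL, s$copyR, s$sumAng,
                            s$gyroL, s$gyroR, grfDiff, th)[1L, ]
  sort(unique(RULE_ROWS$flag[fired]))
}

# Pick the output flag for one sample given the fired rows, the previous
# flag and the mode. `fired` is a named logical 8-vector.
arbitrate <- function(fired, current, mode) {
  order <- RULE_PRIORITY
  if (mode == "strict" && current != FLAG_UNKNOWN) {
    legal <- vapply(order, function(r) {
      RULE_ROWS$flag[RULE_ROWS$row == r] == current ||
        current %in% RULE_FROM[[r]]
    }, logical(1L))
    order <- order[legal]
  }
  for (r in order) {
    if (fired[[r]]) return(RULE_ROWS$flag[RULE_ROWS$row == r])
  }
  current
}

#' Online detector state
#'
#' Creates the streaming state for sample-by-sample detection with
#' [detector_step()]. The state holds the current flag and the bounded
#' (50-sample) GRF history buffers from which the windowed asymmetry is
#' recomputed every sample.
#'
#' In `free` mode (the default, matching a detector that is not restricted
#' to the gait-cycle series) any firing rule row may set the flag, chosen by
#' a fixed priority when several fire; when no row fires the previous flag
#' is retained. In `strict` mode only rows that constitute a legal
#' transition from the current state in the state diagram are accepted,
#' emulating a finite-state prosthesis controller that pauses until an
#' allowed transition arrives.
#'
#' @param th a [threshold_set()].
#' @param mode `"free"` or `"strict"`.
#' @param current initial flag (default `UNKNOWN`, i.e. unclassified).
#' @param window asymmetry window length in samples.
#' @return an object of class `gait_detector`.
#' @seealso [detect_trial()] for whole-trial application.
#' @export
new_detector <- function(th, mode = c("free", "strict"),
                         current = 0L, window = 50L) {
  mode <- match.arg(mode)
  stopifnot(inherits(th, "threshold_set"), current %in% phase_flags())
  structure(list(th = th, mode = mode, current = as.integer(current),
                 window = as.integer(window),
                 bufL = numeric(0), bufR = numeric(0)),
            class = "gait_detector")
}

#' Advance the detector by one sensor frame
#'
#' @param det a [new_detector()] state.
#' @param frame a one-row trial data.frame.
#' @return list with elements `flag` (the emitted phase flag) and `detector`
#'   (the updated state to pass to the next call).
#' @export
detector_step <- function(det, frame) {
  stopifnot(inherits(det, "gait_detector"), nrow(frame) == 1L)
  det$bufL <- c(det$bufL, frame$grfL)
  det$bufR <- c(det$bufR, frame$grfR)
  if (length(det$bufL) > det$window) {
    keep <- seq.int(length(det$bufL) - det$window + 1L, length(det$bufL))
    det$bufL <- det$bufL[keep]
    det$bufR <- det$bufR[keep]
  }
  gd <- grf_diff(det$bufL, det$bufR, det$window)
  s <- frame_signals(frame)
  fired <- eval_rule_matrix(s$grfL, s$grfR, s$copyL, s$copyR, s$sumAng,
                            s$gyroL, s$gyroR, gd, det$th)[1L, ]
  det$current <- arbitrate(as.list(fired), det$current, det$mode)
  list(flag = det$current, detector = det)
}

#' Detect phases over a whole trial
#'
#' Applies the rule-based detector to every frame in order. The computation
#' is causal: the flag at sample `i` depends only on frames `1..i`, and the
#' output is identical whether frames are fed one by one through
#' [detector_step()] or as a batch.
#'
#' @param trial a [gait_trial()] (or conforming data.frame).
#' @param th a [threshold_set()].
#' @param mode `"free"` or `"strict"` (see [new_detector()]).
#' @param window asymmetry window length in samples.
#' @return integer vector of phase flags, one per frame (empty input gives
#'   empty output).
#' @examples
#' trial <- simulate_trial(gait_params(n_strides = 3, seed = 1))
#' flags <- detect_trial(trial, default_thresholds(600))
#' table(flags)
#' @export
detect_trial <- function(trial, th, mode = c("free", "strict"),
                         window = 50L) {
  mode <- match.arg(mode)
  stopifnot(inherits(th, "threshold_set"))
  validate_trial(trial)
  n <- nrow(trial)
  if (n == 0L) return(integer(0))
  gd <- rolling_grf_diff(trial$grfL, trial$grfR, window)
  sumAng <- sum_ang(trial$hipL, trial$hipR, trial$kneeL, trial$kneeR)
  fired <- eval_rule_matrix(trial$grfL, trial$grfR, trial$copyL, trial$copyR,
                            sumAng, trial$gyroL, trial$gyroR, gd, th)
  flags <- integer(n)
  current <- FLAG_UNKNOWN
  row_flags <- RULE_ROWS$flag[match(RULE_PRIORITY, RULE_ROWS$row)]
  fired <- fired[, RULE_PRIORITY, drop = FALSE]
  if (mode == "free") {
    # fast path: first fired row in priority order, else retain
    hit <- apply(fired, 1L, function(f) {
      w <- which(f)
      if (length(w)) w[1L] else 0L
    })
    for (i in seq_len(n)) {
      if (hit[i] > 0L) current <- row_flags[hit[i]]
      flags[i] <- current
    }
  } else {
    for (i in seq_len(n)) {
      f <- as.list(fired[i, ])
      names(f) <- RULE_PRIORITY
      current <- arbitrate(f, current, "strict")
      flags[i] <- current
    }
  }
  flags
}

#' Construct a frame that satisfies one rule row
#'
#' Builds a single synthetic sensor frame (plus the implied single-sample
#' GRF asymmetry) for which the targeted condition row fires, every
#' comparison in the row cleared by the stated relative margin. Signals not
#' constrained by the row are set so that rows of equal or higher priority
#' do not fire accidentally, where that is logically possible (the
#' single-stance rows, for instance, necessarily imply the initiation row,
#' which is resolved by priority). Useful for worked examples and for
#' stress-testing thresholds.
#'
#' @param target the flag of the targeted row (4, 5, 6, 11, 12, 13 or 14;
#'   5 builds a frame satisfying both quiet-standing rows).
#' @param th a [threshold_set()].
#' @param margin relative clearing margin for each comparison (fraction).
#' @param body_scale reference force (N) used for loaded, unconstrained GRFs.
#' @return a one-row data.frame in the trial schema, with attribute
#'   `"target"` set to the targeted flag. Feeding it to a fresh detector
#'   (empty history, so `grfDiff = |grfL - grfR|`) emits the target flag.
#' @examples
#' th <- default_thresholds(600)
#' fr <- make_snapshot(12, th)
#' eval_rows(fr, grfDiff = abs(fr$grfL - fr$grfR), th = th)
#' @export
make_snapshot <- function(target, th, margin = 0.2, body_scale = 600) {
  stopifnot(inherits(th, "threshold_set"), margin > 0, margin < 1)
  target <- as.integer(target)
  if (!target %in% c(4L, 5L, 6L, WALKING)) {
    stop("target must be one of the flags 4, 5, 6, 11, 12, 13, 14")
  }
  up <- 1 + margin
  dn <- 1 - margin
  # defaults: quiet midfoot-loaded standing-ish frame, overridden per target
  grfL <- grfR <- NA_real_
  copyL <- copyR <- NA_real_
  gyroL <- gyroR <- 0
  sumAng <- 0
  mid_between <- function(a, b) (a + b) / 2  # used when margins conflict
  if (target == FLAG_LEFT || target == FLAG_RIGHT) {
    lo <- th[["stanceR"]] * dn          # unloaded foot, below stance threshold
    hi <- max(th[["stanceL"]] * up, lo + th[["init1"]] * up)
    sumAng <- th[["sumAngInit"]] * up
    if (target == FLAG_LEFT) {
      grfL <- hi; grfR <- th[["stanceR"]] * dn
      copyL <- mid_between(th[["toeCOP"]], th[["midCOP"]])
      gyroR <- 1  # swinging foot
    } else {
      grfR <- max(th[["stanceR"]] * up, th[["stanceL"]] * dn + th[["init1"]] * up)
      grfL <- th[["stanceL"]] * dn
      copyR <- mid_between(th[["toeCOP"]], th[["midCOP"]])
      gyroL <- 1
    }
  } else if (target == FLAG_LR || target == FLAG_RL) {
    grfL <- th[["stanceL"]] * up
    grfR <- th[["stanceR"]] * up
    # keep sumAng above sumQS too so the quiet-standing rows stay silent
    sumAng <- max(th[["minAng"]], th[["sumQS"]]) * up
    if (target == FLAG_LR) {
      copyL <- th[["toeCOP"]] * dn   # trailing left foot on its toes
      copyR <- th[["midCOP"]] * up   # leading right foot behind midline
    } else {
      copyL <- th[["midCOP"]] * up
      copyR <- th[["toeCOP"]] * dn
    }
  } else if (target == FLAG_INITIATION) {
    grfL <- th[["QSgrf"]] * dn
    grfR <- grfL + th[["init1"]] * up
    sumAng <- th[["sumAngInit"]] * up
    copyL <- copyR <- th[["midCOP"]] * up  # heel-ward: silences both DS rows
    gyroL <- 0.5
  } else if (target == FLAG_TERMINATION) {
    grfL <- grfR <- th[["QSgrf"]] * up
    # sumAng must sit between sumQS and sumAngTerm (quiet standing is higher
    # priority); fall back to the midpoint when the margins cannot both hold
    sumAng <- th[["sumAngTerm"]] * dn
    if (sumAng <= th[["sumQS"]] * up) {
      sumAng <- mid_between(th[["sumQS"]], th[["sumAngTerm"]])
    }
    if (sumAng <= th[["sumQS"]] || sumAng >= th[["sumAngTerm"]]) {
      stop("termination snapshot impossible: sumQS and sumAngTerm leave no gap")
    }
    copyL <- copyR <- th[["midCOP"]] * up
    # feet still (below termG) but not below minG, silencing the
    # quiet-standing-from-termination row when minG < termG
    g <- if (th[["minG"]] < th[["termG"]]) {
      mid_between(th[["minG"]], th[["termG"]])
    } else {
      th[["termG"]] * dn
    }
    gyroL <- gyroR <- g
  } else { # quiet standing: both rows
    grfL <- grfR <- th[["QSgrf"]] * dn   # below QSgrf silences termination
    sumAng <- th[["sumQS"]] * dn
    copyL <- copyR <- th[["midCOP"]] * up
    gyroL <- gyroR <- th[["minG"]] * dn
  }
  if (!is.na(grfL) && grfL < CONTACT_EPS) copyL <- NA_real_
  if (!is.na(grfR) && grfR < CONTACT_EPS) copyR <- NA_real_
  frame <- data.frame(t = 0, grfL = grfL, grfR = grfR,
                      copyL = copyL, copyR = copyR,
                      hipL = sumAng / 4, hipR = sumAng / 4,
                      kneeL = sumAng / 4, kneeR = sumAng / 4,
                      gyroL = gyroL, gyroR = gyroR)
  attr(frame, "target") <- target
  frame
}

#' @export
print.gait_detector <- function(x, ...) {
  cat(sprintf("<gait_detector> mode=%s current=%d (%d buffered samples)\n",
              x$mode, x$current, length(x$bufL)))
  invisible(x)
}
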