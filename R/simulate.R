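#' Parameters of the synthetic gait generator
#'
#' Describes one simulated walking trial: quiet standing, gait initiation,
#' `n_strides` steady-state strides, termination and quiet standing again,
#' sampled at 100 Hz. Waveform morphology follows the characteristic shapes
#' of insole/IMU walking data: a double-bump stance GRF (two lobes peaking
#' near `grf_peak` times body weight with a mid-stance valley near
#' `grf_valley`), a heel-to-toe COP progression, a summed-flexion signal
#' oscillating between a double-stance trough and a mid-swing peak, and
#' biphasic swing-phase gyro bursts. The left leg swings first, so each
#' stride cycles right stance (13), right-left double stance (14), left
#' stance (11), left-right double stance (12).
#'
#' A prosthetic side scales that leg's GRF amplitude by `asym_amp` and its
#' stance time by `asym_time` (mild, so the shortened double stance remains
#' resolvable at 100 Hz).
#'
#' @param body_weight body weight W in N.
#' @param stride_period stride duration in s (1 stride per second at normal
#'   speed).
#' @param n_strides number of steady-state strides.
#' @param stance_fraction fraction of the stride each foot is on the ground
#'   (duty factor, in (0.5, 0.95)); each double-stance fraction is
#'   `stance_fraction - 0.5`.
#' @param insole_length insole length L in mm.
#' @param prosthetic_side `"none"`, `"left"` or `"right"`.
#' @param asym_amp GRF amplitude scale of the prosthetic leg.
#' @param asym_time stance-time scale of the prosthetic leg.
#' @param sigma_grf,sigma_cop,sigma_ang,sigma_gyro additive Gaussian noise
#'   s.d. per channel (N, mm, deg on the summed angle, rad/s).
#' @param stand_before,stand_after quiet-standing durations (s).
#' @param init_duration,term_duration initiation/termination durations (s).
#' @param grf_peak,grf_valley stance GRF peak and valley, relative to W.
#' @param cop_heel,cop_toe COP at foot strike and toe off, relative to L.
#' @param sumang_peak,sumang_trough summed-flexion extremes (deg).
#' @param sumang_stand,sumang_settle summed flexion in quiet standing and at
#'   the end of termination (deg).
#' @param gyro_peak swing gyro amplitude (rad/s).
#' @param seed RNG seed for the noise (NULL leaves the RNG state alone).
#' @return an object of class `gait_params`.
#' @seealso [simulate_trial()]
#' @export
gait_params <- function(body_weight = 600, stride_period = 1.0,
                        n_strides = 10L, stance_fraction = 0.62,
                        insole_length = 260, prosthetic_side = "none",
                        asym_amp = 0.9, asym_time = 0.95,
                        sigma_grf = 0, sigma_cop = 0, sigma_ang = 0,
                        sigma_gyro = 0,
                        stand_before = 3, stand_after = 3,
                        init_duration = 0.8, term_duration = 1.2,
                        grf_peak = 1.1, grf_valley = 0.8,
                        cop_heel = 0.85, cop_toe = 0.10,
                        sumang_peak = 70, sumang_trough = 5,
                        sumang_stand = 2, sumang_settle = 17,
                        gyro_peak = 3, seed = NULL) {
  p <- as.list(environment())
  if (!prosthetic_side %in% c("none", "left", "right")) {
    stop("prosthetic_side must be none, left or right")
  }
  stopifnot(body_weight > 0, stride_period > 0, n_strides >= 1,
            insole_length > 0, asym_amp > 0, asym_amp <= 1,
            asym_time > 0, asym_time <= 1,
            sigma_grf >= 0, sigma_cop >= 0, sigma_ang >= 0, sigma_gyro >= 0,
            stand_before >= 1, stand_after >= 1,
            init_duration > 0, term_duration > 0)
  if (stance_fraction <= 0.5 || stance_fraction >= 0.95) {
    stop("stance_fraction must lie in (0.5, 0.95)")
  }
  ds <- stance_fraction - 0.5
  if (2 * ds >= stance_fraction) stop("double stance too long for the stance")
  f_pros <- stance_fraction * asym_time
  if (prosthetic_side != "none" && f_pros <= 0.51) {
    stop("prosthetic-side stance fraction too short (asym_time too small)")
  }
  structure(p, class = "gait_params")
}

# stance GRF shape: sine lobe with a Gaussian mid-stance dip; zero at both
# stance edges, two bumps with a valley near grf_valley/grf_peak of the peak
grf_shape <- function(p) {
  sin(pi * p) * (1 - 0.42 * exp(-((p - 0.5) / 0.17)^2))
}
GRF_SHAPE_MAX <- max(grf_shape(seq(0, 1, by = 1e-4)))

cop_shape <- function(p, heel, toe) heel + (toe - heel) * p

cos_blend <- function(tau) (1 - cos(pi * pmin(pmax(tau, 0), 1))) / 2

#' Simulate a labelled walking trial
#'
#' Generates a 100 Hz [gait_trial()] with per-sample ground-truth phase
#' labels assigned analytically from the phase schedule: quiet standing (5),
#' initiation (6), `n_strides` cycles of 13-14-11-12, termination (4) and
#' quiet standing again. The same seed reproduces the trial exactly.
#'
#' @param params a [gait_params()] object.
#' @return a labelled [gait_trial()].
#' @examples
#' trial <- simulate_trial(gait_params(n_strides = 5, seed = 42))
#' table(trial$label)
#' @export
simulate_trial <- function(params) {
  stopifnot(inherits(params, "gait_params"))
  q <- params
  if (!is.null(q$seed)) set.seed(q$seed)
  dt <- 0.01
  W <- q$body_weight
  L <- q$insole_length
  Tp <- q$stride_period
  n_str <- as.integer(q$n_strides)
  fL <- q$stance_fraction
  fR <- q$stance_fraction
  ampL <- ampR <- 1
  if (q$prosthetic_side == "left") {
    fL <- fL * q$asym_time; ampL <- q$asym_amp
  } else if (q$prosthetic_side == "right") {
    fR <- fR * q$asym_time; ampR <- q$asym_amp
  }
  d13 <- (1 - fL) * Tp         # right single stance (left swing)
  d14 <- (fR - 0.5) * Tp       # right-left double stance
  d11 <- (1 - fR) * Tp         # left single stance (right swing)
  d12 <- (fL - 0.5) * Tp       # left-right double stance
  t_i0 <- q$stand_before                 # initiation start
  t_w <- t_i0 + q$init_duration          # walking start (left toe off)
  t_e <- t_w + n_str * Tp                 # walking end (termination start)
  t_t1 <- t_e + q$term_duration          # termination end
  t_end <- t_t1 + q$stand_after
  n <- floor(t_end / dt) + 1L
  t <- (seq_len(n) - 1L) * dt

  scale_grf <- function(amp) q$grf_peak * W * amp / GRF_SHAPE_MAX

  # ---- phase schedule & labels -------------------------------------------
  cyc0 <- t_w + (seq_len(n_str) - 1L) * Tp
  cyc_bounds <- cumsum(c(d13, d14, d11, d12))  # ends of 13, 14, 11, 12
  bounds <- c(0, t_i0, t_w,
              as.vector(t(outer(cyc0, cyc_bounds, `+`))),
              t_t1)
  lab_seq <- c(5L, 6L, rep(c(13L, 14L, 11L, 12L), n_str), 4L, 5L)
  labels <- lab_seq[findInterval(t, bounds)]

  # ---- per-foot GRF and COP ----------------------------------------------
  # stance intervals: list of (start, duration of full stance, amp)
  left_stances <- lapply(seq_len(n_str) - 1L, function(k) {
    list(start = t_w + k * Tp + d13, dur = fL * Tp)
  })
  right_land0 <- t_w - d12               # virtual start of the first stance
  right_stances <- c(
    list(list(start = right_land0, dur = fR * Tp)),
    lapply(seq_len(n_str) - 1L, function(k) {
      list(start = t_w + k * Tp + d13 + d14 + d11, dur = fR * Tp)
    })
  )

  foot_grf_cop <- function(stances, amp, contact0_end, swing_int) {
    grf <- rep(W / 2, n)
    cop <- rep(0.5 * L, n)
    sc <- scale_grf(amp)
    # walking stance waveforms (clipped to [t_w, t_e])
    for (s in stances) {
      i <- which(t >= max(s$start, t_w) & t < min(s$start + s$dur, t_e))
      if (!length(i)) next
      p <- (t[i] - s$start) / s$dur
      grf[i] <- sc * grf_shape(p)
      cop[i] <- L * cop_shape(p, q$cop_heel, q$cop_toe)
    }
    # swings: foot in the air
    for (s in swing_int) {
      i <- which(t >= s[1] & t < s[2])
      grf[i] <- 0
      cop[i] <- NA_real_
    }
    # initiation blend from standing to the walking value at t_w
    i <- which(t >= t_i0 & t < t_w)
    b <- cos_blend((t[i] - t_i0) / q$init_duration)
    gw <- if (is.na(contact0_end)) 0 else {
      s <- stances[[1L]]
      sc * grf_shape((t_w - s$start) / s$dur)
    }
    cw <- if (is.na(contact0_end)) q$cop_toe * L else {
      s <- stances[[1L]]
      L * cop_shape((t_w - s$start) / s$dur, q$cop_heel, q$cop_toe)
    }
    grf[i] <- W / 2 * (1 - b) + gw * b
    cop[i] <- 0.5 * L * (1 - b) + cw * b
    # termination blend from the walking value at t_e back to standing
    s_last <- stances[[length(stances)]]
    p_e <- (t_e - s_last$start) / s_last$dur
    g_e <- sc * grf_shape(p_e)
    c_e <- L * cop_shape(p_e, q$cop_heel, q$cop_toe)
    i <- which(t >= t_e & t < t_t1)
    b <- cos_blend((t[i] - t_e) / q$term_duration)
    grf[i] <- g_e * (1 - b) + W / 2 * b
    cop[i] <- c_e * (1 - b) + 0.5 * L * b
    list(grf = grf, cop = cop)
  }

  left_swings <- lapply(seq_len(n_str) - 1L, function(k) {
    c(t_w + k * Tp, t_w + k * Tp + d13)
  })
  right_swings <- lapply(seq_len(n_str) - 1L, function(k) {
    c(t_w + k * Tp + d13 + d14, t_w + k * Tp + d13 + d14 + d11)
  })

  lf <- foot_grf_cop(left_stances, ampL, NA, left_swings)
  # the left foot lifts at t_w: its initiation blend goes to zero load
  rf <- foot_grf_cop(right_stances, ampR, 0, right_swings)

  # ---- summed flexion -----------------------------------------------------
  ds_mids <- c(cyc0 + d13 + d14 / 2, cyc0 + d13 + d14 + d11 + d12 / 2)
  ds_halfw <- rep(c(d14 / 2, d12 / 2) * 0.85, each = n_str)
  walk_sumang <- function(tt) {
    dips <- vapply(seq_along(ds_mids), function(j) {
      exp(-((tt - ds_mids[j]) / ds_halfw[j])^2)
    }, numeric(length(tt)))
    dip <- if (is.matrix(dips)) apply(dips, 1L, max) else max(dips)
    q$sumang_peak - (q$sumang_peak - q$sumang_trough) * dip
  }
  sumang <- rep(q$sumang_stand, n)
  i <- which(t >= t_w & t < t_e)
  sumang[i] <- walk_sumang(t[i])
  i <- which(t >= t_i0 & t < t_w)
  b <- cos_blend((t[i] - t_i0) / q$init_duration)
  sumang[i] <- q$sumang_stand * (1 - b) + walk_sumang(t_w) * b
  i <- which(t >= t_e & t < t_t1)
  b <- cos_blend((t[i] - t_e) / q$term_duration)
  sumang[i] <- walk_sumang(t_e) * (1 - b) + q$sumang_settle * b
  i <- which(t >= t_t1)
  b <- cos_blend((t[i] - t_t1) / 0.8)     # settle to upright in ~0.8 s
  sumang[i] <- q$sumang_settle * (1 - b) + q$sumang_stand * b

  # ---- foot angular velocity ---------------------------------------------
  gyro_burst <- function(swings, amp) {
    g <- numeric(n)
    for (s in swings) {
      i <- which(t >= s[1] & t < s[2])
      g[i] <- q$gyro_peak * amp * sin(2 * pi * (t[i] - s[1]) / (s[2] - s[1]))
    }
    g
  }
  gyroL <- gyro_burst(left_swings, ampL)
  gyroR <- gyro_burst(right_swings, ampR)

  # ---- noise --------------------------------------------------------------
  grfL <- pmax(lf$grf + stats::rnorm(n, 0, q$sigma_grf), 0)
  grfR <- pmax(rf$grf + stats::rnorm(n, 0, q$sigma_grf), 0)
  copL <- lf$cop + stats::rnorm(n, 0, q$sigma_cop)
  copR <- rf$cop + stats::rnorm(n, 0, q$sigma_cop)
  copL <- pmin(pmax(copL, 0), L)
  copR <- pmin(pmax(copR, 0), L)
  copL[lf$grf == 0 | grfL < CONTACT_EPS] <- NA_real_
  copR[rf$grf == 0 | grfR < CONTACT_EPS] <- NA_real_
  joint_noise <- function() stats::rnorm(n, 0, q$sigma_ang / 2)
  hipL <- sumang / 4 + joint_noise()
  hipR <- sumang / 4 + joint_noise()
  kneeL <- sumang / 4 + joint_noise()
  kneeR <- sumang / 4 + joint_noise()
  gyroL <- gyroL + stats::rnorm(n, 0, q$sigma_gyro)
  gyroR <- gyroR + stats::rnorm(n, 0, q$sigma_gyro)

  frames <- data.frame(t = t, grfL = grfL, grfR = grfR,
                       copyL = copL, copyR = copR,
                       hipL = hipL, hipR = hipR,
                       kneeL = kneeL, kneeR = kneeR,
                       gyroL = gyroL, gyroR = gyroR)
  gait_trial(frames, labels = labels, body_weight = W,
             prosthetic_side = q$prosthetic_side, seed = q$seed,
             params = q)
}
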