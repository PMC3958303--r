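#' Windowed GRF asymmetry
#'
#' Mean absolute difference between the left and right vertical ground
#' reaction forces over the most recent `window` samples (50 samples = 0.5 s
#' at 100 Hz). At a trial start, when fewer than `window` samples exist, the
#' mean is taken over the available samples (no zero padding).
#'
#' @param grfL,grfR numeric histories of the two vertical GRFs in N, oldest
#'   first, equal length >= 1.
#' @param window number of most recent samples to average over.
#' @return the asymmetry in N (a nonnegative scalar).
#' @examples
#' grf_diff(rep(600, 60), rep(0, 60))  # 600
#' @export
grf_diff <- function(grfL, grfR, window = 50L) {
  n <- length(grfL)
  if (n == 0L) stop("grf_diff() requires at least one sample")
  if (length(grfR) != n) stop("grfL and grfR histories must have equal length")
  if (window < 1L) stop("window must be >= 1")
  k <- min(as.integer(window), n)
  mean(abs(grfL[seq.int(n - k + 1L, n)] - grfR[seq.int(n - k + 1L, n)]))
}

#' Per-sample windowed GRF asymmetry over a whole trial
#'
#' Vectorised, causal version of [grf_diff()]: element `i` is the mean of
#' `|grfL - grfR|` over samples `max(1, i - window + 1) .. i`, so a batch
#' computation equals sample-by-sample streaming.
#'
#' @inheritParams grf_diff
#' @return numeric vector of the same length as the inputs.
#' @export
rolling_grf_diff <- function(grfL, grfR, window = 50L) {
  n <- length(grfL)
  if (length(grfR) != n) stop("grfL and grfR histories must have equal length")
  if (n == 0L) return(numeric(0))
  window <- as.integer(window)
  if (window < 1L) stop("window must be >= 1")
  d <- abs(grfL - grfR)
  cs <- cumsum(d)
  i <- seq_len(n)
  lag <- pmax(i - window, 0L)
  (cs - c(0, cs)[lag + 1L]) / pmin(i, window)
}

#' Summed lower-limb flexion
#'
#' Sum of both hip and both knee flexion angles, in degrees. The single
#' signal tracks the total amount of flexion in the lower extremities: near
#' zero in upright standing, oscillating during walking with maxima at
#' mid-swing.
#'
#' @param hipL,hipR,kneeL,kneeR joint flexion angles in degrees (vectors of
#'   equal length are summed element-wise).
#' @return numeric, the arithmetic sum.
#' @examples
#' sum_ang(20, 20, 10, 10)  # 60
#' @export
sum_ang <- function(hipL, hipR, kneeL, kneeR) {
  hipL + hipR + kneeL + kneeR
}
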