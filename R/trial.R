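TRIAL_COLUMNS <- c("t", "grfL", "grfR", "copyL", "copyR",
                   "hipL", "hipR", "kneeL", "kneeR", "gyroL", "gyroR")

# GRF below this force (N) means the foot is not in ground contact, and the
# COP of that foot is undefined (sentinel NA).
CONTACT_EPS <- 5

#' Construct a sensor trial
#'
#' A trial is a data.frame of 100 Hz sensor frames with columns `t` (s),
#' `grfL`/`grfR` (vertical GRF per foot, N), `copyL`/`copyR` (longitudinal
#' COP per foot in mm, origin at the toes increasing toward the heel; `NA`
#' is the "unloaded" sentinel whenever the foot carries less than the
#' contact epsilon), `hipL`/`hipR`/`kneeL`/`kneeR` (flexion angles, deg) and
#' `gyroL`/`gyroR` (sagittal foot angular velocity, rad/s), plus an optional
#' integer `label` column of ground-truth phase flags. Subject metadata
#' (body weight in N, prosthetic side, generator seed and parameters) is
#' carried in the `"meta"` attribute.
#'
#' @param frames data.frame with the columns above (a `label` column is
#'   allowed and kept).
#' @param labels optional integer vector of per-sample ground-truth phase
#'   flags (same length as `nrow(frames)`); stored as column `label`.
#' @param body_weight subject body weight in N (NA if unknown).
#' @param prosthetic_side `"left"`, `"right"` or `"none"`.
#' @param seed,params generator bookkeeping, stored verbatim.
#' @param validate run [validate_trial()] on the result.
#' @return an object of class `gait_trial` (a data.frame).
#' @export
gait_trial <- function(frames, labels = NULL, body_weight = NA_real_,
                       prosthetic_side = "none", seed = NULL, params = NULL,
                       validate = TRUE) {
  frames <- as.data.frame(frames)
  if (!is.null(labels)) {
    if (length(labels) != nrow(frames)) {
      stop("labels and frames must have equal length")
    }
    frames$label <- as.integer(labels)
  }
  structure(frames,
            class = c("gait_trial", "data.frame"),
            meta = list(body_weight = body_weight,
                        prosthetic_side = prosthetic_side,
                        seed = seed, params = params)) -> trial
  if (validate) validate_trial(trial)
  trial
}

#' @rdname gait_trial
#' @param trial a `gait_trial` or plain data.frame.
#' @export
trial_meta <- function(trial) {
  m <- attr(trial, "meta")
  if (is.null(m)) list(body_weight = NA_real_, prosthetic_side = "none",
                       seed = NULL, params = NULL) else m
}

#' Validate the trial schema and sampling
#'
#' Checks the column schema, that timestamps are strictly increasing at the
#' nominal 10 ms spacing (100 Hz; a mismatched rate is an error, resampling
#' is out of scope), that GRFs are nonnegative, that the COP is the sentinel
#' `NA` whenever the corresponding GRF is below the contact epsilon (5 N),
#' and that any labels are valid phase flags.
#'
#' @param trial a trial data.frame.
#' @param rate nominal sampling rate in Hz.
#' @return the trial, invisibly; errors describe the first violated check.
#' @export
validate_trial <- function(trial, rate = 100) {
  missing <- setdiff(TRIAL_COLUMNS, names(trial))
  if (length(missing)) {
    stop("trial is missing columns: ", paste(missing, collapse = ", "))
  }
  n <- nrow(trial)
  if (n == 0L) return(invisible(trial))
  for (col in TRIAL_COLUMNS) {
    if (!is.numeric(trial[[col]])) stop("column ", col, " must be numeric")
  }
  dt <- diff(trial$t)
  if (n > 1L && any(dt <= 0)) stop("timestamps must be strictly increasing")
  if (n > 1L && any(abs(dt - 1 / rate) > 1e-6)) {
    stop("sampling spacing must be ", format(1 / rate),
         " s (nominal ", rate, " Hz)")
  }
  if (any(trial$grfL < 0, na.rm = TRUE) || any(trial$grfR < 0, na.rm = TRUE)) {
    stop("ground reaction forces must be nonnegative")
  }
  if (any(is.na(trial$grfL)) || any(is.na(trial$grfR))) {
    stop("ground reaction forces must not be missing")
  }
  if (any(!is.na(trial$copyL) & trial$grfL < CONTACT_EPS) ||
      any(!is.na(trial$copyR) & trial$grfR < CONTACT_EPS)) {
    stop("COP must be the unloaded sentinel (NA) when GRF is below ",
         CONTACT_EPS, " N")
  }
  if (!is.null(trial$label) && !all(trial$label %in% phase_flags())) {
    stop("label column contains values that are not phase flags")
  }
  invisible(trial)
}

#' Read/write a trial CSV
#'
#' The CSV schema is the header
#' `t,grfL,grfR,copyL,copyR,hipL,hipR,kneeL,kneeR,gyroL,gyroR[,label]` with
#' one row per 10 ms sample; the unloaded-COP sentinel is encoded as an
#' empty field. Values are written with full (17 significant digit)
#' precision so a write/read round trip reproduces finite values exactly.
#'
#' @param path file path.
#' @param trial a [gait_trial()] (for writing).
#' @return `read_trial()` returns a validated [gait_trial()];
#'   `write_trial()` returns `path` invisibly.
#' @export
read_trial <- function(path) {
  df <- utils::read.csv(path, colClasses = "numeric")
  missing <- setdiff(TRIAL_COLUMNS, names(df))
  if (length(missing)) {
    stop("trial file lacks columns: ", paste(missing, collapse = ", "))
  }
  extra <- setdiff(names(df), c(TRIAL_COLUMNS, "label"))
  if (length(extra)) {
    stop("trial file has unknown columns: ", paste(extra, collapse = ", "))
  }
  if (!is.null(df$label)) df$label <- as.integer(df$label)
  gait_trial(df, validate = TRUE)
}

#' @rdname read_trial
#' @export
write_trial <- function(trial, path) {
  cols <- intersect(c(TRIAL_COLUMNS, "label"), names(trial))
  out <- as.data.frame(trial)[, cols, drop = FALSE]
  fmt <- vapply(out, function(col) {
    s <- sprintf("%.17g", col)
    s[is.na(col)] <- ""
    s
  }, character(nrow(out)))
  if (nrow(out) == 0L) fmt <- matrix(character(0), 0, length(cols))
  if (is.null(dim(fmt))) fmt <- matrix(fmt, nrow = 1L)
  utils::write.table(fmt, path, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = cols)
  invisible(path)
}

#' @export
print.gait_trial <- function(x, ...) {
  m <- trial_meta(x)
  cat(sprintf("<gait_trial> %d frames (%.2f s at 100 Hz)%s\n", nrow(x),
              nrow(x) / 100,
              if (!is.null(x$label)) ", labelled" else ""))
  cat(sprintf("  body weight: %s N, prosthetic side: %s\n",
              format(m$body_weight), m$prosthetic_side))
  if (nrow(x)) {
    utils::str(utils::head(as.data.frame(x), 3), give.attr = FALSE)
  }
  invisible(x)
}
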