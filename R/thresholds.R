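THRESHOLD_NAMES <- c("QSgrf", "stanceL", "stanceR", "init1", "init2",
                     "sumQS", "sumAngInit", "sumAngTerm", "minAng",
                     "midCOP", "toeCOP", "minG", "termG")

#' Threshold set for the transition rules
#'
#' The thirteen named thresholds on the input signals. Force thresholds are
#' in N, COP thresholds in mm (longitudinal coordinate, origin at the toes,
#' increasing toward the heel), angle thresholds in degrees, angular-velocity
#' thresholds in rad/s. `QSgrf` separates quiet standing from motion on each
#' foot's ground reaction force; `stanceL`/`stanceR` detect foot-ground
#' contact; `init1`/`init2` act on the windowed GRF asymmetry (entering and
#' leaving the initiation/termination states respectively, so `init2 <=
#' init1`); `sumQS`/`sumAngInit`/`sumAngTerm`/`minAng` act on the summed
#' hip+knee flexion; `midCOP`/`toeCOP` discriminate the two double-stance
#' phases on the COP (`toeCOP <= midCOP`); `minG`/`termG` bound the foot
#' angular velocity for standing-still detection.
#'
#' @param ... the thirteen thresholds as named numeric scalars (all must be
#'   supplied; use [default_thresholds()] for body-scaled defaults).
#' @return an object of class `threshold_set` (a named numeric vector).
#' @seealso [default_thresholds()], [read_thresholds()]
#' @export
threshold_set <- function(...) {
  vals <- c(...)
  if (is.list(vals)) vals <- unlist(vals)
  missing <- setdiff(THRESHOLD_NAMES, names(vals))
  if (length(missing)) {
    stop("missing thresholds: ", paste(missing, collapse = ", "))
  }
  unknown <- setdiff(names(vals), THRESHOLD_NAMES)
  if (length(unknown)) {
    stop("unknown thresholds: ", paste(unknown, collapse = ", "))
  }
  vals <- vals[THRESHOLD_NAMES]
  if (!all(is.finite(vals))) stop("all thresholds must be finite numbers")
  nonneg <- setdiff(THRESHOLD_NAMES,
                    c("sumQS", "sumAngInit", "sumAngTerm", "minAng"))
  if (any(vals[nonneg] < 0)) {
    stop("thresholds other than angle thresholds must be >= 0")
  }
  if (vals["init2"] > vals["init1"]) stop("init2 must be <= init1")
  if (vals["toeCOP"] > vals["midCOP"]) stop("toeCOP must be <= midCOP")
  structure(vals, class = "threshold_set")
}

#' Default thresholds scaled to the subject
#'
#' Thresholds are subject-specific in practice (tuned to weight and insole
#' size before use); these defaults express them relative to body weight
#' `W` (N) and insole length `L` (mm): `QSgrf = 0.30 W`,
#' `stanceL = stanceR = 0.05 W`, `init1 = 0.15 W`, `init2 = 0.10 W`,
#' `sumQS = 15`, `sumAngInit = 25`, `sumAngTerm = 20`, `minAng = 10` degrees,
#' `midCOP = 0.45 L`, `toeCOP = 0.30 L`, `minG = 0.2`, `termG = 0.3` rad/s.
#'
#' @param body_weight subject body weight in N.
#' @param insole_length insole length in mm.
#' @return a [threshold_set()].
#' @examples
#' default_thresholds(600)
#' @export
default_thresholds <- function(body_weight = 600, insole_length = 260) {
  stopifnot(body_weight > 0, insole_length > 0)
  threshold_set(
    QSgrf = 0.30 * body_weight,
    stanceL = 0.05 * body_weight,
    stanceR = 0.05 * body_weight,
    init1 = 0.15 * body_weight,
    init2 = 0.10 * body_weight,
    sumQS = 15,
    sumAngInit = 25,
    sumAngTerm = 20,
    minAng = 10,
    midCOP = 0.45 * insole_length,
    toeCOP = 0.30 * insole_length,
    minG = 0.2,
    termG = 0.3
  )
}

#' Read/write a threshold configuration file
#'
#' The configuration is a flat JSON or YAML mapping of the thirteen
#' threshold names to numbers (units as in [threshold_set()]); unknown or
#' missing keys are rejected. The format is chosen by file extension
#' (`.json` vs `.yaml`/`.yml`).
#'
#' @param path file path.
#' @param th a [threshold_set()] (for writing).
#' @return `read_thresholds()` returns a [threshold_set()];
#'   `write_thresholds()` returns `path` invisibly.
#' @export
read_thresholds <- function(path) {
  ext <- tolower(tools::file_ext(path))
  vals <- switch(ext,
    json = jsonlite::fromJSON(path),
    yaml = ,
    yml = yaml::read_yaml(path),
    stop("unsupported threshold config format: .", ext)
  )
  if (!length(vals) || is.null(names(vals))) {
    stop("threshold config must be a named mapping")
  }
  do.call(threshold_set, as.list(unlist(vals)))
}

#' @rdname read_thresholds
#' @export
write_thresholds <- function(th, path) {
  stopifnot(inherits(th, "threshold_set"))
  ext <- tolower(tools::file_ext(path))
  vals <- as.list(unclass(th))
  switch(ext,
    json = jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA),
    yaml = ,
    yml = yaml::write_yaml(vals, path),
    stop("unsupported threshold config format: .", ext)
  )
  invisible(path)
}

#' @export
print.threshold_set <- function(x, ...) {
  cat("<threshold_set>\n")
  print(stats::setNames(as.numeric(x), names(unclass(x))))
  invisible(x)
}
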