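#' Phase flag codes
#'
#' Integer codes identifying the detector states. The four walking phases of
#' a steady-state stride carry the flags 11 (left single stance), 12
#' (left-right double stance), 13 (right single stance) and 14 (right-left
#' double stance); the bracketing maneuver states are quiet standing (5),
#' initiation (6) and termination (4). `UNKNOWN` (0) is emitted only before
#' the first classified sample.
#'
#' @return `phase_flags()` returns a named integer vector of all valid flag
#'   codes; `walking_flags()` the four walking-phase codes in cyclic order.
#' @examples
#' phase_flags()
#' walking_flags()
#' @export
phase_flags <- function() {
  c(UNKNOWN = 0L, TERMINATION = 4L, QUIET_STANDING = 5L, INITIATION = 6L,
    LEFT_STANCE = 11L, LR_DOUBLE = 12L, RIGHT_STANCE = 13L, RL_DOUBLE = 14L)
}

#' @rdname phase_flags
#' @export
walking_flags <- function() {
  c(LEFT_STANCE = 11L, LR_DOUBLE = 12L, RIGHT_STANCE = 13L, RL_DOUBLE = 14L)
}

# internal shorthands
FLAG_UNKNOWN <- 0L
FLAG_TERMINATION <- 4L
FLAG_QUIET <- 5L
FLAG_INITIATION <- 6L
FLAG_LEFT <- 11L
FLAG_LR <- 12L
FLAG_RIGHT <- 13L
FLAG_RL <- 14L
WALKING <- c(11L, 12L, 13L, 14L)

is_walking_flag <- function(flag) flag %in% WALKING

#' Map a walking flag to the sound/prosthetic side phase
#'
#' Walking phases are detected in left/right terms; for comparison across
#' subjects they are renamed by the role of the limb: `SS_s`/`SS_p` for
#' single stance of the sound/prosthetic leg, and `DS_sp`/`DS_ps` for the
#' double stances named trailing-to-leading limb (sound-to-prosthetic,
#' prosthetic-to-sound). With the prosthesis on the right, left stance (11)
#' is `SS_s`, the left-right double stance (12) is `DS_sp`, right stance
#' (13) is `SS_p` and the right-left double stance (14) is `DS_ps`; the
#' mapping mirrors for a left-side prosthesis.
#'
#' @param flag integer vector of walking flags (11, 12, 13, 14).
#' @param prosthetic_side `"left"` or `"right"`.
#' @return character vector of side-phase names (`"SS_s"`, `"SS_p"`,
#'   `"DS_sp"`, `"DS_ps"`).
#' @examples
#' map_to_side(c(11, 12, 13, 14), "right")
#' @export
map_to_side <- function(flag, prosthetic_side = c("right", "left")) {
  prosthetic_side <- match.arg(prosthetic_side)
  flag <- as.integer(flag)
  if (!all(flag %in% WALKING)) {
    stop("map_to_side() is defined only for walking flags 11, 12, 13, 14")
  }
  right_map <- c(`11` = "SS_s", `12` = "DS_sp", `13` = "SS_p", `14` = "DS_ps")
  left_map <- c(`11` = "SS_p", `12` = "DS_ps", `13` = "SS_s", `14` = "DS_sp")
  m <- if (prosthetic_side == "right") right_map else left_map
  unname(m[as.character(flag)])
}

# Cyclic order of walking phases within a stride: 11 -> 12 -> 13 -> 14 -> 11.
# Forward distance from a to b in that cycle (1..3; 0 only if a == b).
cyclic_steps <- function(from, to) {
  idx <- match(c(from, to), WALKING)
  (idx[2L] - idx[1L]) %% 4L
}

# State-diagram topology. Transition designators (letters) follow the state
# diagram: a: 5->6, b: 6->5, c: 6->11/13, d: 14->11, e: 11->12, f: 12->13,
# g: 13->14, h/i: 12->4 and 14->4, j: 4->5.
topology_successors <- function(flag) {
  switch(as.character(flag),
    `5` = 6L,
    `6` = c(5L, 11L, 13L),
    `11` = 12L,
    `12` = c(13L, 4L),
    `13` = 14L,
    `14` = c(11L, 4L),
    `4` = 5L,
    integer(0)
  )
}
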