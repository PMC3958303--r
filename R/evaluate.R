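#' Segment a flag sequence into walking-phase occurrences
#'
#' Run-length encodes the walking flags (11, 12, 13, 14) of a detector
#' output or label sequence into segments with half-open sample ranges
#' `[start, end)`. Non-walking samples break and separate runs. Runs shorter
#' than `debounce` samples are treated as jitter: they take the flag of the
#' preceding segment (of the following one at the very start), and adjacent
#' same-flag segments are then merged.
#'
#' @param flags integer vector of phase flags.
#' @param debounce minimum run length in samples (runs shorter than this are
#'   merged into their neighbours); `1` disables debouncing.
#' @return data.frame with columns `flag`, `start`, `end` (1-based,
#'   half-open) ordered by `start`; zero rows if no walking samples exist.
#' @examples
#' segment_phases(c(5, 5, 11, 11, 11, 12, 12, 13, 13, 13, 5))
#' @export
segment_phases <- function(flags, debounce = 3L) {
  n <- length(flags)
  work <- ifelse(flags %in% WALKING, as.integer(flags), NA_integer_)
  if (all(is.na(work))) {
    return(data.frame(flag = integer(0), start = integer(0),
                      end = integer(0)))
  }
  if (debounce > 1L) {
    r <- rle(work)
    # short walking runs inherit the previous walking flag (next at start)
    prev <- NA_integer_
    for (j in seq_along(r$values)) {
      v <- r$values[j]
      if (is.na(v)) next
      if (r$lengths[j] < debounce) {
        repl <- prev
        if (is.na(repl)) {
          nxt <- which(!is.na(r$values) & seq_along(r$values) > j &
                         r$lengths >= debounce)
          repl <- if (length(nxt)) r$values[nxt[1L]] else v
        }
        r$values[j] <- repl
      }
      prev <- r$values[j]
    }
    work <- inverse.rle(r)
  }
  r <- rle(ifelse(is.na(work), -1L, work))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != -1L
  seg <- data.frame(flag = r$values[keep], start = starts[keep],
                    end = ends[keep] + 1L)
  # bridge same-flag segments separated only by a shorter-than-debounce
  # non-walking gap (jitter); distinct occurrences stay distinct
  if (nrow(seg) > 1L) {
    merged <- seg[1L, ]
    for (j in 2:nrow(seg)) {
      last <- nrow(merged)
      if (seg$flag[j] == merged$flag[last] &&
          seg$start[j] - merged$end[last] < debounce) {
        merged$end[last] <- seg$end[j]
      } else {
        merged <- rbind(merged, seg[j, ])
      }
    }
    seg <- merged
  }
  rownames(seg) <- NULL
  seg
}

# forward step count a -> b in the 11->12->13->14 cycle (0..3)
seg_consistent <- function(segments, j, max_skip = 1L) {
  ok_step <- function(from, to) {
    s <- cyclic_steps(from, to)
    s >= 1L && s <= 1L + max_skip
  }
  if (j > 1L && !ok_step(segments$flag[j - 1L], segments$flag[j])) {
    return(FALSE)
  }
  if (j < nrow(segments) && !ok_step(segments$flag[j], segments$flag[j + 1L])) {
    return(FALSE)
  }
  TRUE
}

#' Per-phase detection success ratios
#'
#' Scores a detected flag sequence against ground truth the way walking
#' phases are scored in practice: each ground-truth phase occurrence counts
#' as correctly recognised iff some detected segment of the same flag
#' overlaps its sample interval and that detected segment sits consistently
#' in the cyclic phase order (its neighbouring detected walking segments are
#' 1 to `1 + max_skip` forward steps away, i.e. an undetected phase may be
#' skipped). The success ratio per phase type is 100 x correct / total. The
#' report carries both the phase-averaged mean and the count-weighted mean
#' over phases.
#'
#' @param detected integer flag sequence from a detector (or a segment
#'   data.frame from [segment_phases()]).
#' @param truth ground-truth flag sequence of the same trial (or segments).
#' @param prosthetic_side `"left"` or `"right"` to report phases as
#'   `SS_s`/`SS_p`/`DS_sp`/`DS_ps`; `"none"` reports them as
#'   `L`/`L-R`/`R`/`R-L`.
#' @param debounce passed to [segment_phases()] for flag sequences.
#' @param max_skip number of phases that may be skipped between detected
#'   segments without breaking sequence consistency.
#' @return an object of class `success_report`: data.frame `phases` with
#'   columns `phase`, `flag`, `n_true`, `n_correct`, `ratio` (percent), plus
#'   `mean_phase` (arithmetic mean of the four ratios) and `mean_weighted`
#'   (pooled-count ratio).
#' @examples
#' tr <- simulate_trial(gait_params(n_strides = 4, seed = 7))
#' fl <- detect_trial(tr, default_thresholds(600))
#' success_ratio(fl, tr$label)
#' @export
success_ratio <- function(detected, truth, prosthetic_side = "none",
                          debounce = 3L, max_skip = 1L) {
  seg_of <- function(x) {
    if (is.data.frame(x)) x else segment_phases(x, debounce = debounce)
  }
  det <- seg_of(detected)
  tru <- seg_of(truth)
  if (nrow(tru) == 0L) stop("ground truth contains no walking phases")
  matched <- logical(nrow(tru))
  for (i in seq_len(nrow(tru))) {
    cand <- which(det$flag == tru$flag[i] &
                    det$start < tru$end[i] & det$end > tru$start[i])
    matched[i] <- any(vapply(cand, function(j) {
      seg_consistent(det, j, max_skip)
    }, logical(1L)))
  }
  phase_label <- function(flag) {
    if (prosthetic_side %in% c("left", "right")) {
      map_to_side(flag, prosthetic_side)
    } else {
      c(`11` = "L", `12` = "L-R", `13` = "R", `14` = "R-L")[as.character(flag)]
    }
  }
  n_true <- vapply(WALKING, function(f) sum(tru$flag == f), 1L)
  n_correct <- vapply(WALKING, function(f) sum(matched[tru$flag == f]), 1L)
  phases <- data.frame(phase = unname(phase_label(WALKING)), flag = WALKING,
                       n_true = n_true, n_correct = n_correct,
                       ratio = ifelse(n_true > 0, 100 * n_correct / n_true,
                                      NA_real_))
  structure(list(phases = phases,
                 mean_phase = mean(phases$ratio, na.rm = TRUE),
                 mean_weighted = 100 * sum(n_correct) / sum(n_true),
                 prosthetic_side = prosthetic_side),
            class = "success_report")
}

#' Pool success reports across trials or subjects
#'
#' Aggregation pools the phase counts (correct and total) rather than
#' averaging ratios, matching the definition of the success ratio over all
#' phases of a particular type.
#'
#' @param reports list of [success_ratio()] reports (same side mapping).
#' @return a pooled `success_report`.
#' @export
pool_reports <- function(reports) {
  stopifnot(length(reports) >= 1L)
  # pooling is keyed by phase name (SS_s, ...), not by flag: subjects with
  # different prosthetic sides map flags to side phases differently
  keys <- reports[[1L]]$phases$phase
  acc <- function(col) {
    rowSums(vapply(reports, function(r) {
      if (!setequal(r$phases$phase, keys)) {
        stop("reports use different phase labellings and cannot be pooled")
      }
      r$phases[[col]][match(keys, r$phases$phase)]
    }, numeric(length(keys))))
  }
  n_true <- acc("n_true")
  n_correct <- acc("n_correct")
  sides <- unique(vapply(reports, `[[`, "", "prosthetic_side"))
  flags <- if (length(sides) == 1L) {
    reports[[1L]]$phases$flag
  } else {
    rep(NA_integer_, length(keys))
  }
  phases <- data.frame(phase = keys, flag = flags, n_true = n_true,
                       n_correct = n_correct,
                       ratio = ifelse(n_true > 0, 100 * n_correct / n_true,
                                      NA_real_))
  structure(list(phases = phases,
                 mean_phase = mean(phases$ratio, na.rm = TRUE),
                 mean_weighted = 100 * sum(n_correct) / sum(n_true),
                 prosthetic_side = if (length(sides) == 1L) sides else
                   "mixed"),
            class = "success_report")
}

#' Index span of the walking maneuver
#'
#' Returns the contiguous sample range from the first to the last
#' walking-flag sample of a label sequence. Useful for scoring classifiers
#' that only model the walking phases (such as the HMM bank, whose output
#' outside the walking maneuver is arbitrary because quiet standing,
#' initiation and termination are not among its classes): slicing both the
#' detected and the truth sequence to this span evaluates detection on the
#' walking portion of a trial.
#'
#' @param labels integer flag sequence (ground truth).
#' @return integer index vector (empty if no walking samples exist).
#' @export
walking_span <- function(labels) {
  w <- which(labels %in% WALKING)
  if (!length(w)) return(integer(0))
  seq.int(min(w), max(w))
}

#' Check a flag sequence against the state-diagram topology
#'
#' Reports segment transitions that are not reachable in the state diagram
#' (quiet standing <-> initiation -> first stance -> the walking cycle ->
#' termination -> quiet standing). Within the walking cycle a skip-one
#' allowance models an undetected phase; `strict = TRUE` disables it.
#'
#' @param flags integer flag sequence (`UNKNOWN` samples are ignored).
#' @param strict disallow skipped walking phases.
#' @return data.frame of violations with columns `sample` (index where the
#'   offending segment starts), `from`, `to`; zero rows means the sequence
#'   is valid.
#' @examples
#' nrow(sequence_check(simulate_trial(gait_params(seed = 1))$label)) == 0
#' @export
sequence_check <- function(flags, strict = FALSE) {
  keep <- flags != FLAG_UNKNOWN
  idx <- which(keep)
  x <- flags[keep]
  if (!length(x)) {
    return(data.frame(sample = integer(0), from = integer(0),
                      to = integer(0)))
  }
  r <- rle(x)
  v <- r$values
  starts <- idx[cumsum(r$lengths) - r$lengths + 1L]
  bad <- list()
  if (length(v) > 1L) for (j in 2:length(v)) {
    from <- v[j - 1L]
    to <- v[j]
    ok <- to %in% topology_successors(from)
    if (!ok && !strict && from %in% WALKING && to %in% WALKING) {
      ok <- cyclic_steps(from, to) %in% c(1L, 2L)
    }
    if (!ok) {
      bad[[length(bad) + 1L]] <- data.frame(sample = starts[j], from = from,
                                            to = to)
    }
  }
  if (length(bad)) do.call(rbind, bad) else {
    data.frame(sample = integer(0), from = integer(0), to = integer(0))
  }
}

#' @export
print.success_report <- function(x, ...) {
  cat("<success_report>\n")
  print(x$phases, row.names = FALSE)
  cat(sprintf("mean over phases: %.1f%%  (count-weighted: %.1f%%)\n",
              x$mean_phase, x$mean_weighted))
  invisible(x)
}
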