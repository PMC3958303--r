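#' Configuration of the synthetic multi-subject benchmark
#'
#' Describes an end-to-end comparison of the detectors on simulated
#' subjects: each synthetic subject draws its own gait parameters (body
#' weight, cadence, duty factor, prosthetic side and asymmetry) from
#' realistic ranges, walks `n_walks` trials, and every configured detector
#' is evaluated on the walks beyond the first `n_train` (which are reserved
#' for HMM training) so all detectors score the same held-out walks.
#'
#' @param n_subjects number of synthetic subjects (>= 2 for the inter
#'   scheme).
#' @param n_walks walking trials per subject.
#' @param n_train walks per subject reserved for HMM training (must be
#'   smaller than `n_walks`).
#' @param n_strides steady-state strides per walk.
#' @param detectors subset of `"fsm"`, `"hmm-intra"`, `"hmm-inter"`,
#'   `"hmm-pooled"`.
#' @param sigma_grf,sigma_cop,sigma_ang,sigma_gyro noise levels passed to
#'   the generator; `sigma_grf` is relative to each subject's body weight.
#' @param seed master seed; all subject draws and per-trial seeds derive
#'   from it.
#' @return an object of class `benchmark_config`.
#' @export
benchmark_config <- function(n_subjects = 3L, n_walks = 6L, n_train = 3L,
                             n_strides = 8L,
                             detectors = c("fsm", "hmm-pooled"),
                             sigma_grf = 0.02, sigma_cop = 5,
                             sigma_ang = 2, sigma_gyro = 0.05,
                             seed = 1L) {
  detectors <- match.arg(detectors,
                         c("fsm", "hmm-intra", "hmm-inter", "hmm-pooled"),
                         several.ok = TRUE)
  stopifnot(n_subjects >= 1L, n_walks >= 2L, n_train >= 1L,
            n_train < n_walks, n_strides >= 2L, seed == as.integer(seed))
  if ("hmm-inter" %in% detectors && n_subjects < 2L) {
    stop("inter-subject HMM scheme requires at least 2 subjects")
  }
  structure(as.list(environment()), class = "benchmark_config")
}

# one subject's parameter draw; RNG state is the caller's responsibility
draw_subject <- function(cfg) {
  list(body_weight = stats::runif(1, 550, 750),
       stride_period = stats::runif(1, 0.9, 1.15),
       stance_fraction = stats::runif(1, 0.60, 0.64),
       asym_amp = stats::runif(1, 0.85, 0.95),
       asym_time = stats::runif(1, 0.92, 0.98),
       prosthetic_side = sample(c("left", "right"), 1))
}

#' Run the synthetic benchmark
#'
#' Simulates the configured subjects and walks, runs every configured
#' detector on the held-out walks, and tabulates per-phase success ratios
#' (per subject, plus a pooled all-subjects row per detector in which the
#' phase counts, not the ratios, are pooled).
#'
#' @param config a [benchmark_config()].
#' @return data.frame with one row per detector x subject (and per detector
#'   a pooled `"all"` row): columns `detector`, `subject`, `SS_s`, `SS_p`,
#'   `DS_sp`, `DS_ps`, `mean_phase`, `mean_weighted`, `n_phases`.
#' @examples
#' \donttest{
#' run_benchmark(benchmark_config(n_subjects = 2, n_walks = 4, n_train = 2,
#'                                n_strides = 4, detectors = "fsm"))
#' }
#' @export
run_benchmark <- function(config) {
  stopifnot(inherits(config, "benchmark_config"))
  cfg <- config
  set.seed(cfg$seed)
  subj_draws <- lapply(seq_len(cfg$n_subjects), function(i) draw_subject(cfg))
  trial_seed <- function(s, w) (cfg$seed %% 1000L) * 1000000L +
    s * 1000L + w  # < 2^31
  subjects <- list()
  for (s in seq_len(cfg$n_subjects)) {
    d <- subj_draws[[s]]
    walks <- lapply(seq_len(cfg$n_walks), function(w) {
      simulate_trial(gait_params(
        body_weight = d$body_weight, stride_period = d$stride_period,
        n_strides = cfg$n_strides, stance_fraction = d$stance_fraction,
        prosthetic_side = d$prosthetic_side,
        asym_amp = d$asym_amp, asym_time = d$asym_time,
        sigma_grf = cfg$sigma_grf * d$body_weight, sigma_cop = cfg$sigma_cop,
        sigma_ang = cfg$sigma_ang, sigma_gyro = cfg$sigma_gyro,
        seed = trial_seed(s, w)))
    })
    subjects[[s]] <- list(id = paste0("S", s), draw = d, walks = walks,
                          th = default_thresholds(d$body_weight))
  }
  test_idx <- seq.int(cfg$n_train + 1L, cfg$n_walks)

  # detectors are scored on the walking span of each trial: the HMM bank has
  # no classes for standing/initiation/termination, so its output outside
  # the maneuver is arbitrary, and the FSM is unaffected by the restriction
  score <- function(detector, s, flags_list) {
    reps <- Map(function(flags, trial) {
      span <- walking_span(trial$label)
      success_ratio(flags[span], trial$label[span],
                    prosthetic_side = s$draw$prosthetic_side)
    }, flags_list, s$walks[test_idx])
    pool_reports(reps)
  }
  report_row <- function(detector, subject, rep) {
    ph <- rep$phases
    vals <- stats::setNames(ph$ratio, ph$phase)
    data.frame(detector = detector, subject = subject,
               SS_s = vals[["SS_s"]], SS_p = vals[["SS_p"]],
               DS_sp = vals[["DS_sp"]], DS_ps = vals[["DS_ps"]],
               mean_phase = rep$mean_phase,
               mean_weighted = rep$mean_weighted,
               n_phases = sum(ph$n_true))
  }

  all_trials <- unlist(lapply(subjects, `[[`, "walks"), recursive = FALSE)
  all_ids <- rep(vapply(subjects, `[[`, "", "id"),
                 each = cfg$n_walks)
  rows <- list()
  for (detector in cfg$detectors) {
    per_subject <- list()
    if (detector == "fsm") {
      for (s in subjects) {
        fl <- lapply(s$walks[test_idx], detect_trial, th = s$th)
        per_subject[[s$id]] <- score(detector, s, fl)
      }
    } else {
      scheme <- sub("^hmm-", "", detector)
      splits <- build_training_sets(all_trials, all_ids, scheme = scheme,
                                    n_train = cfg$n_train)
      for (sp in splits) {
        s <- subjects[[match(sp$subject, vapply(subjects, `[[`, "", "id"))]]
        bank <- train_hmm_bank(all_trials[sp$train], seed = cfg$seed)
        fl <- lapply(all_trials[sp$test], detect_trial_hmm, bank = bank)
        per_subject[[s$id]] <- score(detector, s, fl)
      }
    }
    for (id in names(per_subject)) {
      rows[[length(rows) + 1L]] <- report_row(detector, id,
                                              per_subject[[id]])
    }
    rows[[length(rows) + 1L]] <-
      report_row(detector, "all", pool_reports(unname(per_subject)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
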