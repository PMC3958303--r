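HMM_FEATURES <- c("grfL", "grfR", "grfDiff", "copyL", "copyR", "sumAng",
                  "gyroL", "gyroR", "loadedL", "loadedR")

#' Extract the observation features for the HMM classifier
#'
#' The classifier observes the same signal combination as the rule-based
#' detector, in the fixed order `grfL, grfR, grfDiff, copyL, copyR, sumAng,
#' gyroL, gyroR`, followed by two companion binary contact features
#' `loadedL, loadedR`. The unloaded-COP sentinel is replaced by the
#' mid-insole coordinate so the vector stays numeric without fabricating
#' heel or toe positions; the binary features carry the contact information
#' instead.
#'
#' @param trial a [gait_trial()] (or conforming data.frame).
#' @param insole_length insole length in mm (mid-insole imputation value is
#'   half of it).
#' @param window asymmetry window for the `grfDiff` feature.
#' @return numeric matrix, one row per sample, columns as above (raw,
#'   unnormalised).
#' @export
extract_features <- function(trial, insole_length = 260, window = 50L) {
  n <- nrow(trial)
  loadedL <- as.numeric(!is.na(trial$copyL))
  loadedR <- as.numeric(!is.na(trial$copyR))
  copL <- ifelse(is.na(trial$copyL), insole_length / 2, trial$copyL)
  copR <- ifelse(is.na(trial$copyR), insole_length / 2, trial$copyR)
  m <- cbind(grfL = trial$grfL, grfR = trial$grfR,
             grfDiff = rolling_grf_diff(trial$grfL, trial$grfR, window),
             copyL = copL, copyR = copR,
             sumAng = sum_ang(trial$hipL, trial$hipR,
                              trial$kneeL, trial$kneeR),
             gyroL = trial$gyroL, gyroR = trial$gyroR,
             loadedL = loadedL, loadedR = loadedR)
  if (n == 0L) m <- matrix(numeric(0), 0L, length(HMM_FEATURES),
                           dimnames = list(NULL, HMM_FEATURES))
  m
}

#' Feature normalisation
#'
#' Per-feature location/scale standardisation shared by the four phase
#' models of a bank. `normalize_features()` applies `(x - center) / scale`;
#' `denormalize_features()` inverts it exactly.
#'
#' @param x feature matrix (rows = samples).
#' @param center,scale numeric vectors, one value per feature.
#' @return matrix of the same shape.
#' @export
normalize_features <- function(x, center, scale) {
  sweep(sweep(x, 2L, center, "-"), 2L, scale, "/")
}

#' @rdname normalize_features
#' @export
denormalize_features <- function(x, center, scale) {
  sweep(sweep(x, 2L, scale, "*"), 2L, center, "+")
}

feature_norm_params <- function(x) {
  center <- colMeans(x)
  scale <- apply(x, 2L, stats::sd)
  scale[!is.finite(scale) | scale < 1e-6] <- 1
  list(center = center, scale = scale)
}

# log of diagonal-Gaussian densities: obs (T x d), means/vars (k x d);
# returns T x k matrix of per-state log emission densities
log_emissions <- function(obs, means, vars) {
  Tn <- nrow(obs)
  k <- nrow(means)
  out <- matrix(0, Tn, k)
  for (j in seq_len(k)) {
    z <- sweep(obs, 2L, means[j, ], "-")
    out[, j] <- -0.5 * rowSums(z^2 / rep(vars[j, ], each = Tn)) -
      0.5 * sum(log(2 * pi * vars[j, ]))
  }
  out
}

# Exact log-space forward recursion (underflow-free); used for likelihood
# evaluation. logB: T x k log emission matrix.
log_forward <- function(init, trans, logB) {
  logT <- log(trans)
  la <- log(init) + logB[1L, ]
  Tn <- nrow(logB)
  if (Tn > 1L) for (tt in 2:Tn) {
    m <- apply(la + logT, 2L, max)          # la recycled down columns
    s <- colSums(exp(la + logT - rep(m, each = length(la))))
    la <- ifelse(is.finite(m), m + log(s), -Inf) + logB[tt, ]
  }
  m <- max(la)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(la - m)))
}

# Scaled forward pass used inside EM (training segments are pure-phase, so
# scaling suffices; a zero scale is guarded to keep the recursion finite).
forward_pass <- function(init, trans, logB, keep = FALSE) {
  Tn <- nrow(logB)
  k <- length(init)
  shift <- apply(logB, 1L, max)
  B <- exp(logB - shift)
  alpha <- matrix(0, Tn, k)
  cvec <- numeric(Tn)
  a <- init * B[1L, ]
  cvec[1L] <- sum(a)
  if (cvec[1L] <= 0) {
    alpha[1L, ] <- 1 / k
    cvec[1L] <- 1e-300
  } else {
    alpha[1L, ] <- a / cvec[1L]
  }
  if (Tn > 1L) for (tt in 2:Tn) {
    a <- (alpha[tt - 1L, ] %*% trans) * B[tt, ]
    cvec[tt] <- sum(a)
    if (cvec[tt] <= 0) {
      alpha[tt, ] <- 1 / k
      cvec[tt] <- 1e-300
    } else {
      alpha[tt, ] <- a / cvec[tt]
    }
  }
  ll <- sum(log(cvec)) + sum(shift)
  if (!keep) return(ll)
  list(loglik = ll, alpha = alpha, cvec = cvec, B = B)
}

backward_pass <- function(trans, fwd) {
  Tn <- nrow(fwd$B)
  k <- ncol(fwd$B)
  beta <- matrix(0, Tn, k)
  beta[Tn, ] <- 1
  if (Tn > 1L) for (tt in (Tn - 1L):1L) {
    beta[tt, ] <- (trans %*% (fwd$B[tt + 1L, ] * beta[tt + 1L, ])) /
      fwd$cvec[tt + 1L]
  }
  beta
}

#' Log-likelihood of an observation window under one phase model
#'
#' Forward-algorithm computation of `log P(window | model)`. Observations
#' must already be normalised with the bank's parameters when the model
#' comes from a bank.
#'
#' @param model a `gait_hmm`.
#' @param obs numeric matrix (rows = samples, columns = features).
#' @return scalar log-likelihood.
#' @export
hmm_loglik <- function(model, obs) {
  stopifnot(inherits(model, "gait_hmm"))
  obs <- rbind(obs)
  log_forward(model$init, model$trans,
              log_emissions(obs, model$means, model$vars))
}

#' Train one per-phase hidden Markov model
#'
#' Fits a `n_states`-state HMM with diagonal-Gaussian emissions to the
#' segments of one walking phase by Baum-Welch expectation-maximisation
#' (maximum-likelihood estimation). Initialisation partitions each segment
#' into `n_states` temporal parts for the emission moments, with a
#' left-to-right-leaning transition prior and a small seeded jitter on the
#' means; the total training log-likelihood is non-decreasing across
#' iterations. Constant (degenerate) features are handled by a variance
#' floor.
#'
#' @param segments list of numeric matrices (one per phase occurrence, rows
#'   = consecutive samples, columns = features, already normalised), each
#'   with at least `n_states` rows.
#' @param n_states number of hidden states.
#' @param phase the walking flag this model represents (bookkeeping).
#' @param seed RNG seed for the initialisation jitter.
#' @param max_iter,tol EM stopping rule: relative log-likelihood improvement
#'   below `tol` or `max_iter` iterations.
#' @param var_floor lower bound on emission variances, in standardised
#'   feature units. The floor keeps degenerate (within-phase constant)
#'   features such as the binary contact indicators well-posed while leaving
#'   them strongly discriminative; a much smaller floor would let a single
#'   mismatched boundary sample of a binary feature outweigh the rest of the
#'   window by orders of magnitude.
#' @return an object of class `gait_hmm` with fields `init`, `trans`,
#'   `means`, `vars`, `phase`, `n_states` and attribute `"loglik_trace"`.
#' @export
train_phase_hmm <- function(segments, n_states = 3L, phase = NA_integer_,
                            seed = 1L, max_iter = 200L, tol = 1e-6,
                            var_floor = 1e-2) {
  stopifnot(length(segments) >= 1L)
  segments <- lapply(segments, rbind)
  if (any(vapply(segments, nrow, 1L) < n_states)) {
    stop("each segment must have at least n_states samples")
  }
  d <- ncol(segments[[1L]])
  k <- as.integer(n_states)
  # --- initialisation: temporal thirds + left-to-right prior --------------
  set.seed(seed)
  parts <- lapply(seq_len(k), function(j) {
    do.call(rbind, lapply(segments, function(s) {
      idx <- cut(seq_len(nrow(s)), k, labels = FALSE)
      s[idx == j, , drop = FALSE]
    }))
  })
  means <- do.call(rbind, lapply(parts, colMeans))
  means <- means + matrix(stats::rnorm(k * d, 0, 1e-3), k, d)
  vars <- do.call(rbind, lapply(parts, function(p) {
    v <- apply(p, 2L, stats::var)
    v[!is.finite(v)] <- 0
    pmax(v, var_floor)
  }))
  trans <- matrix(0.05 / k, k, k)
  diag(trans) <- 0.8
  nxt <- cbind(seq_len(k), c(seq_len(k)[-1L], 1L))
  trans[nxt] <- trans[nxt] + 0.15
  trans <- trans / rowSums(trans)
  init <- (k:1)^2
  init <- init / sum(init)

  loglik_trace <- numeric(0)
  prev <- -Inf
  for (iter in seq_len(max_iter)) {
    tr_num <- matrix(0, k, k)
    tr_den <- numeric(k)
    init_acc <- numeric(k)
    g_sum <- numeric(k)
    mu_acc <- matrix(0, k, d)
    sq_acc <- matrix(0, k, d)
    total_ll <- 0
    for (s in segments) {
      logB <- log_emissions(s, means, vars)
      fwd <- forward_pass(init, trans, logB, keep = TRUE)
      beta <- backward_pass(trans, fwd)
      gamma <- fwd$alpha * beta
      gamma <- gamma / rowSums(gamma)
      Tn <- nrow(s)
      if (Tn > 1L) for (tt in seq_len(Tn - 1L)) {
        xi <- (fwd$alpha[tt, ] %o% (fwd$B[tt + 1L, ] * beta[tt + 1L, ])) *
          trans / fwd$cvec[tt + 1L]
        tr_num <- tr_num + xi
        tr_den <- tr_den + gamma[tt, ]
      }
      init_acc <- init_acc + gamma[1L, ]
      g_sum <- g_sum + colSums(gamma)
      mu_acc <- mu_acc + t(gamma) %*% s
      sq_acc <- sq_acc + t(gamma) %*% (s^2)
      total_ll <- total_ll + fwd$loglik
    }
    loglik_trace <- c(loglik_trace, total_ll)
    if (is.finite(prev) &&
        (total_ll - prev) < tol * max(1, abs(prev))) break
    prev <- total_ll
    # --- M step -------------------------------------------------------------
    trans_new <- tr_num / pmax(tr_den, 1e-300)
    bad <- rowSums(tr_num) <= 0
    trans_new[bad, ] <- 1 / k
    trans <- trans_new / rowSums(trans_new)
    init <- init_acc / sum(init_acc)
    means <- mu_acc / pmax(g_sum, 1e-300)
    vars <- pmax(sq_acc / pmax(g_sum, 1e-300) - means^2, var_floor)
  }
  structure(list(phase = as.integer(phase), n_states = k, init = init,
                 trans = trans, means = means, vars = vars),
            class = "gait_hmm", loglik_trace = loglik_trace)
}

#' Train the four-phase model bank
#'
#' Cuts every contiguous run of each walking flag out of the labelled
#' training trials, standardises the features over all walking samples, and
#' fits one [train_phase_hmm()] per walking phase.
#'
#' @param trials list of labelled [gait_trial()]s.
#' @param n_states hidden states per phase model.
#' @param seed RNG seed (one derived seed per phase model).
#' @param window asymmetry window for feature extraction.
#' @param insole_length mid-insole COP imputation reference (mm).
#' @return an object of class `hmm_bank`: four `gait_hmm`s keyed by flag,
#'   plus the shared normalisation parameters and feature names.
#' @export
train_hmm_bank <- function(trials, n_states = 3L, seed = 1L, window = 50L,
                           insole_length = 260) {
  stopifnot(length(trials) >= 1L)
  feats <- lapply(trials, extract_features, insole_length = insole_length,
                  window = window)
  labs <- lapply(trials, function(tr) {
    if (is.null(tr$label)) stop("training trials must be labelled")
    tr$label
  })
  walking_rows <- do.call(rbind, Map(function(f, l) {
    f[l %in% WALKING, , drop = FALSE]
  }, feats, labs))
  if (!nrow(walking_rows)) stop("no walking-phase samples in training data")
  np <- feature_norm_params(walking_rows)
  segments_of <- function(flag) {
    segs <- list()
    for (i in seq_along(feats)) {
      r <- rle(labs[[i]] == flag)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (j in which(r$values)) {
        segs[[length(segs) + 1L]] <-
          normalize_features(feats[[i]][starts[j]:ends[j], , drop = FALSE],
                             np$center, np$scale)
      }
    }
    segs[vapply(segs, nrow, 1L) >= n_states]
  }
  models <- list()
  for (idx in seq_along(WALKING)) {
    flag <- WALKING[idx]
    segs <- segments_of(flag)
    if (!length(segs)) stop("no usable segments for phase ", flag)
    models[[as.character(flag)]] <-
      train_phase_hmm(segs, n_states = n_states, phase = flag,
                      seed = seed + idx)
  }
  structure(list(models = models, center = np$center, scale = np$scale,
                 features = HMM_FEATURES, window = as.integer(window),
                 insole_length = insole_length),
            class = "hmm_bank")
}

#' Classify one observation window
#'
#' Computes the forward log-likelihood of the window under each of the four
#' phase models and returns the flag of the maximising model; exact ties are
#' broken deterministically by ascending flag order (11 < 12 < 13 < 14).
#'
#' @param window raw (unnormalised) feature matrix of consecutive samples,
#'   ordinarily the current and past 9 samples (10 rows).
#' @param bank an [train_hmm_bank()] bank.
#' @return the winning walking flag (integer).
#' @export
classify_window <- function(window, bank) {
  stopifnot(inherits(bank, "hmm_bank"))
  obs <- normalize_features(rbind(window), bank$center, bank$scale)
  lls <- vapply(bank$models, hmm_loglik, numeric(1L), obs = obs)
  flags <- as.integer(names(bank$models))
  ord <- order(flags)
  flags[ord][which.max(lls[ord])]
}

#' Detect phases over a trial with the HMM bank
#'
#' Causal sliding-window application: the flag at sample `i` is
#' [classify_window()] on samples `i-9 .. i`. The first nine samples, where
#' no full 10-sample window exists yet, are emitted as `UNKNOWN` (0) rather
#' than padded.
#'
#' @param trial a [gait_trial()].
#' @param bank an [train_hmm_bank()] bank.
#' @param window_size likelihood window length in samples.
#' @return integer vector of flags, one per sample.
#' @export
detect_trial_hmm <- function(trial, bank, window_size = 10L) {
  stopifnot(inherits(bank, "hmm_bank"))
  validate_trial(trial)
  n <- nrow(trial)
  if (n == 0L) return(integer(0))
  feats <- normalize_features(
    extract_features(trial, insole_length = bank$insole_length,
                     window = bank$window),
    bank$center, bank$scale)
  flags <- as.integer(names(bank$models))
  ord <- order(flags)
  flags <- flags[ord]
  models <- bank$models[ord]
  # precompute per-model log emission densities for all samples
  logBs <- lapply(models, function(m) log_emissions(feats, m$means, m$vars))
  out <- integer(n)
  if (n < window_size) return(out)
  for (i in window_size:n) {
    idx <- (i - window_size + 1L):i
    lls <- vapply(seq_along(models), function(j) {
      log_forward(models[[j]]$init, models[[j]]$trans,
                  logBs[[j]][idx, , drop = FALSE])
    }, numeric(1L))
    out[i] <- flags[which.max(lls)]
  }
  out
}

#' Training/evaluation splits for the three verification schemes
#'
#' Mirrors the three verification designs: `intra` trains one bank per
#' subject on that subject's own first `n_train` walks; `inter` trains the
#' bank for each subject on the other subjects' training walks only
#' (excluding the verified subject); `pooled` trains a single generalised
#' bank on every subject's training walks. In every scheme a subject is
#' evaluated on its walks beyond the first `n_train`, so train and test sets
#' are disjoint.
#'
#' @param trials list of labelled [gait_trial()]s.
#' @param subjects character/integer vector of subject IDs, one per trial.
#' @param scheme `"intra"`, `"inter"` or `"pooled"`.
#' @param n_train training walks per subject.
#' @return list with one element per evaluated subject: `subject`, `train`
#'   and `test` (index vectors into `trials`).
#' @export
build_training_sets <- function(trials, subjects,
                                scheme = c("intra", "inter", "pooled"),
                                n_train = 3L) {
  scheme <- match.arg(scheme)
  stopifnot(length(subjects) == length(trials), n_train >= 1L)
  ids <- unique(subjects)
  if (scheme == "inter" && length(ids) < 2L) {
    stop("inter-subject scheme requires at least two subjects")
  }
  train_of <- function(s) {
    idx <- which(subjects == s)
    if (length(idx) <= n_train) {
      stop("subject ", s, " needs more than ", n_train,
           " walks to leave an evaluation set")
    }
    idx[seq_len(n_train)]
  }
  lapply(ids, function(s) {
    idx <- which(subjects == s)
    test <- setdiff(idx, train_of(s))
    train <- switch(scheme,
      intra = train_of(s),
      inter = unlist(lapply(setdiff(ids, s), train_of), use.names = FALSE),
      pooled = unlist(lapply(ids, train_of), use.names = FALSE)
    )
    list(subject = s, train = train, test = test)
  })
}

#' Serialise/deserialise a model bank as JSON
#'
#' The JSON schema is an object with `features`, `window`, `insole_length`,
#' `center`, `scale` and a `models` object keyed by flag, each model holding
#' `phase`, `n_states`, `init`, `trans` (row-major), `means` and `vars`
#' (state-major).
#'
#' @param bank an `hmm_bank`.
#' @param path file path.
#' @return `read_hmm_bank()` returns the bank; `write_hmm_bank()` returns
#'   `path` invisibly.
#' @export
write_hmm_bank <- function(bank, path) {
  stopifnot(inherits(bank, "hmm_bank"))
  ser <- list(features = bank$features, window = bank$window,
              insole_length = bank$insole_length,
              center = as.numeric(bank$center),
              scale = as.numeric(bank$scale),
              models = lapply(bank$models, function(m) {
                list(phase = m$phase, n_states = m$n_states,
                     init = as.numeric(m$init),
                     trans = as.numeric(t(m$trans)),
                     means = as.numeric(t(m$means)),
                     vars = as.numeric(t(m$vars)),
                     n_features = ncol(m$means))
              }))
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_hmm_bank
#' @export
read_hmm_bank <- function(path) {
  ser <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  models <- lapply(ser$models, function(m) {
    k <- m$n_states
    d <- m$n_features
    dn <- list(NULL, ser$features)
    structure(list(phase = as.integer(m$phase), n_states = as.integer(k),
                   init = as.numeric(m$init),
                   trans = matrix(m$trans, k, k, byrow = TRUE),
                   means = matrix(m$means, k, d, byrow = TRUE,
                                  dimnames = dn),
                   vars = matrix(m$vars, k, d, byrow = TRUE,
                                 dimnames = dn)),
              class = "gait_hmm")
  })
  structure(list(models = models,
                 center = stats::setNames(as.numeric(ser$center),
                                          ser$features),
                 scale = stats::setNames(as.numeric(ser$scale),
                                         ser$features),
                 features = ser$features, window = as.integer(ser$window),
                 insole_length = ser$insole_length),
            class = "hmm_bank")
}

#' @export
print.gait_hmm <- function(x, ...) {
  cat(sprintf("<gait_hmm> phase %d, %d states, %d features\n",
              x$phase, x$n_states, ncol(x$means)))
  invisible(x)
}

#' @export
print.hmm_bank <- function(x, ...) {
  cat(sprintf("<hmm_bank> phases %s, %d features, window %d\n",
              paste(names(x$models), collapse = "/"),
              length(x$features), x$window))
  invisible(x)
}
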