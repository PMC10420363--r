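# Shared fixtures and independent oracles. Everything is generated in code;
# expensive simulated objects are memoized per test run.

.fixture_env <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, force(expr), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# A hand-built minimal trial: constant markers except a linear AP ramp on
# the ankles (so walking speed is well-defined), with optional events.
flat_trial <- function(T = 100L, fs = 150, events = gait_events(),
                       speed_mps = 0) {
  ramp <- (seq_len(T) - 1L) * speed_mps * 1000 / fs
  mk <- function(ap0, ml, v, ramped = FALSE) {
    cbind(AP = ap0 + if (ramped) ramp else rep(0, T),
          ML = rep(ml, T), V = rep(v, T))
  }
  gait_trial(
    list(L_HEEL = mk(0, 80, 25, TRUE), L_TOE = mk(160, 80, 15, TRUE),
         L_ANKLE = mk(30, 80, 70, TRUE), R_HEEL = mk(0, -80, 25, TRUE),
         R_TOE = mk(160, -80, 15, TRUE), R_ANKLE = mk(30, -80, 70, TRUE)),
    fs = fs, events = events, trial_id = "flat", subject_id = "subj-flat"
  )
}

# Short, fast profiles for unit tests (4 s at 150 Hz, ~4 cycles).
quick_profile <- function(name = "quick", strike = "HEEL", noise = 0, ...) {
  gait_profile(name, walking_speed = 1.2, cadence = 120,
               strike_pattern = strike,
               heel_toe_offset_ms = if (strike == "FOREFOOT") -60 else
                 if (strike == "MIDFOOT") 0 else 60,
               noise_sd_mm = noise, duration_s = 4, ...)
}

mirror_trial <- function(trial) {
  trial$markers <- lapply(trial$markers, function(m) {
    m[, "AP"] <- -m[, "AP"]
    m
  })
  trial
}

# ---- oracle: exhaustive one-to-one event assignment -----------------------
# Considers every injective truth->prediction matching within the window
# (all 2^m prediction subsets, including crossing matchings), maximizing
# matched count then minimizing total |error|. Returns the optimal
# (count, total_error). Independent of the package's sorted-stream DP.
brute_match_value <- function(truth, pred, window) {
  n <- length(truth)
  m <- length(pred)
  stopifnot(m <= 16)
  BIG <- 1e7
  n_mask <- bitwShiftL(1L, m)
  masks <- 0:(n_mask - 1L)
  f_next <- numeric(n_mask)                  # value for truths > i
  if (n > 0) {
    for (i in n:1) {
      f_i <- f_next                          # leave truth i unmatched
      for (j in seq_len(m)) {
        d <- abs(truth[i] - pred[j])
        if (d > window) next
        bit <- bitwShiftL(1L, j - 1L)
        idx <- which(bitwAnd(masks, bit) != 0L)
        cand <- f_next[bitwXor(masks[idx], bit) + 1L] + BIG - d
        f_i[idx] <- pmax(f_i[idx], cand)
      }
      f_next <- f_i
    }
  }
  v <- f_next[n_mask]
  count <- round(v / BIG)
  c(count, count * BIG - v)
}

# ---- oracle: exhaustive peak-subset enumeration ---------------------------
# All subsets of candidate peaks respecting the separation, maximizing kept
# probability mass. DFS keeps the enumeration linear in the number of valid
# subsets.
brute_peaks_value <- function(frames, heights, sep) {
  k <- length(frames)
  best <- 0
  rec <- function(i, last_frame, mass) {
    if (i > k) {
      best <<- max(best, mass)
      return(invisible())
    }
    rec(i + 1L, last_frame, mass)
    if (is.na(last_frame) || frames[i] - last_frame >= sep) {
      rec(i + 1L, frames[i], mass + heights[i])
    }
  }
  rec(1L, NA_integer_, 0)
  best
}

# Candidate local maxima of a numeric vector above a threshold (1-based),
# plateau ties to the first frame; independent re-statement of the
# definition used for the oracle comparisons.
oracle_local_maxima <- function(x, threshold) {
  out <- integer(0)
  n <- length(x)
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && x[j + 1L] == x[i]) j <- j + 1L
    left <- if (i == 1L) -Inf else x[i - 1L]
    right <- if (j == n) -Inf else x[j + 1L]
    if (x[i] > left && x[i] > right && x[i] > threshold && !(i == 1L && j == n)) {
      out <- c(out, i)
    }
    i <- j + 1L
  }
  out
}

# Total probability mass kept by a detect_events() result for one class.
kept_mass <- function(events, side, probs, col) {
  sum(probs[events$frame[events$side == side] + 1L, col])
}

# Standard reduced cohort for detector tests: mixed strike patterns,
# 2 mm marker noise.
mixed_cohort <- function(n_subjects, trials_per_subject, seed,
                         duration_s = 8) {
  profs <- preset_profiles()
  hc <- profs[["HC-heel"]]; icp <- profs[["ICP-forefoot"]]
  hc$duration_s <- duration_s; icp$duration_s <- duration_s
  simulate_cohort(cohort_spec(list(
    list(profile = hc, n_subjects = n_subjects,
         trials_per_subject = trials_per_subject),
    list(profile = icp, n_subjects = n_subjects,
         trials_per_subject = trials_per_subject)
  ), seed = seed))
}
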