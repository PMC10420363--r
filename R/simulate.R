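#' Parametric gait profile for the synthetic simulator
#'
#' A profile describes one walking persona: overall speed and cadence, the
#' stance/swing split, cycle-to-cycle step-length variability, the
#' foot-strike pattern (heel, forefoot or midfoot first), the delay between
#' heel and toe ground contact, swing-phase foot drag and marker noise.
#' Profiles are test personas emulating the structure of clinical gait,
#' not biomechanical models of specific pathologies.
#'
#' @param name profile name; simulated trials carry pathology
#'   `SYNTH-<name>`.
#' @param walking_speed mean progression speed in m/s (> 0).
#' @param cadence steps per minute (> 0); one gait cycle is two steps.
#' @param stance_fraction fraction of the gait cycle spent in stance, in
#'   (0.4, 0.8).
#' @param step_length_cv coefficient of variation of stride length across
#'   cycles (>= 0).
#' @param strike_pattern `"HEEL"`, `"FOREFOOT"` or `"MIDFOOT"`: which marker
#'   touches down first at initial contact.
#' @param heel_toe_offset_ms signed delay between heel and toe ground
#'   contact; positive means heel first (required for HEEL, non-positive for
#'   FOREFOOT).
#' @param drag_severity in \[0, 1\]; scales down swing toe clearance to mimic
#'   foot drag.
#' @param noise_sd_mm standard deviation of additive white Gaussian marker
#'   noise (>= 0).
#' @param duration_s trial length in seconds (> 0).
#' @param fs sampling rate in Hz; 150 matches the clinical capture setup.
#' @return object of class `gait_profile`.
#' @export
gait_profile <- function(name,
                         walking_speed = 1.25,
                         cadence = 112,
                         stance_fraction = 0.62,
                         step_length_cv = 0.02,
                         strike_pattern = c("HEEL", "FOREFOOT", "MIDFOOT"),
                         heel_toe_offset_ms = 60,
                         drag_severity = 0,
                         noise_sd_mm = 2,
                         duration_s = 8,
                         fs = 150) {
  strike_pattern <- match.arg(strike_pattern)
  p <- structure(list(
    name = as.character(name), walking_speed = walking_speed,
    cadence = cadence, stance_fraction = stance_fraction,
    step_length_cv = step_length_cv, strike_pattern = strike_pattern,
    heel_toe_offset_ms = heel_toe_offset_ms, drag_severity = drag_severity,
    noise_sd_mm = noise_sd_mm, duration_s = duration_s, fs = fs
  ), class = "gait_profile")
  validate_profile(p)
  p
}

validate_profile <- function(p) {
  stopifnot_msg(p$walking_speed > 0, "walking_speed must be > 0")
  stopifnot_msg(p$cadence > 0, "cadence must be > 0")
  stopifnot_msg(p$stance_fraction > 0.4 && p$stance_fraction < 0.8,
                "stance_fraction must be in (0.4, 0.8)")
  stopifnot_msg(p$step_length_cv >= 0, "step_length_cv must be >= 0")
  stopifnot_msg(p$drag_severity >= 0 && p$drag_severity <= 1,
                "drag_severity must be in [0, 1]")
  stopifnot_msg(p$noise_sd_mm >= 0, "noise_sd_mm must be >= 0")
  stopifnot_msg(p$duration_s > 0 && p$fs > 0, "duration_s and fs must be > 0")
  if (p$strike_pattern == "HEEL" && p$heel_toe_offset_ms < 0) {
    stop_fmt("HEEL strike requires heel_toe_offset_ms >= 0")
  }
  if (p$strike_pattern == "FOREFOOT" && p$heel_toe_offset_ms > 0) {
    stop_fmt("FOREFOOT strike requires heel_toe_offset_ms <= 0")
  }
  invisible(p)
}

stopifnot_msg <- function(ok, msg) if (!isTRUE(ok)) stop_fmt("%s", msg)

#' Shipped simulator presets
#'
#' Five personas covering the structural variety the detectors must cope
#' with: a brisk heel-striking control, a forefoot striker, a forefoot
#' striker with pronounced foot drag, a short-stride fast-cadence walker and
#' an unremarkable baseline. The names echo clinical class abbreviations
#' only as mnemonics.
#'
#' @return named list of `gait_profile` objects.
#' @export
preset_profiles <- function() {
  list(
    "HC-heel" = gait_profile("HC-heel", walking_speed = 1.25, cadence = 112,
                             strike_pattern = "HEEL", heel_toe_offset_ms = 60),
    "ICP-forefoot" = gait_profile("ICP-forefoot", walking_speed = 0.95, cadence = 120,
                                  stance_fraction = 0.6, step_length_cv = 0.05,
                                  strike_pattern = "FOREFOOT", heel_toe_offset_ms = -60,
                                  drag_severity = 0.2),
    "DF-forefoot-drag" = gait_profile("DF-forefoot-drag", walking_speed = 1.0, cadence = 108,
                                      stance_fraction = 0.6, step_length_cv = 0.04,
                                      strike_pattern = "FOREFOOT", heel_toe_offset_ms = -60,
                                      drag_severity = 0.6),
    "CF-short-stride" = gait_profile("CF-short-stride", walking_speed = 0.85, cadence = 128,
                                     stance_fraction = 0.63, step_length_cv = 0.06,
                                     strike_pattern = "HEEL", heel_toe_offset_ms = 40,
                                     drag_severity = 0.1),
    "MD-baseline" = gait_profile("MD-baseline", walking_speed = 1.15, cadence = 114,
                                 step_length_cv = 0.03,
                                 strike_pattern = "HEEL", heel_toe_offset_ms = 50)
  )
}

## Geometry constants (mm): marker ground offsets and foot dimensions.
## Conventions of the simulator, not anatomical claims.
SIM_GEOM <- list(
  heel_offset = 25, toe_offset = 15, ankle_offset = 70,
  foot_length = 160,          # AP distance heel -> toe marker
  ankle_back = 30,            # ankle marker AP lead over heel
  ml_half_width = 80,         # lateral distance of each foot from midline
  heel_clearance = 110,       # peak swing heel lift (above ground offset)
  toe_clearance = 35,         # peak swing toe lift before drag scaling
  heel_off_fraction = 0.65    # heel leaves ground at this fraction of stance
)

## Smooth swing interpolants. Phase s in [0,1]; both are C1 with zero
## derivative at s = 1 (gentle landing). The AP advance uses a Beta(1.5, 3)
## CDF: velocity rises steeply just after lift-off (the push-off signature
## that velocity-threshold heuristics key on) and decays smoothly into
## touchdown.
swing_advance <- function(s) stats::pbeta(s, 1.5, 3)
swing_lift <- function(s) sin(pi * s)^2

#' Simulate one walking trial
#'
#' Builds six marker trajectories from a per-foot cyclic phase schedule.
#' During stance a foot's markers are ground-fixed; during swing the foot
#' advances by one stride along a smooth arc with a vertical clearance bump
#' (scaled down by `drag_severity` for the toe). Feet are anti-phased. The
#' strike-leading marker (heel for HEEL, toe for FOREFOOT, both for
#' MIDFOOT) defines initial contact; foot off is the first frame after the
#' toe's last stance frame. Ground-truth events are therefore known by
#' construction and attached with source `"TRUTH"`. Stride-length jitter
#' and additive marker noise are drawn from a generator derived from
#' `seed`, so identical `(profile, seed)` yields a bitwise identical trial.
#'
#' @param profile a [gait_profile()].
#' @param subject_id,trial_id identifiers stored on the trial.
#' @param seed integer seed for this trial's randomness.
#' @return a `gait_trial` with pathology `SYNTH-<profile name>`.
#' @export
simulate_trial <- function(profile, subject_id = "S01", trial_id = "S01-T01",
                           seed = 1L) {
  validate_profile(profile)
  p <- profile
  cycle_t <- 120 / p$cadence            # seconds per gait cycle (2 steps)
  if (p$duration_s < 2 * cycle_t) {
    stop_fmt("duration_s %.2f allows fewer than 2 full gait cycles (cycle %.2f s)",
             p$duration_s, cycle_t)
  }
  fs <- p$fs
  T_ <- as.integer(round(p$duration_s * fs))
  tt <- (seq_len(T_) - 1L) / fs
  stride <- p$walking_speed * cycle_t * 1000   # mm per cycle

  with_seed(derive_seed(seed, "trial", subject_id, trial_id), {
    feet <- list(
      L = sim_foot_schedule(p, cycle_t, stride, start = 0.25, fs = fs),
      R = sim_foot_schedule(p, cycle_t, stride, start = 0.25 + cycle_t / 2, fs = fs)
    )
    markers <- list()
    ev_list <- list()
    for (side in c("L", "R")) {
      sched <- feet[[side]]
      ml <- if (side == "L") SIM_GEOM$ml_half_width else -SIM_GEOM$ml_half_width
      heel <- sim_marker_track(tt, sched$heel, SIM_GEOM$heel_offset,
                               SIM_GEOM$heel_clearance, ml)
      toe_clear <- SIM_GEOM$toe_clearance * (1 - 0.9 * p$drag_severity)
      toe <- sim_marker_track(tt, sched$toe, SIM_GEOM$toe_offset, toe_clear, ml)
      ankle <- heel
      ankle[, "AP"] <- heel[, "AP"] + SIM_GEOM$ankle_back
      ankle[, "V"] <- heel[, "V"] + (SIM_GEOM$ankle_offset - SIM_GEOM$heel_offset)
      markers[[paste0(side, "_HEEL")]] <- heel
      markers[[paste0(side, "_TOE")]] <- toe
      markers[[paste0(side, "_ANKLE")]] <- ankle

      ic <- sched$ic_frames
      fo <- sched$fo_frames
      ic <- ic[ic >= 0L & ic < T_]
      fo <- fo[fo >= 0L & fo < T_]
      ev_list[[side]] <- data.frame(
        etype = c(rep("IC", length(ic)), rep("FO", length(fo))),
        side = side,
        frame = c(ic, fo),
        source = "TRUTH", stringsAsFactors = FALSE
      )
    }
    if (p$noise_sd_mm > 0) {
      markers <- lapply(markers, function(m) {
        m + matrix(stats::rnorm(length(m), 0, p$noise_sd_mm), nrow(m), 3L)
      })
    }
    ev <- do.call(rbind, ev_list)
    gait_trial(markers[MARKER_NAMES], fs = fs,
               events = gait_events(ev$etype, ev$side, ev$frame, ev$source),
               trial_id = trial_id, subject_id = subject_id,
               pathology = paste0("SYNTH-", p$name))
  })
}

## Build per-marker contact schedules for one foot. Contact times are
## snapped to the frame grid so ground truth is exact in frames. Returns
## heel/toe schedules (touchdown, liftoff, stance AP position per cycle)
## and the IC/FO frames.
sim_foot_schedule <- function(p, cycle_t, stride, start, fs) {
  dur <- p$duration_s
  n_cycles <- ceiling((dur + 2 * cycle_t - start) / cycle_t) + 1L
  lead_td <- start + (seq_len(n_cycles) - 1L) * cycle_t - cycle_t  # lead marker touchdowns
  strides <- stride * (1 + p$step_length_cv * stats::rnorm(n_cycles))
  strides <- pmax(strides, 0.1 * stride)
  # stance AP position of the heel marker for each cycle
  heel_x <- cumsum(c(0, strides[-n_cycles])) - stride
  stance_dur <- p$stance_fraction * cycle_t
  off_s <- p$heel_toe_offset_ms / 1000

  snap <- function(t) round(t * fs) / fs
  lead_td <- snap(lead_td)
  if (p$strike_pattern == "HEEL") {
    heel_td <- lead_td
    toe_td <- snap(lead_td + off_s)
  } else if (p$strike_pattern == "FOREFOOT") {
    toe_td <- lead_td
    heel_td <- snap(lead_td - off_s)   # off_s <= 0, heel lands later
  } else {
    heel_td <- lead_td
    toe_td <- lead_td
  }
  heel_lo <- snap(lead_td + SIM_GEOM$heel_off_fraction * stance_dur)
  toe_lo <- snap(lead_td + stance_dur)
  heel_lo <- pmax(heel_lo, heel_td + 2 / fs)
  toe_lo <- pmax(toe_lo, toe_td + 2 / fs)

  list(
    heel = list(td = heel_td, lo = heel_lo, x = heel_x),
    toe = list(td = toe_td, lo = toe_lo, x = heel_x + SIM_GEOM$foot_length),
    ic_frames = as.integer(round(lead_td * fs)),
    fo_frames = as.integer(round(toe_lo * fs))
  )
}

## Piecewise trajectory of one marker from its contact schedule.
## Stance [td_k, lo_k): fixed at (x_k, ground offset). Swing [lo_k, td_{k+1}):
## smooth AP advance and vertical clearance arc.
sim_marker_track <- function(tt, sched, ground_offset, clearance, ml) {
  n_cycles <- length(sched$td)
  ap <- numeric(length(tt))
  v <- numeric(length(tt))
  # before the first liftoff: stance at x_1
  idx <- tt < sched$lo[1L]
  ap[idx] <- sched$x[1L]
  v[idx] <- ground_offset
  for (k in seq_len(n_cycles - 1L)) {
    sw <- tt >= sched$lo[k] & tt < sched$td[k + 1L]
    if (any(sw)) {
      s <- (tt[sw] - sched$lo[k]) / (sched$td[k + 1L] - sched$lo[k])
      ap[sw] <- sched$x[k] + (sched$x[k + 1L] - sched$x[k]) * swing_advance(s)
      v[sw] <- ground_offset + clearance * swing_lift(s)
    }
    st <- tt >= sched$td[k + 1L] &
      (if (k + 1L < n_cycles) tt < sched$lo[k + 1L] else TRUE)
    if (any(st)) {
      ap[st] <- sched$x[k + 1L]
      v[st] <- ground_offset
    }
  }
  cbind(AP = ap, ML = rep(ml, length(tt)), V = v)
}

#' Cohort specification for the simulator
#'
#' @param profiles list of entries `list(profile = <gait_profile>,
#'   n_subjects = <int>, trials_per_subject = <int>)`.
#' @param seed integer master seed; all subject jitter and trial noise
#'   derive from it.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(profiles, seed = 1L) {
  nms <- vapply(profiles, function(e) e$profile$name, "")
  if (anyDuplicated(nms)) stop_fmt("duplicate profile name '%s'", nms[duplicated(nms)][1L])
  for (e in profiles) {
    stopifnot_msg(e$n_subjects >= 1, "n_subjects must be >= 1")
    stopifnot_msg(e$trials_per_subject >= 1, "trials_per_subject must be >= 1")
  }
  structure(list(profiles = profiles, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Simulate a cohort of subjects
#'
#' Generates `n_subjects * trials_per_subject` trials per profile. Each
#' subject receives a small multiplicative jitter (3% SD) of walking speed
#' and cadence so subjects are distinguishable; each trial then draws its
#' own stride jitter and marker noise. Fully deterministic given
#' `spec$seed`.
#'
#' @param spec a [cohort_spec()].
#' @return a `gait_dataset` (unpartitioned).
#' @export
simulate_cohort <- function(spec) {
  trials <- list()
  for (e in spec$profiles) {
    p <- e$profile
    for (i in seq_len(e$n_subjects)) {
      sid <- sprintf("%s-S%02d", p$name, i)
      jit <- with_seed(derive_seed(spec$seed, "subject", sid),
                       1 + 0.03 * stats::rnorm(2))
      pj <- p
      pj$walking_speed <- p$walking_speed * max(jit[1L], 0.5)
      pj$cadence <- p$cadence * max(jit[2L], 0.5)
      for (j in seq_len(e$trials_per_subject)) {
        tid <- sprintf("%s-T%02d", sid, j)
        trials[[tid]] <- simulate_trial(pj, subject_id = sid, trial_id = tid,
                                        seed = derive_seed(spec$seed, "noise", tid))
      }
    }
  }
  gait_dataset(trials)
}
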