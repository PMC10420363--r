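test_that("IC count over both feet matches the commanded cadence", {
  p <- gait_profile("cad", cadence = 110, duration_s = 8, noise_sd_mm = 0)
  tr <- simulate_trial(p, seed = 1)
  # 110 steps/min for 8 s ~ 14.7 initial contacts across both feet
  expect_true(sum(tr$events$etype == "IC") %in% c(14L, 15L))
})

test_that("noise-free heel stance is exactly ground-fixed", {
  tr <- cached("heel_trial", simulate_trial(quick_profile(), seed = 2))
  for (side in c("L", "R")) {
    ic <- trial_events(tr, etype = "IC", side = side)$frame
    fo <- trial_events(tr, etype = "FO", side = side)$frame
    heel <- tr$markers[[paste0(side, "_HEEL")]]
    for (k in seq_along(ic)) {
      nxt <- fo[fo > ic[k]]
      if (length(nxt) == 0L) next
      # heel is fixed from IC until at least half of stance
      span <- ic[k]:floor((ic[k] + nxt[1]) / 2) + 1L
      expect_equal(diff(range(heel[span, "V"])), 0)
      expect_equal(diff(range(heel[span, "AP"])), 0)
    }
  }
})

test_that("simulation is bitwise deterministic in (profile, seed)", {
  p <- quick_profile(noise = 2)
  t1 <- simulate_trial(p, seed = 9)
  t2 <- simulate_trial(p, seed = 9)
  expect_identical(t1, t2)
  t3 <- simulate_trial(p, seed = 10)
  expect_false(identical(t1$markers, t3$markers))
})

test_that("too-short trials are rejected", {
  expect_error(gait_profile("short", cadence = 100, duration_s = 2) |>
                 simulate_trial(seed = 1), "2 full gait cycles")
})

test_that("cohorts have the right shape and valid trials", {
  ds <- cached("unit_cohort", {
    p1 <- quick_profile("a"); p2 <- quick_profile("b", strike = "FOREFOOT")
    simulate_cohort(cohort_spec(list(
      list(profile = p1, n_subjects = 3, trials_per_subject = 2),
      list(profile = p2, n_subjects = 3, trials_per_subject = 2)
    ), seed = 4))
  })
  expect_length(ds$trials, 12L)
  expect_length(unique(vapply(ds$trials, function(t) t$subject_id, "")), 6L)
  for (tr in ds$trials) {
    expect_silent(validate_trial(tr))
    expect_gte(sum(tr$events$source == "TRUTH"), 4L)
  }
  # determinism of the whole cohort
  ds2 <- {
    p1 <- quick_profile("a"); p2 <- quick_profile("b", strike = "FOREFOOT")
    simulate_cohort(cohort_spec(list(
      list(profile = p1, n_subjects = 3, trials_per_subject = 2),
      list(profile = p2, n_subjects = 3, trials_per_subject = 2)
    ), seed = 4))
  }
  expect_identical(ds$trials, ds2$trials)
  expect_error(simulate_cohort(cohort_spec(list(
    list(profile = quick_profile("a"), n_subjects = 1, trials_per_subject = 1),
    list(profile = quick_profile("a"), n_subjects = 1, trials_per_subject = 1)
  ), seed = 1)), "duplicate profile")
})

test_that("simulator speed calibration holds within 5% at zero noise", {
  for (speed in c(0.9, 1.25)) {
    p <- gait_profile("cal", walking_speed = speed, noise_sd_mm = 0,
                      step_length_cv = 0)
    tr <- simulate_trial(p, seed = 5)
    expect_lt(abs(walking_speed(tr) - speed) / speed, 0.05)
  }
})

test_that("IC and FO alternate per foot: IC(k) < FO(k) < IC(k+1)", {
  trs <- list(cached("heel_trial", simulate_trial(quick_profile(), seed = 2)),
              simulate_trial(quick_profile("ff", strike = "FOREFOOT"), seed = 6))
  for (tr in trs) {
    for (side in c("L", "R")) {
      ev <- trial_events(tr, side = side)
      # drop a leading FO (trial may start mid-cycle)
      if (ev$etype[1] == "FO") ev <- ev[-1, ]
      expect_true(all(ev$etype == rep_len(c("IC", "FO"), nrow(ev))))
      expect_true(all(diff(ev$frame) > 0))
    }
  }
})

test_that("forefoot IC: toe velocity settles while the heel still descends", {
  p <- gait_profile("ff", strike_pattern = "FOREFOOT", heel_toe_offset_ms = -60,
                    noise_sd_mm = 0)
  tr <- simulate_trial(p, seed = 7)
  ic <- trial_events(tr, etype = "IC", side = "L")$frame
  ic <- ic[ic > 10 & ic < n_frames(tr) - 20]
  toe_v <- compute_velocity(tr$markers$L_TOE, tr$fs)[, "V"]
  heel_v <- compute_velocity(tr$markers$L_HEEL, tr$fs)[, "V"]
  for (f in ic) {
    expect_lt(abs(toe_v[f + 2L]), 30)   # toe vertically at rest just after IC (mm/s)
    expect_lt(heel_v[f + 1L], -10)      # heel still descending at IC
  }
})

test_that("drag severity lowers swing toe clearance", {
  base <- simulate_trial(quick_profile("nodrag"), seed = 8)
  dragged <- simulate_trial(quick_profile("drag", drag_severity = 0.8), seed = 8)
  clearance <- function(tr) max(tr$markers$L_TOE[, "V"]) - 15
  expect_lt(clearance(dragged), 0.4 * clearance(base))
})
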