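test_that("velocity is exact for linear motion and zero for rest", {
  T_ <- 60L
  ramp <- cbind(10 * (seq_len(T_) - 1L), rep(0, T_), rep(3, T_))
  v <- compute_velocity(ramp, fs = 150)
  expect_equal(unname(v[, 1]), rep(1500, T_))   # 10 mm/frame at 150 Hz
  expect_equal(unname(v[, 2]), rep(0, T_))
  expect_equal(unname(v[, 3]), rep(0, T_))
  expect_error(compute_velocity(ramp[1, , drop = FALSE], 150), "at least 2")
})

test_that("velocity approximates the analytic derivative of a sinusoid", {
  fs <- 150
  t <- seq(0, 3, by = 1 / fs)
  x <- cbind(20 * sin(2 * pi * 1.0 * t), 0 * t, 0 * t)
  v <- compute_velocity(x, fs)
  analytic <- 20 * 2 * pi * cos(2 * pi * t)
  interior <- 2:(length(t) - 1L)
  expect_lt(max(abs(v[interior, 1] - analytic[interior])), 0.01 * 20 * 2 * pi)
})

test_that("assemble_features yields the fixed 36-channel layout", {
  tr <- cached("heel_trial", simulate_trial(quick_profile(), seed = 2))
  ft <- assemble_features(tr)
  expect_equal(ncol(ft$values), 36L)
  expect_equal(ft$channel_names[1], "L_HEEL.pos.AP")
  expect_equal(ft$channel_names[4], "L_HEEL.vel.AP")
  expect_equal(ft$channel_names[36], "R_ANKLE.vel.V")
  expect_true(all(ft$mask))
  broken <- tr
  broken$markers$R_TOE <- NULL
  expect_error(assemble_features(broken), "missing marker R_TOE")
})

test_that("crop keeps the first event within the commanded buffer", {
  ev <- gait_events(c("IC", "FO"), c("L", "L"), c(300L, 400L))
  tr <- flat_trial(600L, events = ev)
  for (s in 1:5) {
    set.seed(s)
    cr <- crop_with_buffer(tr)
    first <- min(cr$events$frame)
    expect_gte(first, 25L)
    expect_lte(first, 125L)
    last_gap <- n_frames(cr) - 1L - max(cr$events$frame)
    expect_gte(last_gap, 25L)
    expect_lte(last_gap, 125L)
  }
  # clamping at the trial start
  tr2 <- flat_trial(600L, events = gait_events("IC", "L", 10L))
  set.seed(1)
  cr2 <- crop_with_buffer(tr2)
  expect_equal(cr2$events$frame, 10L)
  # reproducibility under a fixed seed
  a <- with(list(), {set.seed(33); crop_with_buffer(tr)})
  b <- with(list(), {set.seed(33); crop_with_buffer(tr)})
  expect_identical(a, b)
  expect_error(crop_with_buffer(flat_trial(50L)), "no TRUTH events")
})

test_that("normalization maps each channel onto [0.1, 1.1]", {
  expect_equal(unname(normalize_features(matrix(c(0, 5, 10), 3, 1))[, 1]),
               c(0.1, 0.6, 1.1))
  expect_equal(unname(normalize_features(matrix(7, 3, 1))[, 1]),
               rep(0.1, 3))
  m <- matrix(rnorm(200), 50, 4)
  nm <- normalize_features(m)
  expect_equal(unname(apply(nm, 2, min)), rep(0.1, 4))
  expect_equal(unname(apply(nm, 2, max)), rep(1.1, 4))
  # idempotence on non-constant channels
  expect_equal(normalize_features(nm), nm)
  # masked frames stay zero and are excluded from the statistics
  mask <- rep(c(TRUE, FALSE), c(30, 20))
  nm2 <- normalize_features(m, mask)
  expect_true(all(nm2[!mask, ] == 0))
  expect_equal(unname(apply(nm2[mask, ], 2, max)), rep(1.1, 4))
  expect_error(normalize_features(matrix(c(1, NA), 2, 1)), "non-finite")
})

test_that("labels are single-frame and event-type specific", {
  ev <- gait_events(c("IC", "IC", "FO"), c("L", "R", "L"), c(10L, 50L, 30L))
  tr <- flat_trial(100L, events = ev)
  lab <- make_labels(tr, "IC")
  expect_equal(lab$classes[11L], 1L)
  expect_equal(lab$classes[51L], 2L)
  expect_equal(sum(lab$classes != 0L), 2L)
  # FO labels ignore IC events and vice versa
  lab_fo <- make_labels(tr, "FO")
  expect_equal(which(lab_fo$classes != 0L), 31L)
  tr_fo_only <- flat_trial(100L, events = gait_events("FO", "L", 30L))
  expect_true(all(make_labels(tr_fo_only, "IC")$classes == 0L))
})

test_that("sample weights honour the 1:w ratio and padding", {
  tr <- flat_trial(100L, events = gait_events("IC", "L", 42L))
  lab <- make_sample_weights(make_labels(tr, "IC"), ratio = 10)
  expect_equal(sum(lab$weights), 99 + 10)
  lab1 <- make_sample_weights(make_labels(tr, "IC"), ratio = 1)
  expect_true(all(lab1$weights == 1))
  mask <- rep(c(TRUE, FALSE), c(80, 20))
  labm <- make_sample_weights(make_labels(tr, "IC"), ratio = 10, mask = mask)
  expect_true(all(labm$weights[81:100] == 0))
  expect_error(make_sample_weights(lab, ratio = 0.5), ">= 1")
})

test_that("pad_batch right-pads to the longest trial", {
  mk <- function(T_, frame) {
    tr <- flat_trial(T_, events = gait_events("IC", "L", frame))
    list(tensor = normalize_features(assemble_features(tr)),
         labels = make_sample_weights(make_labels(tr, "IC"), 10))
  }
  a <- mk(50L, 20L); b <- mk(70L, 30L)
  batch <- pad_batch(list(a$tensor, b$tensor), list(a$labels, b$labels))
  expect_equal(dim(batch$values), c(2L, 70L, 36L))
  expect_true(all(batch$values[1, 51:70, ] == 0))
  expect_false(any(batch$mask[1, 51:70]))
  expect_equal(unname(rowSums(batch$mask)), c(50L, 70L))
  expect_true(all(batch$weights[1, 51:70] == 0))
  single <- pad_batch(list(a$tensor), list(a$labels))
  expect_equal(matrix(single$values[1, , ], 50L), unname(a$tensor$values))
  bad <- b$tensor
  bad$channel_names <- rev(bad$channel_names)
  expect_error(pad_batch(list(a$tensor, bad), list(a$labels, b$labels)),
               "channel order")
})

test_that("resampling rescales the grid and remaps events by time", {
  ev <- gait_events("IC", "L", 150L)
  tr <- flat_trial(450L, events = ev, speed_mps = 1.2)
  rs <- resample_trial(tr, 100)
  expect_equal(n_frames(rs), 300L)
  expect_equal(rs$fs, 100)
  expect_equal(rs$events$frame, 100L)
  same <- resample_trial(tr, 150)
  expect_equal(n_frames(same), 450L)
  expect_equal(same$events, tr$events)
  expect_equal(same$markers$L_HEEL, tr$markers$L_HEEL, tolerance = 1e-10)
  expect_error(resample_trial(tr, 0.1), "fewer than 2")
})

test_that("the crop/assemble/normalize/pad pipeline keeps events aligned", {
  tr <- cached("heel_trial", simulate_trial(quick_profile(), seed = 2))
  batch <- prepare_batch(list(tr), "IC", seed = 21)
  len <- batch$lengths[1]
  classes <- batch$classes[1, seq_len(len)]
  # at every labelled left-IC frame the left heel is at its stance height,
  # i.e. the normalized heel V channel sits at its per-trial minimum 0.1
  heel_v_col <- which(assemble_features(tr)$channel_names == "L_HEEL.pos.V")
  vals <- batch$values[1, seq_len(len), heel_v_col]
  expect_true(all(abs(vals[classes == 1L] - 0.1) < 1e-6))
})
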