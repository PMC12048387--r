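test_that("torque labels follow the lever-arm model", {
  sub <- subject_params()
  expect_equal(sub$foot_weight, 10.98)
  expect_equal(sub$shank_length, 0.47)
  expect_equal(torque_label(sub, 58.8, 90), 32.80, tolerance = 1e-3)
  expect_equal(torque_label(sub, 0, 20), 1.765, tolerance = 1e-3)
  expect_equal(torque_label(sub, 123, 0), 0)
  expect_error(torque_label(sub, -1, 45), "non-negative")
  expect_error(torque_label(sub, 1, 190), "angle")
  expect_error(subject_params(shank_length = -0.5))
})

test_that("the default condition grid has nine distinct torque classes", {
  cond <- motion_conditions()
  expect_equal(nrow(cond), 9)
  expect_equal(length(unique(cond$torque)), 9)
  expect_equal(sort(cond$class), 0:8)
  expect_equal(max(cond$torque), 32.7966, tolerance = 1e-4)
  # duplicated torques make the class map ill-defined
  expect_error(motion_conditions(loads = c(0, 0, 58.8)), "duplicate")
})

test_that("standard compression test reproduces the bench calibration", {
  cal <- generator_calibration()
  w <- simulate_standard_test(cal, 2, 11.5, n_cycles = 5, noise = FALSE)
  expect_s3_class(w, "waveform")
  expect_equal(length(w$samples), 2500)
  pk <- cycle_peaks(w, 2)
  expect_equal(length(pk), 5)
  expect_equal(unname(pk), rep(5.76, 5), tolerance = 1e-6)
  # voltage returns to baseline after unloading
  expect_lt(abs(w$samples[length(w$samples)]), 1e-9)
  # frequency attenuation matches the printed sweep
  w10 <- simulate_standard_test(cal, 10, 11.5, noise = FALSE)
  expect_equal(max(w10$samples) / max(w$samples), 3.89 / 5.76, tolerance = 1e-3)
  # zero force, noise off: flat trace
  expect_equal(max(abs(simulate_standard_test(cal, 2, 0, noise = FALSE)$samples)), 0)
  expect_error(simulate_standard_test(cal, 600, 1, fs = 1000), "Nyquist")
})

test_that("peak voltage is linear in force with slope equal to the sensitivity", {
  cal <- generator_calibration()
  forces <- seq(2, 12, by = 2)
  peaks <- vapply(forces, function(f)
    max(simulate_standard_test(cal, 2, f, noise = FALSE)$samples), numeric(1))
  fit <- suppressWarnings(estimate_sensitivity(forces, peaks))  # exact line
  expect_equal(fit$slope, cal$sensitivity, tolerance = 1e-9)
  expect_equal(fit$intercept, 0, tolerance = 1e-9)
})

test_that("attenuation is non-increasing over the calibrated band", {
  cal <- generator_calibration()
  g <- attenuation(cal, seq(2, 10, by = 0.25))
  expect_true(all(diff(g) <= 1e-12))
  expect_equal(attenuation(cal, 2), 1)
  # clamped outside the tabulated range
  expect_equal(attenuation(cal, 1), 1)
  expect_equal(attenuation(cal, 15), 3.89 / 5.76)
  expect_error(generator_calibration(atten = c(1, 1.2, 0.9, 0.8)),
               "non-increasing")
})

test_that("sessions place one pulse per event and respect the schedule", {
  cond <- motion_conditions()
  sch <- regular_schedule(cond, 100, interval = 3)
  ses <- simulate_session(subject_params(), sch, duration = 300, noise = FALSE)
  expect_equal(length(ses$waveform$samples), 300000)
  expect_identical(ses$schedule, sch)
  # pulse energy present in each 3-s event window
  e <- vapply(seq_len(100), function(i) {
    idx <- round(sch$onset[i] * 1000) + 1:3000
    max(abs(ses$waveform$samples[idx]))
  }, numeric(1))
  expect_true(all(e > 1))
  # empty schedule, noise off: flat zero trace
  empty <- simulate_session(subject_params(), event_schedule(numeric(0), 0, 20),
                            duration = 2, noise = FALSE)
  expect_equal(max(abs(empty$waveform$samples)), 0)
  # overlapping events are rejected
  bad <- event_schedule(c(0, 0.1), 0, 20)
  expect_error(simulate_session(subject_params(), bad), "overlap")
  expect_error(event_schedule(c(1, 1), 0, 20), "increasing")
})

test_that("same seed reproduces the trace; different seeds differ only in noise", {
  cond <- motion_conditions()[1:2, ]
  sch <- regular_schedule(cond, 4)
  s1 <- simulate_session(subject_params(), sch, seed = 5)
  s2 <- simulate_session(subject_params(), sch, seed = 5)
  s3 <- simulate_session(subject_params(), sch, seed = 6)
  expect_identical(s1$waveform$samples, s2$waveform$samples)
  expect_false(identical(s1$waveform$samples, s3$waveform$samples))
  expect_identical(s1$schedule, s3$schedule)
  # both realizations share the deterministic pulse component
  clean <- simulate_session(subject_params(), sch, noise = FALSE)
  expect_gt(stats::cor(s1$waveform$samples, clean$waveform$samples), 0.99)
  expect_gt(stats::cor(s3$waveform$samples, clean$waveform$samples), 0.99)
})

test_that("dataset construction yields labelled fixed-length segments", {
  cond <- motion_conditions()
  ds <- build_dataset(cond, n_per_condition = 5, seed = 3)
  expect_equal(nrow(ds$segments), 9 * 5 + 5)   # rest ratio 1:9
  expect_equal(ncol(ds$segments), 3000)
  expect_equal(sum(ds$labels$torque == 0), 5)
  expect_equal(length(unique(ds$labels$class)), 10)
  no_rest <- build_dataset(cond, n_per_condition = 4, include_rest = FALSE,
                           seed = 3)
  expect_equal(nrow(no_rest$segments), 36)
  expect_equal(length(unique(no_rest$labels$class)), 9)
  dup <- cond; dup$torque[2] <- dup$torque[1]
  expect_error(build_dataset(dup, 2), "duplicate")
})
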