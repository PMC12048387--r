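test_that("the circular buffer retains exactly the most recent samples", {
  st <- stream_state(small_model())
  st <- buffer_push(st, seq_len(100))
  expect_equal(length(st$buffer), 100)
  st <- buffer_push(st, 100 + seq_len(3400))
  expect_equal(length(st$buffer), 3000)
  # the first 500 samples were evicted, arrival order preserved
  expect_equal(st$buffer, 501:3500)
  expect_equal(st$capacity, 3000)
  expect_equal(st$ingested, 3500)
  expect_error(buffer_push(st, c(1, NA)), "finite")
})

test_that("inference is a no-op until the buffer is full", {
  st <- stream_state(small_model())
  st <- buffer_push(st, numeric(100))
  expect_message(res <- step_inference(st), "not full")
  expect_false(res$ready)
  expect_true(is.na(res$torque))
})

test_that("alerts fire if and only if decoded torque exceeds the threshold", {
  net <- small_model()
  ds <- small_dataset()
  st <- stream_state(net)
  # rest-only buffer: near-zero torque, no alert
  rest_row <- which(ds$labels$torque == 0)[1]
  st_rest <- buffer_push(st, ds$segments[rest_row, ])
  res <- step_inference(st_rest)
  expect_true(res$ready)
  expect_lt(res$torque, 5)
  expect_null(res$alert)
  # maximum-torque condition: decoded ~32.8 Nm > 30 Nm threshold
  hi_row <- which.max(ds$labels$torque)
  st_hi <- buffer_push(st, ds$segments[hi_row, ])
  res_hi <- step_inference(st_hi)
  expect_gt(res_hi$torque, 30)
  expect_false(is.null(res_hi$alert))
  expect_match(res_hi$alert$message, "exceeds")
  # mid-torque condition (11.2 Nm): no alert
  mid_row <- which(abs(ds$labels$torque - 11.217098) < 1e-6)[1]
  res_mid <- step_inference(buffer_push(st, ds$segments[mid_row, ]))
  expect_lt(res_mid$torque, 30)
  expect_null(res_mid$alert)
})

test_that("streaming logs one prediction per cadence step", {
  net <- small_model()
  cond <- motion_conditions()
  sch <- regular_schedule(cond, 53, interval = 3, start = 0.5)
  ses <- simulate_session(subject_params(), sch, duration = 160, seed = 21)
  st <- stream_state(net)
  log_path <- tempfile(fileext = ".csv")
  log <- run_stream(ses$waveform, st, log_path = log_path)
  expect_equal(nrow(log), 53)          # floor(160 / 3) steps, first at t = 3 s
  expect_equal(log$t_s, 3 * seq_len(53))
  expect_true(all(log$alert == (log$torque_Nm > st$threshold)))
  on_disk <- utils::read.csv(log_path)
  expect_equal(on_disk$torque_Nm, log$torque_Nm, tolerance = 1e-9)
  # deterministic given a fixed model and trace
  log2 <- run_stream(ses$waveform, stream_state(net))
  expect_equal(log$torque_Nm, log2$torque_Nm)
  # shorter than one buffer: empty log with a warning
  expect_warning(short <- run_stream(waveform(numeric(1000)), stream_state(net)),
                 "shorter")
  expect_equal(nrow(short), 0)
})

test_that("streaming predictions agree with the batch pipeline on aligned windows", {
  net <- small_model()
  cond <- motion_conditions()
  sch <- regular_schedule(cond[c(9, 1, 5), ], 6, interval = 3, start = 0.5)
  ses <- simulate_session(subject_params(), sch, duration = 21, seed = 31)
  log <- run_stream(ses$waveform, stream_state(net))
  # batch route: the same cadence-aligned 3000-sample windows
  for (k in seq_len(nrow(log))) {
    win <- ses$waveform$samples[(k - 1) * 3000 + 1:3000]
    v <- mean_spectrum_features(stft_spectrogram(
      suppress_artefacts(win, fs = 1000), fs = 1000))
    v[1] <- 0
    batch_t <- predict(net, matrix(v, 1), type = "value")
    expect_equal(log$torque_Nm[k], batch_t, tolerance = 1e-9)
  }
})

test_that("alternating rest and high-torque events alert only on the latter", {
  net <- small_model()
  ds <- small_dataset()
  hi <- ds$segments[which.max(ds$labels$torque), ]
  rest <- ds$segments[which(ds$labels$torque == 0)[1], ]
  stream <- c(rest, hi, rest, hi)
  log <- run_stream(stream, stream_state(net))
  expect_equal(log$alert, c(FALSE, TRUE, FALSE, TRUE))
})
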