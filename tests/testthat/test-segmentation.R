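test_that("noiseless contacts are detected within 2 samples with no extras", {
  sim <- simulate_trace(sym_params(), seed = 4)
  filt <- lowpass_filter(sim$trace)
  earth <- to_earth_frame(filt, estimate_tilt(filt))
  ev <- detect_initial_contacts(extract_ap(earth), fs = 100)
  expect_equal(nrow(ev), nrow(sim$truth$ic))
  expect_true(all(abs(ev$time - sim$truth$ic$time) <= 0.02 + 1e-9))
})

test_that("degenerate signals raise a no-gait error", {
  expect_error(detect_initial_contacts(rep(1, 500), fs = 100), "constant")
  expect_error(detect_initial_contacts(rep(0, 100), fs = 100), "2 s of signal")
})

test_that("side labels match the generator and obey the sign convention", {
  sim <- simulate_trace(sym_params(), seed = 6)
  filt <- lowpass_filter(sim$trace)
  earth <- to_earth_frame(filt, estimate_tilt(filt))
  ap <- extract_ap(earth); ml <- earth$data[, "ml"]
  ev <- detect_initial_contacts(ap, fs = 100)
  lab <- label_sides(ev, ml, fs = 100)
  expect_equal(lab$side, sim$truth$ic$side)
  flipped <- label_sides(ev, ml, fs = 100, positive_ml = "left")
  expect_true(all(flipped$side != lab$side))
  expect_error(label_sides(ev, rep(0, length(ml)), fs = 100), "indeterminate")
})

test_that("cycles run contact-to-ipsilateral-contact and tile without gaps", {
  ev <- data.frame(sample_index = c(1L, 51L, 101L, 151L, 201L),
                   time = c(0, 0.5, 1, 1.5, 2),
                   side = c("left", "right", "left", "right", "left"))
  cyc <- split_cycles(ev)
  left <- cyc[cyc$side == "left", ]
  right <- cyc[cyc$side == "right", ]
  expect_equal(left$start_index, c(1L, 101L))
  expect_equal(left$end_index, c(101L, 201L))
  expect_equal(right$start_index, 51L)
  expect_equal(right$end_index, 151L)
  # consecutive ipsilateral cycles share boundaries exactly
  expect_equal(left$start_index[-1], left$end_index[-nrow(left)])
})

test_that("implausible cycle durations are gated out with a reason", {
  ev <- data.frame(sample_index = c(1L, 51L, 101L, 151L, 601L, 651L, 701L),
                   time = c(0, 0.5, 1, 1.5, 6, 6.5, 7),
                   side = c("left", "right", "left", "right", "left", "right", "left"))
  expect_message(cyc <- split_cycles(ev), "dropped")
  dropped <- attr(cyc, "dropped")
  expect_true(all(dropped$duration > 2.5))
  expect_false(any(cyc$duration > 2.5))
  # a side losing all its cycles is an error
  ev2 <- data.frame(sample_index = c(1L, 51L, 601L),
                    time = c(0, 0.5, 6), side = c("left", "right", "left"))
  expect_error(suppressMessages(split_cycles(ev2)), "fewer than 1 valid left cycle")
})

test_that("a simulated 8-stride trial yields 7 cycles per side within jitter bounds", {
  p <- gait_sim_params(n_strides = 8, stride_jitter_cv = 0.03, noise_sd = 0.2)
  res <- compute_trial_si(simulate_trace(p, seed = 12)$trace)
  expect_equal(res$n_left, 7)
  expect_equal(res$n_right, 7)
  cyc_dur <- c(diff(res$events$time[res$events$side == "left"]),
               diff(res$events$time[res$events$side == "right"]))
  expect_true(all(abs(cyc_dur - 1 / p$stride_frequency) < 5 * 0.03 / p$stride_frequency))
})

test_that("time normalization is exact on ramps and identity on P-sample cycles", {
  ap <- seq(0, 10, length.out = 201)  # linear ramp
  out <- time_normalize(ap, 1L, 201L, P = 101L)
  expect_equal(out, ap[1] + (0:100) * 200 / 101 * (ap[2] - ap[1]), tolerance = 1e-12)
  expect_equal(out[1], ap[1])

  ap2 <- rnorm(101)
  expect_equal(time_normalize(c(ap2, 0), 1L, 102L, P = 101L), ap2)
  expect_error(time_normalize(ap2, 1L, 200L), "outside the signal bounds")
  expect_error(time_normalize(ap2, 1L, 4L), "4 samples")
})

test_that("sine interpolation error respects the analytic bound", {
  L <- 40L
  ap <- sin(2 * pi * (0:L) / L)
  out <- time_normalize(ap, 1L, L + 1L, P = 101L)
  truth <- sin(2 * pi * (0:100) / 101)
  expect_lt(max(abs(out - truth)), (2 * pi / L)^2 / 8)
})

test_that("mean waveforms average pointwise and handle cancellation", {
  w <- sin(seq(0, 2 * pi, length.out = 101))
  one <- mean_waveform(matrix(w, 1), "left")
  expect_equal(one$waveform, w)
  expect_equal(one$n_cycles, 1)
  two <- mean_waveform(rbind(w, -w), "right")
  expect_equal(two$waveform, rep(0, 101))
  expect_error(mean_waveform(matrix(numeric(0), 0, 101), "left"), "no left cycles")
  # noiseless identical cycles reproduce the generator template up to the
  # sub-sample offset between the detected (integer-sample) and true contact
  sim <- simulate_trace(sym_params(), seed = 8)
  res <- compute_trial_si(sim$trace)
  tmpl <- colMeans(sim$truth$templates$left)
  expect_lt(max(abs(res$left_mean - tmpl)), 0.15)
  expect_gt(cor(res$left_mean, tmpl), 0.999)
})

test_that("relabeling left and right leaves the symmetry index unchanged", {
  p <- gait_sim_params(asymmetry_alpha = 0.25)
  tr <- simulate_trace(p, seed = 13)$trace
  a <- compute_trial_si(tr, gait_config(positive_ml = "right"))
  b <- compute_trial_si(tr, gait_config(positive_ml = "left"))
  expect_equal(a$si, b$si, tolerance = 1e-9)
  expect_equal(a$left_mean, b$right_mean)
})

test_that("contact timing is accurate across a seeded Monte-Carlo set", {
  errs <- c()
  for (i in 1:20) {
    sim <- simulate_trace(gait_sim_params(), seed = 400 + i, templates = FALSE)
    res <- compute_trial_si(sim$trace)
    tru <- sim$truth$ic$time
    det <- res$events$time
    m <- vapply(det, function(t) min(abs(tru - t)), numeric(1))
    errs <- c(errs, m)
  }
  expect_lt(median(errs), 0.02)
})
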