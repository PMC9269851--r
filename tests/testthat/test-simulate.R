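test_that("parameter validation rejects out-of-range inputs", {
  expect_error(gait_sim_params(asymmetry_alpha = 1.2), "\\[0, 1\\]")
  expect_error(gait_sim_params(asymmetry_alpha = NA), "finite")
  expect_error(gait_sim_params(stride_jitter_cv = -0.1), ">= 0")
  expect_error(gait_sim_params(fs = 0), "> 0")
  expect_error(gait_sim_params(n_strides = 0), ">= 1")
  expect_error(gait_sim_params(tilt_pitch = 2), "pi/2")
})

test_that("symmetric generator emits identical left and right cycle templates", {
  sim <- simulate_trace(sym_params(asymmetry_alpha = 0), seed = 3)
  tl <- sim$truth$templates$left
  tr <- sim$truth$templates$right
  expect_equal(nrow(tl), 7)
  expect_equal(nrow(tr), 7)
  # all cycles of both sides collapse onto one template
  all_cycles <- rbind(tl, tr)
  expect_lt(max(abs(sweep(all_cycles, 2, all_cycles[1, ]))), 1e-9)
})

test_that("gravity-only parameters give a constant (0, 0, g) trace", {
  h <- default_harmonics()
  for (ax in names(h)) h[[ax]]$amplitude <- 0
  sim <- simulate_trace(gait_sim_params(harmonics = h, noise_sd = 0,
                                        stride_jitter_cv = 0), seed = 1)
  expect_lt(max(abs(sweep(sim$trace$data, 2, c(0, 0, 9.81)))), 1e-12)
})

test_that("amplitude asymmetry scales per-cycle AP peaks by (1-a)/(1+a)", {
  a <- 0.3
  sim <- simulate_trace(sym_params(asymmetry_alpha = a, asymmetry_mode = "amplitude"),
                        seed = 2)
  # a cycle starts at its side's contact peak, so the first template point
  # is the side's peak amplitude
  peak_l <- sim$truth$templates$left[, 1]
  peak_r <- sim$truth$templates$right[, 1]
  expect_equal(unname(peak_r / peak_l), rep((1 - a) / (1 + a), length(peak_l)),
               tolerance = 1e-9)
})

test_that("phase-mode asymmetry shifts alternate contacts in time", {
  sim0 <- simulate_trace(sym_params(), seed = 1)
  simp <- simulate_trace(sym_params(asymmetry_alpha = 0.4, asymmetry_mode = "phase"),
                         seed = 1)
  shift <- simp$truth$ic$time - sim0$truth$ic$time
  # left and right contacts move in opposite directions
  expect_true(all(shift[simp$truth$ic$side == "left"] < 0) !=
                all(shift[simp$truth$ic$side == "right"] < 0))
  expect_gt(max(abs(shift)), 0.001)
})

test_that("ground truth is consistent: contacts per side, alternation, jitter", {
  p <- gait_sim_params(n_strides = 8, stride_jitter_cv = 0.05, noise_sd = 0.3)
  cv_hat <- numeric(40)
  for (i in seq_len(40)) {
    sim <- simulate_trace(p, seed = 100 + i, templates = FALSE)
    ic <- sim$truth$ic
    expect_equal(sum(ic$side == "left"), 8)
    expect_equal(sum(ic$side == "right"), 8)
    expect_true(all(diff(ic$time) > 0))
    expect_true(all(ic$side[-1] != ic$side[-nrow(ic)])) # strict alternation
    sd_ <- sim$truth$stride_durations
    cv_hat[i] <- sd(sd_) / mean(sd_)
  }
  # mean per-trial stride-time CV close to the requested jitter (8 strides
  # per trial, so the estimate is biased slightly low)
  expect_gt(mean(cv_hat), 0.03)
  expect_lt(mean(cv_hat), 0.07)
})

test_that("anthropometric draws hit the group means when SDs are zeroed", {
  p1 <- simulate_participant("Children", seed = 5, sd_scale = 0)
  expect_equal(p1$weight_kg, 37.5)
  expect_equal(p1$height_cm, 140.8)
  p2 <- simulate_participant("Elderly", seed = 5, sd_scale = 0)
  expect_equal(p2$weight_kg, 69)
  expect_equal(p2$height_cm, 160.3)
  expect_error(simulate_participant("Toddlers", seed = 1), "unknown group")
})

test_that("truncated-normal sampler recovers the Teenager height mean", {
  h <- vapply(seq_len(10000), function(i)
    simulate_participant("Teenagers", seed = i)$height_cm, numeric(1))
  expect_lt(abs(mean(h) - 167.5) / 167.5, 0.01)
  # truncation bounds respected
  expect_true(all(abs(h - 167.5) <= 3 * 9.9 + 1e-9))
})

test_that("cohort simulation is reproducible and honours the design counts", {
  groups <- gait_groups(c("Children", "Adults"), n = 2)
  des <- cohort_design(groups = groups, trials_per_condition = 2)
  c1 <- simulate_cohort(des, seed = 9)
  c2 <- simulate_cohort(des, seed = 9)
  expect_identical(serialize(c1$traces, NULL), serialize(c2$traces, NULL))
  expect_identical(c1$participants, c2$participants)
  expect_equal(nrow(c1$trials), 2 * 2 * 3 * 2)  # participants x conditions x trials
  c3 <- simulate_cohort(des, seed = 10)
  expect_false(identical(c1$traces[[1]]$data, c3$traces[[1]]$data))
})

test_that("the default design reproduces the study layout: 137 participants, 1233 trials", {
  coh <- simulate_cohort(cohort_design(), seed = 1,
                         keep_traces = FALSE, keep_truth = FALSE)
  expect_equal(nrow(coh$participants), 137)
  expect_equal(nrow(coh$trials), 1233)
  expect_equal(as.vector(table(coh$participants$group)[unique(coh$participants$group)]),
               c(19, 20, 20, 20, 20, 20, 18))
  # conditions scale speed in the expected order for every participant
  sp <- tapply(coh$trials$true_speed, coh$trials$condition, mean)
  expect_true(sp[["Slow"]] < sp[["Comfortable"]])
  expect_true(sp[["Comfortable"]] < sp[["Fast"]])
})

test_that("mean pipeline SI decreases monotonically in the asymmetry level", {
  alphas <- seq(0, 0.5, by = 0.1)
  mean_si <- vapply(alphas, function(a) {
    si <- vapply(seq_len(50), function(i) {
      sim <- simulate_trace(gait_sim_params(asymmetry_alpha = a), seed = 1000 * a + i,
                            templates = FALSE)
      compute_trial_si(sim$trace)$si
    }, numeric(1))
    mean(si)
  }, numeric(1))
  expect_true(all(diff(mean_si) < 0))
  expect_gt(mean_si[1], 99.5)
  expect_lt(mean_si[6], 85)
})
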