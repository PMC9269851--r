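test_that("mean speed is path over duration and matches the generator truth", {
  expect_equal(mean_speed(10, 10), 1)
  expect_equal(mean_speed(10, 8), 1.25)
  expect_error(mean_speed(10, 0), "positive")
  sim <- simulate_trace(gait_sim_params(), seed = 3, templates = FALSE)
  v <- mean_speed(sim$truth$path_m, sim$truth$duration)
  expect_equal(v, sim$truth$true_mean_speed, tolerance = 0.02)
})

test_that("the speed model recovers exact and degenerate linear structures", {
  set.seed(1)
  d <- data.frame(weight_kg = runif(30, 40, 90), height_cm = runif(30, 140, 190))
  d$observed_speed <- 0.01 * d$height_cm
  m <- fit_speed_model(d, scope = "pooled")
  cf <- coef(m)["pooled", ]
  expect_equal(unname(cf[2]), 0, tolerance = 1e-10)   # weight
  expect_equal(unname(cf[3]), 0.01, tolerance = 1e-10) # height
  expect_lt(sum(residuals(m$models$pooled)^2), 1e-16)

  d$observed_speed <- 1.3
  m2 <- fit_speed_model(d, scope = "pooled")
  cf2 <- coef(m2)["pooled", ]
  expect_equal(unname(cf2), c(1.3, 0, 0), tolerance = 1e-10)

  expect_error(fit_speed_model(d[1:2, ], scope = "pooled"), "at least 3")
  d$height_cm <- d$weight_kg * 2
  expect_error(fit_speed_model(d, scope = "pooled"), "collinear")
})

test_that("OLS recovers known generating coefficients within 2 SE", {
  set.seed(42)
  n <- 120
  d <- data.frame(weight_kg = rnorm(n, 65, 12), height_cm = rnorm(n, 165, 10))
  b <- c(intercept = -0.2, weight = 0.002, height = 0.007)
  d$observed_speed <- b[1] + b[2] * d$weight_kg + b[3] * d$height_cm + rnorm(n, 0, 0.08)
  m <- fit_speed_model(d, scope = "pooled")$models$pooled
  est <- summary(m)$coefficients
  for (i in 1:3)
    expect_lt(abs(est[i, "Estimate"] - b[i]), 2 * est[i, "Std. Error"] + 1e-12)
})

test_that("speed normalization is a ratio with unit within-scope mean", {
  set.seed(7)
  d <- data.frame(condition = rep(c("Slow", "Fast"), each = 40),
                  weight_kg = rnorm(80, 65, 12), height_cm = rnorm(80, 165, 10))
  base <- ifelse(d$condition == "Slow", 0.8, 1.5)
  d$observed_speed <- base * (d$height_cm / 165) + rnorm(80, 0, 0.05)
  m <- fit_speed_model(d, scope = "condition")
  out <- normalize_speed(d, m)
  expect_equal(out$normalized_speed, out$observed_speed / out$predicted_speed)
  for (cond in c("Slow", "Fast")) {
    mu <- mean(out$normalized_speed[out$condition == cond])
    expect_gt(mu, 0.98); expect_lt(mu, 1.02)
  }
  # observed = predicted gives exactly 1
  one <- normalize_speed(data.frame(condition = "Slow",
                                    weight_kg = 65, height_cm = 165,
                                    observed_speed = predict(m, data.frame(
                                      condition = "Slow", weight_kg = 65,
                                      height_cm = 165))), m)
  expect_equal(one$normalized_speed, 1)
})

test_that("scaling all speeds scales ratios under a fixed model but refitting restores unit means", {
  set.seed(8)
  d <- data.frame(condition = "Comfortable",
                  weight_kg = rnorm(50, 65, 10), height_cm = rnorm(50, 165, 9))
  d$observed_speed <- 1.1 * d$height_cm / 165 + rnorm(50, 0, 0.04)
  m <- fit_speed_model(d, scope = "condition")
  base <- normalize_speed(d, m)$normalized_speed
  d2 <- d; d2$observed_speed <- 1.5 * d$observed_speed
  fixed <- normalize_speed(d2, m)$normalized_speed
  expect_equal(fixed, 1.5 * base, tolerance = 1e-12)
  refit <- normalize_speed(d2, fit_speed_model(d2, scope = "condition"))$normalized_speed
  expect_equal(mean(refit), 1, tolerance = 0.02)
})

test_that("speed tracks anthropometry in simulated cohorts while SI does not", {
  # the correlations are taken within age groups: group membership shifts
  # both anthropometrics and gait, so the global association would mix the
  # age effect into the anthropometric one
  r_si_w <- r_si_h <- c()
  r_sp_h <- numeric(5)
  for (i in 1:5) {
    groups <- gait_groups()  # full 7-group, 137-participant design
    des <- cohort_design(groups = groups, trials_per_condition = 1L,
                         profile = null_asymmetry_profile(groups = groups$group))
    coh <- simulate_cohort(des, seed = 500 + i, keep_truth = FALSE)
    res <- suppressMessages(process_cohort(coh))
    per_part <- stats::aggregate(cbind(si, observed_speed) ~ participant_id + group,
                                 data = res$table, FUN = mean)
    per_part <- merge(per_part, coh$participants)
    for (g in unique(per_part$group)) {
      pg <- per_part[per_part$group == g, ]
      r_si_w <- c(r_si_w, cor(pg$si, pg$weight_kg))
      r_si_h <- c(r_si_h, cor(pg$si, pg$height_cm))
    }
    comf <- res$table[res$table$condition == "Comfortable", ]
    r_sp_h[i] <- cor(comf$observed_speed, comf$height_cm)
  }
  expect_lt(abs(mean(r_si_w)), 0.1)
  expect_lt(abs(mean(r_si_h)), 0.1)
  expect_gt(mean(r_sp_h), 0.4)  # bounded away from zero
})
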