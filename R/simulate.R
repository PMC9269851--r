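#' Default harmonic content of the synthetic gait signal
#'
#' Harmonic orders are integer multiples of the stride frequency. Symmetric
#' walking produces trunk AP and vertical acceleration that repeats every
#' *step*, i.e. only even stride orders (the step fundamental at twice the
#' stride frequency and its harmonic), while mediolateral sway alternates
#' with the stance side and therefore carries the odd stride fundamental.
#' Left/right asymmetry injected by [simulate_trace()] adds odd
#' (stride-frequency) content to the AP channel.
#'
#' @return A list with per-axis data frames (`ap`, `ml`, `v`) holding
#'   columns `order`, `amplitude` (m/s^2) and `phase` (rad).
#' @export
default_harmonics <- function() {
  # phases put the AP contact peak mid-step and align the ML sway so the
  # trunk leans toward the stance side around each contact
  list(
    ap = data.frame(order = c(2, 4), amplitude = c(1.0, 0.4), phase = c(-0.6 * pi, 0.3 * pi)),
    ml = data.frame(order = c(1, 3), amplitude = c(0.6, 0.1), phase = c(0.95 * pi, 0)),
    v  = data.frame(order = c(2, 4), amplitude = c(1.5, 0.3), phase = c(-pi / 2, 0))
  )
}

#' Parameters of the synthetic gait-trace generator
#'
#' Bundles and validates everything [simulate_trace()] needs to emit one
#' walking trial: a stride-periodic harmonic signal per axis, a controllable
#' left/right asymmetry, stride-time jitter, static sensor tilt, additive
#' white sensor noise, and gravity.
#'
#' @param stride_frequency stride (full gait cycle) frequency in Hz.
#' @param n_strides number of strides in the trial (>= 1).
#' @param stride_length_m stride length in metres; together with
#'   `n_strides` it defines the path length and hence the true mean speed.
#' @param harmonics per-axis harmonic table, see [default_harmonics()].
#' @param asymmetry_alpha dimensionless asymmetry knob in \[0, 1\]; 0 is a
#'   perfectly symmetric left/right AP shape.
#' @param asymmetry_mode `"amplitude"` scales alternate steps by
#'   (1 +/- alpha); `"phase"` time-shifts alternate step templates by
#'   alpha*pi/8 radians of step phase; `"both"` applies both.
#' @param stride_jitter_cv coefficient of variation of stride time (>= 0).
#' @param tilt_pitch,tilt_roll static sensor inclination in rad,
#'   magnitude < pi/2.
#' @param noise_sd additive white Gaussian sensor noise, m/s^2 per axis.
#' @param fs sampling frequency in Hz (default 100).
#' @param g gravitational acceleration, m/s^2.
#' @return An object of class `gait_sim_params`.
#' @examples
#' p <- gait_sim_params(asymmetry_alpha = 0.3, noise_sd = 0)
#' sim <- simulate_trace(p, seed = 1)
#' sim$trace
#' @export
gait_sim_params <- function(stride_frequency = 0.9,
                            n_strides = 8L,
                            stride_length_m = 1.25,
                            harmonics = default_harmonics(),
                            asymmetry_alpha = 0,
                            asymmetry_mode = c("amplitude", "phase", "both"),
                            stride_jitter_cv = 0.02,
                            tilt_pitch = 0,
                            tilt_roll = 0,
                            noise_sd = 0.3,
                            fs = 100,
                            g = 9.81) {
  asymmetry_mode <- match.arg(asymmetry_mode)
  num1 <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      stop(sprintf("'%s' must be a single finite number", nm))
    x
  }
  stride_frequency <- num1(stride_frequency, "stride_frequency")
  if (stride_frequency <= 0) stop("stride_frequency must be > 0")
  n_strides <- as.integer(num1(n_strides, "n_strides"))
  if (n_strides < 1L) stop("n_strides must be >= 1")
  num1(stride_length_m, "stride_length_m")
  if (stride_length_m <= 0) stop("stride_length_m must be > 0")
  asymmetry_alpha <- num1(asymmetry_alpha, "asymmetry_alpha")
  if (asymmetry_alpha < 0 || asymmetry_alpha > 1)
    stop("asymmetry_alpha must lie in [0, 1]")
  stride_jitter_cv <- num1(stride_jitter_cv, "stride_jitter_cv")
  if (stride_jitter_cv < 0) stop("stride_jitter_cv must be >= 0")
  tilt_pitch <- num1(tilt_pitch, "tilt_pitch")
  tilt_roll <- num1(tilt_roll, "tilt_roll")
  if (abs(tilt_pitch) >= pi / 2 || abs(tilt_roll) >= pi / 2)
    stop("tilt angles must have magnitude < pi/2")
  noise_sd <- num1(noise_sd, "noise_sd")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  fs <- num1(fs, "fs")
  if (fs <= 0) stop("fs must be > 0")
  num1(g, "g")
  for (ax in c("ap", "ml", "v")) {
    h <- harmonics[[ax]]
    if (is.null(h) || !all(c("order", "amplitude", "phase") %in% names(h)))
      stop("harmonics must hold ap/ml/v tables with order, amplitude, phase")
    if (!all(is.finite(as.matrix(h[c("order", "amplitude", "phase")]))))
      stop("harmonic parameters must be finite")
  }
  structure(list(stride_frequency = stride_frequency, n_strides = n_strides,
                 stride_length_m = stride_length_m, harmonics = harmonics,
                 asymmetry_alpha = asymmetry_alpha, asymmetry_mode = asymmetry_mode,
                 stride_jitter_cv = stride_jitter_cv, tilt_pitch = tilt_pitch,
                 tilt_roll = tilt_roll, noise_sd = noise_sd, fs = fs, g = g),
            class = "gait_sim_params")
}

#' @export
print.gait_sim_params <- function(x, ...) {
  cat(sprintf(paste0("<gait_sim_params> %g Hz stride, %d strides, alpha = %g (%s),\n",
                     "  jitter cv = %g, tilt = (%.1f, %.1f) deg, noise sd = %g m/s^2, fs = %g Hz\n"),
              x$stride_frequency, x$n_strides, x$asymmetry_alpha, x$asymmetry_mode,
              x$stride_jitter_cv, x$tilt_pitch * 180 / pi, x$tilt_roll * 180 / pi,
              x$noise_sd, x$fs))
  invisible(x)
}

# evaluate a harmonic table at stride phase Phi (vectorized)
harm_eval <- function(h, Phi) {
  out <- numeric(length(Phi))
  for (i in seq_len(nrow(h)))
    out <- out + h$amplitude[i] * sin(2 * pi * h$order[i] * Phi + h$phase[i])
  out
}

# earth -> sensor rotation for static tilt: a_sensor = S %*% a_earth
tilt_matrix <- function(pitch, roll) {
  Ry <- matrix(c(cos(pitch), 0, -sin(pitch),
                 0, 1, 0,
                 sin(pitch), 0, cos(pitch)), 3, 3)
  Rx <- matrix(c(1, 0, 0,
                 0, cos(roll), sin(roll),
                 0, -sin(roll), cos(roll)), 3, 3)
  Rx %*% Ry
}

#' Simulate one walking trial with known ground truth
#'
#' Generates a sensor-frame triaxial trace as
#' `rotate(tilt) %*% (gravity + periodic gait signal) + noise`. The AP
#' channel is built step by step: within step `j` of phase `phi` the stride
#' phase is `(k_j + phi)/2` (k alternates 0/1 for left/right), alternate
#' steps are amplitude-scaled by `1 + s*alpha` and/or time-shifted by
#' `alpha*pi/8` radians of step phase with `s = +1` (left) / `-1` (right).
#' The ground truth records every initial contact (placed at the noiseless
#' AP peak of each step), the exact noiseless AP waveform of every left and
#' right stride cycle on the 101-point percent-of-cycle grid, and the true
#' mean walking speed.
#'
#' @param params a [gait_sim_params()] object.
#' @param seed integer seed; identical (params, seed) give bit-identical
#'   output.
#' @param templates compute the noiseless per-cycle AP templates (set
#'   `FALSE` to skip the extra work in large simulations).
#' @return A list with elements `trace` (a [raw_trace()]) and `truth`, a
#'   list holding `ic` (data frame of contact `time`/`side`), `templates`
#'   (`left`/`right` matrices, one row per cycle, 101 columns), `duration`
#'   (s), `path_m`, `true_mean_speed` (m/s) and `earth_clean` (noiseless
#'   earth-frame matrix).
#' @export
simulate_trace <- function(params, seed = 1L, templates = TRUE) {
  if (!inherits(params, "gait_sim_params"))
    stop("params must be created by gait_sim_params()")
  set.seed(as.integer(seed))
  p <- params
  n_steps <- 2L * p$n_strides
  stride_dur <- (1 / p$stride_frequency) *
    pmax(0.2, 1 + stats::rnorm(p$n_strides, 0, p$stride_jitter_cv))
  step_dur <- rep(stride_dur / 2, each = 2L)
  step_start <- cumsum(c(0, step_dur[-n_steps]))
  total_dur <- sum(step_dur)
  side_step <- rep(c(1L, -1L), p$n_strides)  # +1 left, -1 right

  amp_mode <- p$asymmetry_mode %in% c("amplitude", "both")
  phs_mode <- p$asymmetry_mode %in% c("phase", "both")
  # C1 modulation envelope: 0 at the step boundaries (so the asymmetric
  # signal stays continuous there) and exactly 1 on a plateau covering the
  # contact peak (so the injected peak modulation is exactly 1 +/- alpha)
  env <- function(phi) {
    ifelse(phi < 0.2, 0.5 * (1 - cos(pi * phi / 0.2)),
           ifelse(phi > 0.9, 0.5 * (1 - cos(pi * (1 - phi) / 0.1)), 1))
  }
  ap_eval <- function(k, phi, side) {
    Phi <- (k + phi) / 2
    w <- env(phi)
    am <- if (amp_mode) 1 + side * p$asymmetry_alpha * w else 1
    dp <- if (phs_mode) side * p$asymmetry_alpha * w / 32 else 0
    am * harm_eval(p$harmonics$ap, Phi + dp)
  }
  ap_at <- function(tq) {
    jq <- pmin(pmax(findInterval(tq, step_start), 1L), n_steps)
    phiq <- (tq - step_start[jq]) / step_dur[jq]
    ap_eval((jq - 1L) %% 2L, phiq, side_step[jq])
  }

  nsamp <- max(4L, floor(total_dur * p$fs))
  t <- (seq_len(nsamp) - 1) / p$fs
  jj <- pmin(pmax(findInterval(t, step_start), 1L), n_steps)
  phi <- (t - step_start[jj]) / step_dur[jj]
  Phi <- (((jj - 1L) %% 2L) + phi) / 2
  ap <- ap_eval((jj - 1L) %% 2L, phi, side_step[jj])
  ml <- harm_eval(p$harmonics$ml, Phi)
  v  <- harm_eval(p$harmonics$v, Phi)
  earth_clean <- cbind(ap = ap, ml = ml, v = v)

  S <- tilt_matrix(p$tilt_pitch, p$tilt_roll)
  sens <- cbind(ap, ml, v + p$g) %*% t(S)
  if (p$noise_sd > 0)
    sens <- sens + matrix(stats::rnorm(3L * nsamp, 0, p$noise_sd), ncol = 3L)
  trace <- raw_trace(sens, fs = p$fs)

  # ground-truth contacts: noiseless AP peak of each step (peak phase is
  # shared by all steps of a side, so locate it once per side)
  grid <- seq(0.01, 0.99, length.out = 491L)
  phi_star <- numeric(2L)
  for (k in 0:1) {
    sgn <- if (k == 0L) 1 else -1
    vals <- ap_eval(k, grid, sgn)
    phi_star[k + 1L] <- grid[which.max(vals)]
  }
  ic_time <- step_start + phi_star[((seq_len(n_steps) - 1L) %% 2L) + 1L] * step_dur
  ic <- data.frame(time = ic_time,
                   side = ifelse(side_step > 0L, "left", "right"),
                   step = seq_len(n_steps))

  P <- 101L
  tmpl <- if (!templates) NULL else lapply(c(left = "left", right = "right"), function(sd_) {
    tt <- ic_time[ic$side == sd_]
    if (length(tt) < 2L) return(matrix(numeric(0), 0L, P))
    m <- vapply(seq_len(length(tt) - 1L), function(i) {
      ap_at(tt[i] + (0:(P - 1L)) / P * (tt[i + 1L] - tt[i]))
    }, numeric(P))
    t(m)
  })

  truth <- list(ic = ic, templates = tmpl, duration = total_dur,
                path_m = p$n_strides * p$stride_length_m,
                true_mean_speed = p$n_strides * p$stride_length_m / total_dur,
                stride_durations = stride_dur, earth_clean = earth_clean)
  list(trace = trace, truth = truth)
}

# --- cohort -----------------------------------------------------------------

# anthropometrics per age group: mean +/- SD of weight (kg) and height (cm)
anthro_table <- function() {
  data.frame(
    group = c("Children", "Teenagers", "Young Adults", "Adults",
              "Middle-Aged", "Senior", "Elderly"),
    age_lo = c(6, 13, 19, 36, 51, 61, 71),
    age_hi = c(12, 18, 35, 50, 60, 70, 84),
    n = c(19L, 20L, 20L, 20L, 20L, 20L, 18L),
    weight_mean = c(37.5, 62.3, 67.3, 68.1, 70.0, 76.5, 69.0),
    weight_sd = c(12.3, 10.1, 13.1, 10.7, 12.67, 13.3, 11.1),
    height_mean = c(140.8, 167.5, 169.0, 166.2, 167.3, 164.8, 160.3),
    height_sd = c(11.4, 9.9, 10.6, 8.9, 9.1, 8.0, 10.7),
    stringsAsFactors = FALSE
  )
}

#' Age-group definitions and anthropometrics of the reference cohort
#'
#' Seven age groups from children (6-12 y) to elderly (71-84 y) with group
#' sizes (19, 20, 20, 20, 20, 20, 18; 137 in total) and weight/height
#' means and SDs of the reference cohort.
#'
#' @param labels optional subset of group labels to keep (in the given
#'   order).
#' @param n optional group size override: a single integer applied to every
#'   group (useful for reduced simulation designs).
#' @return Data frame with columns `group`, `age_lo`, `age_hi`, `n`,
#'   `weight_mean`, `weight_sd`, `height_mean`, `height_sd`.
#' @export
gait_groups <- function(labels = NULL, n = NULL) {
  tab <- anthro_table()
  if (!is.null(labels)) {
    if (!all(labels %in% tab$group))
      stop("unknown group label(s): ", paste(setdiff(labels, tab$group), collapse = ", "))
    tab <- tab[match(labels, tab$group), , drop = FALSE]
  }
  if (!is.null(n)) tab$n <- as.integer(n)
  rownames(tab) <- NULL
  tab
}

#' Group-by-condition asymmetry profile
#'
#' Builds the matrix of generator asymmetry levels used by
#' [simulate_cohort()]. The default reproduces the qualitative study
#' pattern: a common baseline everywhere, with asymmetry elevated only in
#' the Fast condition for the developmentally or degeneratively affected
#' groups, while Young Adults and Adults stay flat across conditions.
#' Through the generator's amplitude-asymmetry mapping
#' (r approx (1-alpha^2)/(1+alpha^2)), alpha 0.15 / 0.28 corresponds to SI
#' of roughly 97.6 / 92.6.
#'
#' @param baseline alpha applied to every group/condition.
#' @param elevated alpha for `affected` groups in `elevated_condition`.
#' @param affected character vector of affected group labels.
#' @param elevated_condition condition receiving the elevated alpha.
#' @param groups,conditions row/column labels of the profile.
#' @return Numeric matrix, groups in rows, conditions in columns.
#' @export
asymmetry_profile <- function(baseline = 0.15, elevated = 0.28,
                              affected = c("Children", "Teenagers", "Middle-Aged",
                                           "Senior", "Elderly"),
                              elevated_condition = "Fast",
                              groups = anthro_table()$group,
                              conditions = c("Slow", "Comfortable", "Fast")) {
  prof <- matrix(baseline, nrow = length(groups), ncol = length(conditions),
                 dimnames = list(groups, conditions))
  aff <- intersect(affected, groups)
  if (elevated_condition %in% conditions)
    prof[aff, elevated_condition] <- elevated
  prof
}

#' Asymmetry profile with no group or condition structure
#'
#' Global-null profile: every group and condition shares the same alpha.
#' Used for type-I-error calibration of the cohort statistics.
#'
#' @param alpha the common asymmetry level.
#' @inheritParams asymmetry_profile
#' @return Numeric matrix, groups in rows, conditions in columns.
#' @export
null_asymmetry_profile <- function(alpha = 0.15,
                                   groups = anthro_table()$group,
                                   conditions = c("Slow", "Comfortable", "Fast")) {
  asymmetry_profile(baseline = alpha, elevated = alpha,
                    groups = groups, conditions = conditions)
}

#' Design of a simulated walking cohort
#'
#' Describes the study layout fed to [simulate_cohort()]: age groups with
#' anthropometrics, the three speed conditions with their stride
#' frequencies and target speeds, trials per condition, path length and the
#' asymmetry profile.
#'
#' @param groups group table as returned by [gait_groups()].
#' @param conditions speed-condition labels.
#' @param stride_frequency named stride frequencies (Hz) per condition.
#' @param base_speed named target mean speeds (m/s) per condition for a
#'   reference-height participant; individual speed scales with body height
#'   and carries a lognormal residual, so that walking speed (but not the
#'   symmetry index) depends on anthropometry.
#' @param trials_per_condition trials walked per condition (study design: 3).
#' @param path_m walkway length in metres (study design: 10).
#' @param profile asymmetry profile matrix, see [asymmetry_profile()].
#' @param subject_alpha_cv lognormal coefficient of variation of the
#'   per-participant asymmetry multiplier.
#' @param speed_noise_cv lognormal residual cv of individual speed.
#' @param cadence_noise_cv lognormal residual cv of individual stride
#'   frequency.
#' @param stride_jitter_cv within-trial stride-time jitter cv.
#' @param noise_sd sensor noise (m/s^2).
#' @param asymmetry_mode see [gait_sim_params()].
#' @param fs sampling frequency (Hz).
#' @return An object of class `cohort_design`.
#' @export
cohort_design <- function(groups = gait_groups(),
                          conditions = c("Slow", "Comfortable", "Fast"),
                          stride_frequency = c(Slow = 0.75, Comfortable = 0.90, Fast = 1.05),
                          base_speed = c(Slow = 0.80, Comfortable = 1.15, Fast = 1.55),
                          trials_per_condition = 3L,
                          path_m = 10,
                          profile = asymmetry_profile(groups = groups$group,
                                                      conditions = conditions),
                          subject_alpha_cv = 0.15,
                          speed_noise_cv = 0.04,
                          cadence_noise_cv = 0.02,
                          stride_jitter_cv = 0.02,
                          noise_sd = 0.3,
                          asymmetry_mode = "amplitude",
                          fs = 100) {
  if (!all(groups$weight_sd > 0) || !all(groups$height_sd > 0))
    stop("anthropometric SDs must be > 0")
  if (!all(conditions %in% names(stride_frequency)) ||
      !all(conditions %in% names(base_speed)))
    stop("stride_frequency and base_speed must be named for every condition")
  if (!all(rownames(profile) == groups$group) ||
      !all(colnames(profile) == conditions))
    stop("profile must have groups in rows and conditions in columns")
  if (any(profile < 0 | profile > 1)) stop("profile values must lie in [0, 1]")
  if (trials_per_condition < 1L) stop("trials_per_condition must be >= 1")
  if (path_m <= 0) stop("path_m must be > 0")
  structure(list(groups = groups, conditions = conditions,
                 stride_frequency = stride_frequency[conditions],
                 base_speed = base_speed[conditions],
                 trials_per_condition = as.integer(trials_per_condition),
                 path_m = path_m, profile = profile,
                 subject_alpha_cv = subject_alpha_cv,
                 speed_noise_cv = speed_noise_cv,
                 cadence_noise_cv = cadence_noise_cv,
                 stride_jitter_cv = stride_jitter_cv,
                 noise_sd = noise_sd, asymmetry_mode = asymmetry_mode, fs = fs),
            class = "cohort_design")
}

#' @export
print.cohort_design <- function(x, ...) {
  cat(sprintf("<cohort_design> %d groups, %d participants, %d conditions x %d trials, %g m path\n",
              nrow(x$groups), sum(x$groups$n), length(x$conditions),
              x$trials_per_condition, x$path_m))
  invisible(x)
}

# deterministic per-unit seed stream: fold ids into a Lehmer-style hash
hash_seed <- function(seed, ...) {
  x <- as.numeric(seed) %% 2147483647
  for (id in c(...)) {
    x <- (x * 48271 + as.numeric(id) * 16807 + 11) %% 2147483647
  }
  as.integer(x)
}

#' Draw one participant's anthropometrics
#'
#' Weight and height are drawn from a normal distribution with the group's
#' mean and SD, truncated at +/- 3 SD and at physiologic floors (weight
#' > 10 kg, height > 90 cm); age is uniform within the group range; sex is
#' a fair draw.
#'
#' @param group_label one of the seven group labels, see [gait_groups()].
#' @param seed integer seed for this participant's stream.
#' @param sd_scale multiplier on the group SDs (0 gives the group means
#'   exactly).
#' @return Data frame with one row: `group`, `age`, `sex`, `weight_kg`,
#'   `height_cm`.
#' @export
simulate_participant <- function(group_label, seed = 1L, sd_scale = 1) {
  tab <- anthro_table()
  i <- match(group_label, tab$group)
  if (is.na(i)) stop("unknown group label: ", group_label)
  set.seed(as.integer(seed))
  rtrunc <- function(mean, sd, floor_) {
    if (sd <= 0) return(mean)
    for (k in 1:1000) {
      x <- stats::rnorm(1L, mean, sd)
      if (abs(x - mean) <= 3 * sd && x > floor_) return(x)
    }
    mean
  }
  weight <- rtrunc(tab$weight_mean[i], sd_scale * tab$weight_sd[i], 10)
  height <- rtrunc(tab$height_mean[i], sd_scale * tab$height_sd[i], 90)
  age <- stats::runif(1L, tab$age_lo[i], tab$age_hi[i])
  sex <- if (stats::runif(1L) < 0.5) "M" else "F"
  data.frame(group = tab$group[i], age = round(age, 1), sex = sex,
             weight_kg = weight, height_cm = height, stringsAsFactors = FALSE)
}

#' Simulate a full walking cohort
#'
#' One trial record (and, optionally, the raw trace plus ground truth) per
#' participant x condition x trial. Stride frequency and walking speed
#' scale with the speed condition and with participant height; the
#' asymmetry level comes from the design's group-by-condition profile
#' multiplied by a per-participant lognormal factor. All randomness derives
#' reproducibly from `seed` via per-participant and per-trial hashed
#' streams, so results do not depend on evaluation order.
#'
#' @param design a [cohort_design()] object.
#' @param seed integer master seed.
#' @param keep_traces keep the simulated `raw_trace` objects (needed to run
#'   the processing pipeline in memory).
#' @param keep_truth keep the per-trial ground truth.
#' @return An object of class `gait_cohort`: list with `participants`
#'   (data frame), `trials` (data frame: `trial_id`, `participant_id`,
#'   `group`, `condition`, `trial`, `path_m`, `duration_s`, `alpha`,
#'   `n_strides`, `stride_frequency`, `true_speed`), `traces`, `truths`,
#'   `design`, `seed`.
#' @export
simulate_cohort <- function(design = cohort_design(), seed = 1L,
                            keep_traces = TRUE, keep_truth = TRUE) {
  if (!inherits(design, "cohort_design")) stop("design must be a cohort_design()")
  gt <- design$groups
  conds <- design$conditions
  n_part <- sum(gt$n)
  n_tr <- n_part * length(conds) * design$trials_per_condition
  participants <- vector("list", n_part)
  traces <- vector("list", n_tr)
  truths <- vector("list", n_tr)
  tcol <- list(trial_id = character(n_tr), participant_id = integer(n_tr),
               group = character(n_tr), condition = character(n_tr),
               trial = integer(n_tr), path_m = numeric(n_tr),
               duration_s = numeric(n_tr), alpha = numeric(n_tr),
               n_strides = integer(n_tr), stride_frequency = numeric(n_tr),
               true_speed = numeric(n_tr))
  ti <- 0L
  pid <- 0L
  ref_height <- 167  # cm, reference stature for the speed/cadence scaling
  for (gi in seq_len(nrow(gt))) {
    for (k in seq_len(gt$n[gi])) {
      pid <- pid + 1L
      pseed <- hash_seed(seed, gi * 1000L + k)
      pp <- simulate_participant(gt$group[gi], seed = pseed)
      pp$participant_id <- pid
      participants[[pid]] <- pp
      set.seed(hash_seed(pseed, 7L))
      u_alpha <- exp(stats::rnorm(1L, 0, design$subject_alpha_cv))
      cad_fac <- exp(stats::rnorm(length(conds), 0, design$cadence_noise_cv))
      spd_fac <- exp(stats::rnorm(length(conds), 0, design$speed_noise_cv))
      for (ci in seq_along(conds)) {
        cond <- conds[ci]
        f_stride <- design$stride_frequency[[cond]] * sqrt(ref_height / pp$height_cm) *
          cad_fac[ci]
        speed <- design$base_speed[[cond]] * (pp$height_cm / ref_height) * spd_fac[ci]
        n_strides <- max(5L, as.integer(round(design$path_m * f_stride / speed)))
        stride_len <- design$path_m / n_strides
        alpha <- min(1, design$profile[gt$group[gi], cond] * u_alpha)
        for (tr in seq_len(design$trials_per_condition)) {
          params <- gait_sim_params(stride_frequency = f_stride,
                                    n_strides = n_strides,
                                    stride_length_m = stride_len,
                                    asymmetry_alpha = alpha,
                                    asymmetry_mode = design$asymmetry_mode,
                                    stride_jitter_cv = design$stride_jitter_cv,
                                    noise_sd = design$noise_sd,
                                    fs = design$fs)
          sim <- simulate_trace(params, seed = hash_seed(pseed, ci, tr),
                                templates = keep_truth)
          tid <- sprintf("P%03d_%s_%d", pid, cond, tr)
          ti <- ti + 1L
          tcol$trial_id[ti] <- tid
          tcol$participant_id[ti] <- pid
          tcol$group[ti] <- gt$group[gi]
          tcol$condition[ti] <- cond
          tcol$trial[ti] <- tr
          tcol$path_m[ti] <- design$path_m
          tcol$duration_s[ti] <- sim$truth$duration
          tcol$alpha[ti] <- alpha
          tcol$n_strides[ti] <- n_strides
          tcol$stride_frequency[ti] <- f_stride
          tcol$true_speed[ti] <- sim$truth$true_mean_speed
          if (keep_traces) traces[[ti]] <- sim$trace
          if (keep_truth) truths[[ti]] <- sim$truth
        }
      }
    }
  }
  names(traces) <- names(truths) <- tcol$trial_id
  structure(list(participants = do.call(rbind, participants),
                 trials = as.data.frame(tcol, stringsAsFactors = FALSE),
                 traces = if (keep_traces) traces else list(),
                 truths = if (keep_truth) truths else list(),
                 design = design, seed = as.integer(seed)),
            class = "gait_cohort")
}

#' @export
print.gait_cohort <- function(x, ...) {
  cat(sprintf("<gait_cohort> %d participants in %d groups, %d trials (seed %d)\n",
              nrow(x$participants), length(unique(x$participants$group)),
              nrow(x$trials), x$seed))
  invisible(x)
}
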