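#' Pipeline configuration
#'
#' Collects the tunable processing parameters with their documented
#' defaults: filter settings, axis mapping from raw columns to the
#' (forward, lateral, vertical-ish) sensor axes, detector thresholds, the
#' percent-of-cycle grid size, the minimum cycle count quality gate, and
#' the trial aggregation strategy.
#'
#' @param cutoff_hz low-pass cutoff (Hz).
#' @param filter_order Butterworth order per pass.
#' @param axes names of the raw trace columns mapped to the forward,
#'   lateral and vertical sensor axes, in that order.
#' @param k_mad detector threshold MAD multiplier.
#' @param min_sep_frac detector minimum peak separation (fraction of step
#'   period).
#' @param positive_ml side-labeling sign convention.
#' @param window_s side-labeling ML window half-width (s).
#' @param duration_gate cycle duration plausibility gate (s).
#' @param P points of the percent-of-cycle grid.
#' @param min_cycles minimum total cycles per trial before a quality flag
#'   is raised.
#' @param aggregation `"mean"` (mean SI across a condition's trials) or
#'   `"pool"` (pool all cycles, then one SI).
#' @param g gravitational acceleration (m/s^2).
#' @return A list of class `gait_config`.
#' @export
gait_config <- function(cutoff_hz = 10, filter_order = 4L,
                        axes = c("ax", "ay", "az"),
                        k_mad = 1, min_sep_frac = 0.35,
                        positive_ml = "right", window_s = 0.05,
                        duration_gate = c(0.6, 2.5),
                        P = 101L, min_cycles = 5L,
                        aggregation = c("mean", "pool"),
                        g = 9.81) {
  aggregation <- match.arg(aggregation)
  if (length(axes) != 3L) stop("axes must name 3 columns")
  if (P < 3L) stop("P must be >= 3")
  if (duration_gate[1L] >= duration_gate[2L]) stop("invalid duration gate")
  structure(list(cutoff_hz = cutoff_hz, filter_order = as.integer(filter_order),
                 axes = axes, k_mad = k_mad, min_sep_frac = min_sep_frac,
                 positive_ml = positive_ml, window_s = window_s,
                 duration_gate = duration_gate, P = as.integer(P),
                 min_cycles = as.integer(min_cycles),
                 aggregation = aggregation, g = g),
            class = "gait_config")
}

#' Pearson correlation between the side-mean waveforms
#'
#' Standard product-moment correlation of the two length-P vectors. A
#' zero-variance waveform makes the correlation undefined and raises an
#' error rather than silently returning 0.
#'
#' @param left,right [mean_waveform()] objects or plain numeric vectors of
#'   equal length.
#' @return The correlation r in \[-1, 1\].
#' @examples
#' pearson_r(c(1, 2, 3, 4), c(1, 3, 2, 4))  # 0.8
#' @export
pearson_r <- function(left, right) {
  wl <- if (inherits(left, "side_mean")) left$waveform else as.numeric(left)
  wr <- if (inherits(right, "side_mean")) right$waveform else as.numeric(right)
  if (length(wl) != length(wr))
    stop("left and right waveforms must have equal length")
  if (stats::var(wl) == 0 || stats::var(wr) == 0)
    stop("zero-variance waveform: Pearson correlation is undefined")
  stats::cor(wl, wr)
}

#' Map a correlation onto the 0-100 Symmetry Index
#'
#' SI = (r + 1) * 100 / 2. SI of 100 means the left and right mean AP
#' waveforms are identical up to a positive affine transform; 0 means they
#' are exactly anti-correlated.
#'
#' @param r Pearson correlation in \[-1, 1\]. Floating-point overshoot up
#'   to `tol` beyond 1 in magnitude is clamped; larger overshoot errors.
#' @param tol clamping tolerance.
#' @return The symmetry index in \[0, 100\].
#' @examples
#' symmetry_index(1)    # 100
#' symmetry_index(-1)   # 0
#' symmetry_index(0.8)  # 90
#' @export
symmetry_index <- function(r, tol = 1e-12) {
  if (!is.finite(r)) stop("r must be finite")
  if (abs(r) > 1 + tol)
    stop(sprintf("|r| = %.15g exceeds 1 beyond the %g tolerance", abs(r), tol))
  r <- min(1, max(-1, r))
  (r + 1) * 100 / 2
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE))
}

#' Compute the Symmetry Index of one trial
#'
#' Runs the full processing chain on a raw trace: low-pass filter, tilt
#' estimation, earth-frame rotation with gravity removal, AP extraction,
#' initial-contact detection, side labeling, cycle splitting,
#' time normalization, side means, Pearson r and the SI mapping. Stage
#' errors are re-raised with the stage name attached.
#'
#' @param trace a [raw_trace()].
#' @param config a [gait_config()].
#' @param participant_id,condition,trial optional identifiers carried into
#'   the result.
#' @return Object of class `gait_si`: list with `r`, `si`, `n_left`,
#'   `n_right`, the side-mean waveforms, the normalized cycle matrices,
#'   the labeled events, QC information and the identifiers.
#' @export
compute_trial_si <- function(trace, config = gait_config(),
                             participant_id = NA, condition = NA_character_,
                             trial = NA_integer_) {
  if (!inherits(trace, "raw_trace")) stop("trace must be a raw_trace")
  if (!all(config$axes %in% colnames(trace$data)))
    stop("config axes not found in the trace columns")
  tr <- trace
  tr$data <- trace$data[, config$axes, drop = FALSE]
  colnames(tr$data) <- c("ax", "ay", "az")

  filt <- with_stage("filter",
                     lowpass_filter(tr, config$cutoff_hz, config$filter_order))
  tilt <- with_stage("tilt", estimate_tilt(filt))
  earth <- with_stage("earth_frame", to_earth_frame(filt, tilt, g = config$g))
  ap <- with_stage("extract_ap", extract_ap(earth))
  ml <- earth$data[, "ml"]
  events <- with_stage("detect_contacts",
                       detect_initial_contacts(ap, v = earth$data[, "v"],
                                               fs = earth$fs,
                                               k_mad = config$k_mad,
                                               min_sep_frac = config$min_sep_frac))
  events <- with_stage("label_sides",
                       label_sides(events, ml, fs = earth$fs,
                                   positive_ml = config$positive_ml,
                                   window_s = config$window_s))
  cycles <- with_stage("split_cycles",
                       split_cycles(events, duration_gate = config$duration_gate))
  norm <- with_stage("time_normalize", {
    lapply(c(left = "left", right = "right"), function(sd_) {
      cc <- cycles[cycles$side == sd_, , drop = FALSE]
      t(vapply(seq_len(nrow(cc)), function(i)
        time_normalize(ap, cc$start_index[i], cc$end_index[i], P = config$P),
        numeric(config$P)))
    })
  })
  lm_ <- with_stage("mean_waveform", mean_waveform(norm$left, "left"))
  rm_ <- with_stage("mean_waveform", mean_waveform(norm$right, "right"))
  n_total <- lm_$n_cycles + rm_$n_cycles
  qc_flags <- character(0)
  if (n_total < config$min_cycles) {
    qc_flags <- c(qc_flags, sprintf("fewer than %d cycles (%d)", config$min_cycles, n_total))
    warning(sprintf("trial has %d cycles, fewer than the %d-cycle quality gate",
                    n_total, config$min_cycles))
  }
  r <- with_stage("pearson_r", pearson_r(lm_, rm_))
  si <- with_stage("symmetry_index", symmetry_index(r))
  structure(list(r = r, si = si,
                 n_left = lm_$n_cycles, n_right = rm_$n_cycles,
                 left_mean = lm_$waveform, right_mean = rm_$waveform,
                 cycles_left = norm$left, cycles_right = norm$right,
                 events = events, tilt = tilt,
                 qc = list(flags = qc_flags,
                           n_events = nrow(events),
                           dropped = attr(cycles, "dropped"),
                           duration_s = nrow(trace$data) / trace$fs),
                 participant_id = participant_id, condition = condition,
                 trial = trial, config = config),
            class = "gait_si")
}

#' @export
print.gait_si <- function(x, ...) {
  cat(sprintf("<gait_si> SI = %.3f (r = %.5f), %d left / %d right cycles\n",
              x$si, x$r, x$n_left, x$n_right))
  if (length(x$qc$flags))
    cat("  QC flags:", paste(x$qc$flags, collapse = "; "), "\n")
  invisible(x)
}

#' @export
summary.gait_si <- function(object, ...) {
  print(object)
  cat(sprintf("  events: %d; tilt pitch/roll: %.2f / %.2f deg\n",
              object$qc$n_events, object$tilt$pitch * 180 / pi,
              object$tilt$roll * 180 / pi))
  invisible(object)
}

#' @export
plot.gait_si <- function(x, ...) {
  pct <- seq(0, 100, length.out = length(x$left_mean))
  ylim <- range(x$left_mean, x$right_mean)
  graphics::plot(pct, x$left_mean, type = "l", col = "firebrick", ylim = ylim,
                 xlab = "gait cycle (%)", ylab = "AP acceleration (m/s^2)",
                 main = sprintf("SI = %.1f (r = %.3f)", x$si, x$r), ...)
  graphics::lines(pct, x$right_mean, col = "navy")
  graphics::legend("topright", c("left", "right"), col = c("firebrick", "navy"),
                   lty = 1, bty = "n")
  invisible(x)
}

#' Aggregate trial symmetry results per participant and condition
#'
#' The study design has three trials per speed condition but reports one SI
#' per participant-condition. The default combiner is the arithmetic mean
#' of the trial SIs; the `"pool"` strategy instead pools all normalized
#' cycles of the condition's trials, recomputes the side means and derives
#' a single SI.
#'
#' @param trials list of [compute_trial_si()] results carrying
#'   `participant_id` and `condition`.
#' @param strategy `"mean"` or `"pool"`.
#' @param conditions optional full set of expected conditions; a
#'   participant missing a condition then yields a flagged `NA` row rather
#'   than a silent drop.
#' @return Data frame with one row per participant x condition:
#'   `participant_id`, `condition`, `si`, `n_trials`, `n_left`, `n_right`,
#'   `qc`.
#' @export
aggregate_si <- function(trials, strategy = c("mean", "pool"), conditions = NULL) {
  strategy <- match.arg(strategy)
  if (length(trials) == 0L) stop("no trial results to aggregate")
  key <- data.frame(
    participant_id = vapply(trials, function(x) as.character(x$participant_id), ""),
    condition = vapply(trials, function(x) as.character(x$condition), ""),
    si = vapply(trials, function(x) x$si, 0),
    n_left = vapply(trials, function(x) x$n_left, 0L),
    n_right = vapply(trials, function(x) x$n_right, 0L),
    stringsAsFactors = FALSE)
  pids <- unique(key$participant_id)
  conds_all <- if (is.null(conditions)) unique(key$condition) else conditions
  grid <- expand.grid(participant_id = pids, condition = conds_all,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cell <- interaction(key$participant_id, key$condition, drop = FALSE)
  gcell <- factor(paste(grid$participant_id, grid$condition, sep = "."),
                  levels = levels(cell))
  si <- if (strategy == "mean") {
    as.numeric(tapply(key$si, cell, mean)[gcell])
  } else {
    vapply(seq_len(nrow(grid)), function(i) {
      sel <- which(key$participant_id == grid$participant_id[i] &
                     key$condition == grid$condition[i])
      if (length(sel) == 0L) return(NA_real_)
      pl <- do.call(rbind, lapply(trials[sel], function(x) x$cycles_left))
      pr <- do.call(rbind, lapply(trials[sel], function(x) x$cycles_right))
      symmetry_index(pearson_r(mean_waveform(pl, "left"),
                               mean_waveform(pr, "right")))
    }, numeric(1L))
  }
  n_trials <- as.integer(tapply(rep(1L, nrow(key)), cell, sum)[gcell])
  n_trials[is.na(n_trials)] <- 0L
  sum0 <- function(x) {
    out <- as.integer(tapply(x, cell, sum)[gcell])
    out[is.na(out)] <- 0L
    out
  }
  data.frame(participant_id = grid$participant_id, condition = grid$condition,
             si = si, n_trials = n_trials,
             n_left = sum0(key$n_left), n_right = sum0(key$n_right),
             qc = ifelse(n_trials == 0L, "missing condition", ""),
             stringsAsFactors = FALSE)
}
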