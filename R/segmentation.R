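#' Detect initial contacts from the AP acceleration
#'
#' Initial contacts are taken as positive AP peaks. The dominant step
#' period is first read off the AP power spectrum (zero-padded FFT,
#' searched over `band`); a peak must exceed an adaptive amplitude
#' threshold, `median + k_mad * MAD`, and candidate peaks closer than
#' `min_sep_frac` of the step period are resolved in favour of the taller
#' one.
#'
#' @param ap numeric AP series (m/s^2), low-pass filtered.
#' @param v optional vertical series; unused by this detector and accepted
#'   for interface compatibility.
#' @param fs sampling frequency (Hz).
#' @param k_mad MAD multiplier of the adaptive threshold.
#' @param min_sep_frac minimum peak separation as a fraction of the
#'   dominant step period.
#' @param band frequency band (Hz) searched for the step rate.
#' @param prominence_floor minimum ratio of the spectral peak to the median
#'   in-band power; below it a "no gait detected" error is raised.
#' @return Data frame of class `gait_events`: `sample_index` (integer peak
#'   sample), `position` (sub-sample peak location from a quadratic fit
#'   through the peak and its neighbours), `time` (s, from `position`) and
#'   `side` (unset, `NA`). The estimated step period (s) is attached as
#'   attribute `step_period`.
#' @export
detect_initial_contacts <- function(ap, v = NULL, fs, k_mad = 1,
                                    min_sep_frac = 0.35,
                                    band = c(0.8, 4), prominence_floor = 10) {
  if (length(ap) < 2 * fs)
    stop("need at least 2 s of signal to detect gait")
  x <- ap - mean(ap)
  if (stats::sd(x) < 1e-10)
    stop("no gait detected: signal is constant")
  nfft <- 2^ceiling(log2(max(2L * length(x), 1024L)))
  pw <- Mod(stats::fft(c(x, numeric(nfft - length(x)))))^2
  freq <- (seq_len(nfft) - 1L) * fs / nfft
  in_band <- freq >= band[1L] & freq <= band[2L]
  if (!any(in_band)) stop("no gait detected: frequency band is empty")
  pk <- which.max(pw[in_band])
  if (pw[in_band][pk] < prominence_floor * stats::median(pw[in_band]))
    stop("no gait detected: no dominant periodicity in the step band")
  step_period <- 1 / freq[in_band][pk]

  thr <- stats::median(ap) + k_mad * stats::mad(ap)
  d <- diff(ap)
  cand <- which(d[-length(d)] > 0 & d[-1L] <= 0) + 1L
  cand <- cand[ap[cand] > thr]
  if (length(cand) == 0L)
    stop("no gait detected: no AP peaks above the adaptive threshold")
  # greedy by height with a minimum separation
  min_sep <- min_sep_frac * step_period * fs
  ord <- cand[order(ap[cand], decreasing = TRUE)]
  kept <- integer(0)
  for (i in ord) {
    if (all(abs(kept - i) >= min_sep)) kept <- c(kept, i)
  }
  kept <- sort(kept)
  # sub-sample refinement: quadratic fit through the peak and its neighbours
  pos <- vapply(kept, function(i) {
    if (i <= 1L || i >= length(ap)) return(as.numeric(i))
    den <- ap[i - 1L] - 2 * ap[i] + ap[i + 1L]
    delta <- if (abs(den) < 1e-12) 0 else 0.5 * (ap[i - 1L] - ap[i + 1L]) / den
    i + max(-0.5, min(0.5, delta))
  }, numeric(1L))
  ev <- data.frame(sample_index = kept, position = pos, time = (pos - 1) / fs,
                   side = NA_character_, stringsAsFactors = FALSE)
  attr(ev, "step_period") <- step_period
  class(ev) <- c("gait_events", "data.frame")
  ev
}

#' Assign left/right sides to detected contacts
#'
#' The side of each contact is read from the sign of the mean mediolateral
#' acceleration in a window of +/- `window_s` around the contact (the trunk
#' sways toward the stance side). Alternation is enforced: whenever two
#' consecutive events share a side, the event with the weaker ML evidence
#' is flipped.
#'
#' @param events a `gait_events` data frame from
#'   [detect_initial_contacts()].
#' @param ml mediolateral series (m/s^2).
#' @param fs sampling frequency (Hz).
#' @param positive_ml which side a positive ML mean maps to (`"right"`,
#'   the default convention, or `"left"`).
#' @param window_s half-width of the averaging window (s).
#' @param floor noise floor (m/s^2); if every window mean is below it in
#'   magnitude, a "sides indeterminate" error is raised.
#' @return The events with `side` set.
#' @export
label_sides <- function(events, ml, fs, positive_ml = c("right", "left"),
                        window_s = 0.05, floor = 1e-6) {
  positive_ml <- match.arg(positive_ml)
  if (nrow(events) < 2L) stop("need at least 2 events to label sides")
  w <- max(1L, round(window_s * fs))
  means <- vapply(events$sample_index, function(i) {
    lo <- max(1L, i - w); hi <- min(length(ml), i + w)
    mean(ml[lo:hi])
  }, numeric(1L))
  if (all(abs(means) < floor))
    stop("sides indeterminate: ML evidence below the noise floor at every contact")
  other <- if (positive_ml == "right") "left" else "right"
  side <- ifelse(means > 0, positive_ml, other)
  # enforce alternation: flip the weaker of two consecutive duplicates
  for (pass in seq_len(nrow(events))) {
    dup <- which(side[-1L] == side[-length(side)])
    if (length(dup) == 0L) break
    i <- dup[1L]
    flip <- if (abs(means[i + 1L]) < abs(means[i])) i + 1L else i
    side[flip] <- if (side[flip] == "left") "right" else "left"
  }
  events$side <- side
  events
}

#' Split contacts into per-side gait cycles
#'
#' A gait cycle (stride) runs from one initial contact to the next
#' ipsilateral contact, as a half-open sample interval. Cycles whose
#' duration falls outside the plausibility gate are dropped with a logged
#' reason.
#'
#' @param events labeled `gait_events` (>= 3 rows).
#' @param duration_gate admissible cycle duration range in seconds.
#' @return Data frame with columns `side`, `start_index`, `end_index`
#'   (half-open), `duration`; dropped cycles are attached as attribute
#'   `dropped`.
#' @export
split_cycles <- function(events, duration_gate = c(0.6, 2.5)) {
  if (nrow(events) < 3L) stop("need at least 3 labeled events to form cycles")
  if (anyNA(events$side)) stop("events must have sides assigned")
  pos <- if ("position" %in% names(events)) events$position else events$sample_index
  parts <- lapply(c("left", "right"), function(sd_) {
    sel <- events$side == sd_
    ev_pos <- pos[sel]; ev_time <- events$time[sel]
    if (length(ev_pos) < 2L) return(NULL)
    i <- seq_len(length(ev_pos) - 1L)
    data.frame(side = sd_, start_index = ev_pos[i],
               end_index = ev_pos[i + 1L],
               duration = ev_time[i + 1L] - ev_time[i],
               stringsAsFactors = FALSE)
  })
  all_cycles <- do.call(rbind, parts)
  if (is.null(all_cycles))
    all_cycles <- data.frame(side = character(0), start_index = integer(0),
                             end_index = integer(0), duration = numeric(0))
  bad <- all_cycles$duration < duration_gate[1L] | all_cycles$duration > duration_gate[2L]
  cycles <- all_cycles[!bad, , drop = FALSE]
  dropped <- NULL
  if (any(bad)) {
    dropped <- all_cycles[bad, , drop = FALSE]
    dropped$reason <- sprintf("duration %.2f s outside [%g, %g] s gate",
                              dropped$duration, duration_gate[1L], duration_gate[2L])
  }
  if (!is.null(dropped))
    message(sprintf("split_cycles: dropped %d cycle(s): %s",
                    nrow(dropped), paste(unique(dropped$reason), collapse = "; ")))
  for (sd_ in c("left", "right")) {
    if (!any(cycles$side == sd_))
      stop(sprintf("fewer than 1 valid %s cycle after the duration gate", sd_))
  }
  attr(cycles, "dropped") <- dropped
  cycles
}

#' Time-normalize one gait cycle onto a percent-of-cycle grid
#'
#' Linearly interpolates the cycle's AP samples onto `P` evenly spaced
#' points over the half-open interval `[start, end)`: point `k` sits at
#' `start + k*(end-start)/P`, `k = 0..P-1`, so the first point equals the
#' AP value at the starting contact and a cycle of exactly `P` samples is
#' returned unchanged.
#'
#' @param ap AP series.
#' @param start_index,end_index cycle bounds (half-open interval; may be
#'   fractional when contacts were refined to sub-sample positions).
#' @param P number of grid points (default 101, the 0-100% grid).
#' @return Numeric vector of length `P`.
#' @export
time_normalize <- function(ap, start_index, end_index, P = 101L) {
  len <- end_index - start_index
  lo <- floor(start_index); hi <- ceiling(end_index)
  if (lo < 1L || hi > length(ap))
    stop("cycle lies outside the signal bounds")
  if (len < 4) stop("cycle too short to normalize (need >= 4 samples)")
  xout <- start_index + (0:(P - 1L)) * len / P
  stats::approx(x = lo:hi, y = ap[lo:hi], xout = xout)$y
}

#' Pointwise mean of a side's normalized cycles
#'
#' @param cycles matrix of normalized cycles (rows = cycles, columns = the
#'   percent-of-cycle grid).
#' @param side `"left"` or `"right"`.
#' @return Object of class `side_mean`: list with `side`, `waveform`
#'   (length-P numeric) and `n_cycles`.
#' @export
mean_waveform <- function(cycles, side = c("left", "right")) {
  side <- match.arg(side)
  if (!is.matrix(cycles)) cycles <- matrix(cycles, nrow = 1L)
  if (nrow(cycles) == 0L)
    stop(sprintf("no %s cycles to average", side))
  structure(list(side = side, waveform = colMeans(cycles),
                 n_cycles = nrow(cycles)),
            class = "side_mean")
}

#' @export
print.side_mean <- function(x, ...) {
  cat(sprintf("<side_mean> %s, mean of %d cycle(s) on %d points\n",
              x$side, x$n_cycles, length(x$waveform)))
  invisible(x)
}
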