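.butter_cache <- new.env(parent = emptyenv())

butter_cached <- function(order, W) {
  key <- sprintf("%d_%.12g", order, W)
  bf <- get0(key, envir = .butter_cache)
  if (is.null(bf)) {
    f <- signal::butter(order, W, type = "low")
    bf <- list(b = as.numeric(f$b), a = as.numeric(f$a))
    assign(key, bf, envir = .butter_cache)
  }
  bf
}

#' Zero-phase low-pass Butterworth filter
#'
#' Filters each axis forward and backward with a Butterworth low-pass
#' (two passes, so the effective magnitude response is the squared
#' single-pass magnitude and the phase is zero). Edges are handled with
#' odd-reflection padding of 3 x order samples; each pass is run on the
#' signal offset by its leading edge value, so a constant signal passes
#' through exactly.
#'
#' @param trace a [raw_trace()] (or [earth_trace()]).
#' @param cutoff_hz cutoff frequency in Hz, must be < fs/2 (default 10).
#' @param order filter order per pass (default 4).
#' @return A filtered object of the same class and length.
#' @examples
#' tr <- raw_trace(matrix(rnorm(600), ncol = 3), fs = 100)
#' lowpass_filter(tr)
#' @export
lowpass_filter <- function(trace, cutoff_hz = 10, order = 4L) {
  if (!inherits(trace, c("raw_trace", "earth_trace")))
    stop("trace must be a raw_trace or earth_trace")
  fs <- trace$fs
  if (cutoff_hz <= 0 || cutoff_hz >= fs / 2)
    stop("cutoff_hz must lie in (0, fs/2)")
  n <- nrow(trace$data)
  min_n <- 4L * order + 1L
  if (n < min_n)
    stop(sprintf("trace too short for stable two-pass filtering: %d samples, need at least %d",
                 n, min_n))
  bf <- butter_cached(order, cutoff_hz / (fs / 2))
  pad <- 3L * order
  nb <- length(bf$b)
  one_pass <- function(x) {
    # direct-form IIR with zero initial conditions on the offset signal
    x0 <- x[1L]
    xz <- c(numeric(nb - 1L), x - x0)
    z <- stats::filter(xz, bf$b, method = "convolution", sides = 1L)[nb - 1L + seq_along(x)]
    as.numeric(stats::filter(z, -bf$a[-1L], method = "recursive")) + x0
  }
  filt_axis <- function(x) {
    xp <- c(2 * x[1L] - x[(pad + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - pad)])
    fwd <- one_pass(xp)
    bwd <- rev(one_pass(rev(fwd)))
    bwd[(pad + 1L):(pad + n)]
  }
  out <- trace
  out$data <- apply(trace$data, 2L, filt_axis)
  colnames(out$data) <- colnames(trace$data)
  out
}

#' Estimate static sensor tilt from the trial-mean acceleration
#'
#' Over a steady walking trial the periodic gait components average out and
#' the mean sensor-frame acceleration points along gravity. The gravity
#' direction is the normalized per-axis mean; pitch and roll are the static
#' inclination angles that rotate the earth vertical onto it (pitch about
#' the lateral axis applied first, then roll about the forward axis).
#'
#' @param trace a [raw_trace()], ideally containing at least 2 full
#'   strides.
#' @return An object of class `tilt_estimate`: list with `pitch`, `roll`
#'   (rad) and the unit `gravity_vector` in the sensor frame.
#' @export
estimate_tilt <- function(trace) {
  if (!inherits(trace, "raw_trace")) stop("trace must be a raw_trace")
  m <- colMeans(trace$data)
  nm <- sqrt(sum(m^2))
  if (nm < 1)
    stop("mean acceleration norm is near zero (free-fall-like input); cannot estimate gravity direction")
  u <- m / nm
  pitch <- asin(min(1, max(-1, u[[1L]])))
  roll <- atan2(-u[[2L]], u[[3L]])
  structure(list(pitch = pitch, roll = roll, gravity_vector = unname(u)),
            class = "tilt_estimate")
}

#' @export
print.tilt_estimate <- function(x, ...) {
  cat(sprintf("<tilt_estimate> pitch %.2f deg, roll %.2f deg\n",
              x$pitch * 180 / pi, x$roll * 180 / pi))
  invisible(x)
}

#' Rotate a sensor-frame trace into the earth frame and remove gravity
#'
#' Applies the inverse tilt rotation (an isometry: per-sample norms are
#' preserved), then subtracts the static gravity vector (0, 0, g). The
#' resulting axes are anterior-posterior, mediolateral and vertical.
#'
#' @param trace a [raw_trace()].
#' @param tilt a [estimate_tilt()] result.
#' @param g gravitational acceleration to subtract (m/s^2).
#' @return An [earth_trace()] of the same length.
#' @export
to_earth_frame <- function(trace, tilt, g = 9.81) {
  if (!inherits(trace, "raw_trace")) stop("trace must be a raw_trace")
  if (!inherits(tilt, "tilt_estimate")) stop("tilt must be a tilt_estimate")
  S <- tilt_matrix(tilt$pitch, tilt$roll)
  rotated <- trace$data %*% S  # rows a_e' = a_s' S since a_e = t(S) a_s
  rotated[, 3L] <- rotated[, 3L] - g
  earth_trace(rotated, fs = trace$fs)
}

#' Extract the anterior-posterior acceleration series
#'
#' Pure projection onto the AP axis of an earth-frame trace; the series the
#' symmetry index is computed from.
#'
#' @param trace an [earth_trace()].
#' @return Numeric vector of AP acceleration (m/s^2).
#' @export
extract_ap <- function(trace) {
  if (!inherits(trace, "earth_trace")) stop("trace must be an earth_trace")
  unname(trace$data[, "ap"])
}
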