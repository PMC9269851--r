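#' Raw sensor-frame acceleration trace
#'
#' Container for a triaxial accelerometer recording at a fixed sampling
#' rate. Values are accelerations in m/s^2 in the (arbitrary, possibly
#' tilted) sensor frame; a static sensor aligned with gravity reads
#' (0, 0, g).
#'
#' @param data numeric matrix with columns `ax`, `ay`, `az` (m/s^2), one row
#'   per sample.
#' @param fs sampling frequency in Hz.
#' @return An object of class `raw_trace`: a list with elements `fs` and
#'   `data`.
#' @examples
#' tr <- raw_trace(cbind(ax = rnorm(200), ay = rnorm(200), az = 9.81 + rnorm(200)), fs = 100)
#' tr
#' @export
raw_trace <- function(data, fs) {
  data <- as.matrix(data)
  if (ncol(data) != 3L)
    stop("a raw trace needs exactly 3 axis columns (ax, ay, az)")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("fs must be a single positive number (Hz)")
  if (!all(is.finite(data)))
    stop("raw trace contains non-finite values")
  colnames(data) <- c("ax", "ay", "az")
  structure(list(fs = fs, data = data), class = "raw_trace")
}

#' Earth-frame, gravity-free acceleration trace
#'
#' Holds anterior-posterior (AP), mediolateral (ML) and vertical (V)
#' acceleration after tilt correction and removal of the static gravity
#' vector. Over steady straight-line walking each axis has approximately
#' zero mean.
#'
#' @param data numeric matrix with columns `ap`, `ml`, `v` (m/s^2).
#' @param fs sampling frequency in Hz.
#' @return An object of class `earth_trace`.
#' @export
earth_trace <- function(data, fs) {
  data <- as.matrix(data)
  if (ncol(data) != 3L)
    stop("an earth trace needs exactly 3 axis columns (ap, ml, v)")
  colnames(data) <- c("ap", "ml", "v")
  structure(list(fs = fs, data = data), class = "earth_trace")
}

#' @export
print.raw_trace <- function(x, ...) {
  cat(sprintf("<raw_trace> %d samples at %g Hz (%.2f s), sensor frame\n",
              nrow(x$data), x$fs, nrow(x$data) / x$fs))
  rng <- apply(x$data, 2, range)
  cat(sprintf("  %s: [%.2f, %.2f] m/s^2\n", colnames(x$data), rng[1, ], rng[2, ]), sep = "")
  invisible(x)
}

#' @export
print.earth_trace <- function(x, ...) {
  cat(sprintf("<earth_trace> %d samples at %g Hz, gravity removed\n",
              nrow(x$data), x$fs))
  m <- colMeans(x$data)
  cat(sprintf("  mean ap/ml/v: %.3f / %.3f / %.3f m/s^2\n", m[1], m[2], m[3]))
  invisible(x)
}

#' @export
plot.earth_trace <- function(x, ...) {
  t <- (seq_len(nrow(x$data)) - 1) / x$fs
  graphics::matplot(t, x$data, type = "l", lty = 1,
                    xlab = "time (s)", ylab = "acceleration (m/s^2)", ...)
  graphics::legend("topright", legend = c("AP", "ML", "V"), col = 1:3, lty = 1, bty = "n")
  invisible(x)
}
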