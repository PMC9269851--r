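# Independent oracles used against the package implementation.

# Analytic squared-magnitude (two-pass) gain of the digital Butterworth
# low-pass designed by bilinear transform: the prototype frequency axis is
# prewarped, so the gain at f is 1 / (1 + (tan(pi f/fs)/tan(pi fc/fs))^(2n))
oracle_butter_gain2 <- function(f, fs, cutoff, order) {
  1 / (1 + (tan(pi * f / fs) / tan(pi * cutoff / fs))^(2 * order))
}

# Least-squares amplitude of a known-frequency sinusoid on a sample subset
fit_amplitude <- function(x, f, fs, idx = seq_along(x)) {
  t <- (idx - 1) / fs
  X <- cbind(1, sin(2 * pi * f * t), cos(2 * pi * f * t))
  cf <- qr.solve(X, x[idx])
  sqrt(cf[2]^2 + cf[3]^2)
}

# Hand-rolled Pearson correlation (independent of stats::cor)
oracle_pearson <- function(a, b) {
  da <- a - sum(a) / length(a)
  db <- b - sum(b) / length(b)
  sum(da * db) / sqrt(sum(da^2) * sum(db^2))
}

# Template-level SI straight from the generator ground truth, bypassing
# tilt estimation, contact detection, side labeling and cycle splitting:
# raw-template variant ignores the method's low-pass entirely
oracle_template_si <- function(truth) {
  ml <- colMeans(truth$templates$left)
  mr <- colMeans(truth$templates$right)
  (oracle_pearson(ml, mr) + 1) * 50
}

# Straight-line oracle for the full noiseless chain: apply the method's
# prescribed two-pass Butterworth to the noiseless AP (own filtering code,
# long odd padding), slice at the generator's true contact times, linearly
# interpolate to the 101-point grid by hand, average per side, Pearson, SI
oracle_si_straightline <- function(sim, cutoff = 10, order = 4) {
  ap <- sim$truth$earth_clean[, "ap"]
  fs <- sim$trace$fs
  bf <- signal::butter(order, cutoff / (fs / 2))
  n <- length(ap)
  pad <- min(n - 1, 300)
  xp <- c(2 * ap[1] - ap[(pad + 1):2], ap, 2 * ap[n] - ap[(n - 1):(n - pad)])
  fwd <- as.numeric(signal::filter(bf, xp - xp[1])) + xp[1]
  y <- rev(as.numeric(signal::filter(bf, rev(fwd) - fwd[length(fwd)]))) + fwd[length(fwd)]
  y <- y[(pad + 1):(pad + n)]
  wf <- function(s) {
    tt <- sim$truth$ic$time[sim$truth$ic$side == s]
    m <- sapply(seq_len(length(tt) - 1), function(i) {
      pos <- 1 + (tt[i] + (0:100) / 101 * (tt[i + 1] - tt[i])) * fs
      lo <- floor(pos); fr <- pos - lo
      y[lo] * (1 - fr) + y[lo + 1] * fr
    })
    rowMeans(m)
  }
  (oracle_pearson(wf("left"), wf("right")) + 1) * 50
}

# Split-plot ANOVA by explicit projection-matrix sums of squares:
# SS(effect) = |P2 y|^2 - |P1 y|^2 for nested column spaces, via QR.
oracle_splitplot <- function(d) {
  proj_ss <- function(X) sum(qr.fitted(qr(X), d$y)^2)
  one <- matrix(1, nrow(d), 1)
  G <- if (nlevels(d$group) > 1) stats::model.matrix(~ 0 + group, d) else one
  S <- stats::model.matrix(~ 0 + subject, d)
  C <- stats::model.matrix(~ 0 + condition, d)
  GC <- if (nlevels(d$group) > 1)
    stats::model.matrix(~ 0 + group:condition, d) else C
  ss1 <- proj_ss(one)
  ssG <- proj_ss(G)
  ssS <- proj_ss(S)           # subjects nested in groups: span(S) > span(G)
  ssSC <- proj_ss(cbind(S, C))
  ssSCI <- proj_ss(cbind(S, C, GC))
  sstot <- sum(d$y^2)
  k <- nlevels(d$condition); g <- nlevels(d$group)
  N <- nlevels(d$subject)
  ss_group <- ssG - ss1
  ss_suberr <- ssS - ssG
  ss_cond <- ssSC - ssS
  ss_int <- ssSCI - ssSC
  ss_res <- sstot - ssSCI
  list(
    ss = c(group = ss_group, condition = ss_cond, interaction = ss_int,
           subj_err = ss_suberr, resid = ss_res),
    F = c(group = (ss_group / (g - 1)) / (ss_suberr / (N - g)),
          condition = (ss_cond / (k - 1)) / (ss_res / ((N - g) * (k - 1))),
          interaction = (ss_int / ((g - 1) * (k - 1))) / (ss_res / ((N - g) * (k - 1)))))
}

# Generalized eigenvalues of det(B - lambda W) = 0 for 2x2 matrices,
# by the closed-form quadratic in lambda
oracle_gen_eigen2 <- function(B, W) {
  a <- W[1, 1] * W[2, 2] - W[1, 2] * W[2, 1]
  b <- -(B[1, 1] * W[2, 2] + B[2, 2] * W[1, 1] - B[1, 2] * W[2, 1] - B[2, 1] * W[1, 2])
  cc <- B[1, 1] * B[2, 2] - B[1, 2] * B[2, 1]
  disc <- sqrt(max(0, b^2 - 4 * a * cc))
  sort(c((-b + disc) / (2 * a), (-b - disc) / (2 * a)), decreasing = TRUE)
}

# Between and within scatter matrices of a labeled feature matrix
scatter_matrices <- function(X, g) {
  g <- factor(g)
  grand <- colMeans(X)
  W <- matrix(0, ncol(X), ncol(X)); B <- W
  for (lev in levels(g)) {
    Xg <- X[g == lev, , drop = FALSE]
    mg <- colMeans(Xg)
    W <- W + crossprod(sweep(Xg, 2, mg))
    B <- B + nrow(Xg) * tcrossprod(mg - grand)
  }
  list(B = B, W = W)
}
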