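#' Canonical linear discriminant analysis of the age groups
#'
#' Canonical discriminant analysis on the between/within scatter
#' generalized eigenproblem, as used to quantify how much the symmetry
#' index and the normalized speed contribute to separating the age groups
#' within one speed condition. Reports, per discriminant function, the
#' eigenvalue, the proportion of discriminating variance, Wilks' lambda
#' for that function and beyond (prod of 1/(1+lambda_i)), Bartlett's
#' chi-square approximation with its p-value, and the structure matrix
#' (pooled within-group correlations between each input variable and the
#' function scores). Discriminant coefficients are scaled so scores have
#' unit pooled within-group variance; group priors are equal.
#'
#' The within-group scatter receives a tiny relative ridge
#' (`ridge` x mean within variance) before inversion, so a feature with
#' vanishing within-group variance yields the degenerate limit (all
#' discriminating variance and a loading of +/-1 on that feature) instead
#' of an outright failure; a scatter still singular after the ridge (a
#' constant feature) errors naming the offending feature.
#'
#' @param table data frame with the feature columns and a `group` column
#'   (>= 3 groups; n must exceed features + groups).
#' @param features names of the feature columns.
#' @param ridge relative ridge added to the within-scatter diagonal.
#' @return Object of class `gait_lda`.
#' @export
lda_groups <- function(table, features = c("si", "normalized_speed"),
                       ridge = 1e-8) {
  if (!all(features %in% names(table)))
    stop("missing feature column(s): ", paste(setdiff(features, names(table)), collapse = ", "))
  keep <- stats::complete.cases(table[, c(features, "group")])
  X <- as.matrix(table[keep, features, drop = FALSE])
  g <- factor(table$group[keep])
  p <- ncol(X); G <- nlevels(g); n <- nrow(X)
  if (p < 2L) stop("need at least 2 features")
  if (G < 3L) stop("need at least 3 groups")
  if (n <= p + G) stop("need n > features + groups observations")

  const <- which(apply(X, 2L, stats::var) == 0)
  if (length(const))
    stop("singular within-group scatter: feature '", features[const[1L]],
         "' is constant")
  grand <- colMeans(X)
  W <- matrix(0, p, p, dimnames = list(features, features))
  B <- matrix(0, p, p, dimnames = list(features, features))
  for (lev in levels(g)) {
    Xg <- X[g == lev, , drop = FALSE]
    mg <- colMeans(Xg)
    W <- W + crossprod(sweep(Xg, 2L, mg))
    B <- B + nrow(Xg) * tcrossprod(mg - grand)
  }
  W <- W + diag(ridge * mean(diag(W)), p)
  R <- tryCatch(chol(W), error = function(e)
    stop("singular within-group scatter even after the regularization floor"))
  # symmetric form R^-T B R^-1 of W^-1 B
  M <- backsolve(R, t(backsolve(R, t(B), transpose = TRUE)), transpose = TRUE)
  ei <- eigen((M + t(M)) / 2, symmetric = TRUE)
  J <- min(p, G - 1L)
  lambda <- pmax(0, ei$values[seq_len(J)])
  A <- backsolve(R, ei$vectors[, seq_len(J), drop = FALSE])  # raw coefficients
  A <- A * sqrt(n - G)  # unit pooled within-group score variance (a' W a = n - G)

  proportion <- 100 * lambda / sum(lambda)
  wilks <- rev(cumprod(rev(1 / (1 + lambda))))
  chisq <- -((n - 1) - (p + G) / 2) * log(wilks)
  df <- (p - seq_len(J) + 1L) * (G - seq_len(J))
  pval <- stats::pchisq(chisq, df, lower.tail = FALSE)

  # structure matrix: pooled within-group correlations feature <-> score,
  # with all within moments taken from the ridged scatter
  WA <- W %*% A / (n - G)                      # within covariance feature x score
  sdf <- sqrt(diag(W) / (n - G))
  structure_mat <- sweep(WA, 1L, sdf, "/")     # score sd is 1 by scaling
  dimnames(structure_mat) <- list(features, paste0("LD", seq_len(J)))
  dimnames(A) <- dimnames(structure_mat)

  structure(list(eigenvalues = lambda, proportion = proportion,
                 wilks = wilks, chisq = chisq, df = df, p = pval,
                 structure = structure_mat, coef = A,
                 group_means = do.call(rbind, lapply(levels(g), function(l)
                   colMeans(X[g == l, , drop = FALSE]))),
                 n = n, groups = levels(g), features = features),
            class = "gait_lda")
}

#' @export
print.gait_lda <- function(x, ...) {
  cat(sprintf("Canonical LDA: %d groups, %d features, n = %d\n",
              length(x$groups), length(x$features), x$n))
  for (j in seq_along(x$eigenvalues)) {
    cat(sprintf("  LD%d: eigenvalue %.4f (%.1f%% of variance), Wilks' lambda %.4f, chi^2(%d) = %.2f, p = %.4g\n",
                j, x$eigenvalues[j], x$proportion[j], x$wilks[j], x$df[j],
                x$chisq[j], x$p[j]))
  }
  cat("Structure matrix (pooled within-group loadings):\n")
  print(round(x$structure, 3))
  invisible(x)
}
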