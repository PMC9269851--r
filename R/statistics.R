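#' Shapiro-Wilk normality test
#'
#' Thin validated wrapper around the standard W statistic: errors on
#' out-of-range sample sizes and on zero-variance samples instead of
#' failing obscurely downstream.
#'
#' @param x numeric sample, 3 <= n <= 5000.
#' @return List with `W` and `p`.
#' @export
shapiro_wilk <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 3L || n > 5000L)
    stop("Shapiro-Wilk needs 3 <= n <= 5000")
  if (stats::var(x) == 0) stop("zero-variance sample: W is undefined")
  ht <- stats::shapiro.test(x)
  list(W = unname(ht$statistic), p = ht$p.value)
}

#' Levene's test for equality of group variances
#'
#' One-way ANOVA on absolute deviations from the group centers; the
#' classic form uses the group mean as center (default), the
#' Brown-Forsythe variant the median.
#'
#' @param x numeric response.
#' @param g grouping factor (>= 2 groups, each with >= 2 values).
#' @param center `"mean"` (classic) or `"median"`.
#' @return List with `F`, `df1`, `df2`, `p`.
#' @export
levene_test <- function(x, g, center = c("mean", "median")) {
  center <- match.arg(center)
  g <- factor(g)
  if (nlevels(g) < 2L || any(table(g) < 2L))
    stop("Levene's test needs >= 2 groups with >= 2 values each")
  centerfun <- if (center == "mean") mean else stats::median
  tab <- car::leveneTest(x, g, center = centerfun)
  list(F = tab[1L, "F value"], df1 = tab[1L, "Df"], df2 = tab[2L, "Df"],
       p = tab[1L, "Pr(>F)"])
}

# Box's Greenhouse-Geisser epsilon from a k x k within-subject covariance
# matrix, via orthonormal contrasts: eps = tr(M)^2 / ((k-1) tr(M^2)).
gg_epsilon_from_cov <- function(S) {
  k <- nrow(S)
  if (k < 2L) stop("need at least 2 within-subject levels")
  C <- stats::contr.helmert(k)
  C <- sweep(C, 2L, sqrt(colSums(C^2)), "/")
  M <- t(C) %*% S %*% C
  tr <- sum(diag(M))
  eps <- tr^2 / ((k - 1L) * sum(M * M))
  min(1, max(1 / (k - 1L), eps))
}

# a (numerically) zero-SS effect carries no evidence: report F = 0, p = 1
# rather than the roundoff garbage a degenerate (e.g. constant-response)
# fit produces; `scale` is the total SS of the decomposition
sanitize_F <- function(ss, F, p, scale = 1) {
  bad <- is.na(F) | ss < 1e-12 * max(1, scale)
  F[bad] <- 0; p[bad] <- 1
  list(F = F, p = p)
}

# long table -> subjects x conditions wide matrix (complete cases only)
rm_wide <- function(table, dv, id = "participant_id", cond = "condition") {
  conds <- unique(as.character(table[[cond]]))
  ids <- unique(table[[id]])
  Y <- matrix(NA_real_, length(ids), length(conds),
              dimnames = list(as.character(ids), conds))
  for (i in seq_len(nrow(table)))
    Y[as.character(table[[id]][i]), as.character(table[[cond]][i])] <- table[[dv]][i]
  complete <- stats::complete.cases(Y)
  if (any(!complete))
    message(sprintf("repeated-measures analysis: %d incomplete participant(s) removed listwise",
                    sum(!complete)))
  Y[complete, , drop = FALSE]
}

#' Split-plot (mixed) two-way ANOVA with Greenhouse-Geisser correction
#'
#' Two-way ANOVA with a between-subjects factor (age group) and a
#' within-subjects factor (speed condition), decomposed in the classical
#' split-plot strata: the group effect is tested against the
#' between-subject residual, the condition and interaction effects against
#' the within-subject residual. Greenhouse-Geisser epsilon is computed
#' from the pooled within-group covariance of the condition columns
#' (Box's formula) and multiplies both numerator and denominator degrees
#' of freedom of the within-stratum tests; `p_gg` is the corrected
#' p-value. Participants with incomplete condition data are removed
#' listwise (logged).
#'
#' @param table long-format cohort table with columns `participant_id`,
#'   `group`, `condition` and the dependent variable.
#' @param dv name of the dependent variable column (e.g. `"si"` or
#'   `"normalized_speed"`).
#' @return Object of class `gait_mixed_anova`: a data frame of effects
#'   (`ss`, `df`, `ms`, `F`, `p`, `df1_gg`, `df2_gg`, `p_gg`) plus
#'   `epsilon` and the stratum residuals.
#' @export
mixed_anova <- function(table, dv = "si") {
  need <- c("participant_id", "group", "condition", dv)
  if (!all(need %in% names(table))) stop("table must contain ", paste(need, collapse = ", "))
  tab <- table[stats::complete.cases(table[, need]), need]
  Y <- rm_wide(tab, dv)
  ids <- rownames(Y)
  tab <- tab[as.character(tab$participant_id) %in% ids, , drop = FALSE]
  grp_of <- tapply(as.character(tab$group), as.character(tab$participant_id),
                   function(z) z[1L])
  grp <- factor(grp_of[ids])
  if (nlevels(grp) < 2L) stop("need at least 2 groups")
  k <- ncol(Y)
  N <- nrow(Y)

  d <- data.frame(y = as.vector(Y),
                  subject = factor(rep(ids, k)),
                  condition = factor(rep(colnames(Y), each = N)),
                  group = factor(rep(as.character(grp), k)))
  fit <- stats::aov(y ~ group * condition + Error(subject), data = d)
  s <- summary(fit)
  btab <- s[["Error: subject"]][[1L]]
  wtab <- s[["Error: Within"]][[1L]]
  rn <- function(tb) trimws(rownames(tb))
  pick <- function(tb, nm) {
    i <- match(nm, rn(tb))
    c(ss = tb[i, "Sum Sq"], df = tb[i, "Df"], F = tb[i, "F value"], p = tb[i, "Pr(>F)"])
  }
  g_row <- pick(btab, "group")
  bres <- pick(btab, "Residuals")
  c_row <- pick(wtab, "condition")
  i_row <- pick(wtab, "group:condition")
  wres <- pick(wtab, "Residuals")

  # pooled within-group covariance of the condition columns
  Yc <- Y
  for (lev in levels(grp))
    Yc[grp == lev, ] <- sweep(Y[grp == lev, , drop = FALSE], 2L,
                              colMeans(Y[grp == lev, , drop = FALSE]))
  S <- crossprod(Yc) / (N - nlevels(grp))
  eps <- gg_epsilon_from_cov(S)
  if (!is.finite(eps)) eps <- 1

  effects <- data.frame(
    effect = c("group", "condition", "group:condition"),
    ss = c(g_row["ss"], c_row["ss"], i_row["ss"]),
    df = c(g_row["df"], c_row["df"], i_row["df"]),
    F = c(g_row["F"], c_row["F"], i_row["F"]),
    p = c(g_row["p"], c_row["p"], i_row["p"]),
    stringsAsFactors = FALSE)
  effects$ms <- effects$ss / effects$df
  fix <- sanitize_F(effects$ss, effects$F, effects$p,
                    scale = sum(effects$ss) + bres["ss"] + wres["ss"])
  effects$F <- fix$F; effects$p <- fix$p
  effects$df1_gg <- c(NA, eps * c_row["df"], eps * i_row["df"])
  effects$df2_gg <- c(NA, eps * wres["df"], eps * wres["df"])
  effects$p_gg <- c(NA,
                    stats::pf(effects$F[2L], eps * c_row["df"], eps * wres["df"], lower.tail = FALSE),
                    stats::pf(effects$F[3L], eps * i_row["df"], eps * wres["df"], lower.tail = FALSE))
  structure(list(effects = effects, epsilon = eps,
                 residuals = data.frame(
                   stratum = c("between-subjects", "within-subjects"),
                   ss = c(bres["ss"], wres["ss"]),
                   df = c(bres["df"], wres["df"])),
                 n_subjects = N, k = k, dv = dv),
            class = "gait_mixed_anova")
}

#' @export
print.gait_mixed_anova <- function(x, digits = 4, ...) {
  cat(sprintf("Split-plot ANOVA on '%s' (%d subjects, %d within levels)\n",
              x$dv, x$n_subjects, x$k))
  cat(sprintf("Greenhouse-Geisser epsilon = %.4f\n\n", x$epsilon))
  ef <- x$effects
  for (i in seq_len(nrow(ef))) {
    if (is.na(ef$p_gg[i])) {
      cat(sprintf("  %-16s F(%g, %g) = %.*f, p = %.4g\n", ef$effect[i],
                  ef$df[i], x$residuals$df[1L], digits, ef$F[i], ef$p[i]))
    } else {
      cat(sprintf("  %-16s F(%.1f, %.1f) = %.*f, p_GG = %.4g\n", ef$effect[i],
                  ef$df1_gg[i], ef$df2_gg[i], digits, ef$F[i], ef$p_gg[i]))
    }
  }
  invisible(x)
}

#' One-way repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Compares the within-subject factor levels (speed conditions) inside a
#' single group of participants; the within-subject covariance supplies
#' Box's epsilon exactly as in [mixed_anova()].
#'
#' @param table long-format table (one group) with `participant_id`,
#'   `condition` and the dependent variable.
#' @param dv dependent-variable column name.
#' @return Object of class `gait_rm_anova` with `F`, `df1`, `df2`, `p`,
#'   `epsilon`, `p_gg`.
#' @export
rm_anova_oneway <- function(table, dv = "si") {
  Y <- rm_wide(table[stats::complete.cases(table[, c("participant_id", "condition", dv)]), ],
               dv)
  k <- ncol(Y); N <- nrow(Y)
  if (N < 2L) stop("need at least 2 complete participants")
  d <- data.frame(y = as.vector(Y),
                  subject = factor(rep(rownames(Y), k)),
                  condition = factor(rep(colnames(Y), each = N)))
  s <- summary(stats::aov(y ~ condition + Error(subject), data = d))
  wtab <- s[["Error: Within"]][[1L]]
  i <- match("condition", trimws(rownames(wtab)))
  j <- match("Residuals", trimws(rownames(wtab)))
  Fv <- wtab[i, "F value"]; df1 <- wtab[i, "Df"]; df2 <- wtab[j, "Df"]
  fx <- sanitize_F(wtab[i, "Sum Sq"], Fv, wtab[i, "Pr(>F)"],
                   scale = wtab[i, "Sum Sq"] + wtab[j, "Sum Sq"])
  Fv <- fx$F
  S <- stats::cov(Y)
  eps <- tryCatch(gg_epsilon_from_cov(S), error = function(e) 1)
  if (!is.finite(eps)) eps <- 1
  structure(list(F = Fv, df1 = df1, df2 = df2, p = fx$p,
                 epsilon = eps, df1_gg = eps * df1, df2_gg = eps * df2,
                 p_gg = stats::pf(Fv, eps * df1, eps * df2, lower.tail = FALSE),
                 ss_condition = wtab[i, "Sum Sq"], ss_residual = wtab[j, "Sum Sq"],
                 n_subjects = N, k = k, dv = dv),
            class = "gait_rm_anova")
}

#' @export
print.gait_rm_anova <- function(x, ...) {
  cat(sprintf("RM one-way ANOVA on '%s': F(%.1f, %.1f) = %.3f, p_GG = %.4g (eps = %.3f)\n",
              x$dv, x$df1_gg, x$df2_gg, x$F, x$p_gg, x$epsilon))
  invisible(x)
}

#' One-way independent-measures ANOVA
#'
#' Compares the groups within a single speed condition.
#'
#' @param table long-format table (one condition) with `group` and the
#'   dependent variable.
#' @param dv dependent-variable column name.
#' @return List with `F`, `df1`, `df2`, `p`, `ss_between`, `ss_within`.
#' @export
oneway_anova <- function(table, dv = "si") {
  d <- data.frame(y = table[[dv]], group = factor(table$group))
  d <- d[stats::complete.cases(d), ]
  if (nlevels(droplevels(d$group)) < 2L) stop("need at least 2 groups")
  a <- suppressWarnings(stats::anova(stats::lm(y ~ group, data = d)))
  fx <- sanitize_F(a[1L, "Sum Sq"], a[1L, "F value"], a[1L, "Pr(>F)"],
                   scale = sum(a[, "Sum Sq"]))
  list(F = fx$F, df1 = a[1L, "Df"], df2 = a[2L, "Df"],
       p = fx$p, ss_between = a[1L, "Sum Sq"], ss_within = a[2L, "Sum Sq"])
}

#' Bonferroni-corrected pairwise comparisons
#'
#' All pairwise comparisons among the levels of `unit`, by two-sample
#' pooled-variance t tests (independent units) or paired t tests (set
#' `paired = TRUE` and supply `subject`). The adjusted p-value is
#' `min(1, m * p_raw)` with `m` the number of comparisons in the declared
#' family (21 for 7 groups, 3 for 3 conditions), capped at 1.
#'
#' @param x numeric response.
#' @param unit factor of units to compare pairwise.
#' @param paired paired comparisons within subject?
#' @param subject subject identifier, required when `paired = TRUE`.
#' @param m family size; defaults to the number of pairs.
#' @return Data frame with `A`, `B`, `mean_diff`, `p_raw`, `p_bonferroni`
#'   and attribute `m`.
#' @examples
#' bonferroni_adjust(0.01, 3)  # 0.03
#' @export
bonferroni_pairwise <- function(x, unit, paired = FALSE, subject = NULL, m = NULL) {
  unit <- factor(unit)
  lev <- levels(droplevels(unit))
  pairs <- utils::combn(lev, 2L)
  if (is.null(m)) m <- ncol(pairs)
  out <- vector("list", ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1L, j]; b <- pairs[2L, j]
    if (paired) {
      if (is.null(subject)) stop("paired comparisons need a subject identifier")
      xa <- x[unit == a][order(subject[unit == a])]
      xb <- x[unit == b][order(subject[unit == b])]
      ht <- stats::t.test(xa, xb, paired = TRUE)
      md <- mean(xa - xb)
    } else {
      ht <- stats::t.test(x[unit == a], x[unit == b], var.equal = TRUE)
      md <- mean(x[unit == a]) - mean(x[unit == b])
    }
    out[[j]] <- data.frame(A = a, B = b, mean_diff = md, p_raw = ht$p.value,
                           p_bonferroni = bonferroni_adjust(ht$p.value, m),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  attr(res, "m") <- m
  res
}

#' @rdname bonferroni_pairwise
#' @param p raw p-value(s).
#' @export
bonferroni_adjust <- function(p, m) pmin(1, m * p)
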