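test_that("Shapiro-Wilk wrapper validates inputs and detects skew", {
  sw <- shapiro_wilk(c(1, 2, 3))
  expect_equal(sw$W, 1, tolerance = 1e-10)
  expect_error(shapiro_wilk(c(1, 2)), "3 <= n")
  expect_error(shapiro_wilk(rep(2, 10)), "zero-variance")
  rej <- vapply(1:200, function(i) {
    set.seed(i)
    shapiro_wilk(exp(rnorm(50)))$p < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.95)
})

test_that("Levene's test is null-calibrated and detects variance ratios", {
  x <- rep(c(1, 2, 3, 4), 2)
  g <- rep(c("a", "b"), each = 4)
  expect_equal(levene_test(x, g)$F, 0)
  expect_error(levene_test(1:3, c("a", "a", "b")), ">= 2 groups")

  set.seed(99)
  rej0 <- rej1 <- logical(1000)
  for (i in 1:1000) {
    g <- rep(c("a", "b"), each = 30)
    rej0[i] <- levene_test(c(rnorm(30), rnorm(30)), g)$p < 0.05
    rej1[i] <- levene_test(c(rnorm(30, sd = 1), rnorm(30, sd = 4)), g)$p < 0.05
  }
  expect_gt(mean(rej0), 0.03); expect_lt(mean(rej0), 0.07)
  expect_gt(mean(rej1), 0.90)
})

test_that("Greenhouse-Geisser epsilon respects its bounds and limits", {
  # compound symmetry: eps = 1 exactly
  S <- matrix(0.3, 3, 3); diag(S) <- 1
  expect_equal(gaitsym:::gg_epsilon_from_cov(S), 1)
  # k = 2 collapses the bound to 1
  expect_equal(gaitsym:::gg_epsilon_from_cov(matrix(c(2, 0.1, 0.1, 0.5), 2)), 1)
  # random covariances stay within [1/(k-1), 1]
  set.seed(5)
  for (i in 1:50) {
    k <- sample(3:5, 1)
    A <- matrix(rnorm(k * k), k)
    eps <- gaitsym:::gg_epsilon_from_cov(crossprod(A))
    expect_gte(eps, 1 / (k - 1)); expect_lte(eps, 1)
  }
  # sample epsilon approaches 1 under compound-symmetric data as n grows
  meds <- vapply(1:20, function(i) {
    set.seed(i)
    Y <- matrix(rnorm(200 * 3), 200, 3) + rnorm(200)
    gaitsym:::gg_epsilon_from_cov(cov(Y))
  }, numeric(1))
  expect_gt(median(meds), 0.9)
})

test_that("the split-plot ANOVA matches the projection-matrix oracle", {
  for (seed in 1:5) {
    d <- make_rm_data(G = sample(2:3, 1), n = sample(3:5, 1), k = 3, seed = seed)
    fit <- mixed_anova(d, dv = "y")
    oracle <- oracle_splitplot(d)
    expect_equal(fit$effects$F, unname(oracle$F), tolerance = 1e-9)
    expect_equal(fit$effects$ss,
                 unname(oracle$ss[c("group", "condition", "interaction")]),
                 tolerance = 1e-9)
    # SS additivity: strata plus effects recover the total SS
    total <- sum((d$y - mean(d$y))^2)
    expect_equal(sum(fit$effects$ss) + sum(fit$residuals$ss), total,
                 tolerance = 1e-9)
  }
})

test_that("degenerate and restricted split-plot fixtures behave as defined", {
  d <- make_rm_data(G = 2, n = 4, k = 3, constant = 7)
  fit <- mixed_anova(d, dv = "y")
  expect_equal(fit$effects$F, c(0, 0, 0))
  d2 <- make_rm_data(G = 2, n = 5, k = 2, seed = 3)
  expect_equal(mixed_anova(d2, dv = "y")$epsilon, 1)
})

test_that("listwise deletion drops incomplete participants with a log message", {
  d <- make_rm_data(G = 2, n = 4, k = 3, seed = 2)
  d <- d[!(d$participant_id == 1 & d$condition == "C2"), ]
  expect_message(fit <- mixed_anova(d, dv = "y"), "1 incomplete")
  expect_equal(fit$n_subjects, 7)
})

test_that("the one-way RM ANOVA agrees with the oracle within a single group", {
  d <- make_rm_data(G = 1, n = 6, k = 3, seed = 9)
  fit <- rm_anova_oneway(d, dv = "y")
  oracle <- oracle_splitplot(d)  # single-group: condition line is the RM test
  expect_equal(fit$F, unname(oracle$F["condition"]), tolerance = 1e-9)
  expect_gte(fit$epsilon, 0.5); expect_lte(fit$epsilon, 1)
  dc <- make_rm_data(G = 1, n = 5, k = 3, constant = 2)
  expect_equal(rm_anova_oneway(dc, dv = "y")$F, 0)
})

test_that("the independent one-way ANOVA matches t^2 and textbook SS", {
  set.seed(4)
  d <- data.frame(group = rep(c("a", "b"), each = 10), si = rnorm(20))
  res <- oneway_anova(d)
  tt <- t.test(si ~ group, data = d, var.equal = TRUE)
  expect_equal(res$F, unname(tt$statistic)^2, tolerance = 1e-12)

  d3 <- data.frame(group = rep(c("A", "B", "C"), each = 3),
                   si = c(1, 2, 3, 2, 4, 6, 3, 6, 9))
  res3 <- oneway_anova(d3)
  expect_equal(res3$ss_between, 24)
  expect_equal(res3$ss_within, 28)
  expect_equal(res3$F, 18 / 7, tolerance = 1e-12)

  const <- oneway_anova(data.frame(group = rep(c("a", "b"), 5), si = 1))
  expect_equal(const$F, 0)
  expect_equal(const$p, 1)
})

test_that("Bonferroni adjustment multiplies, caps and covers the family", {
  expect_equal(bonferroni_adjust(0.01, 3), 0.03)
  expect_equal(bonferroni_adjust(0.5, 3), 1)
  expect_equal(bonferroni_adjust(0.2, 1), 0.2)
  set.seed(11)
  d <- data.frame(g = rep(paste0("G", 1:7), each = 6), y = rnorm(42))
  pw <- bonferroni_pairwise(d$y, d$g)
  expect_equal(nrow(pw), 21)
  expect_equal(attr(pw, "m"), 21)
  expect_true(all(pw$p_bonferroni >= pw$p_raw))
  expect_true(all(pw$p_bonferroni <= 1))
  expect_equal(pw$p_bonferroni, pmin(1, 21 * pw$p_raw))
  # paired comparisons respect subject pairing
  d2 <- data.frame(s = rep(1:8, 2), cond = rep(c("x", "z"), each = 8),
                   y = c(rnorm(8), rnorm(8, 1)))
  pw2 <- bonferroni_pairwise(d2$y, d2$cond, paired = TRUE, subject = d2$s, m = 3)
  tt <- t.test(d2$y[d2$cond == "x"], d2$y[d2$cond == "z"], paired = TRUE)
  expect_equal(pw2$p_raw, tt$p.value)
  expect_equal(pw2$p_bonferroni, min(1, 3 * tt$p.value))
})
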