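# The fixed 5x3 integer matrix used for the brute-force decomposition
# checks; expected values were computed by hand as exact fractions.
ORACLE_X <- matrix(c(3, 4, 5,
                     6, 5, 7,
                     2, 3, 2,
                     8, 9, 9,
                     5, 6, 4), 5, 3, byrow = TRUE)

test_that("ANOVA decomposition matches hand-computed sums of squares", {
  a <- rm_anova(ORACLE_X)
  expect_equal(unname(a$ss["subjects"]), 1006 / 15, tolerance = 1e-12)
  expect_equal(unname(a$ss["trials"]), 6 / 5, tolerance = 1e-12)
  expect_equal(unname(a$ss["residual"]), 92 / 15, tolerance = 1e-12)
  expect_equal(unname(a$ss["total"]), 372 / 5, tolerance = 1e-12)
  expect_equal(unname(a$ms["subjects"]), 503 / 30, tolerance = 1e-12)
  expect_equal(unname(a$ms["trials"]), 3 / 5, tolerance = 1e-12)
  expect_equal(unname(a$ms["residual"]), 23 / 30, tolerance = 1e-12)
  expect_equal(a$F, 18 / 23, tolerance = 1e-12)
  expect_equal(icc_oneway(ORACLE_X)$icc, 481 / 547, tolerance = 1e-12)
  expect_equal(sem_abs(ORACLE_X), sqrt(11 / 15), tolerance = 1e-12)
})

test_that("ANOVA agrees with the aov() cross-check", {
  set.seed(8)
  X <- matrix(rnorm(21, 5, 2), 7, 3)
  a <- rm_anova(X)
  df <- data.frame(y = as.vector(X), s = factor(rep(1:7, 3)),
                   t = factor(rep(1:3, each = 7)))
  fit <- summary(stats::aov(y ~ t + Error(s), data = df))
  within <- fit[["Error: Within"]][[1]]
  expect_equal(a$F, within["t", "F value"], tolerance = 1e-10)
  expect_equal(a$p, within["t", "Pr(>F)"], tolerance = 1e-10)
  expect_equal(unname(a$ss["residual"]), within["Residuals", "Sum Sq"],
               tolerance = 1e-10)
})

test_that("Mauchly statistic matches the mlm cross-check", {
  set.seed(9)
  X <- matrix(rnorm(29 * 4), 29, 4)
  X[, 4] <- X[, 4] * 2 + X[, 1]          # break sphericity
  a <- rm_anova(X)
  mt <- stats::mauchly.test(stats::lm(X ~ 1), X = ~1)
  expect_equal(unname(a$mauchly_W), unname(mt$statistic), tolerance = 1e-10)
  # the p-values use slightly different variants of Box's second-order
  # term; they agree to well under a percent
  expect_equal(a$mauchly_p, mt$p.value, tolerance = 1e-3)
  expect_false(a$sphericity_assumed)
  expect_lt(a$gg_epsilon, 1)
})

test_that("sum-of-squares decomposition conserves the total", {
  set.seed(10)
  for (i in 1:25) {
    n <- sample(4:30, 1); k <- sample(2:5, 1)
    X <- matrix(rnorm(n * k, 10, 3), n, k)
    a <- rm_anova(X)
    expect_equal(unname(a$ss["total"]),
                 unname(sum(a$ss[c("subjects", "trials", "residual")])),
                 tolerance = 1e-9)
    # SEM^2 (within) plus the between-subject component rebuild the
    # total sum of squares of the one-way decomposition
    m <- motorkin:::oneway_ms(X)
    expect_equal((n - 1) * m$msb + n * (k - 1) * sem_abs(X)^2,
                 sum((X - mean(X))^2), tolerance = 1e-9)
  }
})

test_that("k = 2 skips Mauchly and fixes epsilon at 1", {
  X <- matrix(rnorm(20), 10, 2)
  a <- rm_anova(X)
  expect_true(is.na(a$mauchly_W))
  expect_identical(a$gg_epsilon, 1)
  expect_true(a$sphericity_assumed)
})

test_that("compound-symmetric data drives W and epsilon to 1", {
  set.seed(11)
  X <- simulate_feature_matrix(500, 3, mu = 0, sigma2_between = 2,
                               sigma2_within = 1, seed = 11)
  a <- rm_anova(X)
  expect_equal(unname(a$mauchly_W), 1, tolerance = 0.02)
  expect_equal(a$gg_epsilon, 1, tolerance = 0.02)
})

test_that("epsilon stays within its theoretical bounds", {
  set.seed(12)
  for (i in 1:20) {
    k <- sample(3:5, 1)
    X <- matrix(rnorm(15 * k), 15, k)
    X[, 1] <- X[, 1] * 3
    eps <- rm_anova(X)$gg_epsilon
    expect_gte(eps, 1 / (k - 1))
    expect_lte(eps, 1)
  }
})

test_that("ICC equals the method-of-moments variance ratio", {
  set.seed(13)
  for (i in 1:40) {
    n <- sample(4:30, 1); k <- sample(2:5, 1)
    X <- matrix(rnorm(n * k, 5, 2), n, k) +
      rnorm(n, 0, runif(1, 0, 3))
    ic <- icc_oneway(X)$icc
    s2w <- sum((X - rowMeans(X))^2) / (n * (k - 1))
    s2b <- stats::var(rowMeans(X)) - s2w / k
    expect_equal(ic, s2b / (s2b + s2w), tolerance = 1e-10)
  }
})

test_that("identical columns give perfect reliability", {
  X <- cbind(1:6, 1:6, 1:6)
  ic <- icc_oneway(X)
  expect_equal(ic$icc, 1)
  expect_equal(ic$upper, 1)
  expect_equal(sem_abs(X), 0)
  expect_warning(ic0 <- icc_oneway(matrix(3, 5, 3)), "constant")
  expect_true(is.nan(ic0$icc))
})

test_that("null subject effect pushes the ICC toward zero", {
  X <- simulate_feature_matrix(1000, 3, mu = 0, sigma2_between = 0,
                               sigma2_within = 1, seed = 14)
  expect_lt(abs(icc_oneway(X)$icc), 0.05)
})

test_that("ICC(3,1) is available and at least as large on trial-shifted data", {
  set.seed(15)
  X <- matrix(rnorm(60, 10), 20, 3)
  X[, 2] <- X[, 2] + 2        # systematic trial shift
  ic1 <- icc_oneway(X, type = "ICC1")
  ic3 <- icc_oneway(X, type = "ICC3")
  expect_gt(ic3$icc, ic1$icc)  # consistency form ignores the shift
})

test_that("SEM is scale-equivariant and CV scale-invariant", {
  set.seed(16)
  X <- matrix(rnorm(36, 20, 2), 12, 3)
  expect_equal(sem_abs(3 * X), 3 * sem_abs(X), tolerance = 1e-12)
  expect_equal(cv_percent(5 * X)$cv, cv_percent(X)$cv, tolerance = 1e-10)
  Xc <- cbind(1:5, 1:5, 1:5)
  expect_equal(cv_percent(Xc)$cv, 0)
  expect_warning(cv_percent(X - 30), "grand mean")
})

test_that("CV acceptability flips exactly at the 10% threshold", {
  make_cv <- function(target) {
    # two trials offset +/- d around each subject mean: SEM = d * sqrt(2),
    # so d = target * mean / (100 * sqrt(2)) gives CV = target exactly
    mu <- 10
    d <- target * mu / 100 / sqrt(2)
    X <- cbind(c(8, 10, 12) + d, c(8, 10, 12) - d)
    X * (mu / mean(X))
  }
  cv_lo <- cv_percent(make_cv(9.9))
  cv_hi <- cv_percent(make_cv(10.1))
  expect_equal(cv_lo$cv, 9.9, tolerance = 1e-6)
  expect_equal(cv_hi$cv, 10.1, tolerance = 1e-6)
  expect_true(cv_lo$acceptable)
  expect_false(cv_hi$acceptable)
})

test_that("ICC categories honor the published bands", {
  expect_equal(categorize_icc(c(0.499, 0.5, 0.699, 0.7, 0.899, 0.9)),
               c("poor", "moderate", "moderate", "high", "high",
                 "excellent"))
  expect_equal(categorize_icc(0.95), "excellent")
  expect_equal(categorize_icc(0.69), "moderate")
  expect_equal(categorize_icc(0.49), "poor")
  expect_equal(categorize_icc(NaN), "undefined")
})

test_that("effect size definition and bands", {
  set.seed(17)
  base <- rnorm(25, 10, 2)
  X <- cbind(base, base + rnorm(25, 0, 0.1), base)
  es0 <- effect_size(X, seed = 1)
  expect_equal(es0$es, 0)
  expect_equal(es0$band, "small")
  X1 <- cbind(base, base, base + sd(base))
  es1 <- effect_size(X1, seed = 1)
  expect_equal(es1$es, 1)
  expect_equal(es1$band, "large")
  expect_true(es1$lower <= 1 && es1$upper >= 1)
  expect_equal(es_band(0.55), "moderate")
  expect_equal(es_band(c(0.409, 0.41, 0.699, 0.70)),
               c("small", "moderate", "moderate", "large"))
  expect_warning(esn <- effect_size(cbind(rep(1, 5), rnorm(5), rnorm(5))),
                 "zero SD")
  expect_true(is.nan(esn$es))
  # seeded bootstrap reproducible
  es_a <- effect_size(X1, seed = 9)
  es_b <- effect_size(X1, seed = 9)
  expect_identical(es_a, es_b)
})

test_that("degenerate residual variance is flagged with infinite F", {
  X <- cbind(c(1, 2, 3, 4), c(2, 3, 4, 5), c(3, 4, 5, 6))
  a <- rm_anova(X)  # perfect additive structure: zero residual
  expect_true(a$degenerate)
  expect_true(is.infinite(a$F))
  expect_equal(a$p, 0)
})

test_that("group comparison picks the right test", {
  set.seed(18)
  g1 <- rnorm(16, 10, 1)
  # identical groups: no difference
  r0 <- compare_groups(c(g1, g1), rep(c("active", "sedentary"), each = 16))
  expect_gt(r0$p, 0.99)
  # 5 pooled SDs apart at n = 16/16: decisive
  r1 <- compare_groups(c(g1, g1 + 5), rep(c("active", "sedentary"), each = 16))
  expect_lt(r1$p, 0.001)
  # heavy tails force the rank test
  heavy <- c(rnorm(14), 40, -35)
  r2 <- compare_groups(c(heavy, heavy + 1),
                       rep(c("active", "sedentary"), each = 16))
  expect_equal(r2$test, "Wilcoxon-Mann-Whitney")
  # normal, equal-variance data earns the t-test
  r3 <- compare_groups(c(g1, g1 + 0.5),
                       rep(c("active", "sedentary"), each = 16))
  expect_equal(r3$test, "Student t")
  expect_warning(compare_groups(c(1, 2, 10, 11, 12, 13),
                                c("active", "active", rep("sedentary", 4))),
                 "fewer than 3")
})

test_that("missing trials are dropped listwise with a message", {
  X <- matrix(rnorm(15), 5, 3)
  X[2, 3] <- NA
  expect_message(a <- rm_anova(X), "1 row")
  expect_equal(a$n, 4)
})
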