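# Relative and absolute test-retest reliability statistics over a
# subjects x trials feature matrix: repeated measures ANOVA with
# sphericity diagnostics, one-way intraclass correlation with exact
# F-based confidence limits, standard error of measurement, coefficient
# of variation, standardized between-attempt effect sizes and
# activity-group comparisons.

check_matrix <- function(X, min_n = 3) {
  X <- as.matrix(X)
  if (!is.numeric(X)) stop("X must be a numeric matrix")
  drop_n <- sum(!stats::complete.cases(X))
  if (drop_n) {
    message(drop_n, " row(s) with missing trials dropped (listwise)")
    X <- X[stats::complete.cases(X), , drop = FALSE]
  }
  if (nrow(X) < min_n) stop("need at least ", min_n, " complete subjects")
  if (ncol(X) < 2) stop("need at least 2 trials")
  X
}

#' One-factor repeated measures ANOVA with sphericity diagnostics
#'
#' Standard within-subject decomposition of an `n x k` subjects-by-trials
#' matrix into subject, trial and residual sums of squares, with the
#' univariate F test for the trial effect. Sphericity of the trial
#' covariance is tested with Mauchly's W on the `k - 1` orthonormal
#' contrasts (chi-square approximation); when Mauchly's test rejects at
#' `alpha`, the F degrees of freedom are multiplied by the
#' Greenhouse-Geisser epsilon and the adjusted p-value is reported as
#' `p_adjusted`. With `k = 2` sphericity holds trivially: the test is
#' skipped and epsilon is exactly 1.
#'
#' @param X numeric matrix, subjects in rows, trials in columns; rows
#'   with missing trials are dropped with a message.
#' @param alpha significance level for the sphericity decision.
#' @return object of class `motorkin_anova`: sums of squares, degrees of
#'   freedom, mean squares, `F`, `p`, `mauchly_W`, `mauchly_p`,
#'   `gg_epsilon`, adjusted df and p, and `sphericity_assumed`.
#' @export
rm_anova <- function(X, alpha = 0.05) {
  X <- check_matrix(X)
  n <- nrow(X); k <- ncol(X)
  grand <- mean(X)
  rowm <- rowMeans(X); colm <- colMeans(X)
  ss_total <- sum((X - grand)^2)
  ss_subj <- k * sum((rowm - grand)^2)
  ss_trial <- n * sum((colm - grand)^2)
  ss_resid <- ss_total - ss_subj - ss_trial
  df_subj <- n - 1; df_trial <- k - 1; df_resid <- (n - 1) * (k - 1)
  ms_subj <- ss_subj / df_subj
  ms_trial <- ss_trial / df_trial
  ms_resid <- ss_resid / df_resid
  degenerate <- ms_resid <= .Machine$double.eps * max(1, abs(grand))^2
  Fval <- if (degenerate) {
    if (ms_trial > 0) Inf else NaN
  } else ms_trial / ms_resid
  p <- if (!is.finite(Fval)) {
    if (is.infinite(Fval)) 0 else NaN
  } else stats::pf(Fval, df_trial, df_resid, lower.tail = FALSE)
  if (k == 2) {
    W <- NA_real_; Wp <- NA_real_; eps <- 1
  } else {
    S <- stats::cov(X)
    C <- stats::contr.helmert(k)
    C <- qr.Q(qr(C))                       # orthonormal contrasts
    Tm <- t(C) %*% S %*% C
    p2 <- k - 1
    detT <- det(Tm); trT <- sum(diag(Tm))
    if (detT <= 0 || trT <= 0) {
      W <- 0; Wp <- 0
    } else {
      # Box's chi-square series for -n rho log W, through the
      # second-order term (which vanishes for k = 3)
      W <- detT / (trT / p2)^p2
      nd <- n - 1
      rho <- 1 - (2 * p2^2 + p2 + 2) / (6 * p2 * nd)
      z <- -nd * rho * log(W)
      f <- p2 * (p2 + 1) / 2 - 1
      w2 <- (p2 + 2) * (p2 - 1) * (p2 - 2) *
        (2 * p2^3 + 6 * p2^2 + 3 * p2 + 2) / (288 * (nd * p2 * rho)^2)
      pr1 <- stats::pchisq(z, f, lower.tail = FALSE)
      pr2 <- stats::pchisq(z, f + 4, lower.tail = FALSE)
      Wp <- pr1 + w2 * (pr2 - pr1)
    }
    eps <- trT^2 / (p2 * sum(Tm^2))
    eps <- min(max(eps, 1 / p2), 1)
  }
  sphericity <- (k == 2) || (is.finite(Wp) && Wp >= alpha)
  df_trial_adj <- eps * df_trial
  df_resid_adj <- eps * df_resid
  p_adj <- if (!is.finite(Fval)) {
    if (is.infinite(Fval)) 0 else NaN
  } else stats::pf(Fval, df_trial_adj, df_resid_adj, lower.tail = FALSE)
  structure(list(
    n = n, k = k,
    ss = c(subjects = ss_subj, trials = ss_trial, residual = ss_resid,
           total = ss_total),
    df = c(subjects = df_subj, trials = df_trial, residual = df_resid),
    ms = c(subjects = ms_subj, trials = ms_trial, residual = ms_resid),
    F = Fval, p = p,
    mauchly_W = W, mauchly_p = Wp, gg_epsilon = eps,
    df_adjusted = c(trials = df_trial_adj, residual = df_resid_adj),
    p_adjusted = p_adj,
    sphericity_assumed = sphericity,
    p_reported = if (sphericity) p else p_adj,
    degenerate = degenerate),
    class = "motorkin_anova")
}

#' @export
print.motorkin_anova <- function(x, ...) {
  cat(sprintf("Repeated measures ANOVA: n = %d subjects, k = %d trials\n",
              x$n, x$k))
  cat(sprintf("  F(%g, %g) = %.4g, p = %.4g\n",
              x$df["trials"], x$df["residual"], x$F, x$p))
  if (x$k > 2)
    cat(sprintf("  Mauchly W = %.4g (p = %.4g); GG epsilon = %.4g%s\n",
                x$mauchly_W, x$mauchly_p, x$gg_epsilon,
                if (x$sphericity_assumed) "" else
                  sprintf("; adjusted p = %.4g", x$p_adjusted)))
  invisible(x)
}

# One-way (subjects) decomposition: between-subject and within-subject
# mean squares, shared by the ICC and SEM.
oneway_ms <- function(X) {
  n <- nrow(X); k <- ncol(X)
  grand <- mean(X); rowm <- rowMeans(X)
  msb <- k * sum((rowm - grand)^2) / (n - 1)
  msw <- sum((X - rowm)^2) / (n * (k - 1))
  list(msb = msb, msw = msw, n = n, k = k)
}

#' Intraclass correlation coefficient with confidence interval
#'
#' Default form is the one-way random-effects single-measure ICC(1,1):
#' `(MSB - MSW) / (MSB + (k - 1) MSW)` from the one-way subjects
#' decomposition, the population ratio of between-subject variance to
#' total variance. The confidence interval is the exact F construction
#' (Shrout-Fleiss): the interval endpoints transform the bounds of
#' `MSB/MSW` by the same ratio formula. `type = "ICC3"` gives the
#' two-way mixed consistency form ICC(3,1) from the repeated measures
#' decomposition.
#'
#' @param X numeric subjects x trials matrix.
#' @param alpha two-sided confidence level is `1 - alpha`.
#' @param type `"ICC1"` (default) or `"ICC3"`.
#' @return list with `icc`, `lower`, `upper`, `type`.
#' @export
icc_oneway <- function(X, alpha = 0.05, type = c("ICC1", "ICC3")) {
  type <- match.arg(type)
  X <- check_matrix(X)
  n <- nrow(X); k <- ncol(X)
  if (type == "ICC1") {
    m <- oneway_ms(X)
    if (m$msb == 0 && m$msw == 0) {
      warning("constant matrix: ICC undefined")
      return(list(icc = NaN, lower = NaN, upper = NaN, type = type))
    }
    icc <- (m$msb - m$msw) / (m$msb + (k - 1) * m$msw)
    df1 <- n - 1; df2 <- n * (k - 1)
    Fobs <- m$msb / m$msw
    FL <- Fobs / stats::qf(1 - alpha / 2, df1, df2)
    FU <- Fobs * stats::qf(1 - alpha / 2, df2, df1)
    lower <- if (is.infinite(FL)) 1 else (FL - 1) / (FL + k - 1)
    upper <- if (is.infinite(FU)) 1 else (FU - 1) / (FU + k - 1)
  } else {
    a <- rm_anova(X)
    msb <- a$ms["subjects"]; mse <- a$ms["residual"]
    if (msb == 0 && mse == 0) {
      warning("constant matrix: ICC undefined")
      return(list(icc = NaN, lower = NaN, upper = NaN, type = type))
    }
    icc <- unname((msb - mse) / (msb + (k - 1) * mse))
    df1 <- n - 1; df2 <- (n - 1) * (k - 1)
    Fobs <- msb / mse
    FL <- Fobs / stats::qf(1 - alpha / 2, df1, df2)
    FU <- Fobs * stats::qf(1 - alpha / 2, df2, df1)
    lower <- unname(if (is.infinite(FL)) 1 else (FL - 1) / (FL + k - 1))
    upper <- unname(if (is.infinite(FU)) 1 else (FU - 1) / (FU + k - 1))
  }
  list(icc = icc, lower = min(lower, icc), upper = max(upper, icc),
       type = type)
}

#' Standard error of measurement
#'
#' The square root of the within-subject (intra-subject) mean square
#' from the one-way decomposition, in the variable's own units: the
#' absolute trial-to-trial measurement error.
#'
#' @param X numeric subjects x trials matrix.
#' @return numeric scalar, same units as `X`.
#' @export
sem_abs <- function(X) {
  X <- check_matrix(X, min_n = 2)
  sqrt(oneway_ms(X)$msw)
}

#' Coefficient of variation
#'
#' SEM expressed as a percentage of the grand mean across all cells
#' (equivalently, of the mean of the per-attempt means). Values of 10%
#' or less are conventionally flagged acceptable.
#'
#' @param X numeric subjects x trials matrix.
#' @param acceptable_threshold percent threshold for the acceptability
#'   flag.
#' @return list with `cv` (percent), `acceptable`, `sem`, `mean`.
#' @export
cv_percent <- function(X, acceptable_threshold = 10) {
  X <- check_matrix(X, min_n = 2)
  grand <- mean(X)
  sem <- sem_abs(X)
  if (grand <= 0)
    warning("grand mean <= 0: CV as a percentage of the mean is not ",
            "interpretable for this variable")
  cv <- 100 * sem / grand
  list(cv = cv, acceptable = is.finite(cv) && cv >= 0 &&
         cv <= acceptable_threshold, sem = sem, mean = grand)
}

#' Categorize an ICC value
#'
#' Bands: below 0.50 "poor", 0.50 to below 0.70 "moderate", 0.70 to
#' below 0.90 "high", 0.90 and above "excellent"; non-finite values are
#' "undefined".
#'
#' @param icc numeric vector of ICC values.
#' @return character vector of categories.
#' @export
categorize_icc <- function(icc) {
  vapply(icc, function(x) {
    if (!is.finite(x)) return("undefined")
    if (x >= 0.90) "excellent"
    else if (x >= 0.70) "high"
    else if (x >= 0.50) "moderate"
    else "poor"
  }, character(1))
}

#' Standardized between-attempt effect size
#'
#' The mean change from the first to the last attempt standardized by
#' the SD of the first attempt (first trial as the reference
#' distribution), with a bias-corrected bootstrap confidence interval
#' over subjects. Bands: below 0.41 small, 0.41 to below 0.70 moderate,
#' 0.70 and above large.
#'
#' @param X numeric subjects x trials matrix.
#' @param conf confidence level of the bootstrap interval.
#' @param n_boot bootstrap resamples.
#' @param seed integer seed for the bootstrap.
#' @return list with `es`, `lower`, `upper`, `band`.
#' @export
effect_size <- function(X, conf = 0.90, n_boot = 2000, seed = 1) {
  X <- check_matrix(X)
  k <- ncol(X)
  sd1 <- stats::sd(X[, 1])
  if (sd1 == 0) {
    warning("first attempt has zero SD: effect size undefined")
    return(list(es = NaN, lower = NaN, upper = NaN, band = "undefined"))
  }
  est <- function(M) (mean(M[, k]) - mean(M[, 1])) / stats::sd(M[, 1])
  es <- est(X)
  boots <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(nrow(X), replace = TRUE)
    M <- X[idx, , drop = FALSE]
    if (stats::sd(M[, 1]) == 0) return(NA_real_)
    est(M)
  }, numeric(1)))
  boots <- boots[is.finite(boots)]
  # bias-corrected percentile interval
  z0 <- stats::qnorm(mean(boots < es))
  if (!is.finite(z0)) z0 <- 0
  za <- stats::qnorm(c((1 - conf) / 2, 1 - (1 - conf) / 2))
  probs <- stats::pnorm(2 * z0 + za)
  ci <- unname(stats::quantile(boots, probs, na.rm = TRUE))
  list(es = es, lower = ci[1], upper = ci[2], band = es_band(es))
}

#' @rdname effect_size
#' @param es numeric effect size value(s).
#' @export
es_band <- function(es) {
  vapply(es, function(x) {
    if (!is.finite(x)) return("undefined")
    ax <- abs(x)
    if (ax >= 0.70) "large" else if (ax >= 0.41) "moderate" else "small"
  }, character(1))
}

#' Compare active and sedentary groups on a variable
#'
#' The per-subject value is the mean of the three attempts. Test choice
#' follows the distributional checks: Shapiro-Wilk normality within each
#' group and Levene's test of equal variances across groups, both at
#' `alpha`. If all pass, Student's t-test (equal variances); otherwise
#' the Wilcoxon-Mann-Whitney rank test. Groups smaller than 3 make
#' normality untestable and force the rank test.
#'
#' @param values numeric per-subject values (means of attempts).
#' @param labels character/factor with levels `active` and `sedentary`.
#' @param alpha level for the assumption checks.
#' @return list with `test` (name), `statistic`, `p`, `conf_int`,
#'   `group_means`, `assumptions`.
#' @export
compare_groups <- function(values, labels, alpha = 0.05) {
  labels <- as.character(labels)
  stopifnot(length(values) == length(labels))
  ok <- is.finite(values)
  values <- values[ok]; labels <- labels[ok]
  g <- split(values, labels)
  if (length(g) != 2) stop("need exactly two groups, got: ",
                           paste(names(g), collapse = ", "))
  small <- any(vapply(g, length, integer(1)) < 3)
  if (small) {
    warning("a group has fewer than 3 subjects; normality untestable, ",
            "using the rank test")
    sw_p <- c(NA_real_, NA_real_); lev_p <- NA_real_
    parametric <- FALSE
  } else {
    sw_p <- vapply(g, function(v)
      if (stats::sd(v) == 0) 0 else stats::shapiro.test(v)$p.value,
      numeric(1))
    lev <- car::leveneTest(values ~ factor(labels), center = mean)
    lev_p <- lev[["Pr(>F)"]][1]
    parametric <- all(sw_p > alpha) && lev_p > alpha
  }
  if (parametric) {
    ht <- stats::t.test(g[[1]], g[[2]], var.equal = TRUE)
    test <- "Student t"
  } else {
    ht <- suppressWarnings(stats::wilcox.test(g[[1]], g[[2]],
                                              conf.int = TRUE))
    test <- "Wilcoxon-Mann-Whitney"
  }
  list(test = test, statistic = unname(ht$statistic), p = ht$p.value,
       conf_int = as.numeric(ht$conf.int),
       group_means = vapply(g, mean, numeric(1)),
       assumptions = list(shapiro_p = sw_p, levene_p = lev_p,
                          parametric = parametric))
}

#' Full reliability table for a set of variables
#'
#' For every variable in a long-format feature table, assembles the
#' subjects x trials matrix and computes the repeated measures ANOVA,
#' ICC with confidence interval and category, SEM, CV with
#' acceptability flag, and the between-attempt effect size.
#'
#' @param features long data.frame with columns `subject_id`,
#'   `series_index`, `variable`, `value`.
#' @param alpha significance level.
#' @param icc_type `"ICC1"` or `"ICC3"`.
#' @param cv_threshold CV acceptability threshold, percent.
#' @param es_seed seed for the effect-size bootstrap.
#' @param holm apply a Holm correction across variables to the reported
#'   ANOVA p-values (off by default, mirroring per-variable reporting).
#' @return data.frame, one row per variable, with attempt means/SDs,
#'   F, p (sphericity-adjusted where required), ICC, CI, category, SEM,
#'   CV, acceptability and effect size columns.
#' @export
reliability_table <- function(features, alpha = 0.05, icc_type = "ICC1",
                              cv_threshold = 10, es_seed = 1,
                              holm = FALSE) {
  vars <- unique(features$variable)
  rows <- lapply(vars, function(v) {
    X <- feature_wide(features, v)
    if (nrow(X) < 3 || sum(stats::complete.cases(X)) < 3)
      return(NULL)
    a <- rm_anova(X, alpha = alpha)
    ic <- icc_oneway(X, alpha = alpha, type = icc_type)
    cv <- suppressWarnings(cv_percent(X, cv_threshold))
    es <- effect_size(X, seed = substream_seed(es_seed, v))
    Xc <- X[stats::complete.cases(X), , drop = FALSE]
    out <- data.frame(
      variable = v, n = a$n,
      mean_1 = mean(Xc[, 1]), sd_1 = stats::sd(Xc[, 1]),
      mean_2 = mean(Xc[, 2]), sd_2 = stats::sd(Xc[, 2]),
      mean_3 = if (ncol(Xc) >= 3) mean(Xc[, 3]) else NA_real_,
      sd_3 = if (ncol(Xc) >= 3) stats::sd(Xc[, 3]) else NA_real_,
      df_trials = unname(if (a$sphericity_assumed) a$df["trials"]
                         else a$df_adjusted["trials"]),
      F = a$F, p = a$p_reported,
      sphericity = a$sphericity_assumed,
      gg_epsilon = a$gg_epsilon,
      icc = ic$icc, icc_lower = ic$lower, icc_upper = ic$upper,
      icc_category = categorize_icc(ic$icc),
      sem = cv$sem, cv = cv$cv, cv_acceptable = cv$acceptable,
      es = es$es, es_lower = es$lower, es_upper = es$upper,
      es_band = es$band,
      stringsAsFactors = FALSE)
    out
  })
  tab <- do.call(rbind, rows)
  if (holm) tab$p_holm <- stats::p.adjust(tab$p, method = "holm")
  rownames(tab) <- NULL
  tab
}

#' Reshape long features to a subjects x trials matrix
#'
#' @param features long feature data.frame (`subject_id`, `series_index`,
#'   `variable`, `value`).
#' @param variable variable name to extract.
#' @return numeric matrix, rows = subjects, columns = trials.
#' @export
feature_wide <- function(features, variable) {
  f <- features[features$variable == variable, ]
  w <- stats::reshape(f[, c("subject_id", "series_index", "value")],
                      idvar = "subject_id", timevar = "series_index",
                      direction = "wide")
  m <- as.matrix(w[, -1, drop = FALSE])
  rownames(m) <- w$subject_id
  m <- m[, order(as.integer(sub("value\\.", "", colnames(m)))), drop = FALSE]
  colnames(m) <- paste0("trial_", seq_len(ncol(m)))
  m
}

#' Group-difference table across variables
#'
#' Per variable: per-subject means of the attempts compared between
#' active and sedentary subjects via [compare_groups()].
#'
#' @param features long feature data.frame.
#' @param subjects subjects data.frame with `subject_id` and
#'   `activity_class`.
#' @param alpha level for assumption checks.
#' @return data.frame, one row per variable.
#' @export
group_table <- function(features, subjects, alpha = 0.05) {
  vars <- unique(features$variable)
  rows <- lapply(vars, function(v) {
    X <- feature_wide(features, v)
    means <- rowMeans(X, na.rm = TRUE)
    cls <- subjects$activity_class[match(rownames(X), subjects$subject_id)]
    keep <- !is.na(cls) & is.finite(means)
    if (length(unique(cls[keep])) < 2) return(NULL)
    g <- compare_groups(means[keep], cls[keep], alpha)
    data.frame(variable = v,
               mean_active = unname(g$group_means["active"]),
               mean_sedentary = unname(g$group_means["sedentary"]),
               test = g$test, statistic = g$statistic, p = g$p,
               conf_low = g$conf_int[1], conf_high = g$conf_int[2],
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  tab
}
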