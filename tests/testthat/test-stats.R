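test_that("mean absolute deviation handles pairs and missingness", {
  expect_equal(mad_pairwise(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(mad_pairwise(c(1, 2, 3), c(2, 2, 1)), 1)
  expect_equal(mad_pairwise(10, 7), 3)
  expect_equal(mad_pairwise(c(1, NA, 3), c(2, 5, 1)), 1.5)
  expect_error(mad_pairwise(c(NA, NA), c(1, 2)), "no complete pairs")
  expect_error(mad_pairwise(1:3, 1:2), "equal length")
})

test_that("pearson correlation matches the direct formula and cases", {
  expect_equal(pearson_ci(1:10, 2 * (1:10) + 1)$r, 1)
  expect_equal(pearson_ci(1:10, -(1:10))$r, -1)
  a <- c(1, 2, 3); b <- c(1, 2, 4)
  res <- pearson_ci(a, b)
  direct <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(res$r, direct, tolerance = 1e-12)
  expect_equal(res$r, 0.98198, tolerance = 1e-4)
  expect_error(pearson_ci(c(1, 1, 1), 1:3), "zero variance")
  expect_error(pearson_ci(1:2, 1:2), "at least 3")
})

test_that("ICC(2,1) matches the mean-squares oracle and edge cases", {
  set.seed(3)
  base <- stats::rnorm(10, 50, 8)
  same <- cbind(base, base)
  r1 <- icc_agreement(same)
  expect_equal(r1$icc, 1, tolerance = 1e-12)
  shifted <- cbind(base, base + 5)
  r2 <- icc_agreement(shifted)
  expect_lt(r2$icc, 1)
  expect_equal(r2$icc, oracle_icc21(shifted), tolerance = 1e-9)
  m6 <- matrix(c(9, 2, 5, 8, 6, 7, 2, 4, 4, 5, 8, 6), 6, 2)
  r3 <- icc_agreement(m6)
  expect_equal(r3$icc, oracle_icc21(m6), tolerance = 1e-9)
  expect_true(r3$ci95[1] <= r3$icc && r3$icc <= r3$ci95[2])
  # 30 random matrices against the aov-based oracle
  for (i in 1:30) {
    m <- matrix(stats::rnorm(8 * 3, 20, 4), 8, 3)
    expect_equal(icc_agreement(m)$icc, oracle_icc21(m), tolerance = 1e-6)
  }
  expect_error(icc_agreement(matrix(1:8, 4, 2)), ">= 5 subjects")
  mm <- matrix(stats::rnorm(12), 6, 2); mm[2, 1] <- NA
  expect_error(icc_agreement(mm), "incomplete")
})

test_that("repeated-measures ANOVA reproduces the within-subject decomposition", {
  m0 <- matrix(rep(c(3, 5, 9, 2), 3), 4, 3)
  r0 <- rm_anova(m0)
  expect_equal(r0$F, 0)
  expect_equal(r0$p_value, 1)
  m <- matrix(c(2, 4, 3, 5, 6, 5, 4, 7, 8, 9, 7, 10), 4, 3)
  r <- rm_anova(m)
  orc <- oracle_rm_anova(m)
  expect_equal(r$F, orc$F, tolerance = 1e-9)
  expect_equal(r$p_value, orc$p, tolerance = 1e-9)
  expect_equal(r$ss_condition, orc$ss_condition, tolerance = 1e-9)
  expect_equal(r$ss_error, orc$ss_error, tolerance = 1e-9)
  expect_equal(r$df_effect, 2)
  expect_equal(r$df_error, 6)
  # incomplete rows dropped and counted
  m2 <- rbind(m, c(NA, 1, 2))
  r2 <- rm_anova(m2)
  expect_equal(r2$n_dropped, 1)
  expect_equal(r2$F, r$F)
  expect_error(rm_anova(m[1, , drop = FALSE]), "2 usable subjects")
  # 30 random matrices against the aov oracle
  set.seed(6)
  for (i in 1:30) {
    mr <- matrix(stats::rnorm(5 * 4), 5, 4)
    expect_equal(rm_anova(mr)$F, oracle_rm_anova(mr)$F, tolerance = 1e-6)
  }
})

test_that("Tukey HSD reduces to t for two groups and matches TukeyHSD", {
  set.seed(9)
  g <- list(a = stats::rnorm(8), b = stats::rnorm(8, 1))
  tk <- tukey_hsd(g)
  tt <- stats::t.test(g$b, g$a, var.equal = TRUE)
  # q = t * sqrt(2): identical p-values
  q <- abs(tk$diff) / sqrt(sum(vapply(g, function(x) sum((x - mean(x))^2),
                                      numeric(1))) / 14 / 8)
  expect_equal(q, abs(tt$statistic[[1]]) * sqrt(2), tolerance = 1e-9)
  expect_equal(tk$p_adj, tt$p.value, tolerance = 1e-9)
  # equal group means: all adjusted p near 1
  ge <- list(a = c(1, 2, 3), b = c(2, 1, 3), c = c(3, 2, 1))
  expect_true(all(tukey_hsd(ge)$p_adj > 0.99))
  # three groups against stats::TukeyHSD
  g3 <- list(a = stats::rnorm(6), b = stats::rnorm(6, 0.8),
             c = stats::rnorm(6, -0.5))
  tk3 <- tukey_hsd(g3)
  d <- data.frame(y = unlist(g3), grp = factor(rep(names(g3), each = 6)))
  ref <- stats::TukeyHSD(stats::aov(y ~ grp, d))$grp
  expect_equal(sort(tk3$p_adj), sort(unname(ref[, "p adj"])), tolerance = 1e-9)
  expect_equal(sort(tk3$diff), sort(unname(ref[, "diff"])), tolerance = 1e-9)
  # within-subject context: pairwise table from the rm_anova error term
  m <- matrix(stats::rnorm(18), 6, 3)
  tkw <- tukey_hsd(rm_anova(m))
  expect_equal(nrow(tkw), 3)
  expect_true(all(tkw$p_adj >= 0 & tkw$p_adj <= 1))
})

test_that("the mixed model collapses to OLS without participant variance", {
  set.seed(10)
  n <- 12; k <- 6
  d <- data.frame(participant = rep(sprintf("P%02d", 1:n), each = k),
                  severity = rep(c("none", "mild", "severe"), n * 2),
                  joint_level = rep(c("hip", "knee"), each = 3, times = n))
  d$dice <- 0.9 - 0.1 * (d$severity == "severe") + stats::rnorm(nrow(d), 0, 0.03)
  fit <- fit_lmm(d, fixed = c("joint_level", "severity"),
                 reference_levels = list(joint_level = "hip", severity = "none"))
  ols <- stats::lm(dice ~ joint_level + severity,
                   data = transform(d,
                                    joint_level = stats::relevel(factor(joint_level), "hip"),
                                    severity = stats::relevel(factor(severity), "none")))
  for (tm in names(fit$coefficients)) {
    expect_equal(fit$coefficients[[tm]]$estimate, unname(coef(ols)[tm]),
                 tolerance = 1e-4)
  }
  expect_gte(fit$variance_components[["participant"]], 0)
  expect_error(fit_lmm(d[d$participant == "P01", ]), ">= 2 participants")
  # aliased factors are reported, not silently dropped
  d$strategy <- d$severity
  expect_error(fit_lmm(d, fixed = c("severity", "strategy")), "aliased")
})

test_that("the mixed model recovers a planted severity effect", {
  set.seed(11)
  ests <- replicate(25, {
    n <- 20
    d <- expand.grid(participant = sprintf("P%02d", 1:n),
                     severity = c("none", "mild", "moderate", "severe"),
                     rep = 1:6)
    u <- stats::rnorm(n, 0, 0.05)
    d$dice <- 0.9 - 0.22 * (d$severity == "severe") -
      0.05 * (d$severity %in% c("mild", "moderate")) +
      u[as.integer(d$participant)] + stats::rnorm(nrow(d), 0, 0.05)
    fit <- fit_lmm(d, fixed = "severity",
                   reference_levels = list(severity = "none"))
    fit$coefficients[["severitysevere"]]$estimate
  })
  expect_lt(abs(mean(ests) - (-0.22)), 0.01)
})

test_that("sample-size search satisfies its defining power property", {
  n5 <- rm_anova_sample_size(0.25, 0.05, 0.80, 0.6, 5)
  expect_gte(attr(n5, "power"), 0.80)
  expect_lt(attr(n5, "power_prev"), 0.80)
  # matches the brute-force power curve: first n whose power reaches 0.8
  pws <- vapply(2:100, function(n) oracle_rm_power(n, 5, 0.25, 0.05, 0.6),
                numeric(1))
  expect_equal(as.integer(n5), (2:100)[which(pws >= 0.80)[1]])
  # the five-acquisition design requires 17 participants
  expect_equal(as.integer(n5), 17L)
  # monotonicity: larger corr and more measurements require fewer subjects
  n_corr <- vapply(c(0.3, 0.6, 0.8),
                   function(cr) as.integer(rm_anova_sample_size(corr = cr,
                                                                n_measurements = 4)),
                   integer(1))
  expect_true(all(diff(n_corr) <= 0))
  n_m <- vapply(3:6, function(m) as.integer(rm_anova_sample_size(n_measurements = m)),
                integer(1))
  expect_true(all(diff(n_m) <= 0))
  expect_error(rm_anova_sample_size(effect_f = 0), "> 0")
  expect_error(rm_anova_sample_size(corr = 1), "corr")
  expect_error(rm_anova_sample_size(n_measurements = 1), ">= 2")
})

test_that("significance labels stratify at the conventional thresholds", {
  expect_equal(p_stars(c(0.0005, 0.005, 0.03, 0.2)),
               c("***", "**", "*", "ns"))
})
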