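# Agreement metrics, repeated-measures tests, mixed-effects modelling,
# and the a-priori sample-size computation.

#' Mean absolute deviation between paired measurements
#'
#' Pairs with a missing entry in either vector are dropped
#' (pairwise-complete); failed automatic measurements therefore reduce
#' the denominator, matching the completed-measurement accounting of the
#' success-rate tables.
#'
#' @param a,b numeric vectors of equal length.
#' @return mean of `|a - b|` over complete pairs.
#' @export
mad_pairwise <- function(a, b) {
  if (length(a) != length(b) || length(a) < 1) {
    abort("mad_pairwise: vectors must have equal length >= 1")
  }
  ok <- is.finite(a) & is.finite(b)
  if (!any(ok)) abort("mad_pairwise: no complete pairs")
  mean(abs(a[ok] - b[ok]))
}

#' Pearson correlation with test and confidence interval
#'
#' Product-moment r, two-sided p-value via the t transform, and a 95%
#' confidence interval via the Fisher z transform (as implemented in
#' [stats::cor.test()]).
#'
#' @param a,b numeric vectors, n >= 3, both with non-zero variance.
#' @return list with `r`, `p_value`, `ci95`.
#' @export
pearson_ci <- function(a, b) {
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 3) abort("pearson_ci: need at least 3 complete pairs")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) abort("pearson_ci: zero variance")
  ct <- stats::cor.test(a, b, method = "pearson", conf.level = 0.95)
  list(r = unname(ct$estimate), p_value = ct$p.value,
       ci95 = as.numeric(ct$conf.int))
}

#' Intraclass correlation, two-way random, absolute agreement, single rater
#'
#' ICC(2,1) from the two-way ANOVA mean squares: with n subjects and k
#' raters, `ICC = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`.
#' The p-value is from the F test `MSR / MSE` on (n-1), (n-1)(k-1)
#' degrees of freedom; the 95% CI follows the standard F-bound
#' construction (McGraw & Wong).
#'
#' @param ratings complete numeric matrix, subjects x raters
#'   (>= 5 subjects, >= 2 raters). No imputation is performed.
#' @return an `icc_result`: `icc`, `p_value`, `ci95`, `model_label`.
#' @export
icc_agreement <- function(ratings) {
  m <- as.matrix(ratings)
  n <- nrow(m); k <- ncol(m)
  if (n < 5 || k < 2) abort("icc_agreement: need >= 5 subjects and >= 2 raters")
  if (any(!is.finite(m))) abort("icc_agreement: incomplete matrix")
  gm <- mean(m)
  row_m <- rowMeans(m); col_m <- colMeans(m)
  SSR <- k * sum((row_m - gm)^2)
  SSC <- n * sum((col_m - gm)^2)
  SST <- sum((m - gm)^2)
  SSE <- SST - SSR - SSC
  MSR <- SSR / (n - 1)
  MSC <- SSC / (k - 1)
  MSE <- SSE / ((n - 1) * (k - 1))
  icc <- (MSR - MSE) / (MSR + (k - 1) * MSE + k * (MSC - MSE) / n)
  Fv <- MSR / MSE
  p <- stats::pf(Fv, n - 1, (n - 1) * (k - 1), lower.tail = FALSE)
  alpha <- 0.05
  Fj <- MSC / MSE
  vn <- (k - 1) * (n - 1) * (k * icc * Fj + n * (1 + (k - 1) * icc) - k * icc)^2
  vd <- (n - 1) * k^2 * icc^2 * Fj^2 + (n * (1 + (k - 1) * icc) - k * icc)^2
  v <- vn / vd
  FL <- stats::qf(1 - alpha / 2, n - 1, v)
  FU <- stats::qf(1 - alpha / 2, v, n - 1)
  lo <- n * (MSR - FL * MSE) /
    (FL * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
  hi <- n * (FU * MSR - MSE) /
    (k * MSC + (k * n - k - n) * MSE + n * FU * MSR)
  structure(list(icc = icc, p_value = p, ci95 = c(lo, hi),
                 model_label = "two-way random, absolute agreement, single rater (ICC(2,1))"),
            class = "icc_result")
}

#' One-way repeated-measures ANOVA
#'
#' Within-subject decomposition of a complete subjects x conditions
#' matrix: `F = MS_condition / MS_error` on (k-1), (n-1)(k-1) degrees of
#' freedom. Rows with missing values are dropped and counted. Residual
#' normality (Shapiro-Wilk) is reported as an advisory flag, never used
#' as a gate.
#'
#' @param values numeric matrix, subjects x conditions (>= 3 subjects
#'   with complete rows, >= 2 conditions).
#' @return an `anova_table`: `F`, `p_value`, `df_effect`, `df_error`,
#'   sums of squares, `normality_ok` flag, `n_dropped`.
#' @export
rm_anova <- function(values) {
  m <- as.matrix(values)
  if (ncol(m) < 2) abort("rm_anova: need >= 2 conditions")
  complete <- stats::complete.cases(m)
  n_dropped <- sum(!complete)
  m <- m[complete, , drop = FALSE]
  n <- nrow(m); k <- ncol(m)
  if (n < 2) abort("rm_anova: fewer than 2 usable subjects")
  gm <- mean(m)
  SScond <- n * sum((colMeans(m) - gm)^2)
  SSsubj <- k * sum((rowMeans(m) - gm)^2)
  SST <- sum((m - gm)^2)
  SSerr <- SST - SScond - SSsubj
  df1 <- k - 1; df2 <- (n - 1) * (k - 1)
  MScond <- SScond / df1
  MSerr <- SSerr / df2
  Fv <- if (MSerr > 0) MScond / MSerr else 0
  p <- if (MSerr > 0) stats::pf(Fv, df1, df2, lower.tail = FALSE) else 1
  if (SScond == 0) { Fv <- 0; p <- 1 }
  resid <- m - outer(rowMeans(m), rep(1, k)) -
    outer(rep(1, n), colMeans(m)) + gm
  norm_ok <- tryCatch(stats::shapiro.test(as.vector(resid))$p.value > 0.05,
                      error = function(e) NA)
  structure(list(F = Fv, p_value = p, df_effect = df1, df_error = df2,
                 ss_condition = SScond, ss_subject = SSsubj, ss_error = SSerr,
                 ms_error = MSerr, n_subjects = n, n_dropped = n_dropped,
                 condition_means = colMeans(m), normality_ok = norm_ok),
            class = "anova_table")
}

#' Tukey Honest Significant Difference test
#'
#' Studentized-range pairwise comparisons. Accepts either the result of
#' [rm_anova()] (post hoc within-subject comparisons against its error
#' mean square) or a list of independent group vectors (one-way ANOVA
#' context).
#'
#' @param x an `anova_table` from [rm_anova()], or a named list of
#'   numeric vectors (independent groups).
#' @param conf_level confidence level for the intervals, default 0.95.
#' @return data.frame with one row per pair: `diff`, `lwr`, `upr`,
#'   `p_adj`.
#' @export
tukey_hsd <- function(x, conf_level = 0.95) {
  if (inherits(x, "anova_table")) {
    means <- x$condition_means
    k <- length(means)
    n <- x$n_subjects
    mse <- x$ms_error
    df <- x$df_error
    se <- sqrt(mse / n)
  } else {
    stopifnot(is.list(x), length(x) >= 2)
    means <- vapply(x, mean, numeric(1))
    ns <- vapply(x, length, numeric(1))
    k <- length(means)
    grand <- unlist(x)
    df <- length(grand) - k
    mse <- sum(vapply(x, function(g) sum((g - mean(g))^2), numeric(1))) / df
    if (length(unique(ns)) != 1) {
      abort("tukey_hsd: groups must be balanced")
    }
    n <- ns[1]
    se <- sqrt(mse / n)
  }
  if (is.null(names(means))) names(means) <- paste0("g", seq_along(means))
  pairs <- utils::combn(k, 2)
  qcrit <- stats::qtukey(conf_level, k, df)
  out <- data.frame(
    pair = apply(pairs, 2, function(ij) paste(names(means)[ij[2]], "-",
                                              names(means)[ij[1]])),
    diff = apply(pairs, 2, function(ij) means[ij[2]] - means[ij[1]])
  )
  out$lwr <- out$diff - qcrit * se
  out$upr <- out$diff + qcrit * se
  out$p_adj <- stats::ptukey(abs(out$diff) / se, k, df, lower.tail = FALSE)
  out
}

#' Random-intercept linear mixed-effects model
#'
#' REML fit of `value ~ fixed factors + (1 | participant)`, the model
#' used to quantify how joint level, artifact severity, and augmentation
#' strategy contribute to segmentation quality. Factors are encoded by
#' treatment contrasts against explicit reference levels, so every
#' coefficient reads as a difference from its reference. Estimation is
#' delegated to \pkg{lme4} with Satterthwaite p-values from
#' \pkg{lmerTest}; singular fits are flagged, not hidden.
#'
#' @param records data.frame in long format.
#' @param response name of the response column.
#' @param fixed character vector of fixed-factor column names.
#' @param random_intercept name of the grouping column (participant).
#' @param reference_levels named list: reference level per fixed factor
#'   (default: first level).
#' @return an `lmm_result`: `coefficients` (estimate, ci95, p_value per
#'   term), `variance_components` (participant, residual),
#'   `reference_levels`, `singular` flag, and the underlying fit.
#' @export
fit_lmm <- function(records, response = "dice",
                    fixed = c("joint_level", "severity"),
                    random_intercept = "participant",
                    reference_levels = NULL) {
  stopifnot(is.data.frame(records))
  cols <- c(response, fixed, random_intercept)
  missing_cols <- setdiff(cols, names(records))
  if (length(missing_cols)) abort("fit_lmm: missing columns: %s",
                                  paste(missing_cols, collapse = ", "))
  d <- records[stats::complete.cases(records[cols]), cols, drop = FALSE]
  grp <- table(d[[random_intercept]])
  if (sum(grp >= 2) < 2) {
    abort("fit_lmm: need >= 2 participants with >= 2 records each")
  }
  refs <- list()
  for (f in fixed) {
    lv <- unique(as.character(d[[f]]))
    ref <- if (!is.null(reference_levels[[f]])) reference_levels[[f]] else lv[1]
    if (!ref %in% lv) abort("fit_lmm: reference level '%s' absent from %s", ref, f)
    d[[f]] <- stats::relevel(factor(d[[f]]), ref = ref)
    refs[[f]] <- ref
  }
  fixed_used <- fixed[vapply(fixed, function(f) nlevels(d[[f]]) > 1, logical(1))]
  rhs <- if (length(fixed_used)) paste(fixed_used, collapse = " + ") else "1"
  # identifiability check on the fixed-effect design
  X <- stats::model.matrix(stats::as.formula(paste("~", rhs)), d)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    abort("fit_lmm: unidentifiable design; aliased terms: %s",
          paste(aliased, collapse = ", "))
  }
  form <- stats::as.formula(paste(response, "~", rhs, "+ (1 |",
                                  random_intercept, ")"))
  fit <- suppressMessages(lmerTest::lmer(form, data = d, REML = TRUE))
  ct <- stats::coef(summary(fit))
  ci <- suppressMessages(stats::confint(fit, parm = "beta_", method = "Wald"))
  vc <- as.data.frame(lme4::VarCorr(fit))
  vpart <- vc$vcov[vc$grp == random_intercept][1]
  vres <- vc$vcov[vc$grp == "Residual"][1]
  coefs <- lapply(rownames(ct), function(tm) {
    list(estimate = unname(ct[tm, "Estimate"]),
         ci95 = unname(ci[tm, ]),
         p_value = unname(ct[tm, "Pr(>|t|)"]))
  })
  names(coefs) <- rownames(ct)
  structure(list(coefficients = coefs,
                 variance_components = c(participant = vpart, residual = vres),
                 reference_levels = refs,
                 singular = lme4::isSingular(fit),
                 fit = fit),
            class = "lmm_result")
}

#' A-priori sample size for repeated-measures ANOVA (within factor)
#'
#' Smallest number of participants n such that the power of the
#' noncentral-F test reaches the target, with noncentrality
#' `lambda = f^2 * n * m / (1 - corr)`, numerator df `m - 1`, denominator
#' df `(n - 1)(m - 1)`, and sphericity epsilon fixed at 1.
#'
#' @param effect_f Cohen's f (> 0).
#' @param alpha significance level (0 < alpha < 1).
#' @param power target power (alpha < power < 1).
#' @param corr correlation among repeated measures, in \[0, 1).
#' @param n_measurements number of repeated measurements m (>= 2).
#' @return smallest n (integer) with attributes `power` (achieved) and
#'   `power_prev` (power at n - 1), satisfying
#'   `power(n) >= target > power(n - 1)`.
#' @export
rm_anova_sample_size <- function(effect_f = 0.25, alpha = 0.05, power = 0.80,
                                 corr = 0.6, n_measurements = 5L) {
  if (effect_f <= 0) abort("rm_anova_sample_size: effect_f must be > 0")
  if (alpha <= 0 || alpha >= 1 || power <= alpha || power >= 1) {
    abort("rm_anova_sample_size: need 0 < alpha < power < 1")
  }
  if (corr < 0 || corr >= 1) abort("rm_anova_sample_size: corr must be in [0, 1)")
  m <- as.integer(n_measurements)
  if (m < 2) abort("rm_anova_sample_size: n_measurements must be >= 2")
  pw <- function(n) {
    if (n < 2) return(0)
    lambda <- effect_f^2 * n * m / (1 - corr)
    df1 <- m - 1
    df2 <- (n - 1) * (m - 1)
    stats::pf(stats::qf(1 - alpha, df1, df2), df1, df2, ncp = lambda,
              lower.tail = FALSE)
  }
  n <- 2L
  while (pw(n) < power) {
    n <- n + 1L
    if (n > 1e6) abort("rm_anova_sample_size: no n <= 1e6 reaches the target power")
  }
  structure(n, power = pw(n), power_prev = pw(n - 1L))
}

#' Significance stratification labels
#'
#' @param p numeric vector of p-values.
#' @return character vector: `***` (p <= 0.001), `**` (p <= 0.01),
#'   `*` (p <= 0.05), `ns` otherwise.
#' @export
p_stars <- function(p) {
  ifelse(p <= 0.001, "***", ifelse(p <= 0.01, "**",
                                   ifelse(p <= 0.05, "*", "ns")))
}
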