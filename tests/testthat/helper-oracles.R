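# independent oracles, deliberately implemented by routes different from
# the package code paths they check

# direct 2D DFT / inverse DFT via explicit exponential matrices
oracle_dft2 <- function(x, inverse = FALSE) {
  n1 <- nrow(x); n2 <- ncol(x)
  s <- if (inverse) 1i else -1i
  W1 <- exp(s * 2 * pi * outer(0:(n1 - 1), 0:(n1 - 1)) / n1)
  W2 <- exp(s * 2 * pi * outer(0:(n2 - 1), 0:(n2 - 1)) / n2)
  out <- W1 %*% x %*% W2
  if (inverse) out / (n1 * n2) else out
}

# geometric least-squares circle fit by nested grid refinement over the
# centre; the optimal radius for a fixed centre is the mean point distance
oracle_circle_fit <- function(pts, init, half_width = 0.5, levels = 9) {
  obj <- function(cy, cx) {
    d <- sqrt((pts[, 1] - cy)^2 + (pts[, 2] - cx)^2)
    sum((d - mean(d))^2)
  }
  ctr <- init
  hw <- half_width
  for (lv in seq_len(levels)) {
    cys <- seq(ctr[1] - hw, ctr[1] + hw, length.out = 21)
    cxs <- seq(ctr[2] - hw, ctr[2] + hw, length.out = 21)
    vals <- outer(cys, cxs, Vectorize(obj))
    ij <- which(vals == min(vals), arr.ind = TRUE)[1, ]
    ctr <- c(cys[ij[1]], cxs[ij[2]])
    hw <- hw / 5
  }
  d <- sqrt((pts[, 1] - ctr[1])^2 + (pts[, 2] - ctr[2])^2)
  list(center = c(y = ctr[1], x = ctr[2]), radius = mean(d))
}

# rotating-line search for the common posterior tangent of two point
# sets: sweep the line angle in fine steps; at each angle the posterior
# support line of each component is found by advancing anteriorly until
# first contact, and the common tangent is where the two support lines
# coincide (sign change of the support difference)
oracle_posterior_tangent <- function(p1, p2, step_deg = 0.01) {
  phis <- seq(-90 + step_deg, 90, by = step_deg)
  th <- phis * pi / 180
  # posterior normal n = (-sin phi, cos phi) in (x, y); support = max n.p
  s1 <- vapply(seq_along(th), function(i) {
    max(-sin(th[i]) * p1[, 2] + cos(th[i]) * p1[, 1])
  }, numeric(1))
  s2 <- vapply(seq_along(th), function(i) {
    max(-sin(th[i]) * p2[, 2] + cos(th[i]) * p2[, 1])
  }, numeric(1))
  dlt <- s1 - s2
  sc <- which(dlt[-1] * dlt[-length(dlt)] <= 0)
  if (length(sc) == 0) return(NA_real_)
  # choose the crossing whose common support line is posterior-most
  cand <- phis[sc]
  cand[which.max(pmin(s1, s2)[sc])]
}

# two-way ANOVA mean squares via stats::aov, used as the independent
# route for the ICC and repeated-measures decompositions
oracle_two_way_ms <- function(m) {
  n <- nrow(m); k <- ncol(m)
  d <- data.frame(y = as.vector(m),
                  subj = factor(rep(seq_len(n), k)),
                  rater = factor(rep(seq_len(k), each = n)))
  tab <- summary(stats::aov(y ~ subj + rater, data = d))[[1]]
  list(MSR = tab["subj", "Mean Sq"], MSC = tab["rater", "Mean Sq"],
       MSE = tab["Residuals", "Mean Sq"])
}

oracle_icc21 <- function(m) {
  ms <- oracle_two_way_ms(m)
  n <- nrow(m); k <- ncol(m)
  (ms$MSR - ms$MSE) /
    (ms$MSR + (k - 1) * ms$MSE + k * (ms$MSC - ms$MSE) / n)
}

# within-subject ANOVA via aov with an Error stratum
oracle_rm_anova <- function(m) {
  n <- nrow(m); k <- ncol(m)
  d <- data.frame(y = as.vector(m),
                  subj = factor(rep(seq_len(n), k)),
                  cond = factor(rep(seq_len(k), each = n)))
  tab <- summary(stats::aov(y ~ cond + Error(subj / cond), data = d))
  s <- tab[["Error: subj:cond"]][[1]]
  list(F = s["cond", "F value"], p = s["cond", "Pr(>F)"],
       ss_condition = s["cond", "Sum Sq"], ss_error = s["Residuals", "Sum Sq"])
}

# direct noncentral-F power curve for the sample-size calculator
oracle_rm_power <- function(n, m, f, alpha, corr) {
  lambda <- f^2 * n * m / (1 - corr)
  df1 <- m - 1; df2 <- (n - 1) * (m - 1)
  stats::pf(stats::qf(1 - alpha, df1, df2), df1, df2, ncp = lambda,
            lower.tail = FALSE)
}
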