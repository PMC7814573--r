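# Independent oracles used to freeze expected values. These are written
# from first principles (mean squares, exhaustive enumeration) and share
# no code with the package implementations they check.

# Closed-form nested-ANOVA variance components for a *balanced* design:
# I cats x J occasions x K replicates, on the ln scale.
oracle_nested_anova <- function(df) {
  y <- log(df$value)
  cat <- factor(df$cat_id)
  occ <- interaction(df$cat_id, df$occasion, drop = TRUE)
  I <- nlevels(cat)
  J <- nlevels(occ) / I
  K <- length(y) / nlevels(occ)
  stopifnot(J == round(J), K == round(K))
  grand <- mean(y)
  cat_means <- tapply(y, cat, mean)
  occ_means <- tapply(y, occ, mean)
  occ_cat <- tapply(as.character(cat), occ, `[`, 1)
  ms_cat <- J * K * sum((cat_means - grand)^2) / (I - 1)
  ms_occ <- K * sum((occ_means - cat_means[occ_cat])^2) / (I * (J - 1))
  ms_rep <- if (K > 1)
    sum((y - occ_means[occ])^2) / (I * J * (K - 1)) else 0
  list(sd2_A = ms_rep,
       sd2_I = (ms_occ - ms_rep) / K,
       sd2_G = (ms_cat - ms_occ) / (J * K))
}

# Exhaustive-enumeration two-sided p for the Wilcoxon rank-sum test
# (tie-free data): distribution of the group-1 rank sum over all
# choose(n1+n2, n1) assignments of ranks.
oracle_wilcoxon_exact <- function(x, y) {
  n1 <- length(x); n <- n1 + length(y)
  ranks <- rank(c(x, y))
  stopifnot(!anyDuplicated(c(x, y)))
  rs_obs <- sum(ranks[seq_len(n1)])
  combos <- utils::combn(n, n1)
  rs_all <- colSums(matrix(seq_len(n)[combos], nrow = n1))
  p_low <- mean(rs_all <= rs_obs)
  p_high <- mean(rs_all >= rs_obs)
  min(1, 2 * min(p_low, p_high))
}

# Moments of a doubly truncated normal, for checking the body-fat
# generator against adjusted targets.
oracle_truncnorm_moments <- function(mean, sd, range) {
  a <- (range[1] - mean) / sd
  b <- (range[2] - mean) / sd
  Z <- pnorm(b) - pnorm(a)
  m1 <- (dnorm(a) - dnorm(b)) / Z
  varf <- 1 + (a * dnorm(a) - b * dnorm(b)) / Z - m1^2
  list(mean = mean + sd * m1, sd = sd * sqrt(varf))
}

# ln-scale SD from a percent CV (Cole's relation inverted); kept local so
# test expectations do not depend on the package's own converter.
oracle_sdln <- function(cv_pct) sqrt(log(1 + (cv_pct / 100)^2))
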