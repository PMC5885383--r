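# Independent oracles, coded from first principles (explicit summation /
# normal equations), never via lm() or the package's own code paths.

# slope/intercept of least squares on (x, y) by raw sums
oracle_ls <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y); sxx <- sum(x^2); sxy <- sum(x * y)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  intercept <- (sy - slope * sx) / n
  c(intercept = intercept, slope = slope)
}

# elimination rate oracle: -slope of log(excess) vs time
oracle_k <- function(time, enrichment, baseline = 0) {
  keep <- enrichment - baseline > 0
  b <- oracle_ls(time[keep], log(enrichment[keep] - baseline))
  unname(-b["slope"])
}

# mean and t-based 95% CI from explicit formulas
oracle_mean_ci <- function(x) {
  n <- length(x)
  m <- sum(x) / n
  s <- sqrt(sum((x - m)^2) / (n - 1))
  half <- stats::qt(0.975, n - 1) * s / sqrt(n)
  c(mean = m, ci_low = m - half, ci_high = m + half)
}

# three-parameter OLS by solving the normal equations directly
oracle_ols3 <- function(y, x1, x2) {
  X <- cbind(1, x1, x2)
  as.numeric(solve(t(X) %*% X, t(X) %*% y))
}

# small deterministic cohort used across tests
toy_cohort <- function() {
  data.frame(
    id = sprintf("P%02d", 1:9),
    course = rep(c("alpha", "bravo", "charlie"), each = 3),
    body_mass_kg = c(80, 82, 84, 76, 78, 80, 88, 90, 92),
    ffm_kg = c(64, 65, 66, 60, 61, 62, 70, 71, 72),
    tdee_kcal_d = c(4200, 4300, 4400, 3800, 3900, 4000, 5100, 5200, 5300),
    intake_kcal_d = c(3000, 3100, 3200, 3600, 3500, 3700, 2500, 2600, 2700),
    paf = rep(c(1L, 0L, 3L), each = 3),
    stringsAsFactors = FALSE)
}
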