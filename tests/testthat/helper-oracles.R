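# Independent brute-force oracles, deliberately coded differently from the
# implementation (matrix normal equations / explicit sums where the package
# uses lm/aov, and lm where the package uses closed forms).

oracle_ols <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  res <- y - X %*% beta
  n <- length(y)
  s2 <- sum(res^2) / (n - 2)
  covb <- s2 * solve(t(X) %*% X)
  list(intercept = beta[1], slope = beta[2],
       slope_se = sqrt(covb[2, 2]),
       r2 = 1 - sum(res^2) / sum((y - mean(y))^2))
}

oracle_through_origin <- function(x, y) {
  unname(coef(lm(y ~ x + 0))[1])
}

oracle_pearson <- function(x, y) {
  xm <- x - mean(x)
  ym <- y - mean(y)
  sum(xm * ym) / sqrt(sum(xm^2) * sum(ym^2))
}

oracle_anova_f <- function(values, groups) {
  groups <- as.factor(groups)
  gm <- mean(values)
  ss_between <- sum(tapply(values, groups, function(v) {
    length(v) * (mean(v) - gm)^2
  }))
  ss_within <- sum(unlist(tapply(values, groups, function(v) {
    (v - mean(v))^2
  })))
  df_b <- nlevels(groups) - 1
  df_w <- length(values) - nlevels(groups)
  (ss_between / df_b) / (ss_within / df_w)
}

# two-covariate OLS (temperature + day indicator) via normal equations
oracle_day_coef <- function(logr, temp, day) {
  X <- cbind(1, temp, as.numeric(day))
  beta <- solve(t(X) %*% X, t(X) %*% logr)
  beta[3]
}

rel_err <- function(est, truth) {
  abs(est - truth) / pmax(abs(truth), .Machine$double.eps)
}
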