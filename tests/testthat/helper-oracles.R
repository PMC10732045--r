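# Independent statistical oracles, written from the published formulas
# (not via the stats:: test functions they are checked against).

# Welch two-sample t: statistic, Welch-Satterthwaite df, two-sided p.
welch_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- sum((x - mean(x))^2) / (nx - 1)
  vy <- sum((y - mean(y))^2) / (ny - 1)
  se2 <- vx / nx + vy / ny
  tstat <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(statistic = tstat, p = 2 * stats::pt(-abs(tstat), df))
}

# Exact Wilcoxon rank-sum by full enumeration of rank assignments
# (feasible for nx + ny <= 12). U = rank sum of x minus nx(nx+1)/2.
wilcox_exact_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  N <- nx + ny
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  sets <- utils::combn(N, nx)
  u_all <- colSums(matrix(seq_len(N)[sets], nrow = nx)) -
    nx * (nx + 1) / 2
  pl <- mean(u_all <= u_obs)
  pg <- mean(u_all >= u_obs)
  list(statistic = u_obs, p = min(1, 2 * min(pl, pg)))
}

# Normal-approximation Wilcoxon with tie correction and continuity
# correction, as defined for large samples.
wilcox_normal_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  N <- nx + ny
  r <- rank(c(x, y))
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- table(r)
  mu <- nx * ny / 2
  sigma2 <- (nx * ny / 12) *
    ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  z <- u - mu
  z <- (z - sign(z) * 0.5) / sqrt(sigma2)
  list(statistic = u, p = min(1, 2 * stats::pnorm(-abs(z))))
}

# Kruskal-Wallis H with tie correction; p from the chi-square tail.
kruskal_oracle <- function(groups) {
  v <- unlist(groups)
  g <- rep(seq_along(groups), lengths(groups))
  N <- length(v)
  r <- rank(v)
  H <- 12 / (N * (N + 1)) *
    sum(tapply(r, g, sum)^2 / lengths(groups)) - 3 * (N + 1)
  ties <- table(v)
  H <- H / (1 - sum(ties^3 - ties) / (N^3 - N))
  list(statistic = H,
       p = stats::pchisq(H, length(groups) - 1, lower.tail = FALSE))
}

# Holm step-down adjustment from its definition.
holm_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- pmin(1, cummax((m - seq_len(m) + 1) * p[o]))
  out <- numeric(m)
  out[o] <- adj
  out
}

# Shapiro-Wilk W and p via Royston's approximation (normal-scores
# weights with polynomial corrections; log-normal / gamma-type null
# transforms for p).
shapiro_oracle <- function(x) {
  x <- sort(x)
  n <- length(x)
  stopifnot(n >= 3)
  if (n == 3) {
    a <- c(sqrt(0.5), 0, -sqrt(0.5))
    W <- sum(a * x)^2 / sum((x - mean(x))^2)
    p <- 6 / pi * (asin(sqrt(W)) - asin(sqrt(0.75)))
    return(list(W = W, p = min(1, max(0, p))))
  }
  m <- stats::qnorm(((1:n) - 0.375) / (n + 0.25))
  ssm <- sum(m^2)
  cvec <- m / sqrt(ssm)
  u <- 1 / sqrt(n)
  a <- cvec
  a[n] <- cvec[n] + 0.221157 * u - 0.147981 * u^2 - 2.071190 * u^3 +
    4.434685 * u^4 - 2.706056 * u^5
  a[1] <- -a[n]
  if (n > 5) {
    a[n - 1] <- cvec[n - 1] + 0.042981 * u - 0.293762 * u^2 -
      1.752461 * u^3 + 5.682633 * u^4 - 3.582633 * u^5
    a[2] <- -a[n - 1]
    phi <- (ssm - 2 * m[n]^2 - 2 * m[n - 1]^2) /
      (1 - 2 * a[n]^2 - 2 * a[n - 1]^2)
    mid <- 3:(n - 2)
  } else {
    phi <- (ssm - 2 * m[n]^2) / (1 - 2 * a[n]^2)
    mid <- 2:(n - 1)
  }
  a[mid] <- m[mid] / sqrt(phi)
  W <- sum(a * x)^2 / sum((x - mean(x))^2)
  if (n >= 12) {
    l <- log(n)
    mu <- -1.5861 - 0.31082 * l - 0.083751 * l^2 + 0.0038915 * l^3
    sig <- exp(-0.4803 - 0.082676 * l + 0.0030302 * l^2)
    z <- (log(1 - W) - mu) / sig
  } else {
    gam <- -2.273 + 0.459 * n
    mu <- 0.5440 - 0.39978 * n + 0.025054 * n^2 - 0.0006714 * n^3
    sig <- exp(1.3822 - 0.77857 * n + 0.062767 * n^2 - 0.0020322 * n^3)
    z <- (-log(gam - log(1 - W)) - mu) / sig
  }
  list(W = W, p = stats::pnorm(z, lower.tail = FALSE))
}
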