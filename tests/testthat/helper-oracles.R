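# Independent oracles used across the suite. Each is a direct, brute-force
# evaluation of the defining formula, kept free of any package internals.

# two-sided Fisher p by full enumeration of margin-preserving 2x2 tables:
# sum the hypergeometric probabilities of all tables no more probable than
# the observed one
fisher_oracle <- function(tab) {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  ks <- lo:hi
  probs <- dhyper(ks, r1, r2, c1)
  p_obs <- dhyper(a, r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# log-rank chi-square by direct risk-set enumeration
logrank_oracle <- function(time, event, group) {
  g <- as.integer(factor(group))
  stopifnot(all(g %in% 1:2))
  ts <- sort(unique(time[event]))
  O1 <- E1 <- V <- 0
  for (t in ts) {
    at_risk <- time >= t
    n <- sum(at_risk); n1 <- sum(at_risk & g == 1)
    d <- sum(event & time == t); d1 <- sum(event & time == t & g == 1)
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O1 - E1)^2 / V
}

# Pearson r and its t-based p straight from the formulas
pearson_oracle <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(t), df = n - 2))
}

# BH step-up applied literally: sort, multiply by m/i, cummin from the top
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}

# smallest sup-distance from the empirical cdf to a unimodal cdf, by
# quadratic programming over piecewise-linear cdfs: for each candidate
# mode knot, slopes must be non-decreasing before it and non-increasing
# after; the chord argument makes this knot enumeration exact for
# distinct data
dip_qp_oracle <- function(x) {
  x <- sort(x); n <- length(x)
  dx <- diff(x)
  best <- Inf
  for (m in 1:n) {
    nv <- n + 1
    A <- NULL; b <- NULL
    add <- function(row, rhs) { A <<- rbind(A, row); b <<- c(b, rhs) }
    for (k in 1:n) {
      r <- numeric(nv); r[k] <- 1; r[nv] <- 1; add(r, k / n)
      r <- numeric(nv); r[k] <- -1; r[nv] <- 1; add(r, -(k - 1) / n)
    }
    for (k in 1:(n - 1)) {
      r <- numeric(nv); r[k] <- -1; r[k + 1] <- 1; add(r, 0)
    }
    r <- numeric(nv); r[1] <- 1; add(r, 0)
    r <- numeric(nv); r[n] <- -1; add(r, -1)
    r <- numeric(nv); r[nv] <- 1; add(r, 0)
    slope_row <- function(k) {
      r <- numeric(nv); r[k] <- -1 / dx[k]; r[k + 1] <- 1 / dx[k]; r
    }
    if (m >= 3) for (k in 1:(m - 2)) add(slope_row(k + 1) - slope_row(k), 0)
    if (m <= n - 2) for (k in m:(n - 2)) add(slope_row(k) - slope_row(k + 1), 0)
    D <- diag(c(rep(1e-9, n), 1))
    sol <- try(quadprog::solve.QP(D, numeric(nv), t(A), b), silent = TRUE)
    if (!inherits(sol, "try-error")) best <- min(best, sol$solution[nv])
  }
  best
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# valid random beta matrix with named dims
rand_beta <- function(n, p, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(runif(n * p, 0.05, 0.95), n, p,
                dimnames = list(sprintf("s%03d", 1:n), sprintf("p%03d", 1:p)))
    m
  })
}
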