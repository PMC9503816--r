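# Independent oracles: each recomputes a quantity by a different route than
# the implementation it checks.

# Richman-Moorman sample entropy by direct template-pair counting.
oracle_sampen <- function(x, m = 2, r = 0.2 * sd(x)) {
  n <- length(x)
  N <- n - m
  count <- function(len) {
    tmpl <- sapply(0:(len - 1), function(k) x[(1 + k):(N + k)])
    cnt <- 0L
    for (i in 1:(N - 1)) {
      for (j in (i + 1):N) {
        if (max(abs(tmpl[i, ] - tmpl[j, ])) <= r) cnt <- cnt + 1L
      }
    }
    cnt
  }
  -log(count(m + 1) / count(m))
}

# ICC(C,k) through an explicit two-way ANOVA fit (stats::aov).
oracle_icc_aov <- function(mat) {
  n <- nrow(mat)
  k <- ncol(mat)
  d <- data.frame(
    y = as.vector(mat),
    subject = factor(rep(seq_len(n), k)),
    rater = factor(rep(seq_len(k), each = n))
  )
  ms <- summary(stats::aov(y ~ subject + rater, data = d))[[1]][["Mean Sq"]]
  (ms[1] - ms[3]) / ms[1]
}

# Exact two-sided rank-sum p-value by full enumeration of group
# assignments, using the same two-sided doubling convention as
# stats::wilcox.test (smaller tail including the point mass, doubled,
# capped at 1).
oracle_ranksum_p <- function(x, y) {
  nx <- length(x)
  ny <- length(y)
  pool <- c(x, y)
  combos <- utils::combn(nx + ny, nx)
  us <- apply(combos, 2, function(idx) {
    sum(outer(pool[idx], pool[-idx], ">"))
  })
  u_obs <- sum(outer(x, y, ">"))
  p <- if (u_obs > nx * ny / 2) mean(us >= u_obs) else mean(us <= u_obs)
  min(2 * p, 1)
}

# Twin-trajectory largest Lyapunov exponent of the Lorenz system: the
# log-distance growth rate of two trajectories started 1e-9 apart,
# measured before saturation. Also returns the x(t) series for the
# Rosenstein estimate under test.
oracle_lorenz <- function(fs = 31.25, duration_s = 120) {
  lorenz <- function(t, y, p) {
    list(c(10 * (y[2] - y[1]), y[1] * (28 - y[3]) - y[2],
           y[1] * y[2] - 8 / 3 * y[3]))
  }
  pre <- deSolve::ode(c(1, 1, 1), seq(0, 30, 0.01), lorenz, NULL,
                      rtol = 1e-10, atol = 1e-10)
  y0 <- pre[nrow(pre), 2:4]
  times <- seq(0, duration_s + 10, by = 1 / fs)
  tr1 <- deSolve::ode(y0, times, lorenz, NULL, rtol = 1e-11, atol = 1e-11)
  tr2 <- deSolve::ode(y0 + c(0, 0, 1e-9), times, lorenz, NULL,
                      rtol = 1e-11, atol = 1e-11)
  d <- sqrt(rowSums((tr1[, 2:4] - tr2[, 2:4])^2))
  use <- d > 1e-8 & d < 0.5 & times > 0.5
  slope <- unname(coef(lm(log(d[use]) ~ times[use]))[2])
  list(lambda = slope, x = tr1[, 2][seq_len(round(duration_s * fs))])
}
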