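# shared fixtures, all generated in code

default_truth <- function(infiltration = 40, ...) {
  subject_truth(infiltration_pct = infiltration, haemoglobin = 120, age = 65,
                ...)
}

# two-phase volume: bright ball (value 1) on dark background (value 0)
bright_ball <- function(n = 24, radius = 7, center = (n + 1) / 2) {
  x <- seq_len(n)
  r2 <- outer(outer((x - center)^2, (x - center)^2, "+"), (x - center)^2, "+")
  array(as.numeric(r2 <= radius^2), c(n, n, n))
}

ball_mask <- function(n = 24, radius = 7, center = (n + 1) / 2) {
  x <- seq_len(n)
  r2 <- outer(outer((x - center)^2, (x - center)^2, "+"), (x - center)^2, "+")
  array(r2 <= radius^2, c(n, n, n))
}

# independent moment oracle: explicit loops, no vectorized shortcuts
naive_histogram_oracle <- function(x) {
  n <- length(x)
  s <- 0
  for (v in x) s <- s + v
  mu <- s / n
  m2 <- m3 <- m4 <- ssq <- 0
  for (v in x) {
    d <- v - mu
    m2 <- m2 + d^2; m3 <- m3 + d^3; m4 <- m4 + d^4
    ssq <- ssq + d^2
  }
  m2 <- m2 / n; m3 <- m3 / n; m4 <- m4 / n
  xs <- sort(x)
  med <- if (n %% 2 == 1) xs[(n + 1) / 2] else (xs[n / 2] + xs[n / 2 + 1]) / 2
  list(mean = mu, median = med, sd = sqrt(ssq / (n - 1)),
       skewness = m3 / m2^1.5, kurtosis = m4 / m2^2 - 3)
}

# independent Wilcoxon oracle: enumerate sign assignments one by one
naive_wilcoxon_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  w_all <- numeric(2^n)
  for (k in seq_len(2^n)) {
    bits <- as.integer(intToBits(k - 1))[seq_len(n)]
    w_all[k] <- sum(r[bits == 1L])
  }
  min(1, 2 * min(mean(w_all <= w_obs + 1e-12), mean(w_all >= w_obs - 1e-12)))
}
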