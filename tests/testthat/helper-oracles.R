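# Independent brute-force oracles: every formula here is evaluated directly
# from its definition (explicit loops, no shared code with the package).

oracle_autocorr <- function(x, lag_max) {
  n <- length(x)
  mx <- mean(x)
  denom <- sum((x - mx)^2)
  vapply(seq_len(lag_max), function(l) {
    s <- 0
    for (t in seq_len(n - l)) s <- s + (x[t] - mx) * (x[t + l] - mx)
    s / denom
  }, numeric(1))
}

# cross-correlation with the acf normalisation: r(k) = C_xy(k) /
# sqrt(C_xx(0) C_yy(0)), C_xy(k) = (1/n) sum_t (x[t+k] - mx)(y[t] - my),
# k = -lag_max..lag_max
oracle_crosscorr <- function(x, y, lag_max) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sxy <- sqrt(sum((x - mx)^2) / n * sum((y - my)^2) / n)
  vapply(-lag_max:lag_max, function(k) {
    s <- 0
    for (t in seq_len(n)) {
      if (t + k >= 1 && t + k <= n) s <- s + (x[t + k] - mx) * (y[t] - my)
    }
    (s / n) / sxy
  }, numeric(1))
}

oracle_skew <- function(x) {
  n <- length(x); m <- mean(x)
  m2 <- sum((x - m)^2) / n; m3 <- sum((x - m)^3) / n
  m3 / m2^1.5
}

oracle_kurt <- function(x) {
  n <- length(x); m <- mean(x)
  m2 <- sum((x - m)^2) / n; m4 <- sum((x - m)^4) / n
  m4 / m2^2 - 3
}

oracle_dtw <- function(a, b) {
  n <- length(a); m <- length(b)
  D <- matrix(Inf, n + 1, m + 1)
  D[1, 1] <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      D[i + 1, j + 1] <- abs(a[i] - b[j]) +
        min(D[i, j + 1], D[i + 1, j], D[i, j])
    }
  }
  D[n + 1, m + 1]
}

oracle_hurst <- function(x) {
  n <- length(x)
  sizes <- unique(round(exp(seq(log(8), log(floor(n / 2)), length.out = 6))))
  rs <- sapply(sizes, function(s) {
    vals <- c()
    for (b in seq_len(n %/% s)) {
      xb <- x[((b - 1) * s + 1):(b * s)]
      if (sd(xb) == 0) next
      y <- cumsum(xb - mean(xb))
      vals <- c(vals, (max(y) - min(y)) / sd(xb))
    }
    mean(vals)
  })
  as.numeric(coef(lm(log(rs) ~ log(sizes)))[2])
}

# explicit DFT of one tapered frame
oracle_dft_mag <- function(frame, w) {
  n <- length(frame)
  v <- frame * w
  vapply(0:(n - 1), function(k) {
    Mod(sum(v * exp(-2i * pi * k * (0:(n - 1)) / n)))
  }, numeric(1))
}

oracle_entropy <- function(p) {
  p <- p / sum(p)
  p <- p[p > 0]
  -sum(p * log(p))
}

# one-way ANOVA F through stats::aov
oracle_f_stat <- function(col, y) {
  summary(aov(col ~ factor(y)))[[1]]$`F value`[1]
}

# pairwise label counter
oracle_confusion <- function(truth, pred, classes) {
  m <- matrix(0L, length(classes), length(classes),
              dimnames = list(classes, classes))
  for (i in seq_along(truth)) {
    m[truth[i], pred[i]] <- m[truth[i], pred[i]] + 1L
  }
  m
}

# two-step decision table
oracle_two_step <- function(p1, p2) {
  if (p1 >= 0.5) "acceptable" else if (p2 >= 0.5) "unacceptable" else "uncertain"
}
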