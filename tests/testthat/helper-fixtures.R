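# Shared fixture builders; everything is generated in code at test time.

# A random (x, y) pair with ties and both labels present.
random_series <- function(n, round_digits = sample(0:2, 1)) {
  x <- round(stats::rnorm(n), round_digits)
  y <- stats::rbinom(n, 1, 0.5)
  if (length(unique(y)) < 2L) y[1L] <- 1L - y[1L]
  list(x = x, y = y)
}

# Hand-computed Pearson correlation, independent of stats::cor.
pearson_by_hand <- function(x, y) {
  n <- length(x)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  sxy / sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# Textbook Welch statistic and Welch-Satterthwaite p, independent of t.test.
welch_by_hand <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- stats::var(a) / na; vb <- stats::var(b) / nb
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (na - 1) + vb^2 / (nb - 1))
  list(t = t, p = 2 * stats::pt(-abs(t), df))
}

# Small hand-written expression matrix with tidy values for exact round trips.
tiny_matrix <- function() {
  m <- rbind(A1BG = c(8.25, 7.5, 9, 8),
             TP53 = c(10, 10.5, 2.25, 3),
             GAPDH = c(12, 12, 12.75, 11.5))
  colnames(m) <- c("S1-T", "S1-N", "S2-T", "S2-N")
  m
}
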