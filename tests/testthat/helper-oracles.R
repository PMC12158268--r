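## Independent oracles used across the suite. These deliberately avoid the
## package's own code paths.

chans12 <- c("R", "G", "B", "L", "a", "b", "H", "S", "V", "Y", "Cb", "Cr")

## Closed-form logistic slope; returns the first 1-based frame index (on the
## 0-based time grid t = 0, 1, ..., n-1 s) after the slope peak at which
## |slope| drops below `threshold` and stays there.
logistic_settle_frame <- function(amplitude, rate, midpoint, threshold,
                                  n_frames) {
  t <- seq_len(n_frames) - 1
  s <- 1 / (1 + exp(-rate * (t - midpoint)))
  slope <- abs(amplitude) * rate * s * (1 - s)
  i <- which(slope < threshold & t > midpoint)[1]
  i # already a 1-based frame index because t = frame - 1
}

## Term-by-term evaluation of the published response surface, written as an
## explicit sum of separately computed terms.
eq2_by_terms <- function(x1, x2) {
  terms <- c(
    4.34e4 * x2,
    -123 * x1,
    -152 * log(x1 + x2 + log(x2) + x2^2),
    1300 * log(x1),
    -668 * log(x2),
    -4.17e4 * x1 * x2^2,
    96.6 * x1^2 * x2,
    -4740
  )
  sum(terms)
}

## Brute-force multiclass ReliefF with plain loops and manual neighbor search.
brute_relieff <- function(X, y, k) {
  y <- factor(y)
  n <- nrow(X); p <- ncol(X)
  rng <- numeric(p)
  Z <- matrix(0, n, p)
  for (j in 1:p) {
    rng[j] <- max(X[, j]) - min(X[, j])
    if (rng[j] > 0) Z[, j] <- (X[, j] - min(X[, j])) / rng[j]
  }
  priors <- table(y) / n
  W <- numeric(p)
  for (i in 1:n) {
    d <- numeric(n)
    for (q in 1:n) d[q] <- sum(abs(Z[q, ] - Z[i, ]))
    d[i] <- Inf
    own <- as.character(y[i])
    for (cl in levels(y)) {
      members <- which(y == cl)
      nn <- members[order(d[members])][1:k]
      contrib <- numeric(p)
      for (m in nn) contrib <- contrib + abs(Z[i, ] - Z[m, ])
      if (cl == own) {
        W <- W - contrib / (n * k)
      } else {
        W <- W + (priors[[cl]] / (1 - priors[[own]])) * contrib / (n * k)
      }
    }
  }
  W
}

## Two-way balanced ANOVA sums of squares by direct mean decomposition.
anova_ss_oracle <- function(y, A, B) {
  A <- factor(A); B <- factor(B)
  grand <- mean(y)
  ss_a <- 0; ss_b <- 0; ss_ab <- 0; ss_w <- 0
  for (ai in levels(A)) {
    ss_a <- ss_a + sum(A == ai) * (mean(y[A == ai]) - grand)^2
  }
  for (bj in levels(B)) {
    ss_b <- ss_b + sum(B == bj) * (mean(y[B == bj]) - grand)^2
  }
  for (ai in levels(A)) {
    for (bj in levels(B)) {
      sel <- A == ai & B == bj
      cell <- mean(y[sel])
      ss_ab <- ss_ab + sum(sel) *
        (cell - mean(y[A == ai]) - mean(y[B == bj]) + grand)^2
      ss_w <- ss_w + sum((y[sel] - cell)^2)
    }
  }
  list(ss_a = ss_a, ss_b = ss_b, ss_ab = ss_ab, ss_w = ss_w,
       ss_t = sum((y - grand)^2))
}

## A Sylvester-construction Hadamard matrix of order 16: its +/-1 columns are
## exactly orthogonal, so dropping the all-ones column leaves 12+ features
## whose sample correlation matrix is exactly the identity.
hadamard16 <- function() {
  h <- matrix(1)
  for (i in 1:4) h <- rbind(cbind(h, h), cbind(h, -h))
  h
}
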