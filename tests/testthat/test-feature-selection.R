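test_that("correlation PCA satisfies trace and reconstruction identities", {
  tab <- generate_feature_table(n_series_per_ph = 2, seed = 3)
  pca <- pca_correlation(tab)
  expect_equal(sum(pca$eigenvalues), 12, tolerance = 1e-8)
  expect_true(all(diff(pca$eigenvalues) <= 1e-12))
  expect_true(all(pca$eigenvalues > -1e-10))
  ## unit-norm loadings and correlation-matrix reconstruction
  expect_equal(unname(colSums(pca$loadings^2)), rep(1, 12), tolerance = 1e-10)
  C <- stats::cor(as.matrix(tab[, chans12]))
  recon <- pca$loadings %*% diag(pca$eigenvalues) %*% t(pca$loadings)
  expect_equal(unname(recon), unname(C), tolerance = 1e-8)
  ## sign convention
  for (j in 1:12) {
    expect_gt(pca$loadings[which.max(abs(pca$loadings[, j])), j], 0)
  }
})

test_that("an exactly orthogonal design has all unit eigenvalues, none retained", {
  H <- hadamard16()
  tab <- as.data.frame(H[, 2:13])
  names(tab) <- chans12
  pca <- pca_correlation(tab)
  expect_equal(pca$eigenvalues, rep(1, 12))
  expect_equal(pca$retained, 0) # strict eigenvalue > 1 rule
})

test_that("three planted latent factors are retained under the Kaiser rule", {
  set.seed(21)
  n <- 600
  f <- matrix(rnorm(3 * n), n, 3)
  X <- cbind(
    f[, 1] + matrix(rnorm(4 * n, sd = 0.3), n, 4),
    f[, 2] + matrix(rnorm(4 * n, sd = 0.3), n, 4),
    f[, 3] + matrix(rnorm(4 * n, sd = 0.3), n, 4)
  )
  tab <- as.data.frame(X)
  names(tab) <- chans12
  pca <- pca_correlation(tab)
  expect_equal(pca$retained, 3)
  ## independent eigen-solver (SVD route) agrees on the retained count
  sv <- svd(scale(X))$d
  ev <- sv^2 / (n - 1)
  expect_equal(sum(ev > 1), 3)
  expect_equal(pca$eigenvalues, ev, tolerance = 1e-8)
})

test_that("constant columns are reported by name", {
  tab <- generate_feature_table(n_series_per_ph = 1, seed = 2)
  tab$Cb <- 0.5
  expect_error(pca_correlation(tab), "Cb",
               class = "halochrom_validation_error")
})

test_that("relieff agrees with a brute-force oracle and honors conventions", {
  set.seed(7)
  n <- 120
  y <- rep(1:3, each = n / 3)
  X <- matrix(runif(n * 5), n, 5)
  X[, 2] <- as.numeric(y == 2) + rnorm(n, sd = 0.05) # class-determining
  X[, 4] <- 0.7                                      # constant
  tab <- as.data.frame(X)
  names(tab) <- c("f1", "f2", "f3", "f4", "f5")
  tab$ph <- y

  w <- relieff(tab, k = 5)
  expect_equal(w$weight, unname(brute_relieff(X, y, k = 5)), tolerance = 1e-12)
  expect_equal(w$channel[which.max(w$weight)], "f2")
  expect_equal(w$weight[w$channel == "f4"], 0)
  expect_true(all(abs(w$weight) <= 1))
})

test_that("a class indicator dominates noise features at the stated size", {
  set.seed(31)
  n <- 500
  y <- sample(rep(1:5, each = n / 5))
  X <- matrix(runif(n * 12), n, 12)
  X[, 7] <- as.numeric(y) / 5 + rnorm(n, sd = 0.02)
  tab <- as.data.frame(X)
  names(tab) <- chans12
  tab$ph <- y
  w <- relieff(tab, k = 10)
  expect_equal(rank_features(w, 1), "H") # column 7 is H in canonical order
})

test_that("pure-noise features receive near-zero weights across seeds", {
  worst <- 0
  for (seed in 1:10) {
    set.seed(seed)
    n <- 500
    y <- rep(1:5, each = n / 5)
    tab <- as.data.frame(matrix(runif(n * 4), n, 4))
    names(tab) <- c("n1", "n2", "n3", "n4")
    tab$ph <- y
    w <- relieff(tab, k = 10)
    worst <- max(worst, max(abs(w$weight)))
  }
  expect_lt(worst, 0.05)
})

test_that("relieff weights are invariant to affine rescaling of a feature", {
  tab <- generate_feature_table(n_series_per_ph = 1, frame_stride = 20,
                                seed = 9)
  w0 <- relieff(tab, k = 8)
  tab$a <- 40 * tab$a - 7
  tab$S <- -3 * tab$S + 2 # sign flip also preserves normalized distances
  w1 <- relieff(tab, k = 8)
  expect_equal(w1$weight, w0$weight, tolerance = 1e-10)
})

test_that("relieff validates class sizes and is reproducible", {
  tab <- data.frame(x = runif(12), ph = rep(1:2, c(9, 3)))
  expect_error(relieff(tab, k = 5), class = "halochrom_validation_error")

  tab2 <- generate_feature_table(n_series_per_ph = 1, frame_stride = 30,
                                 seed = 5)
  expect_identical(relieff(tab2, k = 5, n_iter = 40, seed = 2),
                   relieff(tab2, k = 5, n_iter = 40, seed = 2))
})

test_that("rank_features orders by weight with canonical tie-breaking", {
  w <- tibble::tibble(
    channel = chans12,
    weight = c(0, 0, 0, 0, 0.1, 0, 0.3, 0.2, 0, 0, 0, 0)
  )
  expect_equal(rank_features(w, 3), c("H", "S", "a"))

  ties <- tibble::tibble(channel = rev(chans12), weight = rep(0.5, 12))
  expect_equal(rank_features(ties, 12), chans12)
  expect_error(rank_features(w, 13), class = "halochrom_validation_error")
})
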