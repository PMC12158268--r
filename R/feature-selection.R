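#' Correlation-matrix PCA with the Kaiser retention criterion
#'
#' Eigendecomposition of the Pearson correlation matrix of the color-channel
#' features. Components with eigenvalue strictly greater than 1 are retained
#' (Kaiser criterion, the natural reference for correlation-matrix PCA where
#' every standardized feature contributes unit variance). Loadings are
#' unit-norm eigenvectors with the sign convention that the largest-magnitude
#' element of each column is positive.
#'
#' @param table A data frame of observations; all numeric columns except
#'   `ph`/`label` columns are treated as features.
#' @return A `channel_pca` object with `eigenvalues` (descending), `loadings`
#'   (features x components), `retained`, and `n` (observations). Errors,
#'   naming the column, if any feature is constant (its correlation is
#'   undefined).
#' @examples
#' tab <- generate_feature_table(n_series_per_ph = 2, seed = 1)
#' pca <- pca_correlation(tab)
#' tidy(pca)
#' @export
pca_correlation <- function(table) {
  X <- feature_matrix(table)
  if (nrow(X) < 2L) {
    abort("need at least 2 rows", class = "halochrom_validation_error")
  }
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    abort(sprintf("constant column `%s`: correlation undefined",
                  colnames(X)[which(sds == 0)[1]]),
          class = "halochrom_validation_error")
  }
  C <- stats::cor(X)
  e <- eigen(C, symmetric = TRUE)
  load <- e$vectors
  ## sign convention: largest-magnitude loading in each component positive
  for (j in seq_len(ncol(load))) {
    k <- which.max(abs(load[, j]))
    if (load[k, j] < 0) load[, j] <- -load[, j]
  }
  dimnames(load) <- list(colnames(X), paste0("PC", seq_len(ncol(load))))
  structure(
    list(eigenvalues = e$values, loadings = load,
         retained = sum(e$values > 1), n = nrow(X)),
    class = "channel_pca"
  )
}

feature_matrix <- function(table, drop = c("ph", "label", "class", "sample_id",
                                           "frame", "t_s", "replicate")) {
  df <- as.data.frame(table)
  df <- df[, setdiff(names(df), drop), drop = FALSE]
  num <- vapply(df, is.numeric, logical(1))
  X <- as.matrix(df[, num, drop = FALSE])
  if (anyNA(X)) {
    abort("feature table contains missing values",
          class = "halochrom_validation_error")
  }
  X
}

#' @export
print.channel_pca <- function(x, ...) {
  cat(sprintf("<channel_pca: %d features, %d observations, %d retained (Kaiser)>\n",
              length(x$eigenvalues), x$n, x$retained))
  cat("eigenvalues:", paste(signif(x$eigenvalues, 4), collapse = " "), "\n")
  invisible(x)
}

#' @export
tidy.channel_pca <- function(x, ...) {
  p <- length(x$eigenvalues)
  tibble(
    component = paste0("PC", seq_len(p)),
    eigenvalue = x$eigenvalues,
    prop_variance = x$eigenvalues / sum(x$eigenvalues),
    cum_variance = cumsum(x$eigenvalues) / sum(x$eigenvalues),
    retained = seq_len(p) <= x$retained
  )
}

#' @export
glance.channel_pca <- function(x, ...) {
  tibble(n_features = length(x$eigenvalues), n_obs = x$n,
         retained = x$retained,
         var_explained_retained = sum(x$eigenvalues[seq_len(x$retained)]) /
           sum(x$eigenvalues))
}

#' Multiclass ReliefF feature weights
#'
#' Instance-based feature weighting (the Kononenko multiclass extension). For
#' each sampled instance the `k` nearest hits (same class) and, for every other
#' class, the `k` nearest misses are located by Manhattan distance on
#' range-normalized features. Each feature's weight is decreased by the mean
#' hit difference and increased by the prior-weighted mean miss difference,
#' scaled by `1 / (n_iter * k)`; weights are bounded in `[-1, 1]` by
#' construction. A constant feature has zero range and, by convention,
#' contributes zero difference — its weight is exactly 0.
#'
#' @param table Data frame with feature columns and a class column.
#' @param class_col Name of the class column (default `"ph"`).
#' @param k Number of neighbors (default 10). Every class must have more than
#'   `k` members.
#' @param n_iter Number of sampled instances; default (`NULL`) uses every row
#'   once, which makes the result independent of `seed`.
#' @param seed Seed used only when `n_iter` is smaller than the number of rows.
#' @return A `relief_weights` tibble: `channel`, `weight`.
#' @export
relieff <- function(table, class_col = "ph", k = 10, n_iter = NULL, seed = 1L) {
  check_number(k, "k", min = 1, integer = TRUE)
  if (!class_col %in% names(table)) {
    abort(sprintf("class column `%s` not found", class_col),
          class = "halochrom_validation_error")
  }
  y <- factor(table[[class_col]])
  X <- feature_matrix(table)
  n <- nrow(X); p <- ncol(X)
  counts <- table(y)
  if (length(counts) < 2L) {
    abort("need at least 2 classes", class = "halochrom_validation_error")
  }
  if (any(counts <= k)) {
    abort(sprintf("class `%s` has <= k members", names(counts)[counts <= k][1]),
          class = "halochrom_validation_error")
  }
  rng <- apply(X, 2, function(v) diff(range(v)))
  Z <- X
  for (j in seq_len(p)) {
    Z[, j] <- if (rng[j] == 0) 0 else (X[, j] - min(X[, j])) / rng[j]
  }
  priors <- as.numeric(counts) / n
  names(priors) <- names(counts)

  if (is.null(n_iter)) {
    idx <- seq_len(n)
  } else {
    check_number(n_iter, "n_iter", min = 1, integer = TRUE)
    set.seed(seed)
    idx <- sample.int(n, min(n_iter, n))
  }
  m <- length(idx)
  W <- numeric(p)
  cls_levels <- levels(y)
  for (i in idx) {
    d <- rowSums(abs(sweep(Z, 2, Z[i, ], `-`)))
    d[i] <- Inf
    own <- as.character(y[i])
    hits <- which(y == own)
    hits <- hits[order(d[hits])][seq_len(k)]
    W <- W - colSums(abs(sweep(Z[hits, , drop = FALSE], 2, Z[i, ], `-`))) / (m * k)
    for (cl in setdiff(cls_levels, own)) {
      miss <- which(y == cl)
      miss <- miss[order(d[miss])][seq_len(k)]
      w_cl <- priors[[cl]] / (1 - priors[[own]])
      W <- W + w_cl *
        colSums(abs(sweep(Z[miss, , drop = FALSE], 2, Z[i, ], `-`))) / (m * k)
    }
  }
  structure(
    tibble(channel = colnames(X), weight = unname(W)),
    class = c("relief_weights", class(tibble())),
    k = k, n_iter = m
  )
}

#' Rank features by ReliefF weight
#'
#' @param weights A `relief_weights` tibble (or any tibble with `channel` and
#'   `weight`).
#' @param top_n How many channels to return. Ties are broken by the canonical
#'   channel order `R, G, B, L, a, b, H, S, V, Y, Cb, Cr` (then by input
#'   order for non-canonical feature names).
#' @return Character vector of channel names, best first.
#' @export
rank_features <- function(weights, top_n = 3) {
  check_number(top_n, "top_n", min = 1, integer = TRUE)
  if (top_n > nrow(weights)) {
    abort("`top_n` exceeds the number of features",
          class = "halochrom_validation_error")
  }
  canon <- match(weights$channel, CHANNELS)
  canon[is.na(canon)] <- length(CHANNELS) + seq_len(sum(is.na(canon)))
  ord <- order(-weights$weight, canon)
  weights$channel[ord][seq_len(top_n)]
}

#' Build a labeled feature table from synthetic kinetics
#'
#' Generates kinetics series for each pH level with the built-in presets and
#' collects sub-sampled frames into an observations-by-channels table labeled
#' by pH — the input shape expected by [pca_correlation()] and [relieff()].
#'
#' @param ph_levels pH classes (default 6-10).
#' @param n_series_per_ph Replicate series per pH (default 3).
#' @param frame_stride Keep every `frame_stride`-th frame (default 10).
#' @param noise_sd Channel noise SD passed to the kinetics generator.
#' @param seed Integer seed.
#' @return A tibble with the 12 channel columns plus `ph`.
#' @export
generate_feature_table <- function(ph_levels = 6:10, n_series_per_ph = 3,
                                   frame_stride = 10, noise_sd = 5e-4,
                                   seed = 1L) {
  seeds <- derive_seeds(seed, length(ph_levels) * n_series_per_ph)
  i <- 0L
  purrr::map_dfr(ph_levels, function(ph) {
    purrr::map_dfr(seq_len(n_series_per_ph), function(r) {
      i <<- i + 1L
      ts <- generate_color_kinetics(default_kinetics(ph, noise_sd = noise_sd),
                                    seed = seeds[i], ph = ph)
      rows <- ts[seq(1, nrow(ts), by = frame_stride), CHANNELS]
      dplyr::mutate(as_tibble(rows), ph = ph)
    })
  })
}
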