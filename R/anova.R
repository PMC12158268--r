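#' Balanced two-factor ANOVA with replication
#'
#' Decomposes the response-time variance into PEG main effect, BTB main
#' effect, their interaction, and within-cell (replicate) variation, using the
#' classical balanced-design sums-of-squares formulas. The design must be
#' fully balanced (equal replicate counts in every factor-A x factor-B cell,
#' at least 2 per cell). P-values are upper-tail F probabilities; critical
#' values are the `1 - alpha` F quantiles.
#'
#' @param data Tibble of records.
#' @param response,factor_a,factor_b Column names (defaults match the
#'   formulation dataset: `response_time_s` on `peg_pct` x `btb_pct`).
#' @param alpha Significance level (default 0.05).
#' @return An `anova_two_way` tibble with columns `source`, `sum_sq`, `df`,
#'   `mean_sq`, `statistic`, `p_value`, `f_critical` and rows for factor A,
#'   factor B, the interaction, within, and total. With zero within-cell
#'   variance the F statistics are undefined (`NaN`) and a warning is issued.
#' @examples
#' dat <- generate_formulation_dataset(seed = 1)
#' two_factor_anova(dat)
#' @export
two_factor_anova <- function(data, response = "response_time_s",
                             factor_a = "peg_pct", factor_b = "btb_pct",
                             alpha = 0.05) {
  check_number(alpha, "alpha", min = 0, max = 1, strict_min = TRUE,
               strict_max = TRUE)
  for (col in c(response, factor_a, factor_b)) {
    if (!col %in% names(data)) {
      abort(sprintf("column `%s` not found", col),
            class = "halochrom_validation_error")
    }
  }
  y <- data[[response]]
  A <- factor(data[[factor_a]])
  B <- factor(data[[factor_b]])
  if (anyNA(y)) {
    abort("response contains missing values", class = "halochrom_validation_error")
  }
  counts <- table(A, B)
  if (length(unique(as.vector(counts))) != 1L || counts[1] < 2L) {
    abort("design must be balanced with at least 2 replicates per cell",
          class = "halochrom_validation_error")
  }
  a <- nlevels(A); b <- nlevels(B); n <- as.vector(counts[1])
  N <- length(y)

  grand <- mean(y)
  mean_a <- tapply(y, A, mean)
  mean_b <- tapply(y, B, mean)
  mean_cell <- tapply(y, list(A, B), mean)

  ss_a <- b * n * sum((mean_a - grand)^2)
  ss_b <- a * n * sum((mean_b - grand)^2)
  ss_ab <- n * sum((sweep(sweep(mean_cell, 1, mean_a, `-`), 2, mean_b, `-`) +
                      grand)^2)
  cell_of <- mean_cell[cbind(as.integer(A), as.integer(B))]
  ss_w <- sum((y - cell_of)^2)
  ss_t <- sum((y - grand)^2)

  df_a <- a - 1L; df_b <- b - 1L; df_ab <- df_a * df_b
  df_w <- N - a * b; df_t <- N - 1L

  if (ss_w == 0) {
    warn("zero within-cell variance: F statistics are undefined")
  }
  complete_anova_table(
    ss = c(ss_a, ss_b, ss_ab, ss_w),
    df = c(df_a, df_b, df_ab, df_w),
    sources = c(factor_a, factor_b, "Interaction", "Within"),
    alpha = alpha
  )
}

#' Complete an ANOVA table from sums of squares and degrees of freedom
#'
#' Fills in the deterministic part of a two-factor ANOVA table: mean squares
#' (`SS/df`), F statistics (`MS/MS_within`), upper-tail p-values and critical
#' F values at `alpha`, plus a total row.
#'
#' @param ss,df Numeric vectors of per-source sums of squares and degrees of
#'   freedom. The last element (or the element named/labelled `"Within"`) is
#'   the within (error) source, which must be present.
#' @param sources Source labels; must include `"Within"`.
#' @param alpha Significance level.
#' @return An `anova_two_way` tibble (see [two_factor_anova()]).
#' @examples
#' complete_anova_table(
#'   ss = c(13619.34, 123344.60, 40259.54, 2401405.26),
#'   df = c(2, 2, 4, 171),
#'   sources = c("PEG", "BTB", "Interaction", "Within")
#' )
#' @export
complete_anova_table <- function(ss, df,
                                 sources = c("A", "B", "Interaction", "Within"),
                                 alpha = 0.05) {
  check_number(alpha, "alpha", min = 0, max = 1, strict_min = TRUE,
               strict_max = TRUE)
  if (length(ss) != length(df) || length(ss) != length(sources)) {
    abort("`ss`, `df` and `sources` must have equal length",
          class = "halochrom_validation_error")
  }
  if (!"Within" %in% sources) {
    abort("a `Within` source is required", class = "halochrom_validation_error")
  }
  if (any(df <= 0) || any(ss < 0)) {
    abort("`df` must be positive and `ss` non-negative",
          class = "halochrom_validation_error")
  }
  wi <- match("Within", sources)
  ms <- ss / df
  ms_w <- ms[wi]
  eff <- seq_along(ss) != wi
  statistic <- rep(NA_real_, length(ss))
  p_value <- rep(NA_real_, length(ss))
  f_crit <- rep(NA_real_, length(ss))
  statistic[eff] <- ms[eff] / ms_w
  p_value[eff] <- pf(statistic[eff], df[eff], df[wi], lower.tail = FALSE)
  f_crit[eff] <- vapply(df[eff], function(d1) f_critical(alpha, d1, df[wi]),
                        numeric(1))
  out <- tibble(
    source = c(sources, "Total"),
    sum_sq = c(ss, sum(ss)),
    df = c(df, sum(df)),
    mean_sq = c(ms, NA_real_),
    statistic = c(statistic, NA_real_),
    p_value = c(p_value, NA_real_),
    f_critical = c(f_crit, NA_real_)
  )
  structure(out, alpha = alpha,
            class = c("anova_two_way", class(tibble())))
}

#' Critical value of the F distribution
#'
#' The `1 - alpha` quantile of the F distribution with `df1` and `df2`
#' degrees of freedom — the threshold an observed F statistic must exceed to
#' be significant at level `alpha`.
#'
#' @param alpha Significance level in (0, 1).
#' @param df1,df2 Degrees of freedom (numerator, denominator), both >= 1.
#' @examples
#' f_critical(0.05, 2, 171) # 3.05 at 2 decimals
#' @export
f_critical <- function(alpha, df1, df2) {
  check_number(alpha, "alpha", min = 0, max = 1, strict_min = TRUE,
               strict_max = TRUE)
  check_number(df1, "df1", min = 1)
  check_number(df2, "df2", min = 1)
  qf(1 - alpha, df1, df2)
}

#' @export
print.anova_two_way <- function(x, ...) {
  cat(sprintf("Two-factor ANOVA with replication (alpha = %g)\n",
              attr(x, "alpha")))
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, 2)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
tidy.anova_two_way <- function(x, ...) {
  as_tibble(x)
}

#' @export
glance.anova_two_way <- function(x, ...) {
  eff <- !x$source %in% c("Within", "Total")
  tibble(
    n_sources = sum(eff),
    df_within = x$df[x$source == "Within"],
    ms_within = x$mean_sq[x$source == "Within"],
    alpha = attr(x, "alpha"),
    n_significant = sum(x$p_value[eff] < attr(x, "alpha"), na.rm = TRUE)
  )
}
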