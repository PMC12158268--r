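## Internal helpers shared across modules.

check_number <- function(x, field, min = -Inf, max = Inf, strict_min = FALSE,
                         strict_max = FALSE, integer = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (strict_min) x > min else x >= min) &&
    (if (strict_max) x < max else x <= max) &&
    (!integer || x == round(x))
  if (!ok) {
    abort(sprintf("invalid value for field `%s`", field),
          class = "halochrom_validation_error")
  }
  invisible(x)
}

## Centered moving average with partial windows at the edges (movmean-style),
## so the output has the same length as the input.
movmean <- function(x, window) {
  n <- length(x)
  if (window <= 1L) return(x)
  half_lo <- floor((window - 1) / 2)
  half_hi <- ceiling((window - 1) / 2)
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(i - half_lo, 1L)
  hi <- pmin(i + half_hi, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

## First start index of a run of >= len consecutive TRUEs, or NA.
first_run_start <- function(flag, len) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- which(r$values & r$lengths >= len)
  if (length(hit) == 0L) return(NA_integer_)
  starts[hit[1L]]
}

## Seeds must stay below 2^31 - 1 (R integers are 32-bit).
derive_seeds <- function(master_seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(master_seed)
  sample.int(.Machine$integer.max - 1L, n)
}
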