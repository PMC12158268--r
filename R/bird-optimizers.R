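#' Published response-surface fitness function
#'
#' The closed-form fitness function relating PEG concentration `x1` (% w/v)
#' and BTB concentration `x2` (% w/v) to the predicted color-transition time:
#'
#' \deqn{y = 4.34\times10^{4} x_2 - 123 x_1
#'   - 152\,\ln(x_1 + x_2 + \ln x_2 + x_2^2) + 1300\,\ln x_1 - 668\,\ln x_2
#'   - 4.17\times10^{4} x_1 x_2^2 + 96.6\, x_1^2 x_2 - 4740}
#'
#' All logarithms are natural. The grouping of the third term was
#' disambiguated numerically: this reading reproduces the published optimum
#' value at the published minimizer to the printed precision, whereas the
#' alternative grouping does not.
#'
#' @param x1 PEG concentration in `[6, 10]` (% w/v); vectorized.
#' @param x2 BTB concentration in `[0.01, 0.05]` (% w/v); vectorized.
#' @return Predicted transition time (fitness units, seconds-scale).
#' @examples
#' fitness_eq2(6, 0.020148)
#' @export
fitness_eq2 <- function(x1, x2) {
  if (!is.numeric(x1) || !is.numeric(x2) || anyNA(x1) || anyNA(x2)) {
    abort("`x1` and `x2` must be numeric", class = "halochrom_validation_error")
  }
  if (any(x1 < 6 - 1e-12) || any(x1 > 10 + 1e-12)) {
    abort("`x1` (PEG) must lie in [6, 10]", class = "halochrom_domain_error")
  }
  if (any(x2 < 0.01 - 1e-12) || any(x2 > 0.05 + 1e-12)) {
    abort("`x2` (BTB) must lie in [0.01, 0.05]", class = "halochrom_domain_error")
  }
  inner <- x1 + x2 + log(x2) + x2^2
  if (any(inner <= 0)) {
    abort("non-positive composite log argument", class = "halochrom_domain_error")
  }
  4.34e4 * x2 - 123 * x1 - 152 * log(inner) + 1300 * log(x1) -
    668 * log(x2) - 4.17e4 * x1 * x2^2 + 96.6 * x1^2 * x2 - 4740
}

#' Construct a bounded objective function
#'
#' @param fn Function of a numeric vector `x` returning a scalar.
#' @param lower,upper Numeric bound vectors of equal length.
#' @param name Objective label.
#' @param fn_vec Optional vectorized form taking an n x d matrix and returning
#'   n values (used by [grid_refine_minimize()] for speed).
#' @export
objective_function <- function(fn, lower, upper, name = "objective",
                               fn_vec = NULL) {
  if (length(lower) != length(upper) || any(lower >= upper)) {
    abort("invalid bounds", class = "halochrom_validation_error")
  }
  structure(list(fn = fn, lower = lower, upper = upper, name = name,
                 fn_vec = fn_vec),
            class = "objective_function")
}

#' The published fitness surface as a bounded objective
#'
#' [fitness_eq2()] over PEG in `[6, 10]` and BTB in `[0.01, 0.05]`.
#' @export
eq2_objective <- function() {
  objective_function(
    fn = function(x) fitness_eq2(x[1], x[2]),
    fn_vec = function(X) fitness_eq2(X[, 1], X[, 2]),
    lower = c(6, 0.01), upper = c(10, 0.05), name = "eq2"
  )
}

#' Wrap a fitted GP model as a bounded objective
#'
#' @param model A `gp_model`.
#' @param lower,upper Bounds (defaults: the formulation design domain).
#' @export
gp_objective <- function(model, lower = c(6, 0.01), upper = c(10, 0.05)) {
  objective_function(
    fn = function(x) predict(model, tibble(x1 = x[1], x2 = x[2])),
    fn_vec = function(X) predict(model, tibble(x1 = X[, 1], x2 = X[, 2])),
    lower = lower, upper = upper, name = "gp_model"
  )
}

clamp_or_reflect <- function(X, lower, upper, boundary) {
  for (j in seq_len(ncol(X))) {
    if (boundary == "reflect") {
      span <- upper[j] - lower[j]
      v <- (X[, j] - lower[j]) %% (2 * span)
      X[, j] <- lower[j] + ifelse(v > span, 2 * span - v, v)
    } else {
      X[, j] <- pmin(pmax(X[, j], lower[j]), upper[j])
    }
  }
  X
}

## Levy flight steps (beta = 1.5), the heavy-tailed exploration move used by
## the parrot and secretary-bird updates.
levy_step <- function(n, beta = 1.5) {
  num <- gamma(1 + beta) * sin(pi * beta / 2)
  den <- gamma((1 + beta) / 2) * beta * 2^((beta - 1) / 2)
  sigma_u <- (num / den)^(1 / beta)
  u <- rnorm(n, 0, sigma_u)
  v <- rnorm(n)
  u / abs(v)^(1 / beta)
}

#' Minimize a bounded objective with a bird-inspired metaheuristic
#'
#' Runs one of three population-based stochastic minimizers:
#' \describe{
#'   \item{`"po"` (Parrot Optimizer)}{each individual performs one of four
#'     behaviours per iteration, chosen uniformly at random: foraging (move
#'     relative to the best position and the flock mean with Levy steps),
#'     staying (perch near the best position), communicating (move toward or
#'     away from the flock mean), and fear of strangers (flight re-orienting
#'     toward the best position).}
#'   \item{`"poa"` (Pelican Optimization Algorithm)}{two phases per iteration:
#'     moving toward randomly located prey (exploration; the move direction
#'     flips if the prey is worse than the pelican) and winging on the water
#'     surface (exploitation in a shrinking neighbourhood of radius
#'     `0.2 * (1 - t/T)`).}
#'   \item{`"sboa"` (Secretary Bird Optimization Algorithm)}{a hunting phase
#'     whose move switches with iteration progress from differential search
#'     between random members, to normally perturbed moves around the best, to
#'     Levy-flight refinement of the best; and an escape phase mixing
#'     camouflage-style local moves around the best with flights relative to
#'     random members.}
#' }
#' All candidates are kept within bounds (clamped by default) and accepted
#' greedily, so the best-so-far curve is non-increasing; identical seeds give
#' identical runs.
#'
#' @param objective An [objective_function()].
#' @param algorithm One of `"po"`, `"poa"`, `"sboa"`.
#' @param pop_size Population size (default 30).
#' @param iterations Iteration count (default 100).
#' @param seed Integer seed.
#' @param boundary Out-of-bounds handling, `"clamp"` (default) or `"reflect"`.
#' @return A `bird_opt` result: `algorithm`, `best_x`, `best_f`,
#'   `convergence` (best-so-far per iteration), `seed`, `pop_size`,
#'   `iterations`, `n_rejected` (candidates whose objective was `NaN`).
#' @examples
#' res <- optimize_formulation(eq2_objective(), "poa", seed = 1)
#' res$best_x
#' @export
optimize_formulation <- function(objective, algorithm = c("po", "poa", "sboa"),
                                 pop_size = 30, iterations = 100, seed = 1L,
                                 boundary = c("clamp", "reflect")) {
  if (!inherits(objective, "objective_function")) {
    abort("`objective` must be an objective_function",
          class = "halochrom_validation_error")
  }
  algorithm <- rlang::arg_match(algorithm)
  boundary <- rlang::arg_match(boundary)
  check_number(pop_size, "pop_size", min = 2, integer = TRUE)
  check_number(iterations, "iterations", min = 1, integer = TRUE)
  lower <- objective$lower; upper <- objective$upper
  d <- length(lower)
  n_rejected <- 0L

  eval_pop <- function(X) {
    f <- apply(X, 1, function(x) {
      v <- tryCatch(objective$fn(x), error = function(e) NaN)
      if (is.nan(v)) NaN else v
    })
    bad <- is.nan(f)
    if (any(bad)) {
      n_rejected <<- n_rejected + sum(bad)
      f[bad] <- Inf
    }
    f
  }

  set.seed(seed)
  X <- sweep(matrix(runif(pop_size * d), pop_size, d), 2, upper - lower, `*`)
  X <- sweep(X, 2, lower, `+`)
  f <- eval_pop(X)
  bi <- which.min(f)
  best_x <- X[bi, ]; best_f <- f[bi]
  convergence <- numeric(iterations)

  for (t in seq_len(iterations)) {
    frac <- t / iterations
    Xm <- colMeans(X)

    if (algorithm == "po") {
      Xn <- X
      for (i in seq_len(pop_size)) {
        b <- sample.int(4, 1)
        Xn[i, ] <- switch(b,
          ## foraging
          (X[i, ] - best_x) * levy_step(d) +
            runif(1) * Xm * (1 - frac)^(2 * frac),
          ## staying (perch on the host/best)
          X[i, ] + best_x * levy_step(d) + runif(d) * (upper - lower) / 10,
          ## communicating with the flock
          if (runif(1) < 0.5) {
            Xm + 0.2 * runif(1) * (1 - frac) * (X[i, ] - Xm)
          } else {
            X[i, ] + 0.2 * runif(1) * exp(-t / (runif(1) * iterations)) *
              (X[i, ] - Xm)
          },
          ## fear of strangers
          X[i, ] + runif(1) * cos(0.5 * pi * frac) * (best_x - X[i, ]) -
            cos(runif(1) * pi) * frac^(2 / iterations) * (X[i, ] - best_x)
        )
      }
      Xn <- clamp_or_reflect(Xn, lower, upper, boundary)
      fn <- eval_pop(Xn)
      improved <- fn < f
      X[improved, ] <- Xn[improved, ]; f[improved] <- fn[improved]
    } else if (algorithm == "poa") {
      ## phase 1: moving toward prey (exploration)
      prey <- lower + runif(d) * (upper - lower)
      f_prey <- eval_pop(matrix(prey, 1))
      Xn <- X
      for (i in seq_len(pop_size)) {
        I <- sample(1:2, 1)
        Xn[i, ] <- if (f_prey < f[i]) {
          X[i, ] + runif(d) * (prey - I * X[i, ])
        } else {
          X[i, ] + runif(d) * (X[i, ] - prey)
        }
      }
      Xn <- clamp_or_reflect(Xn, lower, upper, boundary)
      fn <- eval_pop(Xn)
      improved <- fn < f
      X[improved, ] <- Xn[improved, ]; f[improved] <- fn[improved]
      ## phase 2: winging on the water surface (exploitation)
      R <- 0.2
      Xn <- X + R * (1 - frac) * (2 * matrix(runif(pop_size * d),
                                             pop_size, d) - 1) * X
      Xn <- clamp_or_reflect(Xn, lower, upper, boundary)
      fn <- eval_pop(Xn)
      improved <- fn < f
      X[improved, ] <- Xn[improved, ]; f[improved] <- fn[improved]
    } else { # sboa
      Xn <- X
      for (i in seq_len(pop_size)) {
        ## hunting strategy (exploration), staged by iteration progress
        Xn[i, ] <- if (frac < 1 / 3) {
          r12 <- sample(setdiff(seq_len(pop_size), i), 2)
          X[i, ] + (X[r12[1], ] - X[r12[2], ]) * runif(d)
        } else if (frac < 2 / 3) {
          best_x + exp(frac^4) * (rnorm(d) - 0.5) * (best_x - X[i, ])
        } else {
          best_x + (1 - frac)^(2 * frac) * X[i, ] * levy_step(d) * 0.5
        }
      }
      Xn <- clamp_or_reflect(Xn, lower, upper, boundary)
      fn <- eval_pop(Xn)
      improved <- fn < f
      X[improved, ] <- Xn[improved, ]; f[improved] <- fn[improved]
      ## escape strategy (exploitation)
      Xn <- X
      for (i in seq_len(pop_size)) {
        Xn[i, ] <- if (runif(1) < 0.5) {
          best_x + (2 * rnorm(d) - 1) * (1 - frac)^2 * X[i, ]
        } else {
          r1 <- sample.int(pop_size, 1)
          K <- sample(1:2, 1)
          X[i, ] + runif(1) * (X[r1, ] - K * X[i, ])
        }
      }
      Xn <- clamp_or_reflect(Xn, lower, upper, boundary)
      fn <- eval_pop(Xn)
      improved <- fn < f
      X[improved, ] <- Xn[improved, ]; f[improved] <- fn[improved]
    }

    bi <- which.min(f)
    if (f[bi] < best_f) { best_f <- f[bi]; best_x <- X[bi, ] }
    convergence[t] <- best_f
  }

  new_bird_opt(algorithm, best_x, best_f, convergence, seed, pop_size,
               iterations, n_rejected)
}

new_bird_opt <- function(algorithm, best_x, best_f, convergence, seed,
                         pop_size, iterations, n_rejected = 0L) {
  structure(
    list(algorithm = algorithm, best_x = best_x, best_f = best_f,
         convergence = convergence, seed = seed, pop_size = pop_size,
         iterations = iterations, n_rejected = n_rejected),
    class = "bird_opt"
  )
}

#' @export
print.bird_opt <- function(x, ...) {
  cat(sprintf("<bird_opt %s: best f = %.6f at (%s), %d iterations>\n",
              x$algorithm, x$best_f,
              paste(signif(x$best_x, 6), collapse = ", "), x$iterations))
  invisible(x)
}

#' @export
tidy.bird_opt <- function(x, ...) {
  tibble(algorithm = x$algorithm,
         iteration = seq_along(x$convergence),
         best_f = x$convergence)
}

#' @export
glance.bird_opt <- function(x, ...) {
  tibble(algorithm = x$algorithm,
         peg_pct = x$best_x[1],
         btb_pct = if (length(x$best_x) > 1) x$best_x[2] else NA_real_,
         best_f = x$best_f,
         iterations = x$iterations,
         pop_size = x$pop_size,
         seed = x$seed)
}

#' Deterministic grid search with coordinate refinement
#'
#' Exhaustively evaluates the objective on a regular grid, then refines the
#' best point by repeated per-coordinate local line searches on successively
#' shrinking windows (each pass evaluates 21 points per coordinate within the
#' current window, clipped to the bounds, then quarters the window) until the
#' window falls below `refine_tolerance`. Fully deterministic; serves as the
#' reference minimizer against which the stochastic algorithms are checked.
#'
#' @param objective An [objective_function()].
#' @param grid_points_per_dim Grid resolution (default 2000).
#' @param refine_tolerance Final window size (default 1e-8).
#' @return A `bird_opt` result with `algorithm = "grid"`; its `convergence`
#'   records the best value after the grid pass and after each refinement pass.
#' @export
grid_refine_minimize <- function(objective, grid_points_per_dim = 2000,
                                 refine_tolerance = 1e-8) {
  if (!inherits(objective, "objective_function")) {
    abort("`objective` must be an objective_function",
          class = "halochrom_validation_error")
  }
  check_number(grid_points_per_dim, "grid_points_per_dim", min = 2, integer = TRUE)
  check_number(refine_tolerance, "refine_tolerance", min = 0, strict_min = TRUE)
  lower <- objective$lower; upper <- objective$upper
  if (any(!is.finite(c(lower, upper)))) {
    abort("bounds must be finite", class = "halochrom_validation_error")
  }
  d <- length(lower)
  fv <- if (!is.null(objective$fn_vec)) objective$fn_vec else {
    function(X) apply(X, 1, objective$fn)
  }
  axes <- lapply(seq_len(d), function(j) {
    seq(lower[j], upper[j], length.out = grid_points_per_dim)
  })
  ## evaluate the full grid in row chunks to bound memory
  grid <- as.matrix(expand.grid(axes, KEEP.OUT.ATTRS = FALSE))
  vals <- fv(grid)
  bi <- which.min(vals)
  best_x <- unname(grid[bi, ]); best_f <- vals[bi]
  convergence <- best_f

  w <- (upper - lower) / (grid_points_per_dim - 1)
  while (any(w > refine_tolerance)) {
    for (j in seq_len(d)) {
      cand <- seq(max(lower[j], best_x[j] - w[j]),
                  min(upper[j], best_x[j] + w[j]), length.out = 21)
      Xc <- matrix(rep(best_x, each = length(cand)), length(cand), d)
      Xc[, j] <- cand
      vc <- fv(Xc)
      k <- which.min(vc)
      if (vc[k] <= best_f) { best_f <- vc[k]; best_x[j] <- cand[k] }
    }
    w <- w / 4
    convergence <- c(convergence, best_f)
  }
  new_bird_opt("grid", best_x, best_f, convergence,
               seed = NA_integer_, pop_size = NA_integer_,
               iterations = length(convergence))
}
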