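sphere_objective <- function(d = 2) {
  objective_function(
    fn = function(x) sum(x^2),
    fn_vec = function(X) rowSums(X^2),
    lower = rep(-5, d), upper = rep(5, d), name = "sphere"
  )
}

test_that("the reconstructed response surface matches its published optima", {
  expect_lt(abs(fitness_eq2(6, 0.020148) - 188.595634), 0.02)
  expect_lt(abs(fitness_eq2(6, 0.020143) - 188.595647), 0.02)
  ## term-by-term arithmetic oracle at an interior point
  expect_equal(fitness_eq2(8, 0.03), eq2_by_terms(8, 0.03), tolerance = 1e-9)
  expect_equal(fitness_eq2(10, 0.013), eq2_by_terms(10, 0.013),
               tolerance = 1e-9)
})

test_that("the response surface rejects out-of-domain input", {
  expect_error(fitness_eq2(5, 0.02), class = "halochrom_domain_error")
  expect_error(fitness_eq2(11, 0.02), class = "halochrom_domain_error")
  expect_error(fitness_eq2(8, 0.005), class = "halochrom_domain_error")
  expect_error(fitness_eq2(8, 0.06), class = "halochrom_domain_error")
})

test_that("all three metaheuristics solve the sphere to 1e-3", {
  for (alg in c("po", "poa", "sboa")) {
    for (seed in 1:10) {
      res <- optimize_formulation(sphere_objective(), alg, pop_size = 30,
                                  iterations = 100, seed = seed)
      expect_lte(res$best_f, 1e-3)
    }
  }
})

test_that("runs are monotone, in-bounds, and seed-deterministic", {
  obj <- eq2_objective()
  for (alg in c("po", "poa", "sboa")) {
    res <- optimize_formulation(obj, alg, seed = 5)
    expect_true(all(diff(res$convergence) <= 0))
    expect_equal(res$best_f, utils::tail(res$convergence, 1))
    expect_true(all(res$best_x >= obj$lower & res$best_x <= obj$upper))
    res2 <- optimize_formulation(obj, alg, seed = 5)
    expect_identical(res$best_x, res2$best_x)
    expect_identical(res$convergence, res2$convergence)
  }
})

test_that("metaheuristics find the published optimum in median over seeds", {
  obj <- eq2_objective()
  for (alg in c("po", "poa", "sboa")) {
    runs <- lapply(1:10, function(s) {
      optimize_formulation(obj, alg, pop_size = 30, iterations = 100,
                           seed = s)
    })
    x1s <- vapply(runs, function(r) r$best_x[1], numeric(1))
    x2s <- vapply(runs, function(r) r$best_x[2], numeric(1))
    fs <- vapply(runs, function(r) r$best_f, numeric(1))
    expect_lt(abs(stats::median(x1s) - 6), 0.01)
    expect_lt(abs(stats::median(x2s) - 0.0201), 5e-4)
    expect_lt(abs(stats::median(fs) - 188.5956), 0.05)
  }
})

test_that("metaheuristics dominate random search at equal budget", {
  obj <- eq2_objective()
  budget_evals <- function(seed) { # random search, 30 * 100 evaluations
    set.seed(seed)
    X <- cbind(runif(3000, 6, 10), runif(3000, 0.01, 0.05))
    min(fitness_eq2(X[, 1], X[, 2]))
  }
  rand_med <- stats::median(vapply(1:10, budget_evals, numeric(1)))
  for (alg in c("po", "poa", "sboa")) {
    fs <- vapply(1:10, function(s) {
      optimize_formulation(obj, alg, pop_size = 30, iterations = 100,
                           seed = s)$best_f
    }, numeric(1))
    expect_lt(stats::median(fs), rand_med)
  }
})

test_that("grid refinement recovers interior and boundary minimizers", {
  parab <- objective_function(
    fn = function(x) (x[1] - 1.3)^2 + (x[2] + 0.4)^2,
    fn_vec = function(X) (X[, 1] - 1.3)^2 + (X[, 2] + 0.4)^2,
    lower = c(-5, -5), upper = c(5, 5), name = "paraboloid"
  )
  res <- grid_refine_minimize(parab, grid_points_per_dim = 101,
                              refine_tolerance = 1e-8)
  expect_equal(res$best_x, c(1.3, -0.4), tolerance = 1e-6)

  eq2 <- grid_refine_minimize(eq2_objective(), grid_points_per_dim = 400,
                              refine_tolerance = 1e-8)
  expect_identical(eq2$best_x[1], 6) # boundary minimizer, exact
  expect_lt(abs(eq2$best_x[2] - 0.020148), 5e-4)
  expect_true(all(diff(eq2$convergence) <= 0))
})

test_that("invalid optimizer arguments are rejected", {
  expect_error(optimize_formulation(eq2_objective(), "cuckoo"))
  expect_error(optimize_formulation(list(), "po"),
               class = "halochrom_validation_error")
  expect_error(objective_function(identity, c(0, 0), c(1, -1)),
               class = "halochrom_validation_error")
})
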