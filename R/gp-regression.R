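#' Hyperparameters of the multigene GP symbolic regression
#'
#' Defaults follow the published evolutionary setup: population 100 over at
#' most 50 generations, tournament selection of size 10, 10% elitism, a 10%
#' chance of a Pareto tournament (rewarding low expression complexity alongside
#' low error), at most 20 genes per model and tree depth at most 10, crossover
#' probability 0.84 and mutation probability 0.14 (the remaining 0.02 is plain
#' reproduction).
#'
#' @param population_size,max_generations,tournament_size Positive integers.
#' @param elite_fraction Fraction of the population copied unchanged.
#' @param pareto_tournament_prob Probability that a tournament selects the
#'   lowest-error individual among the Pareto-nondominated contestants on
#'   (RMSE, total node count) instead of by RMSE alone.
#' @param max_genes,max_tree_depth Structural caps enforced at every generation.
#' @param crossover_prob,mutation_prob Genetic-operator probabilities; their
#'   sum must not exceed 1.
#' @param const_range Range of ephemeral random constants.
#' @param stop_rmse Early-stop threshold: evolution halts once the best-ever
#'   training RMSE falls to or below this value (default `1e-12`, i.e. an
#'   exact interpolant has been found).
#' @export
gp_hyperparams <- function(population_size = 100,
                           max_generations = 50,
                           tournament_size = 10,
                           elite_fraction = 0.1,
                           pareto_tournament_prob = 0.1,
                           max_genes = 20,
                           max_tree_depth = 10,
                           crossover_prob = 0.84,
                           mutation_prob = 0.14,
                           const_range = c(-10, 10),
                           stop_rmse = 1e-12) {
  check_number(population_size, "population_size", min = 2, integer = TRUE)
  check_number(max_generations, "max_generations", min = 1, integer = TRUE)
  check_number(tournament_size, "tournament_size", min = 1, integer = TRUE)
  check_number(elite_fraction, "elite_fraction", min = 0, max = 1)
  check_number(pareto_tournament_prob, "pareto_tournament_prob", min = 0, max = 1)
  check_number(max_genes, "max_genes", min = 1, integer = TRUE)
  check_number(max_tree_depth, "max_tree_depth", min = 1, integer = TRUE)
  check_number(crossover_prob, "crossover_prob", min = 0, max = 1)
  check_number(mutation_prob, "mutation_prob", min = 0, max = 1)
  if (crossover_prob + mutation_prob > 1 + 1e-12) {
    abort("crossover_prob + mutation_prob must not exceed 1",
          class = "halochrom_validation_error")
  }
  structure(
    list(population_size = as.integer(population_size),
         max_generations = as.integer(max_generations),
         tournament_size = as.integer(tournament_size),
         elite_fraction = elite_fraction,
         pareto_tournament_prob = pareto_tournament_prob,
         max_genes = as.integer(max_genes),
         max_tree_depth = as.integer(max_tree_depth),
         crossover_prob = crossover_prob,
         mutation_prob = mutation_prob,
         const_range = const_range,
         stop_rmse = stop_rmse),
    class = "gp_hyperparams"
  )
}

## ---- expression trees -----------------------------------------------------
## A tree is a list: list(type = "op", op, args = list(...)) with binary ops
## "+", "-", "*" and unary ops "log" (natural log) and "sq" (square); or
## list(type = "var", name) over {x1, x2}; or list(type = "const", value).
## The function set is the smallest one able to express the published
## response-surface terms (products, squares, natural logs).

GP_BINARY <- c("+", "-", "*")
GP_UNARY <- c("log", "sq")
GP_VARS <- c("x1", "x2")

tree_depth <- function(tree) {
  if (tree$type != "op") return(1L)
  1L + max(vapply(tree$args, tree_depth, integer(1)))
}

tree_nodes <- function(tree) {
  if (tree$type != "op") return(1L)
  1L + sum(vapply(tree$args, tree_nodes, integer(1)))
}

eval_tree <- function(tree, x1, x2) {
  switch(tree$type,
    var = if (tree$name == "x1") x1 else x2,
    const = rep(tree$value, length(x1)),
    op = {
      a <- eval_tree(tree$args[[1]], x1, x2)
      switch(tree$op,
        "+" = a + eval_tree(tree$args[[2]], x1, x2),
        "-" = a - eval_tree(tree$args[[2]], x1, x2),
        "*" = a * eval_tree(tree$args[[2]], x1, x2),
        "log" = log(a),
        "sq" = a * a
      )
    }
  )
}

fmt_num <- function(x) sprintf("%.17g", x)

tree_to_string <- function(tree) {
  switch(tree$type,
    var = tree$name,
    const = fmt_num(tree$value),
    op = switch(tree$op,
      "log" = paste0("log(", tree_to_string(tree$args[[1]]), ")"),
      "sq" = paste0("(", tree_to_string(tree$args[[1]]), ")^2"),
      paste0("(", tree_to_string(tree$args[[1]]), " ", tree$op, " ",
             tree_to_string(tree$args[[2]]), ")")
    )
  )
}

random_terminal <- function(const_range) {
  if (runif(1) < 0.5) {
    list(type = "var", name = sample(GP_VARS, 1))
  } else {
    list(type = "const", value = runif(1, const_range[1], const_range[2]))
  }
}

random_tree <- function(max_depth, full = FALSE, const_range = c(-10, 10)) {
  if (max_depth <= 1 || (!full && runif(1) < 0.3)) {
    return(random_terminal(const_range))
  }
  if (runif(1) < 0.25) {
    list(type = "op", op = sample(GP_UNARY, 1),
         args = list(random_tree(max_depth - 1, full, const_range)))
  } else {
    list(type = "op", op = sample(GP_BINARY, 1),
         args = list(random_tree(max_depth - 1, full, const_range),
                     random_tree(max_depth - 1, full, const_range)))
  }
}

## Uniform random node access by preorder index.
get_node <- function(tree, idx) {
  env <- new.env(); env$i <- 0L; env$found <- NULL
  walk <- function(t) {
    if (!is.null(env$found)) return()
    env$i <- env$i + 1L
    if (env$i == idx) { env$found <- t; return() }
    if (t$type == "op") for (a in t$args) walk(a)
  }
  walk(tree)
  env$found
}

set_node <- function(tree, idx, replacement) {
  env <- new.env(); env$i <- 0L
  walk <- function(t) {
    env$i <- env$i + 1L
    if (env$i == idx) return(replacement)
    if (t$type == "op") {
      t$args <- lapply(t$args, walk)
    }
    t
  }
  walk(tree)
}

subtree_crossover <- function(recipient, donor, max_depth) {
  for (try in 1:8) {
    i <- sample.int(tree_nodes(recipient), 1)
    j <- sample.int(tree_nodes(donor), 1)
    child <- set_node(recipient, i, get_node(donor, j))
    if (tree_depth(child) <= max_depth) return(child)
  }
  recipient
}

subtree_mutate <- function(tree, max_depth, const_range) {
  for (try in 1:8) {
    i <- sample.int(tree_nodes(tree), 1)
    child <- set_node(tree, i, random_tree(3, full = FALSE, const_range))
    if (tree_depth(child) <= max_depth) return(child)
  }
  tree
}

## ---- evaluation -----------------------------------------------------------

## Least-squares output weighting: prediction = bias + sum_i w_i * gene_i(x).
## Singular designs fall back to a small ridge penalty (counted and reported).
fit_weights <- function(G, y) {
  D <- cbind(1, G)
  qd <- qr(D)
  if (qd$rank < ncol(D)) {
    coef <- tryCatch(
      solve(crossprod(D) + 1e-8 * diag(ncol(D)), crossprod(D, y)),
      error = function(e) NULL
    )
    if (is.null(coef)) return(NULL)
    list(coef = as.numeric(coef), ridge = TRUE)
  } else {
    list(coef = as.numeric(qr.coef(qd, y)), ridge = FALSE)
  }
}

evaluate_genes <- function(genes, x1, x2, y) {
  ## log() of a negative subexpression yields NaN with a warning; such
  ## offspring are silently assigned infinite fitness below
  G <- suppressWarnings(
    vapply(genes, eval_tree, numeric(length(x1)), x1 = x1, x2 = x2)
  )
  if (!is.matrix(G)) G <- matrix(G, ncol = length(genes))
  if (!all(is.finite(G)) || max(abs(G)) > 1e12) return(NULL)
  fw <- fit_weights(G, y)
  if (is.null(fw) || !all(is.finite(fw$coef))) return(NULL)
  pred <- as.numeric(cbind(1, G) %*% fw$coef)
  rmse <- sqrt(mean((pred - y)^2))
  if (!is.finite(rmse)) return(NULL)
  list(bias = fw$coef[1], weights = fw$coef[-1], rmse = rmse,
       complexity = sum(vapply(genes, tree_nodes, integer(1))),
       ridge = fw$ridge)
}

## ---- evolution ------------------------------------------------------------

#' Evolve a multigene GP model of response time on formulation
#'
#' Symbolic regression of the response time `y` (seconds) on the PEG
#' concentration `x1` and BTB concentration `x2`. A model is a set of
#' expression trees (genes) combined linearly; the gene output weights and
#' bias are re-fit by least squares at every fitness evaluation, and fitness
#' is the training RMSE. Evolution is generational with tournament selection,
#' subtree crossover and mutation, gene-level crossover, elitism, and an
#' occasional Pareto tournament on (RMSE, node count). Offspring whose genes
#' produce non-finite values on any training point (e.g. the log of a
#' non-positive subexpression) are assigned infinite fitness rather than
#' repaired.
#'
#' @param data Tibble with columns `peg_pct`, `btb_pct`, `response_time_s`
#'   (or `x1`, `x2`, `y`).
#' @param params A [gp_hyperparams()].
#' @param seed Integer seed; the full run is seed-deterministic.
#' @return A `gp_model` with elements `genes`, `weights`, `bias`,
#'   `train_rmse`, `history` (best-ever RMSE per generation, non-increasing),
#'   `generations_run`, `ridge_fallbacks`, `params`, `seed`, `train`.
#' @examples
#' \donttest{
#' dat <- generate_formulation_dataset(noise_sd = 0, ph_effect = NULL)
#' mod <- gp_evolve(dat, gp_hyperparams(population_size = 30,
#'                                      max_generations = 5), seed = 1)
#' glance(mod)
#' }
#' @export
gp_evolve <- function(data, params = gp_hyperparams(), seed = 1L) {
  d <- as_xy(data)
  if (nrow(d) < params$max_genes + 2L) {
    abort("need at least max_genes + 2 records", class = "halochrom_validation_error")
  }
  if (stats::sd(d$x1) == 0 || stats::sd(d$x2) == 0) {
    abort("degenerate dataset: an input variable is constant",
          class = "halochrom_validation_error")
  }
  set.seed(seed)
  x1 <- d$x1; x2 <- d$x2; y <- d$y
  pop_n <- params$population_size
  ridge_count <- 0L

  eval_ind <- function(genes) {
    ev <- evaluate_genes(genes, x1, x2, y)
    if (is.null(ev)) {
      return(list(genes = genes, rmse = Inf,
                  complexity = sum(vapply(genes, tree_nodes, integer(1))),
                  bias = NA_real_, weights = rep(NA_real_, length(genes))))
    }
    if (ev$ridge) ridge_count <<- ridge_count + 1L
    c(list(genes = genes), ev)
  }

  init_depth <- min(4L, params$max_tree_depth)
  pop <- lapply(seq_len(pop_n), function(i) {
    genes <- lapply(seq_len(sample(1:3, 1)), function(j) {
      random_tree(sample(2:init_depth, 1), full = runif(1) < 0.5,
                  const_range = params$const_range)
    })
    eval_ind(genes)
  })

  tournament <- function() {
    contestants <- pop[sample.int(pop_n, min(params$tournament_size, pop_n))]
    rmses <- vapply(contestants, `[[`, numeric(1), "rmse")
    pick <- if (runif(1) < params$pareto_tournament_prob) {
      cx <- vapply(contestants, `[[`, numeric(1), "complexity")
      nondom <- vapply(seq_along(contestants), function(i) {
        !any(rmses <= rmses[i] & cx <= cx[i] &
               (rmses < rmses[i] | cx < cx[i]))
      }, logical(1))
      cand <- which(nondom)
      cand[which.min(rmses[cand])]
    } else {
      which.min(rmses)
    }
    contestants[[pick]]
  }

  crossover_genes <- function(g1, g2) {
    if (runif(1) < 0.5) {
      ## high-level: recombine whole genes from both parents
      keep1 <- g1[runif(length(g1)) < 0.7]
      keep2 <- g2[runif(length(g2)) < 0.5]
      child <- c(keep1, keep2)
      if (length(child) == 0L) child <- g1[1]
      if (length(child) > params$max_genes) {
        child <- child[sample.int(length(child), params$max_genes)]
      }
      child
    } else {
      child <- g1
      i <- sample.int(length(child), 1)
      j <- sample.int(length(g2), 1)
      child[[i]] <- subtree_crossover(child[[i]], g2[[j]],
                                      params$max_tree_depth)
      child
    }
  }

  mutate_genes <- function(g) {
    r <- runif(1)
    if (r < 0.15 && length(g) < params$max_genes) {
      c(g, list(random_tree(3, FALSE, params$const_range)))
    } else if (r < 0.25 && length(g) > 1) {
      g[-sample.int(length(g), 1)]
    } else {
      i <- sample.int(length(g), 1)
      g[[i]] <- subtree_mutate(g[[i]], params$max_tree_depth,
                               params$const_range)
      g
    }
  }

  best <- pop[[which.min(vapply(pop, `[[`, numeric(1), "rmse"))]]
  history <- numeric(0)
  gens <- 0L
  n_elite <- max(1L, ceiling(params$elite_fraction * pop_n))

  for (gen in seq_len(params$max_generations)) {
    gens <- gen
    rmses <- vapply(pop, `[[`, numeric(1), "rmse")
    elites <- pop[order(rmses)[seq_len(n_elite)]]
    children <- vector("list", pop_n - n_elite)
    for (i in seq_along(children)) {
      r <- runif(1)
      if (r < params$crossover_prob) {
        p1 <- tournament(); p2 <- tournament()
        genes <- crossover_genes(p1$genes, p2$genes)
      } else if (r < params$crossover_prob + params$mutation_prob) {
        genes <- mutate_genes(tournament()$genes)
      } else {
        genes <- tournament()$genes
      }
      children[[i]] <- eval_ind(genes)
    }
    pop <- c(elites, children)
    gen_best <- pop[[which.min(vapply(pop, `[[`, numeric(1), "rmse"))]]
    if (gen_best$rmse < best$rmse) best <- gen_best
    history[gen] <- best$rmse
    if (best$rmse <= params$stop_rmse) break
  }

  structure(
    list(genes = best$genes, weights = best$weights, bias = best$bias,
         train_rmse = best$rmse, history = history, generations_run = gens,
         ridge_fallbacks = ridge_count, params = params, seed = seed,
         train = d),
    class = "gp_model"
  )
}

as_xy <- function(data) {
  nm <- names(data)
  if (all(c("x1", "x2", "y") %in% nm)) {
    tibble(x1 = data$x1, x2 = data$x2, y = data$y)
  } else if (all(c("peg_pct", "btb_pct", "response_time_s") %in% nm)) {
    tibble(x1 = data$peg_pct, x2 = data$btb_pct, y = data$response_time_s)
  } else {
    abort("data must carry (peg_pct, btb_pct, response_time_s) or (x1, x2, y)",
          class = "halochrom_validation_error")
  }
}

#' Predict response time from a GP model
#'
#' @param object A `gp_model`.
#' @param newdata Tibble with `peg_pct`/`btb_pct` (or `x1`/`x2`) columns;
#'   default: the training data.
#' @param ... Unused.
#' @return Numeric vector of predicted response times (s). A gene whose
#'   evaluation is non-finite (e.g. log of a non-positive subexpression)
#'   raises a domain error naming the gene.
#' @export
predict.gp_model <- function(object, newdata = NULL, ...) {
  d <- if (is.null(newdata)) object$train else {
    nm <- names(newdata)
    if (all(c("x1", "x2") %in% nm)) {
      tibble(x1 = newdata$x1, x2 = newdata$x2)
    } else if (all(c("peg_pct", "btb_pct") %in% nm)) {
      tibble(x1 = newdata$peg_pct, x2 = newdata$btb_pct)
    } else {
      abort("newdata must carry (peg_pct, btb_pct) or (x1, x2)",
            class = "halochrom_validation_error")
    }
  }
  if (length(object$genes) == 0L) {
    return(rep(object$bias, nrow(d)))
  }
  G <- suppressWarnings(
    vapply(object$genes, eval_tree, numeric(nrow(d)), x1 = d$x1, x2 = d$x2)
  )
  if (!is.matrix(G)) G <- matrix(G, ncol = length(object$genes))
  bad <- which(colSums(!is.finite(G)) > 0)
  if (length(bad) > 0L) {
    abort(sprintf("domain error (non-finite value) in gene %d", bad[1]),
          class = "halochrom_domain_error")
  }
  as.numeric(object$bias + G %*% object$weights)
}

#' Render a GP model as a closed-form expression string
#'
#' The returned string uses only `+`, `-`, `*`, `^2`, natural `log()` and
#' numeric literals printed at full precision, and can be re-evaluated with
#' [evaluate_expression()]; the round trip agrees with [predict.gp_model()] to
#' numerical precision.
#'
#' @param model A `gp_model`.
#' @return A single string in the variables `x1` (PEG) and `x2` (BTB).
#' @export
model_to_expression <- function(model) {
  out <- fmt_num(model$bias)
  for (i in seq_along(model$genes)) {
    w <- model$weights[i]
    sgn <- if (w < 0) " - " else " + "
    out <- paste0(out, sgn, fmt_num(abs(w)), "*",
                  "(", tree_to_string(model$genes[[i]]), ")")
  }
  out
}

#' Evaluate a rendered model expression
#'
#' Parses an expression string produced by [model_to_expression()] (or any
#' arithmetic expression in `x1`, `x2` using `+ - * / ^ log exp sqrt`) and
#' evaluates it, vectorized over the inputs.
#'
#' @param text Expression string.
#' @param x1,x2 Numeric vectors (PEG and BTB concentrations).
#' @export
evaluate_expression <- function(text, x1, x2) {
  e <- str2lang(text)
  eval(e, list(x1 = x1, x2 = x2), baseenv())
}

#' @export
print.gp_model <- function(x, ...) {
  cat(sprintf("<gp_model: %d genes, train RMSE %.6g, %d generations>\n",
              length(x$genes), x$train_rmse, x$generations_run))
  cat(model_to_expression(x), "\n")
  invisible(x)
}

#' @export
tidy.gp_model <- function(x, ...) {
  g <- tibble(
    term = c("(bias)", paste0("gene", seq_along(x$genes))),
    expression = c("1", vapply(x$genes, tree_to_string, character(1))),
    weight = c(x$bias, x$weights),
    nodes = c(0L, vapply(x$genes, tree_nodes, integer(1))),
    depth = c(0L, vapply(x$genes, tree_depth, integer(1)))
  )
  g
}

#' @export
glance.gp_model <- function(x, ...) {
  tibble(
    n_genes = length(x$genes),
    train_rmse = x$train_rmse,
    complexity = sum(vapply(x$genes, tree_nodes, integer(1))),
    generations_run = x$generations_run,
    ridge_fallbacks = x$ridge_fallbacks,
    seed = x$seed
  )
}
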