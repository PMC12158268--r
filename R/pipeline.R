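#' Configure an end-to-end analysis run
#'
#' Bundles every stage's settings and validates inter-stage dependencies
#' before any computation happens. Stages: `"simulate"` (synthetic kinetics +
#' formulation dataset, or ingestion of a supplied dataset), `"stabilize"`
#' (response-time detection on the kinetics series), `"select_features"`
#' (PCA + ReliefF on a labeled feature table), `"gp_fit"` (symbolic
#' regression), `"optimize"` (metaheuristic minimization of the fitted or
#' published surface), `"anova"` (two-factor ANOVA of the response dataset).
#'
#' @param stages Character vector of stages to run (default: all).
#' @param seed Master seed; per-stage seeds are derived deterministically from
#'   it (a fixed-seed `sample.int` draw), so any stage can be re-run
#'   independently with identical results.
#' @param design A [design_spec()].
#' @param data Optional pre-existing response dataset (tibble with `peg_pct`,
#'   `btb_pct`, `ph`, `response_time_s`); replaces the simulated one.
#' @param noise_sd,kinetics_noise_sd Noise levels for the simulated response
#'   dataset (seconds) and kinetics series (channel units).
#' @param stab_params A [stabilization_params()].
#' @param gp_params A [gp_hyperparams()].
#' @param objective `"eq2"` (the published surface) or `"gp"` (the model
#'   fitted in the `gp_fit` stage) as the optimization target.
#' @param algorithms Metaheuristics to run (subset of `po`, `poa`, `sboa`).
#' @param pop_size,iterations Optimizer budget.
#' @param alpha ANOVA significance level.
#' @param out_dir Optional directory; when set, stage outputs are written as
#'   CSV/JSON files.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(stages = c("simulate", "stabilize",
                                       "select_features", "gp_fit",
                                       "optimize", "anova"),
                            seed = 1L,
                            design = design_spec(),
                            data = NULL,
                            noise_sd = 100,
                            kinetics_noise_sd = 5e-4,
                            stab_params = stabilization_params(),
                            gp_params = gp_hyperparams(),
                            objective = c("eq2", "gp"),
                            algorithms = c("po", "poa", "sboa"),
                            pop_size = 30,
                            iterations = 100,
                            alpha = 0.05,
                            out_dir = NULL) {
  known <- c("simulate", "stabilize", "select_features", "gp_fit",
             "optimize", "anova")
  if (!all(stages %in% known)) {
    abort(sprintf("unknown stage `%s`", setdiff(stages, known)[1]),
          class = "halochrom_config_error")
  }
  objective <- rlang::arg_match(objective)
  if ("optimize" %in% stages && objective == "gp" && !"gp_fit" %in% stages) {
    abort("optimization over the GP surface requires the `gp_fit` stage",
          class = "halochrom_config_error")
  }
  needs_data <- intersect(c("gp_fit", "anova"), stages)
  if (length(needs_data) > 0 && is.null(data) && !"simulate" %in% stages) {
    abort(sprintf("stage `%s` needs `simulate` or a supplied `data` table",
                  needs_data[1]),
          class = "halochrom_config_error")
  }
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  structure(
    list(stages = stages, seed = as.integer(seed), design = design,
         data = data, noise_sd = noise_sd,
         kinetics_noise_sd = kinetics_noise_sd, stab_params = stab_params,
         gp_params = gp_params, objective = objective,
         algorithms = algorithms, pop_size = pop_size,
         iterations = iterations, alpha = alpha, out_dir = out_dir),
    class = "pipeline_config"
  )
}

#' Run the configured analysis pipeline
#'
#' Executes the enabled stages in dependency order and returns all stage
#' results plus a provenance manifest (stage name, derived seed, and a content
#' hash of the stage output). Identical config and master seed give an
#' identical manifest; disabling a downstream stage never changes an upstream
#' stage's output because stage seeds are pre-derived from the master seed.
#'
#' @param config A [pipeline_config()].
#' @return A `pipeline_run` list: `results` (named by stage), `manifest`
#'   (tibble), `config_hash`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) {
    abort("`config` must be a pipeline_config", class = "halochrom_config_error")
  }
  stage_names <- c("simulate", "stabilize", "select_features", "gp_fit",
                   "optimize", "anova")
  seeds <- setNames(derive_seeds(config$seed, length(stage_names)),
                    stage_names)
  results <- list()

  dataset <- config$data
  if ("simulate" %in% config$stages) {
    dataset <- generate_formulation_dataset(
      design = config$design, noise_sd = config$noise_sd,
      seed = seeds[["simulate"]]
    )
    kin <- purrr::map(
      setNames(config$design$ph_levels, paste0("ph", config$design$ph_levels)),
      function(ph) generate_color_kinetics(
        default_kinetics(ph, noise_sd = config$kinetics_noise_sd),
        seed = seeds[["simulate"]] + which(config$design$ph_levels == ph),
        ph = ph
      )
    )
    results$simulate <- list(dataset = dataset, kinetics = kin)
  }

  if ("stabilize" %in% config$stages) {
    kin <- results$simulate$kinetics
    if (is.null(kin)) {
      abort("`stabilize` needs kinetics from the `simulate` stage",
            class = "halochrom_config_error")
    }
    results$stabilize <- purrr::imap_dfr(kin, function(ts, nm) {
      dplyr::mutate(response_time(clean_series(ts), config$stab_params),
                    series = nm, .before = 1)
    })
  }

  if ("select_features" %in% config$stages) {
    tab <- generate_feature_table(
      ph_levels = config$design$ph_levels,
      noise_sd = max(config$kinetics_noise_sd, 1e-3),
      seed = seeds[["select_features"]]
    )
    pca <- pca_correlation(tab)
    wts <- relieff(tab, k = 10)
    results$select_features <- list(
      pca = pca, weights = wts,
      top_channels = rank_features(wts, 3)
    )
  }

  if ("gp_fit" %in% config$stages) {
    if (is.null(dataset)) {
      abort("`gp_fit` needs a response dataset", class = "halochrom_config_error")
    }
    results$gp_fit <- gp_evolve(dataset, config$gp_params,
                                seed = seeds[["gp_fit"]])
  }

  if ("optimize" %in% config$stages) {
    obj <- if (config$objective == "eq2") eq2_objective() else {
      gp_objective(results$gp_fit)
    }
    runs <- purrr::map(setNames(config$algorithms, config$algorithms),
                       function(alg) {
      optimize_formulation(obj, alg, pop_size = config$pop_size,
                           iterations = config$iterations,
                           seed = seeds[["optimize"]])
    })
    results$optimize <- list(
      runs = runs,
      summary = purrr::map_dfr(runs, glance)
    )
  }

  if ("anova" %in% config$stages) {
    if (is.null(dataset)) {
      abort("`anova` needs a response dataset", class = "halochrom_config_error")
    }
    results$anova <- two_factor_anova(dataset, alpha = config$alpha)
  }

  manifest <- tibble(
    stage = names(results),
    seed = unname(seeds[names(results)]),
    hash = vapply(results, rlang::hash, character(1))
  )

  if (!is.null(config$out_dir)) {
    write_pipeline_outputs(results, config$out_dir)
  }

  structure(
    list(results = results, manifest = manifest,
         config_hash = rlang::hash(unclass(config))),
    class = "pipeline_run"
  )
}

write_pipeline_outputs <- function(results, out_dir) {
  p <- function(...) file.path(out_dir, ...)
  if (!is.null(results$simulate)) {
    utils::write.csv(results$simulate$dataset, p("response_dataset.csv"),
                     row.names = FALSE)
    for (nm in names(results$simulate$kinetics)) {
      utils::write.csv(as.data.frame(results$simulate$kinetics[[nm]]),
                       p(paste0("kinetics_", nm, ".csv")), row.names = FALSE)
    }
  }
  if (!is.null(results$stabilize)) {
    jsonlite::write_json(results$stabilize, p("stabilization.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(results$select_features)) {
    fs <- results$select_features
    jsonlite::write_json(
      list(eigenvalues = fs$pca$eigenvalues, retained = fs$pca$retained,
           loadings = fs$pca$loadings, weights = fs$weights,
           top_channels = fs$top_channels),
      p("feature_selection.json"), dataframe = "rows", auto_unbox = TRUE,
      digits = NA, matrix = "rowmajor"
    )
  }
  if (!is.null(results$gp_fit)) {
    m <- results$gp_fit
    jsonlite::write_json(
      list(expression = model_to_expression(m), bias = m$bias,
           weights = m$weights, train_rmse = m$train_rmse,
           generations_run = m$generations_run),
      p("gp_model.json"), auto_unbox = TRUE, digits = NA
    )
  }
  if (!is.null(results$optimize)) {
    utils::write.csv(results$optimize$summary, p("optimization_summary.csv"),
                     row.names = FALSE)
    conv <- purrr::map_dfr(results$optimize$runs, tidy)
    utils::write.csv(conv, p("convergence.csv"), row.names = FALSE)
  }
  if (!is.null(results$anova)) {
    utils::write.csv(as.data.frame(results$anova), p("anova_table.csv"),
                     row.names = FALSE)
  }
  invisible(NULL)
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("<pipeline_run>\n")
  print(x$manifest)
  invisible(x)
}
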