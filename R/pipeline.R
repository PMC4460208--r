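# End-to-end orchestration of the modeling workflow: data (synthetic or
# CSV) -> folds -> network sweep -> collective sensitivity and input
# reduction -> symbolic regression (direct and/or indirect) -> multistage
# cross-validated fitting -> machine-readable summary.

default_pipeline_config <- function() {
  list(
    seed = 1,
    output_dir = NULL,
    verbose = TRUE,
    data = list(source = "synthetic", path = NULL, noise_sd = 1),
    stages = list(ann = TRUE, sensitivity = TRUE, gp_direct = TRUE,
                  gp_indirect = TRUE, crossval = TRUE),
    ann = list(architectures = list(4, 6), activation = "tanh",
               max_epochs = 10000, inputs = c("d_mm", "L_mm", "t_min"),
               n_best = 10),
    sensitivity = list(threshold = 0.05, aggregate = "mean"),
    gp = list(population_size = 200, max_generations = 25, size_limit = 30,
              use_reduced_inputs = TRUE),
    fit = list(equation_id = "weibull_diffusion", preprocessing = "original",
               sann_maxit = 2000)
  )
}

read_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    assert_that(requireNamespace("yaml", quietly = TRUE),
                "the yaml package is needed to read config files",
                "dissolvegp_config_error")
    config <- yaml::read_yaml(config)
  }
  assert_that(is.list(config), "config must be a list or a YAML file path",
              "dissolvegp_config_error")
  merge_config(default_pipeline_config(), config)
}

merge_config <- function(base, user) {
  for (k in names(user)) {
    if (is.list(base[[k]]) && is.list(user[[k]]) &&
        !is.null(names(base[[k]]))) {
      base[[k]] <- merge_config(base[[k]], user[[k]])
    } else {
      base[[k]] <- user[[k]]
    }
  }
  base
}

validate_pipeline_config <- function(cfg) {
  st <- cfg$stages
  assert_that(cfg$data$source %in% c("synthetic", "csv"),
              "data$source must be 'synthetic' or 'csv'",
              "dissolvegp_config_error")
  if (cfg$data$source == "csv") {
    assert_that(is.character(cfg$data$path),
                "data$path required for CSV source", "dissolvegp_config_error")
  }
  if (isTRUE(st$sensitivity) && !isTRUE(st$ann)) {
    abort("sensitivity stage requires the ann stage",
          class = "dissolvegp_config_error")
  }
  if ((isTRUE(st$gp_direct) || isTRUE(st$gp_indirect)) &&
      isTRUE(cfg$gp$use_reduced_inputs) && !isTRUE(st$sensitivity)) {
    abort(paste("GP stages are configured to use the reduced input vector",
                "but the sensitivity stage is disabled"),
          class = "dissolvegp_config_error")
  }
  invisible(cfg)
}

pipeline_log <- function(verbose, stage, fmt, ...) {
  if (isTRUE(verbose)) {
    message(sprintf("[%s] [%s] %s", format(Sys.time(), "%H:%M:%S"),
                    stage, sprintf(fmt, ...)))
  }
}

#' Run the full modeling pipeline
#'
#' Executes the enabled stages in the workflow order — data acquisition,
#' leave-one-formulation-out splitting, network sweep, collective
#' sensitivity with input reduction, direct and indirect symbolic
#' regression, and cross-validated multistage fitting — under a single
#' top-level seed from which every stage seed is derived. Test folds are
#' only ever read for snapshot selection and final generalization error,
#' never for training or fitting.
#'
#' @param config A nested list, or the path to a YAML file with the same
#'   structure; unspecified entries fall back to defaults sized for a
#'   quick run. Keys: `seed`, `output_dir`, `verbose`, `data` (`source` =
#'   `"synthetic"`/`"csv"`, `path`, `noise_sd`), `stages` (logical flags
#'   `ann`, `sensitivity`, `gp_direct`, `gp_indirect`, `crossval`), `ann`
#'   (`architectures`, `activation`, `max_epochs`, `inputs`, `n_best`),
#'   `sensitivity` (`threshold`, `aggregate`), `gp` (`population_size`,
#'   `max_generations`, `size_limit`, `use_reduced_inputs`), `fit`
#'   (`equation_id`, `preprocessing`, `sann_maxit`).
#' @return A list of class `pipeline_report` with one element per executed
#'   stage plus a JSON-ready `summary`; when `output_dir` is set the
#'   summary is written to `summary.json` there.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- read_pipeline_config(config)
  validate_pipeline_config(cfg)
  verbose <- cfg$verbose
  report <- list()
  summary <- list(seed = cfg$seed)

  # --- data ---------------------------------------------------------------
  ds <- if (cfg$data$source == "synthetic") {
    pipeline_log(verbose, "data", "simulating study-design dataset (noise sd %g)",
                 cfg$data$noise_sd)
    simulate_profiles(noise_sd = cfg$data$noise_sd,
                      seed = derive_seed(cfg$seed, 1))
  } else {
    pipeline_log(verbose, "data", "reading %s", cfg$data$path)
    read_dissolution_csv(cfg$data$path)
  }
  report$data <- ds
  summary$data <- list(source = cfg$data$source, n_records = nrow(ds),
                       n_formulations = length(unique(ds$formulation_id)))

  folds <- split_leave_one_formulation_out(ds)
  report$folds <- folds
  summary$n_folds <- nrow(folds)

  # --- ann sweep ------------------------------------------------------------
  ensemble <- NULL
  if (isTRUE(cfg$stages$ann)) {
    inputs <- cfg$ann$inputs
    spec <- scaling_spec(ds, variables = c(inputs, "Q_pct"),
                         target_min = if (cfg$ann$activation == "logistic") 0.2 else -0.8,
                         target_max = 0.8)
    train_s <- scale_linear(folds$train[[1]], spec)
    test_s <- scale_linear(folds$test[[1]], spec)
    models <- list()
    scores <- numeric(0)
    for (j in seq_along(cfg$ann$architectures)) {
      arch <- unlist(cfg$ann$architectures[[j]])
      pipeline_log(verbose, "ann", "training %s-net (%s), %d epochs",
                   paste(arch, collapse = "-"), cfg$ann$activation,
                   cfg$ann$max_epochs)
      mcfg <- mlp_config(hidden = arch, activation = cfg$ann$activation,
                         max_epochs = cfg$ann$max_epochs,
                         seed = derive_seed(cfg$seed, 100 + j))
      tr <- mlp_train(train_s, mcfg, test = test_s, inputs = inputs)
      best <- select_best_snapshot(tr$trace, "test_rmse")
      models[[j]] <- best
      scores[j] <- min(tr$trace$test_rmse, na.rm = TRUE)
    }
    keep <- order(scores)[seq_len(min(cfg$ann$n_best, length(models)))]
    ensemble <- models[keep]
    report$ann <- list(models = ensemble, test_rmse = scores[keep])
    summary$ann <- list(n_models = length(ensemble),
                        best_test_rmse = min(scores))
    pipeline_log(verbose, "ann", "best held-out RMSE %.4g (scaled units)",
                 min(scores))
  }

  # --- sensitivity ----------------------------------------------------------
  retained <- cfg$ann$inputs
  if (isTRUE(cfg$stages$sensitivity)) {
    ranking <- collective_sensitivity(ensemble, ds,
                                      aggregate = cfg$sensitivity$aggregate)
    retained <- reduce_inputs(ranking, threshold = cfg$sensitivity$threshold)
    report$sensitivity <- ranking
    summary$sensitivity <- list(
      scores = setNames(as.list(ranking$mean_score), ranking$input),
      retained = retained)
    pipeline_log(verbose, "sensitivity", "retained inputs: %s",
                 paste(retained, collapse = ", "))
  }

  gp_terminals <- c(d = "d_mm", L = "L_mm", t = "t_min")
  if (isTRUE(cfg$gp$use_reduced_inputs)) {
    gp_terminals <- gp_terminals[gp_terminals %in% retained]
  }

  # --- direct GP ------------------------------------------------------------
  if (isTRUE(cfg$stages$gp_direct)) {
    pipeline_log(verbose, "gp-direct", "evolving Q = f(%s), population %d",
                 paste(names(gp_terminals), collapse = ", "),
                 cfg$gp$population_size)
    gcfg <- gp_config(population_size = cfg$gp$population_size,
                      max_generations = cfg$gp$max_generations,
                      size_limit = cfg$gp$size_limit,
                      seed = derive_seed(cfg$seed, 200))
    direct <- evolve_direct(ds, gcfg, terminals = gp_terminals)
    report$gp_direct <- direct
    summary$gp_direct <- list(expression = direct$expression,
                              rmse = direct$rmse,
                              generations = direct$generations)
    pipeline_log(verbose, "gp-direct", "RMSE %.4g: %s", direct$rmse,
                 direct$expression)
  }

  # --- indirect GP ----------------------------------------------------------
  if (isTRUE(cfg$stages$gp_indirect)) {
    wt <- ds |>
      dplyr::group_by(.data$formulation_id, .data$d_mm, .data$L_mm) |>
      dplyr::group_modify(function(df, key) {
        f <- fit_weibull_profile(df)
        tibble(A = f$A, K = f$K, profile_rmse = f$rmse)
      }) |>
      dplyr::ungroup()
    geo_terms <- gp_terminals[gp_terminals %in% c("d_mm", "L_mm")]
    if (length(geo_terms) == 0) geo_terms <- c(d = "d_mm")
    pipeline_log(verbose, "gp-indirect",
                 "evolving A and K maps over (%s) from %d profiles",
                 paste(names(geo_terms), collapse = ", "), nrow(wt))
    gcfg <- gp_config(population_size = cfg$gp$population_size,
                      max_generations = cfg$gp$max_generations,
                      size_limit = cfg$gp$size_limit,
                      seed = derive_seed(cfg$seed, 300))
    indirect <- evolve_indirect(wt, gcfg, terminals = geo_terms)
    report$weibull_table <- wt
    report$gp_indirect <- indirect
    summary$gp_indirect <- list(
      A = list(expression = indirect$A$expression, rmse = indirect$A$rmse),
      K = list(expression = indirect$K$expression, rmse = indirect$K$rmse))
    pipeline_log(verbose, "gp-indirect", "A: %s (RMSE %.4g); K: %s (RMSE %.4g)",
                 indirect$A$expression, indirect$A$rmse,
                 indirect$K$expression, indirect$K$rmse)
  }

  # --- cross-validated fitting ---------------------------------------------
  if (isTRUE(cfg$stages$crossval)) {
    pipeline_log(verbose, "crossval", "fitting %s on %d folds (%s data)",
                 cfg$fit$equation_id, nrow(folds), cfg$fit$preprocessing)
    cv <- crossval_fit(cfg$fit$equation_id, folds,
                       preprocessing = cfg$fit$preprocessing,
                       seed = derive_seed(cfg$seed, 400),
                       sann_maxit = cfg$fit$sann_maxit)
    report$crossval <- cv
    summary$crossval <- list(
      equation_id = cv$equation_id,
      pooled_test_rmse = cv$pooled_test_rmse,
      cv_percent = as.list(cv$cv_percent),
      params = lapply(seq_along(cv$fits), function(i) cv$fits[[i]]$params))
    pipeline_log(verbose, "crossval", "pooled test RMSE %.4g",
                 cv$pooled_test_rmse)
  }

  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(summary, file.path(cfg$output_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    pipeline_log(verbose, "report", "summary written to %s",
                 file.path(cfg$output_dir, "summary.json"))
  }
  report$summary <- summary
  class(report) <- "pipeline_report"
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report> stages run: ",
      paste(setdiff(names(x), "summary"), collapse = ", "), "\n", sep = "")
  invisible(x)
}
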