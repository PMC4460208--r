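# De-novo parameter fitting of the registered release equations: a global
# simulated-annealing stage started from constant parameter values (0.1),
# followed by a suite of local optimizers each launched independently from
# the annealing optimum (no follow-on chaining); the winner is the lowest
# training RMSE. On top of that, the leave-one-formulation-out
# cross-validated fitting protocol with per-parameter CV% stability.

.local_methods <- c("Nelder-Mead", "BFGS", "CG", "L-BFGS-B", "nlminb",
                    "hooke-jeeves")

fit_objective <- function(equation_id, ds, variant, K_variant) {
  d <- as.numeric(ds$d_mm)
  t <- as.numeric(ds$t_min)
  q <- as.numeric(ds$Q_pct)
  entry <- .equation_registry[[equation_id]]
  function(par) {
    pred <- tryCatch(
      if (equation_id == "eq_indirect") {
        entry$fn(par, d, t, variant = variant, K_variant = K_variant)
      } else {
        entry$fn(par, d, t)
      },
      error = function(e) NULL, warning = function(w) NULL
    )
    if (is.null(pred)) return(1e10)
    v <- sqrt(mean((pred - q)^2))
    if (!is.finite(v)) 1e10 else v
  }
}

run_local_method <- function(method, par0, obj) {
  res <- tryCatch(
    switch(method,
      "nlminb" = {
        r <- nlminb(par0, obj)
        list(par = r$par, value = r$objective, convergence = r$convergence)
      },
      "hooke-jeeves" = {
        r <- pracma::hooke_jeeves(par0, obj)
        list(par = r$xmin, value = r$fmin, convergence = 0L)
      },
      {
        r <- optim(par0, obj, method = method,
                   control = list(maxit = 1000))
        list(par = r$par, value = r$value, convergence = r$convergence)
      }
    ),
    error = function(e) NULL
  )
  if (is.null(res) || !all(is.finite(res$par)) || !is.finite(res$value)) {
    return(NULL)
  }
  res
}

#' Multistage fit of a release equation to a dataset
#'
#' Stage 1 is simulated annealing (`optim` method `"SANN"`) started from
#' all parameters equal to `init_value` (0.1); stage 2 launches each local
#' optimizer independently from the stage-1 optimum — Nelder-Mead, BFGS,
#' CG, L-BFGS-B, `nlminb` (PORT) and the Hooke-Jeeves pattern search — and
#' the winner is the parameter vector with the lowest training RMSE. The
#' final RMSE can therefore never exceed the annealing-stage RMSE. If all
#' local methods fail, the annealing result is returned flagged as
#' degraded.
#'
#' @param equation_id A registered equation id (see [list_equations()]).
#' @param ds Training dissolution dataset.
#' @param init_value Common starting value of every parameter; default 0.1.
#' @param seed Integer seed driving the annealing proposals.
#' @param sann_maxit,sann_temp Annealing schedule: function evaluations and
#'   initial temperature (geometric cooling as in `optim`).
#' @param test Optional held-out dataset; when given, the winner's RMSE on
#'   it is reported as `test_rmse`.
#' @param variant,K_variant Passed to the `eq_indirect` family.
#' @return An object of class `dissolution_fit`: equation id, fitted
#'   `params`, `train_rmse`, optional `test_rmse`, `winning_method`,
#'   `degraded` flag and a `stages` tibble tracing every method tried.
#' @export
multistage_fit <- function(equation_id, ds, init_value = 0.1, seed = 1,
                           sann_maxit = 10000, sann_temp = 10,
                           test = NULL, variant = "power",
                           K_variant = "ratio") {
  assert_that(equation_id %in% names(.equation_registry),
              paste0("unknown equation id '", equation_id, "'"),
              "dissolvegp_argument_error")
  assert_that(is.data.frame(ds) && nrow(ds) > 0, "ds must be nonempty",
              "dissolvegp_argument_error")
  arity <- .equation_registry[[equation_id]]$arity
  obj <- fit_objective(equation_id, ds, variant, K_variant)
  par0 <- rep(init_value, arity)

  sann <- with_seed(seed, {
    optim(par0, obj, method = "SANN",
          control = list(maxit = sann_maxit, temp = sann_temp))
  })

  stages <- tibble(stage = "global", method = "SANN",
                   rmse = sann$value, converged = TRUE)
  best <- list(par = sann$par, value = sann$value, method = "SANN")
  any_local <- FALSE
  for (method in .local_methods) {
    res <- run_local_method(method, sann$par, obj)
    if (is.null(res)) {
      stages <- dplyr::bind_rows(stages, tibble(
        stage = "local", method = method, rmse = NA_real_, converged = FALSE))
      next
    }
    any_local <- TRUE
    stages <- dplyr::bind_rows(stages, tibble(
      stage = "local", method = method, rmse = res$value,
      converged = res$convergence == 0))
    if (res$value < best$value) {
      best <- list(par = res$par, value = res$value, method = method)
    }
  }

  test_rmse <- NULL
  if (!is.null(test)) {
    m <- equation_model(equation_id, best$par, variant = variant,
                        K_variant = K_variant)
    pred <- eval_equation(m, test$d_mm, test$t_min)
    test_rmse <- sqrt(mean((pred - test$Q_pct)^2))
  }

  structure(
    list(equation_id = equation_id, params = best$par,
         train_rmse = best$value, test_rmse = test_rmse,
         winning_method = best$method, degraded = !any_local,
         stages = stages, variant = variant, K_variant = K_variant,
         n = nrow(ds)),
    class = "dissolution_fit"
  )
}

#' @export
print.dissolution_fit <- function(x, ...) {
  cat("<dissolution_fit> ", x$equation_id, "\n", sep = "")
  cat("  params: ", paste(signif(x$params, 6), collapse = ", "), "\n", sep = "")
  cat(sprintf("  train RMSE %.4g (winner: %s%s)", x$train_rmse,
              x$winning_method, if (x$degraded) ", degraded" else ""))
  if (!is.null(x$test_rmse)) cat(sprintf(", test RMSE %.4g", x$test_rmse))
  cat("\n")
  invisible(x)
}

#' @rdname multistage_fit
#' @param x A `dissolution_fit`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.dissolution_fit <- function(x, ...) {
  tibble(term = paste0("c", seq_along(x$params)), estimate = x$params)
}

#' @rdname multistage_fit
#' @exportS3Method generics::glance
glance.dissolution_fit <- function(x, ...) {
  tibble(
    equation_id = x$equation_id,
    train_rmse = x$train_rmse,
    test_rmse = if (is.null(x$test_rmse)) NA_real_ else x$test_rmse,
    winning_method = x$winning_method,
    degraded = x$degraded,
    n = x$n
  )
}

#' As an eq_model
#'
#' @param fit A `dissolution_fit`.
#' @return The fitted equation as an [equation_model()].
#' @export
as_equation_model <- function(fit) {
  assert_that(inherits(fit, "dissolution_fit"), "fit must be a dissolution_fit")
  equation_model(fit$equation_id, fit$params, variant = fit$variant,
                 K_variant = fit$K_variant)
}

#' Cross-validated equation fitting
#'
#' Runs [multistage_fit()] on every leave-one-formulation-out fold:
#' the training member is preprocessed as requested (the test member is
#' never touched, preserving a pure generalization assessment), the fitted
#' equation is evaluated on the held-out formulation, and parameter
#' stability is summarized as the per-parameter coefficient of variation
#' across folds. The pooled test RMSE is computed over the concatenated
#' per-fold prediction/observation pairs.
#'
#' @param equation_id A registered equation id.
#' @param folds Fold table from [split_leave_one_formulation_out()].
#' @param preprocessing One of `"original"`, `"noised"`, `"balanced"`,
#'   `"enhanced"`.
#' @param noise_amplitude Relative amplitude for `"noised"`.
#' @param predictor_builder For `"enhanced"`: a function
#'   `f(train, test, fold_index)` returning a predictor accepted by
#'   [build_enhanced_dataset()]. Required for that mode.
#' @param seed Top-level seed; per-fold seeds are derived from it.
#' @param ... Further arguments to [multistage_fit()] (e.g. `sann_maxit`).
#' @return An object of class `dissolution_cv`: per-fold fits, the
#'   parameter table, per-parameter `cv_percent`, pooled and per-fold test
#'   RMSE, and the concatenated predictions.
#' @export
crossval_fit <- function(equation_id, folds,
                         preprocessing = c("original", "noised", "balanced",
                                           "enhanced"),
                         noise_amplitude = 0.05, predictor_builder = NULL,
                         seed = 1, ...) {
  preprocessing <- match.arg(preprocessing)
  assert_that(is.data.frame(folds) && all(c("train", "test") %in% names(folds)),
              "folds must come from split_leave_one_formulation_out()",
              "dissolvegp_argument_error")
  if (preprocessing == "enhanced") {
    assert_that(is.function(predictor_builder),
                "preprocessing = 'enhanced' needs a predictor_builder function",
                "dissolvegp_dependency_error")
  }
  n_folds <- nrow(folds)
  fits <- vector("list", n_folds)
  preds <- vector("list", n_folds)
  for (i in seq_len(n_folds)) {
    train <- folds$train[[i]]
    test <- folds$test[[i]]
    fold_seed <- derive_seed(seed, i)
    train_pp <- switch(preprocessing,
      original = train,
      noised = add_noise(train, amplitude = noise_amplitude, seed = fold_seed),
      balanced = balance_by_output(train),
      enhanced = build_enhanced_dataset(
        train, predictor_builder(train, test, i), test = test)
    )
    fit <- multistage_fit(equation_id, train_pp, seed = fold_seed,
                          test = test, ...)
    fits[[i]] <- fit
    m <- as_equation_model(fit)
    preds[[i]] <- tibble(
      fold = i,
      held_out_formulation = folds$held_out_formulation[i],
      d_mm = test$d_mm, t_min = test$t_min,
      observed = test$Q_pct,
      predicted = eval_equation(m, test$d_mm, test$t_min)
    )
  }
  predictions <- dplyr::bind_rows(preds)
  params <- do.call(rbind, lapply(fits, function(f) f$params))
  colnames(params) <- paste0("c", seq_len(ncol(params)))
  param_tbl <- dplyr::bind_cols(
    tibble(fold = seq_len(n_folds),
           held_out_formulation = folds$held_out_formulation),
    as_tibble(params)
  )
  cv <- if (n_folds >= 2) apply(params, 2, cv_percent) else
    setNames(rep(NA_real_, ncol(params)), colnames(params))
  pooled <- sqrt(mean((predictions$predicted - predictions$observed)^2))
  structure(
    list(equation_id = equation_id, preprocessing = preprocessing,
         fits = fits, params = param_tbl, cv_percent = cv,
         fold_test_rmse = vapply(fits, function(f) f$test_rmse, numeric(1)),
         pooled_test_rmse = pooled, predictions = predictions),
    class = "dissolution_cv"
  )
}

#' @export
print.dissolution_cv <- function(x, ...) {
  cat("<dissolution_cv> ", x$equation_id, " on ", length(x$fits),
      " fold(s), preprocessing = ", x$preprocessing, "\n", sep = "")
  cat(sprintf("  pooled test RMSE %.4g\n", x$pooled_test_rmse))
  cat("  per-parameter CV%: ",
      paste(sprintf("%s = %.2f%%", names(x$cv_percent), x$cv_percent),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @rdname crossval_fit
#' @param x A `dissolution_cv`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.dissolution_cv <- function(x, ...) {
  out <- x$params
  out$train_rmse <- vapply(x$fits, function(f) f$train_rmse, numeric(1))
  out$test_rmse <- x$fold_test_rmse
  out
}

#' @rdname crossval_fit
#' @exportS3Method generics::glance
glance.dissolution_cv <- function(x, ...) {
  cvs <- as.list(setNames(x$cv_percent,
                          paste0("cv_", names(x$cv_percent), "_pct")))
  dplyr::bind_cols(
    tibble(equation_id = x$equation_id, preprocessing = x$preprocessing,
           n_folds = length(x$fits), pooled_test_rmse = x$pooled_test_rmse),
    as_tibble(cvs)
  )
}
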