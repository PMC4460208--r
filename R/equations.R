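# Registry of closed-form release equations.
#
# Every entry maps a parameter vector c and the point (d, t) to cumulative
# release Q (%). Two of the printed forms (eq7_direct, eq_previous) come
# from flattened typography; the parse used here is documented in the
# methods vignette and they are validated for finiteness on the study
# domain rather than for point values.

.equation_registry <- list(
  weibull = list(
    arity = 2,
    description = "Weibull release model: Q = 100*(1 - exp(-(t/A)^K)); params (A, K)",
    fn = function(params, d, t) {
      weibull_Q(t, A = params[1], K = params[2])
    }
  ),
  eq7_direct = list(
    arity = 3,
    description = paste(
      "Direct symbolic-regression release equation:",
      "Q = ln(d) + d + (c1*t + c2) / (t + c3*d^2 + d^2)"
    ),
    fn = function(params, d, t) {
      log(d) + d + (params[1] * t + params[2]) / (t + params[3] * d^2 + d^2)
    }
  ),
  eq_indirect = list(
    arity = 3,
    description = paste(
      "Weibull with diameter-dependent constants:",
      "K = c1*d/(d + c2*d), A = c3^d (variants: A = c3*d; K = c1*d/(d + c2))"
    ),
    fn = function(params, d, t, variant = c("power", "linear"),
                  K_variant = c("ratio", "shifted")) {
      ak <- .indirect_AK(params, d, match.arg(variant), match.arg(K_variant))
      100 * (1 - exp(-(t / ak$A)^ak$K))
    }
  ),
  weibull_diffusion = list(
    arity = 3,
    description = paste(
      "Weibull with diffusion-like constants:",
      "A = c3*d^2, K = c1*d/(d + c2); the synthetic ground-truth family"
    ),
    fn = function(params, d, t) {
      A <- params[3] * d^2
      K <- params[1] * d / (d + params[2])
      100 * (1 - exp(-(t / A)^K))
    }
  ),
  eq_previous = list(
    arity = 6,
    description = paste(
      "Earlier mechanistically-derived release equation:",
      "Q = 100*(1 - exp(-(t/(c5^d + c6))^exp(c1*d + c2*d*ln(c3*d) + c4)))"
    ),
    fn = function(params, d, t) {
      A <- params[5]^d + params[6]
      K <- exp(params[1] * d + params[2] * d * log(params[3] * d) + params[4])
      100 * (1 - exp(-(t / A)^K))
    }
  )
)

.indirect_AK <- function(params, d, variant = "power", K_variant = "ratio") {
  A <- switch(variant,
    power = params[3]^d,
    linear = params[3] * d,
    abort("unknown A variant", class = "dissolvegp_argument_error")
  )
  K <- switch(K_variant,
    ratio = params[1] * d / (d + params[2] * d),
    shifted = params[1] * d / (d + params[2]),
    abort("unknown K variant", class = "dissolvegp_argument_error")
  )
  list(A = A, K = K)
}

#' Closed-form release equations available for fitting
#'
#' @return A tibble with one row per registered equation: its id, the
#'   number of adjustable parameters, and a human-readable description of
#'   the functional form.
#' @export
list_equations <- function() {
  tibble(
    equation_id = names(.equation_registry),
    n_params = vapply(.equation_registry, function(e) as.integer(e$arity),
                      integer(1)),
    description = vapply(.equation_registry, function(e) e$description, character(1))
  )
}

#' Construct an equation model
#'
#' Pairs a registered equation id with a parameter vector, checked against
#' the registry arity before any evaluation.
#'
#' @param equation_id One of `list_equations()$equation_id`.
#' @param params Numeric parameter vector of the registered length.
#' @param variant For `eq_indirect`, the parse of the time-scale map:
#'   `"power"` (A = c3^d, default) or `"linear"` (A = c3*d).
#' @param K_variant For `eq_indirect`, the parse of the shape map:
#'   `"ratio"` (K = c1*d/(d + c2*d), default) or `"shifted"`
#'   (K = c1*d/(d + c2)).
#' @return An object of class `eq_model`.
#' @examples
#' m <- equation_model("weibull", c(A = 100, K = 0.8))
#' eval_equation(m, d = 1, t = 100)
#' @export
equation_model <- function(equation_id, params, variant = "power",
                           K_variant = "ratio") {
  assert_that(equation_id %in% names(.equation_registry),
              paste0("unknown equation id '", equation_id, "'"),
              "dissolvegp_argument_error")
  entry <- .equation_registry[[equation_id]]
  params <- as.numeric(params)
  assert_that(length(params) == entry$arity,
              sprintf("equation '%s' takes %d parameters, got %d",
                      equation_id, entry$arity, length(params)),
              "dissolvegp_parameter_error")
  structure(
    list(equation_id = equation_id, params = params,
         variant = variant, K_variant = K_variant),
    class = "eq_model"
  )
}

#' @export
print.eq_model <- function(x, ...) {
  cat("<eq_model> ", x$equation_id, "\n", sep = "")
  cat("  params: ", paste(signif(x$params, 6), collapse = ", "), "\n", sep = "")
  cat("  ", .equation_registry[[x$equation_id]]$description, "\n", sep = "")
  invisible(x)
}

#' Evaluate the Weibull release model
#'
#' \eqn{Q = 100 (1 - e^{-(t/A)^K})} with time-scale constant A (min) and
#' dimensionless shape constant K. Q is 0 at t = 0, reaches
#' \eqn{100(1-e^{-1}) \approx 63.2} at t = A, and is bounded by 100.
#'
#' @param t Time, min (vectorized).
#' @param A Time-scale constant, > 0.
#' @param K Shape constant, > 0.
#' @return Cumulative percent released at each `t`.
#' @export
weibull_Q <- function(t, A, K) {
  assert_that(all(is.finite(c(A, K))) && A > 0 && K > 0,
              "Weibull constants A and K must be positive",
              "dissolvegp_parameter_error")
  assert_that(all(t >= 0), "t must be nonnegative")
  100 * (1 - exp(-(t / A)^K))
}

#' Evaluate a registered release equation at (d, t)
#'
#' @param m An `eq_model`.
#' @param d Extrudate diameter, mm (vectorized, recycled against `t`).
#' @param t Time, min.
#' @return Numeric vector of Q (%) values.
#' @export
eval_equation <- function(m, d, t) {
  assert_that(inherits(m, "eq_model"), "m must be an eq_model")
  entry <- .equation_registry[[m$equation_id]]
  if (m$equation_id == "eq_indirect") {
    entry$fn(m$params, d, t, variant = m$variant, K_variant = m$K_variant)
  } else {
    entry$fn(m$params, d, t)
  }
}

#' Weibull constants implied by an indirect model at a diameter
#'
#' For the indirect equation families the release curve is a Weibull model
#' whose constants depend on the diameter; this returns that (A, K) pair so
#' the composition can be inspected (and tested) directly.
#'
#' @param m An `eq_model` with id `eq_indirect` or `weibull_diffusion`.
#' @param d Diameter(s), mm.
#' @return A tibble with columns `d`, `A`, `K`.
#' @export
weibull_constants <- function(m, d) {
  assert_that(inherits(m, "eq_model"), "m must be an eq_model")
  if (m$equation_id == "eq_indirect") {
    ak <- .indirect_AK(m$params, d, m$variant, m$K_variant)
  } else if (m$equation_id == "weibull_diffusion") {
    ak <- list(A = m$params[3] * d^2, K = m$params[1] * d / (d + m$params[2]))
  } else {
    abort("weibull_constants is defined for the indirect equation families",
          class = "dissolvegp_argument_error")
  }
  tibble(d = d, A = ak$A, K = ak$K)
}

#' Fit the Weibull model to a single dissolution profile
#'
#' Least-squares estimation of (A, K) for one formulation's profile,
#' minimizing the RMSE of [weibull_Q()] against the observed points. The
#' search runs on log(A), log(K) (enforcing positivity) by BFGS from a
#' landmark start: A at the time the profile crosses 63.2% release
#' (interpolated), K = 1.
#'
#' @param profile A data frame with columns `t_min` and `Q_pct` for one
#'   formulation; at least 3 distinct time points.
#' @return An object of class `weibull_fit`: list with `A`, `K`, `rmse`,
#'   `n`, and `converged`.
#' @export
fit_weibull_profile <- function(profile) {
  assert_that(is.data.frame(profile) && all(c("t_min", "Q_pct") %in% names(profile)),
              "profile must have columns t_min and Q_pct")
  t <- as.numeric(profile$t_min)
  Q <- as.numeric(profile$Q_pct)
  keep <- t > 0
  assert_that(length(unique(t)) >= 3,
              "profile needs at least 3 distinct time points",
              "dissolvegp_argument_error")
  assert_that(all(Q >= 0 & Q <= 110), "Q must lie in [0, 110]")
  if (diff(range(Q)) == 0) {
    abort("degenerate profile: all Q values identical",
          class = "dissolvegp_degenerate_profile_error")
  }
  t <- t[keep]
  Q <- Q[keep]

  # landmark start: time of 63.2% release, linearly interpolated
  target <- 100 * (1 - exp(-1))
  A0 <- if (max(Q) >= target) {
    i <- which(Q >= target)[1]
    if (i == 1) t[1] else {
      t[i - 1] + (target - Q[i - 1]) * (t[i] - t[i - 1]) / (Q[i] - Q[i - 1])
    }
  } else {
    # slow-releasing profile: extrapolate the scale from the last point
    ft <- pmin(max(Q[length(Q)], 1e-3) / 100, 0.999)
    t[length(t)] / (-log(1 - ft))
  }
  A0 <- max(A0, min(t[t > 0]) / 10)

  obj <- function(lp) {
    pred <- 100 * (1 - exp(-(t / exp(lp[1]))^exp(lp[2])))
    v <- sqrt(mean((pred - Q)^2))
    if (!is.finite(v)) 1e10 else v
  }
  fit <- optim(c(log(A0), 0), obj, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-12))
  # polish with Nelder-Mead in case BFGS stalled on a flat ridge
  fit2 <- optim(fit$par, obj, method = "Nelder-Mead",
                control = list(maxit = 2000, reltol = 1e-14))
  best <- if (fit2$value < fit$value) fit2 else fit
  structure(
    list(A = exp(best$par[1]), K = exp(best$par[2]), rmse = best$value,
         n = length(t), converged = best$convergence == 0),
    class = "weibull_fit"
  )
}

#' @export
print.weibull_fit <- function(x, ...) {
  cat(sprintf("<weibull_fit> A = %.4g min, K = %.4g, RMSE = %.4g (n = %d)\n",
              x$A, x$K, x$rmse, x$n))
  invisible(x)
}

#' @rdname fit_weibull_profile
#' @param x A `weibull_fit`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.weibull_fit <- function(x, ...) {
  tibble(term = c("A", "K"), estimate = c(x$A, x$K))
}

#' Serialize an equation model to JSON
#'
#' @param m An `eq_model`.
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to a file.
#' @export
equation_to_json <- function(m, path = NULL) {
  assert_that(inherits(m, "eq_model"), "m must be an eq_model")
  x <- list(equation_id = m$equation_id, params = m$params,
            variant = m$variant, K_variant = m$K_variant)
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' @rdname equation_to_json
#' @param json A JSON string or file path produced by [equation_to_json()].
#' @export
equation_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  equation_model(x$equation_id, x$params,
                 variant = x$variant %||% "power",
                 K_variant = x$K_variant %||% "ratio")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
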