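# Input-importance screening of trained networks: the mean absolute
# output-input derivative per input (exact Jacobian through the layers),
# aggregated over an ensemble of the best networks. Used to reduce the
# input vector from (d, L, t) to (d, t).

# Exact Jacobian dY/dX (n x p) of the network at every record.
mlp_jacobian <- function(weights, X, activation) {
  act <- .activations[[activation]]
  fwd <- mlp_forward_matrix(weights, X, activation, keep = TRUE)
  L <- length(weights)
  D <- act$grad(fwd$pre[[L]])            # n x 1
  D <- matrix(D, ncol = 1)
  for (l in seq(L, 2)) {
    Wl <- weights[[l]][, -ncol(weights[[l]]), drop = FALSE]
    D <- (D %*% Wl) * act$grad(fwd$pre[[l - 1]])
  }
  D %*% weights[[1]][, -ncol(weights[[1]]), drop = FALSE]
}

#' Input sensitivity of a trained network
#'
#' Scores each input by the mean over records of the absolute derivative
#' of the network output with respect to that input (exact chain-rule
#' Jacobian), normalized to sum to one. Derivatives are taken in the
#' network's own (scaled) input space so the scores are unit-free; when
#' the model carries a scaling spec, `ds` may be given in original units
#' and is scaled first.
#'
#' @param m An `mlp_model`.
#' @param ds Dataset holding the model's input columns.
#' @return A named numeric vector of nonnegative scores summing to 1.
#' @export
input_sensitivity <- function(m, ds) {
  assert_that(inherits(m, "mlp_model"), "m must be an mlp_model")
  missing_cols <- setdiff(m$inputs, names(ds))
  assert_that(length(missing_cols) == 0,
              paste0("ds lacks model input(s): ",
                     paste(missing_cols, collapse = ", ")),
              "dissolvegp_shape_error")
  X <- as.matrix(as.data.frame(ds)[, m$inputs, drop = FALSE])
  spec <- m$scaling
  if (!is.null(spec)) {
    for (j in seq_along(m$inputs)) {
      row <- spec[spec$variable == m$inputs[j], ]
      if (nrow(row) == 1) {
        X[, j] <- row$target_min + (X[, j] - row$source_min) *
          (row$target_max - row$target_min) / (row$source_max - row$source_min)
      }
    }
  }
  J <- mlp_jacobian(m$weights, X, m$activation)
  score <- colMeans(abs(J))
  total <- sum(score)
  if (total > 0) score <- score / total
  setNames(score, m$inputs)
}

#' Collective sensitivity ranking over a network ensemble
#'
#' Aggregates per-model normalized sensitivity scores across a set of the
#' best trained networks (rather than trusting a single model) and ranks
#' the inputs. Aggregation is the mean of the normalized scores by
#' default; `"rank_mean"` averages per-model ranks instead.
#'
#' @param models List of `mlp_model`s sharing the same input vector.
#' @param ds Dataset for the derivative evaluation.
#' @param aggregate `"mean"` (default) or `"rank_mean"`.
#' @return A tibble of class `sensitivity_ranking`: one row per input with
#'   `input`, `mean_score`, `rank` (1 = most important), sorted by rank.
#'   Ties are broken by input order.
#' @export
collective_sensitivity <- function(models, ds, aggregate = c("mean", "rank_mean")) {
  aggregate <- match.arg(aggregate)
  if (inherits(models, "mlp_model")) models <- list(models)
  assert_that(is.list(models) && length(models) >= 1,
              "models must be a nonempty list of mlp_model objects",
              "dissolvegp_argument_error")
  inputs <- models[[1]]$inputs
  for (m in models) {
    assert_that(identical(m$inputs, inputs),
                "all models must share the same input vector",
                "dissolvegp_shape_error")
  }
  scores <- vapply(models, input_sensitivity, numeric(length(inputs)), ds = ds)
  scores <- matrix(scores, nrow = length(inputs))
  mean_score <- rowMeans(scores)
  key <- if (aggregate == "mean") {
    -mean_score
  } else {
    rowMeans(apply(-scores, 2, rank, ties.method = "first"))
  }
  ord <- order(key, seq_along(inputs))
  out <- tibble(
    input = inputs,
    mean_score = mean_score,
    rank = match(seq_along(inputs), ord)
  )
  out <- dplyr::arrange(out, .data$rank)
  attr(out, "input_order") <- inputs
  class(out) <- c("sensitivity_ranking", class(out))
  out
}

#' Reduce the input vector by sensitivity threshold
#'
#' Retains the inputs whose mean collective score reaches `threshold`
#' (default 5% of the total derivative mass), preserving the original
#' input order — the screening step that discards the extrudate length.
#'
#' @param ranking A `sensitivity_ranking` from [collective_sensitivity()].
#' @param threshold Minimum mean score to keep an input; default 0.05.
#' @return Character vector of retained input names in original order.
#' @export
reduce_inputs <- function(ranking, threshold = 0.05) {
  assert_that(inherits(ranking, "sensitivity_ranking"),
              "ranking must come from collective_sensitivity()")
  assert_that(threshold >= 0, "threshold must be nonnegative",
              "dissolvegp_argument_error")
  keep <- ranking$input[ranking$mean_score >= threshold]
  assert_that(length(keep) > 0,
              "all inputs fall below the sensitivity threshold",
              "dissolvegp_reduction_error")
  original_order <- attr(ranking, "input_order") %||% ranking$input
  keep[order(match(keep, original_order))]
}
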