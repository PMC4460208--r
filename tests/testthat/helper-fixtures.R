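# Shared fixtures and independent oracles, all built in code.

# One noiseless Weibull profile as a dissolution tibble.
make_weibull_profile <- function(A, K, d = 1, L = 10, id = "P1",
                                 t = seq(5, 1000, by = 5)) {
  tibble::tibble(
    formulation_id = id, d_mm = d, L_mm = L, t_min = t,
    Q_pct = 100 * (1 - exp(-(t / A)^K))
  )
}

# Independent straight-loop RMSE (oracle for the vectorized version).
rmse_loop <- function(obs, pred) {
  acc <- 0
  for (i in seq_along(obs)) acc <- acc + (pred[i] - obs[i])^2
  sqrt(acc / length(obs))
}

# Independent re-evaluator for GP trees: plain recursion with the same
# protection contract, written without reusing package internals.
eval_tree_oracle <- function(tree, bindings) {
  rec <- function(nd) {
    if (nd$type == "const") return(nd$value)
    if (nd$type == "var") return(bindings[[nd$name]])
    a <- rec(nd$args[[1]])
    v <- if (nd$op %in% c("+", "-", "*", "/", "pow")) {
      b <- rec(nd$args[[2]])
      if (nd$op == "+") a + b
      else if (nd$op == "-") a - b
      else if (nd$op == "*") a * b
      else if (nd$op == "/") ifelse(b == 0, 1, a / b)
      else {
        base <- abs(a)
        r <- ifelse(base == 0, ifelse(b > 0, 0, 1),
                    exp(pmin(pmax(b * log(ifelse(base == 0, 1, base)), -500),
                             500)))
        r
      }
    } else if (nd$op == "ln") {
      ifelse(a == 0, 0, log(abs(a)))
    } else if (nd$op == "sqrt") {
      sqrt(abs(a))
    } else {
      exp(pmin(a, 500))
    }
    pmin(pmax(v, -1e150), 1e150)
  }
  rec(tree)
}

# Independent loop-based grid axis builder (oracle for the enhancement
# grid): walk from lo in fixed steps while within the extended bound.
grid_axis_loop <- function(v, step_frac, extend) {
  lo <- min(v)
  hi <- extend * max(v)
  step <- step_frac * (max(v) - min(v))
  out <- c()
  x <- lo
  while (x <= hi + 1e-9 * step) {
    out <- c(out, x)
    x <- x + step
  }
  if (hi - out[length(out)] > 1e-9 * step) out <- c(out, hi)
  out
}

# Histogram bin counts over equal-width Q bins (oracle for balancing).
q_bin_counts <- function(q, n_bins = 10) {
  breaks <- seq(min(q), max(q), length.out = n_bins + 1)
  counts <- tabulate(cut(q, breaks = breaks, include.lowest = TRUE,
                         labels = FALSE), nbins = n_bins)
  counts[counts > 0]
}

# Train a small ensemble on study-shaped data whose length column has
# been shuffled record-wise (so L is planted noise), and return the
# collective ranking. Used by the screening tests.
planted_irrelevance_ranking <- function(seed, max_epochs = 8000) {
  ds <- simulate_profiles(noise_sd = 1, seed = seed * 1000 + 1)
  set.seed(seed * 1000 + 2)
  ds$L_mm <- sample(ds$L_mm)
  spec <- scaling_spec(ds)
  folds <- split_leave_one_formulation_out(ds)
  train_s <- scale_linear(folds$train[[1]], spec)
  test_s <- scale_linear(folds$test[[1]], spec)
  models <- lapply(c(4, 6, 8), function(h) {
    fit <- mlp_train(train_s,
                     mlp_config(hidden = h, max_epochs = max_epochs,
                                seed = seed * 1000 + h),
                     test = test_s, inputs = c("d_mm", "L_mm", "t_min"))
    select_best_snapshot(fit$trace, "test_rmse")
  })
  collective_sensitivity(models, ds)
}

# Hand-construct a model with fixed weights (weights[[l]] is
# n_out x (n_in + 1), bias in the last column).
manual_mlp <- function(weights, activation = "tanh",
                       inputs = c("x1", "x2")) {
  cfg <- mlp_config(hidden = vapply(weights[-length(weights)], nrow,
                                    integer(1)),
                    activation = activation, max_epochs = 1)
  dissolvegp:::new_mlp_model(weights, cfg, inputs, "y", 0)
}
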