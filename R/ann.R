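# Multilayer perceptron engine with the training algorithm used for the
# dissolution surrogates: online (pattern-by-pattern) backpropagation with
# momentum, delta-bar-delta per-weight adaptive learning rates, and
# jog-of-weights noise restarts under a patience criterion, with weight
# snapshots taken at a schedule of stop points for later selection by
# generalization error.

.activations <- list(
  linear = list(
    fn = function(a) a,
    grad = function(a) rep(1, length(a)),
    range = c(-Inf, Inf)
  ),
  logistic = list(
    fn = function(a) 1 / (1 + exp(-a)),
    grad = function(a) { s <- 1 / (1 + exp(-a)); s * (1 - s) },
    range = c(0, 1)
  ),
  tanh = list(
    fn = function(a) tanh(a),
    grad = function(a) 1 - tanh(a)^2,
    range = c(-1, 1)
  ),
  # "fsr" logarithmic squashing: odd, unbounded, log-tempered growth
  fsr = list(
    fn = function(a) sign(a) * log1p(abs(a)),
    grad = function(a) 1 / (1 + abs(a)),
    range = c(-Inf, Inf)
  )
)

.default_stop_points <- c(5e3, 1e4, 1.5e4, 2e4, 3e4, 5e4, 1e5, 1.5e5, 2e5,
                          3e5, 5e5, 7.5e5, 1e6)

#' Configuration of an MLP surrogate and its training run
#'
#' Defaults follow the study's training protocol: momentum factor 0.3,
#' initial delta-bar-delta learning rate 0.65, a 100,000-epoch patience
#' before a jog-of-weights restart, snapshots at the standard stop-point
#' schedule, and single-pattern epochs (one weight update per randomly
#' drawn record).
#'
#' @param hidden Integer vector of hidden-layer widths (1 to 7 layers).
#' @param activation One of `"linear"`, `"logistic"`, `"tanh"`, `"fsr"`
#'   (logarithmic squashing `sign(a) log(1+|a|)`), applied to hidden and
#'   output units.
#' @param momentum Momentum factor in \[0, 1); default 0.3.
#' @param lr_init Initial per-weight learning rate; default 0.65.
#' @param patience_epochs Epochs without train-RMSE improvement before the
#'   weights are jogged; default 100,000.
#' @param stop_points Epoch counts at which weight snapshots are taken;
#'   points beyond `max_epochs` are dropped and the final epoch is always
#'   snapshotted.
#' @param max_epochs Total training epochs (single-record updates).
#' @param seed Integer seed for weight init, record draws and jogs.
#' @param dbd_kappa,dbd_phi,dbd_theta Delta-bar-delta hyperparameters:
#'   additive rate increase on consistent gradient sign, multiplicative
#'   decrease on a sign flip, and the exponential-trace decay.
#' @param jog_rel,jog_abs Jog noise half-width per weight:
#'   `max(jog_rel * |w|, jog_abs)`.
#' @param eval_every Epoch interval at which the full-train RMSE is
#'   evaluated for the patience criterion.
#' @return A validated list of class `mlp_config`.
#' @export
mlp_config <- function(hidden = c(5), activation = "tanh", momentum = 0.3,
                       lr_init = 0.65, patience_epochs = 1e5,
                       stop_points = .default_stop_points,
                       max_epochs = 1e6, seed = 1,
                       dbd_kappa = 0.01, dbd_phi = 0.9, dbd_theta = 0.7,
                       jog_rel = 0.1, jog_abs = 0.01, eval_every = 1000) {
  hidden <- as.integer(hidden)
  assert_that(length(hidden) >= 1 && length(hidden) <= 7,
              "hidden must name 1 to 7 layers", "dissolvegp_argument_error")
  assert_that(all(hidden >= 1), "hidden widths must be >= 1",
              "dissolvegp_argument_error")
  assert_that(activation %in% names(.activations),
              paste0("unknown activation '", activation, "'"),
              "dissolvegp_argument_error")
  assert_that(momentum >= 0 && momentum < 1, "momentum must be in [0, 1)",
              "dissolvegp_argument_error")
  assert_that(lr_init > 0, "lr_init must be positive", "dissolvegp_argument_error")
  stop_points <- sort(unique(as.double(stop_points)))
  stop_points <- stop_points[stop_points <= max_epochs]
  stop_points <- unique(c(stop_points, max_epochs))
  structure(
    list(hidden = hidden, activation = activation, momentum = momentum,
         lr_init = lr_init, patience_epochs = patience_epochs,
         stop_points = stop_points, max_epochs = max_epochs, seed = seed,
         dbd_kappa = dbd_kappa, dbd_phi = dbd_phi, dbd_theta = dbd_theta,
         jog_rel = jog_rel, jog_abs = jog_abs, eval_every = eval_every),
    class = "mlp_config"
  )
}

# Layer widths incl. input and the single output (MISO).
mlp_layout <- function(n_inputs, cfg) c(n_inputs, cfg$hidden, 1L)

mlp_init_weights <- function(n_inputs, cfg) {
  sizes <- mlp_layout(n_inputs, cfg)
  lapply(seq_len(length(sizes) - 1), function(l) {
    matrix(runif(sizes[l + 1] * (sizes[l] + 1), -0.5, 0.5),
           nrow = sizes[l + 1], ncol = sizes[l] + 1)
  })
}

# Forward pass on a matrix of inputs; returns output vector, or all layer
# pre-activations when keep = TRUE (needed for backprop and Jacobians).
mlp_forward_matrix <- function(weights, X, activation, keep = FALSE) {
  act <- .activations[[activation]]
  h <- X
  pre <- if (keep) vector("list", length(weights)) else NULL
  for (l in seq_along(weights)) {
    a <- cbind(h, 1) %*% t(weights[[l]])
    if (keep) pre[[l]] <- a
    h <- act$fn(a)
  }
  if (keep) list(y = h[, 1], pre = pre) else h[, 1]
}

#' Feed-forward evaluation of an MLP
#'
#' @param m An `mlp_model` (e.g. from [mlp_train()] or
#'   [select_best_snapshot()]).
#' @param x A numeric vector (one record) or matrix/data frame of records
#'   in the model's input order; values must be in the network's own input
#'   space (no automatic rescaling — see `predict.mlp_model` for that).
#' @return The network output, one value per record.
#' @export
mlp_forward <- function(m, x) {
  assert_that(inherits(m, "mlp_model"), "m must be an mlp_model")
  if (is.data.frame(x)) x <- as.matrix(x[, m$inputs, drop = FALSE])
  if (is.null(dim(x))) {
    assert_that(length(x) == ncol(m$weights[[1]]) - 1,
                sprintf("input arity mismatch: expected %d, got %d",
                        ncol(m$weights[[1]]) - 1, length(x)),
                "dissolvegp_shape_error")
    x <- matrix(x, nrow = 1)
  }
  assert_that(ncol(x) == ncol(m$weights[[1]]) - 1,
              sprintf("input arity mismatch: expected %d, got %d",
                      ncol(m$weights[[1]]) - 1, ncol(x)),
              "dissolvegp_shape_error")
  mlp_forward_matrix(m$weights, x, m$activation)
}

new_mlp_model <- function(weights, cfg, inputs, output, epochs_trained,
                          scaling = NULL) {
  structure(
    list(weights = weights, activation = cfg$activation, config = cfg,
         inputs = inputs, output = output, epochs_trained = epochs_trained,
         scaling = scaling),
    class = "mlp_model"
  )
}

#' @export
print.mlp_model <- function(x, ...) {
  widths <- c(ncol(x$weights[[1]]) - 1, vapply(x$weights, nrow, integer(1)))
  cat(sprintf("<mlp_model> %s, %s activation, trained %s epochs\n",
              paste(widths, collapse = "-"), x$activation,
              format(x$epochs_trained, big.mark = ",")))
  cat("  inputs: ", paste(x$inputs, collapse = ", "),
      " -> ", x$output, "\n", sep = "")
  invisible(x)
}

#' Predict from a trained MLP
#'
#' If the network was trained on linearly scaled data (the scaling spec is
#' carried on the training set by [scale_linear()]), `newdata` is expected
#' in original units: inputs are scaled into the network's space and the
#' output is unscaled back, so predictions are in Q (%).
#'
#' @param object An `mlp_model`.
#' @param newdata Data frame holding the model's input columns.
#' @param rescale Apply the stored scaling spec (default `TRUE` when one
#'   is present).
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.mlp_model <- function(object, newdata, rescale = !is.null(object$scaling),
                              ...) {
  X <- as.matrix(as.data.frame(newdata)[, object$inputs, drop = FALSE])
  spec <- object$scaling
  if (isTRUE(rescale) && !is.null(spec)) {
    for (j in seq_along(object$inputs)) {
      row <- spec[spec$variable == object$inputs[j], ]
      if (nrow(row) == 1) {
        X[, j] <- row$target_min + (X[, j] - row$source_min) *
          (row$target_max - row$target_min) / (row$source_max - row$source_min)
      }
    }
  }
  y <- mlp_forward_matrix(object$weights, X, object$activation)
  if (isTRUE(rescale) && !is.null(spec)) {
    row <- spec[spec$variable == object$output, ]
    if (nrow(row) == 1) {
      y <- row$source_min + (y - row$target_min) *
        (row$source_max - row$source_min) / (row$target_max - row$target_min)
    }
  }
  y
}

#' Train an MLP on a dissolution dataset
#'
#' Online backpropagation with the study protocol: one weight update per
#' randomly drawn record ("epoch size 1"), momentum, delta-bar-delta
#' per-weight learning rates, and jog-of-weights noise applied whenever the
#' training RMSE has not improved for `patience_epochs` epochs. Weight
#' snapshots are taken at the configured stop points; the generalization
#' error at each snapshot is recorded when a test set is supplied. Fully
#' deterministic for a fixed `cfg$seed`.
#'
#' @param ds Training data, already scaled into the activation's output
#'   range when a bounded activation is used (see [scale_linear()]).
#' @param cfg An [mlp_config()].
#' @param test Optional held-out dataset (same units/scaling as `ds`) for
#'   snapshot generalization error.
#' @param inputs Input column names; default `c("d_mm", "t_min")` (the
#'   reduced input vector).
#' @param output Target column; default `"Q_pct"`.
#' @return A list of class `mlp_training` with elements `model` (the
#'   final-epoch `mlp_model`) and `trace` (an `mlp_trace` tibble with one
#'   row per snapshot: epoch, train/test RMSE, weights; jog epochs in
#'   `attr(trace, "jog_events")`).
#' @export
mlp_train <- function(ds, cfg, test = NULL,
                      inputs = c("d_mm", "t_min"), output = "Q_pct") {
  assert_that(inherits(cfg, "mlp_config"), "cfg must be an mlp_config")
  assert_that(all(c(inputs, output) %in% names(ds)),
              "ds must contain the input and output columns",
              "dissolvegp_argument_error")
  X <- as.matrix(as.data.frame(ds)[, inputs, drop = FALSE])
  y <- as.numeric(ds[[output]])
  rng <- .activations[[cfg$activation]]$range
  if (is.finite(rng[1]) && (any(y <= rng[1]) || any(y >= rng[2]))) {
    abort(sprintf(
      "targets outside the open %s output range (%g, %g): scale the data first",
      cfg$activation, rng[1], rng[2]),
      class = "dissolvegp_training_domain_error")
  }
  XT <- NULL; yT <- NULL
  if (!is.null(test)) {
    XT <- as.matrix(as.data.frame(test)[, inputs, drop = FALSE])
    yT <- as.numeric(test[[output]])
  }
  act <- .activations[[cfg$activation]]
  n <- nrow(X)

  with_seed(cfg$seed, {
    W <- mlp_init_weights(ncol(X), cfg)
    V <- lapply(W, function(w) w * 0)       # momentum velocity
    LR <- lapply(W, function(w) w * 0 + cfg$lr_init)
    BAR <- lapply(W, function(w) w * 0)     # delta-bar gradient trace
    L <- length(W)

    stop_set <- cfg$stop_points
    snapshots <- vector("list", length(stop_set))
    snap_i <- 0L
    jog_events <- integer(0)
    best_rmse <- Inf
    last_improve <- 0L
    check_points <- sort(unique(c(
      seq(cfg$eval_every, cfg$max_epochs, by = cfg$eval_every), stop_set)))
    next_check <- 1L

    train_rmse <- function() {
      pred <- mlp_forward_matrix(W, X, cfg$activation)
      sqrt(mean((pred - y)^2))
    }

    for (epoch in seq_len(cfg$max_epochs)) {
      i <- sample.int(n, 1L)
      # forward, keeping pre-activations
      h <- vector("list", L + 1)
      pre <- vector("list", L)
      h[[1]] <- X[i, ]
      for (l in seq_len(L)) {
        a <- drop(W[[l]] %*% c(h[[l]], 1))
        pre[[l]] <- a
        h[[l + 1]] <- act$fn(a)
      }
      # backward: all gradients from the pre-update weights
      G <- vector("list", L)
      delta <- (h[[L + 1]] - y[i]) * act$grad(pre[[L]])
      for (l in seq(L, 1)) {
        G[[l]] <- tcrossprod(delta, c(h[[l]], 1))
        if (l > 1) {
          delta <- drop(crossprod(delta, W[[l]][, -ncol(W[[l]]), drop = FALSE])) *
            act$grad(pre[[l - 1]])
        }
      }
      for (l in seq_len(L)) {
        # delta-bar-delta rate adaptation
        s <- BAR[[l]] * G[[l]]
        LR[[l]] <- LR[[l]] + cfg$dbd_kappa * (s > 0) -
          (1 - cfg$dbd_phi) * LR[[l]] * (s < 0)
        BAR[[l]] <- (1 - cfg$dbd_theta) * G[[l]] + cfg$dbd_theta * BAR[[l]]
        V[[l]] <- cfg$momentum * V[[l]] - LR[[l]] * G[[l]]
        W[[l]] <- W[[l]] + V[[l]]
      }

      at_check <- next_check <= length(check_points) &&
        epoch == check_points[next_check]
      if (at_check) {
        next_check <- next_check + 1L
        tr <- train_rmse()
        if (is.finite(tr) && tr < best_rmse * (1 - 1e-6) - 1e-12) {
          best_rmse <- tr
          last_improve <- epoch
        }
        if (epoch - last_improve >= cfg$patience_epochs) {
          # jog-of-weights: uniform noise, reset momentum and gradient trace
          W <- lapply(W, function(w) {
            amp <- pmax(cfg$jog_rel * abs(w), cfg$jog_abs)
            w + runif(length(w), -amp, amp)
          })
          V <- lapply(V, function(v) v * 0)
          BAR <- lapply(BAR, function(b) b * 0)
          jog_events <- c(jog_events, epoch)
          last_improve <- epoch
        }
        if (epoch %in% stop_set) {
          snap_i <- snap_i + 1L
          test_rmse <- if (is.null(XT)) NA_real_ else {
            predT <- mlp_forward_matrix(W, XT, cfg$activation)
            sqrt(mean((predT - yT)^2))
          }
          snapshots[[snap_i]] <- list(epoch = epoch, train_rmse = tr,
                                      test_rmse = test_rmse, weights = W)
        }
      }
    }

    snapshots <- snapshots[seq_len(snap_i)]
    trace <- tibble(
      epoch = vapply(snapshots, function(s) s$epoch, numeric(1)),
      train_rmse = vapply(snapshots, function(s) s$train_rmse, numeric(1)),
      test_rmse = vapply(snapshots, function(s) s$test_rmse, numeric(1)),
      weights = lapply(snapshots, function(s) s$weights)
    )
    attr(trace, "jog_events") <- jog_events
    attr(trace, "config") <- cfg
    attr(trace, "inputs") <- inputs
    attr(trace, "output") <- output
    attr(trace, "scaling") <- attr(ds, "scaling")
    class(trace) <- c("mlp_trace", class(trace))

    model <- new_mlp_model(W, cfg, inputs, output, cfg$max_epochs,
                           scaling = attr(ds, "scaling"))
    structure(list(model = model, trace = trace), class = "mlp_training")
  })
}

#' @export
print.mlp_training <- function(x, ...) {
  print(x$model)
  cat(sprintf("  %d snapshot(s); final train RMSE %.4g",
              nrow(x$trace), x$trace$train_rmse[nrow(x$trace)]))
  if (!all(is.na(x$trace$test_rmse))) {
    cat(sprintf(", best test RMSE %.4g", min(x$trace$test_rmse, na.rm = TRUE)))
  }
  cat("\n")
  jogs <- attr(x$trace, "jog_events")
  if (length(jogs) > 0) {
    cat("  jog-of-weights at epoch(s): ", paste(jogs, collapse = ", "), "\n",
        sep = "")
  }
  invisible(x)
}

#' Select the best training snapshot
#'
#' Picks the stop-point snapshot minimizing the chosen criterion (held-out
#' RMSE by default, mirroring selection of the most favourable training
#' length by generalization error); ties go to the earliest epoch.
#'
#' @param trace An `mlp_trace` from [mlp_train()].
#' @param criterion `"test_rmse"` (requires a test set at training time) or
#'   `"train_rmse"`.
#' @return The selected snapshot as an `mlp_model`.
#' @export
select_best_snapshot <- function(trace, criterion = c("test_rmse", "train_rmse")) {
  criterion <- match.arg(criterion)
  assert_that(inherits(trace, "mlp_trace") && nrow(trace) > 0,
              "trace must be a nonempty mlp_trace", "dissolvegp_selection_error")
  vals <- trace[[criterion]]
  assert_that(!all(is.na(vals)),
              paste0(criterion, " not available in this trace"),
              "dissolvegp_selection_error")
  best <- which(vals == min(vals, na.rm = TRUE))[1]
  cfg <- attr(trace, "config")
  new_mlp_model(trace$weights[[best]], cfg, attr(trace, "inputs"),
                attr(trace, "output"), trace$epoch[best],
                scaling = attr(trace, "scaling"))
}

#' @rdname mlp_train
#' @param x An `mlp_training` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.mlp_training <- function(x, ...) {
  out <- x$trace[, c("epoch", "train_rmse", "test_rmse")]
  class(out) <- class(tibble())
  out
}

#' @rdname mlp_train
#' @exportS3Method generics::glance
glance.mlp_training <- function(x, ...) {
  tibble(
    layers = paste(x$model$config$hidden, collapse = "-"),
    activation = x$model$activation,
    epochs = x$model$epochs_trained,
    final_train_rmse = x$trace$train_rmse[nrow(x$trace)],
    best_test_rmse = if (all(is.na(x$trace$test_rmse))) NA_real_
                     else min(x$trace$test_rmse, na.rm = TRUE),
    n_jogs = length(attr(x$trace, "jog_events"))
  )
}

#' Save / load an MLP as JSON
#'
#' @param m An `mlp_model`.
#' @param path File path.
#' @return `path` invisibly; `mlp_from_json()` returns the model.
#' @export
mlp_to_json <- function(m, path) {
  assert_that(inherits(m, "mlp_model"), "m must be an mlp_model")
  x <- list(
    activation = m$activation,
    inputs = m$inputs,
    output = m$output,
    epochs_trained = m$epochs_trained,
    hidden = m$config$hidden,
    weights = m$weights,
    scaling = if (is.null(m$scaling)) NULL else as.data.frame(m$scaling)
  )
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' @rdname mlp_to_json
#' @export
mlp_from_json <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  weights <- lapply(x$weights, function(w) {
    w <- as.matrix(w)
    dimnames(w) <- NULL
    w
  })
  cfg <- mlp_config(hidden = x$hidden, activation = x$activation,
                    max_epochs = max(1, x$epochs_trained))
  scaling <- NULL
  if (!is.null(x$scaling)) {
    scaling <- as_tibble(x$scaling)
    class(scaling) <- c("scaling_spec", class(scaling))
  }
  new_mlp_model(weights, cfg, x$inputs, x$output, x$epochs_trained, scaling)
}
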