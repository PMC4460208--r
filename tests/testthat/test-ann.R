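test_that("mlp_forward matches a hand-computed 2-2-1 tanh pass", {
  W1 <- rbind(c(0.5, -0.3, 0.1), c(0.2, 0.4, -0.2))
  W2 <- rbind(c(0.7, -0.6, 0.05))
  m <- manual_mlp(list(W1, W2))
  x <- c(0.3, -0.5)
  h1 <- tanh(c(0.5 * 0.3 - 0.3 * (-0.5) + 0.1,
               0.2 * 0.3 + 0.4 * (-0.5) - 0.2))
  y_hand <- tanh(0.7 * h1[1] - 0.6 * h1[2] + 0.05)
  expect_equal(mlp_forward(m, x), y_hand, tolerance = 1e-12)

  # all-zero weights with tanh output 0 whatever the input
  zeros <- manual_mlp(list(W1 * 0, W2 * 0))
  expect_equal(mlp_forward(zeros, c(5, -7)), 0)

  # identity-weight linear net passes its input through
  ident <- manual_mlp(list(rbind(c(1, 0)), rbind(c(1, 0))),
                      activation = "linear", inputs = "x1")
  expect_equal(mlp_forward(ident, 3.25), 3.25)

  expect_error(mlp_forward(m, c(1, 2, 3)), class = "dissolvegp_shape_error")
})

test_that("training learns a linear map on scaled data", {
  set.seed(1)
  n <- 200
  df <- tibble::tibble(formulation_id = "X", d_mm = runif(n, 0.5, 3.5),
                       L_mm = 10, t_min = runif(n, 0, 1000), Q_pct = 0)
  df$Q_pct <- df$t_min / 10
  spec <- scaling_spec(df, variables = c("d_mm", "t_min", "Q_pct"))
  dfs <- scale_linear(df, spec)
  tr <- mlp_train(dfs, mlp_config(hidden = 5, max_epochs = 50000, seed = 3),
                  inputs = c("d_mm", "t_min"))
  expect_lt(tr$trace$train_rmse[nrow(tr$trace)], 0.05)
})

test_that("training solves XOR with a small tanh net", {
  xor_df <- tibble::tibble(formulation_id = "x", d_mm = c(-1, -1, 1, 1),
                           L_mm = 1, t_min = c(-1, 1, -1, 1),
                           Q_pct = c(-0.8, 0.8, 0.8, -0.8))
  tr <- mlp_train(xor_df,
                  mlp_config(hidden = 4, max_epochs = 200000, seed = 2,
                             eval_every = 2000),
                  inputs = c("d_mm", "t_min"))
  pred <- mlp_forward(tr$model, as.matrix(xor_df[, c("d_mm", "t_min")]))
  expect_true(all(sign(pred) == sign(xor_df$Q_pct)))
})

test_that("snapshots follow the stop-point schedule and training is seeded", {
  ds <- simulate_profiles(noise_sd = 1, seed = 4)
  spec <- scaling_spec(ds)
  dss <- scale_linear(ds, spec)
  cfg <- mlp_config(hidden = 4, max_epochs = 12000, seed = 7)
  tr1 <- mlp_train(dss, cfg)
  expect_true(all(c(5000, 10000, 12000) %in% tr1$trace$epoch))
  # bit-reproducible under the same seed
  tr2 <- mlp_train(dss, cfg)
  expect_identical(tr1$model$weights, tr2$model$weights)
  expect_equal(tr1$trace$train_rmse, tr2$trace$train_rmse)
  expect_equal(glance(tr1)$epochs, 12000)
})

test_that("unscaled targets are rejected before any training", {
  ds <- simulate_profiles(noise_sd = 1, seed = 4)  # Q in percent units
  expect_error(mlp_train(ds, mlp_config(hidden = 3, max_epochs = 100)),
               class = "dissolvegp_training_domain_error")
})

test_that("patience expiry jogs the weights and perturbs at least one", {
  # a tiny net on constant-ish data stops improving almost immediately
  df <- tibble::tibble(formulation_id = "X", d_mm = runif(50), L_mm = 1,
                       t_min = runif(50), Q_pct = 0.5)
  cfg <- mlp_config(hidden = 2, max_epochs = 3000, seed = 5,
                    patience_epochs = 100, eval_every = 100)
  tr <- mlp_train(df, cfg, inputs = c("d_mm", "t_min"))
  jogs <- attr(tr$trace, "jog_events")
  expect_gt(length(jogs), 0)
})

test_that("snapshot selection minimizes the criterion with earliest-tie", {
  ds <- simulate_profiles(noise_sd = 1, seed = 4)
  spec <- scaling_spec(ds)
  folds <- split_leave_one_formulation_out(ds)
  tr <- mlp_train(scale_linear(folds$train[[1]], spec),
                  mlp_config(hidden = 4, max_epochs = 10000, seed = 8),
                  test = scale_linear(folds$test[[1]], spec))
  best <- select_best_snapshot(tr$trace, "test_rmse")
  expect_s3_class(best, "mlp_model")
  i <- which(tr$trace$epoch == best$epochs_trained)
  expect_equal(tr$trace$test_rmse[i], min(tr$trace$test_rmse))

  # constructed trace with a known minimum and a tie
  fake <- tr$trace[1:4, ]
  fake$test_rmse <- c(0.5, 0.2, 0.2, 0.4)
  attr(fake, "config") <- attr(tr$trace, "config")
  attr(fake, "inputs") <- attr(tr$trace, "inputs")
  attr(fake, "output") <- attr(tr$trace, "output")
  class(fake) <- class(tr$trace)
  expect_equal(select_best_snapshot(fake, "test_rmse")$epochs_trained,
               fake$epoch[2])
  expect_error(select_best_snapshot(fake[0, ]),
               class = "dissolvegp_selection_error")

  # single-snapshot trace returns that snapshot
  one <- fake[1, ]
  class(one) <- class(fake)
  attr(one, "config") <- attr(fake, "config")
  attr(one, "inputs") <- attr(fake, "inputs")
  attr(one, "output") <- attr(fake, "output")
  expect_equal(select_best_snapshot(one, "test_rmse")$epochs_trained,
               one$epoch[1])
})

test_that("a trained surrogate beats the mean-Q null predictor out of fold", {
  ds <- simulate_profiles(noise_sd = 1, seed = 10)
  spec <- scaling_spec(ds)
  folds <- split_leave_one_formulation_out(ds)
  train_s <- scale_linear(folds$train[[2]], spec)
  test <- folds$test[[2]]
  tr <- mlp_train(train_s, mlp_config(hidden = 6, max_epochs = 15000,
                                      seed = 11),
                  test = scale_linear(test, spec))
  best <- select_best_snapshot(tr$trace, "test_rmse")
  pred <- predict(best, test)     # original units via the stored scaling
  null_rmse <- rmse(test$Q_pct, rep(mean(folds$train[[2]]$Q_pct), nrow(test)))
  expect_true(is.finite(rmse(test$Q_pct, pred)))
  expect_lt(rmse(test$Q_pct, pred), null_rmse)
})

test_that("models survive a JSON round-trip", {
  ds <- simulate_profiles(noise_sd = 1, seed = 4)
  spec <- scaling_spec(ds)
  tr <- mlp_train(scale_linear(ds, spec),
                  mlp_config(hidden = 3, max_epochs = 5000, seed = 1))
  path <- withr::local_tempfile(fileext = ".json")
  mlp_to_json(tr$model, path)
  back <- mlp_from_json(path)
  newdata <- ds[seq(1, 1000, by = 97), ]
  expect_equal(predict(back, newdata), predict(tr$model, newdata),
               tolerance = 1e-12)
})
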