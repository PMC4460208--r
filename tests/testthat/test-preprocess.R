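test_that("linear scaling maps endpoints and midpoint as specified", {
  df <- tibble::tibble(formulation_id = "F", d_mm = 1, L_mm = 10,
                       t_min = c(0, 1, 2), Q_pct = c(0, 50, 100))
  spec <- scaling_spec(variables = "Q_pct", source_min = 0, source_max = 100,
                       target_min = -0.8, target_max = 0.8)
  out <- scale_linear(df, spec)
  expect_equal(out$Q_pct, c(-0.8, 0, 0.8))
  expect_identical(provenance(out), "scaled")

  spec2 <- scaling_spec(variables = "Q_pct", source_min = 0, source_max = 100,
                        target_min = 0.2, target_max = 0.8)
  expect_equal(scale_linear(df, spec2)$Q_pct, c(0.2, 0.5, 0.8))
})

test_that("unscale_linear inverts scale_linear on random datasets", {
  set.seed(11)
  for (i in 1:5) {
    ds <- simulate_profiles(noise_sd = runif(1, 0, 3), seed = i)
    spec <- scaling_spec(ds)
    back <- unscale_linear(scale_linear(ds, spec), spec)
    for (col in c("d_mm", "L_mm", "t_min", "Q_pct")) {
      expect_equal(back[[col]], ds[[col]], tolerance = 1e-12)
    }
  }
  expect_error(scaling_spec(variables = "Q_pct", source_min = 5,
                            source_max = 5),
               class = "dissolvegp_degenerate_range_error")
})

test_that("add_noise appends jittered copies bounded by the amplitude", {
  ds <- simulate_profiles(noise_sd = 1, seed = 2)
  noised <- add_noise(ds, amplitude = 0.05, seed = 9)
  expect_equal(nrow(noised), 2 * nrow(ds))
  expect_equal(noised[seq_len(nrow(ds)), ], ds, ignore_attr = TRUE)
  jit <- noised[nrow(ds) + seq_len(nrow(ds)), ]
  for (col in c("d_mm", "L_mm", "t_min", "Q_pct")) {
    v <- ds[[col]]
    expect_true(all(jit[[col]] >= v * 0.95 - 1e-12))
    expect_true(all(jit[[col]] <= v * 1.05 + 1e-12))
  }
  expect_true(all(jit$Q_pct >= 0 & jit$Q_pct <= 110))

  # zero amplitude copies are exact; fixed seed is deterministic
  same <- add_noise(ds, amplitude = 0, seed = 1)
  expect_equal(same$Q_pct[nrow(ds) + seq_len(nrow(ds))], ds$Q_pct)
  expect_equal(add_noise(ds, seed = 5), add_noise(ds, seed = 5))
  expect_error(add_noise(ds, amplitude = -0.1),
               class = "dissolvegp_argument_error")
})

test_that("balance_by_output equalizes occupied bins without inventing data", {
  # skewed fixture: 90% of records in the top of the Q range
  set.seed(4)
  q <- c(runif(900, 80, 100), runif(100, 0, 80))
  skew <- tibble::tibble(formulation_id = "F", d_mm = 1, L_mm = 10,
                         t_min = seq_along(q), Q_pct = q)
  bal <- balance_by_output(skew, n_bins = 10)
  counts <- q_bin_counts(bal$Q_pct, 10)
  expect_lte(max(counts) / min(counts), 2)
  expect_gte(nrow(bal), nrow(skew))                 # never deletes
  expect_setequal(unique(bal$Q_pct), unique(skew$Q_pct))  # no new Q values

  # already-uniform data is returned unchanged
  unif <- tibble::tibble(formulation_id = "F", d_mm = 1, L_mm = 10,
                         t_min = 1:100, Q_pct = seq(0.5, 99.5, by = 1))
  expect_equal(nrow(balance_by_output(unif)), 100)

  flat <- tibble::tibble(formulation_id = "F", d_mm = 1, L_mm = 10,
                         t_min = 1:5, Q_pct = rep(50, 5))
  expect_warning(out <- balance_by_output(flat), "one output bin")
  expect_equal(nrow(out), 5)
})

test_that("leave-one-formulation-out folds partition the study dataset", {
  ds <- simulate_profiles(noise_sd = 1, seed = 6)
  folds <- split_leave_one_formulation_out(ds)
  expect_equal(nrow(folds), 5)
  for (i in 1:5) {
    test <- folds$test[[i]]
    train <- folds$train[[i]]
    expect_equal(nrow(test), 200)               # 20% of the database
    expect_equal(unique(test$formulation_id), folds$held_out_formulation[i])
    expect_length(intersect(unique(train$formulation_id),
                            unique(test$formulation_id)), 0)
    expect_equal(nrow(train) + nrow(test), nrow(ds))
  }
  # union of test folds is the dataset, pairwise disjoint by construction
  all_test <- dplyr::bind_rows(folds$test)
  expect_equal(nrow(all_test), nrow(ds))
  expect_equal(dplyr::arrange(all_test, formulation_id, t_min),
               dplyr::arrange(ds, formulation_id, t_min),
               ignore_attr = TRUE)

  single <- ds[ds$formulation_id == "F1", ]
  expect_error(split_leave_one_formulation_out(single),
               class = "dissolvegp_split_error")
})

test_that("design-space enhancement respects boundaries and test exclusion", {
  ds <- simulate_profiles(noise_sd = 0)
  folds <- split_leave_one_formulation_out(ds)
  train <- folds$train[[1]]
  test <- folds$test[[1]]
  truth <- equation_model("weibull_diffusion", c(1.35, 0.55, 23.2))
  enh <- build_enhanced_dataset(train, truth, test = test)

  expect_identical(provenance(enh), "enhanced")
  art <- enh[enh$formulation_id == "grid", ]
  expect_equal(max(art$d_mm), 1.10 * max(train$d_mm), tolerance = 1e-9)
  expect_equal(max(art$t_min), 1.10 * max(train$t_min), tolerance = 1e-9)
  expect_false(any(abs(art$d_mm - unique(test$d_mm)) <= 1e-9))
  # result contains the training set untouched
  expect_equal(enh[seq_len(nrow(train)), ], train, ignore_attr = TRUE)

  # grid node count agrees with the loop-based oracle
  d_axis <- grid_axis_loop(train$d_mm, 0.0333, 1.10)
  t_axis <- grid_axis_loop(train$t_min, 0.0333, 1.10)
  held <- unique(test$d_mm)
  d_kept <- d_axis[!sapply(d_axis, function(x) any(abs(x - held) <= 1e-9))]
  expect_equal(nrow(art), length(d_kept) * length(t_axis))
})
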