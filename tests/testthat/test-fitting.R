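test_that("multistage fit recovers known parameters from noiseless data", {
  truth <- c(1.35, 0.55, 23.2)
  ds <- simulate_profiles(truth = equation_model("weibull_diffusion", truth),
                          noise_sd = 0, dt = 20)
  fit <- multistage_fit("weibull_diffusion", ds, seed = 5, sann_maxit = 3000)
  expect_true(all(abs(fit$params - truth) / abs(truth) < 0.01))
  expect_lt(fit$train_rmse, 0.1)
  expect_false(fit$degraded)
  expect_equal(tidy(fit)$term, c("c1", "c2", "c3"))
})

test_that("the local suite never loses to the annealing stage", {
  ds <- simulate_profiles(noise_sd = 1, seed = 8, dt = 25)
  fit <- multistage_fit("weibull_diffusion", ds, seed = 2, sann_maxit = 1000)
  sann_rmse <- fit$stages$rmse[fit$stages$method == "SANN"]
  expect_lte(fit$train_rmse, sann_rmse)
  # every local method was launched independently from the SANN point
  expect_setequal(fit$stages$method[fit$stages$stage == "local"],
                  c("Nelder-Mead", "BFGS", "CG", "L-BFGS-B", "nlminb",
                    "hooke-jeeves"))
})

test_that("fitting is invariant to record order", {
  ds <- simulate_profiles(noise_sd = 0.5, seed = 9, dt = 25)
  fit1 <- multistage_fit("weibull_diffusion", ds, seed = 4, sann_maxit = 1000)
  set.seed(123)
  perm <- sample(nrow(ds))
  fit2 <- multistage_fit("weibull_diffusion", ds[perm, ], seed = 4,
                         sann_maxit = 1000)
  expect_equal(fit1$train_rmse, fit2$train_rmse, tolerance = 1e-6)
})

test_that("parameter recovery improves as the noise vanishes", {
  truth <- c(1.35, 0.55, 23.2)
  m <- equation_model("weibull_diffusion", truth)
  med_err <- sapply(c(2, 0.5, 0), function(sdv) {
    errs <- sapply(0:4, function(s) {
      ds <- simulate_profiles(truth = m, noise_sd = sdv, dt = 50,
                              seed = s + 1)
      fit <- multistage_fit("weibull_diffusion", ds, seed = s + 1,
                            sann_maxit = 500)
      max(abs(fit$params - truth) / abs(truth))
    })
    median(errs)
  })
  expect_true(all(diff(med_err) < 0))
})

test_that("cross-validated fitting reports folds, CV% and pooled error", {
  ds <- simulate_profiles(noise_sd = 0.5, seed = 12)
  folds <- split_leave_one_formulation_out(ds)
  cv <- crossval_fit("weibull_diffusion", folds, preprocessing = "original",
                     seed = 3, sann_maxit = 800)
  expect_length(cv$fits, 5)
  expect_equal(nrow(cv$params), 5)
  # pooled RMSE equals an independent accumulation over folds
  acc_obs <- c(); acc_pred <- c()
  for (i in 1:5) {
    m <- as_equation_model(cv$fits[[i]])
    test <- folds$test[[i]]
    acc_obs <- c(acc_obs, test$Q_pct)
    acc_pred <- c(acc_pred, eval_equation(m, test$d_mm, test$t_min))
  }
  expect_equal(cv$pooled_test_rmse, rmse_loop(acc_obs, acc_pred),
               tolerance = 1e-12)
  # stable parameters on low-noise synthetic data
  expect_true(all(cv$cv_percent < 25))
  expect_equal(glance(cv)$n_folds, 5)
})

test_that("preprocessed training never touches the held-out fold", {
  ds <- simulate_profiles(noise_sd = 0.5, seed = 13, dt = 50)
  folds <- split_leave_one_formulation_out(ds)
  cv <- crossval_fit("weibull_diffusion", folds, preprocessing = "noised",
                     seed = 3, sann_maxit = 300)
  # predictions are made on the raw test records of each fold
  for (i in 1:5) {
    test <- folds$test[[i]]
    sub <- cv$predictions[cv$predictions$fold == i, ]
    expect_equal(sub$observed, test$Q_pct)
    expect_equal(sub$t_min, test$t_min)
  }
  expect_error(crossval_fit("weibull_diffusion", folds,
                            preprocessing = "enhanced", seed = 1),
               class = "dissolvegp_dependency_error")
})

test_that("enhanced-mode cross-validation consumes a surrogate builder", {
  ds <- simulate_profiles(noise_sd = 0.5, seed = 14, dt = 100)
  folds <- split_leave_one_formulation_out(ds)
  builder <- function(train, test, i) {
    equation_model("weibull_diffusion", c(1.35, 0.55, 23.2))
  }
  cv <- crossval_fit("weibull_diffusion", folds, preprocessing = "enhanced",
                     predictor_builder = builder, seed = 3, sann_maxit = 300)
  expect_length(cv$fits, 5)
  expect_true(is.finite(cv$pooled_test_rmse))
})
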