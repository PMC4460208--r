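test_that("weibull_Q hits its analytic landmarks", {
  expect_equal(weibull_Q(0, A = 100, K = 2), 0)
  expect_equal(weibull_Q(100, A = 100, K = 2), 100 * (1 - exp(-1)))
  expect_equal(round(weibull_Q(100, A = 100, K = 2), 3), 63.212)
  expect_equal(weibull_Q(50, A = 100, K = 2), 100 * (1 - exp(-0.25)))
  expect_equal(round(weibull_Q(50, A = 100, K = 2), 3), 22.120)
  expect_error(weibull_Q(10, A = -1, K = 1),
               class = "dissolvegp_parameter_error")
  expect_error(weibull_Q(10, A = 1, K = 0),
               class = "dissolvegp_parameter_error")
})

test_that("weibull_Q is monotone and bounded for random valid constants", {
  set.seed(12)
  t <- seq(0, 1100, by = 10)
  for (i in 1:20) {
    A <- runif(1, 1, 500)
    K <- runif(1, 0.2, 3)
    q <- weibull_Q(t, A, K)
    expect_true(all(diff(q) >= 0))
    expect_true(all(q >= 0 & q <= 100))
  }
})

test_that("registry enforces arity before any evaluation", {
  expect_equal(nrow(list_equations()), 5)
  expect_error(equation_model("weibull", c(1, 2, 3)),
               class = "dissolvegp_parameter_error")
  expect_error(equation_model("eq7_direct", c(1, 2)),
               class = "dissolvegp_parameter_error")
  expect_error(equation_model("nope", 1), class = "dissolvegp_argument_error")
})

test_that("the indirect family is exactly Weibull composed with its maps", {
  d <- c(0.6, 1.0, 1.5, 2.7, 3.5)
  t <- seq(5, 1000, by = 5)
  grid <- expand.grid(d = d, t = t)
  for (m in list(equation_model("eq_indirect", c(0.9, 0.2, 6)),
                 equation_model("eq_indirect", c(1.1, 0.4, 3),
                                variant = "linear", K_variant = "shifted"),
                 equation_model("weibull_diffusion", c(1.35, 0.55, 23.2)))) {
    ak <- weibull_constants(m, grid$d)
    direct <- eval_equation(m, grid$d, grid$t)
    composed <- 100 * (1 - exp(-(grid$t / ak$A)^ak$K))
    expect_equal(direct, composed, tolerance = 1e-12)
  }
  # Weibull landmarks transfer: t = A(d) gives 63.212 at any diameter
  m <- equation_model("eq_indirect", c(0.9, 0.2, 6))
  ak <- weibull_constants(m, d)
  expect_equal(eval_equation(m, d, rep(0, 5)), rep(0, 5))
  expect_equal(eval_equation(m, d, ak$A), rep(100 * (1 - exp(-1)), 5))
})

test_that("printed-form equations are finite across the study domain", {
  grid <- expand.grid(d = seq(0.6, 3.5, by = 0.1), t = seq(0, 1100, by = 20))
  ref <- reference_fit_params()
  m7 <- equation_model("eq7_direct", c(ref$c1[1], ref$c2[1], ref$c3[1]))
  q7 <- eval_equation(m7, grid$d, grid$t)
  expect_true(all(is.finite(q7)))

  m11 <- equation_model("eq_previous", c(0.1, 0.1, 2, 0.1, 3, 10))
  q11 <- eval_equation(m11, grid$d, grid$t)
  expect_true(all(is.finite(q11)))
})

test_that("the direct equation releases from ~0 toward its plateau", {
  ref <- reference_fit_params()
  m7 <- equation_model("eq7_direct", c(ref$c1[1], ref$c2[1], ref$c3[1]))
  early <- eval_equation(m7, 1.0, 0)
  late <- eval_equation(m7, 1.0, 1e6)
  expect_lt(abs(early), 5)
  expect_equal(late, log(1) + 1 + ref$c1[1], tolerance = 0.1)
})

test_that("fit_weibull_profile recovers known constants and beats a grid", {
  prof <- make_weibull_profile(A = 50, K = 0.8)
  fit <- fit_weibull_profile(prof)
  expect_equal(fit$A, 50, tolerance = 1e-3)
  expect_equal(fit$K, 0.8, tolerance = 1e-3)
  expect_lt(fit$rmse, 1e-6)

  # coarse 50x50 grid-search oracle can never beat the optimizer
  noisy <- prof
  set.seed(5)
  noisy$Q_pct <- pmin(pmax(prof$Q_pct + rnorm(nrow(prof), sd = 2), 0), 110)
  fit2 <- fit_weibull_profile(noisy)
  grid_best <- Inf
  for (A in seq(10, 200, length.out = 50)) {
    for (K in seq(0.2, 2, length.out = 50)) {
      r <- rmse(noisy$Q_pct, weibull_Q(noisy$t_min, A, K))
      grid_best <- min(grid_best, r)
    }
  }
  expect_lte(fit2$rmse, grid_best)

  flat <- make_weibull_profile(A = 50, K = 0.8)
  flat$Q_pct <- 42
  expect_error(fit_weibull_profile(flat),
               class = "dissolvegp_degenerate_profile_error")
  expect_error(fit_weibull_profile(prof[1:2, ]),
               class = "dissolvegp_argument_error")
  expect_equal(tidy(fit)$term, c("A", "K"))
})

test_that("equation models serialize to JSON and back", {
  m <- equation_model("eq_indirect", c(0.9, 0.2, 6), variant = "linear",
                      K_variant = "shifted")
  path <- withr::local_tempfile(fileext = ".json")
  equation_to_json(m, path)
  back <- equation_from_json(path)
  expect_equal(back$params, m$params)
  expect_equal(back$variant, "linear")
  d <- runif(10, 0.6, 3.5); t <- runif(10, 0, 1000)
  expect_equal(eval_equation(back, d, t), eval_equation(m, d, t))
})
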