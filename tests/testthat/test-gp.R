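gv <- dissolvegp:::gp_var
gc_ <- dissolvegp:::gp_const
gop <- dissolvegp:::gp_op

test_that("eval_tree implements the protected semantics", {
  expect_equal(eval_tree(gop("+", gv("d"), gv("t")), list(d = 1, t = 2)), 3)
  expect_equal(eval_tree(gop("/", gv("x"), gc_(0)), list(x = 5)), 1)
  expect_equal(eval_tree(gop("ln", gc_(0)), list()), 0)
  expect_equal(eval_tree(gop("ln", gc_(-exp(2))), list()), 2)
  expect_equal(eval_tree(gop("sqrt", gc_(-9)), list()), 3)
  expect_equal(eval_tree(gop("pow", gc_(0), gc_(-1)), list()), 1)
  expect_equal(eval_tree(gop("pow", gc_(0), gc_(2)), list()), 0)
  expect_equal(eval_tree(gop("pow", gc_(-2), gc_(2)), list()), 4)
  expect_true(is.finite(eval_tree(gop("exp", gc_(1e4)), list())))
  expect_error(eval_tree(gv("z"), list(x = 1)),
               class = "dissolvegp_binding_error")
})

test_that("random trees stay finite and match an independent re-evaluator", {
  set.seed(14)
  bindings <- list(d = runif(50, 0.6, 3.5), t = runif(50, 0, 1100))
  for (i in 1:40) {
    tr <- dissolvegp:::random_tree(c("d", "t"), c(-10, 10), max_depth = 5)
    v <- eval_tree(tr, bindings)
    expect_true(all(is.finite(v)))
    expect_equal(v, eval_tree_oracle(tr, bindings), tolerance = 1e-12)
  }
})

test_that("prefix serialization round-trips arbitrary trees", {
  set.seed(15)
  bindings <- list(d = runif(20, 0.6, 3.5), t = runif(20, 0, 1100))
  for (i in 1:20) {
    tr <- dissolvegp:::random_tree(c("d", "t"), c(-10, 10), max_depth = 4)
    back <- tree_from_prefix(tree_to_prefix(tr))
    expect_equal(eval_tree(back, bindings), eval_tree(tr, bindings),
                 tolerance = 1e-12)
    expect_equal(tree_size(back), tree_size(tr))
  }
  expect_error(tree_from_prefix("(+ d t) junk"),
               class = "dissolvegp_argument_error")
})

test_that("evolution rediscovers a planted square-root law exactly", {
  ds <- simulate_profiles(noise_sd = 0)
  ds$Q_pct <- sqrt(ds$t_min)
  g <- evolve_direct(ds, gp_config(population_size = 500,
                                   max_generations = 15, size_limit = 20,
                                   fitness_stop = 1e-9, seed = 3))
  expect_lt(g$rmse, 1e-6)
  expect_lte(tree_size(g$tree), 20)
})

test_that("evolution recovers a planted saturating release law", {
  ds <- simulate_profiles(noise_sd = 0)
  ds$Q_pct <- 2 * ds$t_min / (ds$t_min + 50)
  g <- evolve_direct(ds, gp_config(population_size = 500,
                                   max_generations = 40, size_limit = 25,
                                   fitness_stop = 0.005, seed = 11))
  expect_lte(g$rmse, 0.01)
  expect_lte(tree_size(g$tree), 25)
})

test_that("the best fitness history is monotone and runs are seeded", {
  ds <- simulate_profiles(noise_sd = 1, seed = 2)
  cfg <- gp_config(population_size = 100, max_generations = 8,
                   size_limit = 20, fitness_stop = 0.1, seed = 5)
  g1 <- evolve_direct(ds, cfg)
  expect_true(all(diff(g1$history$best_rmse) <= 1e-12))
  g2 <- evolve_direct(ds, cfg)
  expect_identical(g1$expression, g2$expression)
  expect_equal(g1$rmse, g2$rmse)
  expect_lte(tree_size(g1$tree), 20)
})

test_that("a zero time budget returns the best of the initial population", {
  ds <- simulate_profiles(noise_sd = 1, seed = 2)
  g <- evolve_direct(ds, gp_config(population_size = 50,
                                   max_generations = 100, size_limit = 15,
                                   time_stop = 0, optimize_constants = FALSE,
                                   seed = 1))
  expect_equal(g$generations, 0)
  expect_true(is.finite(g$rmse))
})

test_that("indirect evolution recovers the planted geometry maps", {
  wt <- dplyr::mutate(study_design(), A = 20^d_mm, K = 0.85)
  # stochastic global search: allow a small multi-start over seeds
  best_A <- Inf
  for (s in 0:2) {
    res <- evolve_indirect(wt, gp_config(population_size = 500,
                                         max_generations = 40,
                                         size_limit = 20, seed = s))
    expect_lte(tree_size(res$A$tree), 20)
    expect_lte(tree_size(res$K$tree), 20)
    expect_lte(res$K$rmse, 1e-8)   # constant K collapses immediately
    best_A <- min(best_A, res$A$rmse)
    if (best_A <= 0.01) break
  }
  expect_lte(best_A, 0.01)

  expect_error(evolve_indirect(wt[1, ]), class = "dissolvegp_argument_error")
})
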