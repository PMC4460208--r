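# Tree-based genetic programming for symbolic regression of release
# equations. Expression trees over {+, -, *, /, pow, ln, sqrt, exp},
# terminal variables and ephemeral numeric constants, evolved by
# tournament selection with subtree crossover and mutation under a
# node-count complexity cap, with protected evaluation semantics so every
# candidate is finite on finite inputs.

.gp_binary_ops <- c("+", "-", "*", "/", "pow")
.gp_unary_ops <- c("ln", "sqrt", "exp")
.gp_clamp <- 1e150

gp_var <- function(name) list(type = "var", name = name)
gp_const <- function(value) list(type = "const", value = value)
gp_op <- function(op, ...) list(type = "op", op = op, args = list(...))

gp_arity <- function(op) if (op %in% .gp_binary_ops) 2L else 1L

#' Size and depth of an expression tree
#'
#' @param tree A GP expression tree.
#' @return `tree_size()`: the node count; `tree_depth()`: the depth
#'   (a lone terminal has depth 1).
#' @export
tree_size <- function(tree) {
  if (tree$type != "op") return(1L)
  1L + sum(vapply(tree$args, tree_size, integer(1)))
}

#' @rdname tree_size
#' @export
tree_depth <- function(tree) {
  if (tree$type != "op") return(1L)
  1L + max(vapply(tree$args, tree_depth, integer(1)))
}

clamp_val <- function(v) pmin(pmax(v, -.gp_clamp), .gp_clamp)

#' Evaluate an expression tree under protected semantics
#'
#' Vectorized evaluation with the standard GP protections so any tree is
#' finite at any finite binding: division by zero yields 1, `ln` and
#' `sqrt` act on the absolute value (with `ln(0) = 0`), `pow` uses
#' magnitude semantics (`0^e` is 0 for positive e, else 1), `exp` is
#' clamped against overflow, and every node output is clamped to a large
#' finite magnitude.
#'
#' @param tree A GP expression tree.
#' @param bindings Named list mapping each terminal variable to a numeric
#'   vector (all the same length).
#' @return Numeric vector of values.
#' @export
eval_tree <- function(tree, bindings) {
  switch(tree$type,
    const = tree$value,
    var = {
      v <- bindings[[tree$name]]
      if (is.null(v)) {
        abort(paste0("unbound variable '", tree$name, "'"),
              class = "dissolvegp_binding_error")
      }
      v
    },
    op = {
      a <- eval_tree(tree$args[[1]], bindings)
      if (gp_arity(tree$op) == 2L) {
        b <- eval_tree(tree$args[[2]], bindings)
        v <- switch(tree$op,
          "+" = a + b,
          "-" = a - b,
          "*" = a * b,
          "/" = ifelse(b == 0, 1, a / b),
          "pow" = {
            absa <- abs(a)
            out <- exp(pmin(pmax(b * log(ifelse(absa == 0, 1, absa)), -500), 500))
            ifelse(absa == 0, ifelse(b > 0, 0, 1), out)
          }
        )
      } else {
        v <- switch(tree$op,
          "ln" = ifelse(a == 0, 0, log(abs(a))),
          "sqrt" = sqrt(abs(a)),
          "exp" = exp(pmin(a, 500))
        )
      }
      clamp_val(v)
    },
    abort("malformed tree node", class = "dissolvegp_argument_error")
  )
}

#' Render an expression tree as a string
#'
#' @param tree A GP expression tree.
#' @param digits Significant digits for constants.
#' @return `tree_to_string()`: infix notation; `tree_to_prefix()`:
#'   parenthesized prefix notation, parseable by [tree_from_prefix()].
#' @export
tree_to_string <- function(tree, digits = 6) {
  switch(tree$type,
    const = as.character(signif(tree$value, digits)),
    var = tree$name,
    op = {
      if (gp_arity(tree$op) == 2L) {
        lhs <- tree_to_string(tree$args[[1]], digits)
        rhs <- tree_to_string(tree$args[[2]], digits)
        if (tree$op == "pow") paste0("(", lhs, " ^ ", rhs, ")")
        else paste0("(", lhs, " ", tree$op, " ", rhs, ")")
      } else {
        paste0(tree$op, "(", tree_to_string(tree$args[[1]], digits), ")")
      }
    }
  )
}

#' @rdname tree_to_string
#' @export
tree_to_prefix <- function(tree, digits = 17) {
  switch(tree$type,
    const = as.character(signif(tree$value, digits)),
    var = tree$name,
    op = paste0("(", paste(c(tree$op,
                             vapply(tree$args, tree_to_prefix, character(1),
                                    digits = digits)),
                           collapse = " "), ")")
  )
}

#' @rdname tree_to_string
#' @param text A prefix-notation string from [tree_to_prefix()].
#' @export
tree_from_prefix <- function(text) {
  tokens <- strsplit(gsub("([()])", " \\1 ", text), "\\s+")[[1]]
  tokens <- tokens[nzchar(tokens)]
  pos <- 1L
  parse_one <- function() {
    tok <- tokens[pos]
    pos <<- pos + 1L
    if (tok == "(") {
      op <- tokens[pos]
      pos <<- pos + 1L
      args <- list()
      while (tokens[pos] != ")") args[[length(args) + 1L]] <- parse_one()
      pos <<- pos + 1L
      assert_that(length(args) == gp_arity(op),
                  paste0("wrong arity for '", op, "'"),
                  "dissolvegp_argument_error")
      do.call(gp_op, c(list(op), args))
    } else if (grepl("^[-+]?([0-9]|\\.[0-9])", tok)) {
      gp_const(as.numeric(tok))
    } else {
      gp_var(tok)
    }
  }
  out <- parse_one()
  assert_that(pos == length(tokens) + 1L, "trailing tokens in prefix string",
              "dissolvegp_argument_error")
  out
}

# --- random trees and variation operators ---------------------------------

random_tree <- function(variables, const_range, max_depth, method = "grow",
                        p_const = 0.3) {
  make <- function(depth) {
    at_leaf <- depth >= max_depth ||
      (method == "grow" && depth > 1 && runif(1) < 0.4)
    if (at_leaf) {
      if (runif(1) < p_const) {
        gp_const(runif(1, const_range[1], const_range[2]))
      } else {
        gp_var(sample(variables, 1))
      }
    } else {
      op <- sample(c(.gp_binary_ops, .gp_unary_ops), 1)
      if (gp_arity(op) == 2L) gp_op(op, make(depth + 1), make(depth + 1))
      else gp_op(op, make(depth + 1))
    }
  }
  make(1)
}

# All node paths of a tree; a path is an integer vector of child indices.
tree_paths <- function(tree, prefix = integer(0)) {
  if (tree$type != "op") return(list(prefix))
  out <- list(prefix)
  for (i in seq_along(tree$args)) {
    out <- c(out, tree_paths(tree$args[[i]], c(prefix, i)))
  }
  out
}

subtree_at <- function(tree, path) {
  for (i in path) tree <- tree$args[[i]]
  tree
}

replace_at <- function(tree, path, sub) {
  if (length(path) == 0) return(sub)
  tree$args[[path[1]]] <- replace_at(tree$args[[path[1]]], path[-1], sub)
  tree
}

gp_crossover <- function(a, b) {
  pa <- sample(tree_paths(a), 1)[[1]]
  pb <- sample(tree_paths(b), 1)[[1]]
  replace_at(a, pa, subtree_at(b, pb))
}

gp_mutate_subtree <- function(tree, variables, const_range) {
  p <- sample(tree_paths(tree), 1)[[1]]
  replace_at(tree, p, random_tree(variables, const_range, max_depth = 3))
}

gp_mutate_point <- function(tree, variables, const_range) {
  p <- sample(tree_paths(tree), 1)[[1]]
  node <- subtree_at(tree, p)
  new_node <- switch(node$type,
    op = {
      pool <- if (gp_arity(node$op) == 2L) .gp_binary_ops else .gp_unary_ops
      node$op <- sample(pool, 1)
      node
    },
    const = gp_const(node$value + rnorm(1, sd = 0.1 * max(abs(node$value), 1))),
    var = if (length(variables) > 1) gp_var(sample(variables, 1)) else node
  )
  replace_at(tree, p, new_node)
}

# Paths of every constant node (for constant refinement).
const_paths <- function(tree) {
  Filter(function(p) subtree_at(tree, p)$type == "const", tree_paths(tree))
}

set_consts <- function(tree, paths, values) {
  for (i in seq_along(paths)) {
    tree <- replace_at(tree, paths[[i]], gp_const(values[i]))
  }
  tree
}

# --- configuration and evolution engine -----------------------------------

#' Configuration of a symbolic-regression GP run
#'
#' Defaults mirror the study settings where stated — population size
#' 10,000, complexity cap (`size_limit`) inside the studied 10-300 range,
#' the eight-function set, direct-mode fitness stop RMSE 1.0 — with the
#' unstated variation operators set to conventional values (tournament
#' size 3, crossover 0.7, subtree mutation 0.2, point mutation 0.1,
#' elitism 1). Tests and examples use much smaller populations and
#' generation budgets.
#'
#' @param population_size Individuals per generation (>= 2).
#' @param size_limit Maximum node count of any individual (>= 3);
#'   offspring exceeding it are replaced by their first parent.
#' @param fitness_stop Stop when the best RMSE reaches this value.
#' @param max_generations Generation budget (reproducible alternative to a
#'   wall-clock stop).
#' @param time_stop Wall-clock budget in seconds (`Inf` to disable).
#' @param tournament_size,p_crossover,p_subtree,p_point,elitism Variation
#'   operator settings.
#' @param const_range Range of ephemeral random constants.
#' @param linear_scaling Evaluate fitness after the optimal affine
#'   transform of the tree output (Keijzer scaling); the returned tree is
#'   wrapped in that transform, and individuals are evolved under
#'   `size_limit - 4` so the wrapped tree still respects the cap. Ignored
#'   (off) when `size_limit < 7`. Default `TRUE`.
#' @param optimize_constants Refine the constants of the generation's
#'   front-runners and a random population subset by Nelder-Mead (memetic
#'   local search); default `TRUE`.
#' @param opt_const_maxit Iteration cap of that refinement.
#' @param seed Integer seed; fixed seed plus a generation-based stop gives
#'   identical runs.
#' @return A validated list of class `gp_config`.
#' @export
gp_config <- function(population_size = 10000, size_limit = 50,
                      fitness_stop = 1.0, max_generations = 100,
                      time_stop = Inf, tournament_size = 3,
                      p_crossover = 0.7, p_subtree = 0.2, p_point = 0.1,
                      elitism = 1, const_range = c(-10, 10),
                      linear_scaling = TRUE,
                      optimize_constants = TRUE, opt_const_maxit = 60,
                      seed = 1) {
  assert_that(population_size >= 2, "population_size must be >= 2",
              "dissolvegp_argument_error")
  assert_that(size_limit >= 3, "size_limit must be >= 3",
              "dissolvegp_argument_error")
  assert_that(fitness_stop > 0, "fitness_stop must be positive",
              "dissolvegp_argument_error")
  structure(
    list(population_size = as.integer(population_size),
         size_limit = as.integer(size_limit), fitness_stop = fitness_stop,
         max_generations = max_generations, time_stop = time_stop,
         tournament_size = tournament_size, p_crossover = p_crossover,
         p_subtree = p_subtree, p_point = p_point, elitism = elitism,
         const_range = const_range,
         linear_scaling = isTRUE(linear_scaling) && size_limit >= 7,
         optimize_constants = optimize_constants,
         opt_const_maxit = opt_const_maxit, seed = seed),
    class = "gp_config"
  )
}

# Optimal affine transform a + b*f of a raw tree output against the
# target (Keijzer linear scaling); degenerate outputs collapse to the
# target mean.
affine_fit <- function(f, target) {
  mf <- mean(f)
  vf <- mean((f - mf)^2)
  if (!is.finite(vf) || vf < 1e-30) {
    return(list(a = mean(target), b = 0))
  }
  b <- mean((f - mf) * (target - mean(target))) / vf
  if (!is.finite(b)) b <- 0
  list(a = mean(target) - b * mf, b = b)
}

gp_fitness <- function(tree, bindings, target, linear_scaling = FALSE) {
  v <- eval_tree(tree, bindings)
  if (length(v) == 1) v <- rep(v, length(target))
  if (linear_scaling) {
    ab <- affine_fit(v, target)
    v <- ab$a + ab$b * v
  }
  out <- sqrt(mean((v - target)^2))
  if (!is.finite(out)) 1e12 else out
}

# Wrap a tree in its fitted affine transform (identity transforms are
# left unwrapped).
wrap_affine <- function(tree, bindings, target) {
  v <- eval_tree(tree, bindings)
  if (length(v) == 1) v <- rep(v, length(target))
  ab <- affine_fit(v, target)
  if (abs(ab$a) < 1e-12 && abs(ab$b - 1) < 1e-12) return(tree)
  gp_op("+", gp_const(ab$a), gp_op("*", gp_const(ab$b), tree))
}

refine_constants <- function(tree, bindings, target, maxit,
                             linear_scaling = FALSE) {
  paths <- const_paths(tree)
  if (length(paths) == 0 || length(paths) > 8) return(tree)
  vals <- vapply(paths, function(p) subtree_at(tree, p)$value, numeric(1))
  obj <- function(v) gp_fitness(set_consts(tree, paths, v), bindings, target,
                                linear_scaling)
  fit <- suppressWarnings(optim(vals, obj, method = "Nelder-Mead",
                                control = list(maxit = maxit, reltol = 1e-12)))
  if (fit$value < obj(vals)) set_consts(tree, paths, fit$par) else tree
}

# Structural local search: repeatedly replace an internal node by one of
# its children (accepting a temporary fitness loss), re-tune the
# constants, and keep the simplification only if the refined result beats
# the original. Strips clutter terms that block constant refinement from
# reaching a planted functional form.
prune_refine <- function(tree, bindings, target, maxit, linear_scaling,
                         max_steps = 6) {
  fit0 <- gp_fitness(tree, bindings, target, linear_scaling)
  best <- tree
  best_fit <- fit0
  cur <- tree
  cur_fit <- fit0
  for (step in seq_len(max_steps)) {
    paths <- Filter(function(p) subtree_at(cur, p)$type == "op",
                    tree_paths(cur))
    if (length(paths) == 0) break
    cand <- NULL
    cand_fit <- Inf
    for (p in paths) {
      node <- subtree_at(cur, p)
      for (child in node$args) {
        alt <- replace_at(cur, p, child)
        af <- gp_fitness(alt, bindings, target, linear_scaling)
        if (af < cand_fit) { cand <- alt; cand_fit <- af }
      }
    }
    if (is.null(cand) || cand_fit > 2 * cur_fit + 1e-8) break
    cur <- refine_constants(cand, bindings, target, maxit, linear_scaling)
    cur_fit <- gp_fitness(cur, bindings, target, linear_scaling)
    if (cur_fit < best_fit ||
        (cur_fit <= best_fit + 1e-12 && tree_size(cur) < tree_size(best))) {
      best <- cur
      best_fit <- cur_fit
    }
  }
  best
}

# Core generational loop shared by the direct and indirect drivers.
gp_evolve <- function(bindings, target, variables, cfg) {
  with_seed(cfg$seed, {
    t0 <- Sys.time()
    lin <- isTRUE(cfg$linear_scaling)
    # affine wrapper adds 4 nodes; evolve the core under the tighter cap
    cap <- if (lin) cfg$size_limit - 4L else cfg$size_limit
    # ramped half-and-half initialization under the size cap
    pop <- vector("list", cfg$population_size)
    for (i in seq_len(cfg$population_size)) {
      repeat {
        cand <- random_tree(variables, cfg$const_range,
                            max_depth = 2 + (i %% 3),
                            method = if (i %% 2 == 0) "grow" else "full")
        if (tree_size(cand) <= cap) break
      }
      pop[[i]] <- cand
    }
    fit <- vapply(pop, gp_fitness, numeric(1), bindings = bindings,
                  target = target, linear_scaling = lin)
    best_i <- which.min(fit)
    best <- pop[[best_i]]
    best_fit <- fit[best_i]
    history <- numeric(0)
    gen <- 0L

    repeat {
      if (cfg$optimize_constants) {
        # Lamarckian memetic step: full-budget refinement of the current
        # front-runners plus a short-budget pass over a random subset, so
        # a correct structure with poor constants is not lost before
        # selection can reward it.
        top <- order(fit)[seq_len(min(3, length(fit)))]
        others <- sample.int(length(fit),
                             min(length(fit), ceiling(0.1 * length(fit))))
        for (idx in unique(c(top, others))) {
          ref <- refine_constants(pop[[idx]], bindings, target,
                                  if (idx %in% top) cfg$opt_const_maxit
                                  else ceiling(cfg$opt_const_maxit / 4),
                                  linear_scaling = lin)
          if (idx == top[1]) {
            ref <- prune_refine(ref, bindings, target, cfg$opt_const_maxit,
                                linear_scaling = lin)
          }
          rf <- gp_fitness(ref, bindings, target, linear_scaling = lin)
          if (rf < fit[idx]) { pop[[idx]] <- ref; fit[idx] <- rf }
          if (rf < best_fit) { best <- ref; best_fit <- rf }
        }
      }
      history <- c(history, best_fit)
      elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
      if (best_fit <= cfg$fitness_stop || gen >= cfg$max_generations ||
          elapsed >= cfg$time_stop) break
      gen <- gen + 1L

      # selection fitness carries a minute parsimony term so that among
      # near-equal candidates the smaller tree wins the tournament
      sel_fit <- fit + 1e-9 * vapply(pop, tree_size, integer(1))
      tournament <- function() {
        idx <- sample.int(cfg$population_size, cfg$tournament_size,
                          replace = TRUE)
        pop[[idx[which.min(sel_fit[idx])]]]
      }
      newpop <- vector("list", cfg$population_size)
      n_elite <- min(cfg$elitism, cfg$population_size)
      if (n_elite > 0) for (k in seq_len(n_elite)) newpop[[k]] <- best
      for (k in n_elite + seq_len(cfg$population_size - n_elite)) {
        p1 <- tournament()
        r <- runif(1)
        child <- if (r < cfg$p_crossover) {
          gp_crossover(p1, tournament())
        } else if (r < cfg$p_crossover + cfg$p_subtree) {
          gp_mutate_subtree(p1, variables, cfg$const_range)
        } else if (r < cfg$p_crossover + cfg$p_subtree + cfg$p_point) {
          gp_mutate_point(p1, variables, cfg$const_range)
        } else {
          p1
        }
        if (tree_size(child) > cap) child <- p1
        newpop[[k]] <- child
      }
      # fresh blood: a small tail of new random individuals keeps
      # structural diversity against premature convergence
      n_fresh <- floor(0.05 * cfg$population_size)
      if (n_fresh > 0) {
        for (k in cfg$population_size - seq_len(n_fresh) + 1L) {
          repeat {
            cand <- random_tree(variables, cfg$const_range, max_depth = 4)
            if (tree_size(cand) <= cap) break
          }
          newpop[[k]] <- cand
        }
      }
      pop <- newpop
      fit <- vapply(pop, gp_fitness, numeric(1), bindings = bindings,
                    target = target, linear_scaling = lin)
      gen_best <- which.min(fit)
      if (fit[gen_best] < best_fit) {
        best <- pop[[gen_best]]
        best_fit <- fit[gen_best]
      }
    }

    if (lin) best <- wrap_affine(best, bindings, target)
    structure(
      list(tree = best, rmse = best_fit, generations = gen,
           expression = tree_to_string(best),
           history = tibble(generation = seq_along(history) - 1L,
                            best_rmse = history),
           config = cfg, variables = variables),
      class = "gp_result"
    )
  })
}

#' @export
print.gp_result <- function(x, ...) {
  cat("<gp_result> RMSE ", signif(x$rmse, 6), " after ", x$generations,
      " generation(s)\n", sep = "")
  cat("  ", x$expression, "\n", sep = "")
  invisible(x)
}

#' Direct symbolic regression of the release profile
#'
#' Evolves an expression Q = f(d, t) (or over any chosen terminals)
#' against a dissolution dataset — the direct modeling mode, run after the
#' input vector has been reduced to diameter and time.
#'
#' @param ds A dissolution dataset.
#' @param cfg A [gp_config()]; the direct-mode default fitness stop is
#'   RMSE 1.0.
#' @param terminals Named character vector mapping terminal names to
#'   dataset columns; default `c(d = "d_mm", t = "t_min")`.
#' @param output Target column, default `"Q_pct"`.
#' @return A `gp_result`: best tree, its training RMSE, the per-generation
#'   best-fitness history, and the rendered expression.
#' @export
evolve_direct <- function(ds, cfg = gp_config(),
                          terminals = c(d = "d_mm", t = "t_min"),
                          output = "Q_pct") {
  assert_that(is.data.frame(ds) && nrow(ds) > 0, "ds must be nonempty",
              "dissolvegp_argument_error")
  assert_that(all(c(terminals, output) %in% names(ds)),
              "terminals/output must name dataset columns",
              "dissolvegp_argument_error")
  bindings <- lapply(terminals, function(col) as.numeric(ds[[col]]))
  names(bindings) <- names(terminals)
  gp_evolve(bindings, as.numeric(ds[[output]]), names(terminals), cfg)
}

#' Indirect symbolic regression through the Weibull constants
#'
#' Given the per-formulation table of fitted Weibull constants (one (A, K)
#' pair per dissolution profile, so typically five rows), evolves two
#' independent expressions A = f1(d) and K = f2(d) over the formulation
#' geometry. Default fitness stops follow the study settings: RMSE 0.01
#' for the A map and 5.0 for the K map.
#'
#' @param weibull_table Data frame with the geometry column(s) and columns
#'   `A` and `K`; at least 2 rows.
#' @param cfg A [gp_config()] shared by both runs (fitness stops are
#'   overridden per run).
#' @param terminals Named character vector of geometry terminals; default
#'   `c(d = "d_mm")` (the reduced input vector).
#' @param fitness_stop_A,fitness_stop_K Per-run RMSE stops.
#' @return A list with elements `A` and `K`, each a `gp_result`.
#' @export
evolve_indirect <- function(weibull_table, cfg = gp_config(),
                            terminals = c(d = "d_mm"),
                            fitness_stop_A = 0.01, fitness_stop_K = 5.0) {
  assert_that(is.data.frame(weibull_table) && nrow(weibull_table) >= 2,
              "weibull_table needs at least 2 rows",
              "dissolvegp_argument_error")
  assert_that(all(c(terminals, "A", "K") %in% names(weibull_table)),
              "weibull_table must hold the terminals plus columns A and K",
              "dissolvegp_argument_error")
  bindings <- lapply(terminals, function(col) as.numeric(weibull_table[[col]]))
  names(bindings) <- names(terminals)
  cfg_A <- cfg; cfg_A$fitness_stop <- fitness_stop_A
  cfg_A$seed <- derive_seed(cfg$seed, 11)
  cfg_K <- cfg; cfg_K$fitness_stop <- fitness_stop_K
  cfg_K$seed <- derive_seed(cfg$seed, 13)
  list(
    A = gp_evolve(bindings, as.numeric(weibull_table$A), names(terminals), cfg_A),
    K = gp_evolve(bindings, as.numeric(weibull_table$K), names(terminals), cfg_K)
  )
}

#' @rdname evolve_direct
#' @param x A `gp_result`.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.gp_result <- function(x, ...) {
  tibble(
    rmse = x$rmse,
    generations = x$generations,
    size = tree_size(x$tree),
    depth = tree_depth(x$tree),
    expression = x$expression
  )
}
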