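# The four preprocessing transforms applied to dissolution datasets before
# model building: linear scaling (for bounded-activation networks), noise
# augmentation, output balancing, and surrogate-model design-space
# enhancement, plus the leave-one-formulation-out splitter.

#' Construct a linear scaling specification
#'
#' Per-variable endpoints of the linear map
#' `v -> target_min + (v - source_min) * (target_max - target_min) /
#' (source_max - source_min)`. The two target ranges used for network
#' training are (0.2, 0.8) (logistic activation) and (-0.8, 0.8)
#' (hyperbolic tangent).
#'
#' @param ds Optional dataset from which `source_min`/`source_max` are
#'   taken per variable.
#' @param variables Character vector of columns to scale.
#' @param target_min,target_max Target range endpoints (recycled).
#' @param source_min,source_max Optional explicit source endpoints
#'   (otherwise the observed range of each variable in `ds`).
#' @return A tibble of class `scaling_spec` with one row per variable.
#' @export
scaling_spec <- function(ds = NULL,
                         variables = c("d_mm", "L_mm", "t_min", "Q_pct"),
                         target_min = -0.8, target_max = 0.8,
                         source_min = NULL, source_max = NULL) {
  if (is.null(source_min) || is.null(source_max)) {
    assert_that(is.data.frame(ds),
                "ds is required when source endpoints are not given",
                "dissolvegp_argument_error")
    variables <- intersect(variables, names(ds))
    source_min <- vapply(variables, function(v) min(ds[[v]]), numeric(1))
    source_max <- vapply(variables, function(v) max(ds[[v]]), numeric(1))
  }
  spec <- tibble(
    variable = variables,
    source_min = as.numeric(source_min),
    source_max = as.numeric(source_max),
    target_min = rep_len(as.numeric(target_min), length(variables)),
    target_max = rep_len(as.numeric(target_max), length(variables))
  )
  bad <- spec$variable[spec$source_max <= spec$source_min]
  assert_that(length(bad) == 0,
              paste0("degenerate source range for: ", paste(bad, collapse = ", ")),
              "dissolvegp_degenerate_range_error")
  class(spec) <- c("scaling_spec", class(spec))
  spec
}

#' Linearly scale (and unscale) dataset variables
#'
#' `scale_linear()` maps each variable named in the spec onto its target
#' range; `unscale_linear()` is the exact inverse, so
#' `unscale_linear(scale_linear(ds, s), s)` returns `ds` to floating-point
#' accuracy.
#'
#' @param ds A dissolution dataset (or any data frame holding the spec's
#'   variables).
#' @param spec A [scaling_spec()].
#' @return The transformed tibble; `scale_linear()` stamps provenance
#'   `"scaled"` and attaches the spec as attribute `"scaling"`.
#' @export
scale_linear <- function(ds, spec) {
  assert_that(inherits(spec, "scaling_spec"), "spec must be a scaling_spec")
  missing_vars <- setdiff(spec$variable, names(ds))
  assert_that(length(missing_vars) == 0,
              paste0("spec covers variables absent from ds: ",
                     paste(missing_vars, collapse = ", ")),
              "dissolvegp_argument_error")
  out <- as_tibble(ds)
  for (i in seq_len(nrow(spec))) {
    v <- spec$variable[i]
    span <- spec$source_max[i] - spec$source_min[i]
    out[[v]] <- spec$target_min[i] +
      (out[[v]] - spec$source_min[i]) * (spec$target_max[i] - spec$target_min[i]) / span
  }
  attr(out, "scaling") <- spec
  set_provenance(out, "scaled")
}

#' @rdname scale_linear
#' @export
unscale_linear <- function(ds, spec = attr(ds, "scaling")) {
  assert_that(inherits(spec, "scaling_spec"),
              "no scaling spec given and none attached to ds",
              "dissolvegp_argument_error")
  out <- as_tibble(ds)
  for (i in seq_len(nrow(spec))) {
    v <- spec$variable[i]
    if (!v %in% names(out)) next
    tspan <- spec$target_max[i] - spec$target_min[i]
    out[[v]] <- spec$source_min[i] +
      (out[[v]] - spec$target_min[i]) * (spec$source_max[i] - spec$source_min[i]) / tspan
  }
  attr(out, "scaling") <- NULL
  set_provenance(out, "original")
}

#' Augment a dataset with jittered copies of its records
#'
#' For each original record one noised copy is appended whose numeric
#' fields are drawn uniformly within +/- `amplitude` (relative) of the
#' source value — the anti-overfitting augmentation applied before network
#' training and equation fitting. Q is clipped to \[0, 110\] to keep the
#' record contract.
#'
#' @param ds A dissolution dataset.
#' @param amplitude Relative jitter half-width; default 0.05 (+/-5%).
#' @param seed Integer seed; fixed seed gives identical output.
#' @return A tibble of `2 * nrow(ds)` records, provenance `"noised"`.
#' @export
add_noise <- function(ds, amplitude = 0.05, seed = NULL) {
  ds <- validate_dissolution_data(ds)
  assert_that(is.numeric(amplitude) && length(amplitude) == 1 && amplitude >= 0,
              "amplitude must be a single nonnegative number",
              "dissolvegp_argument_error")
  jittered <- with_seed(seed, {
    out <- ds
    for (col in c("d_mm", "L_mm", "t_min", "Q_pct")) {
      v <- out[[col]]
      out[[col]] <- v * runif(length(v), 1 - amplitude, 1 + amplitude)
    }
    out$Q_pct <- pmin(pmax(out$Q_pct, 0), 110)
    out
  })
  set_provenance(dplyr::bind_rows(ds, jittered), "noised")
}

#' Balance a dataset by its output distribution
#'
#' Records are binned by Q into `n_bins` equal-width bins; records in
#' under-represented bins (typically the low-Q early-release region) are
#' duplicated until every occupied bin holds at least half the count of
#' the fullest bin. No record is deleted and no new Q value is invented.
#'
#' @param ds A dissolution dataset.
#' @param n_bins Number of equal-width Q bins (>= 2); default 10.
#' @return The balanced tibble, provenance `"balanced"`.
#' @export
balance_by_output <- function(ds, n_bins = 10) {
  ds <- validate_dissolution_data(ds)
  assert_that(is.numeric(n_bins) && n_bins >= 2, "n_bins must be >= 2",
              "dissolvegp_argument_error")
  rng <- range(ds$Q_pct)
  if (diff(rng) == 0) {
    warn("all records fall in one output bin; dataset returned unchanged")
    return(set_provenance(ds, "balanced"))
  }
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  bin <- cut(ds$Q_pct, breaks = breaks, include.lowest = TRUE, labels = FALSE)
  counts <- tabulate(bin, nbins = n_bins)
  occupied <- which(counts > 0)
  if (length(occupied) == 1) {
    warn("all records fall in one output bin; dataset returned unchanged")
    return(set_provenance(ds, "balanced"))
  }
  target <- ceiling(max(counts) / 2)
  extra_idx <- unlist(lapply(occupied, function(b) {
    n_b <- counts[b]
    if (n_b >= target) return(integer(0))
    members <- which(bin == b)
    # deterministic recycling of the bin's own records
    rep_len(members, target - n_b)
  }))
  out <- dplyr::bind_rows(ds, ds[extra_idx, , drop = FALSE])
  set_provenance(out, "balanced")
}

#' Leave-one-formulation-out cross-validation folds
#'
#' One fold per formulation: the test member holds every record of that
#' formulation and the training member the rest, simulating prediction for
#' an unseen formulation. With the five-formulation study design this is
#' the 5-fold scheme in which each test fold is 20% of the database.
#'
#' @param ds A dissolution dataset with at least two formulations.
#' @return A tibble with one row per fold: `held_out_formulation`, and
#'   list-columns `train` and `test` holding the member datasets.
#' @export
split_leave_one_formulation_out <- function(ds) {
  ds <- validate_dissolution_data(ds)
  ids <- sort(unique(ds$formulation_id))
  assert_that(length(ids) >= 2,
              "need at least two formulations to split",
              "dissolvegp_split_error")
  tibble(
    held_out_formulation = ids,
    train = lapply(ids, function(id) {
      set_provenance(ds[ds$formulation_id != id, , drop = FALSE], provenance(ds))
    }),
    test = lapply(ids, function(id) {
      set_provenance(ds[ds$formulation_id == id, , drop = FALSE], provenance(ds))
    })
  )
}

#' Enhance a training set from a fitted surrogate model
#'
#' Samples the (d, t) design space on a regular grid — from each input's
#' training minimum up to `extend` times its maximum, in steps of
#' `step_frac` of the observed min-max range — evaluates the surrogate
#' (typically the best network) at each node to synthesize Q, and appends
#' these artificial records to the training data. Grid nodes whose
#' diameter coincides with a held-out test formulation are discarded so the
#' generalization assessment stays untouched.
#'
#' @param train Training dissolution dataset.
#' @param predictor Either a function `f(newdata)` taking a data frame with
#'   columns `d_mm` and `t_min` and returning Q (%), or a fitted model with
#'   a compatible `predict()` method (e.g. an MLP fit from [mlp_train()]
#'   trained on those inputs).
#' @param test Optional held-out dataset; artificial records overlapping
#'   its formulation diameters (within `tol`) are dropped.
#' @param step_frac Grid step as a fraction of each input's min-max range;
#'   default 0.0333 (3.33%).
#' @param extend Upper grid boundary as a multiple of the training maximum;
#'   default 1.10 (110%).
#' @param tol Diameter-overlap tolerance, mm.
#' @return `train` plus the artificial records (formulation_id `"grid"`,
#'   `L_mm = NA`), provenance `"enhanced"`.
#' @export
build_enhanced_dataset <- function(train, predictor, test = NULL,
                                   step_frac = 0.0333, extend = 1.10,
                                   tol = 1e-9) {
  train <- validate_dissolution_data(train)
  assert_that(step_frac > 0, "step_frac must be positive", "dissolvegp_argument_error")
  pred_fun <- as_predictor(predictor)
  d_grid <- design_grid_axis(train$d_mm, step_frac, extend)
  t_grid <- design_grid_axis(train$t_min, step_frac, extend)
  grid <- tidyr::expand_grid(d_mm = d_grid, t_min = t_grid)
  if (!is.null(test)) {
    held_d <- unique(test$d_mm)
    grid <- grid[!vapply(grid$d_mm,
                         function(d) any(abs(d - held_d) <= tol), logical(1)), ]
  }
  q <- rep(NA_real_, nrow(grid))
  ok <- rep(TRUE, nrow(grid))
  q <- tryCatch(pred_fun(grid), error = function(e) {
    # fall back to nodewise evaluation so single bad nodes are skipped
    vapply(seq_len(nrow(grid)), function(i) {
      tryCatch(pred_fun(grid[i, , drop = FALSE]), error = function(e) NA_real_)
    }, numeric(1))
  })
  ok <- is.finite(q)
  if (any(!ok)) {
    warn(sprintf("predictor failed at %d grid node(s); nodes skipped", sum(!ok)))
  }
  artificial <- tibble(
    formulation_id = "grid",
    d_mm = grid$d_mm[ok],
    L_mm = NA_real_,
    t_min = grid$t_min[ok],
    Q_pct = pmin(pmax(q[ok], 0), 110)
  )
  set_provenance(dplyr::bind_rows(train, artificial), "enhanced")
}

# One axis of the enhancement grid: min .. extend*max in steps of
# step_frac * (max - min).
design_grid_axis <- function(v, step_frac, extend) {
  lo <- min(v)
  hi <- extend * max(v)
  step <- step_frac * (max(v) - min(v))
  assert_that(step > 0, "degenerate input range for the design grid",
              "dissolvegp_degenerate_range_error")
  n <- floor((hi - lo) / step + 1e-9) + 1L
  axis <- lo + step * (seq_len(n) - 1L)
  # the extended boundary itself belongs to the sampled design space
  if (hi - axis[n] > 1e-9 * step) axis <- c(axis, hi)
  axis
}

# Normalize the predictor argument to a function(newdata) -> numeric.
as_predictor <- function(predictor) {
  if (is.function(predictor)) return(predictor)
  if (inherits(predictor, "mlp_fit") || inherits(predictor, "mlp_model")) {
    return(function(newdata) predict(predictor, newdata))
  }
  if (inherits(predictor, "eq_model")) {
    return(function(newdata) eval_equation(predictor, newdata$d_mm, newdata$t_min))
  }
  abort("predictor must be a function, an mlp fit, or an eq_model",
        class = "dissolvegp_argument_error")
}
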