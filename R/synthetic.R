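# Synthetic dissolution data faithful to the study design: five solid
# lipid extrudate formulations differing in diameter and length, sampled
# every 5 minutes up to 1000 minutes (200 time points each, 1000 records
# in total), with release curves drawn from a Weibull-family ground truth.

#' The five-formulation extrudate study design
#'
#' Geometry of the five solid lipid extrudate formulations: diameters from
#' 0.6 to 3.5 mm with lengths from 5 to 29 mm. Diameter and length are the
#' time-independent variables characterizing each formulation.
#'
#' @return A tibble with columns `formulation_id`, `d_mm`, `L_mm` (five
#'   rows, distinct diameters).
#' @examples
#' study_design()
#' @export
study_design <- function() {
  tibble(
    formulation_id = paste0("F", 1:5),
    d_mm = c(0.6, 1.0, 1.5, 2.7, 3.5),
    L_mm = c(14, 10, 29, 8, 5)
  )
}

#' Simulate dissolution profiles from a ground-truth release model
#'
#' Evaluates a known closed-form release equation on the study time grid
#' for each formulation and adds Gaussian measurement noise (clipped to
#' \[0, 110\]). With the defaults this reproduces the study's data volume:
#' 5 formulations x 200 samples = 1000 records. Replicate assays are
#' represented by their mean, i.e. one averaged profile per formulation.
#'
#' @param specs Formulation table as from [study_design()].
#' @param truth Ground-truth `eq_model`. The default, the
#'   `weibull_diffusion` family with c = (1.35, 0.55, 23.2), is a Weibull
#'   model whose time scale grows with the squared diameter
#'   (A = 23.2 d^2 min) and whose shape constant rises from 0.70 (d = 0.6)
#'   to 1.17 (d = 3.5) — monotone sigmoidal curves spanning fast thin-
#'   extrudate to slow thick-extrudate release.
#' @param t_max Last sampling time, min (default 1000).
#' @param dt Sampling interval, min (default 5).
#' @param noise_sd Gaussian noise standard deviation on Q, percentage
#'   points (default 1).
#' @param seed Integer seed; fixed seed gives an identical dataset.
#' @return A dissolution dataset tibble, provenance `"synthetic"`.
#' @examples
#' ds <- simulate_profiles(seed = 1)
#' nrow(ds) # 1000
#' @export
simulate_profiles <- function(specs = study_design(),
                              truth = equation_model("weibull_diffusion",
                                                     c(1.35, 0.55, 23.2)),
                              t_max = 1000, dt = 5, noise_sd = 1,
                              seed = NULL) {
  assert_that(dt > 0 && t_max >= dt, "need dt > 0 and t_max >= dt",
              "dissolvegp_argument_error")
  assert_that(inherits(truth, "eq_model"), "truth must be an eq_model")
  assert_that(noise_sd >= 0, "noise_sd must be nonnegative",
              "dissolvegp_argument_error")
  t_grid <- seq(dt, t_max, by = dt)
  base <- tidyr::expand_grid(specs, t_min = t_grid)
  q <- suppressWarnings(eval_equation(truth, base$d_mm, base$t_min))
  bad <- which(!is.finite(q))
  if (length(bad) > 0) {
    abort(sprintf("ground-truth model undefined at d = %g mm, t = %g min",
                  base$d_mm[bad[1]], base$t_min[bad[1]]),
          class = "dissolvegp_generation_error")
  }
  q <- with_seed(seed, q + rnorm(length(q), sd = noise_sd))
  out <- tibble(
    formulation_id = base$formulation_id,
    d_mm = base$d_mm,
    L_mm = base$L_mm,
    t_min = base$t_min,
    Q_pct = pmin(pmax(q, 0), 110)
  )
  set_provenance(out, "synthetic")
}
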