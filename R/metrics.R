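#' Root mean squared error
#'
#' The goodness-of-fit criterion used throughout the workflow:
#' \eqn{\mathrm{RMSE} = \sqrt{\sum_i (pred_i - obs_i)^2 / n}}.
#'
#' @param obs Numeric vector of observed values.
#' @param pred Numeric vector of predicted values, paired with `obs`.
#' @return A single nonnegative number; zero iff the vectors are identical.
#' @examples
#' rmse(c(0, 0), c(3, 4)) # sqrt(12.5)
#' @export
rmse <- function(obs, pred) {
  assert_that(is.numeric(obs) && is.numeric(pred), "obs and pred must be numeric")
  assert_that(length(obs) > 0, "obs and pred must be nonempty", "dissolvegp_argument_error")
  assert_that(length(obs) == length(pred),
              "obs and pred must have equal length", "dissolvegp_shape_error")
  sqrt(mean((pred - obs)^2))
}

#' Similarity factor f2 between two dissolution profiles
#'
#' The FDA similarity factor
#' \deqn{f_2 = 50 \log_{10}\left[\left(1 + \frac{1}{n}\sum_t (R_t-T_t)^2\right)^{-0.5} \cdot 100\right]}
#' comparing a reference and a test profile paired by time point. Identical
#' profiles score 100; profiles are conventionally called "similar" at
#' \eqn{f_2 \ge 50}. A uniform 10% offset gives 49.89.
#'
#' @param R Reference profile, percent released per time point.
#' @param T_ Test profile, same time points. (Named `T_` to avoid masking
#'   `T`.)
#' @param truncate_85 If `TRUE`, drop the time points after the first where
#'   both profiles exceed 85% release (one such point is kept), the common
#'   regulatory convention. Off by default.
#' @return The f2 value (dimensionless).
#' @examples
#' f2(c(10, 20, 30), c(10, 20, 30)) # 100
#' @export
f2 <- function(R, T_, truncate_85 = FALSE) {
  assert_that(is.numeric(R) && is.numeric(T_), "profiles must be numeric")
  assert_that(length(R) == length(T_),
              "profiles must have equal length", "dissolvegp_shape_error")
  assert_that(length(R) >= 1, "profiles must be nonempty", "dissolvegp_argument_error")
  if (isTRUE(truncate_85)) {
    over <- which(R > 85 & T_ > 85)
    if (length(over) > 1) {
      keep <- seq_len(over[1])
      R <- R[keep]
      T_ <- T_[keep]
    }
  }
  msd <- mean((R - T_)^2)
  50 * log10((1 + msd)^(-0.5) * 100)
}

#' Coefficient of variation, percent
#'
#' `100 * sd(x) / |mean(x)|` with the sample (n-1) standard deviation; used
#' to judge the stability of fitted equation parameters across
#' cross-validation folds.
#'
#' @param values Numeric vector, at least two values, nonzero mean.
#' @return CV as a percentage.
#' @examples
#' cv_percent(c(97.76, 97.25, 97.05, 96.72, 97.14)) # ~0.39
#' @export
cv_percent <- function(values) {
  assert_that(is.numeric(values), "values must be numeric")
  assert_that(length(values) >= 2,
              "CV needs at least two values", "dissolvegp_argument_error")
  m <- mean(values)
  assert_that(m != 0, "CV undefined for zero mean", "dissolvegp_argument_error")
  100 * sd(values) / abs(m)
}
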