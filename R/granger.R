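# Bivariate VAR fitting and Geweke causality measures.  The numerical work
# (orthogonal search / OLS on the lagged design) lives in compiled code;
# these wrappers validate input and shape the results.

.check_pair <- function(x, y, order) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) <= 10 * order)
    stop("series length must exceed 10 x order")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("series must be non-constant")
  list(x = x, y = y)
}

# shape the geweke_core() output into a VarModel object
.var_model <- function(core, order, fitter, threshold) {
  p <- order
  name_coef <- function(v, own_first) {
    lags <- function(pre) paste0(pre, "_lag", seq_len(p))
    names(v) <- c("intercept",
                  if (own_first == "x") c(lags("x"), lags("y"))
                  else c(lags("y"), lags("x")))
    v
  }
  structure(list(
    order = p,
    fitter = fitter,
    mse_reduction_threshold = threshold,
    coefficients = list(
      x_equation = name_coef(as.numeric(core$coef_x_full), "x"),
      y_equation = name_coef(as.numeric(core$coef_y_full), "y"),
      x_restricted = stats::setNames(as.numeric(core$coef_x_restricted),
                                     c("intercept",
                                       paste0("x_lag", seq_len(p)))),
      y_restricted = stats::setNames(as.numeric(core$coef_y_restricted),
                                     c("intercept",
                                       paste0("y_lag", seq_len(p))))),
    residual_variance_full = c(x = core$var_x_full, y = core$var_y_full),
    residual_variance_restricted = c(x = core$var_x_restricted,
                                     y = core$var_y_restricted),
    residual_covariance = matrix(c(core$var_x_full, core$cov_xy_full,
                                   core$cov_xy_full, core$var_y_full),
                                 2, 2, dimnames = list(c("x", "y"),
                                                       c("x", "y"))),
    n_effective = core$n_effective), class = "var_model")
}

#' Fit a bivariate VAR by ordinary least squares
#'
#' The full model regresses each series on an intercept plus lags 1..p of
#' both series; the restricted model of each series uses an intercept plus
#' its own lags only.  Residual variances are RSS / n_effective with
#' n_effective = T - p, so the restricted variance can never fall below the
#' full one.
#'
#' @param x,y Numeric series of equal length T > 10 p, non-constant.
#' @param order VAR order p (default 5, matching a regional haemodynamic
#'   delay of roughly 8 s at TR = 2 s).
#' @return An object of class `var_model` holding per-equation
#'   coefficients, full and restricted residual variances, the full-model
#'   innovation covariance and `n_effective`.
#' @export
fit_var_ols <- function(x, y, order = 5) {
  s <- .check_pair(x, y, order)
  core <- geweke_core(s$x, s$y, as.integer(order), 0)
  .check_degenerate(core)
  .var_model(core, order, "ols", 0)
}

#' Fit a bivariate VAR by Fast Orthogonal Search
#'
#' Greedy orthogonal regressor selection over the candidate set
#' \{intercept, lags 1..p of both series\}: at each step the candidate
#' giving the largest reduction in residual sum of squares (computed
#' through Gram-Schmidt orthogonalization against the admitted terms) is
#' admitted; the search stops when the best relative reduction falls below
#' `mse_reduction_threshold`.  Un-admitted candidates get coefficient zero.
#' The intercept is always admitted first.  With threshold 0 every
#' independent candidate is admitted and the fit equals [fit_var_ols()].
#'
#' @inheritParams fit_var_ols
#' @param mse_reduction_threshold Minimal relative MSE reduction to admit a
#'   further term (default 1e-3).
#' @return A `var_model`; see [fit_var_ols()].
#' @export
fit_var_fos <- function(x, y, order = 5, mse_reduction_threshold = 1e-3) {
  s <- .check_pair(x, y, order)
  if (mse_reduction_threshold < 0)
    stop("'mse_reduction_threshold' must be >= 0")
  core <- geweke_core(s$x, s$y, as.integer(order), mse_reduction_threshold)
  .check_degenerate(core)
  .var_model(core, order, "fos", mse_reduction_threshold)
}

.check_degenerate <- function(core) {
  if (core$var_x_full <= 0 || core$var_y_full <= 0)
    stop("zero residual variance: a series is perfectly predictable ",
         "from the lagged design")
  invisible(core)
}

#' @export
print.var_model <- function(x, ...) {
  cat(sprintf("bivariate var_model: order %d, fitter %s, n_eff %d\n",
              x$order, x$fitter, x$n_effective))
  cat(sprintf("residual variance (full/restricted): x %.4g/%.4g, y %.4g/%.4g\n",
              x$residual_variance_full["x"],
              x$residual_variance_restricted["x"],
              x$residual_variance_full["y"],
              x$residual_variance_restricted["y"]))
  invisible(x)
}

#' Geweke's linear-feedback (Granger causality) measures
#'
#' For two series x and y, the directed measure
#' F_(x->y) = ln(restricted variance of y / full variance of y) quantifies
#' how much the past of x improves prediction of y beyond y's own past;
#' F_(y->x) is symmetric; the instantaneous measure
#' F_(x.y) = ln(var_x var_y / det(innovation covariance)) captures
#' same-lag dependence that cannot be assigned a direction.  All values are
#' non-negative and invariant under per-series affine rescaling.
#'
#' @inheritParams fit_var_fos
#' @param fitter `"fos"` (pipeline default) or `"ols"`.
#' @return An object of class `gc_result` with fields `f_x_to_y`,
#'   `f_y_to_x`, `f_instantaneous`, the underlying `var_model`, and unset
#'   (`NA`) p-value slots to be filled by the surrogate test.
#' @examples
#' set.seed(1)
#' x <- rnorm(600)
#' y <- c(0, 0.9 * x[-600]) + rnorm(600)
#' geweke_measures(x, y, order = 5)$f_x_to_y  # close to ln(1.81)
#' @export
geweke_measures <- function(x, y, order = 5, fitter = c("fos", "ols"),
                            mse_reduction_threshold = 1e-3) {
  fitter <- match.arg(fitter)
  thr <- if (fitter == "ols") 0 else mse_reduction_threshold
  s <- .check_pair(x, y, order)
  core <- geweke_core(s$x, s$y, as.integer(order), thr)
  .check_degenerate(core)
  structure(list(
    f_x_to_y = core$f_x_to_y,
    f_y_to_x = core$f_y_to_x,
    f_instantaneous = core$f_instantaneous,
    p_x_to_y = NA_real_, p_y_to_x = NA_real_,
    significant_x_to_y = NA, significant_y_to_x = NA,
    model = .var_model(core, order, fitter, thr)), class = "gc_result")
}

#' @export
print.gc_result <- function(x, ...) {
  fmt_p <- function(p, s) {
    if (is.na(p)) "p not tested"
    else sprintf("p = %.4g%s", p, if (isTRUE(s)) " *" else "")
  }
  cat(sprintf("F_x->y = %.4f (%s)\n", x$f_x_to_y,
              fmt_p(x$p_x_to_y, x$significant_x_to_y)))
  cat(sprintf("F_y->x = %.4f (%s)\n", x$f_y_to_x,
              fmt_p(x$p_y_to_x, x$significant_y_to_x)))
  cat(sprintf("F_x.y  = %.4f (instantaneous, not tested)\n",
              x$f_instantaneous))
  invisible(x)
}
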