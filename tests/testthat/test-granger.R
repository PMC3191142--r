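# 2-node helper VAR used to generate data with known coefficients
sim_pair <- function(T, coef_xy = 0, coef_yx = 0, lag = 1, ar = 0.3,
                     sd = 1, seed = 1) {
  nodes <- c("x", "y")
  edges <- data.frame(source = character(0), target = character(0),
                      lag = integer(0), coefficient = numeric(0))
  if (coef_xy != 0)
    edges <- rbind(edges, data.frame(source = "x", target = "y",
                                     lag = lag, coefficient = coef_xy))
  if (coef_yx != 0)
    edges <- rbind(edges, data.frame(source = "y", target = "x",
                                     lag = lag, coefficient = coef_yx))
  self <- matrix(0, 2, 5)
  self[, 1] <- ar
  spec <- coupling_spec(nodes, "x", edges, self, noise_sd = sd, order = 5)
  ts <- simulate_subject(spec, T, seed = seed)
  list(x = ts$values[, 1], y = ts$values[, 2])
}

test_that("OLS recovers generating coefficients at vanishing noise", {
  # x drives y at the maximal lag 5 with near-zero target innovation.
  # (Shorter generating lags would put the recursion's exact linear
  # dependency inside the order-5 design and destroy identifiability.)
  set.seed(7)
  T <- 2000
  x <- as.numeric(arima.sim(list(ar = 0.4), T))
  y <- numeric(T)
  for (t in 6:T) y[t] <- 0.3 * y[t - 5] + 0.5 * x[t - 5] + rnorm(1, 0, 1e-6)
  m <- fit_var_ols(x, y, order = 5)
  co <- m$coefficients$y_equation
  expect_equal(unname(co["y_lag5"]), 0.3, tolerance = 1e-3)
  expect_equal(unname(co["x_lag5"]), 0.5, tolerance = 1e-3)
  others <- co[setdiff(names(co), c("y_lag5", "x_lag5", "intercept"))]
  expect_lt(max(abs(others)), 1e-3)
})

test_that("independent white noise yields null cross structure", {
  set.seed(8)
  x <- rnorm(10000)
  y <- rnorm(10000)
  m <- fit_var_ols(x, y, order = 5)
  cross <- m$coefficients$y_equation[paste0("x_lag", 1:5)]
  expect_lt(max(abs(cross)), 0.05)
  g <- geweke_measures(x, y, order = 5, fitter = "ols")
  expect_lt(g$f_x_to_y, 0.01)
  expect_lt(g$f_y_to_x, 0.01)
})

test_that("restricted variance never falls below the full variance", {
  for (seed in 1:8) {
    set.seed(seed)
    T <- 80 + seed * 10
    x <- as.numeric(arima.sim(list(ar = 0.5), T))
    y <- 0.3 * c(0, x[-T]) + rnorm(T)
    m <- fit_var_ols(x, y, order = 5)
    expect_lte(m$residual_variance_full["x"],
               m$residual_variance_restricted["x"] + 1e-12)
    expect_lte(m$residual_variance_full["y"],
               m$residual_variance_restricted["y"] + 1e-12)
    g <- geweke_measures(x, y, order = 5, fitter = "ols")
    expect_gte(g$f_x_to_y, 0)
    expect_gte(g$f_y_to_x, 0)
    expect_gte(g$f_instantaneous, 0)
  }
})

test_that("Geweke F matches the closed form for a lag-1 unit-coupling", {
  # y_t = 0.9 x_{t-1} + e_t with x, e unit white noise: restricted variance
  # of y is 0.81 + 1, full variance 1, so F = ln(1.81)
  set.seed(9)
  T <- 10000
  x <- rnorm(T)
  y <- 0.9 * c(0, x[-T]) + rnorm(T)
  g <- geweke_measures(x, y, order = 5, fitter = "ols")
  expect_equal(g$f_x_to_y, log(1.81), tolerance = 0.05)
  expect_lt(g$f_y_to_x, 0.02)
  # the default FOS fitter agrees closely here
  gf <- geweke_measures(x, y, order = 5, fitter = "fos")
  expect_equal(gf$f_x_to_y, log(1.81), tolerance = 0.05)
})

test_that("F measures are invariant under per-series affine maps", {
  p <- sim_pair(500, coef_xy = 0.5, seed = 4)
  g1 <- geweke_measures(p$x, p$y, order = 5, fitter = "ols")
  g2 <- geweke_measures(10 * p$x + 100, -3 * p$y + 7, order = 5,
                        fitter = "ols")
  expect_equal(g1$f_x_to_y, g2$f_x_to_y, tolerance = 1e-8)
  expect_equal(g1$f_y_to_x, g2$f_y_to_x, tolerance = 1e-8)
  expect_equal(g1$f_instantaneous, g2$f_instantaneous, tolerance = 1e-6)
})

test_that("FOS with threshold zero reproduces OLS exactly", {
  for (seed in 1:5) {
    p <- sim_pair(300, coef_xy = 0.4, coef_yx = 0.2, seed = seed)
    ols <- fit_var_ols(p$x, p$y, order = 5)
    fos <- fit_var_fos(p$x, p$y, order = 5, mse_reduction_threshold = 0)
    expect_equal(fos$coefficients$y_equation, ols$coefficients$y_equation,
                 tolerance = 1e-8)
    expect_equal(fos$coefficients$x_equation, ols$coefficients$x_equation,
                 tolerance = 1e-8)
    expect_equal(fos$residual_variance_full, ols$residual_variance_full,
                 tolerance = 1e-10)
  }
})

test_that("FOS admits true strong terms and prunes pure noise", {
  p <- sim_pair(600, coef_xy = 0.8, lag = 2, seed = 6)
  fos <- fit_var_fos(p$x, p$y, order = 5, mse_reduction_threshold = 1e-3)
  expect_true(fos$coefficients$y_equation["x_lag2"] != 0)

  set.seed(10)
  x <- rnorm(400)
  y <- rnorm(400)
  sparse <- fit_var_fos(x, y, order = 5, mse_reduction_threshold = 0.05)
  cross <- sparse$coefficients$y_equation[paste0("x_lag", 1:5)]
  expect_lte(sum(cross != 0), 1)
})

test_that("degenerate inputs are rejected with clear errors", {
  expect_error(fit_var_ols(rep(1, 100), rnorm(100), 5), "non-constant")
  expect_error(fit_var_ols(rnorm(50), rnorm(50), 5), "length")
  expect_error(fit_var_ols(rnorm(100), rnorm(99), 5), "equal length")
})
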