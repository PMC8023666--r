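hyp1 <- list(lengthscales = 60, sigma_f = 0.5)

test_that("the periodic kernel is symmetric, periodic and PSD", {
  expect_equal(kernel_eval(hyp1, 12, 12)[1, 1], hyp1$sigma_f^2)
  expect_equal(kernel_eval(hyp1, 10, 370), kernel_eval(hyp1, 10, 10))
  hyp2 <- list(lengthscales = c(40, 90), sigma_f = 1.2)
  set.seed(7)
  X <- matrix(runif(40, -180, 180), 20, 2)
  K <- kernel_eval(hyp2, X, X)
  expect_equal(K, t(K))
  expect_gt(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values), -1e-9)
  # shifting any component of either argument by 360 deg changes nothing
  X2 <- X; X2[, 1] <- X2[, 1] + 360
  expect_equal(kernel_eval(hyp2, X2, X), K)
  expect_error(kernel_eval(hyp2, c(1, 2, 3), c(1, 2)), "dimension mismatch")
})

test_that("a constant function is reproduced everywhere", {
  gp <- fit_1d_gp(function(x) 1.234, n = 7)
  xs <- matrix(seq(-180, 175, by = 15), ncol = 1)
  expect_lt(max(abs(gp_posterior(gp, xs)$mean - 1.234)), 1e-3)
})

test_that("a cosine landscape is learned from a 13-point grid", {
  k <- 0.3
  gp <- fit_1d_gp(function(x) k * cos(x * pi / 180), n = 13)
  held_out <- matrix(seq(-173, 180, by = 13), ncol = 1)
  err <- gp_posterior(gp, held_out)$mean - k * cos(held_out * pi / 180)
  expect_lt(max(abs(err)), 1e-2 * k)
})

test_that("refitting the same data gives identical hyperparameters", {
  f <- function(x) 0.2 * cos(2 * x * pi / 180) + 0.05 * sin(x * pi / 180)
  gp1 <- fit_1d_gp(f)
  gp2 <- fit_1d_gp(f)
  expect_identical(gp1$lengthscales, gp2$lengthscales)
  expect_identical(gp1$sigma_f, gp2$sigma_f)
})

test_that("the posterior interpolates the data and respects variance bounds", {
  set.seed(8)
  X <- matrix(runif(100, -180, 180), 50, 2)
  y <- 0.3 * cos(X[, 1] * pi / 180) + 0.2 * sin(2 * X[, 2] * pi / 180)
  gp <- gp_fit(X, y, noise_var = 1e-10)
  p <- gp_posterior(gp, X)
  expect_lt(max(abs(p$mean - y)), 1e-3)                 # exact interpolation
  expect_true(all(p$variance <= gp$noise_var + 1e-9))   # vanishes at the data
  expect_true(all(abs(p$mean - y) <= 3 * sqrt(gp$noise_var) + 1e-6))
  grid <- matrix(runif(400, -180, 180), 200, 2)
  v <- gp_posterior(gp, grid)$variance
  expect_true(all(v >= 0 & v <= gp$sigma_f^2 + 1e-9))
})

test_that("far from all data the prior variance is recovered", {
  gp <- gp_fit(matrix(c(-2, 0, 2), ncol = 1), c(0.1, 0.0, 0.1),
               optimize = FALSE,
               init = list(lengthscales = 10, sigma_f = 0.7))
  v <- gp_posterior(gp, 180)$variance
  expect_equal(v, 0.7^2, tolerance = 1e-6)
})

test_that("posterior mean gradient matches central finite differences", {
  f <- function(x) 0.3 * cos(x * pi / 180) + 0.1 * cos(3 * x * pi / 180 + 1)
  gp <- fit_1d_gp(f, n = 15)
  h <- 1e-3
  for (x in c(-150, -33.3, 0, 77, 179)) {
    fd <- (gp_posterior(gp, x + h)$mean - gp_posterior(gp, x - h)$mean) / (2 * h)
    expect_equal(gp_posterior_gradient(gp, x), fd, tolerance = 1e-4)
  }
  # periodicity of the gradient
  expect_equal(gp_posterior_gradient(gp, 45),
               gp_posterior_gradient(gp, 45 + 360), tolerance = 1e-12)
})

test_that("the gradient vanishes at a symmetry point of symmetric data", {
  # data symmetric about 0: even function
  gp <- fit_1d_gp(function(x) 0.2 * cos(x * pi / 180), n = 12)
  expect_lt(abs(gp_posterior_gradient(gp, 0)), 1e-6)
})

test_that("predictions are invariant under a global 360-degree input shift", {
  f <- function(x) 0.25 * cos(2 * x * pi / 180 + 0.3)
  x <- seq(-180, 168, by = 29)
  y <- f(x)
  gp1 <- gp_fit(matrix(x, ncol = 1), y)
  gp2 <- gp_fit(matrix(x + 360, ncol = 1), y)
  xs <- matrix(seq(-170, 170, by = 35), ncol = 1)
  expect_equal(gp_posterior(gp1, xs)$mean, gp_posterior(gp2, xs)$mean,
               tolerance = 1e-9)
})

test_that("a surrogate checkpoint survives a save/load round trip", {
  gp <- fit_1d_gp(function(x) 0.2 * cos(2 * x * pi / 180))
  path <- withr::local_tempfile(fileext = ".json")
  gp_save(gp, path)
  gp2 <- gp_load(path)
  xs <- matrix(seq(-179, 179, by = 17), ncol = 1)
  expect_equal(gp_posterior(gp2, xs)$mean, gp_posterior(gp, xs)$mean,
               tolerance = 1e-10)
  expect_equal(gp2$lengthscales, gp$lengthscales)
})

test_that("unfitted or mismatched inputs raise state errors", {
  expect_error(gp_posterior(list(), 0), "not a fitted")
  expect_error(gp_fit(matrix(1, 1, 1), 1), ">= 2")
})
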