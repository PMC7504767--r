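# Gaussian-process potency surface: fitting, alpha selection,
# rasterization.

test_that("constant potencies reproduce the constant everywhere", {
  set.seed(21)
  x <- cbind(runif(40), runif(40))
  surf <- fit_surface(x, rep(6.4, 40))
  grid <- cbind(runif(50), runif(50))
  expect_true(all(abs(predict(surf, grid) - 6.4) < 1e-3))
  ras <- evaluate_surface(surf, width = 28, height = 30)
  expect_true(all(abs(ras$values - 6.4) < 1e-3))
})

test_that("a smooth function is recovered at held-out points", {
  set.seed(22)
  x <- cbind(runif(200, 0, 3), runif(200, 0, 3))
  f <- function(p) 6 + sin(p[, 1]) + cos(p[, 2])
  y <- f(x) + rnorm(200, sd = 0.05)
  surf <- fit_surface(x, y)
  xs <- cbind(runif(100, 0.2, 2.8), runif(100, 0.2, 2.8))
  expect_lt(max(abs(predict(surf, xs) - f(xs))), 0.1)
})

test_that("training residuals are bounded by the fitted noise scale", {
  set.seed(23)
  x <- cbind(runif(150), runif(150))
  y <- 6 + sin(4 * x[, 1]) + cos(4 * x[, 2]) + rnorm(150, sd = 0.15)
  surf <- fit_surface(x, y)
  sigma <- sqrt(surf$noise_level + surf$alpha) * surf$scale
  res <- y - predict(surf, x)
  # ~2 sigma bound holds for the bulk of the points (Gaussian residuals)
  expect_gte(mean(abs(res) <= 2 * sigma), 0.9)
})

test_that("the selected alpha maximizes the log marginal likelihood", {
  set.seed(24)
  x <- cbind(runif(80), runif(80))
  y <- 5 + x[, 1] + rnorm(80, sd = 0.2)
  surf <- fit_surface(x, y)
  expect_length(surf$alpha_lml, 10L)
  expect_equal(surf$alpha_candidates, 10^seq(-7, -1, length.out = 10))
  sel <- which(surf$alpha_candidates == surf$alpha)
  expect_true(all(surf$alpha_lml[sel] >= surf$alpha_lml - 1e-9))
  expect_equal(surf$lml, surf$alpha_lml[sel])
})

test_that("predictions agree with an independent direct GPR oracle", {
  set.seed(25)
  x <- cbind(runif(30), runif(30))
  y <- 6 + sin(3 * x[, 1]) + rnorm(30, sd = 0.1)
  surf <- fit_surface(x, y)
  # oracle: plain R linear algebra from the stored hyperparameters
  matk <- function(a, b, ls) {
    d <- sqrt(outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2)
    (1 + sqrt(3) * d / ls) * exp(-sqrt(3) * d / ls)
  }
  K <- matk(x, x, surf$length_scale)
  diag(K) <- diag(K) + surf$noise_level + surf$alpha
  z <- (y - surf$offset) / surf$scale
  new <- cbind(runif(15), runif(15))
  oracle <- as.vector(matk(new, x, surf$length_scale) %*% solve(K, z)) *
    surf$scale + surf$offset
  expect_equal(predict(surf, new), oracle, tolerance = 1e-8)
})

test_that("held-out error decreases with the noise level", {
  set.seed(26)
  x <- cbind(runif(120, 0, 2), runif(120, 0, 2))
  f <- 6 + sin(2 * x[, 1]) + cos(2 * x[, 2])
  hold <- cbind(runif(60, 0.2, 1.8), runif(60, 0.2, 1.8))
  fh <- 6 + sin(2 * hold[, 1]) + cos(2 * hold[, 2])
  rmse <- vapply(c(0.5, 0.15, 0.02), function(s) {
    yy <- f + rnorm(120, sd = s)
    sqrt(mean((predict(fit_surface(x, yy), hold) - fh)^2))
  }, numeric(1))
  expect_true(all(diff(rmse) < 0))
})

test_that("degenerate inputs are rejected", {
  expect_error(fit_surface(matrix(0.5, 10, 2), runif(10)), "degenerate")
  expect_error(fit_surface(cbind(1:5, 1:5), runif(4)), "does not match")
  set.seed(27)
  surf <- fit_surface(cbind(runif(10), runif(10)), runif(10, 5, 7))
  expect_error(evaluate_surface(surf, extent = c(0, 1, 1, 1)), "extent")
})

test_that("rasterization is consistent with pointwise prediction", {
  set.seed(28)
  x <- cbind(runif(60), runif(60))
  y <- 6 + sin(3 * x[, 1]) + cos(3 * x[, 2]) + rnorm(60, sd = 0.02)
  surf <- fit_surface(x, y)
  ras <- evaluate_surface(surf)
  expect_equal(dim(ras$values), c(300L, 280L))
  expect_true(all(is.finite(ras$values)))
  # raster value at the pixel nearest a training point tracks the model
  ext <- ras$extent
  for (i in sample(60, 10)) {
    col <- pmin(pmax(round((x[i, 1] - ext[1]) / (ext[2] - ext[1]) * 280 + 0.5), 1), 280)
    row <- pmin(pmax(round((ext[4] - x[i, 2]) / (ext[4] - ext[3]) * 300 + 0.5), 1), 300)
    expect_lt(abs(ras$values[row, col] - predict(surf, x[i, , drop = FALSE])),
              0.05)
  }
  # doubling the resolution then 2x2 averaging reproduces the raster
  ras2 <- evaluate_surface(surf, extent = ext, width = 560, height = 600)
  down <- 0.25 * (ras2$values[seq(1, 599, 2), seq(1, 559, 2)] +
                  ras2$values[seq(2, 600, 2), seq(1, 559, 2)] +
                  ras2$values[seq(1, 599, 2), seq(2, 560, 2)] +
                  ras2$values[seq(2, 600, 2), seq(2, 560, 2)])
  expect_lt(max(abs(down - ras$values)), 0.05)
})

test_that("surface archives restore an equivalent model", {
  set.seed(29)
  x <- cbind(runif(40), runif(40))
  y <- runif(40, 4, 9)
  surf <- fit_surface(x, y)
  path <- withr::local_tempfile(fileext = ".json")
  write_surface(surf, path)
  back <- read_surface(path)
  new <- cbind(runif(10), runif(10))
  expect_equal(predict(back, new), predict(surf, new), tolerance = 1e-8)
  expect_equal(coef(back), coef(surf))
})
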