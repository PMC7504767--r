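# KLD, symmetric relative entropy, cosine distance, pairwise comparison.

# independent brute-force oracles
kld_loop <- function(p, q, base = exp(1)) {
  s <- 0
  for (i in seq_along(p)) s <- s + p[i] * log(p[i] / q[i], base = base)
  s
}
cd_loop <- function(x, y) {
  dot <- 0; nx <- 0; ny <- 0
  for (i in seq_along(x)) {
    dot <- dot + x[i] * y[i]; nx <- nx + x[i]^2; ny <- ny + y[i]^2
  }
  1 - dot / sqrt(nx * ny)
}
rand_dist <- function(k = 8) {
  p <- runif(k, 0.01, 1)
  p / sum(p)
}

test_that("KLD matches direct summation and its known asymmetry", {
  p <- c(0.5, 0.5); q <- c(0.25, 0.75)
  expect_equal(kl_divergence(p, q), 0.5 * log(2) + 0.5 * log(2 / 3))
  expect_equal(kl_divergence(p, q), 0.14384, tolerance = 1e-4)
  expect_equal(kl_divergence(q, p), 0.13081, tolerance = 1e-4)
  expect_false(isTRUE(all.equal(kl_divergence(p, q), kl_divergence(q, p))))
  expect_equal(kl_divergence(p, p), 0)
  expect_equal(kl_divergence(p, q, base = 2),
               kl_divergence(p, q) / log(2))
  expect_error(kl_divergence(c(0.5, 0.5, 0), c(0.5, 0.25, 0.25)),
               "smoothed")
  expect_error(kl_divergence(p, c(0.2, 0.2)), "sum to 1")
  expect_error(kl_divergence(p, rand_dist(3)), "length")
})

test_that("symmetric relative entropy averages the two divergences", {
  p <- c(0.5, 0.5); q <- c(0.25, 0.75)
  expect_equal(relative_entropy(p, q), (0.14384 + 0.13081) / 2,
               tolerance = 1e-4)
  expect_equal(relative_entropy(p, p), 0)
})

test_that("formulas match brute force on 100 random distribution pairs", {
  set.seed(51)
  for (k in 1:100) {
    p <- rand_dist(); q <- rand_dist()
    expect_equal(kl_divergence(p, q), kld_loop(p, q), tolerance = 1e-12)
    expect_equal(relative_entropy(p, q),
                 (kld_loop(p, q) + kld_loop(q, p)) / 2, tolerance = 1e-12)
    expect_equal(relative_entropy(p, q), relative_entropy(q, p))
    expect_gte(relative_entropy(p, q), 0)
    x <- runif(8, 0, 100); y <- runif(8, 0, 100)
    expect_equal(cosine_distance(x, y), cd_loop(x, y), tolerance = 1e-12)
    expect_true(cosine_distance(x, y) >= 0 && cosine_distance(x, y) <= 1)
    expect_equal(cosine_distance(x, x), 0)
    expect_equal(cosine_distance(x, 3.7 * x), 0)
  }
})

test_that("cosine distance closed forms and errors", {
  expect_equal(cosine_distance(c(1, 0, 0), c(0, 1, 0)), 1)
  expect_equal(cosine_distance(c(1, 0), c(1, 1)), 1 - 1 / sqrt(2))
  expect_error(cosine_distance(c(0, 0), c(1, 1)), "zero vector")
})

test_that("RE and CD rank perturbation size the same way", {
  set.seed(52)
  for (k in 1:10) {
    p <- rand_dist()
    bump <- function(eps) {
      q <- p + eps * (rand_dist() - p)
      q / sum(q)
    }
    q_small <- bump(0.05); q_big <- bump(0.8)
    expect_lt(relative_entropy(p, q_small), relative_entropy(p, q_big))
    expect_lt(cosine_distance(p, q_small), cosine_distance(p, q_big))
  }
})

test_that("compare_all produces sorted, order-invariant pairs", {
  set.seed(53)
  mk <- function(id) {
    fv <- categorize_cells(matrix(runif(3360, -1, 1), 60, 56), id = id)
    fv
  }
  fvs <- lapply(c("b", "d", "a", "c"), mk)
  res <- compare_all(fvs)
  expect_equal(nrow(res), 6L)
  expect_equal(res$id_a, c("a", "a", "a", "b", "b", "c"))
  res2 <- compare_all(rev(fvs))
  expect_equal(res, res2, ignore_attr = TRUE)
  expect_true(all(res$re >= 0))
  # identical feature vectors compare at exactly zero
  res0 <- compare_all(list(mk("x"), local({f <- mk("x"); f$id <- "y"; f})))
  expect_true(res0$re[1] >= 0)
  dup <- fvs; dup[[2]]$id <- "b"; dup[[1]]$id <- "b"
  expect_error(compare_all(dup), "duplicate")
})

test_that("identical distributions give RE = 0 and CD = 0", {
  fv <- categorize_cells(matrix(runif(3360, -1, 1), 60, 56), id = "a")
  fv2 <- fv; fv2$id <- "b"
  res <- compare_all(list(fv, fv2))
  expect_equal(res$re, 0)
  expect_equal(res$cd, 0)
})
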