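# Grid partitioning and the eight-category cell distribution.

test_that("cell means equal the 25-pixel block averages", {
  v <- matrix(0.3, 300, 280)
  cells <- partition_cells(v)
  expect_equal(dim(unclass(cells)), c(60L, 56L))
  expect_true(all(abs(cells - 0.3) < 1e-12))
  # a single +1 block in a -1 image flips exactly one cell
  v <- matrix(-1, 300, 280)
  v[11:15, 26:30] <- 1
  cells <- partition_cells(v)
  expect_equal(sum(cells == 1), 1L)
  expect_equal(cells[3, 6], 1)
  expect_equal(sum(cells == -1), 3359L)
  # brute-force oracle on random cells
  set.seed(41)
  v <- matrix(runif(300 * 280, -1, 1), 300, 280)
  cells <- partition_cells(v)
  for (k in 1:20) {
    r <- sample(60, 1); c <- sample(56, 1)
    block <- v[(5 * (r - 1) + 1):(5 * r), (5 * (c - 1) + 1):(5 * c)]
    acc <- 0
    for (val in block) acc <- acc + val
    expect_equal(cells[r, c], acc / 25)
  }
  expect_error(partition_cells(matrix(0, 100, 90)), "280 x 300")
})

test_that("categorization uses lower-inclusive bins covering [-1, 1]", {
  g <- matrix(0.8, 60, 56)
  expect_equal(categorize_cells(g)$counts, c(0, 0, 0, 0, 0, 0, 0, 3360))
  # boundary conventions
  vals <- c(-1, -0.75, -0.5, -0.25, 0, 0.25, 0.5, 0.75, 1)
  cats <- vapply(vals, function(v)
    which(categorize_cells(matrix(v, 1, 1))$counts == 1L), integer(1))
  expect_equal(cats, c(1L, 2L, 3L, 4L, 5L, 6L, 7L, 8L, 8L))
  # counts always conserve the number of cells
  set.seed(42)
  for (k in 1:10) {
    fv <- categorize_cells(matrix(runif(3360, -1, 1), 60, 56))
    expect_equal(sum(fv$counts), 3360L)
    expect_equal(sum(fv$probabilities), 1, tolerance = 1e-12)
  }
})

test_that("probability smoothing keeps every bin strictly positive", {
  fv <- categorize_cells(matrix(0.8, 60, 56), epsilon = 0.5)
  expect_true(all(fv$probabilities > 0))
  expect_equal(fv$probabilities[8], 3360.5 / 3364)
  expect_equal(fv$probabilities[1], 0.5 / 3364)
})

test_that("feature vectors are orientation-invariant", {
  for (s in 1:4) {
    img <- generate_heatmap_fixture(c("smooth", "rugged")[s %% 2 + 1], seed = s)
    base <- feature_vector(img)$counts
    hflip <- structure(img[, dim(img)[2]:1, , drop = FALSE],
                       class = "heatmap_image")
    vflip <- structure(img[dim(img)[1]:1, , , drop = FALSE],
                       class = "heatmap_image")
    rot180 <- structure(img[dim(img)[1]:1, dim(img)[2]:1, , drop = FALSE],
                        class = "heatmap_image")
    expect_identical(feature_vector(hflip)$counts, base)
    expect_identical(feature_vector(vflip)$counts, base)
    expect_identical(feature_vector(rot180)$counts, base)
  }
})

test_that("the end-to-end feature vector is deterministic and sane", {
  d <- tiny_dataset(seed = 6, n = 40, series = 3)
  f1 <- feature_vector(d$compounds, seed = 4, id = "x")
  f2 <- feature_vector(d$compounds, seed = 4, id = "x")
  expect_identical(f1$counts, f2$counts)
  expect_equal(sum(f1$counts), 3360L)
  # uniformly high-potency dataset saturates the top category
  cs <- compound_set(sprintf("c%02d", 1:30), runif(30, 9, 10),
                     fingerprints = fp_fixture(30, seed = 43))
  fv <- feature_vector(cs, seed = 1)
  expect_equal(fv$counts[8], 3360L)
})

test_that("feature JSON and CSV round-trip", {
  fv <- feature_vector(generate_heatmap_fixture("rugged", seed = 9),
                       id = "rug")
  jp <- withr::local_tempfile(fileext = ".json")
  write_features(fv, jp)
  back <- read_features(jp)
  expect_equal(back$counts, fv$counts)
  expect_equal(back$probabilities, fv$probabilities)
  expect_equal(back$id, "rug")
  expect_equal(back$grid, "56x60")
  cp <- withr::local_tempfile(fileext = ".csv")
  write_features_csv(fv, cp)
  df <- read.csv(cp)
  expect_equal(df$count, fv$counts)
})
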