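# Synthetic dataset generator and heatmap fixtures.

test_that("datasets are reproducible and validate their parameters", {
  d1 <- generate_dataset(n_compounds = 80, n_series = 5, seed = 7)
  d2 <- generate_dataset(n_compounds = 80, n_series = 5, seed = 7)
  expect_identical(d1$compounds$potencies, d2$compounds$potencies)
  expect_identical(d1$compounds$fingerprints, d2$compounds$fingerprints)
  d3 <- generate_dataset(n_compounds = 80, n_series = 5, seed = 8)
  expect_false(identical(d1$compounds$potencies, d3$compounds$potencies))
  expect_equal(d1$compounds$n, 80L)
  expect_equal(length(unique(d1$series)), 5L)
  expect_error(generate_dataset(n_compounds = 3, n_series = 5), "n_series")
  expect_error(generate_dataset(ruggedness = 1.4), "ruggedness")
  expect_error(generate_dataset(potency_range = c(9, 4)), "potency_range")
})

test_that("ruggedness 0 with no noise gives flat series potencies", {
  d <- generate_dataset(n_compounds = 60, n_series = 4, ruggedness = 0,
                        noise_sd = 0, seed = 9)
  for (s in unique(d$series)) {
    p <- d$compounds$potencies[d$series == s]
    expect_lt(diff(range(p)), 1e-12)
  }
  expect_false(any(d$cliff))
  expect_true(all(d$compounds$potencies >= 4 - 1e-9 &
                  d$compounds$potencies <= 10 + 1e-9))
})

test_that("ruggedness creates potency-extreme activity-cliff subgroups", {
  d <- generate_dataset(n_compounds = 100, n_series = 10, ruggedness = 0.8,
                        noise_sd = 0, seed = 10)
  # cliffs live in exactly 8 of the 10 series, as a minority subgroup
  expect_equal(length(unique(d$series[d$cliff])), 8L)
  expect_lt(sum(d$cliff), 50L)
  for (i in which(d$cliff)) {
    s <- d$series[i]
    others <- d$compounds$potencies[d$series == s & !d$cliff]
    if (length(others))
      expect_gt(abs(d$compounds$potencies[i] - mean(others)), 2)
  }
  # same-seed datasets are topology variants with nested cliff sets
  d4 <- generate_dataset(n_compounds = 100, n_series = 10, ruggedness = 0.4,
                         noise_sd = 0, seed = 10)
  expect_true(all(which(d4$cliff) %in% which(d$cliff)))
  expect_identical(d4$compounds$fingerprints, d$compounds$fingerprints)
  expect_equal(d4$compounds$potencies[!d$cliff],
               d$compounds$potencies[!d$cliff])
})

test_that("Tanimoto distances track the latent chemical space", {
  within <- numeric(20); between <- numeric(20); cors <- numeric(20)
  for (s in 1:20) {
    d <- generate_dataset(n_compounds = 40, n_series = 4, seed = s)
    dm <- tanimoto_distance_matrix(d$compounds)
    latent <- as.matrix(dist(d$latent))
    same <- outer(d$series, d$series, "==") & upper.tri(dm)
    diff_s <- !outer(d$series, d$series, "==") & upper.tri(dm)
    within[s] <- mean(dm[same]); between[s] <- mean(dm[diff_s])
    cors[s] <- cor(dm[upper.tri(dm)], latent[upper.tri(latent)])
  }
  expect_true(all(within < between))
  expect_gt(median(cors), 0.5)
})

test_that("heatmap fixtures have the promised exact structure", {
  cst <- generate_heatmap_fixture("constant")
  expect_equal(feature_vector(cst)$counts, c(0, 0, 0, 0, 0, 0, 0, 3360))
  spl <- generate_heatmap_fixture("split")
  expect_equal(feature_vector(spl)$counts, c(1680, 0, 0, 0, 0, 0, 0, 1680))
  smo <- generate_heatmap_fixture("smooth", seed = 2)
  expect_equal(dim(unclass(smo)), c(300L, 280L, 3L))
  rug <- generate_heatmap_fixture("rugged", seed = 2)
  # rugged images put mass in both valley and peak categories
  fr <- feature_vector(rug)$counts
  expect_gt(fr[8], 0); expect_gt(sum(fr[1:4]), 0)
  expect_error(generate_heatmap_fixture("spiky"), "arg")
})

test_that("smooth and rugged fixtures are farther apart than two smooths", {
  re <- function(a, b)
    relative_entropy(feature_vector(a)$probabilities,
                     feature_vector(b)$probabilities)
  gaps <- vapply(1:5, function(s) {
    smooth1 <- generate_heatmap_fixture("smooth", seed = s)
    smooth2 <- generate_heatmap_fixture("smooth", seed = s + 100)
    rugged <- generate_heatmap_fixture("rugged", seed = s)
    re(smooth1, rugged) - re(smooth1, smooth2)
  }, numeric(1))
  expect_gt(median(gaps), 0)
})
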