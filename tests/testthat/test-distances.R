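test_that("Euclidean distances are metric and exact on known points", {
  x <- rbind(a = c(0, 0), b = c(3, 4), c = c(0, 0))
  d <- euclidean_distances(x)
  expect_equal(d["a", "b"], 5)
  expect_equal(d["a", "c"], 0)
  expect_equal(d, t(d))
  set.seed(8)
  y <- matrix(runif(40), nrow = 8)
  dy <- euclidean_distances(y)
  for (i in 1:8) for (j in 1:8) for (k in 1:8)
    expect_lte(dy[i, j], dy[i, k] + dy[k, j] + 1e-12)
  expect_error(euclidean_distances(rbind(c(1, NA))),
               class = "eh_missing_values")
})

test_that("Bray-Curtis follows its definition, with pairwise deletion", {
  x <- rbind(u = c(2, 2), v = c(1, 1), w = c(1, 0), z = c(0, 1))
  d <- bray_curtis_distances(x)
  expect_equal(d["u", "v"], 1 / 3)
  expect_equal(d["w", "z"], 1.0)
  expect_equal(d["u", "u"], 0)
  expect_true(all(d >= 0 & d <= 1))
  # both-zero pair is defined as distance 0
  x0 <- rbind(a = c(0, 0), b = c(0, 0))
  expect_equal(bray_curtis_distances(x0)["a", "b"], 0)
  # pairwise deletion drops the missing feature from both sums
  xm <- rbind(u = c(1, NA, 2), v = c(1, 1, 4))
  expect_error(bray_curtis_distances(xm), class = "eh_missing_values")
  dm <- bray_curtis_distances(xm, pairwise_deletion = TRUE)
  expect_equal(dm["u", "v"], (0 + 2) / (2 + 6))
  expect_error(bray_curtis_distances(rbind(c(-1, 2), c(1, 1))),
               class = "eh_negative_values")
})

test_that("classical MDS reproduces Euclidean geometry exactly", {
  # collinear points embed perfectly in one dimension
  d3 <- euclidean_distances(cbind(c(0, 1, 3)))
  fit1 <- classical_mds(d3, k = 1)
  expect_equal(as.matrix(dist(fit1$points)), unname(d3), tolerance = 1e-9,
               ignore_attr = TRUE)
  # full-rank recovery of 10 random 3-D points
  set.seed(14)
  pts <- matrix(rnorm(30), ncol = 3)
  rownames(pts) <- paste0("p", 1:10)
  d <- euclidean_distances(pts)
  fit <- classical_mds(d, k = 3)
  expect_equal(as.matrix(dist(fit$points)), d, tolerance = 1e-9)
  expect_false(fit$padded)
  # duplicated sample lands on identical coordinates
  dd <- euclidean_distances(pts[c(1, 1, 2, 3), ])
  fd <- classical_mds(dd, k = 2)
  expect_equal(fd$points[1, ], fd$points[2, ])
  # requesting more axes than the rank pads with zeros and flags it
  fpad <- classical_mds(d3, k = 2)
  expect_true(fpad$padded)
  expect_equal(unname(fpad$points[, 2]), rep(0, 3))
  # deterministic sign convention: largest-magnitude loading positive
  expect_gte(max(fit$points[, 1]), abs(min(fit$points[, 1])))
})

test_that("Mantel test is exact on self-comparison and seed-reproducible", {
  set.seed(2)
  x <- matrix(rnorm(24), nrow = 8,
              dimnames = list(paste0("s", 1:8), NULL))
  d1 <- euclidean_distances(x)
  mt <- mantel_test(d1, d1, n_permutations = 999, seed = 10)
  expect_equal(mt$r, 1.0)
  expect_equal(mt$p_value, 1 / 1000)
  # scale invariance of Pearson r
  expect_equal(mantel_test(d1, 2 * d1, n_permutations = 99, seed = 1)$r, 1.0)
  # reproducibility
  y <- matrix(rnorm(24), nrow = 8, dimnames = list(paste0("s", 1:8), NULL))
  d2 <- euclidean_distances(y)
  p1 <- mantel_test(d1, d2, n_permutations = 199, seed = 7)$p_value
  p2 <- mantel_test(d1, d2, n_permutations = 199, seed = 7)$p_value
  expect_identical(p1, p2)
  rownames(d2) <- colnames(d2) <- paste0("t", 1:8)
  expect_error(mantel_test(d1, d2), class = "eh_mismatched_samples")
})

test_that("pairwise mixed model recovers the generating slope", {
  sim <- simulate_pairwise_distances(n_individuals = 30, beta = 0.5,
                                     sd_id = 0.2, sd_resid = 0.1, seed = 4)
  fit <- fit_pairwise_mixed_model(sim$epi_d, sim$gen_d, sim$samples)
  expect_gt(fit$coefficients[["gen"]], 0.35)
  expect_lt(fit$coefficients[["gen"]], 0.65)
  expect_gt(fit$variance_components[["id1"]] + fit$variance_components[["id2"]], 0)
  # the random effects earn their AIC keep when they exist
  expect_gt(fit$delta_aic, 0)
})

test_that("AIC drops the random effects when individual effects are absent", {
  prefer_fixed <- 0
  for (s in 1:10) {
    sim <- simulate_pairwise_distances(n_individuals = 20, beta = 0.5,
                                       sd_id = 0, sd_resid = 0.1, seed = 100 + s)
    fit <- suppressMessages(
      fit_pairwise_mixed_model(sim$epi_d, sim$gen_d, sim$samples))
    if (fit$delta_aic < 0) prefer_fixed <- prefer_fixed + 1
  }
  expect_gte(prefer_fixed, 5)
})

test_that("constant genetic distances are rejected", {
  sim <- simulate_pairwise_distances(n_individuals = 10, seed = 5)
  gen0 <- sim$gen_d; gen0[] <- 1; diag(gen0) <- 0
  expect_error(fit_pairwise_mixed_model(sim$epi_d, gen0, sim$samples),
               class = "eh_degenerate_design")
})
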