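test_that("at dispersion 0 the exact test reduces to the conditional binomial", {
  # one sample per group, equal libraries: counts 0 vs 10
  m <- make_counts(rbind(c(0, 10), c(5, 5)), c("parent1", "parent2"))
  res <- dmc_test(m, "parent1", "parent2", dispersion = 0)
  expect_equal(res$p_value[1], 2 * 0.5^10, tolerance = 1e-12)
  expect_equal(res$p_value[2], 1.0)
})

test_that("identical groups give logFC 0 and p near 1", {
  counts <- matrix(rep(c(3, 8, 0, 15), 2), ncol = 2)
  m <- make_counts(counts, c("parent1", "parent2"))
  res <- dmc_test(m, "parent1", "parent2", dispersion = 0.1)
  expect_true(all(res$logFC == 0))
})

test_that("p-values are label-symmetric and logFC flips sign", {
  set.seed(42)
  counts <- matrix(rnbinom(60, size = 5, mu = 20), ncol = 6)
  m <- make_counts(counts, rep(c("parent1", "parent2"), each = 3))
  a <- dmc_test(m, "parent1", "parent2", dispersion = 0.2)
  b <- dmc_test(m, "parent2", "parent1", dispersion = 0.2)
  expect_equal(a$p_value, b$p_value)
  expect_equal(a$logFC, -b$logFC)
})

test_that("dispersion estimator recovers the simulation truth", {
  # Poisson counts: estimate must sit near zero
  m0 <- make_null_counts(200, 10, dispersion = 0, seed = 5)
  expect_lt(estimate_dispersion(m0)$common, 0.05)
  # NB dispersion 0.4 recovered within a factor-ish band
  m4 <- make_null_counts(500, 10, dispersion = 0.4, seed = 6)
  est <- estimate_dispersion(m4)$common
  expect_gt(est, 0.2); expect_lt(est, 0.6)
  # a single locus with identical counts everywhere has zero dispersion
  m1 <- make_counts(matrix(7, 1, 4), rep(c("parent1", "parent2"), each = 2))
  d1 <- estimate_dispersion(m1)
  expect_equal(unname(d1$per_locus), 0)
  expect_error(estimate_dispersion(
    make_counts(matrix(0, 2, 4), rep(c("parent1", "parent2"), each = 2))),
    class = "eh_all_zero")
})

test_that("exact test agrees with an independent NB implementation", {
  m <- make_null_counts(300, 8, dispersion = 0.25, seed = 9)
  disp <- estimate_dispersion(m, shrinkage_weight = 1)  # common only
  mine <- dmc_test(m, "parent1", "parent2", disp)
  y <- edgeR::DGEList(counts = m$counts, group = m$samples$group,
                      lib.size = m$samples$library_size)
  y$common.dispersion <- disp$common
  et <- edgeR::exactTest(y, pair = c("parent2", "parent1"))
  pe <- et$table$PValue[match(mine$locus_id, rownames(et$table))]
  expect_gt(cor(log10(mine$p_value + 1e-300), log10(pe + 1e-300)), 0.99)
  expect_lt(median(abs(log10((mine$p_value + 1e-300) / (pe + 1e-300)))), 0.2)
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(1.0), 1.0)
  set.seed(1)
  p <- runif(50)^2
  q <- bh_fdr(p)
  expect_true(all(q >= p) && all(q <= 1))
  perm <- sample(50)
  expect_equal(bh_fdr(p[perm]), q[perm])
  expect_error(bh_fdr(c(0.5, 1.2)), class = "eh_bad_pvalues")
})

test_that("call_dmcs finds strong shifts and controls the null", {
  set.seed(77)
  n_null <- 100; n_shift <- 20; n <- 20
  base <- rlnorm(n_null + n_shift, log(30), 0.5)
  mu <- cbind(matrix(base, n_null + n_shift, n / 2),
              matrix(base, n_null + n_shift, n / 2))
  mu[n_null + seq_len(n_shift), seq_len(n / 2)] <-
    mu[n_null + seq_len(n_shift), seq_len(n / 2)] * 8
  counts <- matrix(rnbinom(length(mu), size = 1 / 0.1, mu = mu), ncol = n)
  m <- make_counts(counts, rep(c("parent1", "parent2"), each = n / 2))
  ds <- call_dmcs(m, "parent1", "parent2")
  sig <- ds$results$significant
  shifted <- ds$results$locus_id %in% m$loci$locus_id[n_null + seq_len(n_shift)]
  expect_gte(sum(sig & shifted), 15)
  expect_lte(sum(sig & !shifted), 3)
  # direction: shifted loci have more reads in parent1 -> hypo in focal
  expect_true(all(ds$results$direction[sig & shifted] == "hypo_in_focal"))
})

test_that("comparing a group against itself yields no DMCs", {
  m <- make_null_counts(100, 10, dispersion = 0.2, seed = 3,
                        groups = c("parent1", "parent1"))
  ds <- call_dmcs(m, "parent1", "parent1")
  expect_equal(sum(ds$results$significant), 0L)
})

test_that("DMC intersection is an ordered set intersection", {
  ids <- locus_ids("s1", c(300, 100, 200, 400), "+")
  a <- fake_dmc_set("hybrid", "parent1", sig_ids = ids[1:3], all_ids = ids)
  b <- fake_dmc_set("hybrid", "parent2", sig_ids = ids[c(1, 3, 4)], all_ids = ids)
  out <- intersect_dmcs(a, b)
  expect_equal(out, c("s1:200:+", "s1:300:+"))  # sorted by position
  expect_equal(intersect_dmcs(a, a), sort(ids[1:3]))
  b2 <- fake_dmc_set("hybrid", "parent2", sig_ids = ids[4], all_ids = ids)
  expect_equal(intersect_dmcs(a, b2), character(0))
  c1 <- fake_dmc_set("parent1", "parent2", sig_ids = ids[1])
  expect_error(intersect_dmcs(a, c1), class = "eh_bad_intersection")
})
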