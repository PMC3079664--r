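test_that("significant-SNP counting is inclusive at the threshold", {
  pv <- c(0.001, 0.5, 0.009, 0.2)
  expect_equal(count_significant(pv, 0.01), 2)
  expect_equal(count_significant(c(0.05, 0.04, 0.06), 0.05), 2)  # P == alpha counts
  expect_equal(count_significant(pv, 1), 4)
  expect_equal(count_in_set(pv, c(1L, 3L), 0.01), 2)
  expect_equal(count_in_set(pv, 2L, 0.01), 0)
  expect_equal(count_in_set(pv, 1:4, 0.01), count_significant(pv, 0.01))
})

test_that("hypergeometric moments match explicit pmf summation", {
  mo <- hypergeom_moments(10, 20, 100)
  or <- oracle_hyper_moments(10, 20, 100)
  expect_equal(mo$mu, or$mu)
  expect_equal(mo$sigma2, or$sigma2)
  expect_equal(mo$mu, 2)
  expect_equal(mo$sigma2, 10 * 0.2 * 0.8 * 90 / 99)
  expect_equal(hypergeom_moments(10, 0, 100), list(mu = 0, sigma2 = 0))
  mo2 <- hypergeom_moments(100, 20, 100)   # whole universe
  expect_equal(mo2$mu, 20)
  expect_equal(mo2$sigma2, 0)
  expect_error(hypergeom_moments(101, 20, 100), "require")
  set.seed(12)
  for (i in 1:20) {
    n <- sample(2:80, 1); d <- sample(0:n, 1); m <- sample(0:n, 1)
    mo <- hypergeom_moments(m, d, n); or <- oracle_hyper_moments(m, d, n)
    expect_equal(mo$mu, or$mu, tolerance = 1e-12)
    expect_equal(mo$sigma2, or$sigma2, tolerance = 1e-12)
  }
})

test_that("restandardized score handles the degenerate-variance convention", {
  expect_equal(standardized_score(2, 10, 20, 100), 0)       # y == mu
  expect_equal(standardized_score(6, 10, 20, 100),
               4 / sqrt(10 * 0.2 * 0.8 * 90 / 99))
  expect_equal(standardized_score(6, 10, 20, 100), 3.316625, tolerance = 1e-6)
  expect_equal(standardized_score(0, 10, 0, 100), 0)        # d = 0 -> sigma2 = 0
  expect_equal(standardized_score(5, 100, 5, 100), 0)       # m = n
})

test_that("permutation p-values follow the indicator-sum definition", {
  expect_equal(enrichment_pvalue(2, c(0.1, 0.5, 1.2)), 0)
  expect_equal(enrichment_pvalue(2, c(0.1, 0.5, 1.2), smooth = TRUE), 1 / 4)
  expect_equal(enrichment_pvalue(2, c(2, 2, 2)), 1)          # >= convention
  expect_equal(enrichment_pvalue(0.3, c(0.1, 0.4, 0.5, 0.2)), 0.5)
})

test_that("permutation p-values are uniform on the permutation grid", {
  # rank-statistic property: with continuous exchangeable scores the count of
  # permuted scores >= the observed one is uniform on {0, ..., Pi}
  set.seed(77)
  Pi <- 19L
  counts <- replicate(4000, {
    z <- rnorm(Pi + 1L)
    enrichment_pvalue(z[1L], z[-1L]) * Pi
  })
  freq <- tabulate(as.integer(counts) + 1L, Pi + 1L)
  gof <- chisq.test(freq, p = rep(1 / (Pi + 1L), Pi + 1L))
  expect_gt(gof$p.value, 0.01)
})

test_that("the identity permutation reproduces the observed scores", {
  d <- make_tiny_dataset()
  sets <- snp_sets_from_indices(list(A = 1:3, B = 4:6), 6L)
  obs <- compute_observed_scores(d$genotypes, d$labels, sets, alpha = 0.5)
  perm <- permutation_scores(d$genotypes, d$labels, sets, alpha = 0.5,
                             Pi = 1L, seed = 1,
                             perm_indices = list(1:8))
  expect_equal(unname(perm$z[1L, ]), obs$z)
  expect_equal(perm$d[1L], obs$d)
  # and the resulting p-values are 1 for every set (>= convention)
  rep <- report_from_scores(obs, perm)
  expect_true(all(rep$p_value == 1))
})

test_that("permutation scores are reproducible from the seed", {
  d <- make_tiny_dataset()
  sets <- snp_sets_from_indices(list(A = 1:3, B = 4:6), 6L)
  p1 <- permutation_scores(d$genotypes, d$labels, sets, alpha = 0.5,
                           Pi = 30, seed = 99)
  p2 <- permutation_scores(d$genotypes, d$labels, sets, alpha = 0.5,
                           Pi = 30, seed = 99)
  expect_identical(p1$z, p2$z)
  expect_identical(p1$d, p2$d)
  p3 <- permutation_scores(d$genotypes, d$labels, sets, alpha = 0.5,
                           Pi = 30, seed = 100)
  expect_false(identical(p1$z, p3$z))
})

test_that("mean permutation significant fraction tracks alpha under the null", {
  ds <- simulate_null_dataset(simulation_config(n_snps = 200, n_genes = 20,
                                                n_sets = 4, genes_per_set = 5,
                                                n_cases = 100, n_controls = 100,
                                                missing_rate = 0, seed = 21))
  sets <- snp_sets_from_indices(list(S = 1:50), 200L)
  perm <- permutation_scores(ds$genotypes, ds$phenotypes, sets, alpha = 0.05,
                             Pi = 200, seed = 4)
  frac <- mean(perm$d) / 200
  mc_se <- sd(perm$d / 200) / sqrt(200)
  # binomial expectation alpha, allowing for finite-sample test discreteness
  expect_lt(abs(frac - 0.05), 0.015 + 3 * mc_se)
})

test_that("FDR follows the permutation exceedance construction", {
  z_obs <- c(3, 1, 0, -1)
  z_perm <- rbind(c(0.5, 0.2, 0.1, 0), c(2.5, 1.5, 0.3, -0.5))
  # top set: no permuted score anywhere reaches 3 -> FDR 0
  fdr <- compute_fdr(z_obs, z_perm)
  expect_equal(fdr[1], 0)
  # direct recomputation of the definition for each set
  for (j in seq_along(z_obs)) {
    num <- mean(apply(z_perm, 1, function(r) mean(r >= z_obs[j])))
    den <- mean(z_obs >= z_obs[j])
    expect_equal(fdr[j], min(1, num / den))
  }
  # saturated null: permuted scores identical to observed -> FDR 1 everywhere
  sat <- rbind(z_obs, z_obs, z_obs)
  expect_equal(compute_fdr(z_obs, sat), rep(1, 4))
})

test_that("FWER is the exceedance rate of the permutation maxima", {
  z_obs <- c(3, 1, -2)
  z_perm <- rbind(c(2, 0, 1), c(3.5, -1, 0), c(0.5, 0.2, 0.4))
  fwer <- compute_fwer(z_obs, z_perm)
  expect_equal(fwer, c(1 / 3, 2 / 3, 1))  # maxima are 2, 3.5, 0.5
  # FWER dominates the per-set p-value
  p <- vapply(1:3, function(j) enrichment_pvalue(z_obs[j], z_perm[, j]),
              numeric(1))
  expect_true(all(fwer >= p))
  # with a single set FWER is exactly the p-value
  expect_equal(compute_fwer(z_obs[1], z_perm[, 1, drop = FALSE]),
               enrichment_pvalue(z_obs[1], z_perm[, 1]))
})

test_that("combining permutation blocks equals one pooled run", {
  d <- make_tiny_dataset()
  sets <- snp_sets_from_indices(list(A = 1:3, B = 4:6), 6L)
  set.seed(8)
  stream <- replicate(40, sample.int(8), simplify = FALSE)
  full <- permutation_scores(d$genotypes, d$labels, sets, alpha = 0.5,
                             Pi = 40, seed = 1, perm_indices = stream)
  b1 <- permutation_scores(d$genotypes, d$labels, sets, alpha = 0.5,
                           Pi = 20, seed = 1, perm_indices = stream[1:20],
                           block_id = 1L)
  b2 <- permutation_scores(d$genotypes, d$labels, sets, alpha = 0.5,
                           Pi = 20, seed = 2, perm_indices = stream[21:40],
                           block_id = 2L)
  pooled <- combine_blocks(list(b1, b2))
  expect_equal(pooled$Pi, 40L)
  expect_equal(pooled$z, full$z)
  expect_equal(pooled$d, full$d)
  obs <- compute_observed_scores(d$genotypes, d$labels, sets, alpha = 0.5)
  expect_equal(as.data.frame(report_from_scores(obs, pooled)),
               as.data.frame(report_from_scores(obs, full)),
               ignore_attr = TRUE)
  # block order does not change p/FDR/FWER
  swapped <- combine_blocks(list(b2, b1))
  expect_equal(as.data.frame(report_from_scores(obs, swapped))[
    , c("name", "p_value", "FDR", "FWER")],
    as.data.frame(report_from_scores(obs, pooled))[
      , c("name", "p_value", "FDR", "FWER")])
  # single block is an identity
  expect_equal(combine_blocks(list(b1))$z, b1$z)
  # mismatched set lists are rejected
  other <- permutation_scores(d$genotypes, d$labels,
                              snp_sets_from_indices(list(C = 1:2), 6L),
                              alpha = 0.5, Pi = 20, seed = 3)
  expect_error(combine_blocks(list(b1, other)), "mismatched")
})

test_that("a saturated threshold collapses every score to zero", {
  d <- make_tiny_dataset()
  sets <- snp_sets_from_indices(list(A = 1:3, B = 4:6), 6L)
  rep <- run_rs_snp(d$genotypes, d$labels, sets, alpha = 1, Pi = 10, seed = 2)
  expect_equal(attr(rep, "d"), 6L)
  expect_equal(rep$y, rep$m_snps)
  expect_true(all(rep$z == 0))
  expect_true(all(rep$p_value == 1))
})

test_that("the indicator score ignores p-value magnitude below alpha", {
  pv1 <- c(1e-10, 0.5, 0.002, 0.9, 0.003, 0.7)
  pv2 <- c(1e-3, 0.5, 0.002, 0.9, 0.003, 0.7)   # member SNP p changed below alpha
  alpha <- 0.01
  idx <- c(1L, 3L, 5L)
  expect_equal(count_in_set(pv1, idx, alpha), count_in_set(pv2, idx, alpha))
  z1 <- standardized_score(count_in_set(pv1, idx, alpha), 3,
                           count_significant(pv1, alpha), 6)
  z2 <- standardized_score(count_in_set(pv2, idx, alpha), 3,
                           count_significant(pv2, alpha), 6)
  expect_identical(z1, z2)
})

test_that("the analytic randomization null matches explicit random set draws", {
  # modest-scale version of the analytic-vs-empirical equivalence: mean and
  # variance of y over explicit uniform draws of m-SNP sets track the
  # hypergeometric moments
  set.seed(2024)
  n <- 40L; d <- 10L; m <- 12L
  B <- 20000L
  y <- replicate(B, sum(sample.int(n, m) <= d))
  mo <- hypergeom_moments(m, d, n)
  se_mean <- sd(y) / sqrt(B)
  expect_lt(abs(mean(y) - mo$mu), 3 * se_mean)
  se_var <- sqrt((mean((y - mean(y))^4) - var(y)^2) / B)
  expect_lt(abs(var(y) - mo$sigma2), 3 * se_var)
})
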