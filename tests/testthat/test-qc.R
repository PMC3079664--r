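test_that("HWE exact test matches enumeration on pinned examples", {
  # monomorphic: only one configuration compatible with the allele margins
  expect_equal(hwe_exact_pvalue(5, 0, 0), 1)
  # two-configuration case: margins 2/2 allow het counts {0, 2};
  # P(h=2) = 2/3, P(h=0) = 1/3, both <= P(obs) -> p = 1
  expect_equal(hwe_exact_pvalue(0, 2, 0), oracle_hwe_pvalue(0, 2, 0))
  expect_equal(hwe_exact_pvalue(0, 2, 0), 1)
  # a heterozygote-deficient table has a tiny exact p-value
  expect_equal(hwe_exact_pvalue(57, 14, 50), oracle_hwe_pvalue(57, 14, 50))
  expect_lt(hwe_exact_pvalue(57, 14, 50), 1e-15)
  expect_error(hwe_exact_pvalue(0, 0, 0), "zero")
})

test_that("HWE exact test is symmetric in the homozygote classes", {
  set.seed(101)
  for (i in 1:50) {
    cts <- as.vector(rmultinom(1, sample(1:40, 1), c(0.3, 0.4, 0.3)))
    if (sum(cts) == 0) next
    expect_equal(hwe_exact_pvalue(cts[1], cts[2], cts[3]),
                 hwe_exact_pvalue(cts[3], cts[2], cts[1]))
  }
})

test_that("minor allele frequency follows its definition and is label-symmetric", {
  expect_equal(minor_allele_frequency(49, 2, 0), 2 / 102)
  expect_equal(minor_allele_frequency(0, 0, 10), 0)
  expect_equal(minor_allele_frequency(25, 50, 25), 0.5)
  set.seed(7)
  for (i in 1:25) {
    cts <- as.vector(rmultinom(1, 60, c(0.5, 0.3, 0.2)))
    expect_equal(minor_allele_frequency(cts[1], cts[2], cts[3]),
                 minor_allele_frequency(cts[3], cts[2], cts[1]))
  }
})

test_that("control-group association test behaves on concordant and discordant cohorts", {
  # identical genotype distributions in both cohorts -> statistic 0, p = 1
  dos <- rep(c(0L, 1L, 2L), 20)
  cohort <- rep(c("A", "B"), each = 30)
  expect_equal(control_group_association_pvalue(dos, cohort), 1)
  # 2-df test matches the textbook chi-square on the 2x3 table
  dos2 <- c(rep(0L, 10), rep(1L, 20), rep(2L, 30),
            rep(0L, 30), rep(1L, 20), rep(2L, 10))
  cohort <- rep(c("A", "B"), each = 60)
  tab <- rbind(c(10, 20, 30), c(30, 20, 10))
  p2 <- control_group_association_pvalue(dos2, cohort, df = 2)
  expect_equal(p2, pchisq(oracle_chisq_stat(tab), 2, lower.tail = FALSE))
  # min of 1-df and 2-df when both requested
  p1 <- control_group_association_pvalue(dos2, cohort, df = 1)
  expect_equal(control_group_association_pvalue(dos2, cohort), min(p1, p2))
  # a single cohort is inapplicable, signalled as NA rather than a p-value
  expect_true(is.na(control_group_association_pvalue(dos, rep("A", 60))))
})

test_that("marker QC removes low-MAF SNPs with the right reason", {
  # 3 SNPs x 100 samples; snp2 has a single minor allele -> MAF 0.005 < 1%
  l <- 100L
  dos <- rbind(rep(c(0L, 1L, 2L), length.out = l),
               c(1L, rep(0L, l - 1L)),
               rep(c(0L, 1L), length.out = l))
  gm <- genotype_matrix(dos, c("snp1", "snp2", "snp3"), sprintf("i%d", 1:l))
  ph <- phenotype_labels(sprintf("i%d", 1:l), rep(c(0L, 1L), each = 50))
  res <- suppressMessages(apply_marker_qc(gm, ph, qc_thresholds()))
  expect_equal(res$genotypes$snp_ids, c("snp1", "snp3"))
  expect_equal(res$report$reason[2], "maf")
  expect_equal(res$report$kept, c(TRUE, FALSE, TRUE))
  expect_equal(sum(!res$report$kept), nrow(res$report) - n_snps(res$genotypes))
})

test_that("vacuous thresholds keep everything; at-threshold markers are kept", {
  d <- make_tiny_dataset()
  res <- apply_marker_qc(d$genotypes, d$labels, qc_thresholds(0, 0, 0))
  expect_equal(n_snps(res$genotypes), n_snps(d$genotypes))
  # boundary convention: MAF exactly at the threshold is kept (strict <)
  l <- 100L
  dos <- rbind(rep(c(0L, 1L, 2L), length.out = l),
               c(1L, 1L, rep(0L, l - 2L)))  # MAF exactly 0.01
  gm <- genotype_matrix(dos, c("a", "b"), sprintf("i%d", 1:l))
  ph <- phenotype_labels(sprintf("i%d", 1:l), rep(c(0L, 1L), each = 50))
  res2 <- apply_marker_qc(gm, ph, qc_thresholds(maf_min = 0.01))
  expect_equal(n_snps(res2$genotypes), 2L)
})

test_that("marker QC is idempotent", {
  set.seed(33)
  ds <- simulate_null_dataset(simulation_config(n_snps = 120, n_genes = 12,
                                                n_sets = 2, genes_per_set = 5,
                                                n_cases = 60, n_controls = 60,
                                                maf_range = c(0.01, 0.5),
                                                seed = 33))
  al <- align_samples(ds$genotypes, ds$phenotypes)
  thr <- qc_thresholds(maf_min = 0.05)  # tight enough to remove something
  r1 <- suppressMessages(apply_marker_qc(al$genotypes, al$labels, thr))
  r2 <- suppressMessages(apply_marker_qc(r1$genotypes, al$labels, thr))
  expect_identical(r1$genotypes, r2$genotypes)
  expect_true(all(r2$report$kept))
})

test_that("HWE on controls drives removal independently of case genotypes", {
  # controls wildly out of HWE (all hets), cases in HWE
  l1 <- 60L; l2 <- 60L
  ctrl <- rep(1L, l1)
  case <- rep(c(0L, 1L, 2L, 1L), length.out = l2)
  dos <- rbind(c(ctrl, case), rep(c(0L, 1L, 2L, 1L), length.out = l1 + l2))
  gm <- genotype_matrix(dos, c("hwe_bad", "hwe_ok"), sprintf("i%d", 1:(l1 + l2)))
  ph <- phenotype_labels(sprintf("i%d", 1:(l1 + l2)),
                         rep(c(0L, 1L), c(l1, l2)))
  thr <- qc_thresholds(hwe_p_min = 1e-4)
  res <- suppressMessages(apply_marker_qc(gm, ph, thr))
  expect_equal(res$report$reason, c("hwe", ""))
  expect_equal(res$genotypes$snp_ids, "hwe_ok")
})
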