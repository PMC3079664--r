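# Marker-level quality control: Hardy-Weinberg exact test, control-group
# concordance, minor allele frequency. Boundary convention: a marker is
# removed on strict inequality (P < threshold, MAF < threshold); values
# exactly at the threshold are kept.

#' QC thresholds
#'
#' Defaults follow the standard WTCCC-style marker filters: remove SNPs with
#' Hardy-Weinberg exact P < 5.7e-7 in controls, control-vs-control
#' association P < 5.7e-7, or MAF < 1\%.
#'
#' @param hwe_p_min remove SNPs with HWE exact p-value strictly below this.
#' @param control_assoc_p_min remove SNPs whose control-group association
#'   p-value is strictly below this (only applied when two control cohorts
#'   are present).
#' @param maf_min remove SNPs with minor allele frequency strictly below this.
#' @return A list of class \code{qc_thresholds}.
#' @export
qc_thresholds <- function(hwe_p_min = 5.7e-7, control_assoc_p_min = 5.7e-7,
                          maf_min = 0.01) {
  for (v in c(hwe_p_min, control_assoc_p_min, maf_min))
    if (!is.numeric(v) || v < 0 || v > 1) stop("thresholds must lie in [0,1]")
  structure(list(hwe_p_min = hwe_p_min,
                 control_assoc_p_min = control_assoc_p_min,
                 maf_min = maf_min),
            class = "qc_thresholds")
}

#' Hardy-Weinberg exact test
#'
#' Exact conditional test for departure from Hardy-Weinberg proportions: with
#' the allele counts held fixed, the p-value is the sum of the conditional
#' probabilities of all heterozygote counts whose probability does not exceed
#' that of the observed count.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (any consistent allele labelling;
#'   the test is symmetric in the homozygote classes).
#' @return Exact p-value in (0, 1].
#' @export
hwe_exact_pvalue <- function(n_AA, n_Aa, n_aa) {
  counts <- c(n_AA, n_Aa, n_aa)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("genotype counts must be non-negative integers")
  N <- sum(counts)
  if (N < 1L) stop("all genotype counts are zero")
  n1 <- 2L * min(n_AA, n_aa) + n_Aa            # rarer allele count
  het <- seq.int(n1 %% 2L, n1, by = 2L)        # feasible heterozygote counts
  # log conditional probability of each het count given allele margins
  lp <- lfactorial(N) - lfactorial((n1 - het) / 2) - lfactorial(het) -
    lfactorial((2L * N - n1 - het) / 2) + het * log(2) -
    (lfactorial(2L * N) - lfactorial(n1) - lfactorial(2L * N - n1))
  p <- exp(lp - max(lp))
  p <- p / sum(p)
  obs <- p[match(n_Aa, het)]
  min(1, sum(p[p <= obs * (1 + 1e-7)]))
}

#' Minor allele frequency from genotype counts
#'
#' @param n_AA,n_Aa,n_aa genotype counts (missing genotypes excluded upstream).
#' @return \code{min(p, 1 - p)} where p is the frequency of the A allele.
#' @export
minor_allele_frequency <- function(n_AA, n_Aa, n_aa) {
  total <- n_AA + n_Aa + n_aa
  if (total < 1) stop("need at least one genotyped individual")
  p <- (2 * n_AA + n_Aa) / (2 * total)
  min(p, 1 - p)
}

# Pearson chi-square on a 2 x k count table after dropping all-zero genotype
# columns; returns list(stat, df, p). One remaining column => stat 0, p 1.
pearson_chisq <- function(tab) {
  tab <- tab[, colSums(tab) > 0, drop = FALSE]
  if (ncol(tab) < 2L || any(rowSums(tab) == 0))
    return(list(stat = 0, df = 0L, p = 1))
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - E)^2 / E)
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  list(stat = stat, df = df,
       p = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Association between two control cohorts at one SNP
#'
#' Concordance check between the two control groups: a 2-degree-of-freedom
#' chi-square test on the 2 x 3 genotype table, a 1-degree-of-freedom
#' Cochran-Armitage trend test, or (default) the minimum of the two.
#'
#' @param dosages_snp dosage vector (0/1/2/NA) for one SNP, control samples.
#' @param cohort cohort label per control sample; exactly two distinct
#'   non-missing labels are required.
#' @param df which test(s): subset of \code{c(1, 2)}; when both are requested
#'   the minimum p-value is returned.
#' @return A p-value, or \code{NA_real_} when fewer than two cohorts are
#'   present (the filter is then inapplicable).
#' @export
control_group_association_pvalue <- function(dosages_snp, cohort, df = c(1, 2)) {
  stopifnot(all(df %in% c(1, 2)))
  ok <- !is.na(cohort) & !is.na(dosages_snp)
  groups <- unique(cohort[ok])
  if (length(groups) < 2L) return(NA_real_)
  if (length(groups) > 2L) stop("more than two control cohorts")
  tab <- matrix(0, 2L, 3L)
  for (g in 1:2)
    tab[g, ] <- tabulate(dosages_snp[ok & cohort == groups[g]] + 1L, 3L)
  ps <- c()
  if (2 %in% df) ps <- c(ps, pearson_chisq(tab)$p)
  if (1 %in% df) ps <- c(ps, trend_test_table(tab)$p)
  min(ps)
}

#' Apply marker-level QC filters
#'
#' Removes SNPs failing any of three rules, evaluated in the order
#' HWE (computed on the combined controls) -> control-group association
#' (only when two control cohorts exist) -> MAF (all samples); the first
#' failing rule is recorded as the removal reason. Missing genotypes are
#' excluded per marker before counting.
#'
#' @param genotypes a \code{\link{genotype_matrix}}.
#' @param labels a \code{\link{phenotype_labels}} object aligned to
#'   \code{genotypes} (see \code{\link{align_samples}}).
#' @param thresholds a \code{\link{qc_thresholds}} object.
#' @param sample_exclude optional character vector of sample ids to drop
#'   before filtering (sample-level QC hook).
#' @param control_df degrees of freedom for the control-group test, passed to
#'   \code{\link{control_group_association_pvalue}}.
#' @return list(genotypes = filtered matrix, report = per-SNP data frame with
#'   columns snp_id, maf, hwe_p, control_assoc_p, kept, reason).
#' @export
apply_marker_qc <- function(genotypes, labels, thresholds = qc_thresholds(),
                            sample_exclude = NULL, control_df = c(1, 2)) {
  stopifnot(inherits(genotypes, "genotype_matrix"),
            inherits(labels, "phenotype_labels"))
  if (!identical(genotypes$sample_ids, labels$sample_id))
    stop("genotypes and labels must be aligned (see align_samples)")
  if (length(sample_exclude)) {
    keep <- !(genotypes$sample_ids %in% sample_exclude)
    genotypes <- genotype_matrix(genotypes$dosages[, keep, drop = FALSE],
                                 genotypes$snp_ids, genotypes$sample_ids[keep])
    labels <- phenotype_labels(labels$sample_id[keep], labels$status[keep],
                               labels$cohort[keep])
  }
  X <- genotypes$dosages
  ctrl <- labels$status == 0L
  n <- nrow(X)
  cnt <- function(v) tabulate(v[!is.na(v)] + 1L, 3L)
  maf <- hwe <- cap <- numeric(n)
  two_cohorts <- length(unique(stats::na.omit(labels$cohort))) >= 2L
  for (i in seq_len(n)) {
    g_all <- cnt(X[i, ])
    g_ctl <- cnt(X[i, ctrl])
    maf[i] <- if (sum(g_all) >= 1) minor_allele_frequency(g_all[1], g_all[2], g_all[3]) else 0
    hwe[i] <- if (sum(g_ctl) >= 1) hwe_exact_pvalue(g_ctl[1], g_ctl[2], g_ctl[3]) else 1
    cap[i] <- if (two_cohorts)
      control_group_association_pvalue(X[i, ctrl], labels$cohort[ctrl], control_df)
    else NA_real_
  }
  fail_hwe <- hwe < thresholds$hwe_p_min
  fail_cap <- !is.na(cap) & cap < thresholds$control_assoc_p_min
  fail_maf <- maf < thresholds$maf_min
  reason <- rep("", n)
  reason[fail_maf] <- "maf"
  reason[fail_cap] <- "control_assoc"
  reason[fail_hwe] <- "hwe"          # rule order: hwe > control_assoc > maf
  kept <- reason == ""
  report <- data.frame(snp_id = genotypes$snp_ids, maf = maf, hwe_p = hwe,
                       control_assoc_p = cap, kept = kept, reason = reason,
                       stringsAsFactors = FALSE)
  if (!any(kept)) stop("all SNPs removed by marker QC")
  if (any(!kept))
    message("marker QC removed ", sum(!kept), " SNP(s): ",
            paste(names(table(reason[!kept])), table(reason[!kept]),
                  sep = "=", collapse = ", "))
  filtered <- genotype_matrix(X[kept, , drop = FALSE],
                              genotypes$snp_ids[kept], genotypes$sample_ids)
  list(genotypes = filtered, report = report)
}
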