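# Single-SNP association statistics under five genetic models. The additive
# (Cochran-Armitage trend) model is the default for the genome scan and has a
# vectorized kernel, since it is recomputed for every label permutation.

#' Build the 2 x 3 genotype contingency table for one SNP
#'
#' Rows are (control, case); columns are dosage 0/1/2. Missing genotypes are
#' excluded from their class (complete-case per marker).
#'
#' @param dosages_snp dosage vector (0/1/2/NA) for one SNP.
#' @param labels a \code{\link{phenotype_labels}} object (or a 0/1 status
#'   vector) matching the sample order.
#' @return 2 x 3 integer matrix with dimnames.
#' @export
genotype_table <- function(dosages_snp, labels) {
  status <- if (inherits(labels, "phenotype_labels")) labels$status else as.integer(labels)
  stopifnot(length(status) == length(dosages_snp))
  ok <- !is.na(dosages_snp)
  tab <- rbind(control = tabulate(dosages_snp[ok & status == 0L] + 1L, 3L),
               case    = tabulate(dosages_snp[ok & status == 1L] + 1L, 3L))
  colnames(tab) <- c("0", "1", "2")
  if (any(rowSums(tab) == 0))
    stop("a phenotype class has no non-missing genotypes")
  tab
}

# Two-sided Fisher exact test for a 2x2 table via the hypergeometric pmf:
# sum of the probabilities of all tables (same margins) whose probability is
# <= the observed one, with the conventional relative tolerance.
fisher_2x2_pvalue <- function(tab) {
  m <- sum(tab[1, ]); n2 <- sum(tab[2, ]); k <- sum(tab[, 1])
  x <- tab[1, 1]
  support <- max(0L, k - n2):min(k, m)
  dens <- stats::dhyper(support, m, n2, k)
  sum(dens[dens <= dens[match(x, support)] * (1 + 1e-7)])
}

# Internal: 1-df chi-square on a 2x2 with Fisher fallback when any expected
# count < 5. Degenerate tables (empty column/row) => stat 0, p 1.
test_2x2 <- function(tab) {
  tab <- tab[, colSums(tab) > 0, drop = FALSE]
  if (ncol(tab) < 2L || any(rowSums(tab) == 0))
    return(list(stat = 0, p = 1))
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - E)^2 / E)
  p <- if (any(E < 5)) fisher_2x2_pvalue(tab)
  else stats::pchisq(stat, 1L, lower.tail = FALSE)
  list(stat = stat, p = p)
}

assoc_result <- function(model, stat, p, snp_id = NA_character_) {
  # one-row data frame, built directly (the data.frame() constructor is too
  # slow for exhaustive table sweeps)
  structure(list(snp_id = snp_id, model = model, D = stat, P = p),
            class = "data.frame", row.names = 1L)
}

#' Genotype-model association tests on a 2 x 3 table
#'
#' \code{test_general}: 2-df Pearson chi-square on the full genotype table
#' (all-zero genotype columns are dropped with the degrees of freedom
#' reduced; a single remaining column gives D = 0, P = 1).
#' \code{test_dominant} collapses dosages \{1,2\} vs \{0\};
#' \code{test_recessive} collapses \{2\} vs \{0,1\};
#' \code{test_multiplicative} tests the 2 x 2 allelic table (allele counts
#' 2n0+n1 vs n1+2n2 per class). The 2 x 2 tests use the 1-df chi-square,
#' switching to Fisher's exact test for the p-value when any expected cell
#' count is below 5.
#'
#' @param tab 2 x 3 genotype table as from \code{\link{genotype_table}}.
#' @param snp_id optional identifier carried into the result.
#' @return One-row data frame: snp_id, model, D (statistic), P (p-value).
#' @export
test_general <- function(tab, snp_id = NA_character_) {
  r <- pearson_chisq(tab)
  assoc_result("general", r$stat, r$p, snp_id)
}

#' @rdname test_general
#' @export
test_dominant <- function(tab, snp_id = NA_character_) {
  t2 <- cbind(tab[, 1], tab[, 2] + tab[, 3])
  r <- test_2x2(t2)
  assoc_result("dominant", r$stat, r$p, snp_id)
}

#' @rdname test_general
#' @export
test_recessive <- function(tab, snp_id = NA_character_) {
  t2 <- cbind(tab[, 1] + tab[, 2], tab[, 3])
  r <- test_2x2(t2)
  assoc_result("recessive", r$stat, r$p, snp_id)
}

#' @rdname test_general
#' @export
test_multiplicative <- function(tab, snp_id = NA_character_) {
  t2 <- cbind(2 * tab[, 1] + tab[, 2], tab[, 2] + 2 * tab[, 3])
  r <- test_2x2(t2)
  assoc_result("multiplicative", r$stat, r$p, snp_id)
}

# Trend statistic on a 2x3 table (rows control/case, columns dosage 0/1/2)
# with weights w. Returns list(stat, p); monomorphic or single-class tables
# give stat 0, p 1. Standard unconditional-variance form:
#   Z^2 = N (N*Sum(w r) - R*Sum(w n))^2 / (R (N-R) (N*Sum(w^2 n) - Sum(w n)^2))
trend_test_table <- function(tab, w = c(0, 1, 2)) {
  r <- tab[2, ]                       # cases
  ncol_tot <- tab[1, ] + tab[2, ]
  N <- sum(ncol_tot); R <- sum(r)
  Swr <- sum(w * r); Swn <- sum(w * ncol_tot); Sw2n <- sum(w^2 * ncol_tot)
  denom <- R * (N - R) * (N * Sw2n - Swn^2)
  if (N < 1 || denom <= 0) return(list(stat = 0, p = 1))
  stat <- N * (N * Swr - R * Swn)^2 / denom
  list(stat = stat, p = stats::pchisq(stat, 1L, lower.tail = FALSE))
}

#' Cochran-Armitage trend test (additive model)
#'
#' 1-df test for a linear trend in case proportion across the dosage classes.
#' The statistic is invariant under affine transformations of the weights.
#' Monomorphic SNPs (zero trend variance) give D = 0, P = 1.
#'
#' @param tab 2 x 3 genotype table (rows control/case, columns dosage 0/1/2).
#' @param weights dosage scores, default \code{c(0, 1, 2)}.
#' @param snp_id optional identifier carried into the result.
#' @return One-row data frame: snp_id, model, D, P.
#' @export
cochran_armitage_trend <- function(tab, weights = c(0, 1, 2),
                                   snp_id = NA_character_) {
  r <- trend_test_table(tab, weights)
  assoc_result("additive", r$stat, r$p, snp_id)
}

# Precompute per-dosage indicator matrices so that per-permutation genotype
# counts are three matrix-vector products. Missing entries contribute to no
# indicator.
trend_precompute <- function(genotypes) {
  X <- genotypes$dosages
  I0 <- (X == 0L); I0[is.na(I0)] <- FALSE; storage.mode(I0) <- "double"
  I1 <- (X == 1L); I1[is.na(I1)] <- FALSE; storage.mode(I1) <- "double"
  I2 <- (X == 2L); I2[is.na(I2)] <- FALSE; storage.mode(I2) <- "double"
  list(I0 = I0, I1 = I1, I2 = I2,
       tot0 = rowSums(I0), tot1 = rowSums(I1), tot2 = rowSums(I2))
}

# Vectorized trend-test p-values for all SNPs given a 0/1 case vector.
trend_pvalues_fast <- function(pre, status) {
  y <- as.numeric(status)
  r0 <- drop(pre$I0 %*% y); r1 <- drop(pre$I1 %*% y); r2 <- drop(pre$I2 %*% y)
  n0 <- pre$tot0; n1 <- pre$tot1; n2 <- pre$tot2
  N <- n0 + n1 + n2
  R <- r0 + r1 + r2
  Swr <- r1 + 2 * r2
  Swn <- n1 + 2 * n2
  Sw2n <- n1 + 4 * n2
  denom <- R * (N - R) * (N * Sw2n - Swn^2)
  stat <- ifelse(N >= 1 & denom > 0, N * (N * Swr - R * Swn)^2 / denom, 0)
  list(D = stat, P = ifelse(stat > 0, stats::pchisq(stat, 1L, lower.tail = FALSE), 1))
}

#' Genome-wide single-SNP association scan
#'
#' Computes the association statistic and p-value for every SNP under the
#' chosen genetic model. A SNP for which a test cannot be computed (e.g. a
#' phenotype class entirely missing) is assigned D = 0, P = 1 with a warning
#' rather than aborting the scan.
#'
#' @param genotypes a \code{\link{genotype_matrix}} (post-QC).
#' @param labels a \code{\link{phenotype_labels}} object aligned to
#'   \code{genotypes}, or a 0/1 status vector.
#' @param model one of \code{"additive"} (default, Cochran-Armitage trend),
#'   \code{"general"}, \code{"dominant"}, \code{"recessive"},
#'   \code{"multiplicative"}.
#' @return Data frame with one row per SNP, input order preserved:
#'   snp_id, model, D, P.
#' @export
associate_all <- function(genotypes, labels,
                          model = c("additive", "general", "dominant",
                                    "recessive", "multiplicative")) {
  model <- match.arg(model)
  status <- if (inherits(labels, "phenotype_labels")) labels$status else as.integer(labels)
  stopifnot(length(status) == n_samples(genotypes))
  if (model == "additive") {
    pre <- trend_precompute(genotypes)
    res <- trend_pvalues_fast(pre, status)
    bad <- bad_class_snps(pre, status)
    if (any(bad)) {
      warning(sum(bad), " SNP(s) with an entirely missing phenotype class; P set to 1")
      res$D[bad] <- 0; res$P[bad] <- 1
    }
    return(data.frame(snp_id = genotypes$snp_ids, model = model,
                      D = res$D, P = res$P, stringsAsFactors = FALSE))
  }
  test_fun <- switch(model, general = test_general, dominant = test_dominant,
                     recessive = test_recessive,
                     multiplicative = test_multiplicative)
  out <- vector("list", n_snps(genotypes))
  n_bad <- 0L
  for (i in seq_len(n_snps(genotypes))) {
    res <- tryCatch({
      tab <- genotype_table(genotypes$dosages[i, ], status)
      test_fun(tab, genotypes$snp_ids[i])
    }, error = function(e) {
      n_bad <<- n_bad + 1L
      assoc_result(model, 0, 1, genotypes$snp_ids[i])
    })
    out[[i]] <- res
  }
  if (n_bad > 0L)
    warning(n_bad, " SNP(s) failed the ", model, " test; P set to 1")
  do.call(rbind, out)
}

# SNPs where all non-missing genotypes fall in one phenotype class.
bad_class_snps <- function(pre, status) {
  y <- as.numeric(status)
  caseN <- drop(pre$I0 %*% y) + drop(pre$I1 %*% y) + drop(pre$I2 %*% y)
  totN <- pre$tot0 + pre$tot1 + pre$tot2
  caseN == 0 | caseN == totN
}
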