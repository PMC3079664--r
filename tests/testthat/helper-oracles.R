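# Independent brute-force oracles used to pin expected values. These are
# deliberately coded from first principles (direct formulas, exhaustive
# enumeration), not by calling the package's own implementation paths.

# Pearson chi-square statistic on a 2 x k table, dropping empty columns.
oracle_chisq_stat <- function(tab) {
  tab <- tab[, colSums(tab) > 0, drop = FALSE]
  if (ncol(tab) < 2 || any(rowSums(tab) == 0)) return(0)
  N <- sum(tab)
  stat <- 0
  for (i in seq_len(nrow(tab)))
    for (j in seq_len(ncol(tab))) {
      e <- sum(tab[i, ]) * sum(tab[, j]) / N
      stat <- stat + (tab[i, j] - e)^2 / e
    }
  stat
}

# Cochran-Armitage trend statistic via the conditional-moments route
# (different algebra from the package's N-scaled closed form):
# U = sum_g w_g (r_g - n_g R/N); Var(U) = p(1-p) (sum w^2 n - (sum w n)^2/N).
oracle_trend_stat <- function(tab, w = c(0, 1, 2)) {
  r <- tab[2, ]; ntot <- tab[1, ] + tab[2, ]
  N <- sum(ntot); R <- sum(r)
  if (N == 0 || R == 0 || R == N) return(0)
  U <- sum(w * (r - ntot * R / N))
  V <- (R / N) * (1 - R / N) * (sum(w^2 * ntot) - sum(w * ntot)^2 / N)
  if (V <= 0) return(0)
  U^2 / V
}

# Exact conditional Hardy-Weinberg test by direct factorial enumeration of
# every heterozygote count compatible with the allele margins.
oracle_hwe_pvalue <- function(n_AA, n_Aa, n_aa) {
  N <- n_AA + n_Aa + n_aa
  nA <- 2 * n_AA + n_Aa
  hets <- seq(nA %% 2, min(nA, 2 * N - nA), by = 2)
  pr <- vapply(hets, function(h) {
    haa <- (nA - h) / 2
    hbb <- N - haa - h
    exp(lfactorial(N) - lfactorial(haa) - lfactorial(h) - lfactorial(hbb) +
          h * log(2) -
          (lfactorial(2 * N) - lfactorial(nA) - lfactorial(2 * N - nA)))
  }, numeric(1))
  obs <- pr[match(n_Aa, hets)]
  min(1, sum(pr[pr <= obs * (1 + 1e-7)]))
}

# Hypergeometric mean/variance by explicit summation over the pmf.
oracle_hyper_moments <- function(m, d, n) {
  y <- 0:min(m, d)
  pmf <- dhyper(y, d, n - d, m)
  mu <- sum(y * pmf)
  list(mu = mu, sigma2 = sum((y - mu)^2 * pmf))
}

# Enumerate all 2 x 3 tables (as a 6-column matrix a0 a1 a2 b0 b1 b2) with
# 1 <= total <= max_total, via stars and bars.
enumerate_2x3_tables <- function(max_total) {
  bars <- utils::combn(max_total + 6L, 6L)
  comp <- apply(rbind(bars, max_total + 7L), 2L,
                function(b) diff(c(0L, b)) - 1L)
  tabs <- t(comp[1:6, , drop = FALSE])
  tabs[rowSums(tabs) >= 1L, , drop = FALSE]
}

# A tiny hand-checkable dataset: 6 SNPs x 8 samples (4 controls, 4 cases).
make_tiny_dataset <- function() {
  dos <- matrix(c(
    0L, 1L, 2L, 1L, 0L, 1L, 2L, 2L,
    0L, 0L, 1L, 1L, 1L, 1L, 0L, 0L,
    2L, 2L, 1L, 0L, 0L, 0L, 1L, 2L,
    NA, 0L, 0L, 1L, 2L, 1L, 0L, 1L,
    1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L,
    0L, 0L, 0L, 0L, 2L, 2L, 2L, 2L), nrow = 6L, byrow = TRUE)
  gm <- genotype_matrix(dos, sprintf("s%d", 1:6), sprintf("ind%d", 1:8))
  ph <- phenotype_labels(sprintf("ind%d", 1:8), c(0, 0, 0, 0, 1, 1, 1, 1),
                         c("A", "B", "A", "B", NA, NA, NA, NA))
  list(genotypes = gm, labels = ph)
}
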