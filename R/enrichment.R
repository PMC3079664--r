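# The random-set enrichment core: indicator counting statistic, analytic
# hypergeometric restandardization, phenotype-label permutation null,
# permutation p-values, FDR and FWER, and permutation-block combination.
#
# For each gene set S with m member SNPs, let d be the number of SNPs
# genome-wide with association p-value P <= alpha and y the number of those
# inside S. Under random selection of m SNPs from the n available, y is
# hypergeometric Hyp(m, d, n); the restandardized enrichment score is
# z = (y - mu) / sigma with the hypergeometric moments. The same score is
# recomputed for every label permutation (with that permutation's d), so the
# permutation p-value simultaneously accounts for both null hypotheses.

#' Count significant SNPs
#'
#' @param pvalues vector of per-SNP association p-values.
#' @param alpha significance threshold; \code{P <= alpha} counts (inclusive).
#' @return d, the genome-wide count of significant SNPs.
#' @export
count_significant <- function(pvalues, alpha) {
  stopifnot(all(pvalues >= 0 & pvalues <= 1), alpha > 0, alpha <= 1)
  sum(pvalues <= alpha)
}

#' Count significant SNPs inside a set
#'
#' @param pvalues vector of per-SNP association p-values (universe order).
#' @param set a set element from \code{\link{build_snp_sets}}, or an integer
#'   vector of 1-based SNP indices.
#' @param alpha significance threshold (inclusive).
#' @return y, the count of set members with \code{P <= alpha}.
#' @export
count_in_set <- function(pvalues, set, alpha) {
  idx <- if (is.list(set)) set$snp_indices else as.integer(set)
  stopifnot(all(idx >= 1L), all(idx <= length(pvalues)))
  sum(pvalues[idx] <= alpha)
}

#' Hypergeometric moments of the set count under random SNP selection
#'
#' Mean and variance of y when the m set members are drawn uniformly without
#' replacement from the n SNPs, of which d are significant:
#' \code{mu = m d / n}, \code{sigma2 = m (d/n) (1 - d/n) (n - m) / (n - 1)}
#' (\code{sigma2 = 0} when n = 1).
#'
#' @param m set size; \code{0 <= m <= n}.
#' @param d genome-wide significant count; \code{0 <= d <= n}.
#' @param n SNP universe size; \code{n >= 1}.
#' @return list(mu, sigma2). Vectorized over m and d.
#' @export
hypergeom_moments <- function(m, d, n) {
  if (any(n < 1) || any(m < 0) || any(m > n) || any(d < 0) || any(d > n))
    stop("require 0 <= m <= n, 0 <= d <= n, n >= 1")
  mu <- m * d / n
  sigma2 <- if (all(n == 1)) rep(0, length(mu))
  else m * (d / n) * (1 - d / n) * (n - m) / (n - 1)
  sigma2[n == 1] <- 0
  list(mu = mu, sigma2 = sigma2)
}

#' Restandardized enrichment score
#'
#' \code{z = (y - mu) / sqrt(sigma2)} with the hypergeometric moments; when
#' \code{sigma2 = 0} (e.g. d = 0, or m in \{0, n\}) y necessarily equals its
#' mean and z is defined as 0.
#'
#' @param y observed count of significant SNPs in the set.
#' @param m,d,n as in \code{\link{hypergeom_moments}}.
#' @return z score(s); vectorized over y, m, d.
#' @export
standardized_score <- function(y, m, d, n) {
  mo <- hypergeom_moments(m, d, n)
  ifelse(mo$sigma2 > 0, (y - mo$mu) / sqrt(mo$sigma2), 0)
}

# Per-label-arrangement scoring: association p-values -> d, y per set, z per
# set. `sets_idx` is a list of integer index vectors; n is the universe size.
score_label_arrangement <- function(pvalues, sets_idx, alpha, n, m) {
  sig <- pvalues <= alpha
  d <- sum(sig)
  y <- unname(vapply(sets_idx, function(ix) sum(sig[ix]), numeric(1L)))
  list(d = d, y = y, z = unname(standardized_score(y, m, d, n)))
}

#' Observed enrichment scores for all sets
#'
#' @param genotypes post-QC \code{\link{genotype_matrix}}.
#' @param labels aligned \code{\link{phenotype_labels}} (or 0/1 vector).
#' @param sets a \code{snp_set_list} from \code{\link{build_snp_sets}}.
#' @param model genetic model for the per-SNP scan (see
#'   \code{\link{associate_all}}).
#' @param alpha per-SNP significance threshold (default 0.01).
#' @return Object of class \code{set_scores}: list with set names, m, y, d,
#'   z, n, alpha, model.
#' @export
compute_observed_scores <- function(genotypes, labels, sets,
                                    model = "additive", alpha = 0.01) {
  stopifnot(inherits(sets, "snp_set_list"))
  n <- n_snps(genotypes)
  m <- vapply(sets, `[[`, integer(1L), "m")
  sets_idx <- lapply(sets, `[[`, "snp_indices")
  pv <- associate_all(genotypes, labels, model)$P
  sc <- score_label_arrangement(pv, sets_idx, alpha, n, m)
  structure(list(set = names(sets), m = m, y = sc$y, d = sc$d, z = sc$z,
                 n = n, alpha = alpha, model = model),
            class = "set_scores")
}

#' Permutation null scores
#'
#' Shuffles the phenotype labels uniformly at random \code{Pi} times (the
#' genotype columns are untouched, preserving each subject's genotype profile
#' and hence the LD structure), recomputes all n association p-values per
#' permutation, and standardizes each set's count against the hypergeometric
#' null Hyp(m, d_pi, n) using that permutation's genome-wide count d_pi.
#'
#' @param genotypes post-QC \code{\link{genotype_matrix}}.
#' @param labels aligned \code{\link{phenotype_labels}} (or 0/1 vector).
#' @param sets a \code{snp_set_list}.
#' @param model genetic model (default additive trend; this model has a
#'   vectorized kernel and is the one intended for large permutation runs).
#' @param alpha per-SNP significance threshold.
#' @param Pi number of label permutations (>= 1).
#' @param seed RNG seed; the score matrix is exactly reproducible from it.
#' @param perm_indices optional list of \code{Pi} integer sample orderings to
#'   use instead of random shuffles (e.g. the identity permutation for
#'   diagnostics, or a shared stream when validating block combination).
#' @param block_id integer tag for block workflows.
#' @return Object of class \code{permutation_scores}: list with \code{z}
#'   (Pi x T matrix), \code{d} (length-Pi vector), set_names, m, n, alpha,
#'   model, Pi, seed, block_id.
#' @export
permutation_scores <- function(genotypes, labels, sets, model = "additive",
                               alpha = 0.01, Pi = 1000L, seed = 1L,
                               perm_indices = NULL, block_id = 1L) {
  stopifnot(inherits(sets, "snp_set_list"), Pi >= 1L)
  status <- if (inherits(labels, "phenotype_labels")) labels$status else as.integer(labels)
  l <- n_samples(genotypes)
  stopifnot(length(status) == l)
  n <- n_snps(genotypes)
  m <- vapply(sets, `[[`, integer(1L), "m")
  sets_idx <- lapply(sets, `[[`, "snp_indices")
  if (!is.null(perm_indices)) {
    stopifnot(length(perm_indices) == Pi,
              all(vapply(perm_indices, length, integer(1L)) == l))
  }
  set.seed(seed)
  pre <- if (model == "additive") trend_precompute(genotypes) else NULL
  zmat <- matrix(NA_real_, nrow = Pi, ncol = length(sets),
                 dimnames = list(NULL, names(sets)))
  dvec <- integer(Pi)
  for (p in seq_len(Pi)) {
    ord <- if (is.null(perm_indices)) sample.int(l) else perm_indices[[p]]
    st <- status[ord]
    pv <- if (model == "additive") trend_pvalues_fast(pre, st)$P
    else suppressWarnings(associate_all(genotypes, st, model)$P)
    sc <- score_label_arrangement(pv, sets_idx, alpha, n, m)
    zmat[p, ] <- sc$z
    dvec[p] <- sc$d
  }
  structure(list(z = zmat, d = dvec, set_names = names(sets), m = m, n = n,
                 alpha = alpha, model = model, Pi = as.integer(Pi),
                 seed = seed, block_id = as.integer(block_id)),
            class = "permutation_scores")
}

#' @export
print.permutation_scores <- function(x, ...) {
  cat("permutation_scores:", x$Pi, "permutations x", ncol(x$z),
      "sets (alpha =", x$alpha, ", model =", x$model, ")\n")
  invisible(x)
}

#' Permutation p-value for one set
#'
#' \code{P = (1/Pi) sum_pi I(z_pi >= z_obs)} (non-strict inequality, so the
#' identity permutation always counts and p is never spuriously 0 from ties).
#' With \code{smooth = TRUE} the add-one form \code{(1 + sum I)/(1 + Pi)} is
#' used, which avoids exact zeros.
#'
#' @param z_obs observed restandardized score for the set.
#' @param z_perm vector of the set's permutation scores.
#' @param smooth use add-one smoothing.
#' @return p-value in [0, 1].
#' @export
enrichment_pvalue <- function(z_obs, z_perm, smooth = FALSE) {
  hits <- sum(z_perm >= z_obs)
  if (smooth) (1 + hits) / (1 + length(z_perm)) else hits / length(z_perm)
}

#' Permutation false-discovery rate
#'
#' Wang et al.-style GSEA construction: for each set S,
#' \code{FDR(S) = mean_pi[#\{S': z_pi(S') >= z(S)\} / T] /
#' [#\{S': z_obs(S') >= z(S)\} / T]}, clamped to [0, 1]. The denominator
#' always includes S itself.
#'
#' @param z_obs length-T vector of observed scores.
#' @param z_perm Pi x T matrix of permutation scores.
#' @return length-T FDR vector.
#' @export
compute_fdr <- function(z_obs, z_perm) {
  stopifnot(ncol(z_perm) == length(z_obs))
  vapply(z_obs, function(z) {
    num <- mean(z_perm >= z)           # mean over pi of per-pi fraction >= z
    den <- mean(z_obs >= z)            # >= 1/T: S itself qualifies
    min(1, num / den)
  }, numeric(1L))
}

#' Permutation family-wise error rate
#'
#' \code{FWER(S)} is the fraction of permutations whose maximum score across
#' all sets reaches the set's observed score:
#' \code{(1/Pi) sum_pi I(max_S' z_pi(S') >= z(S))}.
#'
#' @inheritParams compute_fdr
#' @return length-T FWER vector; satisfies \code{FWER(S) >= p(S)}.
#' @export
compute_fwer <- function(z_obs, z_perm) {
  stopifnot(ncol(z_perm) == length(z_obs))
  row_max <- apply(z_perm, 1L, max)
  vapply(z_obs, function(z) mean(row_max >= z), numeric(1L))
}

#' Combine permutation blocks
#'
#' Row-concatenates permutation score blocks computed on the same inputs with
#' distinct seeds, so a long permutation run can be split across jobs. The
#' pooled object yields the same p/FDR/FWER as a single run over the
#' concatenated permutation stream.
#'
#' @param blocks list of \code{permutation_scores} objects sharing the same
#'   set list, universe size, alpha and model.
#' @return A pooled \code{permutation_scores} object (Pi = sum of block Pi).
#' @export
combine_blocks <- function(blocks) {
  stopifnot(length(blocks) >= 1L,
            all(vapply(blocks, inherits, logical(1L), "permutation_scores")))
  ref <- blocks[[1L]]
  for (b in blocks[-1L]) {
    if (!identical(b$set_names, ref$set_names))
      stop("blocks have mismatched set lists")
    if (!identical(b$n, ref$n) || !identical(b$alpha, ref$alpha) ||
        !identical(b$model, ref$model))
      stop("blocks have mismatched n/alpha/model")
  }
  structure(list(z = do.call(rbind, lapply(blocks, `[[`, "z")),
                 d = unlist(lapply(blocks, `[[`, "d"), use.names = FALSE),
                 set_names = ref$set_names, m = ref$m, n = ref$n,
                 alpha = ref$alpha, model = ref$model,
                 Pi = sum(vapply(blocks, `[[`, integer(1L), "Pi")),
                 seed = vapply(blocks, function(b) b$seed[1L], numeric(1L)),
                 block_id = unlist(lapply(blocks, `[[`, "block_id"))),
            class = "permutation_scores")
}

#' Assemble the enrichment report from observed and permutation scores
#'
#' @param obs a \code{set_scores} object from
#'   \code{\link{compute_observed_scores}}.
#' @param perm a \code{permutation_scores} object on the same sets.
#' @param smooth_p use add-one smoothing in the permutation p-values.
#' @return An \code{enrichment_report}: a data frame (name, m_snps, y, d, z,
#'   p_value, FDR, FWER) sorted by p-value, then decreasing z, then name,
#'   with global run metadata in attributes (n, d, alpha, Pi, seed, model).
#' @export
report_from_scores <- function(obs, perm, smooth_p = FALSE) {
  stopifnot(inherits(obs, "set_scores"), inherits(perm, "permutation_scores"))
  if (!identical(obs$set, perm$set_names) || !identical(obs$n, perm$n) ||
      !identical(obs$alpha, perm$alpha))
    stop("observed and permutation scores do not match")
  pvals <- vapply(seq_along(obs$z), function(j)
    enrichment_pvalue(obs$z[j], perm$z[, j], smooth = smooth_p), numeric(1L))
  fdr <- compute_fdr(obs$z, perm$z)
  fwer <- compute_fwer(obs$z, perm$z)
  df <- data.frame(name = obs$set, m_snps = obs$m, y = obs$y, d = obs$d,
                   z = obs$z, p_value = pvals, FDR = fdr, FWER = fwer,
                   stringsAsFactors = FALSE)
  df <- df[order(df$p_value, -df$z, df$name), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("enrichment_report", "data.frame"),
            n = obs$n, d = obs$d, alpha = obs$alpha, Pi = perm$Pi,
            seed = perm$seed, model = obs$model)
}

#' Run the full random-set SNP enrichment analysis
#'
#' Computes the per-SNP association scan, observed set scores, the label
#' permutation null, and the per-set permutation p-value, FDR and FWER.
#' Deterministic given \code{seed}.
#'
#' @inheritParams permutation_scores
#' @param smooth_p use add-one smoothing in the permutation p-values.
#' @param keep_perm attach the permutation score object as
#'   \code{attr(, "perm")} (and the observed scores as \code{attr(, "obs")}).
#' @return An \code{enrichment_report} (see \code{\link{report_from_scores}}).
#' @export
run_rs_snp <- function(genotypes, labels, sets, model = "additive",
                       alpha = 0.01, Pi = 1000L, seed = 1L,
                       smooth_p = FALSE, perm_indices = NULL,
                       keep_perm = FALSE) {
  obs <- compute_observed_scores(genotypes, labels, sets, model, alpha)
  perm <- permutation_scores(genotypes, labels, sets, model, alpha, Pi, seed,
                             perm_indices = perm_indices)
  rep <- report_from_scores(obs, perm, smooth_p = smooth_p)
  if (keep_perm) {
    attr(rep, "perm") <- perm
    attr(rep, "obs") <- obs
  }
  rep
}

#' @export
print.enrichment_report <- function(x, ...) {
  cat("RS-SNP enrichment report: T =", nrow(x), "sets, n =", attr(x, "n"),
      "SNPs, d =", attr(x, "d"), "significant at alpha =", attr(x, "alpha"),
      ", Pi =", attr(x, "Pi"), "permutations\n")
  print.data.frame(utils::head(as.data.frame(x), 10L), digits = 4)
  if (nrow(x) > 10L) cat("... (", nrow(x) - 10L, " more sets)\n", sep = "")
  invisible(x)
}
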