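# Synthetic case/control genotype data with known truth: biallelic SNPs drawn
# from Hardy-Weinberg proportions at a configurable MAF spectrum, genes tiled
# along synthetic chromosomes, gene sets partitioning the genes, and optional
# planted per-SNP effects (additive genotypic relative risk) concentrated in
# chosen sets.

#' Simulation configuration
#'
#' Defaults give the desk-scale study design used throughout the package's
#' tests: 2,000 independent SNPs over 200 genes grouped into 40 disjoint
#' 5-gene sets, 250 cases and 250 controls, MAF uniform on (0.05, 0.5).
#'
#' @param n_snps number of SNPs.
#' @param n_cases,n_controls sample sizes.
#' @param maf_range range of the uniform minor-allele-frequency distribution.
#' @param n_genes number of genes tiled along the synthetic chromosomes
#'   (20 genes per chromosome, 10 kb gene bodies, 50 kb intergenic gaps, so
#'   the default 5 kb mapping window assigns each SNP to exactly one gene).
#' @param genes_per_set genes per gene set; sets partition the genes in
#'   order, any leftover genes belong to no set.
#' @param n_sets number of gene sets (requires
#'   \code{n_sets * genes_per_set <= n_genes}).
#' @param planted_set_ids names of sets carrying planted association
#'   (\code{"SET_01"} style); empty for a null dataset.
#' @param fraction_associated fraction of each planted set's SNPs carrying
#'   the effect (the first \code{ceiling(fraction * m)} SNPs of the set in
#'   annotation order, a deterministic choice so that
#'   \code{genotype_relative_risk = 1} reproduces the null dataset exactly).
#' @param genotype_relative_risk per-allele relative risk (>= 1) under the
#'   additive disease model; case genotypes at an associated SNP are drawn
#'   with probability proportional to HWE frequency times RR^dosage.
#' @param missing_rate per-entry missing-genotype probability.
#' @param seed RNG seed; all generator randomness flows from it.
#' @return A validated list of class \code{simulation_config}.
#' @export
simulation_config <- function(n_snps = 2000L, n_cases = 250L,
                              n_controls = 250L, maf_range = c(0.05, 0.5),
                              n_genes = 200L, genes_per_set = 5L,
                              n_sets = 40L, planted_set_ids = character(0),
                              fraction_associated = 0.3,
                              genotype_relative_risk = 1.5,
                              missing_rate = 0.01, seed = 1L) {
  stopifnot(n_snps >= 1L, n_cases >= 1L, n_controls >= 1L, n_genes >= 1L,
            genes_per_set >= 1L, n_sets >= 1L,
            n_sets * genes_per_set <= n_genes,
            length(maf_range) == 2L, maf_range[1] > 0, maf_range[2] < 1,
            maf_range[1] <= maf_range[2],
            fraction_associated > 0, fraction_associated <= 1,
            genotype_relative_risk >= 1,
            missing_rate >= 0, missing_rate < 1)
  structure(list(n_snps = as.integer(n_snps), n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls), maf_range = maf_range,
                 n_genes = as.integer(n_genes),
                 genes_per_set = as.integer(genes_per_set),
                 n_sets = as.integer(n_sets),
                 planted_set_ids = as.character(planted_set_ids),
                 fraction_associated = fraction_associated,
                 genotype_relative_risk = genotype_relative_risk,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "simulation_config")
}

# Gene layout: 20 genes per chromosome, 10 kb bodies, 50 kb gaps.
simulate_gene_annotation <- function(n_genes) {
  genes_per_chrom <- 20L
  body <- 10000L; gap <- 50000L
  j <- seq_len(n_genes)
  chrom <- as.character((j - 1L) %/% genes_per_chrom + 1L)
  within <- (j - 1L) %% genes_per_chrom
  start <- within * (body + gap) + gap + 1L
  data.frame(gene_id = sprintf("gene%03d", j), chrom = chrom,
             start = start, end = start + body - 1L,
             stringsAsFactors = FALSE)
}

simulate_dataset <- function(config, planted) {
  cfg <- config
  set.seed(cfg$seed)
  genes <- simulate_gene_annotation(cfg$n_genes)
  n <- cfg$n_snps
  snp_ids <- sprintf("snp%05d", seq_len(n))
  gene_of_snp <- ((seq_len(n) - 1L) %% cfg$n_genes) + 1L
  pos <- genes$start[gene_of_snp] +
    sample.int(genes$end[1L] - genes$start[1L] + 1L, n, replace = TRUE) - 1L
  snp_ann <- data.frame(snp_id = snp_ids, chrom = genes$chrom[gene_of_snp],
                        pos = pos, stringsAsFactors = FALSE)
  # gene sets: consecutive genes_per_set genes per set
  set_names <- sprintf("SET_%02d", seq_len(cfg$n_sets))
  sets <- lapply(seq_len(cfg$n_sets), function(k)
    genes$gene_id[((k - 1L) * cfg$genes_per_set + 1L):(k * cfg$genes_per_set)])
  names(sets) <- set_names
  desc <- stats::setNames(rep("synthetic gene set", cfg$n_sets), set_names)
  collection <- structure(list(sets = sets, descriptions = desc),
                          class = "gene_set_collection")
  # per-SNP relative risk (1 = null)
  rr <- rep(1, n)
  truth <- data.frame(snp_id = character(), set = character(), grr = numeric(),
                      stringsAsFactors = FALSE)
  if (planted) {
    unknown <- setdiff(cfg$planted_set_ids, set_names)
    if (length(unknown)) stop("unknown planted set id(s): ",
                              paste(unknown, collapse = ", "))
    for (ps in cfg$planted_set_ids) {
      k <- match(ps, set_names)
      member_genes <- ((k - 1L) * cfg$genes_per_set + 1L):(k * cfg$genes_per_set)
      snps_in <- which(gene_of_snp %in% member_genes)
      n_assoc <- ceiling(cfg$fraction_associated * length(snps_in))
      chosen <- snps_in[seq_len(n_assoc)]   # deterministic: first SNPs in order
      rr[chosen] <- cfg$genotype_relative_risk
      truth <- rbind(truth, data.frame(snp_id = snp_ids[chosen], set = ps,
                                       grr = cfg$genotype_relative_risk,
                                       stringsAsFactors = FALSE))
    }
  }
  maf <- stats::runif(n, cfg$maf_range[1], cfg$maf_range[2])
  l1 <- cfg$n_controls; l2 <- cfg$n_cases
  dos <- matrix(NA_integer_, nrow = n, ncol = l1 + l2)
  for (i in seq_len(n)) {
    p <- maf[i]
    hwe <- c((1 - p)^2, 2 * p * (1 - p), p^2)
    wcase <- hwe * rr[i]^(0:2)
    dos[i, seq_len(l1)] <- sample(0:2, l1, replace = TRUE, prob = hwe)
    dos[i, l1 + seq_len(l2)] <- sample(0:2, l2, replace = TRUE,
                                       prob = wcase / sum(wcase))
  }
  if (cfg$missing_rate > 0) {
    miss <- stats::runif(length(dos)) < cfg$missing_rate
    dos[miss] <- NA_integer_
  }
  sample_ids <- c(sprintf("ctrl%04d", seq_len(l1)),
                  sprintf("case%04d", seq_len(l2)))
  cohort <- c(rep_len(c("ctrlA", "ctrlB"), l1), rep(NA_character_, l2))
  out <- list(genotypes = genotype_matrix(dos, snp_ids, sample_ids),
              phenotypes = phenotype_labels(sample_ids,
                                            c(rep(0L, l1), rep(1L, l2)),
                                            cohort),
              snp_annotation = snp_ann, gene_annotation = genes,
              gene_sets = collection, maf = maf, config = cfg)
  if (planted) out$truth <- truth
  out
}

#' Simulate a null dataset
#'
#' Genotypes are drawn per SNP from Hardy-Weinberg proportions at its sampled
#' MAF, independently of case/control status; controls are split into two
#' alternating cohorts (for the control-concordance QC filter). The output
#' realizes the permutation-model null: the sample columns are i.i.d.
#'
#' @param config a \code{\link{simulation_config}} with empty
#'   \code{planted_set_ids}.
#' @return list(genotypes, phenotypes, snp_annotation, gene_annotation,
#'   gene_sets, maf, config).
#' @export
simulate_null_dataset <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  if (length(config$planted_set_ids))
    stop("null dataset requires empty planted_set_ids; use simulate_planted_dataset")
  simulate_dataset(config, planted = FALSE)
}

#' Simulate a dataset with planted pathway signal
#'
#' Same generator as \code{\link{simulate_null_dataset}}, plus an additive
#' disease model at the associated SNPs: case genotype g is drawn with
#' probability proportional to HWE(g) * RR^g. A truth table records every
#' associated SNP and its host set. With \code{genotype_relative_risk = 1}
#' the output is bit-identical to the null dataset under the same seed.
#'
#' @param config a \code{\link{simulation_config}} with non-empty
#'   \code{planted_set_ids}.
#' @return As \code{\link{simulate_null_dataset}} plus \code{truth}
#'   (data.frame snp_id, set, grr).
#' @export
simulate_planted_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  if (!length(config$planted_set_ids))
    stop("planted dataset requires planted_set_ids")
  simulate_dataset(config, planted = TRUE)
}

#' Write a simulated dataset to disk
#'
#' Emits all fixture files in the formats the package reads: genotypes.tsv,
#' phenotypes.tsv, snps.tsv, genes.tsv, sets.gmt, and truth.tsv when present.
#'
#' @param dataset output of \code{\link{simulate_null_dataset}} or
#'   \code{\link{simulate_planted_dataset}}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genotypes(dataset$genotypes, file.path(dir, "genotypes.tsv"))
  write_phenotypes(dataset$phenotypes, file.path(dir, "phenotypes.tsv"))
  utils::write.table(dataset$snp_annotation, file.path(dir, "snps.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$gene_annotation, file.path(dir, "genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_gmt(dataset$gene_sets, file.path(dir, "sets.gmt"))
  if (!is.null(dataset$truth))
    utils::write.table(dataset$truth, file.path(dir, "truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
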