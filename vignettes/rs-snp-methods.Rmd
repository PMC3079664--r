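---
title: "Random-set enrichment analysis of SNP sets: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Random-set enrichment analysis of SNP sets: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

## The problem

A genome-wide association study (GWAS) tests each of n SNPs for association
with a binary phenotype, but single-marker tests leave most of the signal of
a polygenic trait below genome-wide significance. Pathway (SNP-set) analysis
asks a complementary question: does a predefined biological set of SNPs —
typically the SNPs positionally mapped to a pathway's genes — contain **more
associated SNPs than chance predicts**?

`rssnp` implements a random-set enrichment procedure for this question. Fix a
per-SNP significance threshold α (default 0.01) and define, after marker QC:

* n — SNPs in the analysis universe,
* d — SNPs genome-wide with association p-value P ≤ α ("significant"),
* m — SNPs in the set S,
* y — significant SNPs inside S.

The raw enrichment evidence is the count y. Its reference distribution is
built from **two null hypotheses simultaneously**:

1. **Randomization (column) null** — S behaves like m SNPs drawn uniformly
   without replacement from the n; then y ~ Hypergeometric(m, d, n) with
   moments
   μ = m·d/n and σ² = m·(d/n)·(1 − d/n)·(n − m)/(n − 1).
   This null is computed **analytically**, which is the method's central
   computational shortcut: no random sets are ever drawn.
2. **Permutation (row) null** — genotypes are independent of phenotype;
   realized by shuffling the phenotype labels across samples, which preserves
   each subject's whole genotype profile and hence linkage disequilibrium.

The **restandardized enrichment score** is

z = (y − μ)/σ,  with z ≡ 0 when σ² = 0 (e.g. d = 0, or m ∈ {0, n}),

and for each of Π label permutations the same score z\_π is recomputed from
that permutation's own genome-wide count d\_π, so the analytic randomization
null is re-anchored inside every permutation. The permutation p-value is

p(S) = (1/Π) Σ\_π I(z\_π ≥ z\_obs),

with the non-strict ≥ convention (the identity arrangement can always tie, so
ties never yield a spuriously small p). An optional add-one form
(1 + Σ I)/(1 + Π) avoids exact zeros. Multiplicity is handled by permutation
estimates: FDR(S) = mean\_π #{S′ : z\_π(S′) ≥ z(S)} / #{S′ : z\_obs(S′) ≥ z(S)}
clamped to [0, 1], and FWER(S) = fraction of permutations whose maximum score
across all sets reaches z(S). FWER(S) ≥ p(S) always, with equality when only
one set is tested.

Why restandardize at all? An unstandardized count (or sum) statistic grows
with m, so large pathways accumulate "significance" from size alone. Dividing
by the hypergeometric σ removes the size effect: under the null, z has mean 0
and unit scale for every m, making 10-SNP and 500-SNP sets directly
comparable (this is verified in the acceptance suite, see below).

## Per-SNP association scan

Each SNP is summarized as a 2 × 3 table of genotype dosage (0/1/2 copies of
the minor allele) by case/control status, using complete cases per marker.
Five genetic models are available:

* **additive** (default) — Cochran–Armitage trend test with weights
  (0, 1, 2); 1 df. The default because it is near-optimal across a wide
  range of true genetic models and admits a fully vectorized kernel, which
  matters in the permutation hot path (Π × n tests).
* **general** — 2-df Pearson chi-square on the 2 × 3 table; empty genotype
  columns are dropped and the df reduced accordingly.
* **dominant** ({1,2} vs {0}), **recessive** ({2} vs {0,1}),
  **multiplicative** (allelic 2 × 2) — 1-df chi-square on the collapsed
  2 × 2 table, switching to Fisher's exact (two-sided, by probability mass)
  whenever any expected cell count is below 5. The test statistic D reported
  alongside remains the chi-square value so that D is comparable across SNPs.

## Marker quality control

`apply_marker_qc()` applies the conventions of large case–control consortium
studies. A marker is removed (strict inequalities; at-threshold markers are
kept) when any of the following holds, with the removal reason recorded by
this priority: Hardy–Weinberg disequilibrium, control-group discordance,
low MAF.

* **HWE**: exact conditional test (enumeration over heterozygote counts with
  fixed allele margins, computed in log space) on the **combined controls**,
  p < 5.7 × 10⁻⁷.
* **Control-group association**: between the two control cohorts, min of the
  1-df trend and 2-df general p-values, p < 5.7 × 10⁻⁷ — a marker whose two
  control groups disagree is a genotyping artifact.
* **MAF** < 1% over all samples.

QC is idempotent: re-applying it to its own output removes nothing.

## SNP-to-gene mapping and set construction

`map_snps_to_genes()` assigns a SNP to every gene on the same chromosome
whose extended body [start − w, end + w] contains the SNP position
(inclusive; default window w = 5 kb). SNPs in the overlap of two genes map to
both; optionally, unmapped SNPs can be assigned to the closest gene. A gene
set (read from GMT) is resolved to the union of its member genes' SNPs,
restricted to the post-QC universe; sets outside [min\_snps, max\_snps]
(default ≥ 2 SNPs) are excluded and reported.

## Synthetic data generator

`simulate_null_dataset()` / `simulate_planted_dataset()` produce a fully
specified desk-scale study with known truth:

* Genotypes per SNP from Hardy–Weinberg proportions at a MAF drawn uniformly
  from (0.05, 0.5); samples i.i.d., so the permutation null is exactly true.
* Genes tiled 20 per chromosome (10 kb bodies, 50 kb gaps), so the default
  5 kb window maps each SNP to exactly one gene; sets partition the genes.
* Defaults: 2,000 SNPs, 200 genes, 40 five-gene sets (50 SNPs each),
  250 cases + 250 controls, 1% missing entries; controls split into two
  alternating cohorts so the control-concordance filter is exercised.
* Planted signal: in chosen sets, the first ⌈fraction · m⌉ SNPs (fraction
  0.3 by default) receive a per-allele genotype relative risk (default 1.5);
  case genotypes g are drawn with probability ∝ HWE(g) · RR^g. The
  associated SNPs are chosen **deterministically** so that RR = 1 reproduces
  the null dataset bit-for-bit — planted and null runs differ only through
  the effect itself.

These sizes are the package's own desk-scale choice: large enough that the
additive scan, QC and permutation machinery run in realistic proportions,
small enough that a 50-replicate calibration study completes in minutes.

The generator is validated in the test suite by: allele-frequency tracking
(joint χ² over standardized errors), HWE conformity of control genotypes
(one-sided excess check rather than KS uniformity, because exact-test
p-values are discrete and conservative), per-SNP power of the planted effect
pinned against an oracle run of the same sampling scheme, and byte-level
round-trips through all file formats.

## Numerical and reproducibility choices

* All heavy kernels are vectorized: the trend statistic is computed for all
  n SNPs at once from three per-dosage indicator matrices and matrix–vector
  products, so each permutation costs one pass over the genotype matrix.
* Missing genotypes are excluded per marker (complete-case 2 × 3 tables);
  a SNP whose table degenerates under some permutation scores D = 0, P = 1
  rather than failing the run.
* Every stochastic step (generator, permutations) is seeded; the same seed
  reproduces the enrichment report byte-for-byte, and reports are written
  with fixed number formatting and newline convention so the bytes are
  platform-stable. Long permutation runs can be split into blocks
  (`permutation_scores()` + `combine_blocks()`) with per-block seeds; the
  pooled result is identical to a single run over the concatenated stream.

## Validation design (acceptance suite)

`tests/testthat/test-acceptance.R` checks one property per block:

1. **Hypergeometric ≡ explicit randomization**: over a grid of (n, d, m),
   moments of 100,000 explicit uniform m-subsets match the analytic values
   within 3 Monte-Carlo SE, and the full empirical distribution passes a
   χ² goodness-of-fit against the exact pmf (sparse support points pooled to
   expected ≥ 5; Bonferroni family level 0.01). The variance check uses the
   second moment about the **known** mean, whose i.i.d. Monte-Carlo SE is
   well defined even for two-point supports.
2. **Exact oracle equality** of all five association statistics on **every**
   2 × 3 table with total ≤ 20 (230,229 tables), against independently coded
   vectorized oracles that are themselves spot-checked against scalar
   textbook formulas.
3. **HWE exact test** equals exhaustive enumeration on all tables with ≤ 30
   individuals.
4. **Type-I calibration** on 50 null replicate studies (Π = 200): the pooled
   fraction of sets with p ≤ 0.05 lies in the binomial 99% band, and the
   tie-aware randomized probability-integral transform
   u = (#{z\_π > z\_obs} + U·(1 + #{z\_π = z\_obs}))/(Π + 1) — exactly
   U(0, 1) under exchangeability despite the Π-point grid — passes per-set
   KS tests at Bonferroni family level 0.01. Per-set testing is essential:
   sets within one replicate share the permutation stream, so pooling their
   PIT values would make the KS test anti-conservative.
5. **Set-size robustness**: null z distributions for a 10-SNP and a 500-SNP
   set are compared by two-sample KS after a randomized continuity
   correction (y jittered uniformly within its unit lattice cell before
   standardizing). The correction removes only the granularity artifact — a
   10-SNP count takes at most 11 values, so raw scores of even a perfect
   implementation live on a visibly coarse lattice — while any statistic
   with size-dependent location or scale still fails the comparison.
6. **Power**: the planted pathway (RR 1.5 on 30% of its SNPs) attains the
   top z rank in over 90% of 50 replicates.
7. **Structural identities**, exact: identity permutation reproduces the
   observed scores; FWER ≥ p with equality for a single set; α = 1 forces
   z ≡ 0, p ≡ 1; block combination equals the pooled run; p-value magnitudes
   below α are irrelevant to every output; same-seed runs are bit-identical
   including report bytes.

## Worked example

```{r example, eval = FALSE}
library(rssnp)

cfg <- simulation_config(planted_set_ids = "SET_07", seed = 13)
ds  <- simulate_planted_dataset(cfg)

al   <- align_samples(ds$genotypes, ds$phenotypes)
qc   <- apply_marker_qc(al$genotypes, al$labels)
map  <- map_snps_to_genes(ds$snp_annotation, ds$gene_annotation, window_kb = 5)
sets <- build_snp_sets(map, ds$gene_sets, qc$genotypes$snp_ids)

report <- run_rs_snp(qc$genotypes, al$labels, sets,
                     alpha = 0.01, Pi = 1000, seed = 14)
print(report)
```

The same pipeline is available from the command line through
`inst/cli/rssnp.R` (`simulate`, `qc`, `assoc`, `enrich`, `combine`
subcommands), which writes a JSON manifest with input digests so any run can
be replayed exactly.

## Limitations

* Binary phenotypes only; no covariate adjustment inside the permutation
  (confounders must be handled upstream, e.g. by matching).
* The randomization null treats sets as uniform draws of SNPs; strong
  local LD inside real pathways makes the effective m smaller than the
  nominal one. Label permutation preserves LD in the permutation null, but
  the analytic hypergeometric variance does not model it.
* The synthetic generator draws independent SNPs; it validates calibration
  and power of the machinery, not robustness to realistic LD structure.
* Permutation p-values have resolution 1/Π; FDR/FWER estimates inherit the
  usual permutation granularity at small Π.
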