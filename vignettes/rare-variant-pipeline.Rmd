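---
title: "Methods: rare-variant association for targeted re-sequencing of founder cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rare-variant association for targeted re-sequencing of founder cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rarelocus)
```

## The study design this package models

`rarelocus` implements the analysis of a targeted re-sequencing association
study in a recently bottlenecked founder population. The design: coding
regions of genes at known GWAS loci are sequenced in a large population
cohort plus an overlapping case-control cohort; replicate genotype call
sets from several centers are merged by majority vote; quantitative
metabolic traits are residualized on demographic covariates; and the
association question is asked at three granularities — single common/
low-frequency variants (marginally and conditional on the locus's known
"array SNP"), genes (collapsing rare non-synonymous variants), and
multivariate models per locus.

The founder-population angle matters because a bottleneck reshapes the
site-frequency spectrum (SFS): many very rare alleles are lost to drift
while some deleterious alleles ride drift up into the 0.5–2% band
("Goldilocks alleles") — rare enough to be population-specific, common
enough that a few thousand samples power a single-variant test.

## The synthetic cohort generator

Real cohort genotypes are not distributable, so the package ships a
generator whose defaults are the study conditions, and every statistical
claim in the test suite is made against it.

**Allele frequencies.** The default `parametric` bottleneck model draws
population MAFs from a two-part mixture: with probability
`goldilocks_weight` (default 0.12) from a log-uniform density on
[0.005, 0.02], otherwise from the standard neutral density proportional to
$1/p$ truncated below at `min_maf_factor` (default 4) times the neutral
minimum $0.5/(2n)$. The two knobs express exactly the two qualitative
bottleneck signatures — an elevated Goldilocks band and a depressed
singleton tail relative to the neutral $1/i$ spectrum at matched sample
size — which is how the study uses the bottleneck (qualitatively, never as
a fitted demographic model). An explicit two-epoch forward Wright–Fisher
mode (`wright_fisher`) is available when an actual drift process is wanted;
it redraws fixed/lost sites so that all returned frequencies segregate.
All frequencies are folded to (0, 0.5].

**Genotypes** are Binomial(2, p) draws (Hardy–Weinberg), with an optional
two-subpopulation Balding–Nichols perturbation at `substructure_fst`
(0–0.1) to exercise the PCA stratification control.

**Phenotypes.** Six fasting metabolic traits (TG, HDL-C, LDL-C, TC, FG, FI)
with the right-skewed ones (TG, FG, FI) generated so that the log of the
trait is linear in the predictors. Covariates: age uniform on 31–62 years,
sex Bernoulli(1/2), oral-contraceptive use and pregnancy only in females
(25% and 3%), a cohort indicator, and a case effect on the glycemic traits
only. Trait means and dispersions are free parameters of the generator
(the source design does not pin them); the defaults in
`default_trait_params()` sit in the physiological range for an adult
northern-European cohort, in mmol/L (mU/L for insulin). Genetic effects are
specified in residual-SD units per allele copy; rare causal variants are
drawn from the *non-synonymous* sites of a locus below the effect set's MAF
ceiling, because the gene-level tests collapse exactly that variant class —
planting causal intronic variants would test nothing.

**Replicate call sets.** Each of three centers reports the truth corrupted
by independent per-genotype flips (`center_error_rate`, default 0.001,
matching the ~99.96% inter-center concordance regime) and missingness
(default 0.005), plus a configurable number of planted alt-allele-discordant
sites that consensus merging must exclude.

**What the generator does not emulate:** linkage disequilibrium between
sites (sites are independent; the only built-in correlation devices are the
planted array-SNP/rare-variant scenarios constructed in tests), read-level
error processes, and within-Finland geographic substructure beyond the
two-subpopulation split. Tests passing on this generator therefore validate
the statistical machinery, not robustness to LD-induced confounding.

**Reproducibility.** One master seed fans out to named sub-streams
(`substream_seed()`), so e.g. the genotype stage is reproducible regardless
of how many draws the frequency stage consumed.

## Consensus calling and the validation ledger

Majority vote is over genotype values, not alleles: a consensus genotype
exists iff at least two centers agree on it; triples with fewer than two
non-missing calls, or all-distinct values, are missing. Sites are excluded
wholesale when centers disagree on the ALT allele or any center reports a
multi-allelic ALT. Concordance is reported over all pairwise center
comparisons at mutually non-missing entries, partitioned by the *consensus*
genotype class — the choice that makes per-class rates well defined when
the pair itself disagrees.

The validation ledger reproduces the arithmetic of a low-count-site
validation campaign. One printed inconsistency is handled explicitly: the
stated retained total (663) differs by one from the sum of its printed
parts (91 + 205 + 366 = 662). `validation_ledger()` derives 662, accepts
the stated 663 as an optional input (which the downstream totals 1,780 and
1,852 require), and raises a warning rather than reconciling silently.

## Association testing

Residualization regresses each (possibly log) trait on age, age², sex,
OC use, pregnancy and cohort in the combined sample; T2D cases are dropped
for FG/FI. A rank-based inverse-normal option maps the residuals to exact
standard-normal quantiles. Stratification control uses the top K = 5
principal components of the LD-pruned (greedy sliding window, 50 SNPs, step
5, r² < 0.5) common-variant genotype matrix, standardized per SNP by
$(x - 2\hat p)/\sqrt{\hat p(1-\hat p)}$ with mean imputation of missing
dosages.

Single-variant tests are per-variant complete-case OLS of the residuals on
the coded genotype plus PCs, with t-distribution p-values at the residual
degrees of freedom (exact at moderate n, rather than the normal
approximation). The MAF floor is 0.1%. Conditional tests append the array
SNP's dosage to the covariates; a tested variant with r² > 0.99 against a
conditioning dosage is flagged non-estimable rather than fitted. Two
variants are called independent iff r² < 0.20 (strict). The case-control
test is a logistic Wald test (MAF > 1%) with a quasi-separation flag.

## Gene-level tests

Gene sets collapse non-synonymous variants with folded MAF strictly below
1%, require at least two qualifying sites, and restrict to individuals with
complete genotypes across the gene's sites.

**Burden (CMC-style).** The per-individual score is
$b_i = \sum_j w_j g_{ij}$ with Madsen–Browning inverse-SD weights
$w_j = 1/\sqrt{n \hat p_j (1-\hat p_j)}$ (the $\hat p_j$ smoothed as
$(\text{MAC}+1)/(2n+2)$ so sites monomorphic within the complete-case
subset keep finite weight); an unweighted 0/1-collapse option is exposed.
The statistic is the squared t of the burden coefficient with PCs in the
model, and the p-value comes from permutations of the residual vector:
$p = (1 + \#\{\text{perm} \ge \text{obs}\})/(1 + B)$, floored at
$1/(B+1)$. The weighted-sum form was chosen because the source study
describes its collapsing test as a weighted-sum-score linear model without
printing the weights; Madsen–Browning is the canonical inverse-variance
choice, and the flat option brackets the alternative. When `escalate =
TRUE`, a p-value under $10/B$ re-runs at $10B$ up to $10^6$ permutations.
The permutation loop is vectorized: burden and permuted residuals are both
projected off the covariates once, after which each permutation statistic
is a pair of cross-products.

**Variance component (SKAT-style).** With null-model residuals $r$ (trait
residuals regressed on intercept + PCs) and weights $W$ (default the
Beta(1, 25) density of the sample MAF, the cited method's published
default; flat option available), the score statistic is
$Q = r' G W^2 G' r / \hat\sigma^2$, distributed under the null as
$\sum_k \lambda_k \chi^2_1$ with $\lambda_k$ the eigenvalues of
$W G' P G W$ ($P$ the covariate annihilator). The tail probability is
computed by Imhof's characteristic-function inversion with
`stats::integrate()`. Two numerical choices matter: (i) eigenvalues and
statistic are first rescaled by the mean eigenvalue — the tail probability
is scale-invariant and the rescaling keeps the oscillatory integrand on an
O(1) scale where the quadrature is reliable (unscaled, raw eigenvalues of
order $10^4$ silently collapse the integral); (ii) below $p \approx
10^{-9}$, where quadrature error dominates, the Liu four-moment chi-square
approximation takes over. A single-eigenvalue set short-circuits to the
exact scaled-chi-square tail, which also makes a one-variant set reduce
exactly to the squared score test. A permutation fallback (with warning)
covers eigenvalue failure, and `skat_test_perm()` exposes the permutation
route for calibration cross-checks.

**Power-ordering scenario.** The property that the burden test beats the
variance-component test under same-direction effects (and vice versa under
mixed signs) is asserted on a scenario fixed in advance of any tuning: 10
non-synonymous sites at MAF 0.2–1%, all causal at ±0.25 residual SD, in
n = 1,000. The effect size was chosen by an operating-characteristic
argument, not by the test outcome: the comparison is between a permutation
p-value (granularity $1/(B+1)$) and an asymptotic one, so both must land in
the mid range (roughly 0.005–0.3); much stronger effects push the burden
p-value onto its permutation floor and the comparison degenerates into an
artifact of resolution rather than power.

## Model selection and multiplicity

The stepwise search starts from intercept + 5 PCs (never dropped), takes at
each step the single addition or deletion of a non-singleton variant that
most decreases $\mathrm{BIC} = n\ln(\mathrm{RSS}/n) + k\ln n$ ($k$ counting
all free coefficients including intercept and PCs), and stops when no move
decreases it. Moves that would make the design singular are skipped, so a
duplicate of a selected variant can never co-select; exact BIC ties break
by genomic position then id, making the search invariant to candidate
ordering. Singletons are excluded from candidacy: with one carrier the
effect is not inferable without parametric leaps. Variance explained is
reported as ordinary R² (percent) of the trait residuals on the array SNP
alone versus array SNP plus selected variants, with PCs partialled out of
all quantities consistently.

Multiplicity control offers the Benjamini–Hochberg step-up cutoff (built on
`stats::p.adjust`; the cutoff is the largest rejected p-value, 0 when
nothing is rejected) and the Bonferroni cutoff $\alpha/m$. The report
builder applies the study's operating rule — a fixed p < 0.001 threshold
for calling a conditional signal independent, combined with the r² < 0.20
rule — with BH-derived cutoffs available as the option.

## Problem sizes in the test suite

The statistical property tests run at sizes chosen to give decisive
Monte-Carlo margins on one CPU: gene-level size is checked on 1,000 null
gene sets of 8 sites in n = 500 (B = 1,000 permutations, three-SE band
around 5%); the power ordering on 200 replicates per direction; asymptotic
vs permutation SKAT calibration on 200 null genes at B = 10,000
(Spearman > 0.95); stepwise recovery on 40 replicates of a 50-candidate
locus at n = 5,000 with three planted signals each explaining ≥ 0.5% of
variance. `scripts/acceptance.R` re-measures the same quantities at
moderately reduced replicate counts and writes them as JSON alongside the
printed-table worked examples.

## Known limitations

- No LD model in the generator: conditional-analysis behaviour under
  realistic haplotype structure is exercised only through the constructed
  two-variant LD scenarios.
- The variance-component test is Gaussian-trait only (no binary-trait
  variant, no SKAT-O style combination), matching the scope of the design.
- Permutation p-values assume exchangeable residuals; with strong
  heteroscedasticity across covariate strata they are approximate.
- The Liu tail approximation used below $10^{-9}$ is known to be slightly
  anti-conservative in the extreme tail; p-values there should be read as
  order-of-magnitude statements.
- Coverage QC consumes a precomputed per-individual coverage fraction;
  depth computation from alignments is out of scope.
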