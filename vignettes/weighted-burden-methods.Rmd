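---
title: "Weighted burden testing with signed log-p statistics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted burden testing with signed log-p statistics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slpburden)
```

## The statistical problem

Very rare coding variants can carry substantial disease risk, but no single
rare variant is frequent enough to test on its own. Burden tests address
this by collapsing a gene's rare variants into one per-subject score and
comparing scores between cases and controls. `slpburden` implements a
weighted form of this idea for case-control exome data, together with the
quality control, population-stratification handling and reporting that such
an analysis needs, and a synthetic cohort generator that reproduces the
statistical structure the methods assume so that every stage can be tested
end to end without access to controlled genotype data.

## The weighted burden score and the SLP statistic

Each analysed variant $v$ receives a functional weight

$$w_v = b(\mathrm{cat}_v) \;+\; 10\cdot[\mathrm{PolyPhen}_v \in
\{\text{possibly, probably damaging}\}] \;+\;
10\cdot[\mathrm{SIFT}_v = \text{deleterious}],$$

where $b(\cdot)$ is a severity-ordered base table anchored at 5 for a
synonymous and 20 for a stop-gained variant (see
`default_weight_table()`); the increments default to 10 and every value is
user-overridable. The full severity ladder between those anchors is this
package's own choice (intronic 1, UTR 3, synonymous 5, splice-region /
in-frame / missense 10, and 20 for splice donor/acceptor, frameshift,
stop-gained/lost and start-lost), preserving the intended ordering while
keeping the table a plain configuration file. A rarity-multiplier flag is
carried in the table but no functional form ships with it: under the MAF
ceiling below, rarity weighting has negligible effect, so the multiplier is
fixed at 1.

The gene-wise score of subject $i$ is
$s_{ig} = \sum_{v \in g} w_v \, g_{iv}$ with $g_{iv} \in \{0,1,2\}$ the
allele count (missing genotypes contribute 0). Scores are compared between
cases and controls with a two-sample t test and summarised as a signed
log-p,

$$\mathrm{SLP} = \pm \log_{10}(1/p),$$

positive when the case mean is higher. An SLP of 3 therefore means an
excess among cases at two-tailed $p < 10^{-3}$. The pooled-variance
(Student) form is the default, with Welch available via `var_equal =
FALSE`; the choice matters little at cohort sizes in the thousands and the
pooled form is the classic behaviour of score-based association tools.
p values are floored at the smallest positive double before taking logs so
an SLP is always finite; the magnitude is computed on the log scale
(`pt(..., log.p = TRUE)`) so extreme tails lose no precision.

Three variant partitions are analysed: *singleton* variants (exactly one
carrier subject in the whole cohort, and absent from the external reference
panel — the package's operational definition of an ultra-rare variant,
URV), *non-singleton* variants, and *all* variants. Scores are additive
across the partition, which the tests assert exactly.

Gene-set (pathway) scores sum each subject's gene-wise scores over the
set's member genes; members outside the analysed universe contribute 0 and
sets with no matched genes are flagged and excluded. Because gene sets
overlap, set-wise SLPs are positively correlated and a QQ plot of them is
expected to run shallower than the identity line.

## Quality control

The filters mirror standard exome case-control practice, in this order:

1. genotype calls with quality below 30 are masked as missing (strict
   `GQ < 30`; genotypes without a GQ value pass by default, as array-style
   inputs carry no GQ — configurable);
2. sites are removed when the VCF FILTER field is not `PASS`;
3. sites are removed when more than 10% of genotypes are missing or of low
   quality in *either* cases or controls (strictly greater than 10%,
   evaluated after masking — whether the original pipelines masked before
   or after counting missingness is not documented anywhere we know of, so
   the order here is fixed and stated);
4. sites are removed when the heterozygote count is smaller than both
   homozygote counts in *both* cohorts (strict inequalities, exactly as the
   rule is usually worded);
5. variants with per-cohort MAF above 0.01 in cases *and* in controls are
   excluded from scoring. The conjunction is deliberate: a variant rare in
   either cohort stays in, so retained variants have MAF below the ceiling
   in cases and/or controls.

The first failing rule is recorded per site for audit (`filter_sites()`
returns the report). Filtering is idempotent, which the tests assert.

## Population stratification

A confounding subpopulation with shifted allele frequencies and a different
ultra-rare-variant rate can mask or fake case-control differences. The
package addresses this three ways.

**Ancestry allele score.** Published pipelines cite a prior method for
identifying subjects with excess alleles from a reference subpopulation;
the algorithm itself is not restated there, so this package defines its own
faithful-in-spirit score and documents it: over "discriminating" variants
(reference frequency ratio $\mathrm{AF_B}/\mathrm{AF_A} \ge$ 5 by default,
base frequency $\le 0.01$),

$$\mathrm{score}(i) = \sum_v g_{iv}\,\log_{10}
\frac{\mathrm{AF_B}(v)}{\mathrm{AF_A}(v)}.$$

It is linear in allele counts, parameterised, and testable: on synthetic
cohorts with a planted subpopulation it separates the groups with AUROC
above 0.9. Subjects scoring more than 3 SD above the mean are flagged;
because an outlying subpopulation inflates the SD, the mean and SD are
recomputed after each exclusion round until stable (both the cutoff and the
iteration are configurable — whether the original exclusion used an
absolute or distribution-relative threshold is unstated, so both are
supported).

**URV/dURV counting and enrichment regression.** Each subject's URV count
is the number of singletons they carry; the dURV subset is "damaging or
disruptive": loss-of-function categories unconditionally, missense only
with a damaging PolyPhen or deleterious SIFT annotation (the exact list is
explicit configuration, since "damaging" is defined differently across
studies). Enrichment of dURVs in cases is tested by logistic regression of
case status on the dURV count, optionally adjusting for the total URV count
and the first $K$ genotype principal components (default 20). Counting
precedes exclusion by default but can be recomputed afterwards.

**Genotype PCs.** Computed on the centred, scaled dosage matrix over
variants with MAF at least 0.001 (a floor that keeps singleton-dominated
directions out of the leading components), with per-variant mean imputation
of missing entries. Because subjects are far fewer than variants, the
decomposition runs on the subject-by-subject cross-product. Components are
deterministic up to sign; the sign is fixed by making each component's
largest-magnitude variant loading positive.

## The synthetic cohort generator

`cohort_spec()` + `simulate_cohort()` generate seeded cohorts whose
statistical structure matches the assumptions above; the same spec and seed
give byte-identical files (VCF 4.2 with `GT:GQ`, phenotype TSV, gene map,
GMT, truth table).

* **Frequencies**: population frequencies follow a Beta(0.5, 250) law
  truncated to (0, 0.01] — a rare-variant site-frequency spectrum with mean
  near 0.002 — with Hardy-Weinberg genotypes (two independent allele
  draws). A Poisson number of such variants per gene (mean 8) keeps a
  1000-gene cohort computable on one CPU; real exomes carry more variants
  per gene, which changes cost, not structure.
* **Disease model**: case status is assigned by a logistic model whose
  linear predictor adds `effect_scale` $\times$ weight per risk allele in
  the designated risk genes, with the intercept set to the requested cohort
  balance; cohort quotas are filled by stratified rejection sampling. This
  induces exactly the enrichment the burden test targets, with a single
  interpretable scale parameter. A scale that saturates the case
  probability is refused rather than truncated. The replicate fixtures in
  the test suite use `effect_scale = 0.05` (odds ratio $e^{1}$ for a
  carrier of one weight-20 allele) — a strong but plausible effect for a
  designated risk gene.
* **Singletons**: materialised post hoc as exactly one alternate allele in
  one subject, guaranteeing the single-subject definition at any cohort
  size, and flagged absent from the reference panel. Per-subject counts are
  Poisson with mean `singleton_rate` (default 2 — a desk-scale choice;
  published exome cohorts report far larger per-subject URV counts, which
  the generator accepts but which multiply the matrix size). The damaging
  subset can be enriched in cases via `durv_case_excess`, which is the knob
  the confounding experiments need.
* **Confounding subpopulation**: a fraction of each cohort (allowed to
  differ between cases and controls) draws its genotypes at frequencies
  multiplied by `subpop_freq_shift` (default 10, echoing variants an order
  of magnitude commoner in a neighbouring population) on a random 30% of
  variants, mirrored in the emitted `AF_POPB`, and has its own singleton
  rate. Cases over-represented in a low-singleton subpopulation mask a
  programmed relative dURV excess, which the covariate-adjusted regression
  recovers — the pattern the acceptance tests reproduce with fractions
  0.20/0.05, singleton rates 3 vs 1.2 and a 1.25-fold case excess.
* **Corruption**: genotype qualities come from a two-component mixture (2%
  below the GQ-30 threshold by default), 1% of genotypes are missing, and
  2% of sites get a non-PASS FILTER, so the QC rules are exercised with
  known expected removal rates.

What the generator does **not** emulate: linkage disequilibrium between
sites, relatedness, sequence-level realism (no reads or alignment),
transcript structure, or annotation error. Passing tests on these cohorts
show that the statistical machinery is correct under the stated model; they
do not certify behaviour on data whose LD or relatedness structure violates
the independence assumptions.

## Numerical and design choices

* **Null calibration**: under a null spec the fraction of gene-wise SLPs
  above +1 is 5% (SLP > 1 is two-sided $p<0.1$ with the case mean higher)
  and the QQ slope is near 1; the acceptance suite checks both on a
  2000+2000-subject, 1000-gene cohort, sizes chosen so the check runs in
  about a minute on one CPU.
* **QQ machinery**: under the null the SLP is distributed as
  $S\cdot(-\log_{10}U)$, $U\sim\mathrm{U}(0,1)$, $S=\pm1$ equiprobable.
  Rank $i$ of $n$ is assigned the closed-form quantile at $(i-0.5)/n$:
  $\log_{10}(2q)$ for $q<1/2$, $-\log_{10}(2(1-q))$ for $q>1/2$ — an
  antisymmetric sequence verified against a $10^6$-draw Monte-Carlo oracle.
  The $(i-0.5)/n$ plotting position is this package's convention, stated
  and tested rather than assumed. The slope is a least-squares fit through
  the origin.
* **t reference vs permutation**: the t-based SLP matches an exact
  permutation test closely when scores are sums over many variants (the
  situation the method is built for); on ultra-sparse scores with a single
  extreme weight at a handful of subjects the t approximation is poor and
  the permutation law is coarse, so the suite checks fine agreement
  (±0.05 in p) only in the smoothed regime and checks sparse instances
  qualitatively. This granularity is also why the singleton-only partition
  is the least well calibrated at small carrier counts.
* **Degenerate genes** (zero variance in both cohorts) are reported with
  SLP 0 and a flag rather than dropped, keeping the gene universe — and
  any Bonferroni denominator `bonferroni_slp_threshold(n, alpha)
  = log10(n/alpha)` — stable across partitions.
* **Multi-allelic sites** are split per alternate allele, with other
  alternates treated as reference for each split allele's dosage, because
  scoring is per allele.
* **Missing annotations** default to class `unknown`, which never adds an
  increment — conservative weighting by construction.
* **Gene assignment** is interval overlap against every gene (1-based
  inclusive coordinates on both sides, matching VCF positions); how the
  original tooling resolved variants spanning several genes' transcripts is
  not documented, so overlap-with-every-gene is this package's stated
  choice, with alias groups (e.g. an overlapping gene cluster analysed
  under one label) merged so a variant counts once per merged gene.
* **Determinism**: ties in reporting are avoided by lexicographic gene
  ordering; PC signs are fixed as above; the generator is a pure function
  of (spec, seed).

## Known limitations

Covariate-adjusted *burden* testing is deliberately absent (the gene and
set tests carry no covariates; stratification is handled by exclusion), as
are variance-component (SKAT-style) tests, kinship handling and any
annotation computation — consequence and PolyPhen/SIFT classes are consumed
as input, never predicted. The exact published weight ladder beyond the two
anchored values is not public, so the default table is an explicit,
overridable reconstruction of its ordering. Cohorts with genuine LD between
rare variants will violate the generator's independence assumptions, and
set-wise SLPs from overlapping sets are correlated by construction, so
Bonferroni thresholds for sets are conservative.
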