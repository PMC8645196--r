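---
title: "Methods: inversion-aware expression analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: inversion-aware expression analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(invexpr)
```

## The problem

Large chromosomal inversions suppress recombination between their two
arrangements (here called α and β), so the three karyotypes — the αα and ββ
homokaryotypes and the αβ heterokaryotype — can accumulate distinct
regulatory variation. `invexpr` analyses bulk RNA-seq designs built around
such an inversion: adults sequenced individually, larvae sequenced as pools
of three with sex undetermined, and karyotype as the factor of primary
interest. The package asks, for a focal inversion spanning roughly 60% of
its linkage group and 10% of the genome:

* which transcripts differ in expression between karyotypes, sexes and life
  stages;
* whether heterokaryotype expression is additive, dominant for one
  arrangement, or over-/underdominant;
* whether karyotype-associated differential expression is *cis* (physically
  inside the inversion) or *trans*;
* whether heterokaryotypes show allele-specific expression (ASE) at SNPs
  fixed between arrangements, and how reliable a read-fraction cutoff
  classifier for this is;
* whether differentially expressed (DE) transcripts sit near
  environmentally associated outlier SNPs more often than chance;
* how much expression variance karyotype explains overall (PERMANOVA on
  Manhattan distances).

Every analysis runs against the package's own synthetic-data generator, so
all statistical contracts are testable without any sequencing data.

## The synthetic-data generator

`sim_params()` fixes the study conditions. The defaults mirror the design
the package targets:

* **Genome**: six linkage groups of 40 Mb; the inversion covers 24 Mb of
  LG1 (60% of LG1, exactly 10% of the genome). Transcripts (log-normal
  lengths, median ~1 kb) are placed uniformly, proportional to linkage-group
  length, so ~10% of transcripts fall inside the inversion by chance.
* **Samples**: 17 adults (4/4/4/5 across sex × homokaryotype, 13 of 17 from
  one population) and 27 larval pools of three individuals with deliberately
  unbalanced karyotypes (2 αα, 10 αβ, 15 ββ). The imbalance reproduces the
  power asymmetry of crossing designs in which heterokaryotype parents are
  easiest to obtain; contrasts involving αα larvae are correspondingly weak.
* **Counts**: negative binomial with mean μ and dispersion k
  (variance μ + μ²/k, k = 10 by default — a typical bulk RNA-seq value;
  there is no published per-gene dispersion table for this system, so k is
  a convention and config-exposed). Baseline means are log-normal
  (meanlog 4, sdlog 1.5). Larval pool counts are sums of three independent
  individual draws, which keeps the pool mean at 3μ and inflates the
  variance accordingly.
* **Effects** (log2 scale): 10% of transcripts sex-DE (adults only; larvae
  have unknown sex and receive no sex effect), 5% karyotype-DE with
  magnitudes uniform on [2.5, 5] so that true effects clear the
  conventional |log2FC| > 2 calling threshold. Karyotype-DE genes fall
  inside the inversion with probability `cis_fraction` (default 0.8).
  Heterokaryote means follow each gene's dominance class: additive = log2
  midpoint, α-/β-dominant = the matching homokaryote mean, over-/under-
  dominant = beyond the homokaryote range by `dominance_dev` (1 log2 unit).
* **ASE**: every inversion transcript gets 3 SNPs fixed between
  arrangements; per pool and SNP the depth is Poisson with mean 44 (the
  read-depth scale the calibration targets) and α-allele reads are
  binomial(depth, 0.5 ± bias). A small fraction of SNPs violate fixedness
  and some homokaryote genotypes are missing, so the SNP filter has real
  work to do.
* **Outlier SNPs**: a configured fraction is placed strictly within the
  overlap window of truly DE transcripts; the rest are uniform.

What the generator does **not** emulate: GC/length biases, batch effects,
correlated gene modules, mapping bias at ASE SNPs, linkage disequilibrium
beyond the inversion itself, and population structure richer than a single
two-level factor. Passing recovery tests therefore demonstrate that the
estimators are correct and calibrated under the stated model, not that real
libraries meet that model.

## Differential expression engine

The engine trades the full empirical-Bayes machinery of the established DE
packages for a small, transparent pipeline whose contract is calibration:

1. **Size factors**: median-of-ratios (per sample, median over transcripts
   with positive geometric mean of count/geomean).
2. **Filter**: transcripts with total raw count strictly below 10 across
   all samples are removed ("less than 10" is read strictly, so a total of
   exactly 10 survives).
3. **Dispersion**: per-gene method-of-moments on normalized counts, with
   residual variance taken within design cells, floored at 1e-8; when at
   least 50 genes are present, the gene-wise estimate is averaged (weight
   0.5) with a lowess trend on the base mean. This mimics the stabilising
   effect of shrinkage without its machinery.
4. **Fit**: per-gene NB log-linear model (log size factors as offset,
   dispersion held fixed) by iteratively reweighted least squares, at most
   50 iterations, deviance tolerance 1e-8.
5. **Test**: two-sided Wald test of the contrast coefficient. The statistic
   is referred to a t distribution on the residual degrees of freedom
   rather than a normal: with 12–27 samples and a plugged-in dispersion the
   normal reference is visibly anticonservative, and the t reference keeps
   the empirical type-I rate inside [0.03, 0.07] at nominal 0.05 (verified
   by the test suite on a 2000-transcript null).
6. **Adjustment and calls**: Benjamini–Hochberg across transcripts;
   DE ⇔ |log2FC| > 2 (strict) and adjusted p < 0.05 (strict). Both
   thresholds are read strictly because the boundary cases are explicit in
   the calling convention.

Numerical choices worth knowing about:

* Contrasts are fitted in a *canonical orientation* (alphabetically sorted
  levels) and the sign flipped afterwards, so swapping the two requested
  levels negates every log2FC exactly — including for transcripts with all
  zeros in one group, where IRLS endpoints would otherwise differ between
  parameterizations.
* For the AA-vs-BB orientation, negative log2FC means higher expression in
  ββ.
* Transcripts with zero counts everywhere get log2FC 0 and p 1.
* Adults are modelled as karyotype + sex with no interaction; sex-stratified
  contrasts (males only, females only) take the place of the interaction
  term. Larval contrasts carry population as a covariate; covariates
  constant within a subset are dropped with a message, and genuinely
  collinear designs are fatal.
* Doubling one sample's counts doubles its size factor relative to the
  others exactly; test statistics are *nearly* invariant (the common
  rescaling cancels), but exact invariance is impossible for a raw-count NB
  likelihood and is not claimed.

## Dominance classification

Per transcript, the two heterokaryotype-versus-homokaryotype relations are
computed from the unadjusted p-values (cutoff 0.05, config-exposed — the
convention "unadjusted" leaves the level open) and the sign of the
normalized group-mean difference: relation = "=" when p ≥ 0.05, else "<" or
">". The decision table over (relation to αα, relation to ββ): strictly
between = additive; below both = underdominant; above both = overdominant;
equal to ββ only = β-dominant; equal to αα only = α-dominant; equal to both
= unknown. The αα-vs-ββ contrast does not enter the table (the two
heterokaryote relations are sufficient and keep the table complete and
disjoint, which the suite checks by enumeration); it is used only for
eligibility, which is DE in at least one of the three larval contrasts. The
residual "unknown" class is our reading of the scheme; no published
enumeration of the residual cases exists.

## Localization and enrichment

A transcript is "inside" the inversion iff its interval overlaps the
inversion interval by ≥ 1 bp. Any-overlap is the conservative reading of
"within" for a 24 Mb interval versus ~1 kb transcripts (midpoint versus
any-overlap differs only for breakpoint-straddling transcripts).
`enrichment_test()` reports both the sample cross-product odds ratio
(a·d)/(b·c) and the conditional-MLE estimate from the Fisher exact test —
published odds ratios for 2×2 tables come from either convention, and on
strongly enriched tables the two differ by several percent, so both are
emitted. Breakpoint distances are gaps between transcript intervals and the
two breakpoint positions (0 when covered). KS comparisons of log2FC
distributions use the asymptotic two-sided formula; the sample sizes here
are thousands, where exact small-sample enumeration is irrelevant.
Coordinates are 0-based half-open everywhere internally, BED on disk, and
strand is carried but ignored by all distance computations.

## Allele-specific expression

SNPs enter the ASE stage only if they are fixed between arrangements
(α-allele frequency 1 in αα homokaryotes and 0 in ββ, or the reverse, in
which case the read columns are re-oriented) — the FST = 1 condition made
exact, which avoids choosing an FST estimator — with mean depth across
heterokaryote pools strictly above 5, at most 25% missing homokaryote
genotypes, and at least 3 pools with data. Read depths are averaged across
a transcript's SNPs within each pool; the α fraction is
mean(α)/(mean(α)+mean(β)).

Significance uses a pooled exact binomial test against 0.5 (per-pool mean
depths summed and rounded; rounding is applied to each allele separately so
that swapping α and β gives exactly complementary counts), BH-adjusted,
significant at adjusted p < 0.1. This is a deliberate, documented stand-in
for mixed-model ASE tests: the module boundary (`ase_test()`) is one
function, so a different test can be substituted without touching the
filters, averaging or classifier, which are the parts under study here. The
pooled binomial ignores between-pool overdispersion and will be liberal
when pools disagree; the directional classifier downstream is the guard
against inconsistent pools.

A significant transcript is α-biased when strictly more than 50% of its
pools have an α fraction strictly above 0.55, β-biased symmetrically, and
otherwise "allele-biased" (inconsistent direction). Both cutoffs are
strict: at depth 44 a read fraction can only exceed 0.55 by reaching 25
reads, so "≥55%" and ">55%" coincide there, and the strict reading is the
one consistent with the calibrated false-positive rates below.

**Calibration.** `calibrate_fp()` draws 10,000 binomial(depth, 0.5) trials
and reports the fraction strictly above the cutoff next to the exact tail:
at depth 44 the 0.55 cutoff gives 22.6% per pool and the 0.50 cutoff 44%.
`scheme_error()` composes the per-pool rate over pools as the exact
binomial tail P(K ≥ k) at the strict majority threshold (k = 4 of 6),
giving ~2.6% at a per-pool rate of 22.6%. Published scheme-level figures
derived from simulation rather than this closed form will differ — the
binomial composition is the declared, reproducible rule here, and the
calibration table reports it for any (depth, cutoff, pools) combination.

## Overlap with outlier SNPs

A transcript is "near" an outlier SNP when the gap between its interval and
a SNP on the same linkage group is strictly below 5 kb (0 if the SNP lies
inside). The null distribution of the overlap count draws, 10,000 times,
|DE| transcripts without replacement from the tested set (optionally
restricted to inversion transcripts, which isolates how much of the signal
is just inversion linkage) and counts near-flags. Reported precision is the
standard error of the null mean, sd/√iterations — on a count with a mean in
the tens, a quoted "±" of a few hundredths can only be a standard error,
not an sd. The empirical p-value uses the add-one convention
(1 + #{null ≥ observed})/(1 + iterations), standard permutation practice
that avoids exact zeros. Sampling is uniform over the (restricted) tested
set; no attempt is made to preserve per-linkage-group composition.

## PERMANOVA

`manhattan_matrix()` computes L1 distances between sample profiles of
size-factor-normalized counts (not log-transformed by default; the transform
is an argument because conventions differ and the choice is consequential).
`permanova()` implements distance-based multivariate ANOVA with sequential
(Type-I) sums of squares: Gower-center the matrix of −½d², project onto
nested design spaces, take trace increments per term. Karyotype is entered
first so that shared variance is attributed to it. R² = SS_term/SS_total;
pseudo-F uses the full-model residual mean square; p-values come from free
permutation of sample labels (no strata — the designs here have no blocking
structure). The suite verifies exact agreement of SS, R² and F with
`vegan::adonis2(by = "terms")`, equality with the classical ANOVA partition
in the Euclidean single-factor case, SS conservation to 1e-8, and
permutation-p uniformity under a shuffled null. Subgroup models follow the
design: males and females — karyotype (plus population when two populations
are present); adults — karyotype + sex; larvae — karyotype + population.

## The PCA summary

`pca_top_variance()` normalizes by size factors, applies log2(x+1), ranks
transcripts by variance on that scale, keeps the top 500 and decomposes the
transcript-centered (not scaled) matrix. Normalized-then-logged input is
the conventional reading of "top variance transcripts" for count data; raw
counts would let library size dominate the ranking. The choice is an
argument (`n_top`) plus the documented transform, and flagged here because
it is a convention, not a requirement.

## Problem sizes and determinism

The test suite and the pipeline default to 500–2000 transcripts, the sample
plan above, 300–10,000 resampling iterations and 99–999 permutations; these
sizes give the calibration checks (type-I rate, KS uniformity at ~150–200
replicates, 4-SE Monte-Carlo bounds) enough resolution while keeping a full
run in tens of seconds. Monte-Carlo uniformity checks for discrete
empirical p-values use designs with widely spread overlap counts, because a
KS test against the continuous uniform fails on lumpy p-value supports no
matter how well calibrated the statistic is. Every randomized stage takes
an explicit seed; `run_all()` derives per-stage seeds from the master seed
and stamps every output with the configuration hash, so a rerun with the
same configuration is bit-identical.

## Known limitations

* The DE engine is not a drop-in replacement for mature DE packages: no
  independent filtering, no outlier (Cook's distance) handling, no
  empirical-Bayes shrinkage of dispersions or fold changes. Low-count genes
  therefore have noisier log2FC than shrinkage-based tools would report.
* The pooled binomial ASE test treats pools as exchangeable binomial draws;
  true mixed-model tests model pool-level random effects.
* The overlap null conditions on the observed SNP positions and transcript
  map; it does not model SNP-placement uncertainty.
* PERMANOVA uses free permutations; designs needing restricted permutation
  (blocks, repeated measures) are out of scope.
* With only two αα larval pools in the default design, the αα-involving
  larval contrasts are intentionally underpowered — recovery tests use
  larger balanced designs where stated.
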