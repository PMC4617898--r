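---
title: "Daughter-design GWAS and QTL-by-environment interactions: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Daughter-design GWAS and QTL-by-environment interactions: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eggqtl)
```

This vignette is the package's account of its statistical machinery: the
models, the simulator's assumptions, the numerical choices, and the open
design decisions we had to settle. Nothing here states an empirical result
that the test-suite or `scripts/acceptance.R` does not itself compute.

## The design

A daughter design genotypes the sires and phenotypes their crossbred
daughters. Daughters are housed twelve half-sisters to a collective cage;
cages are split between a high-energy and a low-energy diet, and egg
quality is measured on eggs collected around 50 and again around 70 weeks
of age. Production traits (egg production rate over defined laying
periods) are cage-level records; quality traits (egg weight, shape, shell
colour and strength, Haugh units, yolk index, spot score) are egg-level
records. The sire's "performance" for a trait is the mean of his
daughters' adjusted records, either over everything or within one of the
four conditions (HE, LE, 50 wk, 70 wk).

## Phenotype adjustment

Per hatch, records are fitted by least squares to

* production: `Y = sire + diet + battery + column + floor + E`
* quality: `Y = sire + diet + age + battery + column + floor + operator
  + β₁W + β₂R + E`

where W is the waiting time between laying and measurement (days) and R
the hen's age (days). Environmental terms with a Type-II F-test p-value
below 0.2 are retained (sire always is), the submodel is refitted, and the
adjusted record subtracts every retained non-sire effect. Records more
than four phenotypic standard deviations from the adjusted mean are then
discarded, once, after adjustment, within hatch.

Two readings of "effects exceeding the significance level (P < 0.2)" are
possible; we retain terms with p *below* 0.2, the standard pre-adjustment
screen — the literal opposite would retain only noise terms.

**Coding.** We use sum-to-zero contrasts for all factors and mean-centred
covariates, so the subtracted environmental part is expressed as
deviations around the hatch mean and the adjusted trait keeps the raw
location; with nothing retained, adjustment reduces to centring. (With
reference-level coding the adjusted values would be shifted by an
arbitrary reference-cell constant; all downstream statistics are invariant
to that shift, so the choice is cosmetic, but sum-to-zero makes the
adjusted records directly interpretable.) Selection uses Type-II F tests —
equivalent to `drop1` since the models contain no interactions — which are
invariant to both the coding and the order of terms; the original analysis
names its GLM software but not the SS type.

## Kinship and the mixed-model scan

The additive relationship matrix A over the sires and their pedigree
ancestors is built by the recursive tabular method
(`a_ii = 1 + F_i`, `a_ij = ½(a(j, sire_i) + a(j, dam_i))`, unknown parents
contributing zero), and validated in the tests against a Monte-Carlo
gene-dropping oracle that assigns founders unique allele labels and counts
identity-by-descent directly.

Per trait and condition the null model on the sire means `z` is

```
z = 1μ + e,   V(e) = A σ²g + I σ²e
```

fitted by REML. We profile the restricted likelihood over the variance
ratio λ = σ²g/σ²e using one eigendecomposition of A: with `A = U D U'`,
rotating by `U'` diagonalises `λA + I`, so each candidate λ costs O(n) and
the eigendecomposition is shared across traits and conditions. The search
runs over log₁₀λ ∈ [−6, 6] with the boundary (σ²g = 0) checked explicitly;
components are clipped at zero and a variance-free phenotype is flagged
degenerate rather than fitted. A dense grid search over λ serves as the
oracle in the tests.

The marker scan holds the null-model variance components fixed for every
SNP (the standard single-decomposition/EMMAX-style approximation — the
alternative of refitting the variance components 284,643 times per trait
is neither stated by the original analysis nor computationally plausible)
and computes, per marker, the GLS estimate of the allele substitution
effect α with covariance `V = Aσ²g + Iσ²e`. The Wald statistic is referred
to the standard normal, the variance being treated as known. Sires missing
a call are dropped for that marker only; markers monomorphic among the
scanned sires are flagged and not tested. Dosages count minor alleles, so
α̂'s sign refers to the minor allele.

Because daughters inherit one sire allele while the sire's dosage spans
two, the regression of daughter-mean performance on sire dosage estimates
**α/2** per planted unit of α. The package reports effects on this
sire-dosage scale throughout, which is the scale any daughter design
observes; the planted-truth tests account for the factor of two.

## Significance thresholds

The chromosome-wide 1 % threshold accounts for correlated markers by
Monte-Carlo calibration: the vector of per-marker Wald statistics is, under
the null, multivariate normal with correlation equal to the correlation of
the GLS-whitened, intercept-residualised genotype columns. We draw
`n_draws` realisations (via an eigendecomposition of that correlation
matrix, robust to duplicated markers), take each draw's minimum p-value,
and use its level-quantile as the threshold. One marker, or perfectly
duplicated markers, reproduce the single-test level; independent markers
approach the Šidák bound — both are asserted in the tests. The original
analysis delegates this calibration to external parallel software whose
algorithm is not recoverable from the text; Monte-Carlo max-statistic
calibration is the standard method for the job, and a plain per-chromosome
Bonferroni fallback is available behind `method = "bonferroni"`.

Genome-wide significance is, exactly as printed, the same machinery run at
level `0.05 / n_chromosomes` — the exact quotient `0.05/32 = 0.0015625` by
default rather than the rounded 0.0015. For groups of unplaced markers the
threshold is the plain per-marker Bonferroni `0.05 / m`. With very few
chromosomes (n < 5) the genome-wide level exceeds the 1 % chromosome-wide
level; QTL calling treats genome-wide significant markers as members of
chromosome-wide runs regardless, so the calling logic is insensitive to
that ordering.

## QTL calling and interactions

Per chromosome, each maximal run of chromosome-wide significant markers
(`gap_tolerance` non-significant markers allowed inside a run; default 0)
containing at least one genome-wide significant marker becomes a QTL: CI =
[first, last] marker of the run, top SNP = maximal |α̂| ("highest estimated
effect" read as absolute value — a signed maximum would be arbitrary under
minor-allele coding), variance explained = `100·2p(1−p)α̂²/var(z)` with
var(z) computed from the sire means actually scanned. QTL whose CIs
overlap on one chromosome merge transitively into catalogue entries,
numbered deterministically by chromosome then position.

Each QTL's top SNP is re-estimated in the two diets and the two ages. The
interaction statistic is implemented literally as printed:

```
Z = |α₁ − α₂| / σ × √n
```

with σ² the mean of the two within-condition null-model residual variances
(the text says "average residual variance" without naming the model; the
null mixed model is the natural source) and n the mean sire count. This
formula omits both the √2 of a difference of two independent estimates and
the genotype-variance factor `1/√(2p(1−p))` of a regression coefficient's
sampling variance, so as a nominal-normal test it is anticonservative; the
acceptance script records its empirical null rejection rate rather than
assuming calibration, and a variance-correct Wald contrast
`|α₁ − α₂|/√(SE₁² + SE₂²)` is available behind `method = "wald"` for
calibration studies. A Fisher two-sided variance-ratio test accompanies it.
Significant interactions (at the loosest reporting level, P < 0.1, by
default) are classified as *sign inversions* when the per-condition
effects have opposite signs and *magnitude changes* otherwise — the
production-trait versus quality-trait signature.

QTL undetected by the whole-data scan but significant within a condition
are flagged *additional*; a QTL planted with α_HE = −α_LE has no marginal
effect and is only discoverable this way.

## The synthetic-data generator

`simulate_dataset()` emulates the design's statistical structure: sires in
paternal half-sib families under ungenotyped grandsire founders (A between
sires has 0.25 blocks), an unrelated dam pool (dams are not genotyped in
this design, and no dam–sire relatedness is reported; we assume none),
cages of half-sisters split evenly between diets, cage-level battery /
column / floor assignments nested in hatches, operator and the W and R
covariates for egg-level records, a polygenic term with pedigree
covariance, and planted QTL transmitted daughter-by-daughter: the sire
allele with probability dosage/2, the dam allele at the population MAF.
Genotypes are drawn at Hardy–Weinberg with uniform MAFs and no linkage
disequilibrium; marker positions are a deterministic 100-kb ladder.

What the generator deliberately does **not** model: LD between markers
(real CIs span correlated SNPs; simulated CIs are typically single
markers), 600K-scale marker density, multi-trait genetic correlations
(each trait draws its own Mendelian-sampling terms), hatch seasonality,
and selection in the parental generation. Passing tests therefore
demonstrate the pipeline's correctness and its operating characteristics
under clean half-sib structure — not the field behaviour of the thresholds
under dense LD.

Scored spot counts (0–3 scales) can be represented by thresholding a
latent Gaussian trait and analysing the score as numeric, which is how
ordinal egg traits are handled in practice.

Default study conditions (chosen once, as the conditions the analyses are
run under): 300 sires in half-sib families of 10, 12 half-sisters per
cage, σ²g = σ²e = 1 unless a scenario states otherwise, MAFs uniform on
[0.1, 0.5]. The planted-recovery analyses use 48 daughters per sire (four
cages, two per diet), σ²g = 0.3 and σ²e = 0.5 — a per-condition residual
small enough that a within-condition α/2 = 0.25 effect is comfortably
detectable at n = 300, which is what the design itself achieves with its
~30 daughters per sire per condition and repeated egg measures. Problem
sizes in the validation battery (100 GLS oracle instances, 20-individual
gene-dropping pedigrees at 10⁵ drops, 5,000-marker null scans, 20-replicate
recovery runs) are the sizes at which the Monte-Carlo error bounds quoted
in the tests are meaningful.

## Worked-example formulas

Two printed formulas are internally inconsistent with their own summary
table, and both variants ship:

* **Shape index.** `(SLE/10)/(EW/10)^(1/3)` evaluates to ≈ 2.37 at the
  table means (SLE 43.37 mm, EW 61.11 g) whose printed index is 1.1; the
  variant `SLE/(10·EW^(1/3))` gives ≈ 1.10. The table-consistent variant
  is the default (`variant = "table"`), the printed one is a flag away.
* **Shell colour.** `100 − (L* − a* − b*)` gives ≈ 75.3 at the table means
  whose printed mean is 24.78 ≈ `L* − a* − b*`. Here we default to the
  printed formula (the two are complementary, so correlations and QTL are
  identical up to sign) with the table-consistent variant behind the flag.

The Haugh unit uses the base-10 logarithm (`100·log₁₀(H − 1.7·EW^0.37 +
7.57)`), the standard definition; the source writes "log" without a base.
Egg-production-rate windows are closed weekly intervals 18–75 (EPR), 18–30
(EPR1), 31–49 (EPR2), 50–75 (EPR3); whether the boundaries are inclusive
is not stated anywhere, and closed intervals match the printed week lists.

## Numerical notes and degenerate inputs

* The Hardy–Weinberg filter uses the 1-df chi-square by default (hundreds
  of sires make the asymptotic test standard); an exact conditional test
  (`hwe_exact`) is available. Monomorphic or untyped markers test as
  p = 1 — no departure is expressible.
* Call rates and MAFs are always computed on the currently surviving set,
  and the five filters run strictly sequentially, so a marker failing
  several criteria is charged to the first step that sees it.
* Whitening uses the Cholesky factor of V; per-marker missingness falls
  back to a dense solve on the surviving subset. Correlation matrices for
  threshold calibration are eigendecomposed with negative eigenvalues
  clipped at zero (duplicated markers make them rank-deficient by
  construction).
* The Monte-Carlo threshold requires `n_draws ≥ 1/level`; the level
  quantile of the min-p sample uses the order statistic (type-1 quantile).
* Gene-dropping standard errors are per-entry binomial SEs; when the test
  compares 210 matrix entries simultaneously, the acceptance bound is
  multiplicity-aware (essentially all entries within 3 SE, none beyond 5)
  rather than a naive simultaneous 3-SE box, which a correct implementation
  would fail about a quarter of the time.
* All randomness flows from explicit seeds; `split_seed` derives
  independent sub-seeds so stages compose deterministically, and re-running
  a pipeline configuration reproduces every output byte-for-byte.

## Known limitations

* No dominance or epistasis models; variance-explained sums over QTL can
  exceed 100 % only through correlated markers, which the LD-free
  simulator does not produce.
* No genomic relationship matrix — kinship is pedigree-based by design.
* No score tests or small-sample corrections in the scan; Z-chromosome
  markers are treated as ordinary dosages (sires are the homogametic sex).
* The literal interaction Z statistic is reported as printed; its nominal
  p-values should be read as a ranking device, with the Wald variant
  available when calibration matters.
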