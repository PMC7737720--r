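---
title: "Haplotype-block GWAS for multi-environment yield trials: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Haplotype-block GWAS: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haplogwas)
```

# Scope

`haplogwas` implements a haplotype-based association workflow for panels of
advanced inbred lines phenotyped in replicated, multi-environment yield
trials: marker and line filtering, linkage-disequilibrium (LD) based
haplotype-block construction, multiallelic mixed-model association,
stability classification across trial cohorts and testing environments,
two- and three-locus epistasis scans, and favorable-haplotype stacking
summaries. A forward-in-time simulator generates genotypes and trial
phenotypes with the statistical structure the analysis assumes, so the whole
pipeline is testable without external data.

This vignette records the models, the defaults and their rationale, the
numerical choices, and the design decisions that were genuinely open.

# Input model and filtering

Genotypes are biallelic SNP calls on near-homozygous inbred lines, coded 0
(major homozygote), 2 (minor homozygote), 1 (residual heterozygote), with
missing calls left missing — genotyping-by-sequencing (GBS) data are sparse
and the workflow performs **no imputation** anywhere. Defaults follow common
GBS practice for elite wheat panels: markers are removed above 30% missing
calls or below a minor allele frequency (MAF) of 0.15 (the high MAF floor
keeps every single-cohort subset above the usual 0.05), then lines above 60%
missing calls are culled, in that order. MAF uses the allele-frequency
convention with heterozygotes contributing one minor allele. Whether MAF is
computed before or after line culling is ambiguous in practice; we compute it
before (markers first, lines second), which matches the published filtering
counts' ordering, and the two filters are exposed separately so the other
order is available.

Heterozygous calls are a design decision in three places: they count as half
a minor-allele dose for MAF, they are excluded (treated as missing) when
two-locus haplotype frequencies and block alleles are read off the inbred
genotypes, and they are mean-imputed only inside the kinship/PC computation.
Rationale: in advanced inbred material heterozygotes are rare (< a few
percent) and mostly artifacts, so phasing machinery (EM) would add cost and
assumptions without information.

# Pairwise LD and the D' confidence interval

For markers $i, j$, two-locus haplotype frequencies are read directly from
lines homozygous at both loci. With $D = p_{AB} - p_A p_B$,

* $D' = |D| / D_{\max}$, where $D_{\max} = \min(p_A p_b,\, p_a p_B)$ for
  $D > 0$ and $\min(p_A p_B,\, p_a p_b)$ otherwise;
* $r^2 = D^2 / (p_A p_a p_B p_b)$.

The 95% confidence interval of $|D'|$ is the one-sided 5%/95% cumulative
bound of the multinomial likelihood evaluated on a $|D'|$ grid of step 0.001
with allele frequencies fixed at their MLEs and $D$ taking its observed sign
(the Haploview convention). A pair is **strong LD** when the CI lower bound
is at least 0.6 and the upper bound at least 0.95; **strong recombination**
when the upper bound falls below 0.90 (the classic Gabriel-method default for
that bound); otherwise **inconclusive**. The grid step is a numerical choice: tests verify the
0.001-step CI sits within ±0.002 of a 10-fold finer grid.

LD decay is a degree-2 LOESS (span 0.5 by default) of $r^2$ against physical
distance over pooled intrachromosomal pairs, evaluated on 512 log-spaced
distances; the decay distance is the first baseline crossing ($r^2 = 0.1$),
linearly interpolated, and reported as undefined when the fitted curve never
crosses.

# Haplotype blocks

Blocks follow the confidence-interval (Gabriel-style) definition. A
contiguous interval $[a, b]$ qualifies when (i) the outermost pair is strong
LD and (ii) at least 95% of the informative comparisons inside it are strong
LD, where informative means strong LD or strong recombination — inconclusive
pairs are excluded from the denominator (a flag switches to all pairs).
Qualifying intervals are accepted greedily: most SNPs first, then widest
span, then leftmost start, discarding candidates that share a marker with an
accepted block. The greedy order is deterministic, and the whole procedure is
verified against exhaustive enumeration on random small instances. Numerical
guards: a candidate needs at least one informative comparison (so 2-SNP
blocks are allowed); a pair needs at least 4 informative lines; candidates
are bounded at a 10 Mb span (observed block spans are two to three orders of
magnitude smaller; the bound only caps compute).

Each block becomes one multiallelic marker: a line's allele is the
concatenation of its homozygous calls over the member SNPs; any missing or
heterozygous member call makes the whole call missing; alleles under 5%
frequency (among called lines) are recoded missing. Blocks are named
`HB<chrom>.<ordinal>` by start position within the chromosome.

# Mixed-model association

Per trial cohort and testing environment, adjusted entry means are tested
block by block under

$$ y = \mu + \text{PCs} + (\text{optional DH, PH}) + \text{allele dummies} + u + e, \quad u \sim N(0, \sigma^2_g K), \; e \sim N(0, \sigma^2_e I) $$

with $K$ the VanRaden (method 1) genomic relationship matrix,
$K = ZZ^\top / 2\sum_k p_k(1-p_k)$ on doses centered by $2p_k$. The number of
principal components (0–10) is chosen by BIC on fixed-effect-only
regressions, ties to fewer. Variance components are estimated **once per
trait × trial × environment** on the no-marker null model — the standard
EMMAX-style approximation — by REML, profiling
$\delta = \sigma^2_e/\sigma^2_g$ on a 64-point log grid refined by golden
search after one spectral decomposition of $K$. Each block is then tested
with a generalized-least-squares F-test on its $k-1$ allele dummies
(reference = most frequent allele) under the fitted covariance; lines missing
the block call are dropped per block (Cholesky on the corresponding submatrix
of the fitted $V$), and allele classes under 10 lines are merged into
missing. When $\sigma^2_g = 0$ the test reduces exactly to the OLS F-test
(asserted to 1e-10 in the tests). The joint F-test treats the block
multiallelically; per-allele effects are descriptive: the favorable allele is
the one with the highest mean, its effect the with/without mean difference in
trait units. A second allele is also reported favorable when its mean exceeds
the without-group mean by more than the standard error of that allele's mean
— an operational rule for the occasional two-favorable-allele block, since no
published rule exists.

# Stability and epistasis

A block is **environment-specific stable** when one cohort gives
$P < 10^{-4}$ and at least three cohorts (the strong one included) give
$P < 10^{-3}$ in that environment; **multi-environment stable** when
$P < 10^{-3}$ hits span at least two environments and two cohorts jointly
(the stricter per-environment reading is a flag). No multiplicity correction
is applied beyond these fixed thresholds, deliberately. Dual labeling is
allowed. Under a complete null with 519 blocks, 7 cohorts and 4 environments,
the expected number of false multi-environment-stable blocks is about 0.13
per dataset — the rule's own combinatorics — which the tests check as an
expected count below one.

Epistasis is scanned by plain linear regression on the same adjusted means
(no kinship residualization by default, matching the original analysis; an
option exists). For a pair, the main-effects model (both blocks' allele
dummies) is compared with the full model adding all interaction cells; the
reported P is the F-test of the interaction group and the reported
"percentage variation" is the incremental (partial)
$R^2 = (RSS_{main} - RSS_{full})/TSS$, on the percentage scale. Interaction
cells under 5 lines are pooled into one level; fully aliased interactions are
skipped. Three-locus scans test the three-way cells beyond all two-way terms
and run only on candidate triples (blocks marginally associated at
$P < 0.01$ or members of a significant pair) — exhaustive three-way scans are
out of scope by design. The significance threshold is $P < 10^{-4}$.
Note that a "pure" interaction indicator is partially collinear with its
margins, so even a perfect interaction has partial $R^2$ well below 1; the
tests assert the decomposition identity rather than a nominal 100%.

# Phenotype adjustment, ANOVA and heritability

Grain yield is adjusted per trial × environment (× experiment) with
replicate fixed, entry fixed, and incomplete block within replicate random
(BLUP shrinkage, via lme4); adjusted entry means are the per-entry means of
the block- and replicate-corrected plot values, so they stay in kg/ha.
Developmental traits (days to heading, plant height) use the check-based
formula $Y = (Y_{ij} - Y_i) + Y_{all}$ with the trial check mean and the
grand check mean; it preserves within-trial ranking by construction.

The genotype × environment ANOVA uses expected mean squares on balanced data
(computed directly from cell means, which is exact and linear in the data
size) with entries random: $\sigma^2_{err} = MS_{err}$,
$\sigma^2_{g\times e} = (MS_{g\times e} - MS_{err})/r$,
$\sigma^2_g = (MS_g - MS_{g\times e})/(er)$, clamped at zero; genotype and
environment are tested against the interaction mean square. Unbalanced
tables switch to an lme4 REML fit (logged), where the genotype P comes from a
boundary-corrected likelihood-ratio test and is therefore approximate — the
exact-uniformity guarantees in the tests apply to the balanced path.
Broad-sense heritability is on the entry-mean basis,
$H^2 = \sigma^2_g / (\sigma^2_g + \sigma^2_{g\times e}/e + \sigma^2_{err}/(er))$,
chosen because trial-level $H^2$ is conventionally reported without a
formula; with one environment the interaction term vanishes. Whether $H^2$
is computed per environment or across environments is exposed simply by what
is passed in; the simulator's target is defined per environment.

# The simulator: what it emulates, and what it does not

`simulation_spec()` defaults define the study conditions: 1,000 inbred lines
from a narrow elite pool of 16 founders, 8 generations of random crossing
with Poisson crossovers (1.5 per chromosome per meiosis), 6 selfing
generations (residual heterozygosity $\approx 2^{-6}$), 2,000 markers on
three 100 Mb chromosomes, 15% missing calls, 7 trial cohorts phenotyped in 4
environments (I, MD, SD, HS) with environment means spanning roughly
2,500–6,000 kg/ha, per-environment genetic-effect scaling, incomplete blocks
of 6 plots with SD 150 kg/ha, 3 replicates, and a per-environment entry-mean
heritability target of 0.5 (residual plot variance is solved from the
realized genetic variance). Founders descend from a handful of ancestral
haplotypes (4 by default) with 20% per-site divergence, over a uniform
ancestral MAF spectrum: the few local haplotypes give the high short-range
r² characteristic of elite germplasm, recombination over the crossing
generations erodes it with distance (the LOESS decay distance lands in the
2–3 Mb range under the defaults), and drift in a crossing pool of 200 sets a
flat long-range LD floor. QTL are planted as carrier (minor-homozygote)
effects in kg/ha, epistatic terms as products of carrier indicators, and a
polygenic value is drawn from $N(0, \sigma^2_{poly} K)$.

What the simulator does **not** emulate: pedigree-accurate crossing schemes
and selection (lines are unselected), ascertainment bias of real GBS markers,
genotyping error beyond a uniform artifact-heterozygote rate, spatial field
trends within trials, and shared checks across years. Passing tests
therefore show the estimators are correct under the assumed model — block LD,
additive-plus-epistatic architecture, alpha-lattice-like noise — not that the
pipeline is robust to structured genotyping artifacts or field spatial
autocorrelation.

One global seed expands into fixed per-stage substreams (genotypes,
phenotypes, fixtures), so adding a stage never perturbs earlier draws, and
everything is reproducible from the seed alone.

# Problem sizes and numerical conventions

The test suite runs its calibration checks at the sizes where their stated
bands are valid: effect recovery and epistasis recovery at n = 1,000 lines
with 100 replicates; mixed-model calibration under a two-subpopulation null
at n = 500 with 519 two-SNP blocks; block-finder/oracle equivalence on 1,000
random instances of up to 8 SNPs; heritability calibration at 1,000 entries
(the ±0.05 band is a sampling statement — at 300 entries the estimator's SD
is itself ~0.05). The acceptance script simulates 7 cohorts × 450 lines with
1,500 markers, plants six additive block QTL (350–450 kg/ha at carrier
frequencies 0.25–0.45) and one strong epistatic pair, and runs the full
pipeline end to end.

Other conventions: ties in the greedy block selection and in allele
cataloguing break deterministically (frequency, then lexicographic);
monomorphic pairs are flagged undefined rather than classified; variance
components are clamped at zero; the fitted mixed-model covariance receives a
relative diagonal jitter of 1e-8 before Cholesky; percentage GY increase in
stacking is taken between the lowest and highest populated count classes and
is undefined with fewer than three classes.

# Known limitations

* The EMMAX-style single variance fit per phenotype slightly deflates very
  large block effects' significance compared with per-marker REML; at
  yield-trial effect sizes the difference is negligible and the test suite's
  calibration bounds cover it.
* The REML path of the G×E ANOVA gives approximate genotype P-values
  (boundary LRT).
* Favorable-allele effects are raw mean differences, not model-based
  contrasts; they inherit winner's-curse bias when filtered by significance.
* Interchromosomal LD, EM-based phasing for heterozygous material, and
  genomic prediction are out of scope.
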