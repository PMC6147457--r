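---
title: "Methods: digenic mapping in a breeding colony"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: digenic mapping in a breeding colony}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(digenicmap)
```

`digenicmap` implements the statistical machinery of a digenic
genetic-mapping study in a closed breeding colony: a kinship-aware
mixed-model association scan, confidence-interval linkage-disequilibrium
(LD) block construction, per-group allele-frequency mapping, two-locus
epistasis testing, digenic penetrance modelling, case-control power, and a
singular-value-decomposition (SVD) filter for expression data. A seeded
colony generator supplies data with exactly the structure these methods
assume, so every stage can be exercised and tested without external data.

This vignette records the models, the tunable parameters, and the design
choices that were genuinely open.

## Mixed-model association

The phenotype is a 0/1 affection indicator treated as a quantitative trait
(the EMMAX convention), modelled as

$$y = X\beta + u + e,\qquad u \sim N(0,\ \sigma_g^2 K),\quad
  e \sim N(0,\ \sigma_e^2 I),$$

with $K$ the identity-by-state (IBS) kinship matrix:
$K_{ij}$ is the mean over co-called variants of $1 - |g_i - g_j|/2$.
Restricted maximum likelihood is profiled over
$\delta = \sigma_e^2/\sigma_g^2$ on the spectral decomposition of the
projected kinship matrix: a 100-point log-spaced grid on
$[10^{-5}, 10^{5}]$ followed by a bracketed 1-D optimizer, with a $10^{-8}$
diagonal jitter before decomposition. When the restricted likelihood is
flat in $\delta$ (e.g. $K = I$) the fit is flagged non-identifiable and
$\delta = 1$ is reported. The null-model components are then reused for
every SNP (the EMMAX approximation) and each SNP is tested by generalized
least squares on the rotated data; an exact per-SNP refit mode exists for
oracle checks. The Wald $t$-test is the default (it reduces exactly to the
ordinary-least-squares $p$-value when $K = I$); a score test is available
because the test statistic inside commercial implementations is rarely
documented. Genome-wide significance is flagged at $p \le 5\times10^{-8}$.

Companion statistics mirror a published association table: BH false
discovery rate, variance explained (squared phenotype-dosage correlation —
the "VAR" convention is never defined in print, so ours is explicit),
cohort minor-allele frequency, the Pearson chi-square on the 2×2
allele-count table, and a carrier relative risk
(carriers of ≥1 minor allele vs non-carriers, Haldane–Anscombe 0.5
correction on zero cells). Missing dosages are mean-imputed within the scan
cohort for the regression only; QC and filters see raw calls.

Variant exclusion follows the study rules: missingness strictly greater
than 10% of the cohort, or minor allele frequency of zero. Hardy–Weinberg
equilibrium is tested with the exact conditional test (sum of genotype
configurations no more probable than the observed one); it is reported,
never used as a filter, since the published analysis retained
HWE-significant SNPs inside its mapped block.

## LD blocks

Two-locus haplotype frequencies are estimated by the standard EM algorithm
for unphased genotypes (uniform start, relative log-likelihood tolerance
$10^{-10}$); only the double heterozygote is phase-ambiguous. With allele
frequencies held at their estimates, the likelihood is profiled over
$|D'|$ on a 101-point grid in $[0,1]$; the 5th and 95th percentiles of the
normalized cumulative likelihood give the confidence interval, and
$\mathrm{LOD} = \log_{10} L(\hat D)/L(0)$. Pairs are classified with the
study thresholds: strong LD when the upper bound reaches 0.95 and the
lower bound 0.55; strong recombination when the upper bound stays below
0.90 (the conventional default, which the study does not override — we read
its "upper CI = 0.95" as a threshold on the upper bound, not a
redefinition of the CI level). A candidate interval is a block when its
endpoint pair is in strong LD and ≥85% of its informative pairs are;
maximal blocks are chosen largest-span first, ties leftmost. Spans are
reported as `end − start` in bp on 1-based coordinates, which reproduces
printed arithmetic such as 6,641,309 − 6,388,292 = 253,017 bp ≈ 253 kb.

Tag SNPs are selected greedily so that every block member reaches
$r^2 \ge 0.8$ with some tag. Group MAF mapping fixes each SNP's minor
allele in the pooled cohort (so group values are comparable), then runs a
one-way ANOVA across diagnosis groups with the block's SNPs as replicates
and Tukey HSD on the group means.

## Epistasis and digenic penetrance

Logistic regression is fitted by damped IRLS to a gradient norm below
$10^{-8}$, with rank-deficiency errors naming collinear columns and
separation detection. The epistasis test compares `y ~ g1 + g2` against
the model adding the product term `g1 × g2` (additive 0/1/2 coding, 1 df;
a genotype-factor mode exists because published analyses rarely state the
coding) by the likelihood ratio. One published table's "LL" column cannot
be reconciled with its chi-squares, so we report `ll_null`, `ll_full` and
the difference explicitly and do not attempt to reproduce that column.

A near-deterministic digenic trait creates a specific pathology in small
samples: the *null* model can separate the data completely, collapsing the
maximum-likelihood LRT to zero. Firth's bias-reduced logistic regression
(Jeffreys-prior score correction) keeps the penalized likelihoods finite
and the test informative; the pipeline uses `method = "firth"` for its
colony-scale epistasis stage, while plain maximum likelihood remains the
default contract of `epistasis_lrt()`. Pipeline epistasis pairs cross the
top occurrence hits with the top onset hits on different chromosomes, and
the stage runs on the whole colony (candidate loci are known, so every
animal is informative), mirroring the retrospective candidate-pair testing
of a colony study.

Penetrance is estimated cell-wise on the 3×3 dosage grid, with
`rule_concordance` the fraction of animals whose phenotype matches the
deterministic rule "affected iff ≥1 variant allele at each locus". Growth
is analyzed by a two-way fixed-effects ANOVA (group, interval,
group×interval) with Tukey–Kramer post hoc tests. The radiographic
classifier follows the colony criteria literally: fused at day 10 → EOS;
day-10→25 growth below the lower bound of the 95% confidence interval of
the *mean* of the unaffected reference cohort → DOS; otherwise ICN. Note
that a CI of the mean is a strict criterion — with a large reference
cohort its lower bound approaches the reference mean, and near-average
animals can fall below it; the generator therefore assigns diagnoses from
the planted rule, and the classifier is exposed as its own operation.

## Case-control power

The disease locus has risk-allele frequency $p$, genotype relative risks
$(1, r_1, r_2)$ and baseline penetrance solved from the population
prevalence. A single published "relative risk" is read as the heterozygote
risk with the homozygote filled in multiplicatively ($r_2 = r_1^2$);
additive and dominant modes are available. Prevalence defaults to 0.10
(the conventional calculator default — the study states none), controls to
a 1:1 ratio, and the marker allele frequency to the risk-allele frequency.
The marker is linked through $D' $: haplotype frequencies follow from
$D = D' D_{max}$, random union of gametes gives marker genotypes jointly
with disease genotypes, and Bayes inversion through the penetrances gives
expected case and control (unaffected) marker-genotype frequencies. The
noncentrality parameter is the Pearson chi-square contrast between the
expected case and control genotype counts, and power is the upper tail of
the noncentral $\chi^2_{df}$ at the $\alpha$ critical value.

At the study's design (24 cases, $p$ = marker MAF = 0.5, $r_1 = 5$,
$D' = 0.85$, $\alpha = 0.05$, 2 df) the analytic power is 0.7929 —
the figure a power statement of "80%" rounds. The asymptotic NCP
approximation is conservative here (expected cell counts as low as ~1):
the package's Monte-Carlo mode, which applies the actual Pearson test to
simulated studies, puts the exact power of the same design near 0.83. Both
are computed by the acceptance checks; neither is hard-coded.

## Expression filter (GIC)

For each probe-set the Gene Information Content is
$\sigma_1^2 / \sum_i \sigma_i^2$ from the SVD of the row-centered
probes×samples submatrix. Probes are row-centered because the score should
reflect co-variation across samples rather than baseline intensity
offsets; an uncentered mode exists since the choice changes the score. The
cutoff permutes the probe→probe-set map (preserving the multiset of set
sizes exactly), recomputes all permuted scores, and takes the 99th
percentile of the pooled null (1000 permutations by default, seeded).
Gene-level summaries for the downstream ANOVA (with Tukey–Kramer post
hocs) and per-group gene-pair regressions default to the mean of the
gene's probes; first-right-singular-vector scores are the alternative.
GIC filtering is applied before the group comparisons by default — the
published order of operations is not stated.

## The synthetic colony

The generator is the package's definition of the study conditions, not a
tuning dial. Founders draw per-block haplotypes from pools of 3 (at most 3
of the 4 two-locus haplotype combinations can occur, so within-block
$|D'| = 1$ by construction, and blocks separate cleanly); blocks span 250
kb with markers every ~23 kb and large inter-block gaps. Founder
haplotypes are allocated to pool haplotypes by largest-remainder
proportional rounding rather than i.i.d. draws: a managed colony is
founded with a known carrier composition, and this keeps realized allele
frequencies at their nominal values instead of superimposing founder-
sampling drift on the breeding drift. Defaults: 24 founders, 3
generations of random pairing with Poisson(4) litters, capped at 104
animals; Mendelian gene-dropping transmits one parental haplotype per
block (free recombination between blocks, none within).

The planted architecture follows the digenic rule: affected iff ≥1
variant allele at both the occurrence locus (founder frequency 0.45) and
the onset modifier (0.65) — frequencies chosen from the printed group
frequency profiles of the emulated study; among affected animals, onset
is early (EOS) for modifier homozygotes, else delayed (DOS). Penetrance
and onset noise default to 0.01: the emulated study's candidate-pair
chi-square of ~97 with a saturating full model implies an essentially
rule-perfect colony, and 0.01 keeps that character while still producing
occasional rule-breakers. Growth gives unaffected animals ~2.5 mm
(day 10→25) and ~2.0 mm (day 25→42) of marker-separation increase
(SD 0.25 mm); affected animals grow at a uniform 70–75% of normal; EOS
animals are fused at day 10 and carry no growth signal.

The expression generator makes probe-sets as rank-1 signal (per-sample
scores × per-probe loadings) plus i.i.d. Gaussian noise, with group sizes
50/50/49/100 and one designated gene pair given a negative score
correlation (−0.5) in the coronal group only.

What the generator does *not* emulate: recombination within blocks,
mutation, genotyping error beyond uniform missingness, X-linked loci,
ascertainment of the sequenced cohort beyond diagnosis counts, and
batch or array effects in expression. Passing tests therefore demonstrate
correctness of the estimators under the planted structure, not robustness
to every artifact of real colony data.

## Problem sizes and numerical choices

The test suite runs the recovery study at 50 seeded colonies of 104
animals × 5,000 markers — the scale of the emulated design — and verifies:
top occurrence hit inside the planted occurrence block, top onset hit
inside the planted modifier block, the top epistatic pair matching the
planted pair, and rule concordance ≥0.95, each in ≥90% of replicates.
Calibration checks use 100 phenotype permutations for the scan, ≥120
null replicates for the interaction test, and pooled null GIC rates over
six seeded studies. Oracle tests pin the REML optimum against a
1,000-point grid, the EM likelihood against a 201-point grid, the D'
confidence bounds against direct likelihood integration ($10^{-12}$),
Gabriel blocks against exhaustive interval search, the exact HWE test
against full enumeration, logistic fits against an independent fitter
($10^{-6}$), and GIC against an eigen-decomposition oracle ($10^{-10}$).

Tie-breaks and degenerate inputs are handled explicitly: block selection
prefers the leftmost of equal spans; monomorphic loci make an LD pair
uninformative rather than erroring; a monomorphic SNP reaching the scan is
a filter-contract violation and errors; zero-variance probe-sets are
flagged rather than scored; and the likelihood-flat $\delta$ ridge under
$K = I$ is reported as non-identifiable.
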