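---
title: "Mapping parent-of-origin QTL with the orthogonal a/d/i model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping parent-of-origin QTL with the orthogonal a/d/i model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poeqtl)
```

## The problem

Genomic imprinting makes the two reciprocal heterozygotes of a two-allele
system — `AB` and `BA`, written as (paternal allele, maternal allele) —
phenotypically different even though they are genetically identical.
Detecting such parent-of-origin effects in a cross of two inbred lines
requires three things an ordinary QTL scan does not provide: *ordered*
genotypes that record which allele came from which parent, a genotypic
model in which the imprinting contrast is separable from additive and
dominance effects, and a follow-up test that rules out the main
non-epigenetic explanation, a maternal genetic effect. `poeqtl`
implements that pipeline for multigeneration intercrosses of the
F0 → F3 kind: two inbred founder pairs crossed reciprocally, an F2
generation from reciprocal F1 pairs, and a large F3 from randomly mated
F2 couples.

## The orthogonal genotypic model

Each ordered genotype at a marker is assigned three index scores:

| class | $x_a$ | $x_d$ | $x_i$ |
|-------|------:|------:|------:|
| AA    |  1    | 0     | 0     |
| AB    |  0    | 1     | 1     |
| BA    |  0    | 1     | -1    |
| BB    | -1    | 0     | 0     |

Solving the resulting design for the four class means gives the
genotypic values: the reference point $r$ (the homozygote midpoint), the
additive value $a$ (half the homozygote difference), the dominance value
$d$ (heterozygote mean minus homozygote midpoint), and the imprinting
value $i$ (half the difference between reciprocal heterozygotes). The
inversion is exact and its own inverse — `genotypic_values_from_means()`
and `class_means_from_values()` round-trip any four means — and under
balanced class counts the three index columns are mutually orthogonal,
so the variance explained by each effect can be computed separately and
summed: $R^2_a = \tfrac{1}{2}a^2/V_p$, $R^2_d = \tfrac{1}{4}d^2/V_p$,
$R^2_i = \tfrac{1}{2}i^2/V_p$ (each times 100 for percent).

The sign conventions identify expression patterns. Pure paternal
expression (the phenotype tracks the paternally inherited allele) forces
$i = a$, $d = 0$; pure maternal expression forces $i = -a$, $d = 0$; and
a significant $i$ with *no* additive effect is the bipolar pattern, in
which the heterozygotes differ from each other while the homozygotes do
not. `classify_pattern()` applies exactly this logic. Because estimates
are never exactly on the theoretical ray, parental-expression calls use
a ratio tolerance: $|i/a|$ must lie within $[1/\rho, \rho]$ with
$\rho = 2$ by default. The effect-presence flags default to a pointwise
LOD of 1.3 per effect; both knobs are arguments.

## The scan

`genome_scan()` fits, at every marker and for every trait,

$$ y = r + a\,x_a + d\,x_d + i\,x_i + u_{\mathrm{family}} + \varepsilon,
   \qquad u \sim N(0, \sigma_f^2),\ \varepsilon \sim N(0, \sigma_e^2), $$

where family is the sire–dam pair (the F1 pair for F2 animals, the F2
pair for F3 animals; both generations are scanned jointly by default).
Phenotypes are pre-adjusted for sex and direction of cross
(`adjust_phenotypes()` residualises on the indicators and re-centres at
the grand mean, keeping trait units so the effect estimates remain
interpretable).

Two likelihood conventions coexist deliberately. Variance components
and effect standard errors are reported from the REML fit. The four LOD
scores, however, are log10 likelihood ratios between models with
*different fixed effects* — `mLOD` drops all three scores, `aLOD`,
`dLOD`, `iLOD` drop one each — and REML likelihoods are not comparable
across fixed-effect structures, so the ratios are computed under ML.
Both choices are recorded in the scan metadata.

The fitter itself profiles the likelihood over the variance ratio
$\lambda = \sigma_f^2/\sigma_e^2$: for a single random intercept the
marginal covariance is block diagonal and
$(I + \lambda J)^{-1/2} = I - c/n_j\,J$ with
$c = 1 - (1 + n_j\lambda)^{-1/2}$, so each candidate $\lambda$ costs one
ordinary least-squares fit on family-shrunken data and the optimisation
is one-dimensional. This is what makes permutation thresholds
affordable; the test suite verifies the fitter against lme4 to six
decimals in the log-likelihood on both ML and REML paths, and verifies
that with a single family (variance ratio pinned at zero) every LOD
equals the brute-force OLS likelihood-ratio LOD to $10^{-6}$.

Numerical conventions: LODs that come out negative by numerical noise
are clamped to zero; markers where any ordered class has fewer than
`min_class_n = 5` individuals are skipped with a status flag rather
than fitted; individuals missing the marker genotype are dropped for
that marker only; a constant phenotype short-circuits to all-zero LODs.

## Significance, calling, naming

Genome-wide thresholds come from permutations
(`permutation_thresholds()`): the (phenotype, family) rows are shuffled
as a unit against the genotype rows — preserving the trait's family
variance structure under the null while destroying genotype–phenotype
association — the scan is re-run, and the genome-wide maximum of each
statistic per trait is collected; the threshold is the
$\lceil(1-\alpha)\,n_{\mathrm{perm}}\rceil$-th order statistic of those
maxima. The study-scale default is 1000 permutations at
$\alpha = 0.05$; a permutation count below $1/\alpha$ is refused
because the quantile would be meaningless.

`call_qtl()` marks every (trait, marker) whose statistic reaches its
genome-wide threshold, merges marked markers on a chromosome within a
20 cM window into one locus (the window is configurable; reported
crosses of this design show one peak per region), takes as peak the
marker with the largest significant statistic (ties to the smaller cM),
and attaches to the locus every further trait whose pointwise LOD
reaches 1.3 at the peak — the pleiotropy rule. Support intervals are
1-LOD drops by default: the widest contiguous marker span around the
peak whose statistic stays within `drop` of the peak value. Loci are
named `Mc<chromosome>.<k>` in position order within a chromosome.

## Imprinting versus maternal genetic effects

A dam's genotype can shape her offspring's phenotype through the
environment she provides. That maternal genetic effect mimics an
imprinting pattern: among offspring of *homozygous* dams, the `AB` and
`BA` classes necessarily have dams of opposite homozygous genotype, so
a dam-genotype effect masquerades as a reciprocal-heterozygote
difference. Among offspring of *heterozygous* dams the two classes
share the same maternal genotype, so a true imprinting contrast — which
rides on the offspring's own alleles — persists while a maternal effect
vanishes. `maternal_vs_imprinting()` therefore augments the locus model
with a mother-class term (homozygous vs heterozygous dam, the dam's
unordered genotype) and the $x_i \times$ mother-class interaction, and
likelihood-ratio-tests the interaction (ML, 1 df). A significant
interaction returns the verdict `maternal_effect`; otherwise
`imprinting`. If either mother class has fewer than `min_n = 5`
informative (heterozygous) offspring the verdict is `inconclusive`
rather than a fragile test.

## The simulator

`simulate_pedigree()`, `simulate_genotypes()` and
`simulate_phenotypes()` generate data with exactly the statistical
structure the analysis assumes. Defaults reproduce the design of the
motivating cross: two reciprocal founder pairs, F1 litters of four,
two reciprocal F1 pairs producing 94 F2, and 345 F3 in litters of
about seven from random non-sibling F2 pairs, of which 331 are flagged
analyzable (attrition by genotyping failure is emulated as a random,
seed-controlled subset of 14). The default map places 164 markers on
19 autosomes at 5 cM spacing with nominal Mb = 2 cM; X and Y are
excluded because the imprinting contrast is not defined for them in
this design. Gametes recombine under the Haldane map function
(crossover probability $(1 - e^{-2d/100})/2$ per interval,
no interference) — the simplest standard choice, adopted because
nothing in the analysis depends on interference.

Phenotypes follow the generative inverse of the scan model: grand mean,
sex and cross-direction covariates, per-QTL $a\,x_a + d\,x_d + i\,x_i$
at the nearest marker, a family intercept shared by full sibs, an
optional maternal effect that is *additive in the dam's B-allele count*
at a locus (one simple form that is confoundable with imprinting, which
is precisely what the discrimination test needs to be exercised
against), and Gaussian residuals. The default eight-trait architecture
mirrors the qualitative layout of a hyper-muscular mouse intercross — a
pleiotropic additive chromosome-1 locus on the mass traits, an
imprinted chromosome-12 body-weight locus, a bipolar chromosome-19
locus on the glycolytic traits, a chromosome-15 dominance locus — with
magnitudes chosen once as biologically plausible for such mice. The
simulator does **not** emulate founder haplotype blocks, linkage
disequilibrium with ungenotyped variation, litter-size or parity
effects, or genotyping error beyond whole-animal attrition; passing
tests therefore demonstrate correctness of the statistical machinery
under the model's own assumptions, not robustness to real-data
artefacts.

## Phasing, and a fundamental ambiguity

`phase_by_transmission()` recovers ordered genotypes from unordered
calls plus the pedigree. Homozygotes order trivially; a heterozygote
with a homozygous parent is forced by that parent's contribution. These
two rules are exactly sound — on simulated data every entry they
resolve equals the simulator's truth — and recover most of the F3
(~88% of entries) because F2 parents are frequently homozygous.

The remaining case, a heterozygote whose parents are both heterozygous,
is where a flanking-marker heuristic (`use_flanking = TRUE`) attempts a
minimum-recombination assignment by tracing which parental haplotype
carried the child's allele at the nearest already-phased informative
anchors. In a three-generation design this turns out to be a tie by
construction: the nearby anchors are the child's own homozygous
markers, and "one crossover in the paternal gamete" versus "one in the
maternal gamete" are indistinguishable there. The ordering of F2
heterozygous blocks is thus fundamentally ambiguous from local
information (breaking it requires whole-pedigree minimum-recombinant
haplotyping, which is out of scope here), and the flanking pass
consequently raises the resolved fraction only where a parent's own
heterozygous phase is known — never in the default design. Unresolved
entries stay missing rather than imputed; the scan drops them per
marker.

## Problem sizes used by the tests and the acceptance script

Statistical properties are verified at deliberately reduced scale so
the whole suite runs in minutes: parameter recovery uses 200 replicates
of the 331-animal F3 cohort at a single locus ($a$ = 0.5, $d$ = 0.25,
$i$ = 0.4, $\sigma_f$ = 0.5, $\sigma_e$ = 1), permutation calibration
uses a 20-marker map with 200 permutations against 200 fresh null
scans, and the imprinting/maternal discrimination uses 200 replicates
per scenario. The acceptance script runs the full 164-marker scan on
two traits with 100 permutations. These sizes are the package's own
verification choices; the user-facing defaults remain the study-scale
ones (1000 permutations, full map).

## Worked example

```{r, eval = FALSE}
library(poeqtl)

ped   <- simulate_pedigree(seed = 1)
map   <- default_genetic_map()
geno  <- simulate_genotypes(ped, map, seed = 2)
pheno <- simulate_phenotypes(ped, geno, map, default_trait_specs(),
                             seed = 3)
adj   <- adjust_phenotypes(pheno)

scan  <- genome_scan(adj, geno, map,
                     traits = "Glycolytic potential")
thr   <- permutation_thresholds(adj, geno, map,
                                traits = "Glycolytic potential",
                                n_perm = 1000, seed = 4)
calls <- call_qtl(scan, thr)
calls$loci

## classify the pattern and test for a maternal genetic effect
peak <- scan[which.max(scan$iLOD), ]
classify_pattern(list(a = peak$a, d = peak$d, i = peak$i),
                 a_significant = peak$aLOD >= 1.3,
                 d_significant = peak$dLOD >= 1.3,
                 i_significant = TRUE)
```

## Known limitations

* Interval mapping between markers is not implemented; the scan tests
  markers only, which is adequate for dense, informative maps.
* No epistasis, QTL-by-sex or QTL-by-environment terms are fitted.
* The maternal-effect test addresses the dam's *genotype at the tested
  locus*; maternal effects driven by other loci or by non-genetic
  maternal variation are absorbed by the family intercept instead.
* Multiple-trait significance is controlled per trait by genome-wide
  permutation only; there is no cross-trait false-discovery control.
* F2 heterozygote ordering from local pedigree information is
  impossible in this design (see the phasing section); analyses
  requiring ordered F2 genotypes should use the simulator's truth or
  an external whole-pedigree phaser.
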