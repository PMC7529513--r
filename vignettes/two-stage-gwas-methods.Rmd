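---
title: "Methods: two-stage mixed-model GWAS with candidate-variant validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-stage mixed-model GWAS with candidate-variant validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dairyqtl)
```

## The analysis this package implements

Dairy-cattle breeding programs detect quantitative trait loci (QTL) in two
stages. A **discovery** scan tests millions of imputed sequence variants in a
population of a few thousand progeny-tested sires, whose pseudo-phenotypes
(daughter-based deregressed proofs) have high reliability. Promising regions
are distilled into a few hundred **candidate variants** that are added to the
customized part of a routine genotyping chip; their effects are then
**validated** in a much larger, statistically independent population of cows
whose phenotypes are single-record yield deviations of much lower
reliability. `dairyqtl` implements that pipeline end to end — association
scan, QTL definition, candidate selection, confirmation — together with a
synthetic-data generator that reproduces the statistical structure the
analysis relies on, because the animal data behind such studies are
proprietary and cannot be redistributed.

## The association model

Both scans fit, for each variant in turn,

$$\mathbf{y} = \mathbf{1}\mu + \mathbf{x} b + \mathbf{u} + \mathbf{e},
\qquad
\mathbf{u} \sim N(0, \mathbf{G}\sigma^2_u),\quad
\mathbf{e} \sim N(0, \mathbf{I}\sigma^2_e),$$

where $\mathbf{y}$ are pseudo-phenotypes standardized by the genetic standard
deviation of the trait (so $b$ is an allelic substitution effect in
genetic-SD units), $\mathbf{x}$ holds dosages coded 0/1/2, and $\mathbf{G}$
is a genomic relationship matrix built from an array panel
(`compute_grm()`): $\mathbf{G} = \mathbf{Z}\mathbf{Z}' / 2\sum_j p_j(1-p_j)$
with columns of $\mathbf{Z}$ centered at $2p_j$. The variance components are
estimated **once**, by REML on the null model $\mathbf{y} = \mathbf{1}\mu +
\mathbf{u} + \mathbf{e}$ (`fit_null()`), and then held fixed for every
variant test (`assoc_scan()`), which is the standard "mlma" contract of
mixed-model association software. Residuals are homoscedastic within a
population: reliability differences between individuals are deliberately not
modelled as residual weights, matching the analysis being reproduced.

Numerically, `fit_null()` eigendecomposes $\mathbf{G}$ once and profiles the
restricted likelihood over the variance ratio
$\lambda = \sigma^2_u/\sigma^2_e$ on a log-spaced grid
($10^{-3}$–$10^{3}$, quarter-decade steps, plus the $\lambda = 0$ boundary),
then refines the bracket around the grid optimum by golden-section search
(tolerance $10^{-9}$ on $\lambda$). Because the GRM is kept in factored form
$\mathbf{G} = \mathbf{Z}\mathbf{Z}'/d$, the eigendecomposition runs through
the smaller of the two Gram matrices; a GRM built from $m$ array SNPs on $n$
individuals costs $O(\min(m,n)^3)$, never $O(n^3)$, and its null space is
handled implicitly. With the components fixed, the per-variant
generalized-least-squares solution for $(\mu, b)$ reduces to a handful of
cross-products against the $K$ retained eigenvectors, so a full scan is two
dense matrix products; p-values are Wald $\chi^2_1$ on $(\hat b/\mathrm{se})^2$,
computed on the log scale so extreme signals do not underflow.

Significance uses a Bonferroni argument: the discovery threshold is
$0.05 / 8\,000\,000$ effective independent tests
($-\log_{10} P = 8.2$ at one decimal), and the validation threshold is the
fixed array-scale cutoff $10^{-6}$ ($-\log_{10} P = 6$). The effective test
count is treated as a constant of the design, not recomputed from LD.

## QTL definition

Within one trait and population, significant variants less than 1 Mbp apart
(strict) are chained into peaks (`cluster_significant()`). Each peak receives
an *individual confidence interval*: with $M$ the peak's maximum
$-\log_{10} P$ and $T$ the threshold, the CI spans the positions of members
with $-\log_{10} P \ge M - (M - T)/3$ — the upper third of the peak measured
between threshold and summit. "Upper third of the peak" admits a second
reading, $-\log_{10} P \ge \tfrac{2}{3}M$; both are implemented
(`individual_ci(rule =)`). The threshold-anchored rule is the default because
it makes CIs shrink as peaks grow taller, which is the behaviour expected of
a well-powered fine-mapping interval.

Individual CIs that overlap or lie less than 1 Mbp apart are merged into QTL
regions (`merge_to_qtl()`): the region's TOP-CI is the individual CI of the
peak holding the most significant variant, its EXT-CI the outermost bounds of
all merged CIs (identical when a single CI is present). Ties for the most
significant variant break deterministically by larger $|\hat b|$, then lower
position. The proportion of genetic variance explained by a region is
$2 p_{ms} (1 - p_{ms}) \hat b^2_{ms}$ from the frequency and effect of its
most significant variant; because $\mathbf{y}$ is standardized this is
directly a fraction of the genetic variance. Regions from different traits
and populations whose EXT-CIs overlap or fall within 1 Mbp share a
cross-analysis region id assigned in genome order
(`group_regions_across()`). Distances between intervals are
$\max(0, \text{start}_2 - \text{end}_1)$ and all "less than" comparisons are
strict. Coordinates are 1-based inclusive everywhere inside the package;
conversion to 0-based half-open happens only in the BED writer.

## Candidate selection

A chip budget (900 custom slots by default) is split evenly across QTL,
remainder to the most significant peaks (`allocate_budget()`). Within a
QTL's EXT-CI, variants with MAF strictly above 0.02 are ranked by
significance; within any run of variants whose $-\log_{10} P$ lies within
1.0 of the local leader, functional annotation refines the order —
coding (missense, loss-of-function) first, then putative regulatory
(splice region, UTRs, upstream, downstream), then other genic, then
intergenic — with position as the final deterministic tie-break
(`rank_candidates()`). The similarity window is a design constant: the
procedure being reproduced says only "similar significance levels", and 1.0
on the $-\log_{10}$ scale (a tenfold p-value ratio) is the natural reading.
Candidates are drawn from the EXT-CI rather than the TOP-CI so merged
sub-peaks stay represented; a switch restricts to TOP-CI. A variant serving
two overlapping QTL counts once toward the chip total. An optional seeded
random dropout emulates assay-design losses; it is off by default.

## Validation

The validation population must be disjoint from discovery —
`validation_scan()` refuses shared individual ids, since the two stages'
statistical independence is what makes confirmation meaningful. The scan
covers the candidate variants plus the polymorphic array SNPs (MAF ≥ 0.01),
with $\mathbf{G}$ rebuilt from the validation population's array genotypes
and variance components refitted there. Per QTL, `confirm_qtl()` ranks all
tested variants in the EXT-CI by $-\log_{10} P$ (ties by position) and
reports significance counts for candidates and array SNPs separately,
candidates among the top ten, the best candidate rank, and a confirmed flag —
true when **any** tested variant in the region reaches the validation
threshold (a candidates-only mode is available). `summarize_confirmations()`
aggregates to mean best ranks over all and over confirmed QTL.

## What the generator simulates

`simulate_genotypes()` builds a founder pool of `n_haplotypes` haplotypes
organised in LD blocks with exponentially distributed lengths (mean
`ld_block_bp`). Each block carries a small set of haplotype *prototypes*
(`n_prototypes`, default 4) related by a random binary genealogy; every
variant marks one clade of that genealogy, so variants on the same branch
are in complete LD and nested or disjoint branches give the graded
within-block $r^2$ structure of real haplotype blocks. Prototype weights are
Dirichlet-distributed, which yields a continuous, roughly U-shaped allele
frequency spectrum; a configurable floor (`maf_min`) is enforced in the pool
by redrawing, with an explicit error when the pool cannot express it.
Founders copy prototypes with a small per-allele error rate, individuals
draw two founders independently per block (free recombination between
blocks, none within), and both populations sample the same pool — causal
variants therefore segregate at similar frequencies in both, which the
frequency-conservation test checks. The small prototype number per block is
deliberate: dairy cattle have a very small effective population size, and
few-lineage blocks are what give mixed-model GWAS its characteristic peak
shapes.

`plant_qtl()` places `n_qtl` causal variants, at least 5 Mbp apart, drawn
from a mid-frequency window (MAF 0.05–0.45 by default) so that planted
regions are separable and detectable; effects are specified in genetic-SD
units. Planted variants are labelled missense by default
(`causal_annotation`), reflecting the working hypothesis of the design being
emulated — that causal variants are enriched in coding sequence — and making
the annotation tie-break consequential in tests; set it to `NA` to leave
labels at their sampled values.

`simulate_phenotypes()` works on the standardized scale directly: the latent
genetic value is
$g = \sum_{\text{QTL}} (x - 2p) b + \sqrt{v_{\text{poly}}}\,u +
\sqrt{v_{\text{iid}}}\,\delta$, with $u$ a marker-structured draw
(covariance proportional to a GRM of non-causal variants) and $\delta$
i.i.d. noise representing Mendelian-sampling variation the marker panel does
not tag. `h2_poly` is the marker-structured share of the non-QTL genetic
variance — with reliability 1 and no QTL, REML on a marker GRM recovers
$h^2 \approx$ `h2_poly`. The variances are scaled so $\mathrm{Var}(g) = 1$
in expectation, and the observation is $y = g + \varepsilon$ with
$\mathrm{Var}(\varepsilon) = (1-r)/r$, so the reliability $r$ is exactly the
genetic fraction of the phenotype variance, the semantics of a deregressed
proof standardized by $\sigma_g$. Residuals are homoscedastic within a
population. The somatic-cell transform `scs_from_scc()`
($3 + \log_2(\mathrm{SCC}/10^5)$) is provided for building udder-health-like
traits from count data.

Default study conditions (one seeded configuration, `sim_config()`):
2,000 discovery individuals at reliability 0.90 and 10,000 validation
individuals at reliability 0.35 (single-record-heritability scale), 20,000
variants on a 100-Mbp chromosome, 400 founder haplotypes, 250-kb mean
blocks, an array panel of 2.5% of variants excluding causal sites, five
planted QTL with effects 0.3–0.6 genetic SD, polygenic share 0.3, and
annotation probabilities equal to the published category frequencies of
variants inside QTL confidence intervals in cattle. These sizes scale the
real design down by roughly two orders of magnitude in variant count while
preserving the ratios that matter to the statistics (reliability contrast
between stages, planted-effect sizes, LD-block granularity relative to the
1-Mbp clustering distance).

## What the generator does *not* capture

No pedigree or overlapping generations, no selection or drift, no X
chromosome, no imputation process (an optional independent genotype-flip
noise can mimic imputation error, but it is not a model of any imputation
algorithm), no multi-breed structure, and LD decays as a step function at
block boundaries rather than continuously. Passing tests therefore
demonstrate that the statistical machinery is correct and well calibrated
under the assumed model — not that the pipeline would achieve any particular
power or confirmation rate on real cattle data.

One scaled-down artefact deserves a note. In the real design the GRM is
built from tens of thousands of array SNPs for at most a comparable number
of individuals, so no single variant direction carries a large eigenvalue.
In a heavily scaled simulation with an array panel much smaller than the
population, the eigenvalue share of a causal variant's LD partners grows as
$n/m$, and the fixed-component GLS then absorbs a sizeable part of the
causal signal into the polygenic term — the proximal-contamination effect of
scans that do not exclude the tested chromosome from the GRM, amplified by
scale. The package keeps the no-exclusion contract (matching the analysis it
reproduces, which accepts slight power deflation); the power-calibration
tests simply use panels with $n/m$ of order one so that the regime matches
the real design. The replicate-study conditions keep the smaller panel, and
their detection rates for the weakest planted effects are correspondingly
conservative.

## Numerical and edge-case policy

Monomorphic or below-floor variants are never silently dropped: scan output
carries an explicit `filtered` status. Phenotype/GRM id mismatches,
constant phenotypes, non-finite values, unconverged variance components,
overlapping discovery/validation ids, unknown annotation categories,
unattainable MAF floors, and QTL placement that cannot satisfy spacing all
raise errors that name the violated constraint. All randomness flows from
integer seeds through configuration objects; identical configurations give
byte-identical outputs, which the manifest writer (md5 digests, relative
paths) makes checkable across runs and directories.

## Problem sizes used by the test-suite studies

The acceptance-style studies run at: 50 replicates of the full pipeline at
the default study conditions above; null-uniformity on a 10,000-variant scan
of 1,000 individuals; REML heritability recovery at $h^2 = 0.5$, $n = 2000$;
GLS-oracle equivalence on instances up to 50 individuals × 20 variants; and
power checks (discovery $b = 0.5$ at MAF ≈ 0.2, $n = 2000$; validation
$b = 0.3$ at MAF ≈ 0.2, $n = 10{,}000$) at 50 seeded replicates each. These
sizes are the package's own choices for routine verification; all scale up
by configuration.

## Known limitations

* The "8 million independent tests" figure is a design constant; the package
  does not estimate effective test counts from LD.
* Gene counts per CI require an external gene annotation and are omitted
  unless interval annotations are supplied.
* Multi-trait runs are independent repetitions sharing genotypes; no
  multi-trait model is fitted.
* Winner's curse is reported (estimated variance explained of detected QTL
  exceeds the planted value on average, which the replicate study asserts
  directionally) but not corrected.
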