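---
title: "Linkage maps, half-tetrad centromeres and QTL scans: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linkage maps, half-tetrad centromeres and QTL scans: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tetramap)
```

tetramap re-implements, as a tested pipeline over simulated data, the
computational chain used to build a salmonid linkage map: marker quality
control, two-point LOD grouping with iterative threshold splitting, marker
ordering, sex-specific map construction, centromere localization from
gynogenetic half-tetrads and maternal recombination profiles, single-QTL
genome scans with permutation significance, chromosome-specific cM/Mb
estimation, and pericentric/paracentric classification of inversions.
This vignette explains the models behind each stage, the defaults and why
they hold, and what the simulation does and does not establish about real
data.

## The meiosis model

Crossovers on each chromosome arise on the four-chromatid bundle from a
count-location process: the count is Poisson with mean twice the map length
in Morgans, locations are uniform on the female map, and each chiasma joins
one chromatid currently carrying homolog-1 DNA with one carrying homolog-2
DNA at that point, chosen uniformly (no chromatid interference).  Exchanged
segments are always distal to the centromere, so sister pairs — defined by
shared centromere — are invariant.  A transmitted gamete is one chromatid
chosen uniformly.  Two consequences anchor the test suite:

* the recombinant fraction between markers $d$ Morgans apart follows the
  Haldane map function $r = (1 - e^{-2d})/2$, and
* a single gamete shows, in expectation, one visible crossover per Morgan,
  uniformly along the chromosome.

Crossover interference is not modeled (an `obligate_chiasma` switch forces
one chiasma per bundle but is off by default): a Poisson process keeps
every closed form and enumeration oracle tractable, at the cost of slightly
wider crossover-count dispersion than real meioses show.

**Male recombination.** Salmonid males recombine almost exclusively near
telomeres.  Rather than prescribing a male map, the simulator *rejects*
male crossovers falling outside a telomeric window covering
`male_telomere_fraction` of each chromosome end (default 0.1).  Male map
lengths are therefore emergent: with the default window, male maps come out
near 20% of female length, a more extreme heterochiasmy than the 1.391
female:male genome ratio reported for real data but similar to its extreme
linkage groups, where male lengths of ~2 cM against ~43 cM female are
observed.  The female:male ratio exceeding 1 whenever the window is
restrictive is a tested invariant, not an input.

**Half-tetrads.** Gynogenetic diploids retain the two sister chromatids of
one secondary oocyte (second-polar-body retention; mitotic gynogenesis is
not modeled because the emulated protocol is heat-shock retention).  A
marker is heterozygous exactly when a crossover separated it from its
centromere on one retained strand.  Under the bundle model the offspring
heterozygosity at distance $d$ Morgans from the centromere is
$y(d) = \tfrac{2}{3}\bigl(1 - e^{-3d}\bigr)$ — approximately $2d$ near the
centromere and saturating at the classical tetrad limit $2/3$.  The tests
verify the simulator against an independent enumeration oracle over
crossover counts and strand assignments rather than against this closed
form, so the oracle does not share code with the implementation.

## Marker quality control

Filters are independent predicates, applied jointly: segregation-distortion
chi-square against the ratio implied by the parental cross type (1:2:1 for
het x het, 1:1 for het x hom; df = classes − 1, no continuity correction;
default p < 0.01 removes), minor allele frequency below 0.05, missingness
above 0.3, and informativeness in at least one family.  Genotypes are hard
A/H/B calls: the likelihood-aware genotype-posterior pipeline used upstream
of the original study is out of scope here, and the biallelic coding means
four-allele (1:1:1:1) cross types cannot occur; such markers would surface
as unknown cross types and are flagged rather than silently tested.

The LOD-position-matrix filter removes markers whose placement is
ambiguous: each marker's vector of LOD scores over candidate positions is
min-max normalized; the marker is dropped when its maximum raw LOD is less
than one standard deviation above the vector mean (the SD rule is applied
to the raw vector; a switch exposes the normalized variant, since the
source description is ambiguous on this point), or when two or more
normalized peaks of height at least 0.95 sit further apart than 25% of the
vector length, measured in position-index units.

RAD-locus thinning keeps the SNP closest to the restriction cut site, ties
broken to the lexicographically smaller marker id, so reruns are
deterministic under input permutation.

## Grouping and ordering

Two-point LOD for a pair with $k$ recombinants of $n$ informative meioses
is evaluated at $\hat r = \min(k/n, 0.5)$ and summed across informative
parents and families; pairs scored nowhere stay missing rather than zero.
Grouping is single-linkage: connected components of the LOD-threshold
graph, mirroring the threshold-component behaviour of the established
mapping software without re-implementing its HMM internals.  Components
below the minimum size (default 50) dissolve into singletons.  Because no
single threshold yields the expected chromosome number in the emulated
study, the largest groups are revisited: within each, assignment is re-run
at every integer threshold in 8-60 and the maximum threshold producing at
least two sufficiently large components is adopted, until the target count
is reached.  Splitting is monotone in the threshold (raising it never
merges), which is tested as a property.  Singletons then rejoin the group
holding their best-LOD partner when that LOD is at least 10 and beats the
second-best group by at least 5, iterated to a fixpoint so the outcome is
independent of scan order.

Ordering minimizes the sum of adjacent recombination fractions (SARF) by
greedy nearest-neighbour construction from 20 random starts, each refined
to 2-opt local optimality, the orientation canonicalized to put the
lexicographically smaller terminal marker first.  This replaces the
external tool's multipoint likelihood ordering; the claim is truth
recovery on simulations (rank correlation ≥ 0.99 at study sizes), not
score equality with that tool.  Map positions accumulate Haldane distances
per sex (Haldane rather than Kosambi, matching the interference-free
simulator; fractions at 0.5 are capped at 0.49 and flagged).  The
sex-averaged position of a marker is the mean of its female and male
positions; unique-position counts are taken on the female map.

## Centromere localization

Two independent routes are reconciled per linkage group:

* **Half-tetrad y profile.**  Offspring heterozygosity per marker among
  gynogenetic diploids, after a VCF-style filter chain (biallelic SNPs;
  genotypes with quality ≤ 10 set missing; markers dropped at > 30%
  missingness, MAF < 0.05, mother not heterozygous, or either homozygote
  class unobserved).  The centromeric interval spans the first to the last
  marker with y < 0.1; no qualifying marker leaves the group unresolved,
  the outcome the emulated study reported for one of its 42 groups.  The
  observed y is used directly, never converted to a second-division
  segregation frequency, matching the delineation rule it emulates.

* **RFm profile.**  Maternal recombination accumulated against the
  terminal marker of each end, computed from phased maternal haplotypes as
  the mean number of crossover events per haplotype in the spanned
  interval (a `fraction` variant — the share of haplotypes in a recombinant
  state — is exposed as an option).  The count form is the default because
  under a no-interference model the recombinant *fraction* saturates at
  $(1-e^{-2d})/2 < 0.45$ for any realistic map length, so the published
  0.45 cutoff could never fire, whereas cumulative counts rise linearly
  and cross it.  The profile is monotone in expectation, so isotonic
  regression is applied before thresholding — a single noisy dip then
  cannot truncate the centromeric run.  Both ends are evaluated; the y
  minimum selects the run(s), and when both ends' runs qualify their
  intersection is taken (the metacentric case).

Reconciliation intersects overlapping intervals and unions disjoint ones
with a conflict flag.  The chromosome class is metacentric when the
midpoint falls in the central 50% of the female map (a configurable
convention standing in for karyotype counts), acrocentric/telocentric
otherwise, and unknown when neither route resolves.

## QTL scans

Evaluation positions are the union of markers and a 1 cM pseudomarker
grid.  Genotype probabilities come from two independent parent chains:
degenerate at observed markers, two-flank Haldane interpolation at
pseudomarkers, single-flank decay where one side is missing and the
uniform prior where both are.  The kinship matrix averages, over a 3 cM
thinned grid, the probability that two individuals share a parental-origin
class, scaled to unit self-kinship.

Normal traits are scanned by Haley-Knott regression on the expected
additive ($P(\mathrm{hom}_2) - P(\mathrm{hom}_1)$) and dominance
($P(\mathrm{het})$) scores, $LOD = (n/2)\log_{10}(RSS_0/RSS_1)$.  With a
kinship matrix the variance ratio is estimated once under the null by
maximum likelihood in the eigenspace of K and reused at every position
(no per-position REML, the standard computational approximation); when
permutations are scanned together with the observed trait the null
variance ratio from the observed trait is reused for the batch.  The
whole-genome kinship is not leave-one-chromosome-out, so a strong QTL is
partially absorbed into the polygenic term and its mixed-model LOD is
attenuated relative to the plain regression — visible in the tests, which
assert location agreement between the two models.  The simulation-recovery
and calibration checks therefore run the plain Haley-Knott scan, which is
also the model the pipeline uses for binary traits (logistic IRLS, max 50
iterations, fitted probabilities clamped to $[10^{-8}, 1-10^{-8}]$,
$LOD = (LL_1 - LL_0)/\ln 10$; a kinship random effect is deliberately not
offered for the binary model).

Peaks are local maxima with LOD ≥ 3; two maxima are distinct only when the
valley between them drops at least 2 below the smaller.  The 95% credible
interval is the smallest position set holding ≥ 95% of the normalized
$10^{LOD}$ mass of the peak's region, truncated where the curve falls 2
below the peak.  Adjacent significant peaks are reported separately (the
emulated study reports two adjacent sex-locus peaks and discusses them as
likely one).  Permutations shuffle trait values with genotypes fixed,
preserving LD; p-values are the share of permuted genome-wide maxima at or
above the observed LOD, floored at $1/(n_{perm}+1)$ and labelled
"< floor" when no permutation reaches it.  PVE converts a peak to variance
explained via $1 - 10^{-2\,LOD/n}$; the printed formula in the source
material is dimensionally inconsistent and this reading reproduces every
published PVE from its LOD and sample size, which the tests assert to
three decimals.

## Recombination rates and synteny

Per linkage group and sex, 100 marker pairs sharing a reference chromosome
(mapping quality ≥ 60; chromosomes holding > 50 such loci) are sampled
without replacement per replicate from all eligible pairs, markers may
recur across pairs within a replicate, and $|\Delta cM|$ is regressed on
$|\Delta Mb|$ through the origin ($\hat\beta = \sum xy / \sum x^2$ — using
absolute pairwise distances makes the estimate orientation-free); the mean
and SD over 100 replicates are reported.  The replicate SD reflects pair
resampling only, not map-estimation error, which is systematic per map.

Homology requires ≥ 50 loci at MQ ≥ 60; smaller counts are reported as
suggestive, never asserted.  Inversion detection formalizes what the
emulated study did by manual dot-plot inspection: the (cM, bp) scatter is
cut at direction changes of the physical coordinate, runs of at most two
markers are absorbed into the neighbour with the higher combined rank
correlation (plain whole-run Spearman merging would silently swallow
minority-orientation blocks covering up to ~30% of a chromosome), and
same-orientation neighbours merge.  Runs opposing the marker-weighted
majority orientation with at least 10 markers are candidate inversions.
Acceptance is on constructed fixtures with known reversals — boundary
recovery within one marker spacing — never on real-genome concordance.
Centricity uses closed-interval overlap with the centromere interval
(boundary contact counts, conservative toward pericentric calls);
unresolved centromeres give class unknown.

## Problem sizes, determinism and limitations

The simulation suite runs at the emulated study's family sizes where they
matter: 45 gynogens for y profiles, ~358 pooled maternal meioses for RFm,
150-180 offspring for grouping/ordering and QTL work, 150 markers per
group for centromere recovery, and scan calibration with 100 null traits
at 200 permutations each on a two-chromosome genome — sizes chosen so each
property is measured at meaningful precision while the whole suite stays
interactive.  All randomness flows from explicit seeds; the pipeline
driver writes a JSON provenance block (package version, configuration and
its MD5) and is byte-deterministic given a seed.

What passing tests do *not* show: the simulator has no crossover
interference, no genotyping-error structure beyond independent flips, no
population history, and uniform marker spacing, so truth-recovery rates
here are upper bounds on real-data performance; the genome-scale published
quantities (15,740 mapped loci, 42 linkage groups, rates against real
reference genomes) depend on raw sequencing data and external genomes and
are exercised only through the property suites above.
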