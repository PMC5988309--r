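---
title: "Divergence and introgression scans with coalescent model selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Divergence and introgression scans with coalescent model selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sticklescan)
```

This vignette documents the models behind `sticklescan`, the
assumptions they make, the defaults of the synthetic-data generator,
and the numerical decisions that shape edge-case behaviour. The
package is built for a recurring analysis situation in speciation
genomics: a pair of lineages that has accumulated high genome-wide
differentiation while still exchanging genes at a very low rate, so
that the signal of interest is a scatter of small genomic tracts of
recent introgression on a strongly diverged background.

## The coalescent simulator

Every statistical claim in the package is testable against simulated
data, so the simulator is a first-class component rather than a test
fixture. It implements the structured coalescent with
piecewise-constant demography: epochs (looking backward from the
present) each carry per-population diploid sizes, a backward migration
matrix ($m_{ij}$ is the per-generation probability that a lineage in
population $i$ derives from population $j$), and a remap applied on
epoch entry that implements population mergers. Mutations fall on the
realised genealogy under an infinite-sites model at rate $\mu$ per
site per generation; alleles are coded ancestral/derived. Loci are
simulated free of intra-locus recombination and independent of one
another, mirroring a short-locus sampling design (2-kb loci drawn at
125-kb spacing); a chromosome is emulated by concatenating independent
locus blocks, which stands in for recombination at the block scale but
not for within-block linkage decay.

The two-population divergence histories combine a scenario — strict
isolation (I), continuous migration (IM), ancient-only (IAM: migration
only in $[T_\mathrm{anc\_stop}, T]$), recent-only (IRM: only in
$[0, T_\mathrm{rec\_start}]$), or both (IARM) — with a size history
for the focal population: constant, an exponential change from
$N_\mathrm{JSB}$ at $T_G$ to $N_\mathrm{JS}$ at present (represented
internally by a 12-step geometric ladder), or a bottleneck at size
$N_\mathrm{JSB}$ during $[T_G, T]$. These epoch definitions are the
simplest histories consistent with the verbal model names; other
parameterisations of "ancient" and "recent" contact would be equally
defensible. Defaults follow the biology of a
$\sim 10^5$–$10^6$-generation-old marine pair: $\mu = 7.1\times10^{-9}$
per site per generation, one-year generations, migrant fractions of
order $10^{-6}$.

An outgroup, when requested, is a lineage splitting at $5T$ — deep
enough to polarise alleles, shallow enough to keep trees small.
Because the simulator knows the ancestral state, derived coding is
exact; with real data the same role is played by an outgroup genome.

The simulator's correctness is pinned by closed-form neutral
expectations ($E[\pi] = 4N\mu$ within Monte-Carlo error; Tajima's $D$
negative under expansion; shared polymorphisms decaying with split
time) rather than by comparison to any particular implementation.

## Windowed statistics

Windows are 0-based half-open intervals tiling each chromosome;
trailing partial windows are dropped. A window's *usable sites* are
its positions minus variant sites whose haplotype call rate falls
below 50%; invariant positions are treated as callable, as in
consensus-call data. Haplotype statistics require the usable count to
reach 5,001 in a 10-kb window — the strict "more than half" rule —
otherwise the window is listed with missing values so that scans stay
positionally complete.

$F_\mathrm{ST}$ uses the haploid Weir–Cockerham variance components,
summed over sites before taking the ratio. That is the standard
windowed estimator; averaging per-site ratios would weight
low-information sites far too heavily. The estimator may be slightly
negative without differentiation; this is left visible.

$d_{XY}$ is computed per inter-population haplotype pair with pairwise
deletion: each pair's denominator is the window's usable count minus
the variant sites at which that pair is not jointly called. The
alternative of dividing by physical window length is equivalent here
because usable sites are the callable fraction of the window;
`dxy_stats()` exposes the denominator so either convention can be
recovered. $G_\mathrm{MIN}$ is the minimum pair divided by the mean;
it is undefined (flagged `NA`) when mean $d_{XY}$ is zero. Tie-breaks
for the minimising pair are lexicographic on haplotype names, so
reruns are reproducible. Tajima's $D$ uses the canonical normalising
constants with the population's full haplotype count; per-site missing
data enter through the per-site unbiased heterozygosity and the
segregating-site count. Zero segregating sites yield `NA`, never 0 —
a monomorphic window carries no information about the frequency
spectrum.

## Site-pattern statistics and direction of gene flow

All pattern statistics are frequency-weighted: a site contributes the
product of its per-taxon derived ($p$) or ancestral ($1-p$)
frequencies, so fixed differences recover the classical ABBA/BABA
counts exactly (a property under test). Sites where the outgroup is
polymorphic contribute with weight $1 - p_O$ rather than being
dropped, keeping the weighting consistent across taxa.

$f_d$ uses the dynamic-donor denominator (donor frequency replaced
site-wise by $\max(p_2, p_3)$, ties to $p_2$). It is emitted for
negative-$D$ windows as well because genome scans legitimately report
negative window means; such values are not interpretable as admixture
proportions, and `mask_negative_d = TRUE` suppresses them.

For five taxa, partitioned $D$ attributes derived-allele sharing with
P2 to one or both members of the P3 pair (D₁: ABBAA vs BABAA; D₂:
ABABA vs BAABA; D₁₂: ABBBA vs BABBA). $D_\mathrm{FOIL}$'s four
components are built from four pattern groups in which DFO/DIL and
DFI/DOL are mirror images under exchanging P1 and P2; their
significant-sign signature is looked up in a table covering the eight
directed events between the younger pair {P1, P2} and the older pair
{P3, P4} plus the two ancestral exchanges. The signatures were
verified against pulse-introgression coalescent simulations of every
event (each event produces a distinct signature, and the two spec
symmetry identities hold analytically). Signatures matching no table
row — including partially significant ones — are reported as `none`
rather than guessed.

Per-component significance is a $\chi^2$ goodness-of-fit on the
left/right weighted sums at $\alpha = 0.01$. Because weighted sums are
much smaller than site counts, this test is deliberately conservative:
under strict-isolation simulations the per-window flag rate is far
below the nominal level, and direction calls in the package's own
validation are evaluated over whole simulated regions, where the
aggregated weight gives the test its power. No misclassification of
direction was observed in those simulations — the cost of the
conservative test is sensitivity, not accuracy.

## Valley and peak detection

The two-state Gaussian HMM is fitted by scaled Baum–Welch (tolerance
$10^{-6}$ log-likelihood units, at most 500 iterations) and decoded by
Viterbi. Transitions are initialised symmetric at stay 0.9 / switch
0.1 — outlier tracts are rare and contiguous — and the chain starts in
the background state. $G_\mathrm{MIN}$ is logit transformed (values
clamped into $(0,1)$ at $10^{-6}$ because 0 and 1 occur exactly);
$f_d$ is used raw. Missing windows are emission-free gaps: they
contribute no likelihood but are still decoded, so valleys can span
them. When Baum–Welch collapses both states onto one emission
distribution the track is all background — a two-state forced split of
a homogeneous track would otherwise invent outliers. Windows in the
target state merge into valleys when their gaps are at most 30 kb.

The permutation null shuffles the order of variant-site rows within a
chromosome — preserving every per-site allele configuration while
destroying the spatial clustering that makes a migrant tract a valley
— and pools permuted window values into usable-site bins; the cutoff
is the pooled 1st percentile (the lower tail of a "lower 99
percentile" rule). Valleys can be called from the HMM alone or
intersected with this threshold; the intersection is used in the
package's own gene-flow-contrast validation because it removes the
forced-split artefact on null tracks.

Gene-overlap enrichment counts unique genes touching any valley
(≥ 1 bp) and compares against draws of equally many, equally long runs
of consecutive non-valley windows, with add-one-corrected empirical
p-values, as does the group-difference permutation test
($p = (b+1)/(n+1)$).

## Ancestry indices

Markers with absolute parental frequency difference strictly greater
than 0.8 qualify as ancestry-informative; each records the allele more
frequent in species 2, so non-diagnostic AIMs contribute fractionally
rather than being forced to a fixed-difference model. The hybrid index
is the proportion of species-2 alleles across typed AIMs and
interspecific heterozygosity the proportion of heterozygous AIMs;
missing genotypes leave both denominators. At diagnostic AIMs the
triangle constraint $H_\mathrm{int} \le 2\min(h, 1-h)$ holds by
construction and is asserted over all simulated pedigree classes
(parents, F1, F2, both backcrosses), which occupy distinct
$(h, H_\mathrm{int})$ regions with high nearest-centroid separability
once a few hundred AIMs are typed.

## Window trees and genealogical sorting

Per-window trees are neighbour-joining on pairwise-deletion difference
matrices, rooted on the outgroup, negative branch lengths clamped to
zero. NJ replaces a per-window maximum-likelihood search deliberately:
it is consistent on additive distances, orders of magnitude faster,
and the downstream classification depends only on topology. Topology
classes are assigned with precedence species > geography > ancestral
(a tree can satisfy more than one monophyly condition; the precedence
makes the assignment deterministic), and a missing lineage yields
`unresolved`.

The genealogical sorting index implemented here measures exclusive
ancestry as follows: with $I_\mathrm{obs}$ the number of internal
nodes on the union of paths from the group's $n$ tips to their most
recent common ancestor and $M$ the tree's internal-node count,
$\mathrm{gsi} = (1/I_\mathrm{obs} - 1/M)\,/\,(1/(n-1) - 1/M)$. This
normalisation attains 1 exactly at monophyly (on a binary tree
$I_\mathrm{obs} = n-1$ if and only if the group is monophyletic), is 0
when the paths touch every internal node, never increases when a group
tip moves deeper into foreign territory, and ignores relabelings
outside the group's spanning subtree. It is the package's own
formulation of the degree-of-exclusive-ancestry idea, chosen for these
provable endpoint and monotonicity properties.

## Recombination

Marker maps interpolate piecewise-linearly in cumulative map distance;
a window's rate is $\Delta\mathrm{cM}/\Delta\mathrm{Mb}$ between its
bounds. Beyond terminal markers the terminal segment's slope is
extended — a zero-rate extrapolation would fabricate rate valleys at
chromosome ends. Interpolation is linear rather than spline because
marker maps are sparse and monotone; conservation of total map length
over tiled windows is the invariant under test. Correlations with scan
statistics are Pearson on pairwise-complete windows with the usual
t-approximation; an optional $\log_{10}$ transform drops zero-rate
windows.

## Approximate Bayesian computation

The reference table records, per simulation, the model, the parameter
draw and 20 summaries: means and variances across loci of
$\{\pi_1, \pi_2, \theta_{W1}, \theta_{W2}, D_1, D_2, F_\mathrm{ST},$
shared, private$_1$, private$_2\}$. This concrete list is the
package's documented choice of a 20-statistic set summarising
diversity, the frequency spectrum, differentiation and the
joint-polymorphism structure — the quantities that separate
divergence-with-gene-flow histories. Undefined per-locus values (e.g.
Tajima's $D$ at zero variation) are excluded from the moments.

Default priors are log-uniform: effective sizes $10^3$–$10^6$, split
time $10^4$–$10^7$ generations, migrant fractions $10^{-9}$–$10^{-4}$,
with conditional times drawn below their parent parameter. Rejection
standardises summary columns by the reference table's median absolute
deviation — robust to the heavy-tailed summaries these models produce
— drops degenerate columns with a warning, and accepts the nearest
tolerance fraction by Euclidean distance; model posteriors are
acceptance shares and parameter posteriors are equal-tailed quantiles
of accepted draws (log-scale copies retained). Acceptance sets are
nested across tolerances by construction. A local regression
adjustment could sharpen posteriors but rejection is the tested
baseline. Hierarchical selection mirrors the two-stage design (growth
variant within scenario, then across scenarios) simply by composing
`select_model()` calls on the corresponding model subsets.

Validation uses pseudo-observed datasets drawn from each model's own
prior. Two properties deserve emphasis. First, these scenario
families are *nested*: an IM draw with $2Nm \approx 0$ is an isolation
history, and a bottleneck draw with $N_\mathrm{JSB} \approx
N_\mathrm{JS}$ is a constant-size history. Under diffuse priors a
substantial prior mass is therefore information-theoretically
indistinguishable from a simpler neighbour, and per-model recovery of
prior-drawn PODs is bounded well below 1 for the migration and
bottleneck models no matter how good the inference is — the package
reports the measured recovery rather than hiding the overlap. Second,
split-time credible intervals are calibrated against PODs with known
parameters, where near-nominal coverage is the expected behaviour
even when identifiability is weak.

## Problem sizes and reproducibility

The packaged validations run at desk scale: 50–200 loci of 2–10 kb,
8–20 haplotypes per population, 5,000 ABC simulations per model, 10
seed replicates for detection contrasts. These sizes make every check
reproducible in minutes on one core while leaving Monte-Carlo margins
(3-SE bands, 8-of-10-seed rules) explicit. All randomness flows
through R's RNG, so a single seed fixes simulator output bit-for-bit.

What passing these checks does *not* show: performance on real
resequencing data with alignment error, coverage heterogeneity,
within-locus recombination, linked selection or reference bias — none
of which the generator emulates. The synthetic data establish that the
statistics, detectors and inference machinery do what their
definitions promise under the model they assume; transferring
conclusions to real genomes still requires the usual filtering care
upstream.
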