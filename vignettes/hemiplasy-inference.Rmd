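---
title: "Hemiplasy and homoplasy under the multispecies network coalescent"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hemiplasy and homoplasy under the multispecies network coalescent}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemicoal)
```

## The problem

When a binary character is incongruent with the species tree — say two
non-sister species share a derived state — the textbook explanation is
convergent evolution (homoplasy): independent mutations on separate
branches.  But when gene trees disagree with the species tree, a single
mutation on an internal branch of a *discordant* gene tree can produce the
same incongruence.  This is hemiplasy.  Discordance arises from incomplete
lineage sorting (ILS) and from introgression, and both must be modelled to
judge how many transitions an incongruent trait actually required.

`hemicoal` implements two complementary approaches:

* an **analytic model** for a rooted three-taxon network ((A,B),C) with a
  single instantaneous introgression pulse between B and C, giving exact
  probabilities of hemiplasy ($P_e$) and homoplasy ($P_o$); and
* a **simulation pipeline** for arbitrary ultrametric trees and pulse sets:
  coalescent gene trees, a Poisson binary-trait overlay, focal-locus
  filtering against the observed trait pattern, and summaries against a
  Fitch-parsimony baseline — plus `subs2coal`, a concordance-factor
  regression that converts substitutions/site trees into coalescent units.

## The analytic model

Time runs backwards in coalescent units (2N generations): `t1` is the A/B
split, `t2` the split of C from the A/B ancestor, and an instantaneous
pulse at `tm < t1` moves a locus between B and C.  A locus follows the
species history (parent tree 1) with probability $1 - (\delta_2 +
\delta_3)$, the C$\to$B history (parent tree 2, B and C sister from `tm`,
joined by A's lineage at `t2`) with probability $\delta_2$, and the
B$\to$C history (parent tree 3, where tracing C through B lets it meet A
already at `t1`) with probability $\delta_3$.

Within each parent tree the multispecies coalescent produces four gene-tree
classes: one by lineage sorting of the sister pair inside its internal
interval, three equiprobable ones by ILS above it.  Each class carries five
branches — tips $\lambda_1,\lambda_2,\lambda_3$ to A, B, C, the internal
branch $\lambda_4$, and the ancestral branch $\lambda_5$ above the
gene-tree root.  With mutation probabilities $\nu(\lambda_i, \tau)$,

$$P_e = \sum_{\tau:\ \mathrm{BC\ sister}} p(\tau)\,
  \nu(\lambda_4, \tau) \prod_{i \ne 4} (1 - \nu(\lambda_i, \tau)),$$

$$P_o = \sum_{\tau} p(\tau) \Big[
  \nu(\lambda_2, \tau)\,\nu(\lambda_3, \tau)
     \prod_{i \ne 2,3}(1 - \nu(\lambda_i, \tau))
  + \nu(\lambda_5, \tau)\,\nu(\lambda_1, \tau)
     \prod_{i \ne 1,5}(1 - \nu(\lambda_i, \tau)) \Big],$$

the two homoplasy routes being parallel forward mutations on the B and C
tips, or a forward mutation ancestral to everything followed by a reversal
on A's tip.

### Mutation probabilities

$\nu$ is the probability of at least one event of a Poisson process run at
rate $\theta/2$ per coalescent unit along the branch, *integrated over the
exact marginal coalescent density of the branch length* (truncated
exponentials for lineage-sorting classes, Exp(3)+Exp(1) stages for ILS
classes), not evaluated at the expected length.  All integrals close in
elementary form; `gene_tree_classes()` exposes the twelve classes with
their probabilities and $\nu$ values, and the Monte-Carlo cross-check
(`simulate_pepo()`) validates them against brute-force simulation.

### The ancestral branch and `root_depth`

The branch above the gene-tree root must be finite for the
mutation-plus-reversal route to have a probability.  We bound the model in
a bookkeeping box of total height `root_depth`, so $\lambda_5 =
\max(0, \mathrm{root\_depth} - T_\mathrm{root})$.  The default,
`default_root_depth` = 16.94052077 coalescent units, is calibrated once so
that the ILS-only model reproduces the published baseline
$P_e/P_o = 0.818$ at `t1 = 1`, `t2 = 3.5`, `theta = 0.002`; it is a model
parameter and can be changed.  Because the box height is fixed, more
recent introgression simultaneously lengthens discordant internal
branches, shortens the B and C tips, and leaves more room above the root —
each of which tilts the balance toward hemiplasy.

```{r baseline}
net <- three_taxon_network(t1 = 1, t2 = 3.5, theta = 0.002)
pepo_ratio(net)
```

`pepo_grid()` scans $P_e/P_o$ over admixture proportions and pulse
timings for the three direction conventions (`"CtoB"`, `"BtoC"`,
`"both"`).  In the `"both"` panel the x-axis is the *total* admixture
proportion split evenly across directions ($\delta_2 = \delta_3 =
\delta/2$), so the three panels share a scale; `split_both = FALSE`
switches to per-direction proportions.  On this grid the ratio increases
with the admixture proportion, increases as the pulse becomes more recent,
and is uniformly lower for B$\to$C than for C$\to$B pulses — the parent
tree 3 window `t1 - tm` is always narrower than `t2 - tm`, giving more
residual ILS and shorter internal branches.

## The simulator

`species_network()` holds a rooted ultrametric tree (ape `phylo`,
coalescent units, ultrametricity tolerance 1e-6) plus pulses.  Simulation
is a backwards-time structured coalescent with one haploid sample per
species: within a population, $k$ lineages coalesce at rate $k(k-1)/2$;
populations merge at species-tree nodes; at a pulse time every lineage in
the recipient population follows the reticulation edge into the donor
population with the pulse probability.  Pulses at distinct times act
independently and a locus records the set of reticulation edges it took.
Pulses *sharing* a time are treated as exclusive alternatives (at most one
fires per locus), because a locus cannot follow two introgressed
histories at one instant; their probabilities must sum to at most 1.
Population size is constant and equal across branches, and time is in 2N
generations end to end — there is no 4N rescaling anywhere.

The core loop is compiled (Rcpp) and streams loci, so runs of $10^7$
trees use constant memory; larger totals are accumulated by pooling
chunked runs with distinct seeds.  Identical seed and configuration give a
byte-identical Newick stream.

## The trait overlay and the pipeline

`evolve_trait()` lays a symmetric two-state Poisson process (rate in
events per 2N generations) with explicit mutation events on each branch;
the root state is 0 and every event flips the state.  Relative to
inferring mutation counts from simulated nucleotide sites, explicit events
make counts exact; multiple hits on one branch are still possible and are
what makes simulated hemiplasy fall slightly short of the analytic value
at high rates.

`run_hemiplasy()` glues everything together: optionally prune to the
smallest clade containing the derived taxa plus the outgroup, simulate,
overlay, keep the loci whose derived tip set matches the observed pattern
exactly (state matching — back-mutation routes count; the outgroup must be
ancestral), and summarize.  The Fitch score of the pattern on the
(pruned) species tree is the homoplasy-only baseline: one mutation is
hemiplasy-only, counts between one and the Fitch score are mixed, counts
at or above it are parsimony-equivalent.

## Benchmark conditions

`make_condition()` reproduces a ladder of four-taxon conditions
(((t4,t3),t2),t1) with derived taxa t4 and t2: `ILS1`–`ILS3` shorten the
internal branch (2N, 1.5N, N generations); `INT1`–`INT3` add a pulse from
t2 into t4 at 0.6N generations with probability 0.01/0.05/0.1;
`INT4`–`INT6` hold the probability at 0.1 and move the pulse to
0.4N/0.2N/0.1N; `CGF1`–`CGF5` jointly raise the pulse probability and
recency while lengthening the internal branch so the frequency of the
discordant topology grouping the derived taxa stays approximately
constant.  Condition times are stated in N generations and divided by two
at construction.  The root is pinned at 8N (= 4 coalescent units) for all
conditions; the age of the t2 split, which the condition table leaves
open, is fixed at 1.75 coalescent units — a one-time least-squares choice
that makes the CGF design's constancy as tight as its printed parameter
sets allow (residual spread about 2.6%, so constancy is approximate by
design and is tested at the 10^5-tree replicate scale).  The default
benchmark mutation rate is 0.05 per 2N generations, with
0.0005–0.05 used for rate sweeps.

## subs2coal

Internal branches of a species tree annotated with concordance factors can
be measured in two unit systems at once: their substitutions/site length,
and the coalescent length implied by the quartet expectation
$\mathrm{CF}(T) = 1 - \tfrac{2}{3}e^{-T}$.  `fit_conversion()` inverts
the CFs ($T = -\log\tfrac{3}{2}(1 - \mathrm{cf})$; values $\le 1/3$ are
excluded, values $> 1$ are read as percentages) and regresses $T$ on the
substitutions/site lengths by OLS; `predict_tips()` converts tip branches
with the fitted line or a 95% t-based prediction-interval bound, flagging
tips that require extrapolation beyond the fitted range and flooring
non-positive predictions at 1e-6.  Two smoothing methods restore
ultrametry: `redistribute` spaces each root-to-tip path's levels evenly
(top-down: a child at `levels` edges above its deepest tip receives
`age(parent)/(levels+1)`), while `extend` lengthens only tip branches and
preserves every internal branch exactly.  An outgroup can be excluded from
smoothing and re-grafted afterwards at a depth proportional to its
original substitutions/site attachment (scaled by the fitted slope,
floored just above the ingroup height) — useful when the regression would
otherwise predict an absurdly long outgroup stem.  Both smoothing
operations bias branch lengths upward relative to the truth, which lowers
discordance and parallel-mutation opportunity alike; the round-trip test in
the suite confirms the resulting hemiplasy estimates are conservative.

Note a floating-point boundary: CF values near 1 carry limited
information, so the CF$\to$T inversion is accurate to 1e-12 only up to
roughly $T = 8$; beyond that one ulp of the stored CF already moves $T$ by
more than 1e-12.

## Synthetic study fixtures

The package ships constructed stand-ins for two published case studies,
clearly labelled synthetic: a 15-taxon skink-like clade in which six
green-blooded taxa require four transitions on the species tree while
near-star internal branches (0.005 coalescent units) make discordance
pervasive, and a seven-taxon butterfly-like network in which four taxa
share a derived chromosomal arrangement in two clades (Fitch score two)
with two pulses totalling probability 0.201 connecting the carriers.
Their geometries are design choices, not estimates from data: the skink
stand-in pairs a 0.05 events/2N trait rate with its near-star clade so
that a desk-scale run of a few million loci yields enough focal trees to
examine, and the acceptance suite asserts only reproducible qualitative
findings on them — one- and two-mutation histories dominate the skink
pattern, and a single origin dominates the butterfly pattern with
introgressed histories enriched among focal loci above the 0.201 input
total.  Matching published conditional percentages would require the
original empirical trees.

## What the simulations do and do not emulate

The generator draws neutral, unlinked, recombination-free loci with one
haploid sample per species, constant population size, a strict molecular
clock for the trait process, and symmetric 0/1 rates.  Real data add
linked selection, per-branch population sizes, rate variation, and errors
in tree, concordance-factor and branch-length estimation; of these, only
the estimation-error pathway is exercised here (through the `subs2coal`
round trip).  Passing tests therefore validate the mathematics and the
machinery, not the biological fidelity of any particular empirical input.

## Numerical and design notes

* Closed-form $\nu$ integrals use `expm1`-stable forms; the two removable
  singularities (rate equal to 1 or 3 per coalescent unit) are bridged by
  limits.
* Problem sizes in the test suite — $10^5$-tree topology checks, $10^6$
  loci per oracle network, ten $10^5$-tree replicates per benchmark
  condition, a few $10^6$ loci for the study fixtures — were chosen so the
  full suite completes on a laptop-class single core while every
  stochastic assertion retains a three-standard-error margin.
* The simulation oracle's hemiplasy count (focal loci with exactly one
  mutation) is bounded above by the analytic $\nu$-product (which counts
  "at least one" hits), so the analytic-minus-simulated discrepancy is
  non-negative and shrinks with $\theta$; the acceptance suite asserts
  exactly this.
* `derived_clade_count()` counts maximal all-derived clades; it is
  cross-checked against an exhaustive partition search over set
  partitions using an independent monophyly test.
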