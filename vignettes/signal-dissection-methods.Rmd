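---
title: "Dissecting conflicting phylogenomic signal: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting conflicting phylogenomic signal: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Concatenated plastome phylogenies often return strongly supported but
mutually incompatible resolutions of a focal clade depending on which loci,
codon positions or inference method is used. In the Selaginellaceae
subfamily Gymnogynoideae this happens for the placements of *Ericetorum*
and *Gymnogynum*: coding, intergenic and codon-filtered datasets each pull
toward different arrangements of the six genera. `phylodissect` implements
the analysis chain used to dissect such conflicts: it quantifies how much
support every site and every locus lends to each candidate resolution,
removes the few loci whose signal is extreme enough to dominate the
concatenation, re-evaluates, counts gene-tree concordance per internode,
reconstructs discrete characters on the resolved tree, and classifies the
plastome repeat architectures that one of those characters encodes.

# Site- and gene-wise likelihood signal

## Model

All likelihood computations use a general time-reversible substitution
model with discrete-Gamma rate heterogeneity (GTR+Γ). The rate matrix is
built as $Q_{ij} = r_{ij}\pi_j$ for $i \ne j$ with the six
exchangeabilities $r_{ij}$ and stationary frequencies $\pi$, rescaled so
the expected rate at stationarity is one; branch lengths are therefore in
expected substitutions per site. Among-site variation uses $k = 4$ discrete
categories whose rates are the means of the quantile classes of a
Gamma($\alpha$, mean 1) distribution, the field-standard discretization.
$k = 1$ disables heterogeneity. Gap, `?` and `N` symbols are fully missing
(partial likelihood 1 for every state); IUPAC ambiguity codes restrict the
state set.

Per-site log-likelihoods are computed by Felsenstein's pruning algorithm
over unique site patterns, with per-node rescaling so 39-taxon saturated
alignments cannot underflow. The engine is validated against exhaustive
enumeration over internal-node states and rate categories on small trees
(tolerance 1e-8, typically agreeing to machine precision) and against an
independent implementation (`phangorn::pml`) on shared models.

## Fixed-topology evaluation

Given a dataset and $k \in \{2,3,4\}$ labeled topology hypotheses
`T1..Tk` over the same taxa, branch lengths are optimized independently for
each hypothesis on the full concatenation by round-robin single-branch
Brent maximization (bounds $[10^{-6}, 10]$, log scale, sweeps until the
total log-likelihood improves by less than `tol`, default $10^{-6}$, at
most 100 sweeps). Bounds that tight at the low end matter because a wrong
resolution typically collapses its conflicting internode toward zero. Free
model parameters are by default estimated once on the reference hypothesis
T1 (empirical base frequencies; exchangeabilities and $\alpha$ by numerical
maximization) and then held fixed across hypotheses, which isolates the
topological component of the signal; a ready model can be supplied instead,
and re-estimation forced. Whether branch lengths are re-optimized per
hypothesis or taken from the input trees is likewise switchable; the
default re-optimizes.

## ΔSLS, ΔGLS, votes and proportions

With per-site log-likelihoods $\ell_s(T_j)$ recorded for every hypothesis,
the package computes, for each alternative $j \ne 1$:

* per site: $\Delta\mathrm{SLS}_j(s) = \ell_s(T_1) - \ell_s(T_j)$, positive
  values supporting the reference;
* per locus: $\Delta\mathrm{GLS}_j = \sum_{s \in \text{locus}}
  \Delta\mathrm{SLS}_j(s)$, and the length-corrected mean
  $\Delta\mathrm{SLS}_j / L$ used everywhere a locus-level comparison could
  otherwise be dominated by locus length.

Every site and locus casts a vote for its argmax hypothesis; two
hypotheses within $10^{-6}$ log-units are a tie and the vote is
"ambiguous". Ambiguous votes are excluded from the proportion denominators
but counted and reported. Proportions over several datasets can be pooled
by summing vote counts (the default) or reported per dataset; both are
provided because pie-style summaries in the literature rarely state which
was used.

## Outlier loci and the pruned-dataset ladder

Outlier loci are detected per comparison on the per-locus mean ΔSLS values
with the boxplot rule: quartiles by linear interpolation (type 7, the
default of mainstream numeric stacks), fences at $Q_1 - 1.5\,\mathrm{IQR}$
and $Q_3 + 1.5\,\mathrm{IQR}$, and a locus is an outlier for a focal clade
if it falls outside the fences for any comparison in that clade's
hypothesis set. From each basic dataset the ladder then derives pruned
datasets: one per focal clade (removing that clade's outliers) and one
removing the union, and recomputes the signal on each. With four basic
datasets and two focal clades this yields the 16-dataset, 12-analyses-per-
clade layout familiar from plastome conflict studies; a manifest records
the provenance (parent dataset, pruning clade, removed loci) of every
derivative.

A statistical caveat that users should know: on null data whose per-locus
mean ΔSLS is approximately normal — which the central limit theorem
guarantees for loci of a few hundred independent sites — the 1.5 IQR rule
intrinsically flags about 0.7–1% of loci per comparison. Across 50 loci
that is roughly a one-in-three chance of at least one spurious flag per
analysis, independent of every scale parameter (the fences scale with the
IQR). Planted strong-signal loci are recovered essentially always in the
package's replicated experiment (`outlier_planting_experiment()`), but the
flagged set should be reviewed, not consumed blindly.

# Gene-tree concordance and internode certainty

Gene trees are compared to a reference tree bipartition by bipartition,
treating all trees as unrooted; a fixed anchor taxon canonicalizes splits.
For each reference internode, each gene tree is restricted to its own
taxon set: the restricted split can be present (concordant), incompatible
with some gene-tree split (conflicting, with the conflicting bipartition
recorded), or neither — too few shared taxa or an unresolved gene tree —
which counts as uninformative. Weakly supported gene-tree edges can be
collapsed to polytomies before counting (threshold 0 by default, because
no universal support cutoff exists; 50 is the common ultrafast-bootstrap
choice); collapsing can only move gene trees from conflicting to
uninformative, never create new conflict.

Internode certainty over all conflicting bipartitions (ICA) is computed
from the concordant count $c_0$ and the counts $c_1..c_m$ of every
distinct conflicting bipartition observed:
$\mathrm{ICA} = 1 + \sum_i p_i \log_n p_i$ with $n = m + 1$ and
$p_i = c_i / \sum c$, defined as 1 with no conflict and negated when the
reference split is not the strict plurality. The implementation is checked
against hand evaluations, including the characteristic values 1 (no
conflict), 0 (even split) and ≈0.30 for a 60-vs-14 split.

# Discrete-character evolution (Mk, equal rates)

Habit (hydrophyte / xerophyte / mesophyte) and plastome master structure
(DR / IR / NR / DR–IR) are modeled as $k$-state equal-rates Markov chains,
whose transition probabilities have the closed form
$P_{ii}(t) = 1/k + (k-1)/k\,e^{-kqt}$,
$P_{ij}(t) = 1/k - 1/k\,e^{-kqt}$. The single rate $q$ is fitted by
maximizing the pruning likelihood with the uniform root prior (the ER
stationary distribution, matching common practice) via Brent search on
$\log q$; only the product $q \times \text{branch length}$ is identifiable,
so an option rescales trees to unit height when absolute rates are not of
interest. Marginal ancestral probabilities come from the standard two-pass
(downward conditional, upward complement) dynamic program and are verified
against exhaustive enumeration. Stochastic character maps sample node
states from the joint conditional distribution root-down, then realize
per-branch change counts by uniformization; their node-state frequencies
converge to the marginals, which the tests assert at three Monte-Carlo
standard errors with 2,000 maps. Missing tip states are uninformative.
Branch lengths are taken from the input tree as-is.

# Plastome repeat architecture

Large repeats are found by exact $k$-mer seeding (default seed 31 bp) on
the doubled sequence — which makes the search circular — for both the
forward/forward (direct) and forward/reverse-complement (inverted)
comparisons, followed by maximal extension and deduplication of seeds on
the same diagonal; an optional mismatch budget (≤5%) merges near-exact
copies. The finder is validated against a quadratic shift-and-compare
oracle on fixtures up to 20 kb, including repeats straddling the origin.

A genome's master structure is the architecture of its qualifying repeats
(default: ≥500 bp at ≥99% identity; the threshold is a prominent knob
because published repeat lengths span 364 bp to 18 kb and no universal
cutoff exists): none → NR; inverted only → IR; direct only → DR; both →
DR–IR. The expected conformation count is a fixed function of the type —
1, 2, 1 and 3 respectively — reflecting the isomers reachable by
homologous recombination between repeat copies; note this is the count
implied by architecture, which assembly-graph evidence may refine. The two
single-copy segments between the dominant pair's copies are labeled LSC
and SSC purely by length. Feature summaries add GC content over non-N
positions, gene/tRNA/rRNA counts from an optional annotation table, and
the ribosomal-operon copy number obtained by clustering rRNA genes with a
5 kb circular gap threshold — which is what makes a single-operon,
repeat-free genome recognizable directly from its annotation.

# The synthetic-data generator

Every stage is testable offline because the package generates its own
inputs with known truth:

* **Conflicting loci.** A `generator_spec` holds a labeled hypothesis set
  with branch lengths, a mixture over hypotheses, locus count and length
  distribution, a GTR+Γ model and a branch-length multiplier. Each locus
  draws its generating topology from the mixture and evolves i.i.d. sites
  root-to-tips; a truth table records the assignment. The bundled
  Gymnogynoideae-style preset has one tip per genus plus an outgroup,
  tip branches of 0.1–0.2 and internodes of 0.08–0.1 substitutions/site —
  a moderately divergent regime in which a few-hundred-bp locus usually
  carries recoverable signal about the focal resolution — and defaults of
  74 loci of 200–2,000 bp with Γ shape 0.5, echoing the scale of plastid
  locus sets; an expansion option gives several tips per genus. Desk-scale
  validation runs use 100 × 500 bp (pure-signal recovery) and
  1,000 × 1,000 bp (70/30 mixture recovery), sizes at which vote
  proportions are estimated to within a few percent in about a minute of
  CPU.
* **Traits** evolve by the ER closed form along the tree; two-state change
  probabilities and the stationary limits are asserted against theory.
* **Plastomes** are uniform random circular sequences, rejection-sampled so
  the background contains no chance repeat at the classifier's threshold,
  with exact (reverse-complemented if inverted) repeat pairs planted at
  recorded coordinates, well separated around the circle.

Reproducibility follows one rule: every generator is a pure function of
its spec and a root seed, and per-locus/replicate streams derive from the
root seed by a fixed counter scheme (`child_seed`), so locus $i$ is
identical no matter how many loci are requested.

What the generator deliberately does **not** emulate: indels and alignment
error (gaps appear only through the missing-data mask, which blanks whole
locus-by-taxon blocks the way failed assemblies do), among-locus rate
variation beyond the global branch-length multiplier, intra-locus
recombination, RNA editing, and base-compositional heterogeneity across
lineages. Passing tests on synthetic data therefore demonstrates that the
statistics are computed correctly and recover known signal under the
model's assumptions — not that those assumptions hold for any particular
empirical alignment.

# Numerical choices and degenerate inputs

* Branch lengths are bounded to $[10^{-6}, 10]$; identical sequences drive
  estimates to the lower bound rather than zero.
* Conditional likelihoods are rescaled per node; pattern compression keys
  the alignment columns, capping cost on long concatenations (a 7-taxon
  alignment has at most $4^7$ patterns however many sites are
  concatenated).
* Vote ties use a $10^{-6}$ log-likelihood tolerance; two topologies that
  optimization renders indistinguishable (e.g. both collapse to the same
  polytomy) vote "ambiguous" rather than arbitrarily.
* An invariant trait drives $\hat q$ to its lower bound with a warning
  instead of failing; a gene tree sharing fewer than four taxa with the
  reference is uninformative at every internode and logged as such.
* Repeat copies covering more than 90% of a genome are rejected as
  degenerate rather than classified.
* Coordinates are 0-based half-open internally everywhere; 1-based
  inclusive appears only in the RAxML partition dialect and annotation
  tables at the file boundary.

# Known limitations

The likelihood engine evaluates fixed topologies only — there is no tree
search, model selection, or support estimation; hypothesis trees come from
upstream inference. The ER model is the only trait model (no asymmetric or
hidden-rate variants), matching its use for these characters. Conformation
counts are architectural expectations, not isomer observations. The
concordance module counts bipartitions, not quartets, so nested conflict
attribution follows the PhyParts convention. Runtime is adequate for
desk-scale replication (minutes, one core) but this is not a
high-performance engine for hundreds of taxa.
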