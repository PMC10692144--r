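---
title: "Models and methods behind smtphylo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind smtphylo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smtphylo)
```

# The inference chain

`smtphylo` reconstructs the evolutionary history of a patchily distributed
animal gene family — the motivating case is the 24-C sterol
methyltransferase (*smt*), the enzyme that methylates carbon 24 of the
sterol side chain and turns a C27 sterol into C28 and C29 sterols. Most
eumetazoans lack the gene; a handful of groups (annelids, rotifers, stony
corals, sponges) carry it. Two hypotheses compete: vertical inheritance
from the animal ancestor followed by massive loss, or repeated horizontal
acquisition. Distinguishing them requires a chain of inferences, each of
which this package implements as a tested, reusable module:

1. **Domain screening** — candidate homologs from transcriptome archives
   are classified by whether they carry both conserved domains
   (methyltransferase + C-terminal), the two domain regions are extracted
   and concatenated, and same-species redundancy is removed at a 90%
   identity cutoff.
2. **Contamination vetting** — shotgun transcriptome assemblies are
   notoriously contaminated by diet and symbionts. A candidate is kept
   only if it sits in a gene-tree clade where two or more genera of one
   phylum group together; within such clades, wrong-phylum members are
   flagged as probable contaminants and near-identical same-species
   members as redundant.
3. **Reconciliation** — the vetted gene tree is rooted and reconciled with
   the species tree under duplication–loss parsimony; poorly supported
   branches are rearranged to the most parsimonious configuration, and
   surviving duplications are classified as species-specific or
   multi-species.
4. **Dollo loss mapping** — gene presence/absence across taxa is explained
   by a single gain (at the MRCA of the carriers) plus the minimum number
   of losses.
5. **Relaxed-clock dating** — node ages of the fixed, reconciled topology
   are estimated by MCMC under an LG+Γ4 amino-acid likelihood, an
   uncorrelated lognormal clock, a Yule tree prior and lognormal fossil
   calibrations.

# Vetting: parameters and their meaning

The vetting rule has three tunables (`vet_params()`):

* `min_genera` (default 2) — a clade counts as evidence only if the
  majority phylum is represented by at least this many distinct genera.
  Two independent genera is the weakest signal that cannot be produced by
  a single contaminated library.
* `majority_fraction` (default 2/3) — the fraction of clade leaves the
  majority phylum must reach. A strict 100% monophyly requirement would
  be self-defeating: the whole point is to find wrong-phylum members
  *inside* otherwise coherent clades and remove them. The default
  tolerates one intruder in a clade of three while still requiring a
  clear majority.
* `redundancy_threshold` (default 0.90) — same-species sequences above
  this identity (exact-match fraction over the shorter sequence at the
  best un-gapped offset, a desk-scale version of greedy
  longest-first clustering) collapse to their longest representative.

Nested qualifying clades are suppressed in favour of the largest, so each
leaf is judged exactly once; the report always partitions the input
leaves into accepted and rejected (`no_clade`, `wrong_phylum`,
`redundant`, or `genome_absent` when external genome evidence is
supplied).

# Reconciliation conventions

Gene-tree nodes are mapped to species-tree nodes by the LCA rule; a node
is a duplication when one of its children maps to the same species node,
and losses follow the standard depth-difference rule (a child edge whose
image sits `k` levels below its parent's image implies `k − 1` losses
under a speciation and `k` under a duplication). Duplications and losses
are weighted equally when scoring rearrangements.

Rearrangement collapses internal edges with support below
`support_threshold` (default 0.9 — the source analyses do not report
their cutoff, so it is exposed and logged) and re-resolves each polytomy
to minimize total cost: exhaustively up to degree 6 (at most 945 candidate
resolutions), greedy stepwise insertion above that. The original
resolution is always among the candidates, so the output never costs more
than the input. Branch lengths are dropped on rearranged trees — the
original estimates no longer apply, and the clock stage re-estimates
everything on the fixed topology.

Rooting uses the outgroup when one is given and forms a bipartition side;
otherwise every edge is tried and the minimum-cost rooting wins, ties
broken by edge order.

Dollo mapping fixes the gain at the MRCA of the present taxa — the
single-origin, vertical-inheritance scenario — and counts the maximal
all-absent subtrees below it. This equals Sankoff small parsimony with a
prohibitive gain cost, which the test suite verifies on 1000 random
instances.

# The relaxed clock

The likelihood is Felsenstein pruning over the fixed rooted topology with
branch length = branch rate × branch duration, under the published LG
exchangeabilities and frequencies (embedded as constants, scaled to one
expected substitution per site) with 4 equal-probability discrete-gamma
categories using mean-of-category rates (the more common convention;
categories average exactly 1). The kernel is a small C++ routine with
per-node rescaling; site patterns are compressed before evaluation.

Time is parameterized relatively: branch rates are independent lognormal
draws whose log-mean is fixed at −σ²/2, so the expected rate is exactly 1
and fossil calibrations supply the absolute scale — the standard
node-dating arrangement. Priors:

* node ages — Yule with birth rate λ: each internal node contributes
  `log λ − λ·age`, the root one extra `−λ·age` term (for two taxa this is
  an exponential density on the root age);
* calibrations — lognormal on (age − offset) with a hard minimum at the
  offset;
* hyperpriors — `gamma_shape ~ Exp(1)`, `rate_log_sd ~ Exp(3)` (mean 1/3),
  `birth_rate ~ Exp(0.1)` (diffuse).

The Metropolis–Hastings move set comprises bounded uniform node-age
slides, a root-age scale, a **whole-tree age scale**, single-branch rate
multipliers, and scale moves on the three scalars, each with its proper
proposal-ratio term. The whole-tree scale is essential: without it the
sampler has no move that contracts or dilates the global time scale
against the calibrations (node slides are parent/child-bounded and the
root move only stretches the gap above the oldest child), and the
parameter-recovery experiment fails to converge. There are no topology
moves — the topology is fixed by the upstream inference, and the clock is
a dating device only.

Traces include the generation-0 state (length `⌊n_gens/sample_every⌋+1`);
summaries discard a 25% burn-in (floor of the sample count), report
per-node posterior medians and 95% HPD intervals (shortest interval
containing 95% of the sorted sample), and assemble a dated consensus tree
from the medians with a monotonicity clamp (marginal medians can
occasionally invert a parent–child pair by a hair).

The pipeline default is 200,000 generations sampled every 100 — a
desk-scale setting; production-style runs can raise `clock_gens` freely.
The package's own validation uses 16 taxa × 300 sites with 8,000
generations per replicate, which recovers strict-clock root ages within
15% in at least 8 of 10 replicates and keeps the whole suite within a
coffee break.

# What the simulator emulates — and what it does not

`sim_config()` defaults define the study conditions used throughout the
tests: a focal fauna of 3 phyla × 3 genera × 2 species (18 species; small
enough for exhaustive oracles, rich enough to exercise the two-genera
rule), a donor pool of 2 extra phyla placed as an outgroup supergroup,
10% per-species contamination, lognormal rate spread σ = 0.3, 200-site
proteins, and a 20% partial-sequence fraction.

Species trees follow a Yule construction built backward from the tips:
while `k` lineages remain, the next merge lies `Exp((k−1)λ)` earlier, so
the two-taxon root age is exponential with mean `1/λ`. In
taxonomy-structured mode, merge partners are chosen within genera before
genera merge within phyla, so the taxonomy plan comes out monophyletic —
a deliberately clean species phylogeny for benchmarking the vetting rule.
Gene families evolve inside the dated species tree by per-copy
duplication and loss; extinct copies are pruned and the observable event
log is retained as truth. Contaminants are verbatim copies of donor
sequences relabeled into a focal species' id space, so identity-based
screens cannot trivially win — the phylogenetic screen has to do the
work.

Real data differ in ways the simulator does not capture: alignment and
assembly error, compositional heterogeneity across lineages, domain-level
rate variation, incomplete lineage sorting, and genuinely ambiguous
taxonomy. Passing the synthetic benchmarks therefore shows the
*algorithms* are correct and calibrated under their stated model, not
that any particular real dataset will be this clean.

# Numerical choices

* Support dialect: numeric internal-node labels in (1, 100] are divided
  by 100; values in [0, 1] are kept. Both bootstrap-percentage and
  posterior-probability dialects occur in the wild.
* NJ negative branch lengths are clamped to zero; saturated corrected
  distances cap at 5 substitutions/site (configurable).
* All randomness flows from explicit integer seeds; there is no hidden
  global state, and every simulator output is byte-reproducible per seed.
* Degenerate inputs fail loudly: empty trees, duplicate leaf labels,
  polytomies handed to the duplication counter (the error points to
  `rearrange`), burn-ins that consume a whole trace, calibrations that
  resolve to a tip.

# Known limitations

Vetting sensitivity is bounded by gene-tree quality; the bundled NJ +
bootstrap builder is a desk-scale stand-in for maximum-likelihood
inference, and clades misplaced by NJ are judged as such. The clock's
move set is minimal by design (no topology moves, no correlated-rate
models), and HPD intervals assume a unimodal marginal. The Dollo mapper
deliberately refuses to consider horizontal transfer — it answers "how
many losses would vertical inheritance require", which is exactly the
quantity of interest when weighing that hypothesis.
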