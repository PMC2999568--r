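---
title: "Models and methods behind hmgtrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind hmgtrace}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

hmgtrace asks a single scientific question with several statistical tools:
is the fungal mating-type α1 domain a derived member of the HMG-box
superfamily — specifically, does it nest *inside* the fungal MATA_HMG
class rather than beside it? This vignette explains each model and
procedure, its assumptions, the tunable parameters, and the design
decisions taken where more than one defensible choice existed. It states
no empirical result beyond what the package's tests and acceptance script
themselves compute.

## The core region and its profiling

All inference operates on a conserved core of roughly 40 aligned residues
shared by α1 and HMG domains. The profiling stages mirror standard
practice:

* **Progressive alignment.** A UPGMA guide tree is built on the distance
  `1 − |shared k-mers| / min(|A|, |B|)` over sets of distinct k-mers
  (default k = 3); sequences are then merged bottom-up by profile–profile
  global alignment. A column pair scores the expectation of the BLOSUM62
  substitution score under the two column frequency vectors; gaps cost
  `open + L·extend` with open 11, extend 1 (the BLASTP defaults). This is
  a deliberately plain progressive aligner: it makes no claim to reproduce
  any specific external aligner's output, and externally aligned FASTA is
  accepted everywhere an alignment is.
* **Coverage filter.** A row is dropped when its non-gap residue count
  over the core columns is *strictly below* 80% of the core length:
  a 32/40 row is kept (0.800 ≥ 0.8), a 31/40 row is removed. The
  at-threshold case is kept because the rule is phrased as "less than 80%
  … removed". The filter is idempotent.
* **Gappy-column removal.** Columns whose gap fraction exceeds 0.5 are
  deleted. The 0.5 default removes insert blocks carried by a minority of
  rows (the HMGB-style variable section) while preserving any column in
  which at least half the rows carry residues — which is exactly the set
  of columns a consensus can be estimated from.
* **Profiles and consensus.** Column frequencies are
  `(count + pseudocount) / (non-gap total + 20·pseudocount)`; gaps and
  `X` are treated as missing and enter no denominator. Information
  content is `log2(20) − H` bits, the height a sequence logo assigns to a
  column; an all-gap column is flagged and reported as uniform with zero
  content. The consensus takes the modal residue per column, breaking
  ties alphabetically by one-letter code — a deterministic,
  input-order-independent rule; ties are genuinely ambiguous and any
  fixed rule is as defensible. The default pseudocount is 0 so that
  consensus calls match what a logo displays; downstream probabilistic
  uses would take a small positive value (0.05) to avoid zeros.

## Consensus comparison statistics

Two consensus (or ancestral) sequences are compared by local affine-gap
alignment under BLOSUM62 (open 11 / extend 1). Identity is the fraction
of aligned pairs with equal residues; *positives* are aligned pairs with
a strictly positive matrix score, the BLAST notion of "identical or
similar". Significance uses the Karlin–Altschul formula
`E = K·m·n·exp(−λS)` with the standard gapped BLOSUM62 constants
λ = 0.267, K = 0.041 and the two sequence lengths as the search space.
These E-values are pairwise-mode order-of-magnitude statements, not
database-search E-values: no composition adjustment is made, and the
constants are configuration, not estimates. Internally each pair is
aligned in a canonical order so that tie-broken alignment optima — and
hence identity and positive counts — do not depend on which sequence is
called query.

## The substitution model

The evolutionary model is LG (Le & Gascuel 2008): a reversible 20-state
Markov process `q_ij = s_ij π_j` built from the published exchangeabilities
and stationary frequencies (embedded as constants), normalized to one
expected substitution per unit branch length. Transition matrices come
from a cached eigendecomposition of the symmetrized generator, so
`P(t) = U e^{Λt} U^{-1}` is exact and cheap at any t.

Rate heterogeneity uses the discrete-gamma approximation: Gamma(α, α)
(mean 1) split into k equal-probability categories, each represented by
its *mean* rate, computed in closed form from incomplete-gamma
differences. Means (not medians) keep the average rate exactly 1 at any
k. Four categories is the field's default and is used throughout; k = 1
reduces the model to plain LG exactly. The α parameter is bounded in
[0.02, 100] during optimization (Brent search on log α, tolerance 1e-4 in
lnL terms); LG+I+G adds an invariant-site spike with proportion
p_inv ∈ [0, 0.9), and p_inv = 0 reduces it to LG+G exactly. Model choice
is by AIC with candidates warm-started in nesting order (LG → LG+G →
LG+I+G) so that the maximized log-likelihoods respect nesting even under
a finite number of coordinate-ascent cycles.

## Likelihood, tree search and supports

Site likelihoods come from Felsenstein pruning over the rate mixture,
with gaps and `X` as missing data (partial vectors of ones) and per-site
rescaling against underflow. The compiled core also maintains, for every
edge, the two flanking partial-likelihood vectors ("down" partials below
the edge, "up" messages from the rest of the tree). The tree likelihood
as a function of one branch length is then an inner product, so each
branch proposal is an exact one-dimensional maximization with everything
else held fixed. Branch-length rounds apply all proposals jointly when
that helps and otherwise fall back to the best single exact update, so
the log-likelihood never decreases; bounds are [1e-8, 50] expected
substitutions per site.

The topology search is deliberately simple and matches the "local
rearrangement" spirit of the support measure: a neighbor-joining start on
pairwise ML distances (each pair's distance maximizes the two-sequence
likelihood under the full mixture model; non-overlapping pairs are capped
and flagged), then hill-climbing over nearest-neighbour interchanges.
Each NNI candidate is scored by exactly re-optimizing the central branch;
the best improving move is accepted (ties to the first in deterministic
edge order), branch lengths are re-optimized, and the search stops when
no move gains more than 1e-3 lnL. No SPR/TBR, no Bayesian sampling.

**LR-ELW edge support.** For each internal edge the three topologies of
its NNI neighbourhood (current plus two rearrangements, the rearranged
trees locally re-optimized around the edge) are compared by expected
likelihood weights under RELL resampling: sites are drawn with
replacement, per-site log-likelihoods re-summed without re-optimization,
and weights `w_j = exp(lnL_j − max)/Σ` averaged over replicates. The
support is 100 × the mean weight of the maximum-likelihood topology. The
exact algorithm behind the original "LR-ELW" label is not published in
detail; the NNI-neighbourhood ELW used here is the closest published
interpretation. Supports are deterministic for a fixed seed; 1000
replicates give stable values at desk scale and a warning is issued below
100. Because the two rearranged topologies receive only local
branch-length re-optimization, their likelihoods are if anything slightly
underestimated, so supports err on the generous side for the current
topology; full re-optimization was measured to change topology decisions
not at all at twice the cost.

**KH and SH tests.** Candidate topologies are branch-length-optimized,
their per-site log-likelihoods RELL-resampled (default 10,000
replicates), and each topology compared with the best: KH as a two-sided
test on the centred resampled log-likelihood difference, SH with the
standard simultaneous max-centred comparison. The best topology receives
p = 1 under both by construction. In the pipeline the alternative tested
is the NNI rearrangement that breaks the α1-within-MATA_HMG nesting —
the biologically meaningful competitor.

## Marginal ancestral reconstruction

The posterior distribution over residues at an internal node is obtained
by re-rooting the tree at that node (legitimate under reversibility),
taking `π_state ×` the product of the partials of the root's subtrees per
rate category, weighting categories by their per-site posterior weights,
and normalizing; the invariant-site spike contributes only at constant
columns. The MAP string breaks ties alphabetically. For a single domain
family with no outgroup the reconstruction node is the midpoint root of
the family's ML tree. This is standard marginal ML reconstruction; the
distance-weighting refinements of specialised ancestral predictors are
intentionally not replicated, since the downstream use — comparing two
family ancestors for mutual similarity — only needs defensible
ancestors, and the reconstruction is validated against brute-force
posterior computation and an independent implementation in the tests.
Indels are not reconstructed: ancestors live on core columns.

## The PROSITE scanner and its calibration

The supported pattern subset is literals, `[sets]`, `{negated sets}`,
`x`, `x(n)` and `x(n,m)`, joined by `-`; anchors are unsupported because
the motif of interest needs none. Matching is case-insensitive with
1-based starts; overlapping matches are reported by default, and at each
start the shortest satisfying match is returned. Under an i.i.d. residue
model the per-window match probability is the product of allowed-set
probabilities over pattern positions (at minimum span), and the expected
hit count is that probability times the number of windows. For
`Y-[LMIF]-x(3)-G-[WL]` under uniform frequencies this product is
(1/20)(4/20)(1/20)(2/20) = 5 × 10⁻⁵ per window — the quantity the
Monte-Carlo calibration test checks to within binomial error. The
~60-residue window downstream of a domain is extracted explicitly, with
the short-protein edge cases (window truncated or empty at the protein
end) flagged rather than erroring, mirroring the budding-yeast proteins
that stop a handful of residues after the domain.

## What the synthetic generator emulates — and what it does not

The generator produces the statistical structure the analysis assumes,
with full ground truth (true tree, true internal sequences, planted motif
positions), so every stage is testable without external data:

* Four classes on a common-ancestor tree whose *true* topology nests a
  monophyletic α1 clade (split into α1-a and α1-b subclades) inside a
  paraphyletic MATA_HMG group, with SOX and HMGB successively more
  distant. Default 6 + 6 + 12 + 12 + 12 = 48 sequences.
* An LG+G process (α = 0.8, four categories) over a 40-residue core, with
  each site's rate category drawn once at the root and held across
  branches — matching the inference model's assumption.
* Class truncations of 2 (α1-a) and 4 (α1-b) core residues at the
  C-terminus, a 5-residue insert block in 25% of HMGB rows, and one
  `Y-[LMIF]-x(3)-G-[WL]` instance planted at a recorded offset within the
  60-residue window downstream of the domain in α1 sequences only.

Branch-length regime: within-class coalescent depth 0.15 expected
substitutions/site (half that within the α1 subclades), inter-class stems
0.15–0.4, and an α1 stem of 0.4. The stems are deep relative to the
within-class depths because that is the study system's shape — compact
classes separated by long internal edges; the α1 stem in particular is
set so that the clade is *decisively* supported in the synthetic system,
as it is in the real one, making the end-to-end recovery checks a
meaningful twin of the real analysis (at 48 taxa and 40 columns a weaker
stem leaves the edge support genuinely equivocal in a large minority of
replicates).

What the generator does **not** emulate, and hence what green tests do
not establish about real data: no among-site composition heterogeneity or
covarion behaviour, no general indel process (only the fixed truncations
and the single insert block), no alignment error (the true core alignment
is known), no model misspecification (data are generated under the
inference model), and class sizes in balanced desk-scale proportions
rather than the real datasets' thousands. Real-data conclusions lean on
the methods being correct — which the oracle tests establish — not on
simulation fidelity.

## Numerical choices

* Likelihood rescaling triggers per site when a partial's maximum drops
  below 1e-80; scalers are tracked in log space and category mixing uses
  log-sum-exp.
* Eigen-decomposition round-off can leave `P(t)` entries at −1e-18; they
  are clamped to 0.
* Branch proposals use golden-section search on log branch length (35
  iterations across [1e-8, 50]); every accepted update's log-likelihood
  is computed exactly, never extrapolated.
* The pairwise-distance cap defaults to 10 substitutions/site; saturated
  and non-overlapping pairs are flagged.
* RELL replicate indices come from R's RNG under an explicit seed, and
  all generator functions take explicit seeds; no function leaves the
  caller's RNG state altered.
* Problem sizes in the test-suite and acceptance script (48 taxa × 40
  columns, 10–20 replicates, 1000–10,000 RELL draws, 10⁶-residue scanner
  calibration) are the desk-scale study conditions; they were chosen so
  the full suite and the acceptance run each complete in minutes on one
  CPU while keeping every check statistically meaningful.

## Known limitations

* The progressive aligner has no iterative refinement; on hard real
  alignments a dedicated aligner's output (read via
  `read_alignment_fasta()`) is preferable.
* E-values are pairwise Karlin–Altschul statements with fixed constants;
  they are comparable within a run, not to database-search E-values.
* The NNI hill-climb can stop in local optima, as any local search can;
  the KH/SH machinery provides the honest check on whether competing
  topologies are distinguishable.
* LR-ELW here means NNI-neighbourhood expected likelihood weights; other
  implementations of the same label may differ in the neighbourhood
  definition.
* `+F` (alignment-derived) frequencies are accepted but not optimized;
  no codon, mixture or covarion models.
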