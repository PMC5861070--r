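---
title: "Methods: models, parameters and design choices in il1evol"
author: "il1evol authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in il1evol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`il1evol` bundles the analyses needed to characterise domain-specific
selection in a duplicated cytokine family: tree reconstruction, per-site
conservation, domain-partitioned dN/dS, nuclear-localisation-signal (NLS)
scoring, isoelectric points, and factorial contrasts, together with a
simulator that generates codon alignments whose true selective regime is
known. This vignette records the models behind each stage, the tunable
parameters with their defaults and rationale, and the design decisions
taken where more than one reasonable choice existed.

## Gap handling: two deletion rules, two purposes

Alignments carry `-` (gap), `X` (undetermined residue) and, in nucleotide
data, `N` (undetermined base); all are treated as one "gap or missing"
class for filtering. Two distinct rules are deliberately kept separate
because they serve different analyses:

* **Complete deletion** (`complete_deletion`) removes every column in
  which *any* sequence has a gap or missing symbol. Distance and
  likelihood computations require fully observed columns, so this is the
  filter wired in front of the tree stage.
* **Modal-gap deletion** (`modal_gap_deletion`) removes only columns whose
  *modal* symbol is the gap class. Conservation profiling wants the
  maximal set of sites at which a meaningful mode exists, so occasional
  gaps stay (they remain in the denominator of the conservation
  percentage and thus penalise, rather than hide, missingness).

When the gap class ties with a residue for the mode, the column is
**kept**: conservation analysis prefers more usable sites, and the tie
means at least half the sequences carry residues. Complete-deletion
columns are always a subset of modal-gap columns, and both operations are
idempotent; the test suite checks both properties on random alignments.

Filtering can remove columns where the chosen reference sequence has a
residue, which would silently shift reference coordinates. Profiles
therefore accept the unfiltered `source` alignment and map coordinates
through the recorded retained-column indices, so a domain partition
defined on the full-length reference stays valid downstream.

## Domain partitions

Domains (`pro`, `mature`, optional `NLS` and `HCPR`, the highly conserved
N-terminal pro-domain region) are intervals on the *ungapped* coordinates
of a named reference sequence, 1-based inclusive — the coordinate
convention used when discussing protein positions (e.g. an NLS "around
residues 70–85"). Columns where the reference is gapped belong to no
domain; this keeps domain semantics well-defined without imputing
reference positions. The reference defaults to a sequence whose id
mentions "human", else the first record, and the choice is logged.

## Phylogenetics

Distances and likelihoods use the Jones–Taylor–Thornton (JTT) empirical
amino-acid model. The exchangeabilities and equilibrium frequencies are
frozen as source-embedded tables (conventional ARNDCQEGHILKMFPSTWYV
ordering, one defining location, checked against an independent copy in
the test suite). The generator is
`Q[i,j] = s[i,j] * pi[j]`, rows summing to zero, scaled so the expected
replacement rate at equilibrium is 1 substitution/site — so branch
lengths are in substitutions per site. Because Q is reversible,
`D^{1/2} Q D^{-1/2}` is symmetric and a single spectral decomposition
gives `P(t) = exp(Qt)` for any `t` as two matrix products.

* **Pairwise ML distances** (`jtt_distance`) maximise
  `sum_k log(pi[a_k] P[a_k,b_k](t))` over `t ∈ [1e-6, 10]` with R's
  bounded scalar optimiser (absolute tolerance `1e-6`). Identical
  sequences return the lower bound; an optimum against the upper bound is
  reported with a saturation flag rather than an error, so saturated
  pairs remain visible in the distance matrix.
* **Tree building** (`nj_tree`) is standard Saitou–Nei neighbor joining.
  Negative intermediate branch lengths — a well-known NJ artefact — are
  clamped to zero and the total deficit recorded. Full ML topology search
  is deliberately out of scope; `tree_loglik` (Felsenstein pruning with
  per-pattern aggregation and per-node rescaling) is provided to compare
  candidate topologies under the same model. The pruning implementation
  is cross-checked in the tests against an independent likelihood engine
  and is invariant to root placement, as reversibility requires.
* **Bootstrap** (`bootstrap_supports`) resamples columns with
  replacement; replicate `r` seeds its RNG with `seed + r`, making
  supports independent of execution order. Supports are the percentage
  of replicate NJ trees containing each bipartition of the full-data
  tree; branches below 50 % (configurable) are contracted to polytomies,
  the conventional presentation threshold.

## Conservation

Conservation at a site is the percentage of sequences carrying the modal
(most frequent non-gap) residue — a deliberately simple, alignment-scale
statistic, not an entropy. Ties between residues resolve alphabetically,
which is deterministic and order-independent; the percentage itself is
unaffected by the tie-break. Gapped sequences stay in the denominator.
Domain summaries are unweighted means of column conservation within each
interval. `group_vs_modal` compares each focal sequence against the modal
consensus of a reference group, excluding columns where either side is
gapped from numerator and denominator — the "build-up of replacements"
contrast between a focal subclade and the modal background.

One tempting invariant is false and worth recording: adding a sequence
identical to an *existing* one can lower a column's conservation (a
duplicate of a non-modal sequence at a 2:2 column turns 66.7 % into
50 %). The invariant that does hold, and is tested, is that adding a copy
of the modal consensus never lowers any column's conservation.

## Nei–Gojobori selection analysis

For each sense codon, each position contributes the fraction of its three
single-nucleotide changes that are synonymous (changes to stop codons
count as nonsynonymous), giving fractional site counts with `s + n = 3`.
Between two codons, all orderings of the differing positions are
enumerated as mutational pathways; pathways passing through a stop codon
are excluded and synonymous/nonsynonymous step counts averaged over the
remainder (if every pathway hits a stop — possible only for a handful of
codon pairs — all pathways are used with stop steps counted
nonsynonymous, and the result flagged). Proportions are corrected with
the Jukes–Cantor transform `d = −(3/4)·ln(1 − (4/3)p)`; `p ≥ 3/4` raises
a typed saturation error carrying the raw proportion. All 61 site counts
and 61×61 pathway averages are verified exhaustively against a
brute-force enumerator written independently in the test suite.

Group estimates (`group_domain_dnds`) default to a **pooled** estimator:
raw counts `S, N, Sd, Nd` are summed over all unordered within-group
pairs *before* normalisation and correction. Small domains (the 4-codon
NLS, say) have so few synonymous sites that per-pair proportions are
unstable or saturated; pooling stabilises them. A mean-of-pairwise
estimator is available via `method = "mean"`. In the pooled table a
saturated domain reports its raw counts with `NA` corrected values and a
`saturated` flag instead of aborting the whole analysis.

Both dN/dS and its reciprocal are reported. Low dN/dS (high dS/dN) means
purifying selection; no interpretation is hard-coded into the output.

## NLS scoring

The published position-specific scoring matrices behind NLS-prediction
servers are proprietary to those tools and are not reproduced. The
package instead uses a transparent additive surrogate on the same 0–10
scale, documented here as the module's central approximation:
monopartite candidates are 4-mers matching `K-(K/R)-X-(K/R)`; the score
is the number of K/R in the core, minus 2 per tryptophan in the core,
plus 1 if an additional K/R lies within two positions of the core;
bipartite candidates (two basic clusters separated by a 10–12 residue
linker) score analogously over both clusters. The functionality
threshold is 2. This scheme reproduces the decisive biological contrast:
an intact KKRR core scores 4 (functional) and its tryptophan-substituted
KKWR form scores 1 (non-functional), while remaining monotone — replacing
any core K/R with W strictly lowers the score. Exact numeric agreement
with external NLS servers is explicitly *not* a goal; only the
functional/non-functional classification is validated.

`nls_window_scores` projects a partition's NLS interval onto each
sequence's own ungapped coordinates and scores the best candidate
overlapping that window, defaulting to monopartite candidates since the
classical basic-core signal is what the intact/lost contrast concerns; a
genome-wide scan would instead use `scan_nls`/`nls_table`.

## Isoelectric points

Net charge is the Henderson–Hasselbalch sum over ionisable groups
(N-terminus, H, K, R positive; C-terminus, D, E, C, Y negative) with the
Bjellqvist pKa set used by standard proteomics pI tools (an alternative
set is selectable for sensitivity; pI values can shift by ~0.1–0.3
between sets). The pI is found by bisection on pH ∈ [0, 14] to
|charge| < 1e-4 and reported to 2 decimals, the conventional precision.
Generic terminal pKa values are used for all residues; reference tools
that refine the termini for particular terminal residues (A/E/M/P/S/T/V
N-termini, D/E C-termini) can differ by up to ~0.2 pH units there, and
the cross-check tests use sequences with generic termini.

## Factorial contrasts

The domain × protein comparison is fit as ordinary least squares with
species indicator terms: `value ~ species + protein * domain`. In
balanced within-species designs this fixed-effects surrogate yields the
same within-subject contrast point estimates as a random-intercept mixed
model, without the extra machinery; the output is labelled as an FE
approximation and by-subject random slopes are out of scope. Term
significance uses nested-model F tests; LS means are model predictions
averaged over species; pairwise contrasts are emitted in two families
(within-protein across domains, within-domain across proteins), each
Holm–Šidák adjusted separately since which family a figure's asterisks
belong to is a presentation choice.

Holm–Šidák: sort p ascending, adjust the i-th smallest to
`1 − (1 − p_(i))^(m − i + 1)`, enforce a running maximum, restore input
order. Degenerate designs with zero residual variance (e.g. a constant
response) are handled explicitly: zero contrasts get p = 1 rather than
NaN.

## The simulator

`simulate_family` generates the statistical structure the analyses
assume, with known truth:

* **Tree**: supplied Newick, or a Yule tree rescaled so the *mean*
  root-to-tip path equals `depth` (in expected substitutions per codon
  site). Mean rather than maximum is used so `depth` matches the average
  divergence a pair of tips exhibits.
* **Codon model**: GY94-style on the 61 sense codons with κ = 1 and
  uniform codon frequencies — the simplest model in which the configured
  per-domain ω is exactly the dN/dS truth. With uniform frequencies the
  rate matrix is symmetric, so one eigendecomposition per ω serves all
  branches; per branch, sites evolve by sampling from the corresponding
  row of `exp(Qt)`.
* **Motif**: the NLS core (default KKRR at pro position 70, inside the
  70–85 window where such signals sit) is written over the simulated
  codons after evolution, with the designated loss clade receiving the
  R→W core (KKWR). The two residues flanking the core are set to alanine
  at the same time: the overwrite is meant to make the
  functional/non-functional contrast deterministic, and a chance basic
  residue in the evolved flank would otherwise add the flank bonus and
  lift KKWR to the threshold. The loss clade must be monophyletic — the
  biological scenario is a single ancestral loss — and a non-monophyletic
  specification is an error, not a warning.
* **Gaps**: whole columns (outside the motif region) receive gaps in a
  random subset of taxa (20–90 % of rows), exercising both deletion
  rules downstream.

Defaults (16 taxa, 200+200 codons, ω = 0.1/0.6, depth 0.3, 4-taxon loss
clade, 5 % gap columns) are the validation conditions used throughout the
tests: they produce pro-vs-mature contrasts large enough to be detected
reliably at desk scale while keeping per-family runtimes below a second.

What the simulator does **not** emulate: indel evolution (gaps are
injected, not evolved), rate heterogeneity among sites within a domain,
codon-usage bias, transition/transversion asymmetry, and selection acting
on the motif itself (it is overwritten). Passing the truth-recovery tests
therefore shows the estimators recover domain-level selection and
conservation structure under a clean codon model — not that they are
robust to alignment error or compositional bias in real data.

## Numerical choices

* Distance optimiser bounds `[1e-6, 10]`, tolerance `1e-6`; saturation
  flagged at the upper bound.
* `P(t)` entries clamped at 0 (spectral round-off) and row-normalised in
  the simulator.
* Pruning rescales partial likelihoods per node, so long trees do not
  underflow.
* Bootstrap replicate `r` uses seed `seed + r`; simulation files are
  byte-identical under a fixed config and seed.
* pI bisection: |charge| < 1e-4 or interval < 1e-10.
* Problem sizes in the validation suite (100 simulated families for
  truth recovery, 1000 replicates for the family-wise-error simulation,
  100 bootstrap replicates) were chosen to give stable Monte-Carlo
  estimates at desk scale.

## Known limitations

* Trees are NJ-on-JTT-distances with fixed-topology likelihood
  evaluation; no heuristic topology search, no Γ rate heterogeneity, and
  only the JTT matrix ships (the model interface accepts alternatives).
* The NLS score is a calibrated surrogate, not a reimplementation of any
  published server's matrices.
* The factorial model approximates random intercepts with fixed effects
  and omits random slopes.
* pI ignores post-translational modifications and uses generic terminal
  pKa values.
* The pipeline refuses unaligned input; alignment construction is the
  user's responsibility.
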