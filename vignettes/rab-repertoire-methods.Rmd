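---
title: "Methods: profile-HMM subfamily classification and ancestral repertoire inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: profile-HMM subfamily classification and ancestral repertoire inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(rabrep)
```

This vignette is the package's own account of its models, parameter
choices, numerical decisions and limitations. It states no empirical
result beyond what the test suite and `scripts/acceptance.R` compute.

## 1. The scientific problem

The Rab GTPases direct vesicle traffic between organelles; each organelle
class is marked by one or more Rab subfamilies, so an organism's Rab
repertoire mirrors its endomembrane complexity. Two questions drive the
package: *how do we assign a new protein sequence to a Rab subfamily with
a quantified confidence*, and *which subfamilies were already present in
the last eukaryotic common ancestor (LECA), given their scattered
presence and absence across extant lineages*?

## 2. The profile HMM and its scoring model

`profile_hmm()` fits one match state per column of a seed alignment.
Because seeds are pre-trimmed with `trim_alignment()` (columns with more
than 25% gaps removed first, then rows with more than 25% gaps — in that
order, once, which makes trimming idempotent), an all-match architecture
is adequate: residual gaps are modelled by delete states, and insert
states (emitting the background) absorb unaligned query residues.

Parameters that matter:

* `alpha` (pseudocount mass, default 1.0, dimensionless): match emissions
  are `(c_j(a) + alpha * q(a)) / (n_j + alpha)`. `alpha = 0` reproduces
  raw column frequencies (with a warning when residues are unobserved);
  very large `alpha` collapses every column to the background.
* `background`: uniform 1/20 by default; the Robinson–Robinson average
  composition is available via `aa_background("robinson")`. The uniform
  default keeps the null model assumption explicit rather than buried in
  a composition table.
* Transitions receive +1 pseudocounts per allowed move, estimated from
  the match/delete paths of the seed. Insert transitions are therefore
  flat (0.5/0.5) unless a seed is gappy enough to inform them.
* Sequence weighting: uniform by default; `weights = "henikoff"` switches
  to Henikoff position-based weights for seeds with redundant taxa.

Scoring is *local*: uniform entry into any of the `L` match states
(a `log2(1/L)` cost), free exit after any match state. Scores are
log2-odds against an i.i.d. background null; `X` residues emit the
background (odds 1) so fragmentary sequences score without error. The
Viterbi and Forward kernels are in C++ (`src/core.cpp`) and are verified
in the tests against a brute-force enumeration of every local alignment
path on small models. One consequence of uniform local entry/exit worth
knowing: even for a point-mass profile and its exact consensus, Forward
exceeds Viterbi by roughly 0.2 bits, the summed mass of partial
sub-alignments; the two converge only relative to the total score.

## 3. E-values and the strict/soft cut-offs

`calibrate_evalue()` scores `n_random` i.i.d. background sequences
(lengths uniform on `[L, 2L]` by default) and fits a Gumbel location and
scale by the method of moments. E-values are
`E = db_size * min(1, exp(-lambda (S - mu)))` with `db_size = 100000` by
default, so classification behaves as if every search ran against a
fixed-size database — the calibration never generates 100,000 physical
decoys. The moment fit is deliberately simple; its 5% tail is accurate
only to within a factor of about two (asserted in the tests), which is
ample for rank-based classification but would not support precise
p-values far in the tail.

Cut-offs live in `-log10 E` space (larger = better). Per model: the
*strict* cut-off is the 5th percentile of member scores (each member's
ungapped sequence scored against its own model), the *soft* cut-off the
95th percentile of decoy scores, floored at zero, and zero when no decoy
set is supplied. Percentiles interpolate linearly between order
statistics (index `p(n-1)`, R's quantile type 7). By construction about
5% of true members fall below their own strict cut-off, so a `possible`
label on a borderline member is expected behaviour, not a defect.
A model whose soft cut-off exceeds its strict cut-off is flagged
unreliable but remains usable — the flag, not silent repair, is the
contract. Member scores are computed per model, not pooled.

## 4. Classification, verification, parent assignment

`classify_batch()` assigns each query to the model with the smallest
E-value; exact ties fall back to higher bit score, then lexicographic
model name, and the tie-break actually used is recorded in the output so
audits can find it. `verify_hits()` automates the triage a curator would
do by eye: `fragment` (span below 60% of model length), `no fit` (label
`none`), `ambiguous` (second model within 2 `-log10 E` units). Flagged
hits are reported, never dropped.

`assign_parent()` resolves subfamilies that cannot be linked to an
ancestral family by HMM score alone: each member is locally aligned
(Smith–Waterman, affine gaps 11/1, BLOSUM62 — implemented in the package
kernel) against candidate sequences *of the same species*, its best hit
casts one vote, and a strict plurality names the parent; exact ties
return `"unresolved"` rather than guessing. Votes use raw alignment
scores: within a single species' pool, length effects are comparable and
a significance transform would not change the argmax.

## 5. Resampling validation

`resample_validate()` mirrors the classical protocol: per replicate,
`ceiling(0.9 n)` members of each family (minimum 4) are drawn without
replacement, models are rebuilt, and every evaluation sequence is
assigned to the best-E model. Defaults are 1000 replicates at database
size 100,000; the tests and the acceptance script run 100 replicates,
which already gives per-model rates stable to well under the 5% margin
the quality bar cares about.

Two design choices deserve explanation:

* *Evaluation scope.* With `eval_scope = "heldout_plus_others"`
  (default), held-out members are always counted, and a training sequence
  enters the counts only if it is misassigned to a foreign model. This
  avoids inflating sensitivity with trivially-correct training self-hits
  while still letting every foreign sequence challenge a model's PPR.
  `eval_scope = "all"` counts everything.
* *Calibration reuse.* The Gumbel fit is computed once per family from
  the full-member model and reused across replicates
  (`calibrate_each_rep = FALSE`). A 90% resample of the same seed yields
  a nearly identical score distribution, and refitting per replicate
  would multiply runtime roughly by the ratio of calibration draws to
  evaluation sequences for no measurable change in the rates.

Sampling uses one derived RNG substream per (replicate, family), so
reports are bit-identical under a fixed seed and invariant to the order
in which families are supplied.

A caveat discovered while testing: if the same family is entered twice
under two names, held-out members of one twin are (with probability
≈ 0.9) in the other twin's training sample, so assignments flow to the
twin that trained on them. Per-twin sensitivity is therefore near zero
even though essentially all assignments stay inside the twin pair. The
tests assert the pair-level property; per-twin rates for duplicated
families are not meaningful under this protocol.

## 6. Iterative refinement

`run_refinement()` automates the classify → verify → re-cluster →
rebuild loop. The similarity stage scores all sequence pairs with the
affine-gap aligner and converts scores to edge weights by a
Karlin–Altschul-style transform (`lambda = 0.267`, `K = 0.041`, the
standard gapped BLOSUM62 11/1 parameters), `w = max(0, -log10(m n
2^{-bits}))`. Clustering is connected components above each cut-off of a
strictly decreasing ladder, which guarantees that partitions nest.
Proposed subgroups must be identical across two consecutive ladder
levels, have at least `min_size = 5` members spanning at least
`min_kingdoms = 2` kingdom tags, and (optionally) be monophyletic in an
NJ tree. Only `confident` members enter model rebuilds; `possible`
sequences stay in the pool. "No further improvement" is formalised as a
repeated partition hash (fixed point or cycle), bounded by `max_iter`.
The cut-off ladder has no universal default: it must bracket the
within-group and between-group weight ranges of the data at hand, which
the audit log (per-iteration counts and hashes) makes easy to check.

## 7. Distance phylogeny

`pairwise_distance()` offers `p`, Poisson (`-ln(1-p)`) and continuous
gamma corrections (`a((1-p)^{-1/a} - 1)`, shape default 1.0) under
pairwise gap deletion; a discrete-category gamma approximation is
unnecessary for distance correction, and an exchangeability-matrix
distance is deliberately out of proportion to the role distances play
here. Saturated pairs (`p = 1`) are capped at 10 substitutions/site with
a warning rather than returned as infinities, keeping downstream NJ
finite; the cap is recorded in the `saturated` attribute.

`neighbor_joining()` is the canonical Q-criterion algorithm with
Studier–Keppler updates, re-implemented so its tie-breaking (smallest
lexicographic pair of cluster labels) and negative-branch handling
(clamp to zero, move the deficit to the sibling edge) are documented and
deterministic. It is validated three ways: exact recovery of random
additive matrices, agreement with an exhaustive least-squares topology
search, and agreement with `ape::nj` on noisy matrices.
`bootstrap_support()` resamples columns, rebuilds NJ trees and reports
bipartition frequencies on the original tree.

## 8. The synthetic generator

`evolve_sequences()` emulates the divergence structure the classifier
assumes: an i.i.d. root sequence, per-site rates `Gamma(shape, mean 1)`
drawn once, Poisson substitution counts per branch with uniform choice
among the 19 alternative residues, and optional Poisson indels with
geometric lengths (default off, so benchmark seeds stay ungapped and
trimmed). The uniform-target process has the closed-form p-distance
`(19/20)(1 - e^{-20 t / 19})` at rate homogeneity, which the tests check
at 5000 sites. `make_family_benchmark()` arranges families on a
two-level star tree; the default study condition for classifier quality
is 5 families × 20 members at `within_depth = 0.2`,
`between_depth = 0.6` substitutions/site (a 3× ratio) and 150-residue
roots — roughly the size of the conserved Rab G-domain motif and a
within-family identity (~70%) typical of a protein subfamily, with
between-family divergence deep enough that subfamilies are distinct but
not trivially so.

What passing these benchmarks does *not* show: robustness to
heterogeneous domain architecture, compositional bias, fragmentary ESTs
or alignment error in real seeds. The generator has no codon structure,
no rate shifts across the tree, and families diverge by a star topology,
so the benchmark is a calibrated separability test, not a realism test.

## 9. The curated Rab compendium

`rab_presence()` encodes the presence/absence of the 20 candidate LECA
Rab subfamilies across ten lineages mapped to the four eukaryotic
supergroups; `rab_ledgers()` carries ordered loss/gain ledgers for the
fungal, human, plant and apicomplexan paths; `rab_rootings()` defines the
three rootings (plus the variant placing the excavates with the
Archaeplastida). The compendium is at lineage resolution, not the
hundreds-of-species resolution of a full survey, and every presence call
carries a confidence grade in `rab_provenance()`: `reported`, `inferred`
(implied by a retained-repertoire count), or `low-confidence` (sparse or
single-species evidence — e.g. the attribution of the full 20-family
complement to the Rab-rich heterolobosean excavates, or Rab24/Rab28 in
single green algae). The metazoan-stem gains in the human ledger cannot
be itemised unambiguously at this resolution and are all flagged
`uncertain`; no headline number depends on them. `leca_dollo()` treats
horizontal transfer as negligible; taxa can be dropped from the matrix
to probe that assumption.

## 10. Numerical choices and degenerate inputs

* Probability tables are validated to sum to 1 within 1e-9 after every
  build.
* Log-space scoring throughout; `-1e30` is the working `-Inf`.
* Zero-variance calibration scores raise `"degenerate calibration"`
  rather than returning an infinite `lambda`.
* Empty trimming results, empty model libraries, empty groups, events
  off the ledger path, losses of absent families and gains of present
  ones are all hard errors naming the offending entity.
* All randomness flows through explicit integer seeds; derived substreams
  stay below 2^31.

## 11. Problem sizes used by the shipped checks

The test suite and acceptance script run the 5×20 benchmark at 100
resampling replicates over five generator seeds, 200-replicate bootstrap
on six-taxon alignments, 500 random matrices for the Dollo oracle, and
1000 random (model, sequence) pairs for the Forward/Viterbi dominance
check — sizes chosen so the full suite exercises every contract at
high statistical resolution on a single CPU. The validation protocol
itself defaults to the classical 1000 replicates.

## 12. Known limitations

* Scores are internally consistent but not comparable to any external
  HMM engine's absolute E-values; engine settings of published analyses
  are generally not knowable.
* Glocal/multi-hit scoring, Dirichlet-mixture priors and acceleration
  filters are out of scope.
* The refinement loop is fully automated where the original workflow it
  mirrors interleaved manual curation; its stability thresholds are
  configurable precisely because no published values exist for them.
* Maximum-likelihood tree search and topology tests are out of scope;
  NJ bootstrap is the only support measure.
* Dollo parsimony cannot see a family that was present in the LECA but
  survives on only one side of the root; the inferred repertoire is a
  lower bound under every rooting.
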