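---
title: "Ranking enzyme homologs from few labels: models and design choices"
author: "EmbedRank"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking enzyme homologs from few labels: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(EmbedRank)
```

## The model

EmbedRank addresses a regime common in enzyme engineering: a homology
search returns thousands of candidate proteins, experiments can measure a
handful, and the question is which candidates to measure next. The
package treats this as few-shot regression over sequence representations.
Each protein of length $L$ is represented by the mean of its per-residue
vectors at one layer of an embedder backend,

$$x = \frac{1}{L}\sum_{l=1}^{L} h_l \in \mathbb{R}^d,$$

and a regressor $\hat f(x)$ is fitted to the labelled examples and
applied to every candidate. Mean pooling is taken over residue positions
only — any special begin/end tokens a backend might emit are excluded by
the contract of `residueRepresentations()`.

Three regressor families are supported, reflecting what works at these
sample sizes: k-nearest neighbours, support vector regression with a
radial kernel, and random forests. Hyperparameters are tuned by
exhaustive search over a small declared grid
(`defaultGrid()`), scored by mean out-of-fold $R^2$ on one fixed seeded
fold partition; *reporting* uses the Spearman rank correlation $\rho$,
because the downstream decision — which candidates to test — depends only
on ranks. Both statistics are always available from `evaluateModel()`.
Ties in grid scores go to the earlier combination in declaration order,
which makes training bit-reproducible given the seed.

The embedding layer can be fixed or chosen by five-fold cross-validation
(`selectBestLayer()`): each layer is scored by the mean out-of-fold
Spearman correlation of the full tuning-and-training procedure, and ties
go to the lowest layer. The fold partition is keyed to sorted sequence
ids, so reordering the input records cannot change the choice. Spearman
rather than $R^2$ decides the layer because layer choice is a ranking
decision; both readings of "predictive performance" were considered and
the rank-based one is used, with $R^2$ still logged per grid point.

## Value transforms

Kinetic parameters such as $k_\mathrm{cat}/K_M$ span orders of magnitude,
and squared-error-based fitting on the raw scale lets a few fast enzymes
dominate. `readFitnessFasta()` therefore defaults to a $\log_{10}$
transform (requiring positive raw values), switchable to `identity` for
measures that are already well scaled (temperatures, wavelengths,
synthetic labels). The transform is stored with the dataset and applied
lazily by `trainingValues()`; predictions come back in transformed space,
which leaves ranks unchanged.

The skewness diagnostic `fisherSkewness()` computes the unadjusted moment
coefficient $g_1 = m_3 / m_2^{3/2}$ (not the sample-adjusted $G_1$) —
strongly skewed label vectors are a warning that a transform is needed
before regression.

## Homology filtering and identity

Homology searches are consumed, not executed: `readHitsM8()` parses the
12- or 14-column BLAST/MMseqs2 tabular format with 1-based inclusive
coordinates. `filterHits()` keeps a hit when its E-value is *strictly*
below $10^{-3}$ and the alignment covers at least 90% of *both* the query
and the target length — the strict/inclusive boundaries follow the
conventions the thresholds are usually quoted with, and both are
parameters.

Pairwise identity is computed from a global (end-to-end)
Needleman–Wunsch alignment under BLOSUM62 with affine gap penalties
(open 11, extend 1), as identical columns divided by total alignment
columns, gaps counted in the denominator. Search tools report identities
under their own, usually local, conventions; a fixed published scheme
makes results reproducible at the cost of small systematic differences
(about a percentage point) from values printed by other software — the
tests tolerate exactly that much where they compare against externally
derived identities.

`redundancyFilter()` removes near-duplicates by greedy incremental
clustering: records are visited longest-first (ties by id), each joins
the first representative it matches at ≥ 90% identity, otherwise founds a
new cluster. Longest-as-representative mirrors common practice in
sequence clustering tools; the order is a declared convention, not a
claim of optimality, and the guaranteed invariant is only that every
non-representative has ≥ threshold identity to its representative.

## The data-requirements protocol

`subsampleCorrelations()` asks how much labelled data the task needs: one
held-out test split (20%) is drawn once and fixed; then for each training
size $s$ and replicate $r$, $s$ examples are drawn without replacement
from the remaining pool, the regressor is re-tuned and re-trained from
scratch, and the test-set $\rho$ is recorded. Fixing the test set across
sizes makes the curve comparable along the size axis; the cost is that
curve values share test-sampling noise, which is acceptable because the
curve is read for trends, not absolute values.

Two summaries are derived per size: the width of the 95% *t* confidence
interval for the mean of the replicate correlations,
$2\,t_{0.975,\,n-1}\,\mathrm{sd}/\sqrt{n}$ (a standard choice at ~10
replicates; nothing in the protocol depends on the interval being exact),
and the success rate, the fraction of replicates with $\rho$ strictly
above 0.5. `minAdequateSize()` reports the smallest size from which the
CI-width criterion holds *at every larger sampled size*: a first-crossing
reading is sensitive to a single lucky size, and the stable reading is
what one would act on.

## The surrogate embedder

All tests and simulations run against `SurrogateEmbedder`, a
deterministic stand-in that honours the same contract as a protein
language model adapter (named layers, per-residue matrices, finite
entries) while being seconds-fast and dependency-free. Its construction
is chosen so that the synthetic benchmark is *meaningful*:

* a dense, low-gain projection of the residue identity and its five
  physicochemical scalars (standardized Kyte–Doolittle hydropathy,
  volume, charge, polarity, aromaticity from a built-in table), plus a
  low-gain mixing of the two neighbouring residues — so a substitution at
  position $i$ changes rows $i-1, i, i+1$ only;
* a **position-addressed channel**: each position writes its residue's
  standardized hydropathy, with a fixed sign, onto one layer-specific
  coordinate chosen by a seeded permutation (injective while $L \le d$).
  This is the analogue of a transformer's positional encoding, and it is
  load-bearing: features that depend only on a local window reduce to
  residue *composition* after mean pooling — the sum over positions of
  one-hot window features is the same whichever positions the residues
  sit at — so position-specific fitness would be unlearnable by any
  regressor from such a pooled vector. Contextual models avoid this
  because their residue vectors encode where in the protein they are; the
  surrogate makes that property explicit and cheap;
* **layer 0 noise**: unit Gaussian noise, seeded by the embedder seed and
  the sequence content, is added to layer 0 only. Higher layers are
  therefore strictly more informative by construction, which gives layer
  selection a known right answer. Seeding the noise by content (rather
  than by, say, a call counter) preserves two invariants the tests rely
  on: identical sequences embed identically, and embedding a singleton
  equals the corresponding row of a batch.

The gains (dense channels 0.05, hydropathy channel 4, noise sd 1) were
fixed once when the surrogate was designed, so that the position channel
dominates the composition channels after pooling and layer 0 is clearly
degraded; they are exposed as constructor arguments but the defaults are
the tested configuration.

## The synthetic landscape

`generateLandscape()` emulates the statistical shape of an engineered
training set: a cloud of variants around one reference at high sequence
identity, as produced by combinatorial mutagenesis of a modest mutation
library. A random reference of length 120 carries 16 functional sites,
each with one alternative residue; every variant includes each library
substitution independently with probability chosen so the expected
per-position mutation rate is 3.5% — hence an expected identity to the
reference of 96.5%, matching the regime the workflow targets. True
fitness is additive over the functional sites, the site coefficient
(drawn once from $N(0,1)$) times the standardized hydropathy of the
residue present, plus $N(0, 0.3^2)$ measurement noise.

Two design points deserve justification:

* **A site library rather than diffuse mutation.** If variants instead
  mutated every position independently and only a handful of positions
  carried fitness weight, most variants would carry *no* functional
  mutation at all; their labels would be pure noise, and even an oracle
  that knows the true fitness would be capped at a held-out Spearman
  correlation far below what the workflow is supposed to demonstrate
  (simulations put the ceiling near 0.55 for 6 weighted positions at this
  mutation rate). Engineered mutant sets are not like that: variants are
  combinations from a curated library targeting functionally relevant
  positions, and most variants differ in activity. With 16 sites each
  present in ~26% of variants, the oracle ceiling is ≈ 0.99 and observed
  model performance is interpretable as learning, not luck.
* **Hydropathy-structured effects.** Site effects are coefficients times
  a fixed residue property rather than independent per-(site, residue)
  draws, so the mapping from sequence to fitness is linearly decodable
  from the surrogate's pooled embedding. That makes the recovery
  thresholds in the tests meaningful: a failure would indicate a real
  defect in the pipeline rather than an unlearnable benchmark. No
  epistasis and no real enzyme biochemistry are modelled, deliberately.

`sampleVariants()` draws fresh panels from the same reference, sites and
weights — the candidate pools used in the ranking-enrichment checks.
`generateToyHits()` plants exact pass/fail ground truth against the hit
filters.

## Problem sizes, determinism, degenerate inputs

The validation suite runs landscapes of 120-residue sequences with
$n$ between 100 and 260 (250 for the recovery experiments, matching a
typical labelled-set size in this regime), embedding dimension 128,
and 3–10 replicates per subsampling size; repeated properties are
asserted over five independently seeded landscapes with a 4-of-5
majority, since any single synthetic draw can be unlucky. The
success-rate monotonicity checks use a noisier labelling (sd 1.0) than
the default, because at noise 0.3 the learner exceeds $\rho = 0.5$
already at the smallest sizes and the success rate saturates at 1, where
a trend is undefined.

All stochastic steps — splits, folds, subsampling, forest fits, the
surrogate's projections — derive their seeds from user-visible integer
seeds through an internal hash, and seeded sections restore the caller's
RNG state, so results are reproducible regardless of call order.

Degenerate inputs are handled by declared rules rather than silent
recovery: Spearman correlation and $R^2$ error on zero variance (and the
rank-versus-identity diagnostic reports an undefined correlation as `NA`
instead of crashing); a constant training target short-circuits the grid
search to the first combination; ties in predictions are ranked by id so
ranked tables are stable; grid ties go to declaration order.

## Limitations

* The surrogate embedder is a designed object, not a trained model:
  passing the synthetic benchmark shows the statistical machinery —
  pooling, tuning, evaluation, filtering, the robustness protocol — is
  correct, *not* that any particular language model predicts any
  particular enzyme's activity. Real-data performance depends on the
  chosen backend and on the label quality.
* The additive, epistasis-free landscape is the easiest terrain a
  sequence–fitness method can face; results on it are upper bounds.
* Identity values depend on the alignment convention; comparisons with
  identities printed by search tools are accurate only to about one
  percentage point.
* The greedy redundancy filter is order-dependent by design and does not
  guarantee that representatives are mutually below the threshold.
* Homology searching itself, taxonomy assignment, and language-model
  training or fine-tuning are out of scope; search results enter only as
  precomputed tabular files.
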