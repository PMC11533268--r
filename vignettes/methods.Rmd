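---
title: "SeqMomentStack: methods, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SeqMomentStack: methods, design choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Overview

SeqMomentStack classifies gene sequences as *normal* or *mutated* (carrying
a driver mutation). The pipeline has four stages, each an exported module:

1. **Corpus** — apply a driver-mutation table to reference sequences and
   assemble a balanced labeled dataset.
2. **Features** — summarize each sequence as a fixed 522-component
   descriptor built from k-mer frequencies, position-incidence summaries
   and statistical moments.
3. **Models** — train three gated recurrent base networks and stack them
   with a logistic-regression meta-learner.
4. **Evaluation** — score the classifier under self-consistency,
   independent-set and 10-fold cross-validation protocols with a full
   confusion-matrix metric panel.

This vignette explains the modelling choices, the tunable parameters, what
the synthetic benchmark does and does not demonstrate, and the known
limitations.

## The corpus and its balance policy

A mutation record is `(gene, position, ref, alt, sample_id)` with 1-based,
fully closed coordinates — the convention of public mutation databases.
Coordinates are converted nowhere else; `applyMutation()` validates the
reference allele in place and supports substitutions and simple indels.
Strand is never inferred: sequences are used as given.

Balance is achieved *per gene*: each gene's normal sequence is replicated
once per mutation of that gene, so `|T⁺| = |T⁻|` holds within every gene
and overall. The alternative — one normal copy per gene — would make the
negative class compositionally different from the positive class wherever
mutation counts are skewed, confounding gene identity with label. The cost
of our choice is that label-0 records of the same gene are *identical*
replicas; the consequences for evaluation are discussed under
*Limitations*.

Ambiguity codes are rejected by default (`ambiguity = "error"`) because
every downstream feature is defined on the 4-letter alphabet; the optional
`"mask"` policy replaces them with `A` and warns, which is acceptable only
when ambiguous bases are rare.

## The 522-component descriptor

For each k-mer width k ∈ {1, 2, 3}, the sequence is encoded as overlapping
base-4 codes (`A=0, C=1, G=2, T=3`, most significant digit first) over an
alphabet of size K = 4ᵏ. Three vector summaries are taken directly on the
code list:

* **frequency vector** — per-symbol counts (conservation: sums to
  `L − k + 1`);
* **AAPIV** — per-symbol sums of 1-based occurrence positions. The name
  (*accumulative absolute position incidence*) dictates the definition: it
  accumulates positions, not frequencies, and its total is always
  `L'(L'+1)/2`. The reverse AAPIV is the same quantity on the reversed
  code list.

Three square arrangements are then each condensed to 30 moments:

* the **sequence matrix** — row-major fill of the codes into an `N × N`
  grid, `N = max(4, ⌈√L'⌉)`, zero-padded. The floor of 4 guarantees that
  degree-3 orthogonal polynomials exist on the grid even for short inputs
  (hence the minimum sequence length of 18, which makes the trinucleotide
  grid 4 × 4);
* the **PRIM** — entry (i, j) accumulates the offsets `p − f_i` of every
  occurrence of symbol j strictly after the *first* occurrence `f_i` of
  symbol i. This is deterministic, integer-valued, and zero on rows of
  absent symbols; first-occurrence anchoring keeps the computation
  O(K² log L) via per-symbol prefix sums;
* the **RPRIM** — the PRIM of the reversed code list.

The moment families, at the ten orders `(a, b)` with `a + b ≤ 3` in the
fixed enumeration `(0,0), (0,1), (1,0), (1,1), (0,2), (2,0), (1,2), (2,1),
(0,3), (3,0)`:

* **raw** `R_ab = Σ_p Σ_q p^a q^b G(p,q)` with 1-based indices;
* **central** — the same sums about the mass centroid
  `x̄ = R₁₀/R₀₀, ȳ = R₀₁/R₀₀`, making them location-invariant. An all-zero
  grid has no centroid; the moment set is returned as zeros with a
  `degenerate` flag rather than an error, since zero grids arise naturally
  from absent symbols;
* **Hahn** `H_ab = Σ_p Σ_q G(p,q) h_a(q, N) h_b(p, N)` with 0-based
  indices, where `h_n` is the discrete Hahn polynomial evaluated as its
  finite Pochhammer sum. The parameter pair defaults to `u = v = 0`, the
  discrete-Chebyshev limit, which keeps `h₀ ≡ 1` and hence `H₀₀` equal to
  the grand sum — a useful analytic anchor that the tests exploit. Only
  degrees up to 3 are needed, so the alternating sum has at most four
  terms and is numerically benign for every grid side the pipeline
  produces (N ≤ 64 for incidence matrices, N ≈ √L for sequence matrices);
  reference values were frozen from an exact-rational evaluation of the
  same sum.

Totals: 3 alphabets × (1 + 2) vector summaries = 252 values, plus
3 alphabets × 3 matrices × 30 moments = 270 values — 522, the only
decomposition consistent with the listed techniques. The layout is
programmatic (`featureLayout()`) and attached to every featurized dataset
as `rowData`, so the block structure is auditable rather than implied.

All features are computed in double precision. PRIM moments on 64 × 64
grids of trinucleotide offsets reach ~10¹², far inside exact integer
representability of doubles; no rescaling is applied at extraction time
because standardization is an evaluation-stage concern (below).

## The base networks and the stack

Each base network is: dense projection 522 → 128, a gated recurrent layer
of width 128, dense 64 → dropout → dense 64 → dropout → sigmoid scalar.
The three kinds differ only in the recurrent cell: LSTM (input/forget/
cell/output gates), GRU (update/reset gates), and bidirectional LSTM (two
independent LSTM cells whose outputs are concatenated, so the first dense
layer widens to 256 inputs).

Two deliberate typing decisions: a token-embedding layer is undefined for
continuous inputs, so the "embedding" stage is realized as a dense linear
projection preserving the stated width; and the 522-vector enters the
recurrent layer as a *length-1 sequence*, since no unrolling order over
heterogeneous feature blocks would be meaningful. With a single timestep
the recurrent weight matrices receive no gradient (there is no previous
state); they remain part of the declared architecture and parameter count,
and the cells' gating nonlinearities still shape the forward computation.

The networks are implemented natively in R: BLAS matrix algebra, manual
backpropagation, inverted dropout (rate 0.3), Adam (learning rate 1e-3,
β₁ = 0.9, β₂ = 0.999), binary cross-entropy, batch size 32. None of the
optimizer constants are sequence-specific; they are the field's customary
defaults and are all exposed through `networkConfig()`. Training is exactly
reproducible: initialization, shuffling and dropout masks all derive from
the configuration seed.

The default budget is 300 epochs (`baseConfigs(epochs = 300L)`); the test
suite and the benchmark runs use a 30-epoch profile at problem sizes of
600 sequences of 0.2–3 kb, sufficient for the stacked ensemble to fully
recover the planted benchmark signal (the acceptance checks measure this
directly).

**Stacking.** The meta-learner is a logistic regression on the three base
probabilities. Fitting it on in-sample base predictions would leak (a
memorizing base model looks spuriously reliable), so the meta-learner is
fitted on *out-of-fold* predictions from an internal stratified 5-fold over
the training split; the base models are then refitted on the full training
split. The fitted stack therefore satisfies: meta dimension = 3 + intercept,
and ensemble training behaviour dominated by the best base model when the
bases agree.

## Evaluation protocols and metrics

* **SCT** — train and test on the full set. Upper-bounds attainable
  performance; reported for comparability, not generalization.
* **IST** — stratified 80/20; standardizer and ensemble fitted on the 80%
  only.
* **10-FCV** — stratified folds built by dealing shuffled class blocks
  cyclically, which guarantees fold sizes differ by ≤ 1 overall *and*
  per class. The headline report pools confusion counts across folds
  (micro-average); per-fold reports are retained so macro summaries can be
  derived if wanted.

Standardization is per-feature min–max fitted on the training portion.
Min–max (rather than z-scoring) keeps the heavily skewed moment features
bounded without assuming normality; constant features map to zero, and
test-set values may legitimately fall outside [0, 1].

Metrics are computed from the confusion matrix with the mutated class
positive. Cohen's kappa uses observed agreement `P_o` (= accuracy) against
chance agreement `P_e` from the marginal products. The AUC is the
rank-based Mann–Whitney statistic (ties count one half), equivalent to the
area under the threshold-swept ROC curve; a likelihood-ratio reading of
"AUC" was considered and rejected because the quantity plotted and compared
in practice is the ROC area. Degenerate denominators yield `NaN` plus an
entry in the report's `flags` instead of an error, so batch evaluations
never abort on a pathological fold.

## The synthetic benchmark

`syntheticConfig()` defaults encode the corpus structure the pipeline is
designed for: 40 genes, 696 mutations, gene lengths uniform on 200–3000 nt,
and a Zipf(1.7) concentration of mutations so that one gene dominates the
table the way real driver-gene tables are dominated by a single oncogene.
Only the qualitative dominance is contractual; 1.7 reproduces the shape of
real per-gene counts reasonably.

The class signal is planted as trinucleotide-motif enrichment: each
mutated sequence has `⌊effectSize · L/10⌋` stride-3 positions rewritten to
the motif (`"GAC"` by default — an arbitrary fixed constant). A
trinucleotide motif is chosen because the feature set is provably
sensitive to it through the k = 3 frequency vector alone, so the benchmark
tests the *pipeline* (features → networks → stack → protocol), not the
generator's realism. `effectSize = 0` plants nothing.

What the generator does **not** emulate: real base composition, codon and
exon structure, mutational signatures, homology between genes, or
sample-level correlation of mutations. Passing the benchmark therefore
shows the machinery is correct and can recover a strong compositional
signal; it does not predict accuracy on real corpora, where the
class-separating signal is far subtler.

## Limitations and honest caveats

* **Replica memorization.** Because balance is achieved by replicating
  normal sequences verbatim, label-0 records are exact duplicates across
  any random split, and a label-1 record differs from a training label-0
  record by a single substitution. A sufficiently trained network can
  therefore score above chance on an *unplanted* (`effectSize = 0`) corpus
  by recognizing whether a vector sits exactly on a reference cluster
  centre — this is a property of the corpus construction, not leakage:
  the standardizer and ensemble never see test rows. Whether it manifests
  depends on training dynamics (seed and epochs). The clean null
  hypothesis for calibration checks is therefore *label shuffling*, which
  breaks the feature–label dependence entirely; the test suite checks
  chance-level accuracy under shuffled labels, and reports the unplanted
  corpus accuracy as a separate, structure-sensitive quantity.
* **Single-timestep recurrence.** With the descriptor entering as one
  timestep, the recurrent cells act as gated feedforward units; the
  architecture is kept for fidelity to the stated design, not because
  recurrence adds modelling power here.
* **SCT optimism.** Self-consistency accuracy is a memorization measure
  and should never be quoted as generalization.
* **Scope.** No feature selection, no hyperparameter search, no
  transcript-model awareness (exon/CDS mapping), no protein alphabet, no
  web retrieval: inputs are local FASTA and delimited tables only.

## Reproducibility

Every stochastic step — corpus generation, split plans, stacking folds,
network initialization, minibatch shuffling, dropout — is driven by an
explicit integer seed. `runPipeline()` writes a manifest (configuration,
seeds, md5 of every artifact) alongside its outputs, and rerunning with an
identical configuration reproduces the feature CSV bit for bit and the
metrics exactly. `scripts/acceptance.R` regenerates the benchmark numbers
from scratch from a single `--seed`.
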