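# SeqMomentStack

Classification of carcinogenic (driver) mutations directly from gene
sequences. Given a set of reference gene sequences and a table of driver
mutations, the package builds a balanced corpus of normal and mutated
sequences, summarizes every sequence as a fixed 522-component numeric
descriptor, trains a stacked ensemble of three gated recurrent networks,
and evaluates the resulting binary classifier under three standard testing
protocols. A deterministic synthetic-corpus generator makes the whole
pipeline runnable and testable offline.

It is aimed at computational biologists who want a transparent, fully
scripted reimplementation of this style of "sequence → hand-crafted
statistical descriptor → deep ensemble" mutation classifier, with every
stage exposed as an ordinary R function and every quantity testable against
closed-form oracles.

## The model

**Corpus.** The dataset is the union `T = T⁺ ∪ T⁻` of normal gene sequences
(label 0) and mutated sequences (label 1) obtained by applying each driver
mutation (1-based position, ref/alt allele) to its reference gene. Balance
is per gene: each gene's normal sequence is replicated once per mutation of
that gene.

**Features (522 per sequence).** For each k-mer configuration k = 1, 2, 3
(alphabet size K = 4, 16, 64, codes `A=0,C=1,G=2,T=3` in base 4):

* frequency vector `β_i` — count of each k-mer (K values);
* AAPIV / reverse AAPIV `λ_i = Σ positions of symbol i` on the forward and
  reversed code list (2K values);
* three square arrangements — the row-major sequence matrix
  (side `N = max(4, ⌈√L'⌉)`, zero-padded), the position-relative incidence
  matrix `PRIM[i,j] = Σ_{p > f_i, s_p = j} (p − f_i)` (with `f_i` the first
  occurrence of symbol i), and its reverse-sequence counterpart RPRIM —
  each summarized by 30 statistical moments: raw
  `R_ab = Σ_p Σ_q p^a q^b G(p,q)`, central
  `C_ab = Σ_p Σ_q (p−x̄)^a (q−ȳ)^b G(p,q)`, and discrete Hahn moments
  `H_ab = Σ_p Σ_q G(p,q) h_a(q,N) h_b(p,N)`, for the ten orders
  `a + b ≤ 3`.

That is 3 × (K + 2K) = 252 incidence/frequency values plus
3 × 3 × 30 = 270 moment values = **522**, in a documented layout
(`featureLayout()`).

**Classifier.** Three base networks — LSTM, GRU and bidirectional LSTM —
share the architecture *dense 522→128 projection → gated recurrent layer
(width 128, single timestep) → dense 64 → dropout → dense 64 → dropout →
sigmoid*, trained with Adam (1e-3) on binary cross-entropy. The networks
are implemented natively in R with BLAS matrix algebra and manual
backpropagation, so training is exactly reproducible from a seed. A
logistic-regression meta-learner is stacked on out-of-fold base
probabilities (internal stratified 5-fold), then the bases are refitted on
the full training split: `ŷ = G(f₁, f₂, f₃)`.

**Evaluation.** Self-consistency (SCT: train = test = everything),
independent-set (IST: stratified 80/20) and stratified 10-fold
cross-validation, each reporting accuracy, precision, recall, sensitivity,
specificity, F1, MCC, Cohen's kappa (`(P_o − P_e)/(1 − P_e)`) and the
rank-based (Mann–Whitney) AUC with the ROC curve. Min–max feature
standardization is always fitted on the training portion only.

## Worked example

```r
library(SeqMomentStack)

cfg <- syntheticConfig(nGenes = 6L, lengthRange = c(120L, 400L),
                       nMutations = 40L, effectSize = 0.8, seed = 42L)
corpus <- generateLabeledCorpus(cfg)
corpus
#> LabeledCorpus with 80 sequences ( 40 mutated / 40 normal ) across 6 genes
#>   sequence lengths: 168 - 347 nt

head(summarizeCorpus(corpus), 3)   # Zipf-skewed per-gene mutation counts
#>   Symbol Mutation Sample
#> 1 GENE01       27     27
#> 2 GENE02        6      6
#> 3 GENE03        3      3

se <- featurize(corpus)            # 522 x 80 SummarizedExperiment
dim(se)
#> [1] 522  80

report <- runIST(se, baseConfigs(epochs = 30L, seed = 42L), seed = 42L)
report
#> MetricsReport [ist]
#>   confusion: TP=8 FP=0 TN=8 FN=0
#>   accuracy     1.0000
#>   precision    1.0000
#>   ...
#>   mcc          1.0000
#>   cohens_kappa 1.0000
#>   auc          1.0000
```

With `effectSize = 0.8` the generator plants a trinucleotide-motif
enrichment in the mutated class, and the held-out 16 samples (20% of 80,
stratified) are classified perfectly — the confusion counts, MCC = 1 and
AUC = 1 say the planted compositional signal is fully recovered by the
feature set and the ensemble. Real corpora are much harder; see the
methods vignette for what this benchmark does and does not demonstrate.

To run on your own data instead of the generator, supply a reference FASTA
and a `gene,position,ref,alt,sample_id` table:

```r
refs <- readReferenceFasta("genes.fa")
muts <- readMutationTable("driver_mutations.csv")
corpus <- buildLabeledDataset(refs, muts)
```

A thin CLI covering simulate / featurize / evaluate / run-all is installed
at `inst/scripts/seqmomentstack.R`; `runPipeline()` drives the same stages
from a single YAML configuration with a reproducibility manifest.

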