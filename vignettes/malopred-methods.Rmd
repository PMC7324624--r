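---
title: "Hybrid malonylation-site prediction: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid malonylation-site prediction: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(malopred)
```

## The problem

Lysine malonylation (Kmal) is a reversible post-translational modification in
which a malonyl group is attached to a lysine side chain. It participates in
metabolic regulation in mammals and plants, and mapping modified sites by mass
spectrometry is slow and expensive, which motivates sequence-based
prediction: given a protein and a candidate lysine, estimate the probability
that the site is malonylated.

`malopred` frames this as binary classification of fixed-length peptide
fragments. A site at position $p$ in a protein is represented by the window

$$R_{-n} \, R_{-(n-1)} \cdots R_{-1} \, K \, R_{1} \cdots R_{n-1} \, R_{n},$$

a string of $2n+1$ residues centered on the lysine. Windows that run past a
protein terminus are completed with the dummy residue `X`, so every fragment
has exactly $2n+1$ characters over a 21-letter alphabet (20 standard amino
acids plus `X`).

## Dataset handling

Training data arrive as a FASTA file plus a site table
(`protein_id`, 1-based `position`, 0/1 `label`). Before modelling, the
pipeline reduces redundancy in two steps, both using ungapped positional
identity in which `X` never counts as a match:

* **Within-set reduction** (`reduce_redundancy()`): a greedy scan that keeps
  a fragment only if its identity to every previously kept fragment is below
  a threshold (default 0.40). Greedy scanning in input order makes the result
  deterministic and idempotent.
* **Cross-class filtering** (`cross_class_filter()`): any negative whose
  identity to some positive reaches the threshold is discarded; positives are
  never touched.

Train/test splitting (`split_dataset()`) is stratified by label. With
realistic site rates around 6% positives, unstratified sampling can produce
folds with almost no positive examples, so stratification is on by default
even though a plain random split would be the minimal reading of the
protocol. Mammalian-style runs use an 80/20 split, plant-style runs 70/30.

## The five fragment encodings

For a window of size $L = 2n + 1$:

| Feature  | Shape            | Center | Consumed by |
|----------|------------------|--------|-------------|
| AAC      | 21-vector        | excluded | random forest |
| one-hot  | $(L-1)\times 21$ | excluded | CNN |
| PAAC     | $(21+\lambda)$-vector | included | random forest |
| AAindex  | $(L-1)\times k$  | excluded | CNN |
| PSSM     | $L\times 20$     | included | CNN |

The center lysine is invariant by construction, so the composition-style and
per-position property encoders drop it; the PSSM profile keeps it because the
evolutionary profile of the central residue is not constant. These choices
reproduce the published dimensionalities exactly (one-hot $30\times 21$ at
window 31, AAindex $32\times 46$ at window 33 with $k=46$, PSSM
$33\times 20$ at window 33, AAC 21, PAAC 34 at $\lambda = 13$).

**PAAC.** The pseudo-amino-acid composition augments the 21-letter
composition with $\lambda$ sequence-order correlation factors
$\theta_1, \dots, \theta_\lambda$ built from standardized hydrophobicity,
hydrophilicity and side-chain mass. The standard descriptor has dimension
$20+\lambda$; the printed dimension 34 at $\lambda = 13$ is only consistent
with a 21-letter composition block, so the padding symbol participates in the
composition (with zero property values) and is skipped in the correlation
sums. The correlation weight is the classical $w = 0.05$ (configurable).
Fragments with fewer than $\lambda + 1$ usable (non-`X`) residues are
rejected with an error naming the minimum window rather than silently
lowering $\lambda$.

**AAindex property selection.** Each of the 531 properties in the packaged
table is scored by summed information gain: at every flank position the
property value of the residue is discretized (median split by default,
configurable bin count) and $IG = H(\text{label}) - H(\text{label}\mid
\text{bin})$ is accumulated over positions; the top $k$ properties are kept
(46 for the mammalian preset, 30 for the plant preset), ties broken by
property ID so selection is deterministic and order-invariant.

The packaged property table (`synthetic_aaindex()`) is a deterministic
synthetic stand-in at full catalogue scale: three published anchor scales
(Kyte-Doolittle hydropathy, Hopp-Woods hydrophilicity, side-chain mass)
followed by seeded synthetic scales up to 531 rows. It exists so the
selection and encoding pathways run at realistic dimensionality with no
external downloads; its synthetic rows carry no biochemical meaning, and any
real property catalogue in AAindex1 flat-file format can be dropped in via
`parse_aaindex1()`.

**PSSM.** Real evolutionary profiles are read from PSI-BLAST
`-out_ascii_pssm` files (`parse_pssm_profile()`), sliced to the fragment
window, and fed to the CNN without rescaling. When profiles are unavailable,
`pseudo_pssm()` substitutes the BLOSUM62 substitution row of each residue
(zero rows for padding) and marks the result as a surrogate. The surrogate
encodes residue identity through substitution scores, not conservation, so
results on surrogate profiles say nothing about the added value of true
evolutionary information.

## Base learners

Matrix features are learned by a compact convolutional network; vector
features by random forests (500 trees), with an RBF-SVM available as an
alternative vector learner.

The CNN (`train_cnn()`) has two convolution + max-pooling blocks followed by
three fully connected layers. Convolutions slide along the position axis
with kernels spanning all feature columns (extent 3, pooling extent 2);
filter counts are 32 and 64; dense widths 128 and 64 precede a 2-unit
softmax. Training uses ReLU activations, dropout 0.3 after each hidden dense
layer, class-weighted cross-entropy (inverse class frequency — the tiny
published decision cutoffs imply raw imbalanced probabilities were kept, so
the cutoff handles imbalance downstream), and Adam at learning rate $10^{-3}$
with batch size 64, at most 50 epochs and early stopping on the AUC of a
stratified 10% validation slice (patience 5). All of this is configurable
through `cnn_config()`. The implementation is vectorised base R (im2col
reshaping makes every layer a BLAS matrix product) and its gradients are
verified against finite differences in the test suite. Given a seed,
training is bit-reproducible.

Windows too short for two pooling stages (below 11 residues for flank
matrices) are rejected with an explicit error; the supported grids (15-35
mammal, 11-39 plant, odd sizes only — the center-lysine construction forces
odd windows) all pass.

## Window selection and cross-validation

`crossvalidate()` assigns stratified folds (default 10), collects exactly one
out-of-fold probability per sample, and reports the pooled out-of-fold AUC.
`window_grid_search()` re-extracts fragments at every window in the grid and
returns the argmax-AUC window, ties going to the smaller window (cheaper
features, deterministic). Invalid windows — PAAC minimums, CNN topology
minimums — are skipped with a warning rather than failing the whole search.
For AAindex, property selection is recomputed within the training set at each
candidate window.

## Stacked ensembles

Each base component (`fit_component()`) produces out-of-fold probabilities
during an internal stratified cross-validation (5 folds by default) and is
then refit on the full training data for deployment.

* **Plant preset (`build_plant_ensemble()`):** the meta-input is the
  5-vector of component positive probabilities, and the meta-model an
  RBF-SVM; decision cutoff 0.195. The meta-SVM is trained on out-of-fold
  probabilities, so it never sees an in-fold score.
* **Mammalian preset (`build_mammal_ensemble()`):** the meta-input
  concatenates the penultimate-layer activations (width 64) of the three CNN
  components with the raw 21-dim AAC and 34-dim PAAC vectors, and the
  meta-model is a single-hidden-layer network (32 units, trained with
  inverse-frequency case weights); decision cutoff 0.046. The RF components
  are excluded from this preset.
* **Majority vote (`build_majority_ensemble()`):** baseline; positive iff
  strictly more than half the components vote positive, even splits negative.

A design point worth recording: out-of-fold stacking is the right leakage
control for *probabilities*, but it is ill-posed for *learned
representations*. The coordinates of the penultimate layer of independently
initialised networks are arbitrary up to permutation and rotation, so a
meta-learner fitted to fold-model representations cannot read the refit
deployment network's representations — in simulation this collapses the
stack to worse-than-chance. The mammalian meta-network is therefore trained
on the deployed CNNs' representations of the training data. The residual
leakage surface (the extractor has seen the training labels) is bounded
empirically: the test suite checks that the fitted stack scores shuffled
held-out labels at chance.

Prediction on a novel protein (`predict_protein()`) enumerates every lysine,
rebuilds each component's fragment at that component's own window size
(best windows differ per feature), and applies the ensemble cutoff with
`score >= cutoff` counting as positive — ties are positive calls, fixed for
determinism.

## Evaluation metrics

From confusion counts at a cutoff: $SEN = TP/(TP+FN)$, $SPE = TN/(FP+TN)$,
$ACC = (TP+TN)/(TP+TN+FP+FN)$, and

$$MCC = \frac{TP \cdot TN - FP \cdot FN}
{\sqrt{(TP+FP)(TP+FN)(FP+TN)(TN+FN)}},$$

computed with the denominator as a product of square roots so counts up to
$\sim 10^5$ stay in safe floating-point range. ROC-AUC is the rank-based
(Mann-Whitney) form, identical to the trapezoidal area with ties counting
one half. Undefined cases are flagged rather than propagated as NaN: a zero
denominator yields `NA_real_` for the ratios, and MCC returns 0 carrying
`attr(undefined = TRUE)`. Reports print at 3 decimals; stored values keep
full precision.

## Sequence statistics

`aac_by_class()` contrasts mean flank composition between classes.
`positional_enrichment()` performs a per-(position, residue) two-proportion
test between the positive and negative sets: a pooled z-test when all
expected counts reach 5, and Fisher's exact test otherwise. Fisher's test
was chosen as the exact fallback because it is symmetric in the two classes,
which preserves the invariant that swapping the input sets exactly exchanges
"enriched" and "depleted" flags. No multiple-testing correction is applied
by default (mirroring common two-sample-logo practice); a Bonferroni option
exists. With roughly $2n \times 20$ cells tested, a per-cell level of
$\alpha$ implies about $40n\alpha$ false flags on pure noise — users scanning
for candidate motifs should either use the correction or read isolated flags
accordingly. `pearson_feature_label()` / `pcc_screen()` give the standard
product-moment screen of encoder dimensions against the label.

## The synthetic-data generator

`generate_fragments()` draws flank residues per position from categorical
distributions: negatives from a background composition (uniform by default),
positives from the background adjusted by a `motif_spec()` — per offset,
named residues gain an excess probability (negative = depletion), specified
residues take `background + excess` clipped at zero, and unspecified
residues share the remaining mass proportionally. `default_motif()` encodes
a qualitative mammalian-like pattern: lysine enriched across offsets
$\pm1..\pm8$ (excess $0.10\,e$), glutamate enriched proximally at
$\pm1..\pm3$ ($0.12\,e$), leucine depleted mid-flank at $\pm4..\pm6$
($-0.04\,e$), with a single effect scale $e$. `generate_annotated_proteome()`
implants such contexts at annotated, window-spaced lysine sites in random
background proteins (default site rate 0.06, matching realistic ~1:15 class
imbalance) and emits exactly the FASTA + site-table formats the package
reads.

What the generator does *not* emulate: real proteome composition biases,
homology structure between sequences (every synthetic fragment is
independent, so redundancy reduction is exercised only logically),
position-dependent background, and genuine evolutionary profiles. Passing
the planted-signal recovery tests therefore demonstrates that the machinery
learns and aggregates positional signal correctly — it does not certify
real-data accuracy, which depends on curated modification databases and
PSI-BLAST profiles outside this package's scope.

## Problem sizes and numerical choices

The shipped verification runs use sizes chosen to make every stochastic
check decisive at desk scale: planted-motif recovery trains on 500+500
fragments at window 21 with effect scale 2 and evaluates on 300+300
held-out fragments (CNNs capped at 20 epochs — early stopping typically
triggers well before that on separable data); enrichment recovery uses
500+500 fragments with a planted 40%-vs-5% lysine excess at offsets
$\pm 1$, where the exact binomial tail probability of the planted cells is
below $10^{-10}$; null controls use label shuffles of the same data. All
randomness flows through explicit integer seeds, and library code saves and
restores the caller's RNG state.

Numerical tie-breaks fixed for determinism: ties in window selection go to
the smaller window; property-selection ties break by property ID; max-pooling
ties take the earliest position; classification ties at the cutoff are
positive calls.

## Known limitations

* The packaged property table is synthetic beyond its three anchor scales;
  information-gain selection over it exercises the algorithm, not real
  biochemistry.
* Surrogate PSSM profiles are substitution-score lookups; conclusions about
  evolutionary features require real PSI-BLAST profiles supplied by the user.
* The greedy identity reducer is quadratic in the number of fragments; for
  very large site tables an external clustering tool is the practical choice,
  and the module's contract was designed so such a tool can be swapped in.
* Published real-data performance figures for this class of predictor depend
  on the original curated datasets and profiles and are not reproducible from
  this package alone; the package verifies its machinery on synthetic data
  and reproduces the published metric arithmetic exactly.
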