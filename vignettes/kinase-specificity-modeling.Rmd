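---
title: "Modeling kinase-substrate specificity with a small transformer encoder"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling kinase-substrate specificity with a small transformer encoder}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Protein kinases phosphorylate serine, threonine and tyrosine residues of
substrate proteins, and each kinase recognizes its sites largely through the
residues immediately flanking the phosphosite: basophilic kinases prefer
basic residues N-terminal to the site (P-3/P-2), proline-directed kinases
require a proline at P+1, acidophilic kinases acidic flanks at P+1..P+3,
SQ-motif kinases a glutamine at P+1, and tyrosine kinases act on Y-centered
sites. Mass spectrometry has produced enormous catalogs of phosphosites but,
for most of them, the identity of the responsible kinase is unknown.

`kinasite` treats kinase assignment as context-based question answering over
sequence alone: the 11-mer peptide window around a candidate site is the
context, the unaligned kinase catalytic-domain sequence is the question, and
the answer is a probability that this kinase phosphorylates this site. A
single model shared across all kinases replaces the per-kinase classifiers
of older tools, so predictions extend to any kinase for which a domain
sequence exists.

## Data curation

The unit of supervision is a labeled pair: an 11-mer window whose center is
S, T or Y (sites within five residues of a terminus are padded with `-` so
the candidate site always sits in the middle), plus a kinase. Three label
classes are built from a verified site table:

* **positive** — the kinase is annotated to phosphorylate that site;
* **hard negative** — the peptide is a known phosphosite of some *other*
  kinase but carries no evidence for the paired kinase (a site annotated to
  both kinases is a hard negative for neither);
* **easy negative** — an S/T/Y-centered window from the substrate proteome
  with no phosphorylation evidence at all.

Annotation rows are verified against the substrate sequences before use:
a row whose residue letter disagrees with the sequence at the stated
position (or names an unknown substrate or a non-S/T/Y residue) is dropped
and reported, never silently corrected.

Positives of kinases with more than 50 examples are split 70:15:15 into
train/validation/test; kinases with at most 50 positives contribute to
training only. Validation and test positives each receive one paired hard
negative drawn without replacement from the kinase's pool; those peptides
are reserved and never reappear in that kinase's training negatives. Every
training positive receives `n_easy` easy and `m_hard` hard negatives
(the published recipe uses 15 + 1, a 1:16 ratio). Because identical 11-mers
can occur at different positions, partitioning is done at the peptide level
within each kinase, so the same (kinase, peptide) pair can never appear in
two partitions. Rounding takes the floor on validation and test and gives
the remainder to train, so evaluation sets are never larger than their
nominal share; a kinase with exactly 50 positives is treated as
training-only (the conservative reading of "more than 50").

## Training augmentations

Four training-time perturbations make the model robust and keep resampled
repeats from being byte-identical. They apply to the training partition
only, and never touch the peptide:

* **Positive resampling** — kinases above the 50-positive threshold are
  upsampled with replacement to 1118 (the largest per-kinase count in the
  curated data this emulates), the rest to 50; a kinase already at or above
  its target is left unchanged.
* **Boundary shifting** — each terminus of the domain interval moves by an
  independent uniform draw from {-5, ..., +5}, clamped to the protein (a
  draw that would empty the interval is re-drawn). Uniform including 0 is
  the minimal assumption consistent with "up to 5 residues".
* **Kinase masking** — each domain position is replaced by the mask marker
  independently with probability 0.05. Bernoulli (expected-rate) semantics
  rather than exactly 5% of positions; the rate tests use a binomial
  tolerance accordingly.
* Augmentations are re-drawn every epoch (online), so resampling plus
  shifting/masking yields varied repeats.

Composition order is resample, then shift, then mask; negatives undergo
shifting and masking only.

## Encoding and model

The vocabulary holds 4 special tokens (`<pad>`, `<cls>`, `<eos>`,
`<mask>`) and 21 residue tokens (20 amino acids plus X), 25 in all. A pair
is encoded as `<cls> peptide <eos> <cls> kinase <eos>` —
`t_peptide + t_kinase + 4` tokens, with the candidate phosphosite always at
position 7. Peptide padding dashes map to `<pad>`; the augmentation mask
marker and the unknown residue X map to `<mask>` (an X is exactly a
position of unknown identity). The same start/end tokens are reused for
both spans; token order disambiguates them.

The encoder is a pre-layer-norm transformer with learned positional
embeddings: the reference architecture is 6 layers x 12 heads x 768
dimensions, while tests and the synthetic benchmark use a desk-scale
configuration (2 x 4 x 32, feed-forward width 64) that trains in seconds
on one CPU. The forward pass and the full analytic backward pass are
implemented in RcppArmadillo and verified against central finite
differences in the test suite; all randomness lives on the R side, so runs
are bit-reproducible given a seed. No dropout is used: the models are
small, the augmentations already inject noise, and determinism keeps the
early-stopping contract exact.

**Pre-training** masks 15% of residue tokens (pure masking — selected
tokens are always replaced by `<mask>`, with no random/keep substitution;
a BERT-style 80/10/10 scheme is available via `mlm_corrupt()` callers that
post-process, but is not the default) and minimizes the mean negative
log-likelihood of the original tokens at masked positions. A uniform
predictor scores exactly ln 25. Published-scale training used AdamW at
5e-5; the desk-scale recipe uses 1e-3 because a 33k-parameter model on a
synthetic corpus is far from the regime that motivated 5e-5.

**Fine-tuning** reads only the encoder output at the center position,
passes it through one hidden layer of width `embed_dim` with a GELU
nonlinearity (the head's width and activation are unspecified in the
source description; one smooth hidden layer is the minimal choice) and a
two-way softmax, and minimizes focal loss

$$\mathrm{FL}(p_t) = -(1-p_t)^{\gamma}\,\log p_t, \qquad \gamma = 2,$$

where $p_t$ is the predicted probability of the true class. At
$\gamma = 0$ this is cross-entropy; larger $\gamma$ down-weights
well-classified examples so the extreme positive:negative imbalance does
not drown the positives. (The formula is sometimes printed without the
minus sign; a loss must be bounded below, so the standard non-negative
form is implemented.) A freshly initialized model has a zero output layer
and scores every pair at exactly 0.5; when fine-tuning starts it re-draws
the head with small random output weights, because a zero output layer is
a saddle point that leaves the encoder without gradient signal on the
first steps — on some seeds training never escaped the all-negative basin
without this. For the same reason fine-tuning uses linear learning-rate
warmup (100 steps by default) and global-norm gradient clipping at 1.0,
both standard for Adam-trained transformers. Early stopping monitors
validation focal loss once per epoch with patience 5 ("early stopping
steps" read as evaluations) and returns the best-validation checkpoint.
All encoder layers remain trainable during fine-tuning. Class imbalance is
handled by focal loss alone — no class re-weighting.

## Evaluation

* `roc_auc()` — Mann-Whitney concordance with ties counted 1/2 (identical
  to trapezoidal integration of the ROC curve).
* `pr_auc()` — area under the step-wise, non-interpolated precision-recall
  curve; linear interpolation is rejected because it overestimates area.
* `fpr()` — on an all-negative easy set, the fraction of scores above the
  decision threshold (0.5 by default; the threshold is exposed because no
  canonical value is stated).

Easy negatives are deliberately excluded from the AUCs — random S/T/Y
windows are too easy and would inflate both — and instead feed the FPR,
which guards against a model that fires on never-phosphorylated peptides.
`stratified_report()` computes per-kinase AUCs on each kinase's positives
and paired hard negatives, unweighted family and group means over member
kinases, and both a pooled overall AUC and the mean per-kinase AUC (the two
readings of an "overall" figure; both are reported).

## Interpretability

`extract_phosphosite_embedding()` returns the encoder output row at the
center index with metadata, for external 2-D projection (UMAP or similar —
the projection itself is delegated). `attention_profile()` aggregates
final-layer attention onto the 11 peptide positions, averaged over heads
and pairs, in two modes: `column-mean` (attention received by each peptide
position from all query tokens) and `center-row` (attention paid by the
phosphosite token itself). The exact aggregation used in the original
analysis is described in supplementary material that is not available, so
both natural readings are implemented and the determinant-position checks
accept either.

## The synthetic kinome

Because the curated multi-database phosphosite compendium cannot be
redistributed or reconstructed offline, the package ships a generator that
emulates its statistical structure: five grammar families (BASO, PRO,
ACID, SQ, TYR as above), four kinases per family derived from a random
family consensus with 5% point mutations, 80-residue domains embedded in
120-residue proteins (so boundary shifting has room to act), 200 random
substrates of 300 residues, per-kinase implanted-site counts drawn from a
power law between 1 and 120 (emulating the strong skew of real per-kinase
substrate counts), and a 5% grammar-violation rate standing in for
annotation noise. Implants never overlap and keep a 5-residue margin from
termini.

A conforming site is annotated as a positive for *every* kinase of the
implanting family: family members share the same planted grammar, so this
is the generator's ground truth, and it makes the generic pool-building
rule produce cross-family hard negatives. Without the sharing, a
same-family hard negative would be statistically indistinguishable from a
positive — label noise by construction that no model could overcome.
Violating sites are annotated only for the kinase they were drawn for.

What the generator does **not** emulate: real kinome phylogeny, substrate
composition biases, structural context, or conflicting annotations between
databases. Passing the synthetic benchmark therefore demonstrates that the
pipeline can learn planted sequence determinants end to end — not that it
reproduces published benchmark figures on real data, which require the
curated compendium and large-scale pre-training.

## Desk-scale problem sizes and numerical choices

The test suite and the synthetic benchmark run one study in a few
minutes on a single CPU: default generator (20 kinases, 200 substrates,
~1500-2500 annotation rows), 4 pre-training epochs (lr 1e-3, batch 16),
up to 10 fine-tuning epochs (lr 1.5e-3 after warmup, gamma 2, batch 32,
patience 5), training negatives n_easy = 6, m_hard = 1, and resampling
targets scaled to 150/50. A generous share of easy negatives matters
doubly here: it is what teaches the model to stay quiet on
never-phosphorylated peptides (the false-positive-rate criterion), echoing
the observation that introducing easy negatives into training dramatically
improves discrimination against non-phosphosites. The motif-recovery
check averages three independent seeds. Probabilities
are clamped to [1e-12, 1 - 1e-12] inside the focal loss; layer-norm uses
eps 1e-5; checkpoints store parameters as JSON at 17 significant digits so
they round-trip bit-exactly through text.

## Known limitations

* Pure-R/Armadillo training is single-threaded and desk-scale; the
  reference 6x12x768 architecture is constructed and exercised for shape
  and interface, not trained here.
* No homology-based leakage control between partitions (none is described
  for the original protocol); identical peptides are controlled, remote
  homology is not.
* The loader takes a single pre-merged annotation table; reconciling
  conflicting source databases is out of scope.
* No zero-shot extension to unseen kinase families is attempted.
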