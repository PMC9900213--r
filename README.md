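# kinasite

Kinase-specific phosphosite prediction from unaligned sequence, as a single
model for the whole kinome.

Thousands of phosphorylation sites are known from proteomics, but for most
of them the kinase responsible is not. `kinasite` frames kinase assignment
as context-based question answering over sequence alone: the 11-mer peptide
window around a candidate serine/threonine/tyrosine is the context, the
kinase catalytic-domain sequence is the question, and the answer is

> P(kinase phosphorylates site) = softmax(FFN(h_center)),

where `h_center` is the transformer-encoder embedding of the candidate
phosphosite inside the token sequence
`<cls> peptide <eos> <cls> kinase-domain <eos>`. The encoder is pre-trained
with masked language modeling (15% of residue tokens masked, mean negative
log-likelihood at masked positions) and fine-tuned with focal loss

    FL(p_t) = -(1 - p_t)^gamma * log(p_t),   gamma = 2,

which down-weights well-classified examples so the extreme 1:16
positive:negative training imbalance does not drown the positives.

The package covers the full workflow in tidyverse-native style (tibbles in,
tibbles out):

* **Curation** — verified site tables; positive / hard-negative /
  easy-negative pools (hard negatives are other kinases' phosphosites;
  easy negatives are never-phosphorylated S/T/Y windows); 70:15:15
  train/validation/test splits with one paired hard negative per
  evaluation positive; kinases with ≤ 50 positives are training-only.
* **Augmentation** — positive resampling to 1118/50, domain-boundary
  shifts of up to ±5 residues per terminus, 5% kinase-token masking.
* **Model** — a configurable transformer encoder (reference architecture
  6 layers × 12 heads × 768 dims; desk-scale 2 × 4 × 32 for testing) with
  MLM and center-residue classification heads, written in RcppArmadillo
  with analytic gradients (finite-difference-verified) and AdamW.
* **Evaluation** — AUC-ROC (Mann–Whitney, ties ½), step-wise AUC-PRC, FPR
  on an all-easy-negative set, stratified per kinase / family / group.
* **Interpretability** — phosphosite embeddings for external projection and
  per-position substrate attention profiles.
* **Synthetic kinome** — a generator with planted specificity grammars
  (basophilic, proline-directed, acidophilic, SQ, tyrosine) so the whole
  pipeline is testable end to end without any external database.

## Worked example

A complete study on the synthetic kinome — generate, curate, pre-train,
fine-tune, evaluate — runs in a few minutes on one CPU:

```r
library(kinasite)

sim   <- simulate_kinome(synthetic_kinome_config(seed = 101))
ann   <- read_annotation_table(sim$annotations, sim$substrates)
pools <- build_pools(ann, sim$substrates)
pools
#> <kinasite_pools> 843 positives (20 kinases), 3537 hard-negative rows,
#>                  8832 easy negatives

split <- split_dataset(pools, seed = 102) |>
  sample_training_negatives(pools, n_easy = 6, m_hard = 1, seed = 103)

model <- init_model(tiny_model_config(), seed = 104) |>
  pretrain(c(kinase_domains(sim$kinases), sim$substrates$sequence),
           train_config("pretrain", lr = 1e-3, batch_size = 16,
                        epochs = 4, seed = 105)) |>
  finetune(split, sim$kinases,
           train_config("finetune", lr = 1.5e-3, batch_size = 32,
                        epochs = 10, seed = 106),
           augmentation_config(resample_target_large = 150))

test <- split$test
test$kinase_domain <- kinase_domains(
  sim$kinases[match(test$kinase_id, sim$kinases$kinase_id), ])
scored <- classify(model, test)
roc_auc(scored$probability, scored$label == "positive")
#> [1] 0.9805057

easy <- sample_easy_test(split, pools, 1000, seed = 107)
easy$kinase_domain <- kinase_domains(
  sim$kinases[match(easy$kinase_id, sim$kinases$kinase_id), ])
fpr(classify(model, easy)$probability)
#> [1] 0.01565762
```

The held-out AUC-ROC of 0.98 says the fine-tuned model ranks true
kinase–peptide pairs above hard negatives (other kinases' sites) almost
perfectly; the 1.5% FPR says it stays quiet on never-phosphorylated
peptides. Fitted models are broom-friendly (`tidy()` for the loss trace,
`glance()` for a one-row summary) and `autoplot()` works on models,
reports and attention profiles. Attention profiles show where the
classifier looks, e.g. the P+1 proline of a proline-directed kinase:

```r
pro <- subset(test, kinase_id == "PRO_1" & label == "positive")
autoplot(attention_profile(model, pro, mode = "center-row"))
```

A command-line front-end mirrors the same workflow
(`inst/cli/kinasite synth | curate | pretrain | finetune | predict |
evaluate | interpret`); see `?cli_main`.

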