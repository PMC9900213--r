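# Reference-scale configuration: the published architecture and training
# recipe. Training at this scale needs the full curated phosphosite data
# and accelerator hardware; it is provided for completeness and for running
# `predict`/`interpret` against externally trained checkpoints.
pretrain:
  n_layers: 6
  n_heads: 12
  embed_dim: 768
  ffn_dim: 3072
  max_len: 512
  lr: 5.0e-5
  batch_size: 48
  epochs: 50
  mlm_rate: 0.15
finetune:
  lr: 2.0e-5
  gamma: 2
  batch_size: 48
  patience: 5
curate:
  n_easy: 15
  m_hard: 1
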