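# Desk-scale configuration: trains on the synthetic kinome in minutes on
# one CPU. This is the configuration exercised by the test suite.
pretrain:
  n_layers: 2
  n_heads: 4
  embed_dim: 32
  ffn_dim: 64
  max_len: 160
  lr: 1.0e-3
  batch_size: 16
  epochs: 4
  mlm_rate: 0.15
finetune:
  lr: 1.5e-3
  gamma: 2
  batch_size: 32
  epochs: 10
  patience: 5
  resample_target: 150
curate:
  n_easy: 6
  m_hard: 1
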