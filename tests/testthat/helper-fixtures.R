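# Shared fixtures: everything is generated in code at test time.

# minimal transformer for shape/determinism tests
probe_config <- function() {
  model_config(n_layers = 2L, n_heads = 2L, embed_dim = 8L, ffn_dim = 12L,
               max_len = 48L)
}

# a couple of valid pairs for encoder-level tests
probe_pairs <- function() {
  tibble::tibble(
    peptide = c("AARKASAAAAA", "----MSAYT--", "QQQQQYQQQQQ"),
    kinase_domain = c("ACDKACDKACDK", "WYHHGGLLMMNP", "ACDKACDKACDK"))
}

# miniature synthetic study for fast invariant checks
mini_synth_config <- function(seed = 1L, epsilon = 0.05,
                              families = default_grammars()[c("BASO", "PRO",
                                                              "TYR")]) {
  synthetic_kinome_config(
    families = families, kinases_per_family = 2L, domain_length = 20L,
    full_length = 34L, n_substrates = 15L, substrate_length = 80L,
    pos_min = 4L, pos_max = 12L, epsilon = epsilon, seed = seed)
}

# hand-built two-kinase toy study used by curation tests
toy_study <- function() {
  substrates <- tibble::tibble(
    substrate_id = c("S1", "S2"),
    sequence = c("AAAAASAAAAATAAAAAYAAAAA",   # S@6, T@12, Y@18
                 "MSAYTGGGGGSGGGGG"),          # S@2, Y@4, T@5, S@11
    organism = NA_character_)
  annotations <- tibble::tibble(
    kinase_id     = c("K1", "K2", "K1"),
    substrate_id  = c("S1", "S1", "S2"),
    site_position = c(6L, 12L, 2L),
    residue       = c("S", "T", "S"))
  list(substrates = substrates, annotations = annotations)
}

rand_seq <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n,
               replace = TRUE), collapse = "")
}
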