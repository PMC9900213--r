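#' The residue vocabulary
#'
#' Four special tokens (`<pad>`, `<cls>`, `<eos>`, `<mask>`) followed by the
#' 20 amino acids and `X`, 25 tokens in all. Ids are 0-based and stable:
#' they are fixed by construction and survive JSON round-trips. The peptide
#' padding character `-` encodes to `<pad>`; the augmentation mask marker
#' `#` and the unknown residue `X` both encode to `<mask>` (an `X` position
#' is by definition of uncertain identity), while `X` keeps its own slot in
#' the prediction vocabulary.
#'
#' @return a `kinasite_vocab` object: tibble with `token` and `id` columns
#'   plus attributes used by the encoders.
#' @export
vocabulary <- function() {
  specials <- c("<pad>", "<cls>", "<eos>", "<mask>")
  tok <- c(specials, AA_ALPHABET)
  vocab <- tibble(token = tok, id = seq_along(tok) - 1L)
  structure(vocab, class = c("kinasite_vocab", class(vocab)),
            pad_id = 0L, cls_id = 1L, eos_id = 2L, mask_id = 3L,
            residue_ids = 4L:(length(tok) - 1L))
}

vocab_size <- function(vocab = vocabulary()) nrow(vocab)

# fast residue-character -> id lookup table
vocab_lookup <- function(vocab = vocabulary()) {
  map <- integer(0)
  map[vocab$token[-(1:4)]] <- vocab$id[-(1:4)]
  map[PAD_CHAR] <- attr(vocab, "pad_id")
  map[MASK_CHAR] <- attr(vocab, "mask_id")
  map["X"] <- attr(vocab, "mask_id")
  map
}

#' Write / read the vocabulary as JSON
#'
#' @param vocab a [vocabulary()].
#' @param path JSON file.
#' @return `path` (write) or the vocabulary tibble (read).
#' @export
write_vocabulary <- function(vocab, path) {
  jsonlite::write_json(list(token = vocab$token, id = vocab$id), path,
                       auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_vocabulary
#' @export
read_vocabulary <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  ref <- vocabulary()
  if (!identical(as.character(x$token), ref$token) ||
      !identical(as.integer(x$id), ref$id)) {
    abort("vocabulary file does not match the package vocabulary")
  }
  ref
}

#' Tokenize a sequence
#'
#' Maps residues to ids and flanks the sequence with `<cls>`/`<eos>`.
#'
#' @param seqs character vector of sequences (may contain `-`, `#`, `X`).
#' @param vocab a [vocabulary()].
#' @param add_specials flank with start/end tokens (default TRUE).
#' @return list of 0-based integer id vectors.
#' @export
tokenize <- function(seqs, vocab = vocabulary(), add_specials = TRUE) {
  map <- vocab_lookup(vocab)
  cls <- attr(vocab, "cls_id"); eos <- attr(vocab, "eos_id")
  lapply(seq_chars(seqs), function(ch) {
    ids <- unname(map[ch])
    if (anyNA(ids)) {
      abort(sprintf("cannot tokenize character '%s'", ch[is.na(ids)][1]))
    }
    if (add_specials) c(cls, ids, eos) else ids
  })
}

#' Decode token ids back to characters
#' @param ids 0-based integer vector.
#' @param vocab a [vocabulary()].
#' @return character vector of tokens.
#' @export
detokenize <- function(ids, vocab = vocabulary()) {
  vocab$token[match(ids, vocab$id)]
}

#' Encode peptide-kinase pairs as token sequences
#'
#' Builds the model input: the tokenized 11-mer peptide flanked by start and
#' end tokens, followed by the tokenized kinase domain flanked by start and
#' end tokens — `t_peptide + t_kinase + 4` tokens in total. The candidate
#' phosphosite (the peptide's middle residue) always sits at position 7
#' (1-based; offset 6 when counting from zero) regardless of kinase length.
#'
#' @param pairs tibble with `peptide` and `kinase_domain` columns (plus any
#'   metadata, carried through).
#' @param vocab a [vocabulary()].
#' @return an `encoded_pairs` object: list with `tokens` (list of 0-based id
#'   vectors), `center` (1-based center positions, all 7), `meta` (the input
#'   tibble) and `vocab`.
#' @export
encode_pairs <- function(pairs, vocab = vocabulary()) {
  pairs <- as_tibble(pairs)
  if (!all(c("peptide", "kinase_domain") %in% names(pairs))) {
    abort("pairs must have 'peptide' and 'kinase_domain' columns")
  }
  validate_windows(pairs$peptide)
  if (any(nchar(pairs$kinase_domain) == 0L)) {
    abort("kinase_domain must be non-empty")
  }
  pep <- tokenize(pairs$peptide, vocab)
  kin <- tokenize(pairs$kinase_domain, vocab)
  tokens <- purrr::map2(pep, kin, c)
  structure(list(tokens = tokens, center = rep(FLANK + 2L, length(tokens)),
                 meta = pairs, vocab = vocab),
            class = "encoded_pairs")
}

#' Encode a single peptide-kinase pair
#'
#' @param peptide an 11-mer window string.
#' @param kinase_domain the kinase-domain sequence.
#' @param vocab a [vocabulary()].
#' @return a list with `token_ids` (0-based), `center_index` (1-based, = 7)
#'   and the component lengths.
#' @export
encode_pair <- function(peptide, kinase_domain, vocab = vocabulary()) {
  enc <- encode_pairs(tibble(peptide = peptide,
                             kinase_domain = kinase_domain), vocab)
  list(token_ids = enc$tokens[[1]], center_index = enc$center[1],
       t_peptide = nchar(peptide), t_kinase = nchar(kinase_domain))
}

#' @export
print.encoded_pairs <- function(x, ...) {
  cat(sprintf("<encoded_pairs> %d sequences, lengths %d..%d\n",
              length(x$tokens), min(lengths(x$tokens)),
              max(lengths(x$tokens))))
  invisible(x)
}

#' Corrupt token sequences for masked language modeling
#'
#' Independently selects each residue token with probability `rate` and
#' replaces it with the `<mask>` token (pure masking; no random-token or
#' keep-as-is substitution). Special tokens are never selected. The original
#' ids at masked positions are retained as prediction targets.
#'
#' @param tokens list of 0-based token-id vectors (from [tokenize()] or
#'   [encode_pairs()]).
#' @param rate masking probability in (0, 1); default 0.15.
#' @param vocab a [vocabulary()].
#' @return an `mlm_batch`: list with `corrupted` (token vectors), `labels`
#'   (per-position original id at masked positions, -1 elsewhere) and `K`
#'   (total masked-token count).
#' @export
mlm_corrupt <- function(tokens, rate = 0.15, vocab = vocabulary()) {
  stopifnot(rate > 0, rate < 1)
  mask_id <- attr(vocab, "mask_id")
  res_ids <- attr(vocab, "residue_ids")
  labels <- vector("list", length(tokens))
  corrupted <- vector("list", length(tokens))
  K <- 0L
  for (i in seq_along(tokens)) {
    ids <- tokens[[i]]
    eligible <- ids %in% res_ids
    hit <- eligible & (runif(length(ids)) < rate)
    lab <- rep(-1L, length(ids))
    lab[hit] <- ids[hit]
    ids[hit] <- mask_id
    corrupted[[i]] <- ids
    labels[[i]] <- lab
    K <- K + sum(hit)
  }
  structure(list(corrupted = corrupted, labels = labels, K = K),
            class = "mlm_batch")
}
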