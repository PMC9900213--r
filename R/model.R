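#' Configure the transformer encoder
#'
#' Defaults mirror the published architecture: 6 attention layers of 12
#' heads producing 768 embedding dimensions. [tiny_model_config()] gives the
#' desk-scale configuration used throughout the test suite and the synthetic
#' benchmarks.
#'
#' @param n_layers number of attention layers.
#' @param n_heads attention heads per layer; must divide `embed_dim`.
#' @param embed_dim embedding dimension.
#' @param ffn_dim feed-forward hidden width (default `4 * embed_dim`).
#' @param max_len maximum token-sequence length (learned positional
#'   embeddings are allocated up to this length).
#' @return a `model_config` list.
#' @export
model_config <- function(n_layers = 6L, n_heads = 12L, embed_dim = 768L,
                         ffn_dim = 4L * embed_dim, max_len = 512L) {
  if (embed_dim %% n_heads != 0) {
    abort("embed_dim must be divisible by n_heads")
  }
  structure(list(n_layers = as.integer(n_layers),
                 n_heads = as.integer(n_heads),
                 embed_dim = as.integer(embed_dim),
                 ffn_dim = as.integer(ffn_dim),
                 max_len = as.integer(max_len),
                 vocab_size = vocab_size()),
            class = "model_config")
}

#' @rdname model_config
#' @export
tiny_model_config <- function(n_layers = 2L, n_heads = 4L, embed_dim = 32L,
                              ffn_dim = 64L, max_len = 160L) {
  model_config(n_layers, n_heads, embed_dim, ffn_dim, max_len)
}

#' Configure a training stage
#'
#' Stage defaults follow the published recipe: AdamW with learning rate 5e-5
#' for masked-language-model pre-training and 2e-5 for fine-tuning, focal
#' scaling factor 2, early-stopping patience 5, batch size 48, and
#' (n_easy, m_hard) = (15, 1) training negatives per positive — a 1:16
#' positive:negative ratio.
#'
#' @param stage `"pretrain"` or `"finetune"`.
#' @param lr learning rate (stage-dependent default).
#' @param gamma focal-loss scaling factor (fine-tuning only).
#' @param batch_size minibatch size.
#' @param epochs maximum epochs.
#' @param patience early-stopping patience, in validation evaluations
#'   (one per epoch).
#' @param weight_decay AdamW decoupled weight decay on weight matrices.
#' @param mlm_rate masking probability for pre-training.
#' @param n_easy,m_hard training negatives per positive.
#' @param warmup_steps linear learning-rate warmup length for fine-tuning,
#'   in optimizer steps.
#' @param seed integer seed controlling all stage randomness.
#' @return a `train_config` list.
#' @export
train_config <- function(stage = c("finetune", "pretrain"),
                         lr = NULL, gamma = 2, batch_size = 48L,
                         epochs = 10L, patience = 5L, weight_decay = 0.01,
                         mlm_rate = 0.15, n_easy = 15L, m_hard = 1L,
                         warmup_steps = 100L, seed = 1L) {
  stage <- match.arg(stage)
  if (is.null(lr)) lr <- if (stage == "pretrain") 5e-5 else 2e-5
  stopifnot(gamma >= 0, patience >= 1, batch_size >= 1, epochs >= 0,
            warmup_steps >= 1)
  structure(list(stage = stage, lr = lr, gamma = gamma,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 patience = as.integer(patience),
                 weight_decay = weight_decay, mlm_rate = mlm_rate,
                 n_easy = as.integer(n_easy), m_hard = as.integer(m_hard),
                 warmup_steps = as.integer(warmup_steps),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Initialize model parameters
#'
#' Weights are drawn N(0, 0.02^2); layer-norm gains start at 1, all biases
#' at 0. The binary classification layer starts at zero so an untrained
#' model scores every pair at exactly 0.5.
#'
#' @param cfg a [model_config()].
#' @param seed integer seed.
#' @return a `kinasite_model`: list with `params`, `config`, `vocab`,
#'   `stage` and an empty training `history`.
#' @export
init_model <- function(cfg = tiny_model_config(), seed = 1L) {
  withr::local_seed(seed)
  d <- cfg$embed_dim; f <- cfg$ffn_dim; V <- cfg$vocab_size
  w <- function(r, c) matrix(rnorm(r * c, sd = 0.02), r, c)
  p <- list(tok = w(V, d), pos = w(cfg$max_len, d))
  for (l in seq_len(cfg$n_layers)) {
    nm <- function(x) paste0("l", l, ".", x)
    p[[nm("ln1.g")]] <- rep(1, d); p[[nm("ln1.b")]] <- rep(0, d)
    p[[nm("Wq")]] <- w(d, d); p[[nm("bq")]] <- rep(0, d)
    p[[nm("Wk")]] <- w(d, d); p[[nm("bk")]] <- rep(0, d)
    p[[nm("Wv")]] <- w(d, d); p[[nm("bv")]] <- rep(0, d)
    p[[nm("Wo")]] <- w(d, d); p[[nm("bo")]] <- rep(0, d)
    p[[nm("ln2.g")]] <- rep(1, d); p[[nm("ln2.b")]] <- rep(0, d)
    p[[nm("W1")]] <- w(d, f); p[[nm("b1")]] <- rep(0, f)
    p[[nm("W2")]] <- w(f, d); p[[nm("b2")]] <- rep(0, d)
  }
  p[["lnf.g"]] <- rep(1, d); p[["lnf.b"]] <- rep(0, d)
  p[["mlm.W"]] <- w(d, V); p[["mlm.b"]] <- rep(0, V)
  p[["cls.Wh"]] <- w(d, d); p[["cls.bh"]] <- rep(0, d)
  p[["cls.Wc"]] <- matrix(0, d, 2); p[["cls.bc"]] <- rep(0, 2)
  structure(list(params = p, config = cfg, vocab = vocabulary(),
                 stage = "initialized", history = tibble(), seed = seed),
            class = "kinasite_model")
}

#' @export
print.kinasite_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, numeric(1)))
  cat(sprintf(
    "<kinasite_model> %d layers x %d heads, dim %d (%s; %s parameters)\n",
    x$config$n_layers, x$config$n_heads, x$config$embed_dim, x$stage,
    format(np, big.mark = ",")))
  invisible(x)
}

#' Run the encoder over token sequences
#'
#' @param model a `kinasite_model`.
#' @param x an `encoded_pairs` object, or a list of 0-based token-id
#'   vectors.
#' @param want_attention also return the final-layer attention tensors
#'   (one `T x T x n_heads` array per sequence).
#' @return list with `embeddings` (one `T x embed_dim` matrix per sequence)
#'   and, when requested, `attention`.
#' @export
model_encode <- function(model, x, want_attention = FALSE) {
  tokens <- if (inherits(x, "encoded_pairs")) x$tokens else x
  over <- lengths(tokens) > model$config$max_len
  if (any(over)) {
    abort(sprintf("input of length %d exceeds the model maximum of %d",
                  max(lengths(tokens)), model$config$max_len))
  }
  cpp_encode(model$params, model$config, tokens, want_attention)
}

#' Masked-language-model loss
#'
#' Mean negative log-probability of the original token at masked positions;
#' unmasked positions contribute nothing. A uniform predictor over the
#' 25-token vocabulary scores exactly `log(25)`.
#'
#' @param model a `kinasite_model`.
#' @param batch an `mlm_batch` from [mlm_corrupt()].
#' @return scalar loss.
#' @export
mlm_loss <- function(model, batch) {
  if (batch$K == 0) abort("MLM batch contains no masked positions")
  cpp_mlm(model$params, model$config, batch$corrupted, batch$labels,
          FALSE)$loss
}

#' Focal loss
#'
#' `-(1 - p_t)^gamma * log(p_t)` where `p_t` is the predicted probability of
#' the true class. At `gamma = 0` this is ordinary cross-entropy; larger
#' `gamma` down-weights well-classified examples so training concentrates on
#' the hard ones — the mechanism used here against the extreme
#' positive:negative imbalance.
#'
#' @param p_t numeric vector of true-class probabilities in (0, 1).
#' @param gamma non-negative scaling factor.
#' @return numeric vector of losses.
#' @export
focal_loss <- function(p_t, gamma = 2) {
  if (gamma < 0) abort("gamma must be non-negative")
  p <- pmin(pmax(p_t, 1e-12), 1 - 1e-12)
  -(1 - p)^gamma * log(p)
}

#' Score peptide-kinase pairs
#'
#' Runs the encoder, reads the embedding at the peptide-center index only,
#' applies the feed-forward classification head and a two-way softmax, and
#' returns the positive-class probability for each pair.
#'
#' @param model a `kinasite_model`.
#' @param pairs a tibble with `peptide` and `kinase_domain` columns, or an
#'   `encoded_pairs` object.
#' @return the pair tibble with a `probability` column.
#' @export
classify <- function(model, pairs) {
  enc <- if (inherits(pairs, "encoded_pairs")) pairs else
    encode_pairs(pairs, model$vocab)
  res <- cpp_classify(model$params, model$config, enc$tokens, enc$center,
                      integer(length(enc$tokens)), 0, FALSE)
  out <- enc$meta
  out$probability <- as.numeric(res$prob)
  out
}

#' @export
#' @rdname classify
#' @param object,newdata,... standard predict-method arguments; `newdata`
#'   is a pair tibble as for [classify()].
predict.kinasite_model <- function(object, newdata, ...) {
  classify(object, newdata)
}

# ---- AdamW ----------------------------------------------------------------

# global-norm gradient clipping; keeps rare large batches from destabilizing
# small-model training
clip_grads <- function(grads, max_norm = 1.0) {
  total <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
  if (is.finite(total) && total > max_norm) {
    grads <- lapply(grads, function(g) g * (max_norm / total))
  }
  grads
}

adamw_state <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

# decoupled weight decay applied to weight matrices only (not biases,
# layer-norm parameters or embeddings-as-vectors)
adamw_step <- function(params, grads, state, lr, weight_decay = 0.01,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (k in names(grads)) {
    gmat <- grads[[k]]
    p <- params[[k]]
    if (is.matrix(p) && !is.matrix(gmat)) gmat <- matrix(gmat, nrow(p), ncol(p))
    if (!is.matrix(p)) gmat <- as.numeric(gmat)
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * gmat
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * gmat^2
    upd <- (state$m[[k]] / bc1) / (sqrt(state$v[[k]] / bc2) + eps)
    if (is.matrix(p)) upd <- upd + weight_decay * p
    params[[k]] <- p - lr * upd
  }
  list(params = params, state = state)
}
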