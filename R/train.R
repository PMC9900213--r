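#' Pre-train the encoder with masked language modeling
#'
#' Runs the self-supervised stage: residue tokens are masked at
#' `cfg$mlm_rate` and the encoder learns to recover them from context.
#' Sequences longer than the model maximum are randomly cropped each epoch.
#'
#' @param model a `kinasite_model` (typically from [init_model()]).
#' @param sequences character vector of kinase-domain and substrate
#'   sequences forming the pre-training corpus.
#' @param cfg a [train_config()] with `stage = "pretrain"`.
#' @return the trained model; `tidy()` exposes the per-epoch loss trace.
#' @export
pretrain <- function(model, sequences, cfg = train_config("pretrain")) {
  if (length(sequences) == 0L) abort("pre-training corpus is empty")
  withr::local_seed(cfg$seed)
  maxres <- model$config$max_len - 2L
  state <- adamw_state(model$params)
  history <- list()
  for (epoch in seq_len(cfg$epochs)) {
    crop <- vapply(sequences, function(s) {
      n <- nchar(s)
      if (n <= maxres) return(s)
      at <- sample.int(n - maxres + 1L, 1L)
      substr(s, at, at + maxres - 1L)
    }, character(1), USE.NAMES = FALSE)
    tokens <- tokenize(crop, model$vocab)
    ord <- sample.int(length(tokens))
    losses <- c()
    for (b in split(ord, ceiling(seq_along(ord) / cfg$batch_size))) {
      batch <- mlm_corrupt(tokens[b], cfg$mlm_rate, model$vocab)
      if (batch$K == 0L) next
      res <- cpp_mlm(model$params, model$config, batch$corrupted,
                     batch$labels, TRUE)
      if (!is.finite(res$loss)) {
        abort(sprintf("MLM loss diverged (%.3g) at epoch %d", res$loss,
                      epoch))
      }
      st <- adamw_step(model$params, res$grads, state, cfg$lr,
                       cfg$weight_decay)
      model$params <- st$params
      state <- st$state
      losses <- c(losses, res$loss)
    }
    history[[epoch]] <- tibble(stage = "pretrain", epoch = epoch,
                               loss = mean(losses), val_loss = NA_real_)
    inform(sprintf("pretrain epoch %d: mlm loss %.4f", epoch, mean(losses)))
  }
  model$history <- bind_rows(model$history, bind_rows(history))
  model$stage <- "pretrained"
  model
}

#' Fine-tune the classifier on labeled kinase-peptide pairs
#'
#' Starts from pre-trained encoder weights with a freshly initialized
#' classification head, trains with focal loss on the (augmented) training
#' partition, and early-stops on validation focal loss with the configured
#' patience, returning the best-validation checkpoint. Augmentations are
#' re-drawn every epoch, so resampled repeats of under-represented kinases
#' are never byte-identical.
#'
#' @param model a pre-trained `kinasite_model`.
#' @param split a `kinasite_split` whose training partition already carries
#'   sampled negatives (see [sample_training_negatives()]).
#' @param kinases kinase record tibble.
#' @param cfg a [train_config()] with `stage = "finetune"`.
#' @param aug an [augmentation_config()]; set the flags there to disable
#'   individual augmentations.
#' @return the fine-tuned model (best validation checkpoint), with the
#'   training log appended to its history.
#' @export
finetune <- function(model, split, kinases,
                     cfg = train_config("finetune"),
                     aug = augmentation_config()) {
  if (nrow(split$validation) == 0L) {
    abort("validation set is empty; cannot early-stop")
  }
  withr::local_seed(cfg$seed)
  # fresh head, as fine-tuning replaces whatever head pre-training carried;
  # the output layer gets small random weights so the encoder receives
  # gradient signal from the first step (a zero output layer is a saddle)
  d <- model$config$embed_dim
  model$params[["cls.Wh"]] <- matrix(rnorm(d * d, sd = 0.02), d, d)
  model$params[["cls.bh"]] <- rep(0, d)
  model$params[["cls.Wc"]] <- matrix(rnorm(d * 2, sd = 0.02), d, 2)
  model$params[["cls.bc"]] <- rep(0, 2)

  val <- split$validation
  val$kinase_domain <- kinase_domains(
    kinases[match(val$kinase_id, kinases$kinase_id), ])
  val_enc <- encode_pairs(val, model$vocab)
  val_y <- as.integer(val$label == "positive")

  state <- adamw_state(model$params)
  best <- list(loss = Inf, params = model$params, epoch = 0L)
  stale <- 0L
  history <- list()
  step <- 0L
  for (epoch in seq_len(cfg$epochs)) {
    train <- augment_batch(split$train, kinases, aug)
    enc <- encode_pairs(train, model$vocab)
    y <- as.integer(train$label == "positive")
    ord <- sample.int(length(enc$tokens))
    losses <- c()
    for (b in split(ord, ceiling(seq_along(ord) / cfg$batch_size))) {
      res <- cpp_classify(model$params, model$config, enc$tokens[b],
                          enc$center[b], y[b], cfg$gamma, TRUE)
      if (!is.finite(res$loss)) {
        abort(sprintf("focal loss diverged (%.3g) at epoch %d", res$loss,
                      epoch))
      }
      step <- step + 1L
      lr_t <- cfg$lr * min(1, step / cfg$warmup_steps)
      st <- adamw_step(model$params, clip_grads(res$grads), state, lr_t,
                       cfg$weight_decay)
      model$params <- st$params
      state <- st$state
      losses <- c(losses, res$loss)
    }
    vres <- cpp_classify(model$params, model$config, val_enc$tokens,
                         val_enc$center, val_y, cfg$gamma, FALSE)
    history[[epoch]] <- tibble(stage = "finetune", epoch = epoch,
                               loss = mean(losses), val_loss = vres$loss)
    inform(sprintf("finetune epoch %d: train %.4f validation %.4f",
                   epoch, mean(losses), vres$loss))
    if (vres$loss < best$loss - 1e-9) {
      best <- list(loss = vres$loss, params = model$params, epoch = epoch)
      stale <- 0L
    } else {
      stale <- stale + 1L
      if (stale >= cfg$patience) {
        inform(sprintf(
          "early stop at epoch %d (no improvement for %d evaluations)",
          epoch, stale))
        break
      }
    }
  }
  model$params <- best$params
  model$history <- bind_rows(model$history, bind_rows(history))
  model$stage <- "finetuned"
  model$best_epoch <- best$epoch
  model
}

# ---- checkpointing --------------------------------------------------------

#' Save / load a model checkpoint
#'
#' A checkpoint directory holds the parameters, model configuration,
#' vocabulary and a manifest (stage, seed, package version) as plain JSON,
#' so checkpoints are portable text.
#'
#' @param model a `kinasite_model`.
#' @param dir checkpoint directory (created if needed).
#' @return `dir` (save) or the restored model (load).
#' @export
save_model <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  flat <- lapply(model$params, function(p) {
    list(dim = if (is.matrix(p)) dim(p) else length(p),
         data = as.vector(p))
  })
  # 17 significant digits: doubles round-trip bit-exactly through JSON
  jsonlite::write_json(flat, file.path(dir, "params.json"), digits = 17,
                       auto_unbox = FALSE)
  jsonlite::write_json(unclass(model$config), file.path(dir, "config.json"),
                       auto_unbox = TRUE)
  write_vocabulary(model$vocab, file.path(dir, "vocab.json"))
  manifest <- list(stage = model$stage, seed = model$seed,
                   best_epoch = model$best_epoch,
                   package = "kinasite",
                   version = as.character(utils::packageVersion("kinasite")))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, null = "null")
  readr::write_tsv(model$history, file.path(dir, "history.tsv"))
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  pfile <- file.path(dir, "params.json")
  if (!file.exists(pfile)) {
    abort(sprintf("no checkpoint found at %s", dir))
  }
  flat <- jsonlite::read_json(pfile, simplifyVector = TRUE)
  params <- lapply(flat, function(x) {
    if (length(x$dim) == 2L) matrix(x$data, x$dim[1], x$dim[2]) else
      as.numeric(x$data)
  })
  cfgl <- jsonlite::read_json(file.path(dir, "config.json"),
                              simplifyVector = TRUE)
  cfg <- model_config(cfgl$n_layers, cfgl$n_heads, cfgl$embed_dim,
                      cfgl$ffn_dim, cfgl$max_len)
  vocab <- read_vocabulary(file.path(dir, "vocab.json"))
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  hfile <- file.path(dir, "history.tsv")
  history <- if (file.exists(hfile) && file.size(hfile) > 1) {
    readr::read_tsv(hfile, show_col_types = FALSE)
  } else tibble()
  structure(list(params = params, config = cfg, vocab = vocab,
                 stage = manifest$stage %||% "unknown",
                 history = history,
                 best_epoch = manifest$best_epoch,
                 seed = manifest$seed),
            class = "kinasite_model")
}
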