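#' @importFrom generics tidy glance augment
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy the training history of a model
#'
#' One row per training epoch across stages, with training and validation
#' losses.
#'
#' @param x a `kinasite_model`.
#' @param ... unused.
#' @return a tibble with `stage`, `epoch`, `loss`, `val_loss`.
#' @export
tidy.kinasite_model <- function(x, ...) {
  if (nrow(x$history) == 0L) {
    return(tibble(stage = character(), epoch = integer(),
                  loss = double(), val_loss = double()))
  }
  as_tibble(x$history)
}

#' One-row model summary
#'
#' Architecture, stage, parameter count and final losses.
#'
#' @param x a `kinasite_model`.
#' @param ... unused.
#' @return a one-row tibble.
#' @export
glance.kinasite_model <- function(x, ...) {
  h <- x$history
  last_of <- function(stage, col) {
    v <- h[h$stage == stage, ][[col]]
    if (length(v)) v[length(v)] else NA_real_
  }
  tibble(
    n_layers = x$config$n_layers, n_heads = x$config$n_heads,
    embed_dim = x$config$embed_dim,
    n_parameters = sum(vapply(x$params, length, numeric(1))),
    stage = x$stage,
    final_mlm_loss = last_of("pretrain", "loss"),
    final_train_loss = last_of("finetune", "loss"),
    best_val_loss = if (nrow(h) && any(h$stage == "finetune"))
      min(h$val_loss[h$stage == "finetune"], na.rm = TRUE) else NA_real_,
    best_epoch = x$best_epoch %||% NA_integer_)
}
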