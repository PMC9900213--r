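#' Extract phosphosite embeddings
#'
#' The encoder-output row at the peptide-center index — the residue
#' embedding of the candidate phosphosite — with pair metadata for
#' downstream projection (UMAP or any other 2-D reduction, done externally
#' on the exported matrix).
#'
#' @param model a `kinasite_model`.
#' @param pairs tibble with `peptide` and `kinase_domain` (metadata columns
#'   such as `kinase_id`, `label` are carried through).
#' @return tibble: metadata columns, `center_residue`, and embedding
#'   dimensions `e1..e<embed_dim>`.
#' @export
extract_phosphosite_embedding <- function(model, pairs) {
  enc <- encode_pairs(pairs, model$vocab)
  out <- model_encode(model, enc)
  emb <- t(vapply(seq_along(out$embeddings), function(i) {
    out$embeddings[[i]][enc$center[i], ]
  }, numeric(model$config$embed_dim)))
  colnames(emb) <- paste0("e", seq_len(ncol(emb)))
  meta <- enc$meta
  meta$center_residue <- substr(meta$peptide, FLANK + 1L, FLANK + 1L)
  bind_cols(meta, as_tibble(emb))
}

#' Export an embedding matrix as TSV
#'
#' Writes vectors plus metadata columns in a shape any projection tool can
#' consume; full double precision so a round-trip read reproduces the
#' vectors exactly.
#'
#' @param embeddings tibble from [extract_phosphosite_embedding()] (at
#'   least 2 rows).
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
export_embedding_matrix <- function(embeddings, path) {
  if (nrow(embeddings) < 2L) abort("need at least 2 embeddings to export")
  dims <- grep("^e\\d+$", names(embeddings))
  if (!length(dims)) abort("no embedding columns (e1..eD) found")
  out <- embeddings
  # 17 significant digits so doubles survive the text round-trip exactly
  out[dims] <- lapply(out[dims], function(x) sprintf("%.17g", x))
  readr::write_tsv(out, path)
  invisible(path)
}

#' Substrate attention profile for one kinase
#'
#' How much final-layer attention each of the 11 peptide positions receives
#' when the model scores that kinase's substrates, averaged over heads and
#' pairs. Two aggregation modes: `"column-mean"` averages the attention
#' received by each peptide position over all query tokens; `"center-row"`
#' reads the attention paid by the phosphosite token itself. Comparing the
#' profile before and after fine-tuning shows which substrate positions the
#' classifier learned to treat as specificity determinants.
#'
#' @param model a `kinasite_model`.
#' @param pairs tibble of pairs, all sharing one kinase.
#' @param mode aggregation mode.
#' @return a `kinasite_profile` tibble with `position` (P-5..P+5 as -5:5),
#'   `attention`, and attributes `kinase_id`, `stage`, `n_pairs`, `mode`.
#' @export
attention_profile <- function(model, pairs,
                              mode = c("column-mean", "center-row")) {
  mode <- match.arg(mode)
  if (nrow(pairs) == 0L) abort("attention_profile needs at least one pair")
  if (length(unique(pairs$kinase_id)) > 1L) {
    abort("all pairs must share the same kinase")
  }
  enc <- encode_pairs(pairs, model$vocab)
  out <- model_encode(model, enc, want_attention = TRUE)
  pep_cols <- 2L:(WINDOW_SIZE + 1L)  # peptide tokens sit after <cls>
  prof <- matrix(0, nrow(pairs), WINDOW_SIZE)
  for (i in seq_along(out$attention)) {
    A <- out$attention[[i]]           # T x T x heads, rows = queries
    Ah <- apply(A, c(1, 2), mean)     # head average
    prof[i, ] <- if (mode == "column-mean") {
      colMeans(Ah[, pep_cols, drop = FALSE])
    } else {
      Ah[enc$center[i], pep_cols]
    }
  }
  structure(tibble(position = -FLANK:FLANK, attention = colMeans(prof)),
            class = c("kinasite_profile", class(tibble())),
            kinase_id = pairs$kinase_id[1], stage = model$stage,
            n_pairs = nrow(pairs), mode = mode)
}
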