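#' Extract candidate phosphosite windows from substrate proteins
#'
#' Enumerates every serine, threonine and tyrosine position in each
#' substrate and returns its 11-mer window (5 residues of flank on each
#' side), padded with `-` when the site lies within five residues of a
#' terminus so the candidate site always occupies the center position.
#' Windows are de-duplicated by residue string within each substrate;
#' identical 11-mers in different substrates are kept as distinct records.
#'
#' @param substrates tibble with `substrate_id` and `sequence` columns.
#' @return tibble with columns `substrate_id`, `site_position` (1-based) and
#'   `peptide`; empty when no S/T/Y occurs.
#' @export
extract_windows <- function(substrates) {
  substrates <- as_tibble(substrates)
  pad <- strrep(PAD_CHAR, FLANK)
  out <- purrr::map2(substrates$substrate_id, substrates$sequence,
                     function(id, s) {
    hits <- gregexpr("[STY]", s)[[1]]
    if (hits[1] == -1L) return(NULL)
    padded <- paste0(pad, s, pad)
    # position p in the original sequence starts the window at p in `padded`
    tibble(substrate_id = id, site_position = as.integer(hits),
           peptide = substring(padded, hits, hits + WINDOW_SIZE - 1L))
  })
  out <- bind_rows(out)
  if (nrow(out) == 0L) {
    return(tibble(substrate_id = character(), site_position = integer(),
                  peptide = character()))
  }
  distinct(out, .data$substrate_id, .data$peptide, .keep_all = TRUE)
}

#' Build positive, hard-negative and easy-negative peptide pools
#'
#' Positives for kinase k are its annotated sites. A hard negative for k is
#' a peptide with phosphorylation evidence for at least one other kinase but
#' none for k; a site annotated to two kinases is a hard negative for
#' neither. Easy negatives are S/T/Y-centered windows from the substrate
#' proteome that appear in no annotation row. Easy and hard pools are
#' disjoint by construction.
#'
#' @param annotations validated annotation table from
#'   [read_annotation_table()].
#' @param substrates substrate tibble.
#' @return an object of class `kinasite_pools`: list with tibbles
#'   `positives` (kinase_id, substrate_id, site_position, peptide),
#'   `hard` (same columns, one row per kinase x foreign site) and
#'   `easy` (substrate_id, site_position, peptide).
#' @export
build_pools <- function(annotations, substrates) {
  windows <- extract_windows(substrates)
  ann <- annotations |>
    mutate(peptide = site_peptide(substrates, annotations))
  positives <- ann |>
    distinct(.data$kinase_id, .data$substrate_id, .data$peptide,
             .keep_all = TRUE) |>
    select("kinase_id", "substrate_id", "site_position", "peptide")

  annotated_sites <- positives |>
    distinct(.data$substrate_id, .data$site_position, .data$peptide)
  kin_ids <- unique(positives$kinase_id)
  hard <- tidyr::crossing(kinase_id = kin_ids, annotated_sites) |>
    anti_join(positives,
              by = c("kinase_id", "substrate_id", "peptide")) |>
    select("kinase_id", "substrate_id", "site_position", "peptide")

  easy <- windows |>
    anti_join(annotated_sites, by = c("substrate_id", "peptide"))

  structure(list(positives = positives, hard = hard, easy = easy),
            class = "kinasite_pools")
}

# 11-mer at an annotated position, used to resolve de-duplicated windows
site_peptide <- function(substrates, ann) {
  s <- substrates$sequence[match(ann$substrate_id, substrates$substrate_id)]
  padded <- paste0(strrep(PAD_CHAR, FLANK), s, strrep(PAD_CHAR, FLANK))
  substring(padded, ann$site_position, ann$site_position + WINDOW_SIZE - 1L)
}

#' @export
print.kinasite_pools <- function(x, ...) {
  cat(sprintf(
    "<kinasite_pools> %d positives (%d kinases), %d hard-negative rows, %d easy negatives\n",
    nrow(x$positives), length(unique(x$positives$kinase_id)),
    nrow(x$hard), nrow(x$easy)))
  invisible(x)
}

#' Split positives into train/validation/test with paired hard negatives
#'
#' Kinases with more than `min_positives` positive examples are split
#' 70:15:15 (validation and test take the floor of their share; the
#' remainder goes to train, so evaluation sets are never larger than their
#' nominal rate). Kinases at or below `min_positives` contribute positives
#' to the training partition only. Every validation and test positive is
#' paired with one hard negative drawn without replacement from the same
#' kinase's pool; when a pool runs dry the remainder is borrowed from the
#' global hard-negative union (with a warning). Hard negatives consumed
#' here are reserved and never reused for that kinase during training
#' negative sampling.
#'
#' @param pools `kinasite_pools` from [build_pools()].
#' @param ratio train/validation/test fractions, summing to 1.
#' @param min_positives evaluation-set threshold (default 50).
#' @param seed integer seed; the split is reproducible given the seed.
#' @return object of class `kinasite_split`: tibbles `train`, `validation`,
#'   `test` (columns of [validate_pairs()]), a per-kinase `counts` table and
#'   the reserved hard negatives in `hard_used`.
#' @export
split_dataset <- function(pools, ratio = c(0.70, 0.15, 0.15),
                          min_positives = 50L, seed = 1L) {
  stopifnot(length(ratio) == 3L, abs(sum(ratio) - 1) < 1e-8)
  withr::local_seed(seed)

  pos <- pools$positives |> mutate(label = "positive")
  parts <- pos |>
    group_by(.data$kinase_id) |>
    group_split_keep() |>
    purrr::map(function(g) {
      n <- nrow(g)
      if (n <= min_positives) {
        g$partition <- "train"
        return(g)
      }
      # partition at the peptide level so duplicated 11-mers (identical
      # windows from different substrates) can never leak across partitions
      up <- unique(g$peptide)
      m <- length(up)
      n_val <- floor(ratio[2] * m)
      n_test <- floor(ratio[3] * m)
      part <- rep("train", m)
      idx <- sample.int(m)
      part[idx[seq_len(n_val)]] <- "validation"
      part[idx[n_val + seq_len(n_test)]] <- "test"
      g$partition <- part[match(g$peptide, up)]
      g
    }) |>
    bind_rows()

  eval_pos <- parts |> filter(.data$partition != "train")
  hard_used <- NULL
  if (nrow(eval_pos)) {
    hard_used <- eval_pos |>
      group_by(.data$kinase_id) |>
      group_split_keep() |>
      purrr::map(function(g) {
        k <- g$kinase_id[1]
        pool <- pools$hard |>
          filter(.data$kinase_id == k) |>
          distinct(.data$peptide, .keep_all = TRUE)
        need <- nrow(g)
        take <- pool[sample.int(nrow(pool), min(need, nrow(pool))), ]
        if (nrow(take) < need) {
          warn(sprintf(
            "hard-negative pool of %s exhausted (%d < %d); borrowing from the global union",
            k, nrow(pool), need))
          global <- pools$hard |>
            filter(.data$kinase_id != k) |>
            distinct(.data$substrate_id, .data$site_position, .data$peptide) |>
            anti_join(pools$positives |> filter(.data$kinase_id == k),
                      by = "peptide") |>
            anti_join(take, by = c("substrate_id", "peptide"))
          extra <- global[sample.int(nrow(global),
                                     min(need - nrow(take), nrow(global))), ]
          extra$kinase_id <- k
          take <- bind_rows(take, extra[names(take)])
        }
        take$partition <- g$partition[seq_len(nrow(take))]
        take
      }) |>
      bind_rows() |>
      mutate(label = "hard_negative")
  }

  pick <- function(p) {
    bind_rows(parts |> filter(.data$partition == p),
              if (!is.null(hard_used))
                hard_used |> filter(.data$partition == p)) |>
      select("kinase_id", "peptide", "label", "substrate_id",
             "site_position")
  }
  counts <- pos |>
    dplyr::count(.data$kinase_id, name = "n_positive") |>
    mutate(in_eval = .data$n_positive > min_positives)

  structure(list(train = pick("train"), validation = pick("validation"),
                 test = pick("test"), counts = counts,
                 hard_used = if (is.null(hard_used))
                   tibble(kinase_id = character(), peptide = character())
                 else hard_used |> select("kinase_id", "peptide"),
                 seed = seed, ratio = ratio,
                 min_positives = min_positives),
            class = "kinasite_split")
}

# group_split() keeping group columns (dplyr drops them with .keep = FALSE)
group_split_keep <- function(g) dplyr::group_split(g, .keep = TRUE)

#' @export
print.kinasite_split <- function(x, ...) {
  cat(sprintf("<kinasite_split> train %d / validation %d / test %d pairs (%d kinases, seed %d)\n",
              nrow(x$train), nrow(x$validation), nrow(x$test),
              nrow(x$counts), x$seed))
  invisible(x)
}

#' Add easy and hard negatives to the training partition
#'
#' Pairs every training positive of kinase k with `n_easy` easy negatives
#' and `m_hard` hard negatives from k's pool (hard negatives reserved for
#' k's validation/test pairing are excluded), giving a final
#' positive:negative ratio of 1:(n_easy + m_hard). Draws are with
#' replacement across positives, mirroring sampling from a large negative
#' universe.
#'
#' @param split `kinasite_split` from [split_dataset()].
#' @param pools `kinasite_pools`.
#' @param n_easy easy negatives per positive.
#' @param m_hard hard negatives per positive.
#' @param seed integer seed.
#' @return the split with an augmented `train` tibble.
#' @export
sample_training_negatives <- function(split, pools, n_easy = 15L,
                                      m_hard = 1L, seed = 1L) {
  stopifnot(is_count(n_easy), is_count(m_hard))
  if (n_easy > 0 && nrow(pools$easy) == 0L) {
    abort("easy-negative pool is empty but n_easy > 0")
  }
  withr::local_seed(seed)
  train_pos <- split$train |> filter(.data$label == "positive")
  negs <- train_pos |>
    group_by(.data$kinase_id) |>
    group_split_keep() |>
    purrr::map(function(g) {
      k <- g$kinase_id[1]
      out <- list()
      if (n_easy > 0) {
        idx <- sample.int(nrow(pools$easy), n_easy * nrow(g), replace = TRUE)
        out$easy <- pools$easy[idx, ] |>
          mutate(kinase_id = k, label = "easy_negative")
      }
      if (m_hard > 0) {
        pool <- pools$hard |>
          filter(.data$kinase_id == k) |>
          anti_join(split$hard_used, by = c("kinase_id", "peptide"))
        if (nrow(pool) == 0L) {
          pool <- pools$hard |>
            filter(.data$kinase_id != k) |>
            anti_join(pools$positives |> filter(.data$kinase_id == k),
                      by = "peptide") |>
            mutate(kinase_id = k)
          warn(sprintf("no unreserved hard negatives for %s; using the global union", k))
        }
        idx <- sample.int(nrow(pool), m_hard * nrow(g), replace = TRUE)
        out$hard <- pool[idx, ] |> mutate(label = "hard_negative")
      }
      bind_rows(out)
    }) |>
    bind_rows()
  if (nrow(negs)) {
    negs <- negs |>
      select("kinase_id", "peptide", "label", "substrate_id",
             "site_position")
  }
  split$train <- bind_rows(split$train, negs)
  split$negative_ratio <- n_easy + m_hard
  split
}

#' Sample a stand-alone easy-negative test set
#'
#' Builds the all-negative benchmark used for the false-positive-rate check:
#' easy-negative peptides paired with evaluation kinases, disjoint from any
#' (kinase, peptide) pair already used in training.
#'
#' @param split `kinasite_split` (after negative sampling).
#' @param pools `kinasite_pools`.
#' @param size number of easy-negative pairs.
#' @param seed integer seed.
#' @return tibble of `easy_negative` pairs.
#' @export
sample_easy_test <- function(split, pools, size = 1000L, seed = 1L) {
  withr::local_seed(seed)
  kin <- unique(c(split$test$kinase_id, split$validation$kinase_id))
  if (!length(kin)) kin <- unique(split$train$kinase_id)
  if (nrow(pools$easy) == 0L) abort("easy-negative pool is empty")
  out <- pools$easy[sample.int(nrow(pools$easy), size, replace = TRUE), ] |>
    mutate(kinase_id = sample(kin, size, replace = TRUE),
           label = "easy_negative") |>
    select("kinase_id", "peptide", "label", "substrate_id",
           "site_position") |>
    anti_join(split$train |> select("kinase_id", "peptide"),
              by = c("kinase_id", "peptide"))
  distinct(out, .data$kinase_id, .data$peptide, .keep_all = TRUE)
}
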