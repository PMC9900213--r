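#' Configure the protein-specific training augmentations
#'
#' Four augmentations are applied to training pairs only: resampling of
#' positives to balance the skewed per-kinase counts, random shifting of the
#' kinase-domain boundaries, random masking of kinase residues, and (as a
#' consequence of resampling plus the stochastic perturbations) non-identical
#' repeats of under-represented examples.
#'
#' @param resample_target_large resample target for kinases above the
#'   threshold (default 1118, the largest per-kinase positive count in the
#'   curated data this mirrors).
#' @param resample_target_small target for kinases at/below the threshold
#'   (default 50).
#' @param resample_threshold the evaluation-set positive-count threshold
#'   (default 50).
#' @param max_shift maximum boundary displacement in residues, per terminus
#'   (default 5).
#' @param kinase_mask_rate per-position probability of replacing a kinase
#'   residue with the mask marker (default 0.05).
#' @param resample,shift,mask logical flags enabling each strategy.
#' @return an `aug_config` list.
#' @export
augmentation_config <- function(resample_target_large = 1118L,
                                resample_target_small = 50L,
                                resample_threshold = 50L,
                                max_shift = 5L,
                                kinase_mask_rate = 0.05,
                                resample = TRUE, shift = TRUE, mask = TRUE) {
  stopifnot(kinase_mask_rate >= 0, kinase_mask_rate < 1, max_shift >= 0)
  structure(list(resample_target_large = as.integer(resample_target_large),
                 resample_target_small = as.integer(resample_target_small),
                 resample_threshold = as.integer(resample_threshold),
                 max_shift = as.integer(max_shift),
                 kinase_mask_rate = kinase_mask_rate,
                 resample = resample, shift = shift, mask = mask),
            class = "aug_config")
}

#' Resample training positives to balance per-kinase counts
#'
#' Kinases with more positives than the threshold are upsampled (with
#' replacement) to `resample_target_large`; kinases at or below it to
#' `resample_target_small`. A kinase already at or above its target is left
#' unchanged — positives are never downsampled.
#'
#' @param train_pos tibble of training positives (must carry `kinase_id`).
#' @param cfg an [augmentation_config()].
#' @return resampled tibble of positives.
#' @export
resample_positives <- function(train_pos, cfg = augmentation_config()) {
  train_pos |>
    group_by(.data$kinase_id) |>
    group_split_keep() |>
    purrr::map(function(g) {
      target <- if (nrow(g) > cfg$resample_threshold)
        cfg$resample_target_large else cfg$resample_target_small
      if (nrow(g) >= target) return(g)
      g[sample.int(nrow(g), target, replace = TRUE), ]
    }) |>
    bind_rows()
}

#' Randomly shift kinase-domain boundaries
#'
#' Draws independent N- and C-terminal displacements uniformly from
#' {-max_shift, ..., +max_shift} and returns the correspondingly widened or
#' narrowed domain substring. Displacements are clamped so the interval
#' stays inside the full-length sequence; a draw that would leave an empty
#' interval is re-drawn. The output is always a substring of the full
#' sequence, so the model cannot rely on exact domain boundaries.
#'
#' @param kinases kinase record tibble (vectorized over rows).
#' @param cfg an [augmentation_config()].
#' @return character vector of shifted domain sequences.
#' @export
shift_domain <- function(kinases, cfg = augmentation_config()) {
  n <- nrow(kinases)
  len <- nchar(kinases$full_sequence)
  s <- cfg$max_shift
  start <- kinases$domain_start
  end <- kinases$domain_end
  new_start <- pmin(pmax(start + sample(-s:s, n, replace = TRUE), 1L), len)
  new_end <- pmin(pmax(end + sample(-s:s, n, replace = TRUE), 1L), len)
  bad <- which(new_start > new_end)
  while (length(bad)) { # degenerate after clamping: re-draw those rows
    new_start[bad] <- pmin(pmax(start[bad] +
                                  sample(-s:s, length(bad), replace = TRUE),
                                1L), len[bad])
    new_end[bad] <- pmin(pmax(end[bad] +
                                sample(-s:s, length(bad), replace = TRUE),
                              1L), len[bad])
    bad <- which(new_start > new_end)
  }
  substr(kinases$full_sequence, new_start, new_end)
}

#' Randomly mask kinase residues
#'
#' Independently replaces each position with the mask marker `#` with
#' probability `kinase_mask_rate` (i.i.d. Bernoulli, so the expected masked
#' fraction equals the rate). The marker encodes to the `<mask>` token.
#' Length is preserved.
#'
#' @param domains character vector of domain sequences.
#' @param cfg an [augmentation_config()].
#' @return character vector with masked positions.
#' @export
mask_kinase <- function(domains, cfg = augmentation_config()) {
  if (any(nchar(domains) == 0L)) abort("cannot mask an empty domain")
  if (cfg$kinase_mask_rate == 0) return(domains)
  vapply(domains, function(d) {
    ch <- strsplit(d, "")[[1]]
    hit <- runif(length(ch)) < cfg$kinase_mask_rate
    ch[hit] <- MASK_CHAR
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Apply the training augmentations to a batch of labeled pairs
#'
#' Composition order: positive resampling, then boundary shifting, then
#' kinase masking. Negatives undergo shifting and masking but are never
#' resampled; peptides are never altered. Refuses to run on validation or
#' test pairs — augmentation is a training-time device only.
#'
#' @param pairs labeled-pair tibble from the training partition.
#' @param kinases kinase record tibble (provides full sequences and domain
#'   coordinates).
#' @param cfg an [augmentation_config()].
#' @param partition partition of origin; anything but "train" is refused.
#' @return tibble of pairs with an added `kinase_domain` column holding the
#'   augmented domain sequence for each row.
#' @export
augment_batch <- function(pairs, kinases, cfg = augmentation_config(),
                          partition = "train") {
  if (!identical(partition, "train")) {
    abort("augmentation applies to the training partition only")
  }
  pos <- pairs |> filter(.data$label == "positive")
  neg <- pairs |> filter(.data$label != "positive")
  if (cfg$resample && nrow(pos)) pos <- resample_positives(pos, cfg)
  out <- bind_rows(pos, neg)
  idx <- match(out$kinase_id, kinases$kinase_id)
  if (anyNA(idx)) {
    abort(sprintf("unknown kinase_id in pairs: %s",
                  out$kinase_id[which(is.na(idx))[1]]))
  }
  krows <- kinases[idx, ]
  dom <- if (cfg$shift) shift_domain(krows, cfg) else kinase_domains(krows)
  if (cfg$mask && cfg$kinase_mask_rate > 0) dom <- mask_kinase(dom, cfg)
  out$kinase_domain <- dom
  out
}
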