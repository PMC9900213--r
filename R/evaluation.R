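#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney concordance probability with ties counted
#' one half — exactly the area obtained by trapezoidal integration of the
#' ROC curve over all thresholds.
#'
#' @param scores numeric prediction scores.
#' @param labels binary labels (0/1 or logical).
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) {
    abort("roc_auc needs both classes present")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Area under the step-wise (non-interpolated) precision-recall curve,
#' swept over all distinct score thresholds: each recall increment
#' contributes the precision at that threshold. Ties in scores are handled
#' by thresholding groups of equal scores together.
#'
#' @inheritParams roc_auc
#' @return AUC-PRC in \[0, 1\].
#' @export
pr_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L)
  if (n1 == 0L) abort("pr_auc needs at least one positive")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  # group ties: cumulative counts evaluated at the last member of each group
  grp_end <- cumsum(rle(s)$lengths)
  tp <- cumsum(y)[grp_end]
  fp <- (grp_end - cumsum(y)[grp_end])
  precision <- tp / (tp + fp)
  recall <- tp / n1
  prev_recall <- c(0, recall[-length(recall)])
  sum((recall - prev_recall) * precision)
}

#' False-positive rate on an all-negative set
#'
#' The fraction of easy-negative pairs scored above the decision threshold —
#' the guard against a model that looks good on paired benchmarks but fires
#' on never-phosphorylated peptides. Equals FP / (TN + FP) since the input
#' contains only negatives.
#'
#' @param scores numeric scores of negative examples.
#' @param threshold decision threshold (default 0.5).
#' @return FPR in \[0, 1\].
#' @export
fpr <- function(scores, threshold = 0.5) {
  if (length(scores) == 0L) abort("fpr needs at least one score")
  mean(scores > threshold)
}

#' Stratified evaluation report
#'
#' Per-kinase AUC-ROC and AUC-PRC on each kinase's positives and paired
#' hard negatives, unweighted family and group means over member kinases, a
#' pooled overall AUC over all scored pairs, and the FPR on the separate
#' easy-negative set. Easy negatives never enter the AUC computations.
#' Kinases lacking a positive or a negative in the scored set are excluded
#' with a message.
#'
#' @param scored tibble with `kinase_id`, `label` and `probability` columns
#'   (e.g. [classify()] output on the test partition).
#' @param kinases kinase record tibble supplying `family` and `group`.
#' @param easy_scored optional tibble of scored easy negatives.
#' @param fpr_threshold decision threshold for the FPR (default 0.5).
#' @return a `kinasite_report`: list of tibbles `overall`, `by_kinase`,
#'   `by_family`, `by_group` and scalar `fpr_easy`.
#' @export
stratified_report <- function(scored, kinases, easy_scored = NULL,
                              fpr_threshold = 0.5) {
  scored <- scored |> filter(.data$label != "easy_negative")
  scored$y <- as.integer(scored$label == "positive")
  meta <- kinases |> select("kinase_id", "family", "group")
  per <- scored |>
    group_by(.data$kinase_id) |>
    summarise(n_pos = sum(.data$y), n_neg = sum(1L - .data$y),
              auc_roc = if (sum(.data$y) > 0 && sum(1 - .data$y) > 0)
                roc_auc(.data$probability, .data$y) else NA_real_,
              auc_prc = if (sum(.data$y) > 0 && sum(1 - .data$y) > 0)
                pr_auc(.data$probability, .data$y) else NA_real_,
              .groups = "drop") |>
    left_join(meta, by = "kinase_id")
  dropped <- per |> filter(is.na(.data$auc_roc))
  if (nrow(dropped)) {
    inform(sprintf("stratified_report: excluded %d kinase(s) lacking both classes: %s",
                   nrow(dropped), paste(dropped$kinase_id, collapse = ", ")))
    per <- per |> filter(!is.na(.data$auc_roc))
  }
  by_family <- per |>
    group_by(.data$family) |>
    summarise(n_kinases = n(), auc_roc = mean(.data$auc_roc),
              auc_prc = mean(.data$auc_prc), .groups = "drop")
  by_group <- per |>
    group_by(.data$group) |>
    summarise(n_kinases = n(), auc_roc = mean(.data$auc_roc),
              auc_prc = mean(.data$auc_prc), .groups = "drop")
  overall <- tibble(
    n_pairs = nrow(scored),
    auc_roc_pooled = roc_auc(scored$probability, scored$y),
    auc_prc_pooled = pr_auc(scored$probability, scored$y),
    auc_roc_mean_kinase = mean(per$auc_roc),
    auc_prc_mean_kinase = mean(per$auc_prc))
  fpr_easy <- if (!is.null(easy_scored) && nrow(easy_scored)) {
    if (any(easy_scored$label != "easy_negative")) {
      abort("easy_scored must contain only easy negatives")
    }
    fpr(easy_scored$probability, fpr_threshold)
  } else NA_real_
  structure(list(overall = overall, by_kinase = per,
                 by_family = by_family, by_group = by_group,
                 fpr_easy = fpr_easy, fpr_threshold = fpr_threshold),
            class = "kinasite_report")
}

#' @export
print.kinasite_report <- function(x, ...) {
  cat(sprintf(
    "<kinasite_report> %d pairs, %d kinases\n  pooled AUC-ROC %.3f | mean per-kinase AUC-ROC %.3f | AUC-PRC %.3f | easy-negative FPR %s\n",
    x$overall$n_pairs, nrow(x$by_kinase), x$overall$auc_roc_pooled,
    x$overall$auc_roc_mean_kinase, x$overall$auc_prc_pooled,
    ifelse(is.na(x$fpr_easy), "-", sprintf("%.3f", x$fpr_easy))))
  invisible(x)
}

#' Flatten an evaluation report to a tidy table
#'
#' One row per stratum (overall, each kinase, each family, each group) —
#' the shape written by the `evaluate` command.
#'
#' @param x a `kinasite_report`.
#' @param ... unused.
#' @return a tibble with `level`, `stratum`, `auc_roc`, `auc_prc`, `n`.
#' @export
tidy.kinasite_report <- function(x, ...) {
  bind_rows(
    tibble(level = "overall", stratum = "pooled",
           auc_roc = x$overall$auc_roc_pooled,
           auc_prc = x$overall$auc_prc_pooled, n = x$overall$n_pairs),
    tibble(level = "overall", stratum = "mean_kinase",
           auc_roc = x$overall$auc_roc_mean_kinase,
           auc_prc = x$overall$auc_prc_mean_kinase,
           n = nrow(x$by_kinase)),
    x$by_kinase |>
      mutate(level = "kinase") |>
      select("level", stratum = "kinase_id", "auc_roc", "auc_prc",
             n = "n_pos"),
    x$by_family |>
      mutate(level = "family") |>
      select("level", stratum = "family", "auc_roc", "auc_prc",
             n = "n_kinases"),
    x$by_group |>
      mutate(level = "group") |>
      select("level", stratum = "group", "auc_roc", "auc_prc",
             n = "n_kinases"))
}
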