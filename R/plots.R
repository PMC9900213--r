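#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an attention profile
#'
#' Bar plot of mean final-layer attention per peptide position (P-5..P+5),
#' the visual used to read which substrate positions the model treats as
#' specificity determinants.
#'
#' @param object a `kinasite_profile` from [attention_profile()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.kinasite_profile <- function(object, ...) {
  lab <- ifelse(object$position == 0, "P",
                ifelse(object$position > 0,
                       paste0("P+", object$position),
                       paste0("P", object$position)))
  df <- tibble(position = factor(lab, levels = lab),
               attention = object$attention)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position,
                                   y = .data$attention)) +
    ggplot2::geom_col(fill = "#2c7fb8") +
    ggplot2::labs(
      x = "peptide position", y = "mean attention",
      title = sprintf("%s (%s, %d pairs, %s)",
                      attr(object, "kinase_id"), attr(object, "stage"),
                      attr(object, "n_pairs"), attr(object, "mode"))) +
    ggplot2::theme_minimal()
}

#' Plot per-kinase evaluation metrics
#'
#' Dot plot of per-kinase AUC-ROC and AUC-PRC, faceted by family.
#'
#' @param object a `kinasite_report` from [stratified_report()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.kinasite_report <- function(object, ...) {
  df <- object$by_kinase |>
    tidyr::pivot_longer(c("auc_roc", "auc_prc"), names_to = "metric",
                        values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$kinase_id, y = .data$value,
                                   colour = .data$metric)) +
    ggplot2::geom_point() +
    ggplot2::facet_grid(. ~ family, scales = "free_x", space = "free_x") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "area under curve") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Relative-frequency sequence logo of peptide windows
#'
#' A simple text logo: at each of the 11 positions, letters are stacked
#' with height proportional to their relative frequency (pad characters
#' excluded). Rendering plumbing for inspecting substrate sets, not a
#' scored method.
#'
#' @param peptides character vector of 11-mer windows.
#' @param min_freq hide residues rarer than this (default 0.05).
#' @return a ggplot object.
#' @export
plot_sequence_logo <- function(peptides, min_freq = 0.05) {
  validate_windows(peptides)
  chars <- do.call(rbind, seq_chars(peptides))
  df <- purrr::map(seq_len(WINDOW_SIZE), function(i) {
    tab <- table(chars[, i])
    tab <- tab[names(tab) != PAD_CHAR]
    if (!length(tab)) return(NULL)
    freq <- as.numeric(tab) / sum(tab)
    keep <- freq >= min_freq
    if (!any(keep)) return(NULL)
    d <- tibble(position = i - FLANK - 1L, residue = names(tab)[keep],
                freq = freq[keep]) |>
      arrange(.data$freq)
    d$top <- cumsum(d$freq)
    d$mid <- d$top - d$freq / 2
    d
  }) |> bind_rows()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$mid,
                                   label = .data$residue,
                                   size = .data$freq)) +
    ggplot2::geom_text(fontface = "bold") +
    ggplot2::scale_size_continuous(range = c(2, 8), guide = "none") +
    ggplot2::scale_x_continuous(breaks = -FLANK:FLANK) +
    ggplot2::labs(x = "peptide position", y = "relative frequency") +
    ggplot2::theme_minimal()
}

#' Plot the training loss trace
#'
#' @param object a `kinasite_model`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.kinasite_model <- function(object, ...) {
  df <- tidy(object) |>
    tidyr::pivot_longer(c("loss", "val_loss"), names_to = "series",
                        values_to = "value") |>
    filter(!is.na(.data$value))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~stage, scales = "free") +
    ggplot2::labs(x = "epoch", y = "loss") +
    ggplot2::theme_minimal()
}
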