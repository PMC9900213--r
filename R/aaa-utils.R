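#' @keywords internal
"_PACKAGE"

#' @useDynLib kinasite, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom rlang .data abort warn inform %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   left_join anti_join semi_join distinct bind_rows bind_cols n row_number
#'   pull rename
#' @importFrom stats runif rnorm predict
#' @importFrom utils head modifyList
NULL

# 20 canonical amino acids, alphabetical one-letter order
AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# residue alphabet accepted in stored sequences: 20 AA plus X (unknown)
AA_ALPHABET <- c(AA20, "X")

PAD_CHAR  <- "-"  # peptide terminal padding
MASK_CHAR <- "#"  # in-sequence mask marker produced by augmentation

CENTER_RESIDUES <- c("S", "T", "Y")
WINDOW_SIZE <- 11L
FLANK <- 5L  # residues on each side of the phosphosite

#' Split sequences into per-residue character matrices
#' @noRd
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)

#' Validate residue strings against the amino-acid alphabet
#'
#' @param x character vector of sequences.
#' @param what label used in error messages.
#' @param extra additional characters to allow (e.g. the peptide pad `-`).
#' @return invisibly, `x`.
#' @noRd
assert_alphabet <- function(x, what = "sequence", extra = character()) {
  allowed <- c(AA_ALPHABET, extra)
  bad <- vapply(seq_chars(x), function(ch) {
    b <- setdiff(unique(ch), allowed)
    if (length(b)) b[1] else NA_character_
  }, character(1))
  if (any(!is.na(bad))) {
    i <- which(!is.na(bad))[1]
    abort(sprintf("invalid character '%s' in %s %d (allowed: %s)",
                  bad[i], what, i, paste(allowed, collapse = "")))
  }
  invisible(x)
}

#' Draw a random amino-acid string
#' @noRd
random_aa <- function(n, alphabet = AA20) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x >= 0 && x == floor(x)

#' Seed helper: derive a reproducible child seed from a base seed
#'
#' Keeps derived seeds inside the 32-bit integer range.
#' @noRd
child_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + k * 7919) %% 2147483647)
}
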