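#' Read kinase sequences from FASTA
#'
#' Reads full-length kinase sequences and attaches catalytic-domain
#' coordinates and optional classification metadata. Coordinates are 1-based
#' inclusive (the convention of most site and domain tables, and of R);
#' when no coordinate table is given the domain defaults to the whole
#' sequence.
#'
#' @param path FASTA file of kinase sequences. The first whitespace-delimited
#'   word of each header is the `kinase_id`.
#' @param coords optional domain coordinates: a data frame (or TSV path) with
#'   columns `kinase_id`, `domain_start`, `domain_end` (1-based inclusive).
#' @param meta optional data frame with `kinase_id` and any of `gene`,
#'   `family`, `group`, `organism`.
#' @return a tibble with columns `kinase_id`, `full_sequence`, `domain_start`,
#'   `domain_end`, `gene`, `family`, `group`, `organism`.
#' @export
read_kinase_fasta <- function(path, coords = NULL, meta = NULL) {
  seqs <- read_fasta(path)
  tbl <- tibble(
    kinase_id = seqs$id,
    full_sequence = seqs$seq,
    domain_start = 1L,
    domain_end = nchar(seqs$seq),
    gene = seqs$id,
    family = NA_character_,
    group = NA_character_,
    organism = NA_character_
  )
  assert_alphabet(tbl$full_sequence, "kinase sequence")
  if (!is.null(coords)) {
    if (is.character(coords)) {
      coords <- readr::read_tsv(coords, show_col_types = FALSE,
                                comment = "#")
    }
    coords <- as_tibble(coords)
    missing_ids <- setdiff(coords$kinase_id, tbl$kinase_id)
    if (length(missing_ids)) {
      abort(sprintf("coordinate table references ids absent from FASTA: %s",
                    paste(missing_ids, collapse = ", ")))
    }
    tbl <- tbl |>
      left_join(coords |>
                  select("kinase_id", cs = "domain_start", ce = "domain_end"),
                by = "kinase_id") |>
      mutate(domain_start = ifelse(is.na(.data$cs), .data$domain_start,
                                   as.integer(.data$cs)),
             domain_end = ifelse(is.na(.data$ce), .data$domain_end,
                                 as.integer(.data$ce))) |>
      select(-"cs", -"ce")
  }
  if (!is.null(meta)) {
    meta <- as_tibble(meta)
    for (col in intersect(c("gene", "family", "group", "organism"),
                          names(meta))) {
      m <- meta[[col]][match(tbl$kinase_id, meta$kinase_id)]
      tbl[[col]] <- ifelse(is.na(m), tbl[[col]], m)
    }
  }
  validate_kinases(tbl)
}

#' Validate a kinase record table
#'
#' Checks the domain interval (1-based inclusive) against the sequence
#' length and the residue alphabet.
#' @param kinases tibble as returned by [read_kinase_fasta()].
#' @return the validated tibble, invisibly unchanged.
#' @export
validate_kinases <- function(kinases) {
  kinases <- as_tibble(kinases)
  assert_alphabet(kinases$full_sequence, "kinase sequence")
  len <- nchar(kinases$full_sequence)
  bad <- which(kinases$domain_start < 1L |
                 kinases$domain_start > kinases$domain_end |
                 kinases$domain_end > len)
  if (length(bad)) {
    abort(sprintf(
      "invalid domain interval for %s: [%d, %d] in sequence of length %d",
      kinases$kinase_id[bad[1]], kinases$domain_start[bad[1]],
      kinases$domain_end[bad[1]], len[bad[1]]))
  }
  kinases
}

#' Read substrate proteins from FASTA
#'
#' @param path FASTA file of full-length substrate sequences.
#' @return tibble with columns `substrate_id`, `sequence`, `organism`.
#' @export
read_substrate_fasta <- function(path) {
  seqs <- read_fasta(path)
  if (any(nchar(seqs$seq) == 0L)) abort("empty substrate sequence in FASTA")
  assert_alphabet(seqs$seq, "substrate sequence")
  tibble(substrate_id = seqs$id, sequence = seqs$seq,
         organism = NA_character_)
}

# Biostrings-backed FASTA reader returning plain id/seq columns.
read_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("FASTA file not found: %s", path))
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) {
                    abort(sprintf("malformed FASTA '%s': %s", path,
                                  conditionMessage(e)))
                  })
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate FASTA id: %s", ids[duplicated(ids)][1]))
  }
  list(id = ids, seq = unname(toupper(as.character(set))))
}

#' Write sequences to FASTA
#'
#' @param ids,seqs character vectors of equal length.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(ids, seqs, path) {
  set <- Biostrings::BStringSet(seqs)
  names(set) <- ids
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read and verify a kinase-specific phosphosite table
#'
#' Loads a TSV of experimentally annotated sites (`kinase_id`,
#' `substrate_id`, `site_position`, `residue`; positions 1-based) and keeps
#' only rows whose stated residue letter matches the substrate sequence at
#' that position — the in-silico analogue of cross-referencing each site
#' against the reference proteome. Rows naming an unknown substrate, an
#' out-of-range position, a mismatching residue, or a non-phosphorylatable
#' (non-S/T/Y) residue are dropped and counted, never corrected.
#'
#' @param path TSV file (or a data frame already in memory).
#' @param substrates substrate table from [read_substrate_fasta()].
#' @return tibble of accepted rows; attribute `rejected` holds the dropped
#'   rows with a `reason` column, and a summary message reports the counts.
#' @export
read_annotation_table <- function(path, substrates) {
  ann <- if (is.data.frame(path)) as_tibble(path) else
    readr::read_tsv(path, show_col_types = FALSE, comment = "#")
  need <- c("kinase_id", "substrate_id", "site_position", "residue")
  if (!all(need %in% names(ann))) {
    abort(sprintf("annotation table must have columns: %s",
                  paste(need, collapse = ", ")))
  }
  ann <- ann |> mutate(site_position = as.integer(.data$site_position))
  idx <- match(ann$substrate_id, substrates$substrate_id)
  slen <- nchar(substrates$sequence)[idx]
  observed <- substr(substrates$sequence[idx], ann$site_position,
                     ann$site_position)
  reason <- rep(NA_character_, nrow(ann))
  reason[is.na(idx)] <- "unknown substrate"
  pos_ok <- !is.na(idx) & ann$site_position >= 1L & ann$site_position <= slen
  reason[is.na(reason) & !pos_ok] <- "position out of range"
  reason[is.na(reason) & observed != ann$residue] <- "residue mismatch"
  reason[is.na(reason) & !(ann$residue %in% CENTER_RESIDUES)] <-
    "not a phosphorylatable residue"
  keep <- is.na(reason)
  rejected <- ann[!keep, , drop = FALSE]
  rejected$reason <- reason[!keep]
  accepted <- distinct(ann[keep, need])
  if (nrow(rejected)) {
    inform(sprintf("read_annotation_table: rejected %d of %d rows (%s)",
                   nrow(rejected), nrow(ann),
                   paste(sprintf("%s: %d", names(table(rejected$reason)),
                                 table(rejected$reason)), collapse = "; ")))
  }
  attr(accepted, "rejected") <- rejected
  accepted
}

#' Write labeled kinase-peptide pairs to TSV
#'
#' @param pairs tibble with columns `kinase_id`, `peptide`, `label`, and
#'   optionally `substrate_id`, `site_position`.
#' @param path output TSV path.
#' @return `path`, invisibly. Round-trips losslessly through
#'   [read_pairs_tsv()].
#' @export
write_pairs_tsv <- function(pairs, path) {
  if (!is.data.frame(pairs) || nrow(pairs) == 0L) {
    abort("pairs must be a non-empty data frame")
  }
  pairs <- as_tibble(pairs)
  if (!"substrate_id" %in% names(pairs)) pairs$substrate_id <- NA_character_
  if (!"site_position" %in% names(pairs)) pairs$site_position <- NA_integer_
  validate_pairs(pairs)
  readr::write_tsv(pairs[, c("kinase_id", "peptide", "label",
                             "substrate_id", "site_position")], path)
  invisible(path)
}

#' Read labeled kinase-peptide pairs from TSV
#' @param path TSV written by [write_pairs_tsv()].
#' @return tibble of labeled pairs.
#' @export
read_pairs_tsv <- function(path) {
  pairs <- readr::read_tsv(path, show_col_types = FALSE,
                           col_types = readr::cols(
                             kinase_id = readr::col_character(),
                             peptide = readr::col_character(),
                             label = readr::col_character(),
                             substrate_id = readr::col_character(),
                             site_position = readr::col_integer()))
  validate_pairs(pairs)
}

LABELS <- c("positive", "hard_negative", "easy_negative")

#' Validate a labeled-pair table
#'
#' Asserts 11-mer peptides with an S/T/Y center, contiguous terminal padding
#' only, and a known label.
#' @param pairs tibble of labeled pairs.
#' @return the validated tibble.
#' @export
validate_pairs <- function(pairs) {
  pairs <- as_tibble(pairs)
  validate_windows(pairs$peptide)
  bad <- setdiff(unique(pairs$label), LABELS)
  if (length(bad)) abort(sprintf("unknown pair label '%s'", bad[1]))
  pairs
}

#' Validate 11-mer peptide windows
#'
#' @param peptides character vector of candidate windows.
#' @return invisibly, `peptides`.
#' @export
validate_windows <- function(peptides) {
  if (any(nchar(peptides) != WINDOW_SIZE)) {
    abort(sprintf("peptide windows must be exactly %d residues", WINDOW_SIZE))
  }
  assert_alphabet(peptides, "peptide", extra = PAD_CHAR)
  center <- substr(peptides, FLANK + 1L, FLANK + 1L)
  if (!all(center %in% CENTER_RESIDUES)) {
    abort("peptide center residue must be S, T or Y")
  }
  # '-' only as a contiguous prefix and/or suffix
  core <- gsub("^-+|-+$", "", peptides)
  if (any(grepl("-", core, fixed = TRUE))) {
    abort("peptide padding '-' must be terminal only")
  }
  invisible(peptides)
}

#' Extract the kinase-domain sequence from kinase records
#'
#' @param kinases kinase record tibble.
#' @return character vector of domain substrings.
#' @export
kinase_domains <- function(kinases) {
  substr(kinases$full_sequence, kinases$domain_start, kinases$domain_end)
}
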