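#' Substrate-specificity grammars for the synthetic kinome
#'
#' Five planted grammars emulate the classical kinase specificity classes:
#' basophilic (R/K at P-3 and P-2), proline-directed (P at P+1),
#' acidophilic (D/E at P+1..P+3), SQ-motif (Q at P+1, serine center) and
#' tyrosine kinases (Y center, E at P-1). A grammar lists the allowed
#' center residues and, per determinant offset, the allowed residue set.
#'
#' @return named list of `specificity_grammar` objects.
#' @export
default_grammars <- function() {
  g <- function(family, center, determinants) {
    structure(list(family = family, center = center,
                   determinants = determinants),
              class = "specificity_grammar")
  }
  list(
    BASO = g("BASO", c("S", "T"), list(`-3` = c("R", "K"),
                                       `-2` = c("R", "K"))),
    PRO  = g("PRO",  c("S", "T"), list(`+1` = "P")),
    ACID = g("ACID", c("S", "T"), list(`+1` = c("D", "E"),
                                       `+2` = c("D", "E"),
                                       `+3` = c("D", "E"))),
    SQ   = g("SQ",   "S",         list(`+1` = "Q")),
    TYR  = g("TYR",  "Y",         list(`-1` = "E"))
  )
}

# offsets are relative to the center; peptide index = offset + 6
grammar_offsets <- function(grammar) {
  as.integer(sub("^\\+", "", names(grammar$determinants)))
}

#' Does a peptide window satisfy a specificity grammar?
#'
#' @param peptides character vector of 11-mer windows.
#' @param grammar a `specificity_grammar`.
#' @return logical vector.
#' @export
grammar_satisfied <- function(peptides, grammar) {
  ok <- substr(peptides, FLANK + 1L, FLANK + 1L) %in% grammar$center
  for (off in names(grammar$determinants)) {
    i <- as.integer(sub("^\\+", "", off)) + FLANK + 1L
    ok <- ok & substr(peptides, i, i) %in% grammar$determinants[[off]]
  }
  ok
}

#' Configure the synthetic kinome
#'
#' Defaults are sized for desk-scale end-to-end runs: 5 grammar families of
#' 4 kinases, 80-residue domains embedded in 120-residue proteins, 200
#' substrates of 300 residues, per-kinase positive-site counts drawn from a
#' power law between 1 and 120 (emulating the strong skew of curated
#' phosphosite sets), and a 5% grammar-violation rate standing in for
#' annotation noise.
#'
#' @param families named list of grammars (default [default_grammars()]).
#' @param kinases_per_family kinases generated per family.
#' @param domain_length catalytic-domain length.
#' @param full_length full kinase-sequence length (domain embedded at a
#'   random offset, leaving flanks for boundary-shifting).
#' @param mutation_rate per-residue probability that a kinase deviates from
#'   its family consensus.
#' @param n_substrates,substrate_length substrate proteome size.
#' @param pos_min,pos_max,pos_alpha power-law support and exponent for
#'   per-kinase implanted-site counts.
#' @param epsilon fraction of implanted sites that violate their grammar.
#' @param share_within_family annotate a conforming site as a positive for
#'   every kinase of the implanting family (they share the same planted
#'   grammar, so this is the generator's ground truth); violating sites are
#'   annotated only for the kinase they were drawn for.
#' @param seed integer seed; regeneration with the same seed is
#'   byte-identical.
#' @return a `synth_config` list.
#' @export
synthetic_kinome_config <- function(families = default_grammars(),
                                    kinases_per_family = 4L,
                                    domain_length = 80L,
                                    full_length = 120L,
                                    mutation_rate = 0.05,
                                    n_substrates = 200L,
                                    substrate_length = 300L,
                                    pos_min = 1L, pos_max = 120L,
                                    pos_alpha = 1.2,
                                    epsilon = 0.05,
                                    share_within_family = TRUE,
                                    seed = 1L) {
  stopifnot(epsilon >= 0, epsilon < 0.5, domain_length < full_length,
            substrate_length >= WINDOW_SIZE)
  structure(list(families = families,
                 kinases_per_family = as.integer(kinases_per_family),
                 domain_length = as.integer(domain_length),
                 full_length = as.integer(full_length),
                 mutation_rate = mutation_rate,
                 n_substrates = as.integer(n_substrates),
                 substrate_length = as.integer(substrate_length),
                 pos_min = as.integer(pos_min),
                 pos_max = as.integer(pos_max),
                 pos_alpha = pos_alpha, epsilon = epsilon,
                 share_within_family = share_within_family,
                 seed = as.integer(seed)),
            class = "synth_config")
}

# discrete power-law draw on [lo, hi]
rpower <- function(n, lo, hi, alpha) {
  u <- runif(n)
  lo1 <- lo - 0.5; hi1 <- hi + 0.5
  if (abs(alpha - 1) < 1e-9) {
    x <- lo1 * (hi1 / lo1)^u
  } else {
    x <- (lo1^(1 - alpha) + u * (hi1^(1 - alpha) - lo1^(1 - alpha)))^(1 / (1 - alpha))
  }
  pmin(pmax(round(x), lo), hi)
}

#' Generate the synthetic kinome
#'
#' Each family gets a random consensus domain; each kinase is the consensus
#' with i.i.d. mutations at `mutation_rate`, embedded at a random offset in
#' a longer full-length sequence so boundary shifting has room to act.
#'
#' @param cfg a [synthetic_kinome_config()].
#' @return kinase record tibble (family and group labels filled in; group
#'   is "TK" for the tyrosine family and "STK" otherwise).
#' @export
generate_kinome <- function(cfg = synthetic_kinome_config()) {
  withr::local_seed(cfg$seed)
  rows <- list()
  for (fam in names(cfg$families)) {
    consensus <- strsplit(random_aa(cfg$domain_length), "")[[1]]
    for (i in seq_len(cfg$kinases_per_family)) {
      dom <- consensus
      hit <- runif(cfg$domain_length) < cfg$mutation_rate
      dom[hit] <- sample(AA20, sum(hit), replace = TRUE)
      flank_total <- cfg$full_length - cfg$domain_length
      start <- sample.int(flank_total + 1L, 1L)
      full <- paste0(random_aa(start - 1L), paste(dom, collapse = ""),
                     random_aa(flank_total - start + 1L))
      id <- sprintf("%s_%d", fam, i)
      rows[[id]] <- tibble(
        kinase_id = id, full_sequence = full,
        domain_start = start, domain_end = start + cfg$domain_length - 1L,
        gene = id, family = fam,
        group = if (identical(cfg$families[[fam]]$center, "Y")) "TK"
                else "STK",
        organism = "synthetic")
    }
  }
  bind_rows(rows)
}

#' Generate substrates and implanted phosphosite annotations
#'
#' Random substrate proteins receive implanted sites matching each kinase's
#' family grammar. A fraction `epsilon` of sites violates the grammar
#' (annotation noise). Implants never overlap within a window and keep a
#' 5-residue margin from the termini so the full determinant context fits.
#' With `share_within_family` (the default), conforming sites are annotated
#' for every kinase of the family; unimplanted S/T/Y windows form the
#' easy-negative universe and implanted sites of other families become hard
#' negatives under the generic pool-building rules.
#'
#' @param cfg a [synthetic_kinome_config()].
#' @param kinome tibble from [generate_kinome()].
#' @return list with `substrates`, `annotations` (kinase_id, substrate_id,
#'   site_position, residue) and `truth` (per implanted site: peptide,
#'   family, conforming flag).
#' @export
generate_substrates_and_sites <- function(cfg = synthetic_kinome_config(),
                                          kinome = generate_kinome(cfg)) {
  withr::local_seed(child_seed(cfg$seed, 1L))
  subs <- tibble(
    substrate_id = sprintf("SUB_%03d", seq_len(cfg$n_substrates)),
    sequence = vapply(seq_len(cfg$n_substrates),
                      function(i) random_aa(cfg$substrate_length),
                      character(1)),
    organism = "synthetic")
  seqs <- strsplit(subs$sequence, "")
  # reserve implanted windows so two implants never overwrite each other
  taken <- lapply(seq_len(cfg$n_substrates), function(i)
    logical(cfg$substrate_length))

  counts <- rpower(nrow(kinome), cfg$pos_min, cfg$pos_max, cfg$pos_alpha)
  ann <- list()
  truth <- list()
  fam_members <- split(kinome$kinase_id, kinome$family)
  for (j in seq_len(nrow(kinome))) {
    k <- kinome$kinase_id[j]
    fam <- kinome$family[j]
    grammar <- cfg$families[[fam]]
    placed <- 0L
    guard <- 0L
    while (placed < counts[j] && guard < counts[j] * 200L) {
      guard <- guard + 1L
      si <- sample.int(cfg$n_substrates, 1L)
      pos <- sample(seq(FLANK + 1L, cfg$substrate_length - FLANK), 1L)
      win <- (pos - FLANK):(pos + FLANK)
      if (any(taken[[si]][win])) next
      conforming <- runif(1) >= cfg$epsilon
      center <- sample(grammar$center, 1L)
      seqs[[si]][pos] <- center
      for (off in names(grammar$determinants)) {
        o <- as.integer(sub("^\\+", "", off))
        allowed <- grammar$determinants[[off]]
        res <- if (conforming) sample(allowed, 1L) else
          sample(setdiff(AA20, c(allowed, CENTER_RESIDUES)), 1L)
        seqs[[si]][pos + o] <- res
      }
      if (!conforming) {
        # a violating site must not satisfy the grammar by accident;
        # determinants were drawn outside the allowed sets, so it cannot
      }
      taken[[si]][win] <- TRUE
      annotate_for <- if (conforming && cfg$share_within_family)
        fam_members[[fam]] else k
      ann[[length(ann) + 1L]] <- tibble(
        kinase_id = annotate_for, substrate_id = subs$substrate_id[si],
        site_position = pos, residue = center)
      truth[[length(truth) + 1L]] <- tibble(
        substrate_id = subs$substrate_id[si], site_position = pos,
        family = fam, conforming = conforming)
      placed <- placed + 1L
    }
  }
  subs$sequence <- vapply(seqs, paste, character(1), collapse = "")
  annotations <- distinct(bind_rows(ann))
  truth <- bind_rows(truth)
  truth$peptide <- site_peptide(subs, truth)
  list(substrates = subs, annotations = annotations, truth = truth)
}

#' Generate a complete synthetic study
#'
#' One-call wrapper: kinome, substrates, annotations and ground truth.
#'
#' @param cfg a [synthetic_kinome_config()].
#' @return list with `kinases`, `substrates`, `annotations`, `truth`,
#'   `grammars` and the config.
#' @export
simulate_kinome <- function(cfg = synthetic_kinome_config()) {
  kinome <- generate_kinome(cfg)
  rest <- generate_substrates_and_sites(cfg, kinome)
  list(kinases = kinome, substrates = rest$substrates,
       annotations = rest$annotations, truth = rest$truth,
       grammars = cfg$families, config = cfg)
}

#' Grammar-oracle score for synthetic pairs
#'
#' The brute-force reference labeler: 1 when the peptide satisfies the
#' grammar of the paired kinase's family, else 0. Used to sanity-check the
#' metric stack and as a perfect-separability baseline.
#'
#' @param pairs tibble with `kinase_id` and `peptide`.
#' @param kinome kinase record tibble with `family` labels.
#' @param grammars named list of grammars.
#' @return integer vector of 0/1 scores.
#' @export
oracle_score <- function(pairs, kinome, grammars = default_grammars()) {
  fam <- kinome$family[match(pairs$kinase_id, kinome$kinase_id)]
  if (anyNA(fam)) {
    abort(sprintf("unknown kinase in pairs: %s",
                  pairs$kinase_id[which(is.na(fam))[1]]))
  }
  out <- integer(nrow(pairs))
  for (f in unique(fam)) {
    i <- fam == f
    out[i] <- as.integer(grammar_satisfied(pairs$peptide[i], grammars[[f]]))
  }
  out
}
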