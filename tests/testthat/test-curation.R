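test_that("extract_windows enumerates S/T/Y sites with terminal padding", {
  subs <- tibble::tibble(substrate_id = "P1", sequence = "MSAYT")
  win <- extract_windows(subs)
  expect_equal(nrow(win), 3L)                      # S@2, Y@4, T@5
  expect_equal(win$site_position, c(2L, 4L, 5L))
  expect_equal(win$peptide[1], "----MSAYT--")
  expect_equal(win$peptide[2], "--MSAYT----")
  expect_equal(win$peptide[3], "-MSAYT-----")
  expect_true(all(nchar(win$peptide) == 11L))
  expect_true(all(substr(win$peptide, 6, 6) %in% c("S", "T", "Y")))

  # no phosphorylatable residue -> empty
  expect_equal(nrow(extract_windows(
    tibble::tibble(substrate_id = "P2", sequence = "AAAAA"))), 0L)

  # exact-length substrate: one unpadded window
  win11 <- extract_windows(
    tibble::tibble(substrate_id = "P3", sequence = "AAAAASAAAAA"))
  expect_equal(nrow(win11), 1L)
  expect_equal(win11$peptide, "AAAAASAAAAA")
  expect_equal(win11$site_position, 6L)
})

test_that("windows are de-duplicated per substrate, kept across substrates", {
  subs <- tibble::tibble(
    substrate_id = c("P1", "P2"),
    sequence = c("AASAAAAASAAAAA", "AASAAAAAAAA"))  # P1 repeats AASAA...
  win <- extract_windows(subs)
  per_sub <- split(win$peptide, win$substrate_id)
  expect_true(all(vapply(per_sub, anyDuplicated, integer(1)) == 0L))
  # the same 11-mer may appear in both substrates as distinct records
  shared <- intersect(per_sub$P1, per_sub$P2)
  expect_true(length(shared) >= 1L)
})

test_that("pool construction follows the negative taxonomy definitions", {
  study <- toy_study()
  suppressMessages(
    ann <- read_annotation_table(study$annotations, study$substrates))
  pools <- build_pools(ann, study$substrates)

  # K1 phosphorylates S1@6 and S2@2; K2 phosphorylates S1@12:
  # each kinase's sites are hard negatives for the other
  k2_hard <- pools$hard[pools$hard$kinase_id == "K2", ]
  expect_setequal(paste(k2_hard$substrate_id, k2_hard$site_position),
                  c("S1 6", "S2 2"))
  k1_hard <- pools$hard[pools$hard$kinase_id == "K1", ]
  expect_setequal(paste(k1_hard$substrate_id, k1_hard$site_position),
                  "S1 12")

  # a site annotated to both kinases is a hard negative for neither
  ann_shared <- dplyr::bind_rows(
    ann, tibble::tibble(kinase_id = "K2", substrate_id = "S2",
                        site_position = 2L, residue = "S"))
  pools2 <- build_pools(ann_shared, study$substrates)
  expect_false(any(pools2$hard$substrate_id == "S2" &
                     pools2$hard$site_position == 2L))

  # easy negatives: S/T/Y windows with no annotation at all
  win <- extract_windows(study$substrates)
  expect_equal(nrow(pools$easy), nrow(win) - 3L)
  expect_equal(nrow(dplyr::inner_join(
    pools$easy, pools$positives,
    by = c("substrate_id", "peptide"))), 0L)
  # hard and easy pools are disjoint on peptides
  expect_equal(length(intersect(
    paste(pools$hard$substrate_id, pools$hard$peptide),
    paste(pools$easy$substrate_id, pools$easy$peptide))), 0L)
})

test_that("a substrate with 10 sites and 3 annotated yields 7 easy negatives", {
  # distinct flanks so the 10 windows are 10 distinct strings
  seq10 <- paste0("ASCSDSESFSGSHSISKSLS", "AAA")  # S at 2,4,..,20
  subs <- tibble::tibble(substrate_id = "Q1", sequence = seq10)
  ann <- tibble::tibble(kinase_id = "K1", substrate_id = "Q1",
                        site_position = c(2L, 4L, 6L), residue = "S")
  suppressMessages(ann <- read_annotation_table(ann, subs))
  pools <- build_pools(ann, subs)
  expect_equal(nrow(pools$easy), 7L)
})

test_that("70:15:15 split sends small kinases to train only", {
  withr::local_seed(7)
  # one kinase with 100 positives, one with 49, one with exactly 50;
  # peptides are index-coded so every window is distinct
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  pepify <- function(n, tag) vapply(seq_len(n), function(i)
    paste0(tag, aa[(i %% 20) + 1], aa[(i %/% 20 %% 20) + 1], "A", "S",
           "AAAAA"), character(1))
  pos <- dplyr::bind_rows(
    tibble::tibble(kinase_id = "BIG", substrate_id = sprintf("B%d", 1:100),
                   site_position = 6L, peptide = pepify(100, "AC")),
    tibble::tibble(kinase_id = "SMALL", substrate_id = sprintf("S%d", 1:49),
                   site_position = 6L, peptide = pepify(49, "AD")),
    tibble::tibble(kinase_id = "EDGE", substrate_id = sprintf("E%d", 1:50),
                   site_position = 6L, peptide = pepify(50, "AE")))
  hard <- tidyr::crossing(
    dplyr::rename(pos, owner = "kinase_id"),
    kinase_id = c("BIG", "SMALL", "EDGE"))
  hard <- hard[hard$kinase_id != hard$owner,
               c("kinase_id", "substrate_id", "site_position", "peptide")]
  pools <- structure(
    list(positives = pos, hard = hard,
         easy = pos[0, c("substrate_id", "site_position", "peptide")]),
    class = "kinasite_pools")
  split <- split_dataset(pools, seed = 99)

  count_pos <- function(part, k) sum(part$kinase_id == k &
                                       part$label == "positive")
  expect_equal(count_pos(split$train, "BIG"), 70L)
  expect_equal(count_pos(split$validation, "BIG"), 15L)
  expect_equal(count_pos(split$test, "BIG"), 15L)
  # at or below 50 positives: training only
  expect_equal(count_pos(split$train, "SMALL"), 49L)
  expect_equal(count_pos(split$train, "EDGE"), 50L)
  expect_equal(count_pos(split$validation, "SMALL") +
                 count_pos(split$test, "SMALL"), 0L)
  expect_equal(count_pos(split$validation, "EDGE") +
                 count_pos(split$test, "EDGE"), 0L)

  # one paired hard negative per evaluation positive
  expect_equal(sum(split$validation$label == "hard_negative"), 15L)
  expect_equal(sum(split$test$label == "hard_negative"), 15L)

  # partitions are disjoint on (kinase, peptide)
  key <- function(p) paste(p$kinase_id, p$peptide)
  expect_equal(length(intersect(key(split$train), key(split$validation))), 0L)
  expect_equal(length(intersect(key(split$train), key(split$test))), 0L)
  expect_equal(length(intersect(key(split$validation), key(split$test))), 0L)

  # same seed reproduces the split exactly
  split2 <- split_dataset(pools, seed = 99)
  expect_identical(split$train, split2$train)
  expect_identical(split$test, split2$test)
})

test_that("training negative sampling hits the configured ratio", {
  sim <- simulate_kinome(mini_synth_config(seed = 31))
  suppressMessages(
    ann <- read_annotation_table(sim$annotations, sim$substrates))
  pools <- build_pools(ann, sim$substrates)
  split <- split_dataset(pools, seed = 5)
  n_pos <- sum(split$train$label == "positive")

  # n = 15, m = 1 gives a 1:16 positive:negative training ratio
  aug <- sample_training_negatives(split, pools, n_easy = 15L, m_hard = 1L,
                                   seed = 6)
  expect_equal(sum(aug$train$label != "positive"), 16L * n_pos)
  expect_equal(aug$negative_ratio, 16L)

  # n = m = 0 leaves the training set unchanged
  same <- sample_training_negatives(split, pools, n_easy = 0L, m_hard = 0L,
                                    seed = 6)
  expect_identical(same$train, split$train)

  # n = m = 1: two negatives per positive
  two <- sample_training_negatives(split, pools, n_easy = 1L, m_hard = 1L,
                                   seed = 6)
  expect_equal(sum(two$train$label == "easy_negative"), n_pos)
  expect_equal(sum(two$train$label == "hard_negative"), n_pos)

  # hard negatives reserved for validation/test are never reused in train
  reserved <- paste(aug$train$kinase_id, aug$train$peptide)[
    aug$train$label == "hard_negative"]
  used <- paste(split$hard_used$kinase_id, split$hard_used$peptide)
  expect_equal(length(intersect(reserved, used)), 0L)

  expect_error(
    sample_training_negatives(
      structure(list(train = split$train, hard_used = split$hard_used),
                class = "kinasite_split"),
      structure(list(positives = pools$positives, hard = pools$hard,
                     easy = pools$easy[0, ]), class = "kinasite_pools"),
      n_easy = 1L, m_hard = 0L),
    "easy-negative pool is empty")
})
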