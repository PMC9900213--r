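test_that("positive resampling balances per-kinase counts without downsampling", {
  withr::local_seed(11)
  pos <- dplyr::bind_rows(
    tibble::tibble(kinase_id = "MANY", peptide = sprintf("p%d", 1:60)),
    tibble::tibble(kinase_id = "FEW", peptide = sprintf("q%d", 1:10)),
    tibble::tibble(kinase_id = "MAX", peptide = sprintf("r%d", 1:1118)))
  cfg <- augmentation_config()
  out <- resample_positives(pos, cfg)
  tab <- table(out$kinase_id)
  expect_equal(unname(tab[["MANY"]]), 1118L)  # above threshold -> 1118
  expect_equal(unname(tab[["FEW"]]), 50L)     # at/below threshold -> 50
  expect_equal(unname(tab[["MAX"]]), 1118L)   # already at target: unchanged
  expect_identical(out$peptide[out$kinase_id == "MAX"],
                   pos$peptide[pos$kinase_id == "MAX"])
  # resampled rows are drawn from the original pool only
  expect_true(all(out$peptide[out$kinase_id == "FEW"] %in%
                    sprintf("q%d", 1:10)))
})

test_that("boundary shifting stays inside the protein and covers +/- max_shift", {
  withr::local_seed(12)
  kin <- tibble::tibble(
    kinase_id = "K", full_sequence = rand_seq(120),
    domain_start = 21L, domain_end = 100L)

  # max_shift = 0 is the identity on the domain string
  cfg0 <- augmentation_config(max_shift = 0L)
  expect_identical(shift_domain(kin, cfg0), kinase_domains(kin))

  # shifted domains are always substrings of the full sequence
  cfg <- augmentation_config(max_shift = 5L)
  reps <- shift_domain(kin[rep(1, 500), ], cfg)
  expect_true(all(vapply(reps, function(s)
    grepl(s, kin$full_sequence, fixed = TRUE), logical(1))))

  # observed displacements cover exactly {-5, ..., 5} over many draws
  many <- shift_domain(kin[rep(1, 10000), ], cfg)
  starts <- vapply(many, function(s)
    as.integer(regexpr(substr(s, 1, 15), kin$full_sequence, fixed = TRUE)),
    integer(1))
  deltas <- sort(unique(starts - kin$domain_start))
  expect_equal(deltas, -5:5)

  # a domain flush at the N-terminus can only shift inward
  kin2 <- tibble::tibble(kinase_id = "K2", full_sequence = rand_seq(100),
                         domain_start = 1L, domain_end = 60L)
  many2 <- shift_domain(kin2[rep(1, 2000), ], cfg)
  lens <- nchar(many2)
  n_starts <- vapply(many2, function(s)
    as.integer(regexpr(substr(s, 1, 15), kin2$full_sequence, fixed = TRUE)),
    integer(1))
  expect_true(all(n_starts >= 1L))            # delta_N clamped to {0..+5}
  expect_true(all(n_starts - 1L <= 5L))
})

test_that("kinase masking is Bernoulli at the configured rate", {
  withr::local_seed(13)
  # rate 0: identity
  cfg0 <- augmentation_config(kinase_mask_rate = 0)
  expect_identical(mask_kinase("ACDEFG", cfg0), "ACDEFG")

  # high rate: nearly everything masked, length preserved
  cfg99 <- augmentation_config(kinase_mask_rate = 0.99)
  m <- mask_kinase(strrep("A", 2000), cfg99)
  expect_equal(nchar(m), 2000L)
  expect_gt(mean(strsplit(m, "")[[1]] == "#"), 0.95)

  # default rate 5% within a tight binomial band over 1e6 positions
  cfg <- augmentation_config()
  big <- mask_kinase(strrep("L", 1000000L), cfg)
  frac <- mean(strsplit(big, "")[[1]] == "#")
  expect_lt(abs(frac - 0.05), 0.001)

  expect_error(mask_kinase("", cfg), "empty")
})

test_that("augment_batch composes correctly and never touches peptides", {
  sim <- simulate_kinome(mini_synth_config(seed = 21))
  suppressMessages(
    ann <- read_annotation_table(sim$annotations, sim$substrates))
  pools <- build_pools(ann, sim$substrates)
  split <- split_dataset(pools, min_positives = 5L, seed = 3)
  split <- sample_training_negatives(split, pools, 1L, 1L, seed = 4)

  # all strategies disabled: rows unchanged, domain = unshifted domain
  off <- augmentation_config(resample = FALSE, shift = FALSE, mask = FALSE)
  withr::local_seed(5)
  plain <- augment_batch(split$train, sim$kinases, off)
  expect_equal(nrow(plain), nrow(split$train))
  expect_identical(
    sort(plain$kinase_domain),
    sort(kinase_domains(sim$kinases[
      match(plain$kinase_id, sim$kinases$kinase_id), ])))

  # full augmentation: negatives are never resampled, peptides unchanged
  cfg <- augmentation_config(resample_target_large = 40L,
                             resample_target_small = 10L,
                             resample_threshold = 5L)
  aug <- augment_batch(split$train, sim$kinases, cfg)
  n_neg_in <- sum(split$train$label != "positive")
  expect_equal(sum(aug$label != "positive"), n_neg_in)
  expect_true(all(aug$peptide %in% split$train$peptide))
  expect_true(all(nchar(aug$kinase_domain) > 0))

  # refuses non-training partitions
  expect_error(augment_batch(split$test, sim$kinases, cfg,
                             partition = "test"),
               "training partition only")
})

test_that("augmentation is deterministic under a fixed seed", {
  kin <- tibble::tibble(kinase_id = "K", full_sequence = rand_seq(200),
                        domain_start = 31L, domain_end = 150L)
  cfg <- augmentation_config()
  a <- withr::with_seed(77, mask_kinase(shift_domain(kin, cfg), cfg))
  b <- withr::with_seed(77, mask_kinase(shift_domain(kin, cfg), cfg))
  c <- withr::with_seed(78, mask_kinase(shift_domain(kin, cfg), cfg))
  expect_identical(a, b)
  expect_false(identical(a, c))
})
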