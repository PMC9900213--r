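make_corpus <- function(n = 60, len = 40, seed = 5) {
  withr::with_seed(seed, replicate(n, rand_seq(len)))
}

test_that("MLM pre-training reduces the loss on a small corpus", {
  corpus <- make_corpus()
  m <- init_model(probe_config(), seed = 1)
  cfg <- train_config("pretrain", lr = 1e-3, batch_size = 16L, epochs = 3L,
                      seed = 2)
  suppressMessages(trained <- pretrain(m, corpus, cfg))
  h <- tidy(trained)
  expect_equal(nrow(h), 3L)
  expect_lt(h$loss[3], h$loss[1])
  expect_equal(trained$stage, "pretrained")

  # zero epochs leaves parameters untouched
  suppressMessages(same <- pretrain(m, corpus,
                                    train_config("pretrain", epochs = 0L)))
  expect_identical(same$params, m$params)

  # identical seeds give identical loss traces; different seeds differ
  suppressMessages(t2 <- pretrain(m, corpus, cfg))
  expect_identical(tidy(trained)$loss, tidy(t2)$loss)
  cfg3 <- train_config("pretrain", lr = 1e-3, batch_size = 16L,
                       epochs = 3L, seed = 99)
  suppressMessages(t3 <- pretrain(m, corpus, cfg3))
  expect_false(identical(tidy(trained)$loss, tidy(t3)$loss))

  expect_error(pretrain(m, character(0)), "empty")
})

test_that("fine-tuning early-stops on validation loss with the given patience", {
  sim <- simulate_kinome(mini_synth_config(seed = 41))
  suppressMessages(
    ann <- read_annotation_table(sim$annotations, sim$substrates))
  pools <- build_pools(ann, sim$substrates)
  split <- split_dataset(pools, min_positives = 3L, seed = 42)
  split <- sample_training_negatives(split, pools, 1L, 1L, seed = 43)
  m <- init_model(probe_config(), seed = 44)

  # lr = 0: validation loss can never improve after the first evaluation,
  # so patience 1 stops right after the second epoch
  cfg <- train_config("finetune", lr = 0, gamma = 2, batch_size = 64L,
                      epochs = 10L, patience = 1L, seed = 45)
  suppressMessages(ft <- finetune(m, split, sim$kinases, cfg,
                                  augmentation_config(resample = FALSE)))
  h <- tidy(ft)
  expect_equal(nrow(h[h$stage == "finetune", ]), 2L)
  expect_equal(ft$best_epoch, 1L)

  # empty validation set is refused
  empty <- split
  empty$validation <- empty$validation[0, ]
  expect_error(finetune(m, empty, sim$kinases, cfg), "validation")
})

test_that("training is reproducible and actually learns on the toy kinome", {
  sim <- simulate_kinome(synthetic_kinome_config(
    families = default_grammars()[c("BASO", "PRO", "TYR")],
    kinases_per_family = 2L, domain_length = 20L, full_length = 34L,
    n_substrates = 30L, substrate_length = 100L,
    pos_min = 8L, pos_max = 25L, epsilon = 0, seed = 51))
  suppressMessages(
    ann <- read_annotation_table(sim$annotations, sim$substrates))
  pools <- build_pools(ann, sim$substrates)
  split <- split_dataset(pools, min_positives = 3L, seed = 52)
  split <- sample_training_negatives(split, pools, 2L, 1L, seed = 53)
  m <- init_model(tiny_model_config(), seed = 54)
  cfg <- train_config("finetune", lr = 2e-3, gamma = 2, batch_size = 32L,
                      epochs = 8L, patience = 10L, warmup_steps = 5L,
                      seed = 55)
  aug <- augmentation_config(resample_target_large = 60L,
                             resample_target_small = 30L,
                             resample_threshold = 3L)
  suppressMessages(ft <- finetune(m, split, sim$kinases, cfg, aug))
  suppressMessages(ft2 <- finetune(m, split, sim$kinases, cfg, aug))
  expect_identical(tidy(ft)$loss, tidy(ft2)$loss)
  expect_identical(tidy(ft)$val_loss, tidy(ft2)$val_loss)

  # the fit separates held-out positives from hard negatives far better
  # than chance
  val <- dplyr::bind_rows(split$validation, split$test)
  val$kinase_domain <- kinase_domains(
    sim$kinases[match(val$kinase_id, sim$kinases$kinase_id), ])
  scored <- classify(ft, val)
  auc <- roc_auc(scored$probability,
                 as.integer(scored$label == "positive"))
  expect_gt(auc, 0.75)

  # a trained model's score responds to kinase-side perturbation
  one <- val[val$label == "positive", ][1, ]
  p0 <- classify(ft, one)$probability
  mutated <- one
  mutated$kinase_domain <- paste0("WWWWWWWWWW",
                                  substr(one$kinase_domain, 11,
                                         nchar(one$kinase_domain)))
  p1 <- classify(ft, mutated)$probability
  expect_false(isTRUE(all.equal(p0, p1)))
})

test_that("checkpoints round-trip through plain-text JSON", {
  m <- init_model(probe_config(), seed = 61)
  m$history <- tibble::tibble(stage = "pretrain", epoch = 1L, loss = 3.2,
                              val_loss = NA_real_)
  m$stage <- "pretrained"
  dir <- withr::local_tempdir()
  save_model(m, dir)
  back <- load_model(dir)
  expect_equal(back$params, m$params, tolerance = 0)
  expect_equal(back$config, m$config)
  expect_equal(back$stage, "pretrained")
  # restored model scores identically
  enc <- encode_pairs(probe_pairs())
  expect_identical(classify(m, enc)$probability,
                   classify(back, enc)$probability)
  expect_error(load_model(file.path(dir, "nope")), "no checkpoint")

  # broom-style summaries
  g <- glance(back)
  expect_equal(nrow(g), 1L)
  expect_equal(g$embed_dim, 8L)
  expect_equal(g$stage, "pretrained")
  expect_equal(g$final_mlm_loss, 3.2)
})
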