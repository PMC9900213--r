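test_that("kinome generation produces labeled families with consensus structure", {
  cfg <- synthetic_kinome_config(seed = 81)
  kin <- generate_kinome(cfg)
  expect_equal(nrow(kin), 20L)           # 5 families x 4 kinases
  expect_equal(sort(unique(kin$family)),
               sort(names(default_grammars())))
  expect_true(all(table(kin$family) == 4L))
  expect_equal(unique(kin$group[kin$family == "TYR"]), "TK")
  expect_true(all(nchar(kin$full_sequence) == cfg$full_length))
  expect_true(all(nchar(kinase_domains(kin)) == cfg$domain_length))

  # zero mutation rate makes family members share an identical domain
  cfg0 <- synthetic_kinome_config(mutation_rate = 0, seed = 82)
  kin0 <- generate_kinome(cfg0)
  doms <- split(kinase_domains(kin0), kin0$family)
  expect_true(all(vapply(doms, function(d)
    length(unique(d)) == 1L, logical(1))))

  # family is recoverable from sequence by nearest-consensus assignment
  kin5 <- generate_kinome(synthetic_kinome_config(seed = 83))
  doms5 <- strsplit(kinase_domains(kin5), "")
  consensus <- lapply(split(seq_len(nrow(kin5)), kin5$family), function(i) {
    apply(do.call(rbind, doms5[i]), 2, function(col)
      names(sort(table(col), decreasing = TRUE))[1])
  })
  assigned <- vapply(doms5, function(d) {
    names(which.max(vapply(consensus, function(cons)
      sum(cons == d), numeric(1))))
  }, character(1))
  expect_gte(mean(assigned == kin5$family), 0.99)
})

test_that("implanted sites obey their grammar up to the violation rate", {
  cfg <- synthetic_kinome_config(seed = 84, epsilon = 0.05)
  sim <- simulate_kinome(cfg)
  sat <- logical(nrow(sim$truth))
  for (f in unique(sim$truth$family)) {
    i <- sim$truth$family == f
    sat[i] <- grammar_satisfied(sim$truth$peptide[i], sim$grammars[[f]])
  }
  # conforming flag and realized grammar satisfaction agree
  expect_true(all(sat[sim$truth$conforming]))
  expect_true(all(!sat[!sim$truth$conforming]))
  # satisfaction rate within 3 binomial SEs of 1 - epsilon
  n <- nrow(sim$truth)
  se <- sqrt(0.05 * 0.95 / n)
  expect_gte(mean(sat), 1 - cfg$epsilon - 3 * se)

  # epsilon 0: every positive satisfies its grammar exactly
  sim0 <- simulate_kinome(synthetic_kinome_config(seed = 85, epsilon = 0))
  for (f in unique(sim0$truth$family)) {
    i <- sim0$truth$family == f
    expect_true(all(grammar_satisfied(sim0$truth$peptide[i],
                                      sim0$grammars[[f]])))
  }

  # a proline-directed kinase's positives carry P at P+1 at >= 1 - epsilon
  pro <- sim$truth[sim$truth$family == "PRO", ]
  se_pro <- sqrt(0.05 * 0.95 / nrow(pro))
  expect_gte(mean(substr(pro$peptide, 7, 7) == "P"),
             1 - cfg$epsilon - 3 * se_pro)
})

test_that("generated annotations validate cleanly and regenerate identically", {
  cfg <- mini_synth_config(seed = 86)
  sim <- simulate_kinome(cfg)
  got <- suppressMessages(
    read_annotation_table(sim$annotations, sim$substrates))
  expect_equal(nrow(got), nrow(sim$annotations))
  expect_equal(nrow(attr(got, "rejected")), 0L)

  sim2 <- simulate_kinome(mini_synth_config(seed = 86))
  expect_identical(sim$kinases, sim2$kinases)
  expect_identical(sim$substrates, sim2$substrates)
  expect_identical(sim$annotations, sim2$annotations)
  sim3 <- simulate_kinome(mini_synth_config(seed = 87))
  expect_false(identical(sim$annotations, sim3$annotations))
})

test_that("the grammar oracle is a perfect labeler on separable families", {
  # PRO and TYR grammars are mutually exclusive by center residue, so with
  # epsilon 0 the oracle separates positives from hard negatives exactly
  cfg <- mini_synth_config(
    seed = 88, epsilon = 0,
    families = default_grammars()[c("PRO", "TYR")])
  sim <- simulate_kinome(cfg)
  suppressMessages(
    ann <- read_annotation_table(sim$annotations, sim$substrates))
  pools <- build_pools(ann, sim$substrates)
  pos <- pools$positives |> dplyr::mutate(label = "positive")
  hard <- pools$hard |> dplyr::mutate(label = "hard_negative")
  pairs <- dplyr::bind_rows(pos, hard)
  sc <- oracle_score(pairs, sim$kinases, sim$grammars)
  expect_equal(roc_auc(sc, as.integer(pairs$label == "positive")), 1.0)

  # cross-class sanity: a basophilic kinase rejects a proline peptide
  kin <- tibble::tibble(kinase_id = c("B", "P"),
                        family = c("BASO", "PRO"))
  toy <- tibble::tibble(kinase_id = c("B", "P"),
                        peptide = c("AAAAASPAAAA", "AAAAASPAAAA"))
  expect_equal(oracle_score(toy, kin), c(0L, 1L))
  expect_error(oracle_score(tibble::tibble(kinase_id = "Z",
                                           peptide = "AAAAASPAAAA"),
                            kin), "unknown kinase")
})

test_that("per-kinase site counts are skewed across the configured range", {
  cfg <- synthetic_kinome_config(seed = 89, share_within_family = FALSE)
  sim <- simulate_kinome(cfg)
  counts <- table(sim$annotations$kinase_id)
  expect_gte(min(counts), cfg$pos_min)
  expect_lte(max(counts), cfg$pos_max)
  # skew: the largest kinase has several times the median count
  expect_gt(max(counts) / stats::median(counts), 2)
})
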