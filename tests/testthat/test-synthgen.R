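test_that("ground-truth bookkeeping matches the configured fractions", {
  cfg0 <- null_sim_config(
    n_tissues = 5, genes_total = 300, signature_genes_per_tissue = 10,
    samples_per_tissue = 10, rng_seed = 3
  )
  truth0 <- simulate_corpus(cfg0)$truth$samples
  expect_equal(sum(truth0$is_mixture), 0L)
  expect_equal(sum(truth0$is_mislabel), 0L)

  cfg <- sim_config(
    n_tissues = 5, genes_total = 300, signature_genes_per_tissue = 10,
    samples_per_tissue = 100, contamination_fraction = 0.1,
    mixing_proportion = 0.5, mislabel_fraction = 0, rng_seed = 4
  )
  truth <- simulate_corpus(cfg)$truth$samples
  expect_equal(sum(truth$is_mixture), 50L) # 10% of 500
  expect_true(all(!is.na(truth$contaminant[truth$is_mixture])))
  expect_true(all(truth$lambda[truth$is_mixture] == 0.5))
  expect_true(all(truth$contaminant[truth$is_mixture] !=
                    truth$annotated_tissue[truth$is_mixture]))
  # mixtures and mislabels are disjoint by construction
  expect_false(any(truth$is_mixture & truth$is_mislabel))
})

test_that("identical seeds give bit-identical corpora; seeds only move values", {
  cfg <- sim_config(
    n_tissues = 3, genes_total = 150, signature_genes_per_tissue = 8,
    samples_per_tissue = 6, rng_seed = 11
  )
  c1 <- simulate_corpus(cfg)
  c2 <- simulate_corpus(cfg)
  expect_identical(c1$expression, c2$expression)
  expect_identical(c1$truth$samples, c2$truth$samples)
  cfg2 <- sim_config(
    n_tissues = 3, genes_total = 150, signature_genes_per_tissue = 8,
    samples_per_tissue = 6, rng_seed = 12
  )
  c3 <- simulate_corpus(cfg2)
  expect_equal(dim(c3$expression), dim(c1$expression))
  expect_false(identical(c3$expression, c1$expression))
})

test_that("planted fold change is recovered empirically", {
  cfg <- null_sim_config(
    n_tissues = 3, genes_total = 400, signature_genes_per_tissue = 20,
    samples_per_tissue = 50, noise_sd = 0.3, rng_seed = 13
  )
  corpus <- simulate_corpus(cfg)
  truth <- corpus$truth
  t_a <- cfg$tissues[1]
  t_b <- cfg$tissues[2]
  sig_a <- truth$genes$gene[!is.na(truth$genes$owner_tissue) &
                              truth$genes$owner_tissue == t_a]
  in_a <- truth$samples$sample_id[truth$samples$true_tissue == t_a]
  in_b <- truth$samples$sample_id[truth$samples$true_tissue == t_b]
  ratio <- mean(corpus$expression[sig_a, in_a]) /
    mean(corpus$expression[sig_a, in_b])
  expect_lt(abs(ratio - cfg$fold_change) / cfg$fold_change, 0.2)
})

test_that("generated corpora pass corpus filtering unchanged", {
  corpus <- simulate_corpus(sim_config(
    n_tissues = 4, genes_total = 200, signature_genes_per_tissue = 10,
    samples_per_tissue = 8, rng_seed = 14
  ))
  fc <- filter_corpus(
    corpus$expression, corpus$annotations,
    identity_vocabulary(corpus$config$tissues)
  )
  expect_equal(ncol(fc$expression), ncol(corpus$expression))
  expect_equal(sum(fc$report$n_dropped), 0L)
})

test_that("impossible configurations are rejected", {
  expect_error(
    sim_config(n_tissues = 10, genes_total = 100,
               signature_genes_per_tissue = 20),
    "exceeds genes_total"
  )
  expect_error(sim_config(contamination_fraction = 0.8,
                          mislabel_fraction = 0.3))
  expect_error(sim_config(mixing_proportion = 1))
})

test_that("truth_confusion scores calls against ground truth", {
  truth <- tibble::tibble(
    sample_id = paste0("s", 1:10),
    true_tissue = c(rep("liver", 8), "blood", "liver"),
    annotated_tissue = "liver",
    contaminant = c("blood", rep(NA, 9)),
    lambda = c(0.3, rep(NA, 9)),
    is_mixture = c(TRUE, rep(FALSE, 9)),
    is_mislabel = c(rep(FALSE, 8), TRUE, FALSE)
  )
  calls <- tibble::tibble(
    sample_id = paste0("s", 1:10), tissue = "liver",
    status = c("moderate", rep("none", 7), "severe", "none")
  )
  tc <- truth_confusion(calls, truth)
  expect_equal(tc$sensitivity, 1)
  expect_equal(tc$specificity, 1)
  expect_equal(tc$severe_given_mislabel, 1)
  expect_equal(tc$moderate_given_mixture, 1)
  all_none <- dplyr::mutate(calls, status = "none")
  tc0 <- truth_confusion(all_none, truth)
  expect_equal(tc0$sensitivity, 0)
  expect_equal(tc0$specificity, 1)
  expect_error(
    truth_confusion(calls[-1, ], truth),
    "different sample ids"
  )
})
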