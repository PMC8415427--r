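test_that("FDR screen, severity rule and self-signatures behave as specified", {
  samples <- sprintf("s%02d", 1:10)
  # two samples with a strong foreign-signature hit, eight null samples;
  # reference p-values vary but do not track the query p-values
  p_query <- setNames(rep(0.9, 10), samples)
  p_query[c("s01", "s02")] <- 1e-6
  p_ref <- setNames(10^-(c(3, 8, 5, 9, 4, 7, 6, 10, 5.5, 8.5)), samples)
  p_ref["s01"] <- 0.01 # own tissue still detected -> moderate
  p_ref["s02"] <- 0.20 # own tissue lost -> severe
  fx <- manual_enrichment(p_ref, p_query)
  det <- detect(fx$enrichment, fx$annotations)
  calls <- det$calls
  expect_equal(calls$status[calls$sample_id == "s01"], "moderate")
  expect_equal(calls$status[calls$sample_id == "s02"], "severe")
  expect_true(all(calls$status[!calls$sample_id %in% c("s01", "s02")] == "none"))
  expect_false(any(det$exclusions$excluded))
  tr <- calls$triggering[calls$sample_id == "s01"][[1]]
  expect_equal(tr$tissue, "blood")
  expect_lt(tr$q, 0.01)
  # q-values above tau leave a sample unflagged even with small raw p
  p_query2 <- setNames(rep(0.012, 10), samples) # q = 0.012 * 10/10 > tau...
  fx2 <- manual_enrichment(p_ref, p_query2)
  det2 <- detect(fx2$enrichment, fx2$annotations)
  expect_true(all(det2$calls$status == "none"))
})

test_that("a query signature of the annotated tissue never triggers", {
  samples <- sprintf("s%02d", 1:6)
  p_ref <- setNames(10^-(3:8), samples)
  et <- dplyr::bind_rows(
    tibble::tibble(
      sample = samples, signature = "liver.ref", tissue = "liver",
      role = "reference", p_value = unname(p_ref)
    ),
    tibble::tibble(
      sample = samples, signature = "liver.extra", tissue = "liver",
      role = "query", p_value = 1e-9 # own-tissue query, hugely enriched
    )
  )
  ann <- tibble::tibble(sample_id = samples, tissue = "liver")
  det <- detect(et, ann)
  expect_true(all(det$calls$status == "none"))
  expect_equal(nrow(det$exclusions), 0L)
})

test_that("correlated signature pairs are excluded before flagging", {
  samples <- sprintf("s%02d", 1:12)
  x <- seq(2, 30, length.out = 12)
  p_ref <- setNames(10^-x, samples)
  p_query <- setNames(10^-(0.5 * x + 1), samples) # tracks the reference
  fx <- manual_enrichment(p_ref, p_query)
  expect_warning(
    det <- detect(fx$enrichment, fx$annotations),
    "0 evaluable"
  )
  excl <- det$exclusions
  expect_true(all(excl$excluded))
  expect_equal(excl$slope, 0.5, tolerance = 1e-6)
  # flagged nowhere despite minuscule q-values
  expect_true(all(det$calls$status == "none"))
})

test_that("detection is invariant to row order of its inputs", {
  set.seed(91)
  corpus <- simulate_corpus(sim_config(
    n_tissues = 4, genes_total = 400, signature_genes_per_tissue = 20,
    samples_per_tissue = 15, rng_seed = 91
  ))
  ann <- dplyr::mutate(corpus$annotations, tissue = tissue_raw)
  refs <- generate_signatures(corpus$expression, ann, gini_min = 0.6, rank_max = 1)
  refs$name <- paste0(refs$name, ".ref")
  qs <- generate_signatures(corpus$expression, ann,
    gini_min = 0.6, rank_max = 1, role = "query"
  )
  coll <- dplyr::bind_rows(qs, refs)
  class(coll) <- class(qs)
  et <- run_enrichment(corpus$expression, coll)
  det1 <- detect(et, ann)
  perm_et <- et[sample(nrow(et)), ]
  perm_ann <- ann[sample(nrow(ann)), ]
  det2 <- detect(perm_et, perm_ann)
  expect_equal(det1$calls, det2$calls)
  expect_equal(det1$exclusions, det2$exclusions)
  # structural invariant: severe counts never exceed flagged counts
  counts <- tissue_fractions(det1)
  expect_true(all(counts$n_severe <= counts$n_moderate_or_severe))
  expect_true(all(counts$n_moderate_or_severe <= counts$n_samples))
})

test_that("missing reference coverage is an error", {
  fx <- manual_enrichment(
    setNames(rep(0.5, 4), paste0("s", 1:4)),
    setNames(rep(0.5, 4), paste0("s", 1:4))
  )
  ann_bad <- dplyr::mutate(fx$annotations, tissue = "pancreas")
  expect_error(detect(fx$enrichment, ann_bad), "pancreas")
})
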