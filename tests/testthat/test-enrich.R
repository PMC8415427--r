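make_small_run <- function(seed = 51, n_genes = 60, n_samples = 3) {
  set.seed(seed)
  expr <- matrix(
    stats::rlnorm(n_genes * n_samples),
    nrow = n_genes,
    dimnames = list(sprintf("G%03d", 1:n_genes), paste0("s", 1:n_samples))
  )
  sigs <- signature_collection(
    name = c("sigA", "sigB"),
    genes = list(sprintf("G%03d", 1:8), sprintf("G%03d", 20:30)),
    tissue = c("liver", "blood")
  )
  list(expr = expr, sigs = sigs)
}

test_that("table dimensions follow the (samples x signatures) contract", {
  r <- make_small_run()
  et <- run_enrichment(r$expr, r$sigs)
  expect_equal(nrow(et), 6L) # 3 samples x 2 signatures
  expect_named(et, c("sample", "signature", "tissue", "role", "p_value"))
  expect_true(all(et$p_value > 0 & et$p_value <= 1))
  expect_equal(
    unname(attr(et, "n_genes_used")), c(8L, 11L)
  )
  expect_equal(enrichment_pair_count(3, 2), 6)
})

test_that("gene-row permutation leaves the table unchanged", {
  r <- make_small_run()
  et1 <- run_enrichment(r$expr, r$sigs)
  perm <- sample(nrow(r$expr))
  et2 <- run_enrichment(r$expr[perm, ], r$sigs)
  expect_equal(et1, et2, ignore_attr = TRUE)
})

test_that("each sample's row depends only on that sample's values", {
  r <- make_small_run()
  et1 <- run_enrichment(r$expr, r$sigs)
  expr2 <- r$expr
  expr2[, "s2"] <- rev(expr2[, "s2"])
  et2 <- run_enrichment(expr2, r$sigs)
  changed <- et1$p_value != et2$p_value
  expect_true(all(et1$sample[changed] == "s2"))
  expect_equal(et1$p_value[et1$sample != "s2"], et2$p_value[et2$sample != "s2"])
})

test_that("signatures with too little gene overlap are dropped with warning", {
  r <- make_small_run()
  sparse <- signature_collection(
    name = c("thin", "fat"),
    genes = list(c("G001", "NOPE1", "NOPE2"), sprintf("G%03d", 1:10))
  )
  expect_warning(et <- run_enrichment(r$expr, sparse), "thin")
  expect_equal(unique(et$signature), "fat")
  none <- signature_collection("gone", list(c("X1", "X2", "X3")))
  suppressWarnings(expect_error(run_enrichment(r$expr, none), "no signature"))
})

test_that("exact and approximate engine modes agree on moderate universes", {
  set.seed(52)
  expr <- matrix(
    stats::rlnorm(20 * 4),
    nrow = 20,
    dimnames = list(sprintf("G%03d", 1:20), paste0("s", 1:4))
  )
  sigs <- signature_collection("s1", list(sprintf("G%03d", 1:5)))
  pe <- run_enrichment(expr, sigs, mode = "exact")$p_value
  pauto <- run_enrichment(expr, sigs, mode = "auto")$p_value
  pa <- run_enrichment(expr, sigs, mode = "approx")$p_value
  expect_equal(pe, pauto) # 20 genes <= exact cutoff
  expect_lt(max(abs(log10(pa) - log10(pe))), 0.2)
})

test_that("missing values are handled pairwise-complete per sample", {
  r <- make_small_run()
  expr_na <- r$expr
  expr_na[5, "s1"] <- NA # a sigA gene missing in s1 only
  expect_message(et <- run_enrichment(expr_na, r$sigs), "pairwise")
  et0 <- run_enrichment(r$expr, r$sigs)
  # dropping a gene re-ranks only the affected sample
  same <- et$sample != "s1"
  expect_equal(et$p_value[same], et0$p_value[same])
  p_changed <- et$p_value[et$sample == "s1"]
  expect_true(all(is.finite(p_changed) & p_changed > 0 & p_changed <= 1))
})
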