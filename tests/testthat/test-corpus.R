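test_that("tissue-term mapping normalizes and never fuzzy-matches", {
  v <- tissue_vocabulary(
    tibble::tibble(
      raw_term = c("liver", "whole blood", "Skin."),
      canonical_tissue = c("liver", "blood", "skin")
    ),
    reference_tissues = c("liver", "blood")
  )
  expect_equal(map_tissue_term("Liver ", v), "liver")
  expect_equal(map_tissue_term("  WHOLE   blood.", v), "blood")
  expect_equal(map_tissue_term("skin", v), "skin") # trailing dot normalized away
  expect_true(is.na(map_tissue_term("hepatocellular carcinoma xenograft", v)))
  # idempotent on self-mapped canonical terms
  expect_equal(
    map_tissue_term(map_tissue_term("liver", v), v),
    map_tissue_term("liver", v)
  )
})

make_toy_corpus <- function() {
  set.seed(61)
  n <- 10
  expr <- matrix(
    stats::rlnorm(40 * n, 3, 1),
    nrow = 40,
    dimnames = list(sprintf("G%03d", 1:40), sprintf("s%02d", 1:n))
  )
  ann <- tibble::tibble(
    sample_id = colnames(expr),
    study_id = rep(c("st1", "st2"), each = 5),
    tissue_raw = c(
      "liver", "Liver", "mystery goo", "???", "brain",
      "liver", "liver", "liver", "liver", "liver"
    ),
    platform = "microarray", year = 2015
  )
  vocab <- tissue_vocabulary(
    tibble::tibble(
      raw_term = c("liver", "brain"),
      canonical_tissue = c("liver", "brain")
    ),
    reference_tissues = "liver"
  )
  list(expr = expr, ann = ann, vocab = vocab)
}

test_that("filtering drops unmapped and non-reference samples with counts", {
  tc <- make_toy_corpus()
  fc <- filter_corpus(tc$expr, tc$ann, tc$vocab)
  expect_equal(ncol(fc$expression), 7L)
  rep <- tibble::deframe(fc$report)
  expect_equal(rep[["unmapped"]], 2L)
  expect_equal(rep[["non_reference"]], 1L)
  expect_equal(sum(fc$report$n_dropped),
               attr(fc$report, "n_in") - attr(fc$report, "n_out"))
  expect_equal(fc$annotations$sample_id, colnames(fc$expression))
  expect_true(all(fc$annotations$tissue == "liver"))
})

test_that("a mean-centred study is dropped as per-gene normalized", {
  tc <- make_toy_corpus()
  centred <- tc$expr
  st2 <- tc$ann$sample_id[tc$ann$study_id == "st2"]
  centred[, st2] <- centred[, st2] - rowMeans(centred[, st2])
  fc <- filter_corpus(centred, tc$ann, tc$vocab)
  expect_equal(tibble::deframe(fc$report)[["normalized_study"]], 5L)
  expect_false(any(fc$annotations$study_id == "st2"))
})

test_that("filtering is idempotent and the identity on clean corpora", {
  corpus <- simulate_corpus(null_sim_config(
    n_tissues = 3, genes_total = 200, signature_genes_per_tissue = 5,
    samples_per_tissue = 6, rng_seed = 62
  ))
  vocab <- identity_vocabulary(corpus$config$tissues)
  fc1 <- filter_corpus(corpus$expression, corpus$annotations, vocab)
  expect_equal(ncol(fc1$expression), ncol(corpus$expression))
  fc2 <- filter_corpus(fc1$expression, fc1$annotations, vocab)
  expect_equal(fc2$expression, fc1$expression)
  expect_equal(fc2$annotations$sample_id, fc1$annotations$sample_id)
})

test_that("an empty post-filter corpus raises a reportable error", {
  tc <- make_toy_corpus()
  vocab_none <- tissue_vocabulary(
    tibble::tibble(raw_term = "spleen", canonical_tissue = "spleen"),
    reference_tissues = "spleen"
  )
  err <- tryCatch(
    filter_corpus(tc$expr, tc$ann, vocab_none),
    error = function(e) e
  )
  expect_s3_class(err, "tissuehet_empty_corpus")
  expect_s3_class(err$report, "filter_report")
  expect_equal(sum(err$report$n_dropped), 10L)
})

test_that("vocabulary files round-trip through TSV", {
  f <- withr::local_tempfile(fileext = ".tsv")
  rf <- withr::local_tempfile()
  readr::write_tsv(
    tibble::tibble(
      raw_term = c("liver", "whole blood"),
      canonical_tissue = c("liver", "blood")
    ),
    f
  )
  writeLines("blood", rf)
  v <- read_vocabulary(f, rf)
  expect_equal(attr(v, "reference_tissues"), "blood")
  expect_equal(map_tissue_term("Whole Blood", v), "blood")
})
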