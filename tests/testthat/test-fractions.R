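make_calls <- function(status_by_tissue) {
  dplyr::bind_rows(lapply(names(status_by_tissue), function(t) {
    st <- status_by_tissue[[t]]
    tibble::tibble(
      sample_id = paste0(t, "_", seq_along(st)), tissue = t, status = st,
      n_triggering = as.integer(st != "none"),
      q_min = ifelse(st != "none", 1e-4, NA_real_),
      p_ref = 1e-10, triggering = vector("list", length(st))
    )
  }))
}

test_that("fractions and degenerate bootstrap intervals are exact", {
  calls <- make_calls(list(
    clean = rep("none", 50),
    dirty = rep(c("moderate", "none"), c(10, 90))
  ))
  summ <- tissue_fractions(calls, detection_config(rng_seed = 5))
  clean <- summ[summ$tissue == "clean", ]
  expect_equal(clean$fraction, 0)
  expect_equal(c(clean$ci_low, clean$ci_high), c(0, 0))
  dirty <- summ[summ$tissue == "dirty", ]
  expect_equal(dirty$fraction, 0.10)
  expect_true(dirty$ci_low <= 0.10 && 0.10 <= dirty$ci_high)
  expect_true(dirty$ci_high - dirty$ci_low < 0.2)
})

test_that("bootstrap intervals are reproducible for a given seed", {
  calls <- make_calls(list(a = rep(c("severe", "none"), c(7, 43))))
  s1 <- tissue_fractions(calls, detection_config(rng_seed = 99))
  s2 <- tissue_fractions(calls, detection_config(rng_seed = 99))
  expect_identical(s1, s2)
  # seeding is local: the caller's RNG stream is not disturbed
  set.seed(1); before <- rnorm(1)
  set.seed(1); invisible(tissue_fractions(calls)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("confusion counts aggregate triggering tissues per sample", {
  samples <- sprintf("s%02d", 1:8)
  p_ref <- setNames(10^-(c(6, 9, 3, 12, 5, 8, 10, 7)), samples)
  p_query <- setNames(rep(0.95, 8), samples)
  p_query["s03"] <- 1e-8 # one liver sample triggered by the blood signature
  fx <- manual_enrichment(p_ref, p_query, tissue = "liver",
                          query_tissue = "blood")
  det <- detect(fx$enrichment, fx$annotations)
  cc <- confusion_counts(det)
  expect_equal(cc$n[cc$tissue == "liver" & cc$signature_tissue == "blood"], 1L)
  expect_false(any(cc$excluded))
  # a run with no flags keeps the all-zero matrix (and the exclusion marks)
  p_query[] <- 0.95
  fx0 <- manual_enrichment(p_ref, p_query)
  cc0 <- confusion_counts(detect(fx0$enrichment, fx0$annotations))
  expect_true(all(cc0$n == 0L))
  expect_equal(nrow(cc0), 1L)
})

test_that("confusion row totals can exceed flagged sample counts", {
  # one sample triggering two foreign tissues counts once per tissue
  samples <- sprintf("s%02d", 1:6)
  p_ref <- setNames(10^-(c(4, 9, 6, 11, 5, 8)), samples)
  base <- manual_enrichment(p_ref, setNames(rep(0.9, 6), samples),
                            query_tissue = "blood")
  extra <- tibble::tibble(
    sample = samples, signature = "skin.q", tissue = "skin", role = "query",
    p_value = c(1e-9, rep(0.8, 5))
  )
  et <- dplyr::bind_rows(base$enrichment, extra)
  et$p_value[et$signature == "blood.q" & et$sample == "s01"] <- 1e-9
  det <- detect(et, base$annotations)
  cc <- confusion_counts(det)
  n_flagged <- sum(det$calls$status != "none")
  expect_equal(n_flagged, 1L)
  expect_equal(sum(cc$n), 2L) # blood and skin both counted for s01
})
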