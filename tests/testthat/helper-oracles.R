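# Independent oracles and fixture builders shared across tests. Oracles use
# deliberately different formulations (brute force, enumeration) than the
# package code paths they check.

# exact WMW upper-tail p by enumerating all C(N, k) signature placements and
# scoring pairwise wins (+ half-ties) -- independent of the rank-sum DP
oracle_wmw_p <- function(x, mask) {
  n_total <- length(x)
  k <- sum(mask)
  u_stat <- function(sig_idx) {
    s <- x[sig_idx]
    b <- x[-sig_idx]
    sum(outer(s, b, ">")) + 0.5 * sum(outer(s, b, "=="))
  }
  u_obs <- u_stat(which(mask))
  combs <- utils::combn(n_total, k)
  mean(apply(combs, 2, u_stat) >= u_obs - 1e-9)
}

# Gini as half the mean pairwise absolute difference over the mean (double loop)
oracle_gini <- function(x) {
  n <- length(x)
  acc <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      acc <- acc + abs(x[i] - x[j])
    }
  }
  0.5 * (acc / n^2) / mean(x)
}

# literal BH step-up on sorted p, mapped back to input order
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- pmin(1, m * p[o] / seq_len(m))
  for (i in rev(seq_len(m - 1))) {
    q_sorted[i] <- min(q_sorted[i], q_sorted[i + 1])
  }
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# planted expression matrix: `k` genes per tissue strongly elevated in that
# tissue and near-zero elsewhere, over a flat background; noise-free
make_planted_matrix <- function(tissues, k = 10, n_background = 30,
                                samples_per_tissue = 3, on = 50, off = 0,
                                background = 5) {
  n_t <- length(tissues)
  genes <- c(
    sprintf("SPEC%03d", seq_len(n_t * k)),
    sprintf("BG%03d", seq_len(n_background))
  )
  samples <- paste0(rep(tissues, each = samples_per_tissue), "_",
                    seq_len(samples_per_tissue))
  m <- matrix(background, nrow = length(genes), ncol = length(samples),
              dimnames = list(genes, samples))
  for (i in seq_len(n_t)) {
    block <- seq.int((i - 1) * k + 1, i * k)
    m[block, ] <- off
    m[block, grepl(paste0("^", tissues[i], "_"), samples)] <- on
  }
  ann <- tibble::tibble(
    sample_id = samples,
    tissue = rep(tissues, each = samples_per_tissue)
  )
  list(expr = m, annotations = ann)
}

# random signature collection for round-trip tests
random_collection <- function(n_sig, gene_pool = sprintf("GENE%03d", 1:200)) {
  signature_collection(
    name = paste0("set", seq_len(n_sig)),
    genes = lapply(seq_len(n_sig), function(i) {
      sample(gene_pool, sample(3:20, 1))
    }),
    description = paste("random signature", seq_len(n_sig))
  )
}

# enrichment table + annotations built directly from numbers, for detect()
# unit tests where every p-value is chosen by hand
manual_enrichment <- function(p_ref_by_sample, p_query_by_sample,
                              tissue = "liver", query_tissue = "blood") {
  samples <- names(p_ref_by_sample)
  et <- dplyr::bind_rows(
    tibble::tibble(
      sample = samples, signature = paste0(tissue, ".ref"),
      tissue = tissue, role = "reference", p_value = unname(p_ref_by_sample)
    ),
    tibble::tibble(
      sample = samples, signature = paste0(query_tissue, ".q"),
      tissue = query_tissue, role = "query",
      p_value = unname(p_query_by_sample)
    )
  )
  ann <- tibble::tibble(sample_id = samples, tissue = tissue)
  list(enrichment = et, annotations = ann)
}

# clean (contamination- and mislabel-free) variant of a sim_config
null_sim_config <- function(...) {
  sim_config(contamination_fraction = 0, mislabel_fraction = 0, ...)
}
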