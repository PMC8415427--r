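#' Run per-sample signature enrichment over an expression matrix
#'
#' Computes, independently for every (sample, signature) pair, the one-sided
#' Wilcoxon-Mann-Whitney p-value for enrichment of the signature genes among
#' the sample's expression ranks (see [wmw_pvalue()]). Only the ranking of
#' genes within each sample matters, so any strictly increasing per-sample
#' transform of the values leaves the result unchanged.
#'
#' Signatures with fewer than `min_genes` genes present in the matrix are
#' dropped with a warning. Genes with missing values are dropped from the
#' affected sample's ranking only (pairwise-complete).
#'
#' @param expr Numeric gene x sample matrix (gene symbols as rownames).
#' @param collection A [signature_collection()].
#' @param min_genes Minimum overlap between a signature and the matrix genes
#'   for the signature to be retained (default 5).
#' @param mode p-value mode passed to the engine: `"approx"` (default, the
#'   corpus-scale path), `"exact"`, or `"auto"` (exact for gene universes of
#'   at most `exact_limit` genes).
#' @param exact_limit See [wmw_pvalue()].
#'
#' @return A tibble of class `enrichment_tbl` with one row per (sample,
#'   signature) pair and columns `sample`, `signature`, `tissue`, `role`,
#'   `p_value`. The per-signature count of genes found in the matrix is
#'   attached as attribute `"n_genes_used"`.
#' @export
run_enrichment <- function(expr, collection,
                           min_genes = 5L,
                           mode = c("approx", "exact", "auto"),
                           exact_limit = 25L) {
  mode <- match.arg(mode)
  expr <- as_expression_matrix(expr)
  stopifnot(inherits(collection, "signature_collection"))
  n_genes <- nrow(expr)
  if (n_genes < 2L) {
    abort("expression matrix must contain at least 2 genes")
  }
  genes <- rownames(expr)
  idx <- lapply(collection$genes, function(g) which(genes %in% g))
  n_used <- lengths(idx)
  drop <- n_used < min_genes | n_used == n_genes
  if (any(drop)) {
    warn(paste0(
      sum(drop), " signature(s) dropped (< ", min_genes,
      " genes present, or no background left): ",
      paste(collection$name[drop], collapse = ", ")
    ))
  }
  collection <- collection[!drop, , drop = FALSE]
  idx <- idx[!drop]
  n_used <- n_used[!drop]
  if (nrow(collection) == 0L) {
    abort("no signature retained: too little gene overlap with the matrix")
  }

  n_samples <- ncol(expr)
  has_na <- anyNA(expr)
  if (any(is.infinite(expr))) {
    abort("non-finite (infinite) expression value in matrix")
  }
  if (has_na) {
    inform("missing expression values present: using pairwise-complete ranks")
  }
  use_exact_all <- mode == "exact" || (mode == "auto" && n_genes <= exact_limit)

  pmat <- matrix(NA_real_, nrow = n_samples, ncol = nrow(collection))
  if (!has_na && !use_exact_all) {
    # fast path: rank every sample once, p-values from signature rank sums
    ranks <- matrix(0, n_genes, n_samples)
    tie_sum <- numeric(n_samples)
    for (j in seq_len(n_samples)) {
      st <- .rank_stats(expr[, j])
      ranks[, j] <- st$r
      tie_sum[j] <- st$tie_sum
    }
    for (k in seq_along(idx)) {
      rs <- colSums(ranks[idx[[k]], , drop = FALSE])
      pmat[, k] <- .wmw_p_approx(rs, n_used[k], n_genes, tie_sum)
    }
  } else {
    for (j in seq_len(n_samples)) {
      x <- expr[, j]
      ok <- !is.na(x)
      st <- .rank_stats(x[ok])
      pos <- which(ok)
      for (k in seq_along(idx)) {
        in_sig <- pos %in% idx[[k]]
        n1 <- sum(in_sig)
        if (n1 == 0L || n1 == length(pos)) {
          pmat[j, k] <- NA_real_
          next
        }
        rs <- sum(st$r[in_sig])
        pmat[j, k] <- if (use_exact_all) {
          .wmw_p_exact(st$r, n1, rs)
        } else {
          .wmw_p_approx(rs, n1, length(pos), st$tie_sum)
        }
      }
    }
  }

  out <- tibble(
    sample = rep(colnames(expr), times = nrow(collection)),
    signature = rep(collection$name, each = n_samples),
    tissue = rep(collection$tissue, each = n_samples),
    role = rep(collection$role, each = n_samples),
    p_value = as.vector(pmat)
  )
  attr(out, "n_genes_used") <- setNames(as.integer(n_used), collection$name)
  class(out) <- c("enrichment_tbl", class(out))
  out
}

#' Number of (sample, signature, p-value) pairs an enrichment run produces
#'
#' The enrichment table contract: one p-value per sample per retained
#' signature, so a corpus of `n_samples` samples scanned with `n_signatures`
#' signatures yields exactly `n_samples * n_signatures` pairs.
#'
#' @param n_samples,n_signatures Non-negative integers.
#' @return The pair count as a double (may exceed integer range).
#' @examples
#' enrichment_pair_count(76576, 129) # 9878304
#' @export
enrichment_pair_count <- function(n_samples, n_signatures) {
  stopifnot(n_samples >= 0, n_signatures >= 0)
  as.numeric(n_samples) * as.numeric(n_signatures)
}

#' Write / read an enrichment table as long-format TSV
#'
#' @param x An `enrichment_tbl`.
#' @param path TSV path (columns sample, signature, tissue, role, p_value).
#' @return `path` invisibly; `read_enrichment()` returns the tibble.
#' @export
write_enrichment <- function(x, path) {
  readr::write_tsv(as_tibble(x), path, progress = FALSE)
  invisible(path)
}

#' @rdname write_enrichment
#' @export
read_enrichment <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  class(out) <- c("enrichment_tbl", class(out))
  out
}
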