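# Per-sample Wilcoxon-Mann-Whitney enrichment core.
#
# The test asks, within a single sample, whether the genes of a signature
# rank higher in expression than the remaining (background) genes. Midranks
# are used for ties; the default large-N path is the normal approximation
# with tie-corrected variance and a continuity correction, and an exact mode
# enumerates the permutation distribution of the rank sum via a subset-sum
# dynamic program over doubled midranks (exact also under ties).

# midranks plus the tie term sum(t^3 - t) used in the variance correction
.rank_stats <- function(x) {
  r <- rank(x, ties.method = "average")
  t <- rle(sort(x))$lengths
  list(r = r, tie_sum = sum(t^3 - t))
}

# upper-tail p for observed rank sum(s) of the signature genes
.wmw_p_approx <- function(rank_sum, n1, n_total, tie_sum) {
  n2 <- n_total - n1
  mu <- n1 * (n_total + 1) / 2
  v <- n1 * n2 / 12 * ((n_total + 1) - tie_sum / (n_total * (n_total - 1)))
  p <- ifelse(v <= 0, 1,
    pnorm((rank_sum - mu - 0.5) / sqrt(pmax(v, 0)), lower.tail = FALSE)
  )
  pmin(pmax(p, 1e-300), 1)
}

# exact P(rank sum >= observed) over all C(N, k) placements of the signature
# among the midranks; works on doubled ranks so all sums are integers
.wmw_p_exact <- function(r, k, rank_sum_obs) {
  w <- as.integer(round(2 * r))
  n_total <- length(w)
  s_max <- sum(w)
  counts <- matrix(0, nrow = k + 1L, ncol = s_max + 1L)
  counts[1L, 1L] <- 1
  for (i in seq_len(n_total)) {
    wi <- w[i]
    for (j in rev(seq_len(min(i, k)))) {
      idx <- seq_len(s_max + 1L - wi)
      counts[j + 1L, idx + wi] <- counts[j + 1L, idx + wi] + counts[j, idx]
    }
  }
  w_obs <- as.integer(round(2 * rank_sum_obs))
  hits <- sum(counts[k + 1L, seq.int(w_obs + 1L, s_max + 1L)])
  p <- hits / choose(n_total, k)
  min(max(p, 1e-300), 1)
}

#' One-sided Wilcoxon-Mann-Whitney enrichment p-value within one sample
#'
#' Tests the alternative that the signature genes have higher expression
#' ranks than the background genes of the same sample. Ties are handled with
#' midranks; the approximate mode uses the normal approximation with
#' tie-corrected variance and continuity correction, the exact mode
#' enumerates the permutation distribution of the rank sum (feasible for
#' small gene universes). With `mode = "auto"` the exact path is taken when
#' the total number of genes is at most `exact_limit`.
#'
#' @param sample_values Numeric vector of expression values over all measured
#'   genes of one sample; must be finite.
#' @param signature Logical mask over `sample_values` (or integer indices, or
#'   character names matching `names(sample_values)`) marking signature genes.
#' @param mode `"auto"`, `"approx"` or `"exact"`.
#' @param exact_limit Largest gene universe for which `"auto"` enumerates
#'   exactly (default 25).
#'
#' @return A single p-value in (0, 1]; exactly 1 when the tie-corrected
#'   variance is zero (all values identical).
#' @examples
#' x <- c(10, 9, 8, 1:7)
#' wmw_pvalue(x, c(TRUE, TRUE, TRUE, rep(FALSE, 7))) # top 3 of 10 ranks
#' @export
wmw_pvalue <- function(sample_values, signature,
                       mode = c("auto", "approx", "exact"), exact_limit = 25L) {
  mode <- match.arg(mode)
  if (!is.numeric(sample_values) || length(sample_values) < 2L) {
    abort("`sample_values` must be numeric with at least 2 genes")
  }
  if (any(!is.finite(sample_values))) {
    abort("non-finite expression value in `sample_values`")
  }
  n_total <- length(sample_values)
  if (is.character(signature)) {
    if (is.null(names(sample_values))) {
      abort("character `signature` needs named `sample_values`")
    }
    signature <- names(sample_values) %in% signature
  } else if (is.numeric(signature)) {
    signature <- seq_len(n_total) %in% signature
  }
  if (!is.logical(signature) || length(signature) != n_total) {
    abort("`signature` must be a logical mask over `sample_values`")
  }
  n1 <- sum(signature)
  if (n1 == 0L || n1 == n_total) {
    abort("both the signature and the background partition must be non-empty")
  }
  st <- .rank_stats(sample_values)
  rs <- sum(st$r[signature])
  use_exact <- mode == "exact" || (mode == "auto" && n_total <= exact_limit)
  if (use_exact) {
    .wmw_p_exact(st$r, n1, rs)
  } else {
    .wmw_p_approx(rs, n1, n_total, st$tie_sum)
  }
}
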