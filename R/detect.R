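# Five-step heterogeneity detection:
#   (i)   BH-adjust the query-signature p-values; samples where no query
#         signature reaches q < tau are not heterogeneous;
#   (ii)  per (tissue, query signature) pair, fit a robust line of
#         |log10 p_query| against |log10 p_ref| over all samples of the tissue;
#   (iii) exclude pairs with slope >= slope_threshold (correlated signatures);
#   (iv)  flagged samples are severe when the annotated tissue's own reference
#         signature is not detected (unadjusted p_ref > severe_alpha), else
#         moderate;
#   (v)   per-tissue heterogeneous fractions with bootstrap percentile CIs.

#' Detection configuration
#'
#' @param fdr_threshold FDR threshold tau on BH-adjusted query p-values
#'   (default 0.01).
#' @param slope_threshold Robust-line slope at or above which a (tissue,
#'   query signature) pair is excluded as correlated (default 0.01).
#' @param severe_alpha A flagged sample is severe when its unadjusted
#'   reference p-value exceeds this (default 0.05).
#' @param bootstrap_n Bootstrap resamples for the per-tissue CI
#'   (default 1000).
#' @param ci_level Confidence level of the percentile interval (default 0.95).
#' @param rng_seed Seed for the bootstrap generator (default 1).
#' @param bh_scope `"global"` adjusts across all (sample, query signature)
#'   pairs of the run; `"per_tissue"` adjusts within each annotated tissue.
#' @return A list of class `detection_config`.
#' @export
detection_config <- function(fdr_threshold = 0.01, slope_threshold = 0.01,
                             severe_alpha = 0.05, bootstrap_n = 1000L,
                             ci_level = 0.95, rng_seed = 1L,
                             bh_scope = c("global", "per_tissue")) {
  stopifnot(
    fdr_threshold > 0, fdr_threshold < 1,
    slope_threshold >= 0,
    severe_alpha > 0, severe_alpha < 1,
    bootstrap_n >= 1,
    ci_level > 0, ci_level < 1
  )
  structure(
    list(
      fdr_threshold = fdr_threshold, slope_threshold = slope_threshold,
      severe_alpha = severe_alpha, bootstrap_n = as.integer(bootstrap_n),
      ci_level = ci_level, rng_seed = as.integer(rng_seed),
      bh_scope = match.arg(bh_scope)
    ),
    class = "detection_config"
  )
}

#' Benjamini-Hochberg adjusted p-values (q-values)
#'
#' Step-up FDR control: on ascending p, q(i) = min over j >= i of
#' min(1, m p(j) / j), returned in the original order.
#'
#' @param pvalues Numeric vector with all values in (0, 1].
#' @return q-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0L) abort("empty p-value vector")
  if (anyNA(pvalues) || any(pvalues <= 0 | pvalues > 1)) {
    abort("p-values must lie in (0, 1]")
  }
  p.adjust(pvalues, method = "BH")
}

#' Robust line fit by Huber M-estimation
#'
#' Iteratively reweighted least squares with the Huber psi (tuning constant
#' 1.345), scale re-estimated each iteration as the median absolute deviation
#' of the residuals rescaled for consistency at the normal, convergence when
#' the largest coefficient change falls below `tol` (or after `max_iter`
#' iterations). Used to decide whether a query signature's p-values merely
#' track the reference signature across a tissue's samples.
#'
#' @param x,y Numeric vectors, typically `|log10 p_ref|` and
#'   `|log10 p_query|` per sample; at least 3 finite points.
#' @param k Huber tuning constant (default 1.345).
#' @param tol Convergence tolerance on coefficients (default 1e-8).
#' @param max_iter Iteration cap (default 50).
#' @return List with `slope`, `intercept`, `n`, `iterations`, `converged`.
#'   Degenerate design (`x` constant) returns slope 0 and the median of `y`
#'   as intercept.
#' @export
fit_robust_line <- function(x, y, k = 1.345, tol = 1e-8, max_iter = 50L) {
  if (length(x) != length(y)) abort("`x` and `y` lengths differ")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 3L) abort("insufficient samples for exclusion fit (need >= 3)")
  if (sd(x) == 0) {
    return(list(
      slope = 0, intercept = median(y), n = n,
      iterations = 0L, converged = TRUE
    ))
  }
  X <- cbind(1, x)
  beta <- qr.solve(X, y) # least-squares start
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    r <- y - X %*% beta
    s <- mad(r, center = 0) # 1.4826 * median(|r|), consistent at the normal
    if (s <= .Machine$double.eps * max(abs(y), 1)) {
      converged <- TRUE # (near-)exact fit
      break
    }
    w <- pmin(1, k * s / abs(as.vector(r)))
    w[!is.finite(w)] <- 1
    fit <- stats::lm.wfit(X, y, w)
    delta <- max(abs(fit$coefficients - beta))
    beta <- fit$coefficients
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  list(
    slope = unname(beta[2]), intercept = unname(beta[1]), n = n,
    iterations = it, converged = converged
  )
}

.floored_log10 <- function(p) abs(log10(pmax(p, 1e-300)))

#' Detect tissue heterogeneity from an enrichment table
#'
#' Implements the five-step detection procedure (see the package vignette)
#' on a per-sample signature enrichment table: global BH adjustment of the
#' query p-values, robust-line exclusion of query signatures correlated with
#' the annotated tissue's reference signature, flagging at `q <
#' fdr_threshold`, and moderate/severe classification by whether the
#' reference signature itself is still detected. Query signatures mapped to
#' the sample's own annotated tissue never count as heterogeneity evidence.
#'
#' @param enrichment An `enrichment_tbl` (or tibble with columns `sample`,
#'   `signature`, `tissue`, `p_value`) containing both reference and query
#'   signatures.
#' @param annotations Data frame with `sample_id` and canonical `tissue` for
#'   every sample in the table.
#' @param ref_map Named character vector mapping tissue -> reference
#'   signature name. Default: derived from rows with `role == "reference"`.
#' @param config A [detection_config()].
#'
#' @return An object of class `het_detection`: list with `calls` (tibble:
#'   `sample_id`, `tissue`, `status` none/moderate/severe, `n_triggering`,
#'   `triggering` list-column of (signature, tissue, q), `q_min`, `p_ref`),
#'   `exclusions` (tibble: `tissue`, `query_signature`, `query_tissue`,
#'   `slope`, `n_samples_fit`, `excluded`), plus the config and ref_map.
#'   Has [tidy()] and [glance()] methods.
#' @export
detect <- function(enrichment, annotations, ref_map = NULL,
                   config = detection_config()) {
  et <- as_tibble(enrichment)
  need <- c("sample", "signature", "tissue", "p_value")
  if (!all(need %in% names(et))) {
    abort(paste0(
      "enrichment table lacks column(s): ",
      paste(setdiff(need, names(et)), collapse = ", ")
    ))
  }
  stopifnot(inherits(config, "detection_config"))
  ann <- check_annotations(annotations, unique(et$sample))
  ann <- select(ann, "sample_id", "tissue")

  if (is.null(ref_map)) {
    if (!"role" %in% names(et)) {
      abort("no `ref_map` given and enrichment table has no `role` column")
    }
    refs <- distinct(filter(et, .data$role == "reference"),
      .data$tissue, .data$signature
    )
    if (anyDuplicated(refs$tissue)) {
      abort("multiple reference signatures for one tissue; pass `ref_map`")
    }
    ref_map <- setNames(refs$signature, refs$tissue)
  }
  missing_ref <- setdiff(unique(ann$tissue), names(ref_map))
  if (length(missing_ref) > 0L) {
    abort(paste0(
      "no reference signature for tissue(s): ",
      paste(missing_ref, collapse = ", ")
    ))
  }
  if (!all(ref_map %in% et$signature)) {
    abort("reference signature absent from the enrichment table")
  }

  # reference p-value of each sample = its own tissue's reference signature
  p_ref_tbl <- et |>
    inner_join(ann, by = c(sample = "sample_id"), suffix = c("", "_annot")) |>
    filter(.data$signature == ref_map[.data$tissue_annot]) |>
    select(sample_id = "sample", annot_tissue = "tissue_annot",
           p_ref = "p_value")
  if (nrow(p_ref_tbl) != nrow(ann)) {
    abort("missing reference-signature p-value for some sample")
  }

  # query family: every (sample, non-reference signature) pair in the run
  query <- et |>
    filter(!.data$signature %in% ref_map) |>
    left_join(p_ref_tbl, by = c(sample = "sample_id"))
  if (nrow(query) == 0L) {
    abort("no query signatures in the enrichment table")
  }
  query <- if (config$bh_scope == "global") {
    mutate(query, q = bh_adjust(.data$p_value))
  } else {
    query |>
      group_by(.data$annot_tissue) |>
      mutate(q = bh_adjust(.data$p_value)) |>
      ungroup()
  }

  # steps (ii)-(iii): robust fit per (annotated tissue, query signature) over
  # all samples of that tissue (flagged or not)
  exclusions <- query |>
    filter(.data$tissue != .data$annot_tissue) |>
    group_by(
      query_tissue = .data$tissue, # bind before annot_tissue masks `tissue`
      tissue = .data$annot_tissue, query_signature = .data$signature
    ) |>
    summarise(
      n_samples_fit = n(),
      slope = if (n() >= 3L) {
        fit_robust_line(
          .floored_log10(.data$p_ref), .floored_log10(.data$p_value)
        )$slope
      } else {
        NA_real_
      },
      .groups = "drop"
    ) |>
    mutate(excluded = !is.na(.data$slope) &
             .data$slope >= config$slope_threshold) |>
    select("tissue", "query_signature", "query_tissue", "n_samples_fit",
           "slope", "excluded") |>
    arrange(.data$tissue, .data$query_signature)

  all_excluded <- exclusions |>
    group_by(.data$tissue) |>
    summarise(all_out = all(.data$excluded), .groups = "drop") |>
    filter(.data$all_out)
  if (nrow(all_excluded) > 0L) {
    warn(paste0(
      "all query signatures excluded for tissue(s): ",
      paste(all_excluded$tissue, collapse = ", "),
      " (0 evaluable signatures)"
    ))
  }

  flags <- query |>
    filter(.data$tissue != .data$annot_tissue) |>
    left_join(
      select(exclusions, "tissue", "query_signature", "excluded"),
      by = c(annot_tissue = "tissue", signature = "query_signature")
    ) |>
    filter(!.data$excluded, .data$q < config$fdr_threshold)

  triggering <- flags |>
    group_by(sample_id = .data$sample) |>
    summarise(
      n_triggering = n(),
      q_min = min(.data$q, Inf), # Inf guard: dplyr probes an empty prototype
      triggering = list(dplyr::pick(dplyr::all_of(c("signature", "tissue", "q")))),
      .groups = "drop"
    )

  calls <- p_ref_tbl |>
    rename(tissue = "annot_tissue") |>
    left_join(triggering, by = "sample_id") |>
    mutate(
      n_triggering = ifelse(is.na(.data$n_triggering), 0L, .data$n_triggering),
      status = dplyr::case_when(
        .data$n_triggering == 0L ~ "none",
        .data$p_ref > config$severe_alpha ~ "severe",
        TRUE ~ "moderate"
      )
    ) |>
    select("sample_id", "tissue", "status", "n_triggering", "q_min",
           "p_ref", "triggering") |>
    arrange(.data$sample_id)

  structure(
    list(calls = calls, exclusions = exclusions, config = config,
         ref_map = ref_map),
    class = "het_detection"
  )
}

#' @export
print.het_detection <- function(x, ...) {
  st <- table(factor(x$calls$status, levels = c("none", "moderate", "severe")))
  cat("Heterogeneity detection over", nrow(x$calls), "samples\n")
  cat(sprintf(
    "  none: %d  moderate: %d  severe: %d\n", st["none"], st["moderate"],
    st["severe"]
  ))
  cat("  excluded signature pairs:", sum(x$exclusions$excluded), "of",
      nrow(x$exclusions), "\n")
  invisible(x)
}

#' @rdname detect
#' @param x,object A `het_detection` object.
#' @param ... Unused.
#' @export
tidy.het_detection <- function(x, ...) {
  x$calls
}

#' @rdname detect
#' @export
glance.het_detection <- function(x, ...) {
  tibble(
    n_samples = nrow(x$calls),
    n_flagged = sum(x$calls$status != "none"),
    n_moderate = sum(x$calls$status == "moderate"),
    n_severe = sum(x$calls$status == "severe"),
    flagged_fraction = mean(x$calls$status != "none"),
    n_excluded_pairs = sum(x$exclusions$excluded),
    fdr_threshold = x$config$fdr_threshold
  )
}

# run fn with a temporarily seeded RNG, restoring the caller's RNG state
.with_seed <- function(seed, fn) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  fn()
}

#' Per-tissue heterogeneous fractions with bootstrap confidence intervals
#'
#' The heterogeneous fraction of a tissue is the number of samples with at
#' least one triggering query signature (status moderate or severe) divided
#' by the tissue's sample count. The CI is a percentile bootstrap over the
#' tissue's per-sample binary flags (`bootstrap_n` resamples with
#' replacement), deterministic given `config$rng_seed`.
#'
#' @param detection A `het_detection` object (or its `calls` tibble).
#' @param config A [detection_config()]; defaults to the one stored in
#'   `detection`.
#' @return A tibble of class `tissue_summary`: `tissue`, `n_samples`,
#'   `n_moderate_or_severe`, `n_severe`, `fraction`, `ci_low`, `ci_high`.
#' @export
tissue_fractions <- function(detection, config = NULL) {
  calls <- if (inherits(detection, "het_detection")) {
    config <- config %||% detection$config
    detection$calls
  } else {
    as_tibble(detection)
  }
  config <- config %||% detection_config()
  alpha <- (1 - config$ci_level) / 2
  out <- .with_seed(config$rng_seed, function() {
    calls |>
      group_by(.data$tissue) |>
      summarise(
        n_samples = n(),
        n_moderate_or_severe = sum(.data$status != "none"),
        n_severe = sum(.data$status == "severe"),
        fraction = mean(.data$status != "none"),
        ci = {
          f <- as.integer(.data$status != "none")
          bm <- matrix(
            sample(f, length(f) * config$bootstrap_n, replace = TRUE),
            nrow = length(f)
          )
          list(quantile(colMeans(bm), c(alpha, 1 - alpha), names = FALSE))
        },
        .groups = "drop"
      ) |>
      mutate(
        ci_low = map_dbl(.data$ci, 1L),
        ci_high = map_dbl(.data$ci, 2L)
      ) |>
      select(-"ci")
  })
  class(out) <- c("tissue_summary", class(out))
  out
}

#' Tissue confusion counts
#'
#' Entry (t, u) counts the samples annotated as tissue t in which at least
#' one query signature of tissue u triggered; pairs removed by the
#' correlation exclusion are marked `excluded` so they can be distinguished
#' from true zero counts.
#'
#' @param detection A `het_detection` object.
#' @return A tibble of class `het_confusion`: `tissue` (annotated),
#'   `signature_tissue` (detected), `n`, `excluded`.
#' @export
confusion_counts <- function(detection) {
  stopifnot(inherits(detection, "het_detection"))
  calls <- detection$calls
  excl <- detection$exclusions |>
    group_by(.data$tissue, signature_tissue = .data$query_tissue) |>
    summarise(excluded = any(.data$excluded), .groups = "drop")
  flagged <- filter(calls, .data$n_triggering > 0L)
  hits <- if (nrow(flagged) == 0L) {
    tibble(tissue = character(), signature_tissue = character(), n = integer())
  } else {
    flagged |>
      select("sample_id", "tissue", "triggering") |>
      unnest("triggering", names_sep = "_") |>
      distinct(.data$sample_id, .data$tissue,
        signature_tissue = .data$triggering_tissue
      ) |>
      count(.data$tissue, .data$signature_tissue)
  }
  out <- excl |>
    left_join(hits, by = c("tissue", "signature_tissue")) |>
    mutate(n = ifelse(is.na(.data$n), 0L, .data$n)) |>
    select("tissue", "signature_tissue", "n", "excluded") |>
    arrange(.data$tissue, .data$signature_tissue)
  class(out) <- c("het_confusion", class(out))
  out
}

#' @rdname tissue_fractions
#' @param object A `tissue_summary`.
#' @param ... Unused.
#' @export
autoplot.tissue_summary <- function(object, ...) {
  ggplot(object, aes(
    x = stats::reorder(.data$tissue, .data$fraction),
    y = .data$fraction
  )) +
    geom_col(fill = "grey35") +
    geom_errorbar(aes(ymin = .data$ci_low, ymax = .data$ci_high), width = 0.3) +
    coord_flip() +
    scale_y_continuous(labels = function(x) paste0(100 * x, "%")) +
    labs(
      x = NULL, y = "fraction of heterogeneous samples",
      title = "Tissue heterogeneity per tissue",
      subtitle = "error bars: bootstrap percentile CI"
    ) +
    theme_minimal()
}

#' @rdname confusion_counts
#' @param object A `het_confusion`.
#' @param ... Unused.
#' @export
autoplot.het_confusion <- function(object, ...) {
  ggplot(object, aes(
    x = .data$signature_tissue, y = .data$tissue, fill = .data$n
  )) +
    geom_tile(colour = "white") +
    geom_tile(
      data = filter(object, .data$excluded),
      fill = NA, colour = "black", linetype = "dashed", linewidth = 0.6
    ) +
    geom_text(aes(label = ifelse(.data$n > 0, .data$n, "")),
      colour = "white", size = 3
    ) +
    scale_fill_viridis_c() +
    labs(
      x = "detected signature tissue", y = "annotated tissue", fill = "samples",
      title = "Tissue confusion matrix",
      subtitle = "dashed tiles: query signature(s) excluded as correlated"
    ) +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 45, hjust = 1))
}
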