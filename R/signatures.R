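#' Build a signature collection
#'
#' A signature collection is a tibble with one row per gene signature and
#' columns `name`, `tissue`, `role`, `description` and a `genes` list-column
#' of uppercase gene symbols. Signatures tag a canonical tissue and play one
#' of two roles in heterogeneity detection: `"reference"` signatures define
#' what the annotated tissue should express, `"query"` signatures scan for
#' foreign-tissue signal.
#'
#' @param name Character vector of unique signature names.
#' @param genes List of character vectors of gene symbols. Symbols are
#'   uppercased and deduplicated (first occurrence kept).
#' @param tissue Canonical tissue term per signature; defaults to `name`.
#' @param role `"query"` or `"reference"`, recycled.
#' @param description Free-text provenance per signature, recycled.
#'
#' @return A tibble of class `signature_collection`.
#' @examples
#' signature_collection(
#'   name  = c("liver", "blood"),
#'   genes = list(c("ALB", "APOA2", "FGA"), c("HBB", "HBA1", "ALAS2"))
#' )
#' @export
signature_collection <- function(name, genes, tissue = name, role = "query",
                                 description = "") {
  if (length(name) == 0L) {
    abort("a signature collection needs at least one signature")
  }
  if (anyDuplicated(name)) {
    dup <- unique(name[duplicated(name)])
    abort(paste0("duplicate signature name(s): ", paste(dup, collapse = ", ")))
  }
  if (!is.list(genes) || length(genes) != length(name)) {
    abort("`genes` must be a list with one character vector per signature")
  }
  genes <- lapply(genes, function(g) {
    g <- toupper(as.character(g))
    g <- g[!duplicated(g)]
    g
  })
  if (any(lengths(genes) == 0L)) {
    abort("every signature must contain at least one gene")
  }
  role <- rep_len(role, length(name))
  if (!all(role %in% c("query", "reference"))) {
    abort("`role` must be \"query\" or \"reference\"")
  }
  out <- tibble(
    name = as.character(name),
    tissue = rep_len(as.character(tissue), length(name)),
    role = role,
    description = rep_len(as.character(description), length(name)),
    genes = genes
  )
  class(out) <- c("signature_collection", class(out))
  out
}

#' Read gene signatures from a GMT file
#'
#' One signature per line: name, description, then member genes, all
#' tab-separated. Gene symbols are uppercased and deduplicated keeping the
#' first occurrence.
#'
#' @param path Path to a GMT file.
#' @param tissue Canonical tissue per signature; defaults to the signature
#'   name (useful when names already are tissue terms).
#' @param role Signature role, `"query"` (default) or `"reference"`.
#'
#' @return A [signature_collection()].
#' @export
read_gmt <- function(path, tissue = NULL, role = "query") {
  if (!file.exists(path)) {
    abort(paste0("GMT file not found: ", path))
  }
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    abort(paste0("GMT file is empty: ", path))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad) > 0L) {
    abort(paste0(
      "malformed GMT line ", bad[1], " in ", path,
      ": expected at least 3 tab-separated fields, got ", lengths(fields)[bad[1]]
    ))
  }
  name <- map_chr(fields, 1L)
  desc <- map_chr(fields, 2L)
  genes <- map(fields, function(f) f[-(1:2)])
  signature_collection(
    name = name, genes = genes,
    tissue = tissue %||% name,
    role = role, description = desc
  )
}

#' Write a signature collection to a GMT file
#'
#' @param collection A [signature_collection()].
#' @param path Output path.
#' @return `path`, invisibly usable in pipes.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "signature_collection"))
  if (nrow(collection) == 0L) {
    abort("cannot write an empty signature collection")
  }
  lines <- pmap(
    list(collection$name, collection$description, collection$genes),
    function(n, d, g) paste(c(n, d, g), collapse = "\t")
  )
  readr::write_lines(unlist(lines), path)
  invisible(path)
}

#' Gini index of a non-negative expression profile
#'
#' Measures how unequally a gene's expression is distributed across tissues:
#' 0 for a perfectly even profile, approaching (n-1)/n when all expression is
#' concentrated in a single tissue. For the ascending-sorted profile x of
#' length n, G = sum_i (2i - n - 1) x_i / (n sum_i x_i).
#'
#' @param x Numeric vector, length >= 2, all values >= 0, not all zero.
#' @return Gini index in \[0, 1\].
#' @examples
#' gini_index(c(1, 1, 1, 1)) # 0
#' gini_index(c(0, 0, 0, 5)) # 0.75
#' @export
gini_index <- function(x) {
  if (!is.numeric(x) || length(x) < 2L) {
    abort("`x` must be a numeric vector of length >= 2")
  }
  if (anyNA(x) || any(!is.finite(x))) {
    abort("`x` must be finite and non-missing")
  }
  if (any(x < 0)) {
    abort("Gini index requires non-negative values")
  }
  s <- sum(x)
  if (s == 0) {
    abort("undefined Gini: all values are zero")
  }
  n <- length(x)
  xs <- sort(x)
  sum((2 * seq_len(n) - n - 1) * xs) / (n * s)
}

#' Generate tissue-specific gene signatures from a labelled expression matrix
#'
#' For each gene, the tissue profile is the median expression across the
#' samples of each tissue. A gene enters the signature of tissue `t` when the
#' Gini index of its profile is at least `gini_min` and `t` ranks among the
#' `rank_max` highest-expressing tissues for that gene (ties at the boundary
#' included). Each signature is truncated to the `max_genes` genes with the
#' highest profile value in its tissue. Both criteria depend only on ranks and
#' relative profiles, so the result is invariant to rescaling the matrix.
#'
#' @param expr Numeric gene x sample matrix with gene symbols as rownames and
#'   sample ids as colnames.
#' @param annotations Data frame with columns `sample_id` and `tissue`
#'   covering every column of `expr`.
#' @param gini_min Minimum Gini index of the per-tissue profile (default 0.8).
#' @param rank_max A tissue must be within the top `rank_max` tissues of a
#'   gene's profile (default 3).
#' @param max_genes Cap on genes per signature (default 200).
#' @param role Role given to the generated signatures (default `"reference"`).
#'
#' @return A [signature_collection()]; tissues whose signature would be empty
#'   yield no row.
#' @export
generate_signatures <- function(expr, annotations, gini_min = 0.8,
                                rank_max = 3L, max_genes = 200L,
                                role = "reference") {
  expr <- as_expression_matrix(expr)
  ann <- check_annotations(annotations, colnames(expr))
  tissues <- sort(unique(ann$tissue))
  if (length(tissues) < 2L) {
    abort("signature generation needs at least 2 tissues")
  }
  # per-gene tissue profile: median across the samples of each tissue
  profile <- vapply(tissues, function(t) {
    cols <- ann$sample_id[ann$tissue == t]
    apply(expr[, cols, drop = FALSE], 1L, median)
  }, numeric(nrow(expr)))
  keep <- rowSums(profile) > 0 # all-zero genes cannot be tissue-enriched
  profile <- profile[keep, , drop = FALSE]
  if (nrow(profile) == 0L) {
    abort("no gene has a non-zero tissue profile")
  }
  gini <- apply(profile, 1L, gini_index)
  eligible <- gini >= gini_min
  sigs <- lapply(tissues, function(t) {
    p <- profile[, t]
    # rank 1 = highest-expressing tissue; ties take the best (inclusive) rank
    rk <- apply(-profile, 1L, rank, ties.method = "min")[t, ]
    g <- rownames(profile)[eligible & rk <= rank_max]
    g[order(p[g], decreasing = TRUE)][seq_len(min(length(g), max_genes))]
  })
  names(sigs) <- tissues
  sigs <- sigs[lengths(sigs) > 0L]
  if (length(sigs) == 0L) {
    abort("no tissue yielded a non-empty signature; lower `gini_min`?")
  }
  signature_collection(
    name = names(sigs), genes = unname(sigs), tissue = names(sigs),
    role = role,
    description = sprintf(
      "generated: gini_min=%g rank_max=%d max_genes=%d aggregation=median",
      gini_min, rank_max, max_genes
    )
  )
}

#' Cross-validate tissue signatures on an independent labelled dataset
#'
#' Runs the per-sample enrichment engine for every signature on every
#' validation sample. The top hit of a sample is the signature with the
#' smallest p-value; per-tissue sensitivity is the fraction of samples whose
#' top-hit tissue matches the annotation.
#'
#' @param collection A [signature_collection()].
#' @param expr Validation gene x sample matrix (gene symbols as rownames).
#' @param annotations Data frame with `sample_id` and `tissue`.
#' @param min_genes Minimum signature genes that must be present in the
#'   matrix (default 1; validation should not silently drop signatures).
#'
#' @return An object of class `sig_validation` with components `scores`
#'   (signature x tissue median enrichment scores, long tibble), `confusion`
#'   (annotated tissue x top-hit tissue counts), `sensitivity` (per-tissue),
#'   and `n_samples`. Has [tidy()], [glance()] and [autoplot()] methods.
#' @export
crossvalidate_signatures <- function(collection, expr, annotations,
                                     min_genes = 1L) {
  stopifnot(inherits(collection, "signature_collection"))
  expr <- as_expression_matrix(expr)
  ann <- check_annotations(annotations, colnames(expr))
  if (!any(collection$tissue %in% ann$tissue)) {
    abort("no signature tissue occurs among the annotation labels")
  }
  et <- run_enrichment(expr, collection, min_genes = min_genes)
  scored <- et |>
    mutate(score = abs(log10(pmax(.data$p_value, 1e-300)))) |>
    left_join(select(ann, "sample_id", annot_tissue = "tissue"),
      by = c(sample = "sample_id")
    )
  scores <- scored |>
    group_by(.data$signature, .data$tissue, .data$annot_tissue) |>
    summarise(median_score = median(.data$score), .groups = "drop")
  top <- scored |>
    group_by(.data$sample, .data$annot_tissue) |>
    slice_min(.data$p_value, n = 1L, with_ties = FALSE) |>
    ungroup()
  confusion <- top |>
    count(annot_tissue = .data$annot_tissue, top_tissue = .data$tissue) |>
    complete(
      annot_tissue = sort(unique(ann$tissue)),
      top_tissue = sort(unique(collection$tissue)),
      fill = list(n = 0L)
    )
  sensitivity <- top |>
    mutate(hit = .data$tissue == .data$annot_tissue) |>
    group_by(tissue = .data$annot_tissue) |>
    summarise(n = n(), sensitivity = mean(.data$hit), .groups = "drop") |>
    filter(.data$tissue %in% collection$tissue)
  structure(
    list(
      scores = scores, confusion = confusion, sensitivity = sensitivity,
      n_samples = nrow(ann)
    ),
    class = "sig_validation"
  )
}

#' @export
print.sig_validation <- function(x, ...) {
  cat("Signature cross-validation on", x$n_samples, "samples\n")
  cat(
    "mean per-tissue sensitivity:",
    format(mean(x$sensitivity$sensitivity), digits = 3), "\n"
  )
  print(x$sensitivity)
  invisible(x)
}

#' @rdname crossvalidate_signatures
#' @param x A `sig_validation` object.
#' @param ... Unused.
#' @export
tidy.sig_validation <- function(x, ...) {
  x$scores
}

#' @rdname crossvalidate_signatures
#' @export
glance.sig_validation <- function(x, ...) {
  tibble(
    n_samples = x$n_samples,
    n_tissues = nrow(x$sensitivity),
    mean_sensitivity = mean(x$sensitivity$sensitivity),
    min_sensitivity = min(x$sensitivity$sensitivity)
  )
}

#' @rdname crossvalidate_signatures
#' @param object A `sig_validation` object.
#' @export
autoplot.sig_validation <- function(object, ...) {
  ggplot(
    object$confusion,
    aes(x = .data$top_tissue, y = .data$annot_tissue, fill = .data$n)
  ) +
    geom_tile() +
    geom_text(aes(label = .data$n), colour = "white", size = 3) +
    scale_fill_viridis_c() +
    labs(
      x = "top-hit signature tissue", y = "annotated tissue",
      fill = "samples", title = "Signature cross-validation"
    ) +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 45, hjust = 1))
}
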