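# Sample-annotation harmonization and corpus-level filtering.

.normalize_term <- function(x) {
  x <- tolower(as.character(x))
  x <- gsub("\\s+", " ", trimws(x))
  sub("[[:punct:][:space:]]+$", "", x)
}

#' Controlled vocabulary for tissue terms
#'
#' Maps normalized free-text tissue descriptions to canonical tissue terms
#' and records which canonical tissues carry a validated reference signature.
#'
#' @param mapping Data frame with columns `raw_term` and `canonical_tissue`.
#' @param reference_tissues Character vector, subset of the canonical
#'   tissues, for which reference signatures exist.
#' @return A tibble of class `tissue_vocabulary` (normalized `raw_term`,
#'   `canonical_tissue`) with attribute `reference_tissues`.
#' @export
tissue_vocabulary <- function(mapping, reference_tissues = character()) {
  m <- as_tibble(mapping)
  if (!all(c("raw_term", "canonical_tissue") %in% names(m))) {
    abort("`mapping` needs columns raw_term and canonical_tissue")
  }
  m <- m |>
    mutate(raw_term = .normalize_term(.data$raw_term)) |>
    distinct(.data$raw_term, .keep_all = TRUE) |>
    select("raw_term", "canonical_tissue")
  extra <- setdiff(reference_tissues, m$canonical_tissue)
  if (length(extra) > 0L) {
    abort(paste0(
      "reference tissue(s) absent from the vocabulary: ",
      paste(extra, collapse = ", ")
    ))
  }
  attr(m, "reference_tissues") <- unique(reference_tissues)
  class(m) <- c("tissue_vocabulary", class(m))
  m
}

#' @rdname tissue_vocabulary
#' @param tissues Canonical tissue names.
#' @export
identity_vocabulary <- function(tissues, reference_tissues = tissues) {
  tissue_vocabulary(
    tibble(raw_term = tissues, canonical_tissue = tissues),
    reference_tissues = reference_tissues
  )
}

#' Read a controlled vocabulary from TSV
#'
#' @param path TSV with columns `raw_term`, `canonical_tissue`.
#' @param reference_path Optional file listing one reference tissue per line.
#' @return A [tissue_vocabulary()].
#' @export
read_vocabulary <- function(path, reference_path = NULL) {
  if (!file.exists(path)) abort(paste0("vocabulary file not found: ", path))
  m <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  ref <- character()
  if (!is.null(reference_path)) {
    if (!file.exists(reference_path)) {
      abort(paste0("reference-tissue list not found: ", reference_path))
    }
    ref <- readr::read_lines(reference_path)
    ref <- ref[nzchar(ref)]
  }
  tissue_vocabulary(m, reference_tissues = ref)
}

#' Map free-text tissue terms to canonical tissues
#'
#' Terms are lowercased, surrounding whitespace stripped, internal whitespace
#' collapsed and trailing punctuation dropped, then matched exactly against
#' the vocabulary; there is no fuzzy matching. Unmapped terms return `NA`.
#'
#' @param raw Character vector of free-text tissue descriptions.
#' @param vocab A [tissue_vocabulary()].
#' @return Character vector of canonical tissues, `NA` where unmapped.
#' @examples
#' v <- identity_vocabulary(c("liver", "blood"))
#' map_tissue_term(c("Liver ", "whole  blood."), v)
#' @export
map_tissue_term <- function(raw, vocab) {
  stopifnot(inherits(vocab, "tissue_vocabulary"))
  vocab$canonical_tissue[match(.normalize_term(raw), vocab$raw_term)]
}

# per-gene normalization heuristic: rank-based testing needs raw-scale,
# within-sample-comparable values; centred/scaled matrices are rejected
.looks_normalized <- function(m, max_negative_fraction, small_rowmean_fraction) {
  if (mean(m < 0) > max_negative_fraction) {
    return(TRUE)
  }
  idr <- diff(quantile(m, c(0.1, 0.9), names = FALSE))
  if (idr <= 0) {
    return(FALSE)
  }
  mean(abs(rowMeans(m)) < 0.01 * idr) > small_rowmean_fraction
}

#' Filter an expression corpus to analysable, reference-tissue samples
#'
#' Applies, in order: (1) drop samples whose free-text tissue cannot be
#' mapped to the controlled vocabulary; (2) drop samples whose canonical
#' tissue has no reference signature; (3) drop whole studies whose matrix
#' looks per-gene normalized (mean-centred values break within-sample
#' ranking); (4) drop studies left with fewer than `min_samples_per_study`
#' samples. Rule-by-rule sample counts are returned in the filter report.
#'
#' @param expr Gene x sample matrix.
#' @param annotations Data frame with `sample_id`, `study_id`, `tissue_raw`
#'   (free text) and optionally `platform`, `year`.
#' @param vocab A [tissue_vocabulary()].
#' @param min_samples_per_study Study-size floor after the other rules
#'   (default 1, i.e. no floor).
#' @param max_negative_fraction,small_rowmean_fraction Thresholds of the
#'   normalization heuristic: a study is flagged when more than
#'   `max_negative_fraction` of its entries are negative, or more than
#'   `small_rowmean_fraction` of its gene rows have an absolute row mean
#'   below 1% of the study's interdecile value range.
#'
#' @return A list of class `filtered_corpus`: `expression` (surviving
#'   columns), `annotations` (with a canonical `tissue` column added), and
#'   `report`, a tibble of class `filter_report` (rule, n_dropped) with
#'   attributes `n_in` / `n_out`.
#' @export
filter_corpus <- function(expr, annotations, vocab,
                          min_samples_per_study = 1L,
                          max_negative_fraction = 0.25,
                          small_rowmean_fraction = 0.5) {
  expr <- as_expression_matrix(expr)
  ann <- check_annotations(annotations, colnames(expr),
    required = c("sample_id", "study_id", "tissue_raw")
  )
  stopifnot(inherits(vocab, "tissue_vocabulary"))
  n_in <- nrow(ann)
  ann$tissue <- map_tissue_term(ann$tissue_raw, vocab)

  drops <- c(unmapped = 0L, non_reference = 0L, normalized_study = 0L,
             small_study = 0L)

  keep <- !is.na(ann$tissue)
  drops["unmapped"] <- sum(!keep)
  ann <- ann[keep, , drop = FALSE]

  ref <- attr(vocab, "reference_tissues")
  keep <- ann$tissue %in% ref
  drops["non_reference"] <- sum(!keep)
  ann <- ann[keep, , drop = FALSE]

  if (nrow(ann) > 0L) {
    flagged <- ann |>
      group_by(.data$study_id) |>
      summarise(
        flagged = .looks_normalized(
          expr[, .data$sample_id, drop = FALSE],
          max_negative_fraction, small_rowmean_fraction
        ),
        .groups = "drop"
      )
    bad_studies <- flagged$study_id[flagged$flagged]
    keep <- !(ann$study_id %in% bad_studies)
    drops["normalized_study"] <- sum(!keep)
    ann <- ann[keep, , drop = FALSE]
  }

  if (nrow(ann) > 0L && min_samples_per_study > 1L) {
    sizes <- ann |> count(.data$study_id)
    small <- sizes$study_id[sizes$n < min_samples_per_study]
    keep <- !(ann$study_id %in% small)
    drops["small_study"] <- sum(!keep)
    ann <- ann[keep, , drop = FALSE]
  }

  report <- tibble(rule = names(drops), n_dropped = unname(drops))
  attr(report, "n_in") <- n_in
  attr(report, "n_out") <- nrow(ann)
  class(report) <- c("filter_report", class(report))

  if (nrow(ann) == 0L) {
    abort(
      "corpus empty after filtering",
      class = "tissuehet_empty_corpus",
      report = report
    )
  }
  structure(
    list(
      expression = expr[, ann$sample_id, drop = FALSE],
      annotations = ann,
      report = report
    ),
    class = "filtered_corpus"
  )
}

#' @export
print.filtered_corpus <- function(x, ...) {
  cat(
    "Filtered corpus:", attr(x$report, "n_out"), "of",
    attr(x$report, "n_in"), "samples retained\n"
  )
  print(as_tibble(x$report))
  invisible(x)
}
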