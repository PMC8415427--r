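# End-to-end orchestration: filter -> enrich -> detect -> summarise -> report.

#' Pipeline run configuration
#'
#' Inputs may be given as file paths (expression TSV/MatrixMarket,
#' annotations TSV, vocabulary TSV, signatures GMT) or as in-memory objects;
#' alternatively a [sim_config()] generates the corpus. When no GMT files are
#' supplied in simulation mode, reference and query signatures are generated
#' from two independent clean training corpora derived from the simulation
#' seed.
#'
#' @param output_dir Directory for the output bundle (created if missing).
#' @param expression,annotations,vocabulary Paths or objects; required unless
#'   `sim` is given.
#' @param signatures,reference_signatures GMT paths or
#'   [signature_collection()]s for query / reference signatures.
#' @param detection A [detection_config()].
#' @param sim Optional [sim_config()]; when set, corpus (and by default
#'   signatures and vocabulary) are synthesized.
#' @param min_samples_per_study Passed to [filter_corpus()].
#' @param min_genes Passed to [run_enrichment()].
#' @param generation_gini_min,generation_rank_max Parameters for signatures
#'   generated from synthetic training corpora. With disjoint planted
#'   expression programs the owning tissue is the unique top tissue, so rank
#'   1 suffices, and the attainable Gini of a single-tissue elevation grows
#'   with the tissue count (e.g. 0.81 for a 100-fold change over 9 tissues
#'   but only 0.65 over 3); 0.5 separates planted genes from background at
#'   any supported tissue count.
#' @param verbose Emit per-stage log lines (default TRUE).
#' @return A list of class `run_config`.
#' @export
run_config <- function(output_dir, expression = NULL, annotations = NULL,
                       vocabulary = NULL, signatures = NULL,
                       reference_signatures = NULL,
                       detection = detection_config(), sim = NULL,
                       min_samples_per_study = 1L, min_genes = 5L,
                       generation_gini_min = 0.5, generation_rank_max = 1L,
                       verbose = TRUE) {
  stopifnot(inherits(detection, "detection_config"))
  if (is.null(sim)) {
    for (nm in c("expression", "annotations", "vocabulary")) {
      v <- get(nm)
      if (is.null(v)) {
        abort(paste0("`", nm, "` is required when no simulation is configured"))
      }
      if (is.character(v) && !file.exists(v)) {
        abort(paste0(nm, " file not found: ", v))
      }
    }
  } else {
    stopifnot(inherits(sim, "sim_config"))
  }
  for (nm in c("signatures", "reference_signatures")) {
    v <- get(nm)
    if (is.character(v) && !file.exists(v)) {
      abort(paste0(nm, " GMT file not found: ", v))
    }
  }
  structure(
    list(
      output_dir = output_dir, expression = expression,
      annotations = annotations, vocabulary = vocabulary,
      signatures = signatures, reference_signatures = reference_signatures,
      detection = detection, sim = sim,
      min_samples_per_study = as.integer(min_samples_per_study),
      min_genes = as.integer(min_genes),
      generation_gini_min = generation_gini_min,
      generation_rank_max = as.integer(generation_rank_max),
      verbose = isTRUE(verbose)
    ),
    class = "run_config"
  )
}

.stage_log <- function(verbose, stage, ...) {
  if (verbose) {
    inform(paste0("[", stage, "] ", paste(..., collapse = " ")))
  }
}

.load_or <- function(x, loader) {
  if (is.character(x)) loader(x) else x
}

# flatten the triggering list-column for TSV serialization
.calls_flat <- function(calls) {
  calls |>
    mutate(triggering = map_chr(.data$triggering, function(tr) {
      if (is.null(tr) || nrow(tr) == 0L) {
        return("")
      }
      paste0(tr$signature, "(", tr$tissue, "):", signif(tr$q, 4),
        collapse = ";"
      )
    })) |>
    select(
      "sample_id", "tissue", "status", "n_triggering", "q_min", "p_ref",
      "triggering"
    )
}

#' Run the full heterogeneity analysis pipeline
#'
#' Executes corpus filtering, per-sample signature enrichment, five-step
#' heterogeneity detection, per-tissue prevalence estimation and confusion
#' counting, and writes the output bundle (`calls.tsv`, `exclusions.tsv`,
#' `summaries.tsv`, `confusion.tsv`, `enrichment.tsv`, `filter_report.json`,
#' `run_metadata.json`, `report.md`, `MANIFEST`) to
#' `config$output_dir`. If a stage fails, the partial bundle is kept and the
#' `MANIFEST` records which stages completed before the error is re-raised.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the in-memory results (`corpus`,
#'   `collection`, `enrichment`, `detection`, `summary`, `confusion`,
#'   `truth_performance` when simulated) and `output_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  done <- character()
  files <- character()
  manifest <- function() {
    readr::write_lines(
      c(
        paste0("completed_stages:\t", paste(done, collapse = ",")),
        paste0("files:\t", paste(files, collapse = ","))
      ),
      file.path(config$output_dir, "MANIFEST")
    )
  }
  on.exit(manifest())
  emit <- function(name, writer) {
    path <- file.path(config$output_dir, name)
    writer(path)
    files <<- c(files, name)
    path
  }
  v <- config$verbose
  res <- list(output_dir = config$output_dir)

  # ---- stage: inputs -------------------------------------------------------
  t0 <- Sys.time()
  if (!is.null(config$sim)) {
    corpus_in <- simulate_corpus(config$sim)
    expr <- corpus_in$expression
    ann <- corpus_in$annotations
    vocab <- config$vocabulary %||%
      identity_vocabulary(config$sim$tissues)
    vocab <- .load_or(vocab, read_vocabulary)
    res$synthetic <- corpus_in
    emit("truth.tsv", function(p) {
      readr::write_tsv(corpus_in$truth$samples, p, progress = FALSE)
    })
    emit("sim_config.json", function(p) {
      jsonlite::write_json(
        corpus_in$config[setdiff(names(corpus_in$config), "tissues")],
        p,
        auto_unbox = TRUE
      )
    })
  } else {
    expr <- .load_or(config$expression, read_expression)
    ann <- .load_or(config$annotations, function(p) {
      readr::read_tsv(p, show_col_types = FALSE, progress = FALSE)
    })
    vocab <- .load_or(config$vocabulary, read_vocabulary)
  }
  done <- c(done, "inputs")
  .stage_log(v, "inputs", ncol(expr), "samples,", nrow(expr), "genes")

  # ---- stage: filter -------------------------------------------------------
  filtered <- filter_corpus(expr, ann, vocab,
    min_samples_per_study = config$min_samples_per_study
  )
  res$corpus <- filtered
  emit("filter_report.json", function(p) {
    jsonlite::write_json(
      list(
        n_in = attr(filtered$report, "n_in"),
        n_out = attr(filtered$report, "n_out"),
        dropped = setNames(
          as.list(filtered$report$n_dropped), filtered$report$rule
        )
      ),
      p,
      auto_unbox = TRUE
    )
  })
  done <- c(done, "filter")
  .stage_log(
    v, "filter", attr(filtered$report, "n_out"), "of",
    attr(filtered$report, "n_in"), "samples retained"
  )

  # ---- stage: signatures ---------------------------------------------------
  refs <- .load_or(
    config$reference_signatures,
    function(p) read_gmt(p, role = "reference")
  )
  queries <- .load_or(config$signatures, read_gmt)
  if (is.null(refs) || is.null(queries)) {
    if (is.null(config$sim)) {
      abort("signatures and reference_signatures are required without `sim`")
    }
    # two independent clean training corpora so generated signatures are not
    # fit on the evaluated samples
    train_cfg <- function(offset) {
      args <- unclass(config$sim)
      args$contamination_fraction <- 0
      args$mislabel_fraction <- 0
      args$rng_seed <- config$sim$rng_seed + offset
      do.call(sim_config, args)
    }
    if (is.null(refs)) {
      tr <- simulate_corpus(train_cfg(1000L))
      tr_ann <- mutate(tr$annotations, tissue = .data$tissue_raw)
      refs <- generate_signatures(tr$expression, tr_ann,
        gini_min = config$generation_gini_min,
        rank_max = config$generation_rank_max, role = "reference"
      )
      refs$name <- paste0(refs$name, ".ref")
    }
    if (is.null(queries)) {
      tr <- simulate_corpus(train_cfg(2000L))
      tr_ann <- mutate(tr$annotations, tissue = .data$tissue_raw)
      queries <- generate_signatures(tr$expression, tr_ann,
        gini_min = config$generation_gini_min,
        rank_max = config$generation_rank_max, role = "query"
      )
    }
  }
  collection <- bind_rows(queries, refs)
  class(collection) <- c("signature_collection", class(tibble()))
  if (anyDuplicated(collection$name)) {
    abort("query and reference signature names overlap")
  }
  res$collection <- collection
  emit("signatures.gmt", function(p) write_gmt(collection, p))
  done <- c(done, "signatures")
  .stage_log(
    v, "signatures", nrow(queries), "query +", nrow(refs), "reference"
  )

  # ---- stage: enrich -------------------------------------------------------
  et <- run_enrichment(filtered$expression, collection,
    min_genes = config$min_genes
  )
  res$enrichment <- et
  emit("enrichment.tsv", function(p) write_enrichment(et, p))
  done <- c(done, "enrich")
  .stage_log(v, "enrich", nrow(et), "(sample, signature, p-value) pairs")

  # ---- stage: detect -------------------------------------------------------
  det <- detect(et, filtered$annotations, config = config$detection)
  res$detection <- det
  emit("calls.tsv", function(p) {
    readr::write_tsv(.calls_flat(det$calls), p, progress = FALSE)
  })
  emit("exclusions.tsv", function(p) {
    readr::write_tsv(det$exclusions, p, progress = FALSE)
  })
  done <- c(done, "detect")
  .stage_log(
    v, "detect", sum(det$calls$status != "none"), "of", nrow(det$calls),
    "samples flagged;", sum(det$exclusions$excluded), "signature pairs excluded"
  )

  # ---- stage: summarise ----------------------------------------------------
  summ <- tissue_fractions(det)
  conf <- confusion_counts(det)
  res$summary <- summ
  res$confusion <- conf
  emit("summaries.tsv", function(p) {
    readr::write_tsv(summ, p, progress = FALSE)
  })
  emit("confusion.tsv", function(p) {
    readr::write_tsv(conf, p, progress = FALSE)
  })
  if (!is.null(config$sim)) {
    res$truth_performance <- truth_confusion(det, res$synthetic)
    emit("truth_performance.tsv", function(p) {
      readr::write_tsv(res$truth_performance, p, progress = FALSE)
    })
  }
  done <- c(done, "summarise")
  .stage_log(v, "summarise", nrow(summ), "tissues summarised")

  # ---- stage: report -------------------------------------------------------
  emit("run_metadata.json", function(p) {
    jsonlite::write_json(
      list(
        package = "tissuehet",
        timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
        detection = unclass(config$detection),
        simulated = !is.null(config$sim),
        n_samples = nrow(det$calls),
        n_signatures = length(unique(et$signature)),
        n_pairs = nrow(et),
        elapsed_seconds = as.numeric(difftime(Sys.time(), t0, units = "secs"))
      ),
      p,
      auto_unbox = TRUE
    )
  })
  render_report(config$output_dir)
  files <- c(files, "report.md")
  done <- c(done, "report")
  manifest()
  .stage_log(v, "report", "bundle written to", config$output_dir)
  invisible(res)
}

#' Render a human-readable markdown report from an output bundle
#'
#' @param output_dir Directory written by [run_pipeline()]; must contain
#'   `summaries.tsv`, `confusion.tsv` and `calls.tsv`.
#' @param path Output file (default `report.md` inside `output_dir`).
#' @return The markdown text, invisibly; the file is (re)written. Rendering
#'   only reads the bundle, so regeneration is idempotent.
#' @export
render_report <- function(output_dir, path = file.path(output_dir, "report.md")) {
  need <- c("summaries.tsv", "confusion.tsv", "calls.tsv")
  missing <- need[!file.exists(file.path(output_dir, need))]
  if (length(missing) > 0L) {
    abort(paste0(
      "incomplete bundle, missing: ", paste(missing, collapse = ", ")
    ))
  }
  rd <- function(f) {
    readr::read_tsv(file.path(output_dir, f),
      show_col_types = FALSE, progress = FALSE
    )
  }
  summ <- rd("summaries.tsv")
  conf <- rd("confusion.tsv")
  calls <- rd("calls.tsv")

  fmt_pct <- function(x) sprintf("%.1f%%", 100 * x)
  lines <- c(
    "# Tissue heterogeneity report",
    "",
    sprintf(
      "%d samples analysed; %d flagged heterogeneous (%s), of which %d severe (%s).",
      nrow(calls), sum(calls$status != "none"),
      fmt_pct(mean(calls$status != "none")),
      sum(calls$status == "severe"),
      fmt_pct(mean(calls$status == "severe"))
    ),
    "",
    "## Fraction of heterogeneous samples per tissue",
    "",
    "| tissue | n | flagged | severe | fraction | 95% CI |",
    "|---|---|---|---|---|---|",
    sprintf(
      "| %s | %d | %d | %d | %s | [%s, %s] |",
      summ$tissue, summ$n_samples, summ$n_moderate_or_severe, summ$n_severe,
      fmt_pct(summ$fraction), fmt_pct(summ$ci_low), fmt_pct(summ$ci_high)
    ),
    "",
    "## Tissue confusion matrix",
    "",
    "Counts of samples per annotated tissue in which a signature of another",
    "tissue triggered; `*` marks pairs with one or more query signatures",
    "excluded as correlated with the reference.",
    ""
  )
  wide <- conf |>
    mutate(cell = paste0(.data$n, ifelse(.data$excluded, "*", ""))) |>
    select("tissue", "signature_tissue", "cell") |>
    pivot_wider(names_from = "signature_tissue", values_from = "cell",
                values_fill = "")
  header <- paste0("| annotated \\ detected | ",
                   paste(names(wide)[-1], collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(wide)), collapse = "|"), "|")
  rows <- apply(wide, 1L, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  lines <- c(lines, header, sep, rows, "")

  severe <- calls[calls$status == "severe", , drop = FALSE]
  lines <- c(lines, "## Severely heterogeneous samples", "")
  if (nrow(severe) == 0L) {
    lines <- c(lines, "0 severe samples detected.", "")
  } else {
    severe <- severe[order(severe$q_min), , drop = FALSE]
    top <- head(severe, 10L)
    lines <- c(
      lines,
      sprintf("%d severe samples; top %d by q-value:", nrow(severe), nrow(top)),
      "",
      "| sample | tissue | q_min | p_ref | triggering |",
      "|---|---|---|---|---|",
      sprintf(
        "| %s | %s | %.3g | %.3g | %s |",
        top$sample_id, top$tissue, top$q_min, top$p_ref,
        ifelse(is.na(top$triggering), "", top$triggering)
      ),
      ""
    )
  }
  readr::write_lines(lines, path)
  invisible(paste(lines, collapse = "\n"))
}
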