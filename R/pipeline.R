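#' Full pipeline configuration
#'
#' One object holding every tunable of the repurposing pipeline. A single
#' global seed derives all stage seeds by fixed offsets (ensemble run
#' \code{r} uses \code{seed + 10000 + r}; the reference fit used for
#' clustering uses \code{seed + 20000}), so one integer reproduces a run
#' bit-identically.
#'
#' @param interactions edge-list path or a \code{\link{dti_matrix}}.
#' @param target_id query target id.
#' @param metadata drug metadata CSV path or data.frame
#'   (\code{\link{drug_records}}); \code{NULL} treats every drug as approved.
#' @param molecules molecule-file path or named \code{\link{mol_descriptor}}
#'   list; \code{NULL} disables the similarity stage.
#' @param pmf a \code{\link{pmf_config}} (its seed is re-derived per stage).
#' @param ensemble an \code{\link{ensemble_config}} (its seed_base is
#'   re-derived from the global seed).
#' @param metrics distance metrics for the cross-metric consensus, a
#'   non-empty subset of euclidean / cosine / cityblock / mahalanobis.
#' @param n_ref_fits reference PMF fits whose latent pairwise distances are
#'   averaged before clustering (fit f uses seed \code{seed + 20000 + f - 1}).
#'   Latent factors are identified only up to rotation, so the pairwise
#'   distance matrix -- not the factor matrix -- is the quantity that can be
#'   ensembled; averaging it over a few seeded fits damps the
#'   negative-sampling noise of any single fit.
#' @param linkage agglomeration linkage.
#' @param alpha BH-adjusted significance level for cluster enrichment.
#' @param min_size,max_size evaluated cluster-size bounds
#'   (\code{\link{enriched_clusters}}).
#' @param similarity a \code{\link{similarity_config}}.
#' @param ref_threshold combo threshold for reference-set expansion
#'   (defaults to the filter threshold).
#' @param seed global seed.
#' @return a list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(interactions, target_id, metadata = NULL,
                            molecules = NULL, pmf = pmf_config(),
                            ensemble = ensemble_config(),
                            metrics = c("euclidean", "cosine", "cityblock"),
                            n_ref_fits = 5L,
                            linkage = "average", alpha = 0.05, min_size = 3L,
                            max_size = NULL, similarity = similarity_config(),
                            ref_threshold = NULL, seed = 1L) {
  metrics <- match.arg(metrics, c("euclidean", "cosine", "cityblock", "mahalanobis"),
                       several.ok = TRUE)
  if (length(metrics) < 1L) stop("metrics must be non-empty", call. = FALSE)
  stopifnot(inherits(pmf, "pmf_config"), inherits(ensemble, "ensemble_config"),
            inherits(similarity, "similarity_config"))
  cfg <- list(interactions = interactions, target_id = as.character(target_id),
              metadata = metadata, molecules = molecules, pmf = pmf,
              ensemble = ensemble, metrics = metrics,
              n_ref_fits = check_count(n_ref_fits, "n_ref_fits"),
              linkage = linkage,
              alpha = check_scalar(alpha, "alpha", 0, 1),
              min_size = check_count(min_size, "min_size"),
              max_size = max_size, similarity = similarity,
              ref_threshold = ref_threshold %||% similarity$combo_threshold,
              seed = check_count(seed, "seed", min = -.Machine$integer.max))
  class(cfg) <- "pipeline_config"
  cfg
}

# run one stage, prefixing errors with the stage name and attaching the
# partial report built so far
run_stage <- function(stage, report, expr) {
  tryCatch(expr, error = function(e) {
    cond <- simpleError(sprintf("pipeline stage '%s' failed: %s", stage,
                                conditionMessage(e)))
    cond$partial_report <- report
    stop(cond)
  })
}

#' Run the drug-repurposing pipeline
#'
#' Executes the full inference chain for one query target: read inputs;
#' collect its known ligands and drop non-approved ones; run the seeded PMF
#' ensemble and select frequent top-k candidates; pool candidates with the
#' approved known set; cluster the pooled drugs' latent vectors (from a
#' dedicated seeded reference fit) under each configured distance metric;
#' keep clusters enriched in known ligands and intersect their candidate
#' members across metrics; and, when molecules are available, expand a
#' chemical reference panel around the known ligands and keep consensus
#' hits that score at least the combo threshold against it.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @return a list of class \code{pipeline_report} recording every stage's
#'   inputs, outputs, seeds and counts; the final ranked hits are in
#'   \code{$final}.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  report <- list(target_id = config$target_id,
                 seeds = list(global = config$seed,
                              ensemble_base = config$seed + 10000L,
                              reference_fits = config$seed + 20000L +
                                seq_len(config$n_ref_fits) - 1L),
                 config_hash = rlang::hash(unclass(config)))
  class(report) <- "pipeline_report"

  # --- read inputs ---------------------------------------------------------
  R <- run_stage("read_inputs", report, {
    if (inherits(config$interactions, "dti_matrix")) config$interactions
    else read_interactions(config$interactions)
  })
  metadata <- run_stage("read_inputs", report, {
    if (is.null(config$metadata)) NULL
    else if (is.data.frame(config$metadata)) config$metadata
    else read_drug_metadata(config$metadata)
  })
  descriptors <- run_stage("read_inputs", report, {
    if (is.null(config$molecules)) NULL
    else if (is.list(config$molecules) && !is.data.frame(config$molecules)) config$molecules
    else read_molecules(config$molecules, config$similarity)
  })
  report$n_drugs <- length(R$drugs)
  report$n_targets <- length(R$targets)

  # --- known ligands and regulatory filter ---------------------------------
  known <- run_stage("filter_known", report, known_drugs(R, config$target_id))
  report$known <- known
  approved_known <- run_stage("filter_known", report, {
    if (is.null(metadata)) known
    else {
      rows <- metadata[match(known, metadata$id), , drop = FALSE]
      if (anyNA(rows$id)) {
        stop(sprintf("known drug(s) missing from metadata: %s",
                     paste(known[is.na(rows$id)], collapse = ", ")))
      }
      filter_approved(rows)$id
    }
  })
  report$approved_known <- approved_known

  # --- PMF ensemble ---------------------------------------------------------
  ens <- config$ensemble
  ens$seed_base <- config$seed + 10000L
  table <- run_stage("ensemble", report,
                     run_ensemble(R, config$pmf, ens, config$target_id,
                                  known_set = known))
  report$candidate_table <- as.data.frame(table)
  candidates <- select_candidates(table)
  report$candidates <- candidates
  if (length(candidates) == 0L) {
    warning("ensemble selected no candidates; downstream hit sets are empty",
            call. = FALSE)
  }

  # --- combined clustering universe ----------------------------------------
  combined <- run_stage("combine", report,
                        combine_candidate_set(approved_known, candidates))
  report$combined <- combined

  # --- latent clustering and enrichment per metric --------------------------
  per_metric <- list()
  if (length(combined) >= max(3L, config$min_size) && length(approved_known) >= 1L &&
      length(candidates) >= 1L) {
    Usubs <- run_stage("clustering", report, {
      lapply(seq_len(config$n_ref_fits), function(f) {
        ref_cfg <- config$pmf
        ref_cfg$seed <- config$seed + 20000L + f - 1L
        pmf_fit(R, ref_cfg)$U[combined, , drop = FALSE]
      })
    })
    for (metric in config$metrics) {
      per_metric[[metric]] <- run_stage("clustering", report, {
        D <- Reduce(`+`, lapply(Usubs, pairwise_distance, metric = metric)) /
          length(Usubs)
        dend <- agglomerate(D, linkage = config$linkage, metric = metric)
        enr <- enriched_clusters(dend, approved_known, alpha = config$alpha,
                                 min_size = config$min_size,
                                 max_size = config$max_size)
        list(enrichment = as.data.frame(enr),
             members = attr(enr, "members"),
             hits = enriched_members(enr))
      })
    }
  } else if (length(candidates) >= 1L) {
    warning("clustering skipped: pooled drug set too small", call. = FALSE)
  }
  report$per_metric <- per_metric

  # --- cross-metric consensus ----------------------------------------------
  consensus <- run_stage("consensus", report, {
    if (length(per_metric) == 0L) character(0)
    else consensus_hits(lapply(per_metric, `[[`, "hits"), candidates)
  })
  report$consensus <- consensus

  # --- chemical similarity filter -------------------------------------------
  if (!is.null(descriptors)) {
    reference <- run_stage("similarity", report, {
      lib_ids <- intersect(names(descriptors), R$drugs)
      known_desc <- descriptors[intersect(approved_known, names(descriptors))]
      if (length(known_desc) == 0L) character(0)
      else expand_reference(known_desc, descriptors[lib_ids], config$ref_threshold)
    })
    report$reference <- reference
    final <- run_stage("similarity", report, {
      if (length(consensus) == 0L || length(reference) == 0L) {
        data.frame(drug_id = character(0), score = numeric(0))
      } else {
        similarity_filter(consensus, descriptors, reference, config$similarity)
      }
    })
    report$similarity_stage <- TRUE
  } else {
    report$reference <- character(0)
    final <- data.frame(drug_id = consensus,
                        score = rep(NA_real_, length(consensus)))
    report$similarity_stage <- FALSE
  }
  report$final <- final

  report$counts <- list(
    known = length(known), approved_known = length(approved_known),
    candidates = length(candidates), combined = length(combined),
    overlap = length(intersect(approved_known, candidates)),
    per_metric_hits = vapply(per_metric, function(x) length(x$hits), 0L),
    consensus = length(consensus), reference = length(report$reference),
    final = nrow(final))
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> target %s\n", x$target_id))
  cat(sprintf("  known ligands      : %d (%d approved)\n",
              x$counts$known, x$counts$approved_known))
  cat(sprintf("  ensemble candidates: %d\n", x$counts$candidates))
  cat(sprintf("  clustering universe: %d\n", x$counts$combined))
  if (length(x$counts$per_metric_hits)) {
    cat(sprintf("  enriched members   : %s\n",
                paste(sprintf("%s=%d", names(x$counts$per_metric_hits),
                              x$counts$per_metric_hits), collapse = ", ")))
  }
  cat(sprintf("  consensus hits     : %d\n", x$counts$consensus))
  if (isTRUE(x$similarity_stage)) {
    cat(sprintf("  similarity filtered: %d (reference panel %d)\n",
                x$counts$final, x$counts$reference))
  }
  if (nrow(x$final)) {
    cat("  final hits:\n")
    for (i in seq_len(nrow(x$final))) {
      cat(sprintf("    %2d. %s%s\n", i, x$final$drug_id[i],
                  if (is.na(x$final$score[i])) ""
                  else sprintf(" (combo %.3f)", x$final$score[i])))
    }
  }
  invisible(x)
}

#' Write a pipeline report as JSON
#'
#' @param report a \code{\link{run_pipeline}} result.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "pipeline_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
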