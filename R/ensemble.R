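#' Ensemble configuration
#'
#' Settings for repeating the PMF fit under many seeds and pooling each
#' run's top-k predictions for the query target. Run \code{r} uses seed
#' \code{seed_base + r}, so one base integer reproduces the whole ensemble.
#'
#' @param n_runs number of seeded PMF fits.
#' @param k per-run top-k predictions retained.
#' @param seed_base base seed; run r uses \code{seed_base + r}.
#' @param freq_threshold fraction of runs a drug must appear in to be
#'   selected, in (0, 1].
#' @return a list of class \code{ensemble_config}.
#' @export
ensemble_config <- function(n_runs = 100L, k = 10L, seed_base = 0L,
                            freq_threshold = 0.5) {
  cfg <- list(
    n_runs = check_count(n_runs, "n_runs"),
    k = check_count(k, "k"),
    seed_base = check_count(seed_base, "seed_base", min = -.Machine$integer.max),
    freq_threshold = check_scalar(freq_threshold, "freq_threshold", min = 1e-12, max = 1)
  )
  class(cfg) <- "ensemble_config"
  cfg
}

#' Pool per-run top-k lists into a candidate table
#'
#' Order of the runs does not affect the result. Exposed separately from
#' \code{\link{run_ensemble}} so aggregation can be checked independently of
#' the fits.
#'
#' @param topk_runs list of character vectors, one per run.
#' @param n_runs total number of runs (denominator for frequencies).
#' @param freq_threshold selection threshold on frequency.
#' @return a \code{data.frame} of class \code{candidate_table} with columns
#'   \code{drug_id}, \code{count}, \code{frequency}, \code{selected}, sorted
#'   by descending frequency then drug id.
#' @export
candidate_table <- function(topk_runs, n_runs, freq_threshold = 0.5) {
  n_runs <- check_count(n_runs, "n_runs")
  pooled <- unlist(topk_runs, use.names = FALSE)
  counts <- table(pooled)
  tab <- data.frame(drug_id = if (length(counts)) names(counts) else character(0),
                    count = as.integer(counts),
                    stringsAsFactors = FALSE)
  tab$frequency <- tab$count / n_runs
  tab$selected <- tab$frequency >= freq_threshold
  tab <- tab[order(-tab$frequency, tab$drug_id, method = "radix"), , drop = FALSE]
  rownames(tab) <- NULL
  class(tab) <- c("candidate_table", "data.frame")
  tab
}

#' Run the PMF ensemble for a query target
#'
#' Fits \code{n_runs} seeded PMF models (run \code{r} with seed
#' \code{seed_base + r}), ranks the top-\code{k} unknown drugs for the query
#' target in each run, and pools appearance counts. Deterministic given
#' \code{(seed_base, n_runs)} and invariant to run execution order.
#'
#' @param R a \code{\link{dti_matrix}}.
#' @param pmf_config a \code{\link{pmf_config}} (its seed field is replaced
#'   per run).
#' @param ens_config an \code{\link{ensemble_config}}.
#' @param target_id query target id.
#' @param known_set drug ids already known to bind the target (excluded from
#'   the per-run rankings).
#' @return a \code{\link{candidate_table}}.
#' @export
run_ensemble <- function(R, pmf_config, ens_config, target_id,
                         known_set = character(0)) {
  stopifnot(inherits(R, "dti_matrix"), inherits(pmf_config, "pmf_config"),
            inherits(ens_config, "ensemble_config"))
  if (!(target_id %in% R$targets)) {
    stop(sprintf("unknown target id: %s", target_id), call. = FALSE)
  }
  topk <- vector("list", ens_config$n_runs)
  for (r in seq_len(ens_config$n_runs)) {
    cfg <- pmf_config
    cfg$seed <- ens_config$seed_base + r
    factors <- tryCatch(pmf_fit(R, cfg), error = function(e) {
      stop(sprintf("ensemble run %d (seed %d): %s", r, cfg$seed,
                   conditionMessage(e)), call. = FALSE)
    })
    topk[[r]] <- rank_candidates(predict_scores(factors), target_id,
                                 ens_config$k, exclude = known_set)
  }
  candidate_table(topk, ens_config$n_runs, ens_config$freq_threshold)
}

#' Candidate drugs passing the frequency threshold
#'
#' @param table a \code{\link{candidate_table}}.
#' @return character vector of selected drug ids, sorted by descending
#'   frequency then drug id.
#' @export
select_candidates <- function(table) {
  stopifnot(inherits(table, "candidate_table"))
  table$drug_id[table$selected]
}

#' Write a candidate table as CSV
#'
#' @param table a \code{\link{candidate_table}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_candidate_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
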