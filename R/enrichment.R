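#' Hypergeometric upper-tail probability
#'
#' Probability of observing at least \code{x} reference ("known") drugs in a
#' cluster of size \code{n_c} drawn without replacement from a universe of
#' \code{N} drugs of which \code{K} are known:
#' \eqn{P[X \ge x]} for \eqn{X \sim} Hypergeometric(N, K, n_c). Evaluated
#' through \code{\link[stats]{phyper}}, which works in log space and is
#' exact to floating-point precision.
#'
#' @param x known drugs observed in the cluster.
#' @param n_c cluster size.
#' @param K known drugs in the universe.
#' @param N universe size.
#' @return upper-tail p-value in [0, 1].
#' @examples
#' hypergeom_tail(4, 5, 6, 20)
#' @export
hypergeom_tail <- function(x, n_c, K, N) {
  x <- check_count(x, "x", min = 0L)
  n_c <- check_count(n_c, "n_c", min = 0L)
  K <- check_count(K, "K", min = 0L)
  N <- check_count(N, "N", min = 1L)
  if (n_c > N || K > N || x > min(n_c, K)) {
    stop("inconsistent hypergeometric arguments: need n_c <= N, K <= N, x <= min(n_c, K)",
         call. = FALSE)
  }
  if (x == 0L) return(1)
  stats::phyper(x - 1L, K, N - K, n_c, lower.tail = FALSE)
}

#' Clusters enriched in known drugs
#'
#' Scans every internal node of an agglomerative merge tree whose size lies
#' in \code{[min_size, max_size]}, scores each with the one-sided
#' hypergeometric tail against the known-drug set, applies
#' Benjamini-Hochberg correction across the evaluated nodes, and keeps
#' nodes with adjusted p-value at most \code{alpha}. Nested significant
#' nodes are collapsed to one representative per ancestor-descendant chain:
#' the maximal (most inclusive) significant node, i.e. significant nodes
#' contained in another significant node are dropped. Tree nodes are either
#' nested or disjoint, so the returned clusters are pairwise disjoint. The
#' maximal representative is the one that serves the downstream extraction
#' of non-known cluster members: collapsing toward minimal or
#' minimal-p-value nodes systematically degenerates to pure known-drug
#' cores, which carry no repurposable candidates.
#'
#' @param dend a \code{\link{agglomerate}} result over the drug universe.
#' @param known_set character vector of known drug ids (non-empty, all
#'   leaves of the tree).
#' @param alpha significance level on BH-adjusted p-values.
#' @param min_size,max_size inclusive bounds on evaluated cluster sizes;
#'   \code{max_size = NULL} means n - 1 (the root is never informative).
#' @return a \code{data.frame} of class \code{enrichment_table} with columns
#'   \code{node}, \code{n_c}, \code{x}, \code{K}, \code{N}, \code{p},
#'   \code{q}, sorted by \code{q} then \code{p}; cluster member ids are in
#'   \code{attr(, "members")} (a list parallel to the rows).
#' @export
enriched_clusters <- function(dend, known_set, alpha = 0.05, min_size = 3L,
                              max_size = NULL) {
  stopifnot(inherits(dend, "dendro"))
  known_set <- unique(as.character(known_set))
  if (length(known_set) == 0L) stop("empty known-drug set", call. = FALSE)
  if (!all(known_set %in% dend$labels)) {
    stop("known_set contains ids that are not leaves of the dendrogram", call. = FALSE)
  }
  N <- length(dend$labels)
  K <- length(known_set)
  min_size <- check_count(min_size, "min_size")
  max_size <- if (is.null(max_size)) N - 1L else check_count(max_size, "max_size")

  members <- dendro_members(dend)
  sizes <- lengths(members)
  eval_idx <- which(sizes >= min_size & sizes <= max_size)
  is_known <- dend$labels %in% known_set

  empty <- function() {
    out <- data.frame(node = integer(0), n_c = integer(0), x = integer(0),
                      K = integer(0), N = integer(0), p = numeric(0), q = numeric(0))
    attr(out, "members") <- list()
    class(out) <- c("enrichment_table", "data.frame")
    out
  }
  if (length(eval_idx) == 0L) return(empty())

  x <- vapply(eval_idx, function(s) sum(is_known[members[[s]]]), 0L)
  n_c <- sizes[eval_idx]
  p <- vapply(seq_along(eval_idx),
              function(i) hypergeom_tail(x[i], n_c[i], K, N), 0)
  q <- stats::p.adjust(p, method = "BH")
  sig <- which(q <= alpha)
  if (length(sig) == 0L) return(empty())

  # collapse nested significant nodes: keep the maximal node per chain
  kept <- sig[vapply(sig, function(i) {
    mi <- members[[eval_idx[i]]]
    !any(vapply(sig, function(j) {
      if (i == j) return(FALSE)
      mj <- members[[eval_idx[j]]]
      length(mi) < length(mj) && all(mi %in% mj)
    }, TRUE))
  }, TRUE)]
  kept <- kept[order(q[kept], p[kept])]
  out <- data.frame(node = eval_idx[kept], n_c = n_c[kept], x = x[kept],
                    K = K, N = N, p = p[kept], q = q[kept])
  rownames(out) <- NULL
  attr(out, "members") <- lapply(kept, function(i) dend$labels[members[[eval_idx[i]]]])
  class(out) <- c("enrichment_table", "data.frame")
  out
}

#' Union of members of enriched clusters
#'
#' @param enrichment an \code{\link{enriched_clusters}} result.
#' @return character vector of all drug ids in the returned clusters.
#' @export
enriched_members <- function(enrichment) {
  sort(unique(unlist(attr(enrichment, "members"), use.names = FALSE)))
}

#' Write an enrichment table as CSV
#'
#' Members are semicolon-joined into a single column.
#'
#' @param enrichment an \code{\link{enriched_clusters}} result.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_enrichment <- function(enrichment, path) {
  df <- as.data.frame(enrichment)
  df$members <- vapply(attr(enrichment, "members"), paste, "", collapse = ";")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Cross-metric consensus hits
#'
#' Drugs recovered inside enriched clusters under every distance metric,
#' restricted to the ensemble-selected candidate universe (known drugs seed
#' the enrichment but are not themselves repurposing hits).
#'
#' @param per_metric_hits list of character vectors, one per metric: the
#'   members of that metric's enriched clusters.
#' @param candidate_universe character vector of ensemble-selected drugs.
#' @return sorted character vector of consensus candidate drugs.
#' @export
consensus_hits <- function(per_metric_hits, candidate_universe) {
  stopifnot(is.list(per_metric_hits), length(per_metric_hits) >= 1L)
  common <- Reduce(intersect, lapply(per_metric_hits, as.character))
  sort(intersect(common, as.character(candidate_universe)))
}
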