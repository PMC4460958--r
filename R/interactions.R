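#' Sparse binary drug-target interaction matrix
#'
#' Container for a bipartite drug-target association network: an ordered
#' registry of drug identifiers (rows), an ordered registry of target
#' identifiers (columns), and the set of observed positive associations.
#' Identifiers are compared case-sensitively.
#'
#' @param drugs character vector of unique drug ids (row registry).
#' @param targets character vector of unique target ids (column registry).
#' @param pairs two-column integer matrix of (drug index, target index)
#'   positive associations; no duplicates, indices within bounds.
#' @return an object of class \code{dti_matrix} with elements \code{drugs},
#'   \code{targets} and \code{pairs}.
#' @examples
#' dti_matrix(c("d1", "d2"), c("t1", "t2"), cbind(c(1L, 2L, 1L), c(1L, 1L, 2L)))
#' @export
dti_matrix <- function(drugs, targets, pairs) {
  drugs <- as.character(drugs)
  targets <- as.character(targets)
  if (length(drugs) < 1L || length(targets) < 1L) {
    stop("registries must contain at least one drug and one target", call. = FALSE)
  }
  if (anyDuplicated(drugs)) stop("duplicate drug ids in registry", call. = FALSE)
  if (anyDuplicated(targets)) stop("duplicate target ids in registry", call. = FALSE)
  pairs <- matrix(as.integer(pairs), ncol = 2L,
                  dimnames = list(NULL, c("drug", "target")))
  if (nrow(pairs) > 0L) {
    if (any(pairs[, 1L] < 1L | pairs[, 1L] > length(drugs)) ||
        any(pairs[, 2L] < 1L | pairs[, 2L] > length(targets))) {
      stop("pair indices out of bounds", call. = FALSE)
    }
    if (anyDuplicated(pair_keys(pairs, length(drugs)))) {
      stop("duplicate (drug, target) pairs", call. = FALSE)
    }
  }
  structure(list(drugs = drugs, targets = targets, pairs = pairs),
            class = "dti_matrix")
}

# linear cell index, used for dedup / set operations on pairs
pair_keys <- function(pairs, n_drugs) {
  (pairs[, 2L] - 1) * as.double(n_drugs) + pairs[, 1L]
}

#' @export
print.dti_matrix <- function(x, ...) {
  cat(sprintf("<dti_matrix> %d drugs x %d targets, %d observed associations (density %.3g)\n",
              length(x$drugs), length(x$targets), nrow(x$pairs),
              nrow(x$pairs) / (length(x$drugs) * length(x$targets))))
  invisible(x)
}

#' @export
dim.dti_matrix <- function(x) c(length(x$drugs), length(x$targets))

#' Convert an interaction matrix to a sparse 0/1 Matrix
#'
#' @param x a \code{dti_matrix}.
#' @return a \code{\link[Matrix]{sparseMatrix}} with drug ids as row names and
#'   target ids as column names.
#' @export
as_sparse_matrix <- function(x) {
  stopifnot(inherits(x, "dti_matrix"))
  Matrix::sparseMatrix(i = x$pairs[, 1L], j = x$pairs[, 2L], x = 1,
                       dims = dim(x), dimnames = list(x$drugs, x$targets))
}

#' Read a drug-target edge list
#'
#' Parses a headerless delimited text file with one association per line
#' (columns: drug id, target id; extra columns ignored). The delimiter is
#' detected from the first data line (tab or comma) unless given. Registries
#' are built in first-appearance order; duplicated edges are collapsed with a
#' warning reporting how many were dropped.
#'
#' @param path path to the edge-list file.
#' @param sep field delimiter; \code{NULL} (default) auto-detects tab/comma.
#' @param header logical; if \code{TRUE} the first line is skipped.
#' @return a \code{\link{dti_matrix}}.
#' @export
read_interactions <- function(path, sep = NULL, header = FALSE) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  offset <- 0L
  if (isTRUE(header) && length(lines) >= 1L) {
    lines <- lines[-1L]
    offset <- 1L
  }
  keep <- nzchar(trimws(lines))
  if (!any(keep)) stop("no associations: empty edge list", call. = FALSE)
  if (is.null(sep)) {
    first <- lines[keep][1L]
    sep <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  }
  fields <- strsplit(lines, sep, fixed = TRUE)
  edges <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    if (!keep[i]) next
    f <- trimws(fields[[i]])
    if (length(f) < 2L || !nzchar(f[1L]) || !nzchar(f[2L])) {
      stop(sprintf("malformed edge list row at line %d: %s",
                   i + offset, lines[i]), call. = FALSE)
    }
    edges[[i]] <- f[1:2]
  }
  edges <- do.call(rbind, edges[keep])
  drugs <- unique(edges[, 1L])
  targets <- unique(edges[, 2L])
  pairs <- cbind(match(edges[, 1L], drugs), match(edges[, 2L], targets))
  dup <- duplicated(pair_keys(pairs, length(drugs)))
  if (any(dup)) {
    warning(sprintf("collapsed %d duplicated association(s)", sum(dup)), call. = FALSE)
    pairs <- pairs[!dup, , drop = FALSE]
  }
  dti_matrix(drugs, targets, pairs)
}

#' Write a drug-target edge list
#'
#' Writes the observed associations of a \code{dti_matrix} as a headerless
#' tab-separated edge list, one (drug id, target id) row per association,
#' in stored pair order. \code{read_interactions()} on the output recovers
#' an identical object whenever the registries were built in
#' first-appearance order (as \code{read_interactions()} builds them) and
#' every registered drug and target carries at least one association.
#'
#' @param x a \code{dti_matrix}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_interactions <- function(x, path) {
  stopifnot(inherits(x, "dti_matrix"))
  df <- data.frame(drug = x$drugs[x$pairs[, 1L]],
                   target = x$targets[x$pairs[, 2L]])
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Known drugs for one target
#'
#' @param x a \code{dti_matrix}.
#' @param target_id a target id present in the registry.
#' @return character vector of drug ids with an observed association to the
#'   target, in registry order.
#' @export
known_drugs <- function(x, target_id) {
  stopifnot(inherits(x, "dti_matrix"))
  j <- match(target_id, x$targets)
  if (is.na(j)) stop(sprintf("unknown target id: %s", target_id), call. = FALSE)
  idx <- sort(x$pairs[x$pairs[, 2L] == j, 1L])
  x$drugs[idx]
}
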