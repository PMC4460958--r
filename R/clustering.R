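#' Pairwise distances between drug latent vectors
#'
#' Full symmetric distance matrix under one of the three metrics used for
#' the cross-metric consensus: \code{euclidean} (L2), \code{cityblock} (L1)
#' and \code{cosine} (1 minus the cosine of the angle). A Mahalanobis
#' variant (whitening by the latent covariance before L2) is available
#' behind the \code{mahalanobis} flag.
#'
#' @param U numeric matrix of latent row vectors, row names = drug ids.
#' @param metric one of \code{"euclidean"}, \code{"cosine"},
#'   \code{"cityblock"}, \code{"mahalanobis"}.
#' @return symmetric n x n matrix with zero diagonal and id dimnames.
#' @export
pairwise_distance <- function(U, metric = c("euclidean", "cosine", "cityblock",
                                            "mahalanobis")) {
  metric <- match.arg(metric)
  U <- as.matrix(U)
  ids <- rownames(U) %||% as.character(seq_len(nrow(U)))
  D <- switch(metric,
    euclidean = as.matrix(stats::dist(U, method = "euclidean")),
    cityblock = as.matrix(stats::dist(U, method = "manhattan")),
    cosine = {
      nrm <- sqrt(rowSums(U * U))
      zero <- nrm < .Machine$double.eps
      if (any(zero)) {
        stop(sprintf("cosine distance undefined for zero-norm latent vector(s): %s",
                     paste(ids[zero], collapse = ", ")), call. = FALSE)
      }
      C <- tcrossprod(U / nrm)
      D <- 1 - pmin(pmax(C, -1), 1)
      D[D < 0] <- 0
      D
    },
    mahalanobis = {
      S <- stats::cov(U)
      # whiten via eigendecomposition; near-null directions are dropped
      e <- eigen(S, symmetric = TRUE)
      keep <- e$values > max(e$values) * 1e-10
      W <- U %*% e$vectors[, keep, drop = FALSE] %*%
        diag(1 / sqrt(e$values[keep]), sum(keep))
      as.matrix(stats::dist(W, method = "euclidean"))
    })
  D <- (D + t(D)) / 2
  diag(D) <- 0
  dimnames(D) <- list(ids, ids)
  D
}

#' Agglomerative hierarchical clustering with deterministic tie-breaking
#'
#' Bottom-up agglomeration over a precomputed distance matrix under single,
#' complete or average linkage (Lance-Williams updates). Clusters are
#' indexed by creation order (leaves 1..n, then n+1, ...); when several
#' pairs attain the minimal distance the pair with the lexicographically
#' smallest (index_a, index_b) is merged, so the tree is fully
#' deterministic.
#'
#' @param D symmetric distance matrix with id dimnames (n >= 2).
#' @param linkage \code{"average"} (default), \code{"complete"} or
#'   \code{"single"}.
#' @param metric optional metric tag carried along for bookkeeping.
#' @return an object of class \code{dendro} with elements \code{merge}
#'   (n-1 x 2, cluster creation indices), \code{height}, \code{labels},
#'   \code{linkage}, \code{metric}.
#' @export
agglomerate <- function(D, linkage = c("average", "complete", "single"),
                        metric = NULL) {
  linkage <- match.arg(linkage)
  D <- as.matrix(D)
  n <- nrow(D)
  if (n < 2L) stop("need at least two observations to cluster", call. = FALSE)
  labels <- rownames(D) %||% as.character(seq_len(n))

  # active clusters keyed by creation index; sizes for Lance-Williams
  act <- seq_len(n)                 # creation indices of active clusters
  size <- rep(1L, n)
  W <- D                            # working inter-cluster distances
  dimnames(W) <- NULL
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)

  for (s in seq_len(n - 1L)) {
    k <- length(act)
    best <- c(NA_integer_, NA_integer_)  # positions in act
    dmin <- Inf
    for (p in seq_len(k - 1L)) {
      for (q in (p + 1L):k) {
        d <- W[p, q]
        # creation-index pair of this candidate, smaller first
        a <- min(act[p], act[q]); b <- max(act[p], act[q])
        if (d < dmin ||
            (d == dmin && (a < min(act[best[1L]], act[best[2L]]) ||
                           (a == min(act[best[1L]], act[best[2L]]) &&
                            b < max(act[best[1L]], act[best[2L]]))))) {
          dmin <- d
          best <- c(p, q)
        }
      }
    }
    p <- best[1L]; q <- best[2L]
    ia <- min(act[p], act[q]); ib <- max(act[p], act[q])
    merge[s, ] <- c(ia, ib)
    height[s] <- dmin
    na <- size[p]; nb <- size[q]
    upd <- switch(linkage,
      single   = pmin(W[p, ], W[q, ]),
      complete = pmax(W[p, ], W[q, ]),
      average  = (na * W[p, ] + nb * W[q, ]) / (na + nb))
    W[p, ] <- upd; W[, p] <- upd; W[p, p] <- 0
    W <- W[-q, -q, drop = FALSE]
    size[p] <- na + nb
    size <- size[-q]
    act[p] <- n + s
    act <- act[-q]
  }
  structure(list(merge = merge, height = height, labels = labels,
                 linkage = linkage, metric = metric),
            class = "dendro")
}

#' @export
print.dendro <- function(x, ...) {
  cat(sprintf("<dendro> %d leaves, %s linkage%s, heights [%.4g, %.4g]\n",
              length(x$labels), x$linkage,
              if (is.null(x$metric)) "" else paste0(", ", x$metric, " metric"),
              min(x$height), max(x$height)))
  invisible(x)
}

#' Leaf members of every internal node
#'
#' @param dend a \code{\link{agglomerate}} result.
#' @return list of length n-1; element s holds the leaf indices under the
#'   node created at merge step s.
#' @export
dendro_members <- function(dend) {
  stopifnot(inherits(dend, "dendro"))
  n <- length(dend$labels)
  members <- vector("list", n - 1L)
  expand <- function(idx) if (idx <= n) idx else members[[idx - n]]
  for (s in seq_len(n - 1L)) {
    members[[s]] <- sort(c(expand(dend$merge[s, 1L]), expand(dend$merge[s, 2L])))
  }
  members
}

#' Convert to a base-R hclust object
#'
#' @param x a \code{dendro}.
#' @param ... unused.
#' @return an object of class \code{hclust}.
#' @export
as.hclust.dendro <- function(x, ...) {
  n <- length(x$labels)
  m <- x$merge
  hm <- ifelse(m <= n, -m, m - n)
  # leaf order for plotting: left-to-right traversal
  ord <- integer(0)
  walk <- function(idx) {
    if (idx < 0) return(-idx)
    c(walk(hm[idx, 1L]), walk(hm[idx, 2L]))
  }
  ord <- walk(n - 1L)
  structure(list(merge = hm, height = x$height, order = ord,
                 labels = x$labels, method = x$linkage,
                 dist.method = x$metric %||% "unknown"),
            class = "hclust")
}

#' Export a dendrogram in Newick format
#'
#' Branch lengths are height differences between a node and its parent, as
#' in a standard ultrametric tree rendering of an agglomerative merge tree.
#'
#' @param dend a \code{dendro}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_newick <- function(dend, path) {
  phy <- ape::as.phylo(as.hclust.dendro(dend))
  ape::write.tree(phy, file = path)
  invisible(path)
}
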