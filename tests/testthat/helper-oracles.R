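# Independent brute-force oracles used to cross-check the implementation.
# Each one recomputes the quantity from first principles by a different
# route than the package code.

# hypergeometric upper tail by exhaustive enumeration of all C(N, n_c)
# draws from a universe where elements 1..K are "known"
oracle_hypergeom_all_x <- function(n_c, K, N) {
  if (n_c == 0L) return(c(`0` = 1))
  combos <- utils::combn(N, n_c)
  hits <- colSums(combos <= K)
  vapply(0:min(n_c, K), function(x) mean(hits >= x), 0)
}

# exact pairwise AUC by double loop
oracle_auc <- function(pos, neg) {
  wins <- 0
  for (p in pos) for (q in neg) {
    wins <- wins + (p > q) + 0.5 * (p == q)
  }
  wins / (length(pos) * length(neg))
}

# naive agglomeration: clusters kept as explicit member sets, inter-cluster
# distance recomputed from the original matrix at every step by the linkage
# definition (no Lance-Williams update), same creation-index tie rule
oracle_agglomerate <- function(D, linkage) {
  n <- nrow(D)
  link_fun <- switch(linkage,
    single   = min,
    complete = max,
    average  = mean)
  clusters <- lapply(seq_len(n), identity)   # member sets
  ids <- seq_len(n)                          # creation indices
  merges <- matrix(0L, n - 1L, 2L)
  heights <- numeric(n - 1L)
  member_sets <- vector("list", n - 1L)
  for (s in seq_len(n - 1L)) {
    best <- NULL
    for (p in seq_along(clusters)[-length(clusters)]) {
      for (q in (p + 1L):length(clusters)) {
        d <- link_fun(D[clusters[[p]], clusters[[q]]])
        key <- c(d, min(ids[p], ids[q]), max(ids[p], ids[q]))
        if (is.null(best) || d < best$key[1L] ||
            (d == best$key[1L] && (key[2L] < best$key[2L] ||
                                   (key[2L] == best$key[2L] && key[3L] < best$key[3L])))) {
          best <- list(p = p, q = q, key = key)
        }
      }
    }
    merges[s, ] <- c(best$key[2L], best$key[3L])
    heights[s] <- best$key[1L]
    member_sets[[s]] <- sort(c(clusters[[best$p]], clusters[[best$q]]))
    clusters[[best$p]] <- member_sets[[s]]
    ids[best$p] <- n + s
    clusters <- clusters[-best$q]
    ids <- ids[-best$q]
  }
  list(merge = merges, height = heights, members = member_sets)
}

# alternating least squares to convergence, used as a factorization oracle
oracle_als <- function(ti, tj, r, n, m, D, reg, iters = 500, seed = 99) {
  set.seed(seed)
  U <- matrix(rnorm(n * D, 0, 0.1), n, D)
  V <- matrix(rnorm(m * D, 0, 0.1), m, D)
  for (it in seq_len(iters)) {
    for (i in seq_len(n)) {
      sel <- which(ti == i)
      if (!length(sel)) next
      Vi <- V[tj[sel], , drop = FALSE]
      U[i, ] <- solve(crossprod(Vi) + reg * diag(D), crossprod(Vi, r[sel]))
    }
    for (j in seq_len(m)) {
      sel <- which(tj == j)
      if (!length(sel)) next
      Uj <- U[ti[sel], , drop = FALSE]
      V[j, ] <- solve(crossprod(Uj) + reg * diag(D), crossprod(Uj, r[sel]))
    }
  }
  list(U = U, V = V)
}
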