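#' PMF hyperparameter configuration
#'
#' Settings for a single probabilistic matrix factorization fit of the
#' binary interaction matrix. The binary matrix carries no explicit
#' negatives, so unobserved cells are negative-sampled at \code{neg_ratio}
#' times the number of positives (seeded, drawn once per fit so the
#' regularized squared-error objective is a fixed function minimized by
#' gradient descent).
#'
#' @param latent_dim number of latent factors D (>= 1).
#' @param reg_u,reg_v nonnegative L2 regularization weights on the drug and
#'   target factor matrices.
#' @param learn_rate initial gradient-descent step size; steps that would
#'   increase the objective are halved until accepted.
#' @param max_iter maximum number of iterations.
#' @param tol convergence threshold on the absolute change in objective.
#' @param seed integer seed controlling initialization and negative sampling.
#' @param neg_ratio negatives sampled per positive.
#' @return a list of class \code{pmf_config}.
#' @export
pmf_config <- function(latent_dim = 20L, reg_u = 0.1, reg_v = 0.1,
                       learn_rate = 0.01, max_iter = 500L, tol = 1e-6,
                       seed = 1L, neg_ratio = 1) {
  cfg <- list(
    latent_dim = check_count(latent_dim, "latent_dim"),
    reg_u = check_scalar(reg_u, "reg_u", min = 0),
    reg_v = check_scalar(reg_v, "reg_v", min = 0),
    learn_rate = check_scalar(learn_rate, "learn_rate", min = 1e-12),
    max_iter = check_count(max_iter, "max_iter"),
    tol = check_scalar(tol, "tol", min = 0),
    seed = check_count(seed, "seed", min = -.Machine$integer.max),
    neg_ratio = check_scalar(neg_ratio, "neg_ratio", min = 0)
  )
  class(cfg) <- "pmf_config"
  cfg
}

# seeded draw of unobserved cells, as linear indices
sample_negatives <- function(R, n_neg) {
  n <- length(R$drugs); m <- length(R$targets)
  obs <- pair_keys(R$pairs, n)
  cand <- setdiff(seq_len(n * m), obs)
  sample(cand, min(n_neg, length(cand)))
}

#' Fit a probabilistic matrix factorization model
#'
#' Factorizes the binary drug-target matrix as \eqn{R \approx U V^T} by
#' minimizing the regularized squared error over observed positives plus
#' seeded sampled negatives,
#' \deqn{\sum_{(i,j)} (R_{ij} - U_i \cdot V_j)^2 + \lambda_U \|U\|^2 +
#'   \lambda_V \|V\|^2,}
#' with i.i.d. Normal(0, 0.1) initialization and full-batch gradient descent
#' with step halving, so the objective is non-increasing across accepted
#' iterations and the result is bit-identical for a given seed.
#'
#' @param R a \code{\link{dti_matrix}}.
#' @param config a \code{\link{pmf_config}}.
#' @return a list of class \code{pmf_factors}: \code{U} (drugs x D, row
#'   names drug ids), \code{V} (targets x D), \code{config},
#'   \code{final_objective}, \code{n_iter}, \code{objective_trace}.
#' @export
pmf_fit <- function(R, config = pmf_config()) {
  stopifnot(inherits(R, "dti_matrix"), inherits(config, "pmf_config"))
  if (nrow(R$pairs) < 1L && config$neg_ratio == 0) {
    stop("no training cells: empty matrix and neg_ratio = 0", call. = FALSE)
  }
  n <- length(R$drugs); m <- length(R$targets); D <- config$latent_dim
  with_seed(config$seed, {
    U <- matrix(stats::rnorm(n * D, 0, 0.1), n, D, dimnames = list(R$drugs, NULL))
    V <- matrix(stats::rnorm(m * D, 0, 0.1), m, D, dimnames = list(R$targets, NULL))
    npos <- nrow(R$pairs)
    n_neg <- max(if (npos == 0L) 1L else 0L, round(config$neg_ratio * npos))
    neg <- if (n_neg > 0L) sample_negatives(R, n_neg) else integer(0)
    ti <- c(R$pairs[, 1L], (neg - 1L) %% n + 1L)
    tj <- c(R$pairs[, 2L], (neg - 1L) %/% n + 1L)
    r <- c(rep(1, npos), rep(0, length(neg)))

    objective <- function(U, V) {
      e <- r - rowSums(U[ti, , drop = FALSE] * V[tj, , drop = FALSE])
      sum(e * e) + config$reg_u * sum(U * U) + config$reg_v * sum(V * V)
    }
    obj <- objective(U, V)
    trace <- numeric(config$max_iter + 1L)
    trace[1L] <- obj
    it <- 0L
    for (it in seq_len(config$max_iter)) {
      e <- r - rowSums(U[ti, , drop = FALSE] * V[tj, , drop = FALSE])
      E <- Matrix::sparseMatrix(i = ti, j = tj, x = e, dims = c(n, m))
      gU <- -2 * as.matrix(E %*% V) + 2 * config$reg_u * U
      gV <- -2 * as.matrix(Matrix::crossprod(E, U)) + 2 * config$reg_v * V
      step <- config$learn_rate
      repeat {
        U2 <- U - step * gU
        V2 <- V - step * gV
        o2 <- objective(U2, V2)
        if (!is.finite(o2)) {
          stop("PMF objective diverged (non-finite); reduce learn_rate",
               call. = FALSE)
        }
        if (o2 <= obj) break
        step <- step / 2
        if (step < 1e-14) { U2 <- U; V2 <- V; o2 <- obj; break }
      }
      converged <- (obj - o2) < config$tol
      U <- U2; V <- V2; obj <- o2
      trace[it + 1L] <- obj
      if (converged) break
    }
    structure(list(U = U, V = V, config = config, final_objective = obj,
                   n_iter = it, objective_trace = trace[seq_len(it + 1L)]),
              class = "pmf_factors")
  })
}

#' @export
print.pmf_factors <- function(x, ...) {
  cat(sprintf("<pmf_factors> %d drugs x %d targets, D = %d, objective %.4g after %d iterations\n",
              nrow(x$U), nrow(x$V), x$config$latent_dim, x$final_objective, x$n_iter))
  invisible(x)
}

#' Predicted association scores
#'
#' Raw dot-product scores \eqn{U V^T} for every drug-target cell. No
#' squashing is applied: downstream stages use only the rank order.
#'
#' @param factors a \code{\link{pmf_fit}} result.
#' @return numeric drugs x targets matrix with id dimnames.
#' @export
predict_scores <- function(factors) {
  stopifnot(inherits(factors, "pmf_factors"))
  factors$U %*% t(factors$V)
}

#' Top-k candidate drugs for one target
#'
#' Ranks drugs by descending predicted score for the query target, removes
#' drugs already known to bind it, and returns the first \code{k}. Score
#' ties are broken by ascending drug id so the ranking is deterministic.
#'
#' @param scores score matrix from \code{\link{predict_scores}}.
#' @param target_id column (target) id to rank against.
#' @param k number of candidates to return (>= 0).
#' @param exclude drug ids to drop before ranking (the known-ligand set).
#' @return character vector of at most \code{k} drug ids.
#' @export
rank_candidates <- function(scores, target_id, k, exclude = character(0)) {
  j <- match(target_id, colnames(scores))
  if (is.na(j)) stop(sprintf("unknown target id: %s", target_id), call. = FALSE)
  k <- check_count(k, "k", min = 0L)
  s <- scores[, j]
  s <- s[!(names(s) %in% exclude)]
  if (k == 0L || length(s) == 0L) return(character(0))
  ord <- order(-s, names(s), method = "radix")
  names(s)[ord][seq_len(min(k, length(s)))]
}

#' Held-out ranking AUC
#'
#' Probability that a randomly chosen withheld true association outscores a
#' randomly chosen sampled negative cell, computed by exact pairwise
#' comparison (ties count one half) -- the exact Wilcoxon/Mann-Whitney
#' statistic, not a trapezoid approximation.
#'
#' @param factors a \code{\link{pmf_fit}} result.
#' @param hidden_positives data.frame with columns \code{drug}, \code{target}
#'   (ids) of withheld true associations, disjoint from the training set.
#' @param sampled_negatives data.frame of the same shape for negative cells.
#' @return AUC in [0, 1].
#' @export
heldout_auc <- function(factors, hidden_positives, sampled_negatives) {
  stopifnot(inherits(factors, "pmf_factors"))
  if (NROW(hidden_positives) == 0L) stop("empty hidden-positive set", call. = FALSE)
  if (NROW(sampled_negatives) == 0L) stop("empty negative set", call. = FALSE)
  score_pairs <- function(p) {
    i <- match(as.character(p$drug), rownames(factors$U))
    j <- match(as.character(p$target), rownames(factors$V))
    if (anyNA(i) || anyNA(j)) stop("pair ids not in the factor registries", call. = FALSE)
    rowSums(factors$U[i, , drop = FALSE] * factors$V[j, , drop = FALSE])
  }
  sp <- score_pairs(hidden_positives)
  sn <- score_pairs(sampled_negatives)
  rk <- rank(c(sp, sn))  # midranks: ties contribute 1/2
  (sum(rk[seq_along(sp)]) - length(sp) * (length(sp) + 1) / 2) /
    (length(sp) * length(sn))
}

#' Serialize latent factors to a text dump
#'
#' Two-block tab-separated dump (drug block then target block) preceded by a
#' config header, written with full double precision so that
#' \code{\link{read_factors}} round-trips exactly.
#'
#' @param factors a \code{\link{pmf_fit}} result.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_factors <- function(factors, path) {
  stopifnot(inherits(factors, "pmf_factors"))
  con <- file(path, "w")
  on.exit(close(con))
  cfg <- factors$config
  writeLines(sprintf("#config\t%s", paste(
    sprintf("%s=%s", names(unclass(cfg)),
            vapply(unclass(cfg), function(v) sprintf("%.17g", v), "")),
    collapse = "\t")), con)
  writeLines(sprintf("#objective\t%.17g\t%d", factors$final_objective, factors$n_iter), con)
  dump_block <- function(tag, M) {
    writeLines(sprintf("#%s\t%d\t%d", tag, nrow(M), ncol(M)), con)
    writeLines(paste(rownames(M),
                     apply(M, 1L, function(v) paste(sprintf("%.17g", v), collapse = "\t")),
                     sep = "\t"), con)
  }
  dump_block("drugs", factors$U)
  dump_block("targets", factors$V)
  invisible(path)
}

#' Read latent factors written by \code{\link{write_factors}}
#'
#' @param path path to the dump.
#' @return a \code{pmf_factors} object.
#' @export
read_factors <- function(path) {
  lines <- readLines(path)
  cfg_fields <- strsplit(sub("^#config\t", "", lines[1L]), "\t")[[1L]]
  kv <- do.call(rbind, strsplit(cfg_fields, "=", fixed = TRUE))
  vals <- as.numeric(kv[, 2L])
  names(vals) <- kv[, 1L]
  cfg <- pmf_config(latent_dim = vals["latent_dim"], reg_u = vals["reg_u"],
                    reg_v = vals["reg_v"], learn_rate = vals["learn_rate"],
                    max_iter = vals["max_iter"], tol = vals["tol"],
                    seed = vals["seed"], neg_ratio = vals["neg_ratio"])
  objline <- strsplit(lines[2L], "\t")[[1L]]
  parse_block <- function(at) {
    hdr <- strsplit(lines[at], "\t")[[1L]]
    nr <- as.integer(hdr[2L]); nc <- as.integer(hdr[3L])
    rows <- strsplit(lines[at + seq_len(nr)], "\t")
    M <- t(vapply(rows, function(f) as.numeric(f[-1L]), numeric(nc)))
    if (nc == 1L) M <- matrix(M, ncol = 1L)
    rownames(M) <- vapply(rows, `[[`, "", 1L)
    list(M = M, next_at = at + nr + 1L)
  }
  b1 <- parse_block(3L)
  b2 <- parse_block(b1$next_at)
  structure(list(U = b1$M, V = b2$M, config = cfg,
                 final_objective = as.numeric(objline[2L]),
                 n_iter = as.integer(objline[3L]),
                 objective_trace = NULL),
            class = "pmf_factors")
}
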