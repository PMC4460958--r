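test_that("regularization drives factors to zero with no positive signal", {
  # all training labels are 0 (only sampled negatives), reg > 0
  R <- dti_matrix(sprintf("d%d", 1:6), sprintf("t%d", 1:4),
                  matrix(integer(0), 0, 2))
  fit <- pmf_fit(R, pmf_config(latent_dim = 2, max_iter = 400, neg_ratio = 1,
                               learn_rate = 0.05, seed = 3))
  expect_lt(max(abs(predict_scores(fit))), 0.01)
})

test_that("fits are bit-identical for a given seed", {
  planted <- make_planted_dti(n = 30, m = 12, D_true = 2, density = 0.2,
                              n_hidden = 0, seed = 5)
  f1 <- pmf_fit(planted$R, fast_pmf(seed = 11))
  f2 <- pmf_fit(planted$R, fast_pmf(seed = 11))
  expect_identical(f1$U, f2$U)
  expect_identical(f1$V, f2$V)
  f3 <- pmf_fit(planted$R, fast_pmf(seed = 12))
  expect_false(identical(f1$U, f3$U))
})

test_that("objective is non-increasing and divergence is caught", {
  planted <- make_planted_dti(n = 40, m = 15, D_true = 3, density = 0.15,
                              n_hidden = 0, seed = 2)
  fit <- pmf_fit(planted$R, fast_pmf(seed = 1))
  expect_true(all(diff(fit$objective_trace) <= 1e-12))
  expect_true(all(is.finite(fit$U)), all(is.finite(fit$V)))
})

test_that("an exactly rank-1 matrix is reconstructed as well as an ALS oracle", {
  # outer product of binary membership vectors: exactly rank-1, so a D = 1
  # model can drive the training error to the regularization floor
  u <- c(1, 1, 0, 1, 0, 1, 1, 0)
  v <- c(1, 0, 1, 1, 0, 1)
  pos <- which(outer(u, v) == 1, arr.ind = TRUE)
  R <- dti_matrix(sprintf("d%d", 1:8), sprintf("t%d", 1:6), pos)
  cfg <- pmf_config(latent_dim = 1, reg_u = 0.01, reg_v = 0.01,
                    learn_rate = 0.05, max_iter = 2000, tol = 1e-12, seed = 9)
  fit <- pmf_fit(R, cfg)
  scores <- predict_scores(fit)

  # mirror the fit's seeded negative draw (init consumes 14 normals first)
  n <- 8L; m <- 6L
  set.seed(9)
  rnorm((n + m) * 1L, 0, 0.1)
  obs_lin <- (R$pairs[, 2] - 1) * n + R$pairs[, 1]
  negs <- sample(setdiff(seq_len(n * m), obs_lin), nrow(R$pairs))
  ti <- c(R$pairs[, 1], (negs - 1) %% n + 1)
  tj <- c(R$pairs[, 2], (negs - 1) %/% n + 1)
  r <- c(rep(1, nrow(R$pairs)), rep(0, length(negs)))
  train_rmse <- sqrt(mean((scores[cbind(ti, tj)] - r)^2))
  expect_lte(train_rmse, 0.05)

  # ALS oracle on the same training cells reaches a comparable fit
  als <- oracle_als(ti, tj, r, n, m, D = 1, reg = 0.01)
  als_rmse <- sqrt(mean(((als$U %*% t(als$V))[cbind(ti, tj)] - r)^2))
  expect_lte(train_rmse, als_rmse + 0.02)
})

test_that("held-out positives outscore held-out negatives on planted data", {
  planted <- make_planted_dti(n = 80, m = 25, D_true = 3, density = 0.1,
                              n_hidden = 10, seed = 21)
  fit <- pmf_fit(planted$R, fast_pmf(seed = 4))
  neg <- sample_eval_negatives(planted, n_neg = 100, seed = 31)
  auc <- heldout_auc(fit, planted$hidden, neg)
  expect_gt(auc, 0.7)
})

test_that("scores are invariant to drug row permutation", {
  planted <- make_planted_dti(n = 25, m = 10, D_true = 2, density = 0.2,
                              n_hidden = 0, seed = 8)
  fit <- pmf_fit(planted$R, fast_pmf(seed = 2))
  s <- predict_scores(fit)
  perm <- rev(seq_along(planted$R$drugs))
  Rp <- dti_matrix(planted$R$drugs[perm], planted$R$targets,
                   cbind(match(planted$R$pairs[, 1], perm), planted$R$pairs[, 2]))
  # same seed gives different draws per cell ordering, so compare geometry:
  # un-permuting recovers the same object when U rows are permuted directly
  fit_perm <- fit
  fit_perm$U <- fit$U[perm, , drop = FALSE]
  sp <- predict_scores(fit_perm)
  expect_identical(sp[planted$R$drugs, ], s[planted$R$drugs, ])
  expect_true(all(dim(Rp) == dim(planted$R)))
})

test_that("rank_candidates orders by score with drug-id tie-break", {
  scores <- matrix(c(0.9, 0.9, 0.1), 3, 1,
                   dimnames = list(c("db", "da", "dc"), "t1"))
  expect_equal(rank_candidates(scores, "t1", 2), c("da", "db"))
  expect_equal(rank_candidates(scores, "t1", 0), character(0))
  expect_equal(rank_candidates(scores, "t1", 5), c("da", "db", "dc"))
  expect_equal(rank_candidates(scores, "t1", 2, exclude = c("da", "db")), "dc")
  expect_error(rank_candidates(scores, "t9", 2), "unknown target")
})

test_that("heldout_auc matches exact pairwise counting", {
  mk_factors <- function(scores_by_drug) {
    # one target with unit factor; drug factor = desired score
    structure(list(
      U = matrix(scores_by_drug, ncol = 1,
                 dimnames = list(names(scores_by_drug), NULL)),
      V = matrix(1, 1, 1, dimnames = list("t", NULL)),
      config = pmf_config(latent_dim = 1)), class = "pmf_factors")
  }
  fac <- mk_factors(c(p1 = 0.8, p2 = 0.3, n1 = 0.5, n2 = 0.1))
  pos <- data.frame(drug = c("p1", "p2"), target = "t")
  neg <- data.frame(drug = c("n1", "n2"), target = "t")
  expect_equal(heldout_auc(fac, pos, neg), 0.75)
  expect_equal(heldout_auc(fac, pos, neg),
               oracle_auc(c(0.8, 0.3), c(0.5, 0.1)))

  # separation and all-tie conventions
  fac2 <- mk_factors(c(p1 = 1, p2 = 1, n1 = 0, n2 = 0))
  expect_equal(heldout_auc(fac2, pos, neg), 1.0)
  fac3 <- mk_factors(c(p1 = 0.4, p2 = 0.4, n1 = 0.4, n2 = 0.4))
  expect_equal(heldout_auc(fac3, pos, neg), 0.5)
  expect_error(heldout_auc(fac, pos[0, ], neg), "empty")

  # random score sets, including ties, agree with the double loop
  for (s in 1:5) {
    set.seed(s)
    sp <- round(runif(7), 1)
    sn <- round(runif(9), 1)
    fac <- mk_factors(stats::setNames(c(sp, sn),
                                      c(sprintf("p%d", 1:7), sprintf("n%d", 1:9))))
    got <- heldout_auc(fac,
                       data.frame(drug = sprintf("p%d", 1:7), target = "t"),
                       data.frame(drug = sprintf("n%d", 1:9), target = "t"))
    expect_equal(got, oracle_auc(sp, sn))
  }
})

test_that("factor dumps round-trip exactly", {
  planted <- make_planted_dti(n = 15, m = 8, D_true = 2, density = 0.2,
                              n_hidden = 0, seed = 13)
  fit <- pmf_fit(planted$R, pmf_config(latent_dim = 3, max_iter = 50, seed = 2))
  path <- withr::local_tempfile(fileext = ".txt")
  write_factors(fit, path)
  back <- read_factors(path)
  expect_identical(back$U, fit$U)
  expect_identical(back$V, fit$V)
  expect_identical(back$final_objective, fit$final_objective)
  expect_identical(unclass(back$config)[c("latent_dim", "reg_u", "seed")],
                   unclass(fit$config)[c("latent_dim", "reg_u", "seed")])
})
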