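test_that("planted networks honour their size contract", {
  planted <- make_planted_dti(n = 200, m = 50, D_true = 5, density = 0.05,
                              n_hidden = 20, seed = 3)
  n_obs <- nrow(planted$R$pairs)
  expect_true(abs(n_obs - 480) <= 50)   # 0.05 * 10000 - 20 withheld
  expect_equal(nrow(planted$hidden), 20L)
  # hidden pairs are disjoint from training positives
  obs_keys <- paste(planted$R$drugs[planted$R$pairs[, 1]],
                    planted$R$targets[planted$R$pairs[, 2]])
  hid_keys <- paste(planted$hidden$drug, planted$hidden$target)
  expect_length(intersect(obs_keys, hid_keys), 0L)
  # density within 10% of request
  expect_lt(abs((n_obs + 20) / (200 * 50) - 0.05) / 0.05, 0.1)
})

test_that("planted networks are pure functions of their seed", {
  a <- make_planted_dti(n = 40, m = 12, D_true = 2, density = 0.15,
                        n_hidden = 5, seed = 9)
  b <- make_planted_dti(n = 40, m = 12, D_true = 2, density = 0.15,
                        n_hidden = 5, seed = 9)
  expect_identical(a$R$pairs, b$R$pairs)
  expect_identical(a$hidden, b$hidden)
  expect_identical(a$U_true, b$U_true)
  c <- make_planted_dti(n = 40, m = 12, D_true = 2, density = 0.15,
                        n_hidden = 5, seed = 10)
  expect_false(identical(a$R$pairs, c$R$pairs))
})

test_that("saturated and infeasible planted configurations behave", {
  sat <- make_planted_dti(n = 6, m = 4, D_true = 2, density = 1,
                          n_hidden = 3, seed = 1)
  expect_equal(nrow(sat$R$pairs) + 3L, 24L)
  expect_error(make_planted_dti(n = 10, m = 5, D_true = 8, density = 0.5,
                                n_hidden = 0), "min\\(n, m\\)")
  expect_error(make_planted_dti(n = 10, m = 5, D_true = 2, density = 0.1,
                                n_hidden = 10), "n_hidden")
})

test_that("label noise perturbs roughly the requested fraction of positives", {
  clean <- make_planted_dti(n = 100, m = 30, D_true = 3, density = 0.1,
                            n_hidden = 0, seed = 4)
  noisy <- make_planted_dti(n = 100, m = 30, D_true = 3, density = 0.1,
                            n_hidden = 0, noise_rate = 0.2, seed = 4)
  keys <- function(p) pmfrepurpose:::pair_keys(p$R$pairs, 100)
  flipped_out <- length(setdiff(keys(clean), keys(noisy)))
  expect_gt(flipped_out, 0.1 * nrow(clean$R$pairs))
  expect_lt(flipped_out, 0.3 * nrow(clean$R$pairs))
})

test_that("drug libraries plant families with the advertised similarity", {
  taus <- numeric(10)
  for (s in 1:10) {
    lib <- make_drug_library(n_molecules = 60, n_families = 4, seed = s)
    fam <- lib$families
    within <- c()
    for (f in unique(fam)) {
      ids <- names(fam)[fam == f]
      pairs <- utils::combn(ids, 2)
      within <- c(within, apply(pairs, 2, function(p) {
        tanimoto(lib$descriptors[[p[1]]]$fp_structural,
                 lib$descriptors[[p[2]]]$fp_structural)
      }))
    }
    taus[s] <- mean(within)
  }
  expect_gte(mean(taus), 0.75)

  # between-family similarity stays low
  lib <- make_drug_library(n_molecules = 40, n_families = 4, seed = 3)
  f1 <- names(lib$families)[lib$families == 1][1:4]
  f2 <- names(lib$families)[lib$families == 2][1:4]
  between <- outer(f1, f2, Vectorize(function(a, b) {
    tanimoto(lib$descriptors[[a]]$fp_structural, lib$descriptors[[b]]$fp_structural)
  }))
  expect_lt(mean(between), 0.3)
})

test_that("degenerate libraries and parameter violations are handled", {
  clones <- make_drug_library(n_molecules = 6, n_families = 2, mutation = 0,
                              seed = 2)
  ids <- names(clones$families)[clones$families == 1]
  expect_equal(combo_score(clones$descriptors[[ids[1]]],
                           clones$descriptors[[ids[2]]]), 2)
  single <- make_drug_library(n_molecules = 3, n_families = 3, seed = 2)
  expect_equal(unname(table(single$families)), array(c(1L, 1L, 1L)))
  expect_error(make_drug_library(tau_in = 0.3, tau_out = 0.5), "tau_in")
  expect_error(make_drug_library(fp_length = 16), "fp_length")
})

test_that("planted scenarios couple latent and fingerprint families", {
  sc <- make_planted_scenario(seed = 8)
  # hidden drugs lack the query-target edge, family knowns have it
  expect_false(any(sc$hidden_ids %in% known_drugs(sc$R, sc$target_id)))
  expect_true(all(sc$approved_known_ids %in% known_drugs(sc$R, sc$target_id)))
  # the illicit member is a known ligand but not approved
  illicit <- setdiff(sc$known_ids, sc$approved_known_ids)
  expect_length(illicit, 1L)
  expect_equal(as.character(sc$metadata$status[sc$metadata$id == illicit]),
               "illicit")
  # fingerprint family: hidden drugs score >= 1.5 against the knowns
  for (h in sc$hidden_ids) {
    best <- max(vapply(sc$approved_known_ids, function(k) {
      combo_score(sc$descriptors[[h]], sc$descriptors[[k]])
    }, 0))
    expect_gte(best, 1.5)
  }
  # decoys do not resemble the known family
  for (d in sc$decoy_ids) {
    best <- max(vapply(sc$approved_known_ids, function(k) {
      combo_score(sc$descriptors[[d]], sc$descriptors[[k]])
    }, 0))
    expect_lt(best, 1.5)
  }
  # determinism
  sc2 <- make_planted_scenario(seed = 8)
  expect_identical(sc$R$pairs, sc2$R$pairs)
  expect_identical(sc$descriptors[[1]], sc2$descriptors[[1]])
})

test_that("scenario files round-trip through the pipeline readers", {
  sc <- make_planted_scenario(seed = 12)
  dir <- withr::local_tempdir()
  paths <- write_scenario(sc, dir)
  R <- read_interactions(paths[["interactions"]])
  # the edge list carries exactly the observed associations (drugs with no
  # edges cannot appear in it, and registries reorder by first appearance)
  edge_keys <- function(x) sort(paste(x$drugs[x$pairs[, 1]],
                                      x$targets[x$pairs[, 2]]))
  expect_identical(edge_keys(R), edge_keys(sc$R))
  meta <- read_drug_metadata(paths[["metadata"]])
  expect_equal(meta$id, sc$metadata$id)
  mols <- read_molecules(paths[["molecules"]], sc$sim_config)
  expect_identical(mols[["d0001"]]$fp_structural,
                   sc$descriptors[["d0001"]]$fp_structural)
})
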