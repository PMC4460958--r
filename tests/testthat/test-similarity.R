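test_that("tanimoto follows its closed form including the empty convention", {
  expect_equal(tanimoto(c(1, 1, 0, 1), c(1, 1, 0, 1)), 1)
  expect_equal(tanimoto(c(1, 1, 0, 0), c(0, 0, 1, 1)), 0)
  expect_equal(tanimoto(c(1, 1, 0, 0), c(1, 0, 1, 0)), 1 / 3)
  expect_equal(tanimoto(c(0, 0), c(0, 0)), 1)
  expect_error(tanimoto(c(1, 0), c(1, 0, 1)), "length mismatch")
})

test_that("combo score is the sum of component Tanimotos and is symmetric", {
  mk <- function(id, fs, ff) mol_descriptor(id, fs, ff, "hex")
  a <- mk("a", c(1, 1, 0, 0), c(1, 0, 0, 0))
  b <- mk("b", c(1, 0, 1, 0), c(1, 1, 0, 0))
  expect_equal(combo_score(a, b), 1 / 3 + 1 / 2)
  expect_equal(combo_score(a, b), combo_score(b, a))
  expect_equal(combo_score(a, a), 2)
  dis <- mk("c", c(0, 0, 1, 1), c(0, 1, 1, 1))
  expect_equal(combo_score(a, dis), 0)
  ob <- structure(list(drug_id = "x", fp_structural = c(1, 1, 0, 0),
                       fp_feature = c(1, 0, 0, 0), scorer = "openbabel"),
                  class = "mol_descriptor")
  expect_error(combo_score(a, ob), "different scorer")
})

test_that("hex featurization is deterministic and validates input", {
  cfg <- similarity_config(fp_length = 8, scorer = "hex")
  d1 <- featurize("a1b2", cfg, "m1")   # 16 bits: 8 structural + 8 feature
  d2 <- featurize("A1B2", cfg, "m1")   # case-insensitive hex
  expect_identical(d1$fp_structural, d2$fp_structural)
  expect_identical(d1$fp_feature, d2$fp_feature)
  expect_equal(d1$fp_structural, c(1, 0, 1, 0, 0, 0, 0, 1))
  expect_error(featurize("a1", cfg, "m2"), "m2")
  expect_error(featurize("00a1", cfg, "m3"), "empty fingerprint")
})

test_that("constant structural component shifts combo scores predictably", {
  cfg <- similarity_config(fp_length = 16, scorer = "hex")
  set.seed(3)
  descs <- lapply(1:4, function(i) {
    mol_descriptor(paste0("m", i), rbinom(16, 1, 0.4) | c(1, rep(0, 15)),
                   rbinom(16, 1, 0.4) | c(1, rep(0, 15)), "hex")
  })
  const1 <- lapply(descs, function(d) {
    d$fp_structural <- rep(1L, 16)
    d
  })
  for (i in 1:3) for (j in (i + 1):4) {
    orig <- combo_score(descs[[i]], descs[[j]])
    shifted <- combo_score(const1[[i]], const1[[j]])
    s_orig <- tanimoto(descs[[i]]$fp_structural, descs[[j]]$fp_structural)
    expect_equal(shifted, orig + (1 - s_orig))
  }
})

test_that("reference expansion recovers a planted family and respects bounds", {
  lib <- make_drug_library(n_molecules = 40, n_families = 4, seed = 2)
  fam1 <- names(lib$families)[lib$families == 1]
  known <- lib$descriptors[fam1[1:2]]
  ref <- expand_reference(known, lib$descriptors, threshold = 1.5)
  # the family is recovered, unrelated families are excluded
  expect_true(all(fam1 %in% ref))
  others <- setdiff(names(lib$descriptors), fam1)
  expect_lte(length(intersect(ref, others)) / length(others), 0.05)

  # library == known set returns the known set (self-match at 2.0)
  expect_setequal(expand_reference(known, known, threshold = 2), names(known))
  expect_error(expand_reference(list(), lib$descriptors), "empty known")
})

test_that("similarity filtering ranks by max combo score and thresholds", {
  lib <- make_drug_library(n_molecules = 30, n_families = 3, seed = 4)
  fam1 <- names(lib$families)[lib$families == 1]
  ref <- fam1[1:3]
  hits <- c(fam1[4:5], names(lib$families)[lib$families == 2][1:2])
  out <- similarity_filter(hits, lib$descriptors, ref, lib$config)
  # family-1 hits survive the 1.5 cut, family-2 hits do not
  expect_setequal(out$drug_id, fam1[4:5])
  expect_true(all(diff(out$score) <= 0))
  expect_true(all(out$score >= 1.5))

  # identical molecule is retained with score 2 at any threshold <= 2
  out2 <- similarity_filter(ref[1], lib$descriptors, ref, lib$config)
  expect_equal(out2$score, 2)
  expect_error(similarity_filter(c("nope"), lib$descriptors, ref, lib$config),
               "nope")
})

test_that("filtered hits shrink monotonically in the combo threshold", {
  lib <- make_drug_library(n_molecules = 30, n_families = 3, seed = 9)
  hits <- names(lib$descriptors)[1:15]
  ref <- names(lib$descriptors)[16:30]
  prev <- Inf
  for (thr in c(0, 0.5, 1, 1.5, 1.9, 2)) {
    cfg <- similarity_config(combo_threshold = thr, fp_length = 256, scorer = "hex")
    out <- similarity_filter(hits, lib$descriptors, ref, cfg)
    expect_lte(nrow(out), prev)
    prev <- nrow(out)
  }
})

test_that("descriptor caches round-trip exactly", {
  lib <- make_drug_library(n_molecules = 10, n_families = 2, seed = 5)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_descriptors(lib$descriptors, path)
  back <- read_descriptors(path)
  expect_equal(names(back), names(lib$descriptors))
  for (id in names(back)) {
    expect_identical(back[[id]]$fp_structural, lib$descriptors[[id]]$fp_structural)
    expect_identical(back[[id]]$fp_feature, lib$descriptors[[id]]$fp_feature)
  }
})

test_that("hex molecule files round-trip through read_molecules", {
  lib <- make_drug_library(n_molecules = 8, n_families = 2, fp_length = 64, seed = 6)
  path <- withr::local_tempfile(fileext = ".txt")
  write_molecules(lib$descriptors, path)
  back <- read_molecules(path, similarity_config(fp_length = 64, scorer = "hex"))
  expect_equal(names(back), names(lib$descriptors))
  expect_identical(back[[3]]$fp_structural, lib$descriptors[[3]]$fp_structural)
})

test_that("SMILES featurization canonicalizes and flags bad input", {
  skip_if_not_installed("ChemmineR")
  skip_if_not_installed("ChemmineOB")
  cfg <- similarity_config(scorer = "openbabel")
  ethanol1 <- featurize("CCO", cfg, "eth1")
  ethanol2 <- featurize("OCC", cfg, "eth2")
  expect_identical(ethanol1$fp_structural, ethanol2$fp_structural)
  expect_identical(ethanol1$fp_feature, ethanol2$fp_feature)
  benzene <- featurize("c1ccccc1", cfg, "benz")
  cyclohexane <- featurize("C1CCCCC1", cfg, "cyhex")
  expect_gte(sum(benzene$fp_structural != cyclohexane$fp_structural), 1)
  expect_equal(combo_score(ethanol1, ethanol2), 2)
  expect_error(featurize("xx((", cfg, "badmol"), "badmol")
})
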