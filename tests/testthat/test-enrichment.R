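test_that("hypergeometric tail handles boundary cases exactly", {
  expect_equal(hypergeom_tail(0, 5, 6, 20), 1)
  expect_equal(hypergeom_tail(4, 4, 4, 4), 1)   # only possible outcome
  expect_equal(hypergeom_tail(4, 5, 6, 20),
               (choose(6, 4) * choose(14, 1) + choose(6, 5)) / choose(20, 5))
  expect_equal(hypergeom_tail(4, 5, 6, 20), 0.013932, tolerance = 1e-4)
  expect_error(hypergeom_tail(5, 4, 6, 20), "inconsistent")
  expect_error(hypergeom_tail(2, 3, 25, 20), "inconsistent")
})

test_that("hypergeometric tail matches exhaustive enumeration for N <= 12", {
  for (N in c(4L, 7L, 10L, 12L)) {
    for (K in 0:N) {
      for (n_c in 1:N) {
        oracle <- oracle_hypergeom_all_x(n_c, K, N)
        for (x in 0:min(n_c, K)) {
          expect_equal(hypergeom_tail(x, n_c, K, N), unname(oracle[x + 1L]),
                       tolerance = 1e-12,
                       info = sprintf("x=%d n_c=%d K=%d N=%d", x, n_c, K, N))
        }
      }
    }
  }
})

test_that("a tight known-rich cluster is detected at alpha = 0.05", {
  U <- tight_cluster_latent(n = 20, n_tight = 5)
  known <- c(rownames(U)[1:5], "d12")  # 5 of 6 knowns packed together
  dend <- agglomerate(pairwise_distance(U, "euclidean"), "average")
  enr <- enriched_clusters(dend, known, alpha = 0.05, min_size = 3)
  expect_gte(nrow(enr), 1L)
  members <- attr(enr, "members")[[1L]]
  expect_true(all(rownames(U)[1:5] %in% members))
  expect_lte(enr$n_c[1L], 8L)  # the tight cluster region, not a diluted ancestor
  expect_lte(enr$q[1L], 0.05)
  expect_equal(enr$K[1L], 6L)
  expect_equal(enr$N[1L], 20L)
})

test_that("degenerate enrichment inputs behave as stated", {
  U <- tight_cluster_latent()
  dend <- agglomerate(pairwise_distance(U, "euclidean"), "average")
  # saturated universe: every leaf known, no cluster can be enriched
  sat <- enriched_clusters(dend, rownames(U), alpha = 0.05)
  expect_equal(nrow(sat), 0L)
  # impossible size bounds
  none <- enriched_clusters(dend, rownames(U)[1:4], min_size = 50)
  expect_equal(nrow(none), 0L)
  expect_error(enriched_clusters(dend, character(0)), "empty known")
  expect_error(enriched_clusters(dend, "not_a_leaf"), "not leaves")
})

test_that("returned clusters are disjoint maximal significant nodes", {
  U <- tight_cluster_latent(n = 24, n_tight = 6, seed = 11)
  known <- rownames(U)[1:5]
  dend <- agglomerate(pairwise_distance(U, "euclidean"), "average")
  enr <- enriched_clusters(dend, known, alpha = 0.05)
  mem <- attr(enr, "members")
  if (length(mem) >= 2L) {
    for (i in seq_along(mem)[-1L]) {
      expect_length(intersect(mem[[1L]], mem[[i]]), 0L)
    }
  }
  expect_true(all(enr$q <= 0.05))
  expect_true(all(enr$p <= enr$q + 1e-15))
})

test_that("enrichment tables export as CSV", {
  U <- tight_cluster_latent()
  dend <- agglomerate(pairwise_distance(U, "euclidean"), "average")
  enr <- enriched_clusters(dend, rownames(U)[1:4], alpha = 0.5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_enrichment(enr, path)
  back <- read.csv(path)
  expect_equal(nrow(back), nrow(enr))
  expect_true(all(c("members", "x", "n_c", "K", "N", "p", "q") %in% names(back)))
})

test_that("consensus intersects per-metric hits within the candidate universe", {
  expect_equal(consensus_hits(list(c("a", "b", "c"), c("b", "c", "d"),
                                   c("b", "c", "e")), letters[1:10]),
               c("b", "c"))
  expect_equal(consensus_hits(list(c("x", "y"), c("x", "y"), c("x", "y")),
                              c("x", "y")), c("x", "y"))
  expect_equal(consensus_hits(list(character(0), c("a"), c("a")), "a"),
               character(0))
  # restriction to the candidate universe
  expect_equal(consensus_hits(list(c("a", "k"), c("a", "k"), c("a", "k")), "a"),
               "a")
  # order-invariant, and contained in every input
  sets <- list(c("a", "b", "d"), c("b", "d", "e"), c("b", "c", "d"))
  got <- consensus_hits(sets, letters[1:5])
  expect_equal(got, consensus_hits(rev(sets), letters[1:5]))
  for (s in sets) expect_true(all(got %in% s))
})
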