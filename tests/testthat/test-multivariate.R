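random_nonneg_matrix <- function(seed, n, p) {
  set.seed(seed)
  m <- matrix(rexp(n * p) + 0.05, n, p)
  dimnames(m) <- list(paste0("g", seq_len(n)), paste0("c", seq_len(p)))
  m
}

test_that("CA reproduces a brute-force residual-SVD oracle", {
  m <- random_nonneg_matrix(1, 4, 5)
  ca <- correspondence_analysis(m)
  or <- oracle_ca(m)
  expect_equal(ca$total_inertia, or$total_inertia, tolerance = 1e-10)
  expect_equal(ca$inertia_fraction, or$inertia_fraction, tolerance = 1e-8)
  expect_equal(abs(ca$row_coords), abs(or$row_coords),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("CA total inertia equals chi-square over grand total", {
  m <- random_nonneg_matrix(2, 6, 8)
  ca <- correspondence_analysis(m)
  chi <- suppressWarnings(chisq.test(m))$statistic
  expect_equal(ca$total_inertia, unname(chi) / sum(m), tolerance = 1e-10)
})

test_that("CA symmetry and degeneracy behave as theory requires", {
  m <- random_nonneg_matrix(3, 5, 6)
  m[2, ] <- m[4, ]  # identical rows -> identical coordinates
  ca <- correspondence_analysis(m)
  expect_equal(ca$row_coords[2, ], ca$row_coords[4, ],
               ignore_attr = TRUE, tolerance = 1e-10)

  # rank-1 independence table has zero inertia and no axes
  indep <- outer(c(1, 2, 3), c(4, 1, 2, 3))
  dimnames(indep) <- list(paste0("r", 1:3), paste0("c", 1:4))
  ca0 <- correspondence_analysis(indep)
  expect_equal(ca0$total_inertia, 0, tolerance = 1e-12)
  expect_length(ca0$inertia_fraction, 0)
})

test_that("CA is invariant to row/column permutation up to axis sign", {
  m <- random_nonneg_matrix(4, 5, 7)
  ca <- correspondence_analysis(m)
  set.seed(99)
  pr <- sample(nrow(m))
  pc <- sample(ncol(m))
  ca_p <- correspondence_analysis(m[pr, pc])
  expect_equal(ca_p$inertia_fraction, ca$inertia_fraction,
               tolerance = 1e-10)
  expect_equal(abs(ca_p$row_coords[rownames(m), ]), abs(ca$row_coords),
               tolerance = 1e-8)
})

test_that("CA matches vegan's correspondence analysis", {
  skip_if_not_installed("vegan")
  m <- random_nonneg_matrix(5, 8, 10)
  ca <- correspondence_analysis(m)
  vg <- vegan::cca(m)
  expect_equal(ca$total_inertia, unname(vg$tot.chi), tolerance = 1e-8)
  expect_equal(ca$inertia_fraction[1:3],
               unname(vg$CA$eig[1:3] / vg$tot.chi), tolerance = 1e-8)
})

test_that("CA input validation: negatives, zero rows, zero columns", {
  m <- random_nonneg_matrix(6, 4, 5)
  m_neg <- m; m_neg[1, 1] <- -1
  expect_error(correspondence_analysis(m_neg), "non-negative")
  m_zr <- m; m_zr[2, ] <- 0
  expect_error(correspondence_analysis(m_zr), "all-zero row")
  m_zc <- m; m_zc[, 3] <- 0
  expect_warning(ca <- correspondence_analysis(m_zc), "all-zero column")
  expect_equal(nrow(ca$col_coords), 4)
})

test_that("average-linkage heights equal a naive O(n^3) oracle", {
  sim <- simulate_cds(synthetic_spec(n_seqs = 10, n_codons = 150,
                                     dirichlet_conc = 2, seed = 8))
  m <- rscu_matrix(sim$seqs)
  hc <- hierarchical_cluster(m)
  expect_equal(hc$height, oracle_average_linkage_heights(m),
               tolerance = 1e-10)
})

test_that("toy dendrograms merge at the expected heights", {
  m <- matrix(c(0, 0, 3, 4), 2, 2, byrow = TRUE,
              dimnames = list(c("a", "b"), NULL))
  hc <- hierarchical_cluster(m)
  expect_equal(hc$height, 5)  # single merge at the Euclidean distance

  m3 <- matrix(c(0, 0, 0, 0, 9, 9), 3, 2, byrow = TRUE,
               dimnames = list(c("a", "b", "c"), NULL))
  hc3 <- hierarchical_cluster(m3)
  expect_equal(hc3$height[1], 0)  # coincident pair first
  expect_error(hierarchical_cluster(m3[c(1, 1), ]), "unique")
})

test_that("cut_tree spans the k range and numbers clusters by appearance", {
  sim <- simulate_cds(synthetic_spec(n_seqs = 6, n_codons = 100, seed = 14))
  hc <- hierarchical_cluster(rscu_matrix(sim$seqs))
  expect_equal(unname(cut_tree(hc, 1)), rep(1L, 6))
  expect_equal(sort(unname(cut_tree(hc, 6))), 1:6)
  cl <- cut_tree(hc, 3)
  expect_equal(cl[[1]], 1L)  # first leaf defines cluster 1
  expect_error(cut_tree(hc, 0), "between")
  expect_error(cut_tree(hc, 7), "between")
})

test_that("planted three-population RSCU structure is recovered at k = 3", {
  pops <- lapply(c(-3, 0, 3), function(b) {
    simulate_cds(synthetic_spec(n_seqs = 6, n_codons = 600, beta = b,
                                dirichlet_conc = 400,
                                seed = 130 + round(10 * b)))$seqs
  })
  seqs <- c(p1 = pops[[1]], p2 = pops[[2]], p3 = pops[[3]])
  names(seqs) <- paste0(rep(c("p1", "p2", "p3"), each = 6), "_",
                        rep(1:6, 3))
  truth <- rep(1:3, each = 6)
  cl <- cut_tree(hierarchical_cluster(rscu_matrix(seqs)), 3)
  expect_true(same_partition(unname(cl), truth))
})

test_that("dendrograms export as readable Newick", {
  sim <- simulate_cds(synthetic_spec(n_seqs = 5, n_codons = 100, seed = 6))
  hc <- hierarchical_cluster(rscu_matrix(sim$seqs))
  f <- withr::local_tempfile(fileext = ".nwk")
  write_dendrogram_newick(hc, f)
  tr <- ape::read.tree(f)
  expect_setequal(tr$tip.label, names(sim$seqs))
})
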