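test_that("rscu matches hand-computed family ratios", {
  # Lys two-fold family with counts 3:1
  cc <- codon_counts(c(s = "AAAAAAAAAAAG"))
  r <- rscu(cc)
  expect_equal(r$values[["AAA"]], 1.5)
  expect_equal(r$values[["AAG"]], 0.5)

  # four-fold family used exclusively through one codon
  cc2 <- codon_counts(c(s = "GGAGGAGGA"))
  r2 <- rscu(cc2)
  expect_equal(r2$values[["GGA"]], 4)
  expect_equal(r2$values[["GGT"]], 0)
  expect_false("G" %in% r2$missing_families)
})

test_that("equal usage in every family gives RSCU 1 everywhere", {
  counts <- make_counts_template()
  counts[] <- 7L
  cc <- structure(list(counts = counts, n_skipped = 0L, source_ids = "x"),
                  class = "codon_count_table")
  r <- rscu(cc)
  expect_true(all(abs(r$values - 1) < 1e-12))
  expect_length(r$missing_families, 0)
})

test_that("rscu family sums equal family sizes and scale-invariance holds", {
  fams <- oracle_families()
  for (seed in 1:5) {
    cc <- random_count_table(seed)
    r <- rscu(cc)
    for (aa in names(fams)) {
      fam <- fams[[aa]]
      if (sum(cc$counts[fam]) > 0) {
        expect_equal(sum(r$values[fam]), length(fam), tolerance = 1e-9)
      }
    }
    cc3 <- cc
    cc3$counts <- cc3$counts * 3L
    expect_equal(rscu(cc3)$values, r$values)
  }
})

test_that("zero-observation families are zero-filled and flagged", {
  cc <- codon_counts(c(s = "AAAAAG"))  # only Lys observed
  r <- rscu(cc)
  expect_true("V" %in% r$missing_families)
  expect_true(all(r$values[c("GTA", "GTC", "GTG", "GTT")] == 0))
  expect_length(r$values, 59)
})

test_that("preferred codons take the family RSCU maximum with tie flags", {
  cc <- random_count_table(42)
  pc <- preferred_codons(rscu(cc))
  r <- rscu(cc)
  fams <- oracle_families()
  for (i in seq_len(nrow(pc))) {
    fam <- fams[[pc$aa[i]]]
    expect_equal(pc$rscu[i], max(r$values[fam]))
  }

  # exact tie -> alphabetically first, flagged
  counts <- make_counts_template()
  counts[c("AAA", "AAG")] <- 5L
  cc_tie <- structure(list(counts = counts, n_skipped = 0L,
                           source_ids = "x"), class = "codon_count_table")
  pc_tie <- preferred_codons(rscu(cc_tie))
  k <- pc_tie[pc_tie$aa == "K", ]
  expect_equal(k$codon, "AAA")
  expect_true(k$tie)

  # single observed codon in a family is preferred outright
  counts2 <- make_counts_template()
  counts2["GGA"] <- 4L
  cc_one <- structure(list(counts = counts2, n_skipped = 0L,
                           source_ids = "x"), class = "codon_count_table")
  pc_one <- preferred_codons(rscu(cc_one))
  expect_equal(pc_one$codon[pc_one$aa == "G"], "GGA")
  expect_false("K" %in% pc_one$aa)
})

test_that("enc hits its theoretical limits", {
  counts <- make_counts_template()
  counts[] <- 50L
  cc_eq <- structure(list(counts = counts, n_skipped = 0L,
                          source_ids = "x"), class = "codon_count_table")
  expect_equal(enc(cc_eq)$enc, 61)

  # exactly one codon used per family
  fams <- oracle_families()
  counts1 <- make_counts_template()
  for (fam in fams) counts1[fam[1]] <- 30L
  cc_one <- structure(list(counts = counts1, n_skipped = 0L,
                           source_ids = "x"), class = "codon_count_table")
  expect_equal(enc(cc_one)$enc, 20)
})

test_that("enc equals a first-principles homozygosity oracle", {
  for (seed in c(1, 7, 101)) {
    cc <- random_count_table(seed, lambda = 4)
    expect_equal(enc(cc)$enc, oracle_enc(cc$counts), tolerance = 1e-12)
  }
})

test_that("missing Ile class falls back to the 2-/4-fold mean", {
  sim <- simulate_cds(synthetic_spec(n_seqs = 1, n_codons = 300, seed = 2))
  cc <- codon_counts(sim$seqs)
  cc$counts[c("ATT", "ATC", "ATA")] <- 0L
  e <- enc(cc)
  expect_equal(e$f_bars[["3"]], (e$f_bars[["2"]] + e$f_bars[["4"]]) / 2)
  expect_true(e$enc >= 20 && e$enc <= 61)
})

test_that("expected ENC curve matches its closed form", {
  expect_equal(expected_enc(0.5), 60.5)
  expect_equal(expected_enc(0), 31)
  expect_equal(expected_enc(1), 32)
  expect_error(expected_enc(1.2), "\\[0, 1\\]")
  expect_error(expected_enc(-0.1), "\\[0, 1\\]")
})

test_that("stronger generator bias lowers mean ENC", {
  mean_enc <- vapply(c(8, 0.8, 0.15), function(conc) {
    sim <- simulate_cds(synthetic_spec(n_seqs = 8, n_codons = 400,
                                       dirichlet_conc = conc, seed = 31))
    mean(vapply(names(sim$seqs),
                function(id) enc(codon_counts(sim$seqs[id]))$enc,
                numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_enc) < 0))
})

test_that("rscu agrees with seqinr's codon usage index on real-style input", {
  sim <- simulate_cds(synthetic_spec(n_seqs = 1, n_codons = 500,
                                     beta = 0.8, seed = 13))
  seq <- sim$seqs[[1]]
  seq <- substr(seq, 1, nchar(seq) - 3)  # seqinr counts the stop codon
  r <- rscu(codon_counts(c(s = seq)))
  uco <- seqinr::uco(strsplit(tolower(seq), "")[[1]], index = "rscu")
  names(uco) <- toupper(names(uco))
  shared <- intersect(names(uco), names(r$values))
  expect_equal(r$values[shared], uco[shared], tolerance = 1e-9)
})
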