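# Independent oracles, written from first principles and kept free of
# the package's internal tables: the genetic code comes from Biostrings.

# amino acid -> codons with synonymous alternatives (DNA, standard code),
# Met/Trp/stops excluded; Leu/Ser/Arg intact.
oracle_families <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc) <- gsub("U", "T", names(gc))
  gc <- gc[gc != "*"]
  fams <- split(names(gc), gc)
  fams[lengths(fams) >= 2]
}

# Wright's Nc from a named codon-count vector, straight from the
# homozygosity definition.
oracle_enc <- function(counts) {
  fams <- oracle_families()
  f_by_class <- list(`2` = c(), `3` = c(), `4` = c(), `6` = c())
  for (aa in names(fams)) {
    x <- counts[fams[[aa]]]
    x[is.na(x)] <- 0
    n <- sum(x)
    if (n < 2) next
    f <- (n * sum((x / n)^2) - 1) / (n - 1)
    if (f > 0) {
      k <- as.character(length(fams[[aa]]))
      f_by_class[[k]] <- c(f_by_class[[k]], f)
    }
  }
  fb <- vapply(f_by_class, function(v) if (length(v)) mean(v) else NA_real_,
               numeric(1))
  if (is.na(fb[["3"]])) fb[["3"]] <- (fb[["2"]] + fb[["4"]]) / 2
  nc <- 2 + 9 / fb[["2"]] + 1 / fb[["3"]] + 5 / fb[["4"]] + 3 / fb[["6"]]
  min(nc, 61)
}

# Correspondence analysis by explicit element-wise construction of the
# standardized residual matrix, then SVD.
oracle_ca <- function(x) {
  p <- x / sum(x)
  r <- rowSums(p)
  cc <- colSums(p)
  s <- matrix(0, nrow(x), ncol(x))
  for (i in seq_len(nrow(x))) {
    for (j in seq_len(ncol(x))) {
      s[i, j] <- (p[i, j] - r[i] * cc[j]) / sqrt(r[i] * cc[j])
    }
  }
  sv <- svd(s)
  k <- min(dim(x)) - 1
  d <- sv$d[seq_len(k)]
  rowc <- sv$u[, seq_len(k), drop = FALSE] %*% diag(d, k) / sqrt(r)
  list(d = d, row_coords = rowc, total_inertia = sum(sv$d[seq_len(k)]^2),
       inertia_fraction = d^2 / sum(sv$d[seq_len(k)]^2))
}

# Naive O(n^3) unweighted average-linkage agglomeration over a
# precomputed Euclidean distance matrix; returns merge heights.
oracle_average_linkage_heights <- function(x) {
  d <- as.matrix(dist(x))
  clusters <- as.list(seq_len(nrow(x)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_len(length(clusters) - 1)) {
      for (j in seq.int(i + 1, length(clusters))) {
        h <- mean(d[clusters[[i]], clusters[[j]]])
        if (h < best[1] - 1e-12) best <- c(h, i, j)
      }
    }
    heights <- c(heights, best[1])
    merged <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters <- clusters[-c(best[2], best[3])]
    clusters[[length(clusters) + 1]] <- merged
  }
  heights
}

# Random codon-count table over the full 64-codon set.
random_count_table <- function(seed, lambda = 8) {
  set.seed(seed)
  codons <- names(make_counts_template())
  counts <- stats::setNames(rpois(64, lambda), codons)
  structure(list(counts = counts, n_skipped = 0L, source_ids = "random"),
            class = "codon_count_table")
}

make_counts_template <- function() {
  bases <- c("T", "C", "A", "G")
  codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  stats::setNames(integer(64), sort(codons))
}

# Two partitions equal up to label permutation?
same_partition <- function(a, b) {
  length(a) == length(b) &&
    all(outer(a, a, "==") == outer(b, b, "=="))
}
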