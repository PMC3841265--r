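#' Count codons across one or more coding sequences
#'
#' Counts frame-0, non-overlapping triplets over the 64 standard codons.
#' Codons containing `N` are skipped and tallied in `n_skipped`. When
#' `drop_terminal_stop` is `TRUE` (the default), a final TAA/TAG/TGA
#' codon in each sequence is excluded from the counts, so downstream
#' statistics never see termination codons of complete CDS.
#'
#' @param seqs Named character vector of CDS strings (lengths multiples
#'   of 3), e.g. from [read_fasta()].
#' @param drop_terminal_stop Exclude a terminal stop codon per sequence?
#' @return Object of class `codon_count_table`: list with `counts`
#'   (named integer vector over all 64 codons), `n_skipped` (codons
#'   containing N), and `source_ids`.
#' @examples
#' codon_counts(c(s1 = "ATGAAATTTTGA"))
#' @export
codon_counts <- function(seqs, drop_terminal_stop = TRUE) {
  stopifnot(is.character(seqs), length(seqs) >= 1L)
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  counts <- stats::setNames(integer(64), ALL_CODONS)
  n_skipped <- 0L
  for (i in seq_along(seqs)) {
    codons <- split_codons(seqs[[i]])
    if (drop_terminal_stop && codons[length(codons)] %in% STOP_CODONS) {
      codons <- codons[-length(codons)]
    }
    has_n <- grepl("N", codons, fixed = TRUE)
    n_skipped <- n_skipped + sum(has_n)
    tab <- table(factor(codons[!has_n], levels = ALL_CODONS))
    counts <- counts + as.integer(tab)
  }
  structure(list(counts = counts, n_skipped = n_skipped,
                 source_ids = names(seqs)),
            class = "codon_count_table")
}

#' @export
print.codon_count_table <- function(x, ...) {
  cat("Codon count table:", sum(x$counts), "codons from",
      length(x$source_ids), "sequence(s);", x$n_skipped,
      "codon(s) skipped for N\n")
  invisible(x)
}

#' Overall nucleotide composition
#'
#' Percentages of A, T, G and C among non-N bases across the full
#' sequence set, plus overall G+C.
#'
#' @param seqs Named character vector of sequences.
#' @return Named numeric vector `a_pct`, `t_pct`, `g_pct`, `c_pct`,
#'   `gc_pct`, on the 0-100 scale.
#' @export
overall_composition <- function(seqs) {
  stopifnot(is.character(seqs), length(seqs) >= 1L)
  all <- paste(seqs, collapse = "")
  base_counts <- vapply(c("A", "T", "G", "C"), function(b) {
    lengths(regmatches(all, gregexpr(b, all, fixed = TRUE)))
  }, integer(1))
  tot <- sum(base_counts)
  if (tot == 0L) stop("no unambiguous (non-N) bases in input")
  pct <- 100 * base_counts / tot
  c(a_pct = pct[["A"]], t_pct = pct[["T"]], g_pct = pct[["G"]],
    c_pct = pct[["C"]], gc_pct = pct[["G"]] + pct[["C"]])
}

#' Nucleotide composition at synonymous third positions
#'
#' Fractions of A/T/G/C at the third position of synonymous sense codons
#' only: the 59-codon set excluding Met (ATG), Trp (TGG) and the three
#' termination codons, which contribute to neither numerator nor
#' denominator. `gc3s` is the conventional GC3s index.
#'
#' @param counts A `codon_count_table`.
#' @return Named numeric vector `a3s_pct`, `t3s_pct`, `g3s_pct`,
#'   `c3s_pct`, `gc3s_pct` (0-100 scale).
#' @export
third_position_composition <- function(counts) {
  stopifnot(inherits(counts, "codon_count_table"))
  syn <- counts$counts[SENSE_CODONS_59]
  tot <- sum(syn)
  if (tot == 0L) stop("no synonymous sense codons observed")
  third <- codon_third_base(SENSE_CODONS_59)
  pct <- vapply(c("A", "T", "G", "C"),
                function(b) 100 * sum(syn[third == b]) / tot, numeric(1))
  c(a3s_pct = pct[["A"]], t3s_pct = pct[["T"]], g3s_pct = pct[["G"]],
    c3s_pct = pct[["C"]], gc3s_pct = pct[["G"]] + pct[["C"]])
}

#' G+C content by codon position
#'
#' G+C percentage among non-N bases at codon positions 1, 2 and 3,
#' across all codons except termination codons (terminal or internal).
#' Unlike GC3s, position 3 here includes ATG and TGG.
#'
#' @param seqs Named character vector of CDS strings.
#' @return Named numeric vector `gc1_pct`, `gc2_pct`, `gc3_pct`.
#' @export
positional_gc <- function(seqs) {
  stopifnot(is.character(seqs), length(seqs) >= 1L)
  gc_num <- numeric(3)
  gc_den <- numeric(3)
  for (s in seqs) {
    codons <- split_codons(s)
    codons <- codons[!(codons %in% STOP_CODONS)]
    for (p in 1:3) {
      b <- substr(codons, p, p)
      b <- b[b != "N"]
      gc_num[p] <- gc_num[p] + sum(b %in% c("G", "C"))
      gc_den[p] <- gc_den[p] + length(b)
    }
  }
  if (any(gc_den == 0)) stop("no unambiguous bases at some codon position")
  pct <- 100 * gc_num / gc_den
  c(gc1_pct = pct[1], gc2_pct = pct[2], gc3_pct = pct[3])
}

#' Per-sequence composition profiles
#'
#' One row per sequence with the composition statistics conventionally
#' reported for viral CDS sets: overall and synonymous-third-position
#' nucleotide percentages, GC, GC3s, positional GC and ENC.
#'
#' @param seqs Named character vector of CDS strings.
#' @return A tibble with columns `id`, `T`, `T3s`, `C`, `C3s`, `A`,
#'   `A3s`, `G`, `G3s`, `GC`, `GC3s`, `GC1`, `GC2`, `GC3`, `ENC`.
#'   Percentages on the 0-100 scale, unrounded.
#' @export
composition_profile <- function(seqs) {
  stopifnot(is.character(seqs), length(seqs) >= 1L)
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  rows <- lapply(names(seqs), function(id) {
    s <- seqs[id]
    cc <- codon_counts(s)
    oc <- overall_composition(s)
    tp <- third_position_composition(cc)
    pg <- positional_gc(s)
    e <- enc(cc)
    tibble::tibble(
      id = id,
      T = oc[["t_pct"]], T3s = tp[["t3s_pct"]],
      C = oc[["c_pct"]], C3s = tp[["c3s_pct"]],
      A = oc[["a_pct"]], A3s = tp[["a3s_pct"]],
      G = oc[["g_pct"]], G3s = tp[["g3s_pct"]],
      GC = oc[["gc_pct"]], GC3s = tp[["gc3s_pct"]],
      GC1 = pg[["gc1_pct"]], GC2 = pg[["gc2_pct"]], GC3 = pg[["gc3_pct"]],
      ENC = e$enc
    )
  })
  do.call(rbind, rows)
}
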