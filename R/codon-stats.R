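#' Relative synonymous codon usage
#'
#' For each synonymous family, the RSCU of codon j is its observed count
#' divided by the family mean count: `RSCU_j = X_j * n / sum(X)`, where n
#' is the family size. Values above 1 mark codons used more often than
#' expected under uniform synonymous usage; 1 marks equal usage. Met,
#' Trp and the termination codons have no synonymous alternatives and
#' are excluded, leaving the standard 59-codon set.
#'
#' @param counts A `codon_count_table` from [codon_counts()].
#' @return Object of class `rscu_vector`: list with `values` (named
#'   numeric over the 59 sense codons; families with zero observations
#'   carry 0) and `missing_families` (character vector of amino acids
#'   with no observations).
#' @examples
#' rscu(codon_counts(c(s = "AAAAAAAAAAAG")))$values[c("AAA", "AAG")]
#' @export
rscu <- function(counts) {
  stopifnot(inherits(counts, "codon_count_table"))
  values <- stats::setNames(numeric(length(SENSE_CODONS_59)),
                            SENSE_CODONS_59)
  missing <- character(0)
  for (aa in names(SYNONYMOUS_FAMILIES)) {
    fam <- SYNONYMOUS_FAMILIES[[aa]]
    x <- counts$counts[fam]
    tot <- sum(x)
    if (tot == 0L) {
      missing <- c(missing, aa)
    } else {
      values[fam] <- x * length(fam) / tot
    }
  }
  structure(list(values = values, missing_families = missing),
            class = "rscu_vector")
}

#' @export
print.rscu_vector <- function(x, ...) {
  cat("RSCU over", length(x$values), "sense codons")
  if (length(x$missing_families)) {
    cat("; unobserved families:", paste(x$missing_families, collapse = ","))
  }
  cat("\n")
  invisible(x)
}

#' Preferred codon per amino acid
#'
#' The codon with maximal RSCU in each observed family. Exact ties are
#' broken alphabetically and flagged.
#'
#' @param rscu_vec An `rscu_vector`.
#' @return Tibble with columns `aa`, `codon`, `rscu`, `tie`; families
#'   with zero observations are omitted.
#' @export
preferred_codons <- function(rscu_vec) {
  stopifnot(inherits(rscu_vec, "rscu_vector"))
  aas <- setdiff(names(SYNONYMOUS_FAMILIES), rscu_vec$missing_families)
  rows <- lapply(aas, function(aa) {
    fam <- sort(SYNONYMOUS_FAMILIES[[aa]])
    v <- rscu_vec$values[fam]
    best <- fam[which.max(v)]  # first of ties, alphabetical since sorted
    tibble::tibble(aa = aa, codon = best, rscu = unname(max(v)),
                   tie = sum(v == max(v)) > 1L)
  })
  do.call(rbind, rows)
}

#' Effective number of codons (Wright's Nc)
#'
#' Estimates codon usage bias as the number of equally-used codons that
#' would produce the observed usage: 20 when exactly one codon is used
#' per amino acid, 61 under uniform synonymous usage. Per family with
#' n >= 2 observations, the codon homozygosity is
#' `F = (n * sum(p^2) - 1) / (n - 1)`; class means of F over the 2-, 3-,
#' 4- and 6-fold degeneracy classes give
#' `ENC = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6`. Leu, Ser and Arg are treated
#' as intact six-fold families. Families with fewer than 2 codons or
#' F <= 0 are omitted from their class mean; a missing three-fold class
#' (Ile unobserved) is replaced by the mean of the 2- and 4-fold class
#' means; any other empty class is an error. Estimates above 61 (finite
#' sampling) are capped at 61; estimates below 20 are possible for tiny
#' samples and raise a warning.
#'
#' @param counts A `codon_count_table`.
#' @return Object of class `enc_result`: list with `enc`, `f_bars`
#'   (named means for classes "2","3","4","6") and `families_used`
#'   (families contributing per class).
#' @export
enc <- function(counts) {
  stopifnot(inherits(counts, "codon_count_table"))
  f_hat <- stats::setNames(rep(NA_real_, length(SYNONYMOUS_FAMILIES)),
                           names(SYNONYMOUS_FAMILIES))
  for (aa in names(SYNONYMOUS_FAMILIES)) {
    x <- counts$counts[SYNONYMOUS_FAMILIES[[aa]]]
    n <- sum(x)
    if (n >= 2L) {
      p <- x / n
      f_hat[aa] <- (n * sum(p^2) - 1) / (n - 1)
    }
  }
  classes <- c("2", "3", "4", "6")
  f_bars <- stats::setNames(rep(NA_real_, 4), classes)
  families_used <- stats::setNames(integer(4), classes)
  for (k in classes) {
    aas <- names(ENC_DEGENERACY)[ENC_DEGENERACY == as.integer(k)]
    f <- f_hat[aas]
    f <- f[!is.na(f) & f > 0]
    families_used[k] <- length(f)
    if (length(f) > 0L) f_bars[k] <- mean(f)
  }
  if (is.na(f_bars[["3"]])) {
    if (is.na(f_bars[["2"]]) || is.na(f_bars[["4"]])) {
      stop("cannot estimate ENC: three-fold class missing and no 2-/4-fold fallback")
    }
    f_bars[["3"]] <- (f_bars[["2"]] + f_bars[["4"]]) / 2
  }
  empty <- classes[is.na(f_bars)]
  if (length(empty) > 0L) {
    stop("cannot estimate ENC: no usable family in degeneracy class ",
         paste(empty, collapse = ", "))
  }
  nc <- 2 + 9 / f_bars[["2"]] + 1 / f_bars[["3"]] +
    5 / f_bars[["4"]] + 3 / f_bars[["6"]]
  if (nc > 61) nc <- 61
  if (nc < 20) {
    warning("ENC estimate ", format(nc), " below the theoretical floor of 20 ",
            "(small-sample noise); not capped")
  }
  structure(list(enc = nc, f_bars = f_bars, families_used = families_used),
            class = "enc_result")
}

#' @export
print.enc_result <- function(x, ...) {
  cat("ENC =", round(x$enc, 2), "\n")
  invisible(x)
}

#' Expected ENC under compositional constraint alone
#'
#' Wright's null curve for the ENC plot: the ENC a gene would show if
#' third-position G+C content (GC3s, as a fraction) were the only force
#' shaping synonymous codon usage:
#' `ENC = 2 + s + 29 / (s^2 + (1 - s)^2)`. Points falling below this
#' curve suggest forces beyond composition, e.g. translational
#' selection.
#'
#' @param gc3s GC3s as a fraction in \[0, 1\] (vectorised).
#' @return Expected ENC value(s).
#' @examples
#' expected_enc(0.5)  # 60.5, the curve's maximum region
#' @export
expected_enc <- function(gc3s) {
  if (any(gc3s < 0 | gc3s > 1 | is.na(gc3s))) {
    stop("gc3s must lie in [0, 1]")
  }
  2 + gc3s + 29 / (gc3s^2 + (1 - gc3s)^2)
}

#' Per-sequence RSCU matrix
#'
#' @param seqs Named character vector of CDS strings.
#' @return Numeric matrix, one row per sequence, 59 sense-codon columns.
#' @export
rscu_matrix <- function(seqs) {
  stopifnot(is.character(seqs), length(seqs) >= 1L)
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  m <- t(vapply(names(seqs),
                function(id) rscu(codon_counts(seqs[id]))$values,
                numeric(length(SENSE_CODONS_59))))
  rownames(m) <- names(seqs)
  m
}
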