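#' Read coding sequences from a FASTA file
#'
#' Reads nucleotide FASTA and returns the records as a named character
#' vector of uppercase DNA strings. RNA-style input is accepted: `U` is
#' mapped to `T` on input. Only `A`, `C`, `G`, `T` and the ambiguity code
#' `N` are permitted after that mapping.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector; names are record ids (first whitespace
#'   token of each header), values are uppercase sequences over
#'   `{A,C,G,T,N}`, in file order.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">s1", "atgaaatga"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path)
  }
  if (file.size(path) == 0L) {
    stop("empty FASTA file: ", path)
  }
  recs <- seqinr::read.fasta(path, seqtype = "DNA", as.string = TRUE,
                             forceDNAtolower = FALSE)
  ids <- vapply(recs, function(r) attr(r, "name"), character(1))
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop("duplicate sequence id(s) in ", path, ": ",
         paste(dup, collapse = ", "))
  }
  seqs <- toupper(vapply(recs, as.character, character(1)))
  seqs <- gsub("U", "T", seqs, fixed = TRUE)
  for (i in seq_along(seqs)) {
    bad <- regexpr("[^ACGTN]", seqs[[i]])
    if (bad > 0L) {
      stop("invalid character '", substr(seqs[[i]], bad, bad),
           "' at position ", bad, " in record '", ids[[i]], "'")
    }
  }
  stats::setNames(seqs, ids)
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  seqinr::write.fasta(as.list(unname(seqs)), names = names(seqs),
                      file.out = path, nbchar = 70)
  invisible(path)
}

#' Validate a coding sequence
#'
#' Asserts that a sequence can be read as consecutive codons: its length
#' must be a positive multiple of 3. A terminal stop codon (TAA/TAG/TGA)
#' is retained but flagged so codon counting can exclude it; internal
#' stop codons raise a warning (naming the first offending codon index),
#' not an error, since sequencing or annotation artefacts are common in
#' public viral CDS.
#'
#' @param seq A single sequence string over `{A,C,G,T,N}`.
#' @param id Label used in messages.
#' @return The sequence, with attributes `terminal_stop` (logical) and
#'   `internal_stops` (integer codon indices, possibly empty).
#' @export
validate_cds <- function(seq, id = "sequence") {
  stopifnot(is.character(seq), length(seq) == 1L)
  n <- nchar(seq)
  if (n == 0L || n %% 3L != 0L) {
    stop("length of '", id, "' (", n, ") is not a positive multiple of 3")
  }
  codons <- split_codons(seq)
  is_stop <- codons %in% STOP_CODONS
  terminal <- is_stop[length(codons)]
  internal <- which(is_stop[-length(codons)])
  if (length(internal) > 0L) {
    warning("'", id, "' has internal stop codon(s) at codon position(s) ",
            paste(internal, collapse = ", "))
  }
  structure(seq, terminal_stop = terminal, internal_stops = internal)
}

#' Read an aligned FASTA file
#'
#' @param path Path to aligned FASTA; `-` is the gap character.
#' @return List with `seqs` (named character vector, equal lengths) and
#'   `ncol` (alignment length).
#' @export
read_alignment <- function(path) {
  if (!file.exists(path)) {
    stop("alignment file not found: ", path)
  }
  recs <- seqinr::read.fasta(path, seqtype = "DNA", as.string = TRUE,
                             forceDNAtolower = FALSE)
  if (length(recs) < 2L) {
    stop("alignment needs at least 2 records, got ", length(recs))
  }
  ids <- vapply(recs, function(r) attr(r, "name"), character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id(s) in alignment: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- toupper(vapply(recs, as.character, character(1)))
  seqs <- gsub("U", "T", seqs, fixed = TRUE)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    off <- ids[lens != lens[1]][1]
    stop("ragged alignment: record '", off, "' has length ",
         nchar(seqs[lens != lens[1]][1]), ", expected ", lens[1])
  }
  bad <- regexpr("[^ACGTN-]", seqs)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1]
    stop("invalid character at position ", bad[i], " in record '",
         ids[i], "'")
  }
  list(seqs = stats::setNames(seqs, ids), ncol = unname(lens[1]))
}

#' @keywords internal
split_codons <- function(seq) {
  n <- nchar(seq)
  stopifnot(n %% 3L == 0L)
  substring(seq, seq(1L, n, 3L), seq(3L, n, 3L))
}
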