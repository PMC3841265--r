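# Standard genetic code tables used throughout the package.
# DNA alphabet; codons in TCAG-block order for readability.

#' @keywords internal
GENETIC_CODE_DNA <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G"
)

ALL_CODONS <- names(GENETIC_CODE_DNA)

STOP_CODONS <- c("TAA", "TAG", "TGA")

# The 59 sense codons with synonymous alternatives: 61 sense codons minus
# ATG (Met) and TGG (Trp), which are the sole codons for their amino acids.
SENSE_CODONS_59 <- setdiff(ALL_CODONS, c(STOP_CODONS, "ATG", "TGG"))

# amino acid -> synonymous codon family (59-codon set only)
SYNONYMOUS_FAMILIES <- split(
  SENSE_CODONS_59,
  GENETIC_CODE_DNA[SENSE_CODONS_59]
)

# Degeneracy classes for Wright's ENC estimator: Leu/Ser/Arg kept as intact
# six-fold families (the CodonW convention), not split 2+4.
ENC_DEGENERACY <- vapply(SYNONYMOUS_FAMILIES, length, integer(1))

#' @keywords internal
codon_third_base <- function(codons) substr(codons, 3L, 3L)
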