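#!/usr/bin/env Rscript
# Spearman correlation structure of the 41-genome TTSuV2 composition
# reference: overall composition vs third-position composition (the
# published mutational-bias table) and GC3s vs ENC.
# Outputs: results/correlations_composition.tsv,
#          results/correlation_gc3s_enc.tsv

library(codonbias)

fx <- ttsuv2_composition_fixture()

cm <- correlation_matrix(fx, rows = c("A", "T", "G", "C", "GC"),
                         cols = c("A3s", "T3s", "G3s", "C3s", "GC3s"))
cm$r <- round(cm$r, 3)
write_tsv_table(cm, "results/correlations_composition.tsv")
cat("composition correlation matrix (r, band):\n")
for (rv in c("A", "T", "G", "C", "GC")) {
  row <- cm[cm$row == rv, ]
  cat(sprintf("  %-3s %s\n", rv,
              paste(sprintf("%6.3f%-3s", row$r,
                            ifelse(row$stars == "NS", "", row$stars)),
                    collapse = " ")))
}

ge <- spearman(fx$GC3s, fx$ENC)
write_tsv_table(data.frame(x = "GC3s", y = "ENC", r = round(ge$r, 3),
                           p = signif(ge$p, 3), band = ge$band),
                "results/correlation_gc3s_enc.tsv")
cat(sprintf("GC3s ~ ENC: r = %.3f (%s), n = %d\n", ge$r, ge$band, ge$n))
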