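# Published per-genome composition reference for 41 complete TTSuV2 CDS
# (GenBank AY823991, GU188046, GU456385-6, GU570197/203-209,
# HM633214-41, HQ204188). Percentages on the 0-100 scale; ENC from
# CodonW. One row per isolate, id = isolate name.
.ttsuv2_rows <- c(
  "2p         20.54 27.81 21.41 33.11 36.33 41.96 21.72 28.10 45.0 46.0 54.55",
  "472142     20.22 26.48 22.54 32.61 35.60 43.24 21.64 26.19 45.9 45.3 55.20",
  "PTTV2b-VA  20.40 27.06 22.41 33.55 34.88 39.46 22.31 29.01 46.7 48.0 57.31",
  "PTTV2c-VA  20.40 27.06 22.41 33.55 34.88 39.46 22.31 29.01 46.7 48.0 57.31",
  "TTV2_GE9   20.75 27.89 21.67 33.33 35.44 40.17 22.14 27.76 45.6 46.5 57.86",
  "TTV2_1907  20.44 27.91 21.83 33.41 35.90 40.40 21.83 28.33 45.5 46.6 58.18",
  "TTV2_G31   20.50 28.07 21.57 32.89 35.74 40.52 22.19 28.17 45.6 46.2 58.16",
  "TTV2_G33   20.39 27.91 21.88 33.41 35.90 40.40 21.83 28.33 45.6 46.6 58.18",
  "TTV2_G43   20.34 27.31 21.37 33.26 36.47 41.72 21.83 28.47 45.1 46.5 53.76",
  "TTV2_G61   20.03 27.63 21.67 32.89 36.47 41.69 21.83 27.25 45.6 45.8 56.04",
  "TTV2_G64   20.03 27.03 21.52 33.19 36.11 41.33 22.34 27.88 45.8 46.4 55.66",
  "TTV2_GE1   20.96 28.54 21.47 32.68 35.44 39.91 22.14 28.13 45.4 46.2 58.18",
  "TTV2Bj7-2  21.50 27.29 21.34 31.99 37.02 44.04 20.15 28.54 43.4 45.1 54.69",
  "TTV2Bj2-3  19.93 28.05 21.52 33.71 36.67 41.83 21.88 27.99 45.4 46.1 55.37",
  "TTV2Bj4-3  20.44 28.28 21.06 34.39 37.03 41.31 21.47 27.62 44.6 46.5 55.04",
  "TTV2Bj6-2  19.81 28.28 21.83 33.71 36.58 40.40 21.78 27.92 45.8 46.5 57.14",
  "TTV2Bj6-3  20.09 26.23 21.79 34.75 36.17 41.24 21.95 29.17 46.1 48.1 57.56",
  "TTV2Bj7-3  19.88 28.41 21.73 33.33 36.72 41.74 21.67 26.97 45.5 45.5 56.51",
  "TTV2Fj2    20.24 28.07 21.62 32.68 35.95 40.35 22.19 29.02 45.8 46.6 57.03",
  "TTV2Jl1    19.93 28.05 21.62 33.71 36.52 41.65 21.93 27.86 45.5 46.1 55.55",
  "TTV2Jl2    20.29 27.95 21.57 32.53 35.90 40.35 22.24 28.78 45.9 46.5 56.86",
  "TTV2Jl27   20.40 27.33 20.87 31.89 37.90 43.16 20.82 30.00 44.2 45.9 57.78",
  "TTV2Bj1-2  20.66 26.29 21.23 33.71 36.12 40.80 22.00 30.26 45.2 48.0 56.84",
  "TTV2Hb1    20.34 28.48 21.06 33.86 36.88 41.31 21.73 28.06 44.8 46.4 54.86",
  "TTV2Bj8    21.81 28.51 20.92 31.63 36.86 45.07 20.40 26.82 42.9 43.8 53.98",
  "TTV2Bj11   19.99 26.29 22.00 35.06 36.01 40.92 22.00 29.10 46.3 48.2 57.24",
  "TTV2Bj12   20.59 28.16 21.57 33.92 36.07 40.77 21.78 28.06 45.3 46.7 54.41",
  "TTV2Gx1    21.09 27.25 21.34 31.21 37.42 44.59 20.16 28.12 43.4 44.4 55.97",
  "TTV2Gx2    20.56 26.15 21.84 33.63 35.55 41.16 22.05 28.95 46.1 47.5 56.81",
  "TTV2Gx3-2  20.34 28.28 21.11 34.39 36.93 40.99 21.62 27.79 44.9 46.7 54.93",
  "TTV2Gx4    21.45 26.81 21.14 31.21 36.90 43.72 20.52 28.50 43.7 44.9 56.01",
  "TTV2Jx1    20.08 26.67 21.57 33.11 36.31 42.54 22.03 28.07 45.3 46.0 56.14",
  "TTV2Jx2    20.38 29.12 21.57 32.28 37.31 43.51 20.74 26.85 44.7 44.1 56.39",
  "TTV2Ln13   20.77 27.27 21.13 31.82 37.64 42.89 20.46 30.56 44.1 46.2 56.61",
  "TTV2Ln14   21.19 29.36 21.19 30.91 37.16 43.94 20.47 26.42 43.7 43.2 56.11",
  "TTV2Ln21   21.18 28.47 20.40 31.48 37.85 42.66 20.56 31.39 43.5 45.9 57.41",
  "TTV2Ln22   21.08 28.37 20.46 31.63 38.21 43.22 20.25 31.22 43.2 45.8 56.27",
  "TTV2Ln23-2 20.43 27.33 21.47 33.78 36.38 40.67 21.72 29.15 45.2 47.3 54.02",
  "lung1      19.88 26.93 21.93 33.55 36.67 42.83 21.52 27.23 45.4 45.8 54.49",
  "lung3      20.40 28.92 21.64 32.96 37.35 43.12 20.61 26.59 44.4 44.4 56.01",
  "SC         20.14 27.11 21.79 33.78 36.27 41.63 21.79 28.85 45.7 47.1 56.25"
)

# The published mean row, for the fixture's self-check.
.ttsuv2_mean_row <- c(T = 20.48, T3s = 27.67, C = 21.52, C3s = 33.04,
                      A = 36.46, A3s = 41.77, G = 21.53, G3s = 28.35,
                      GC = 45.09, GC3s = 46.18, ENC = 56.21)

#' Reference composition table for 41 TTSuV2 coding sequences
#'
#' The published per-genome nucleotide composition statistics for the 41
#' complete TTSuV2 CDS (Brazil/Germany/USA/Spain/China isolates,
#' 2005-2011): overall and synonymous-third-position percentages of each
#' base, GC, GC3s and CodonW's ENC. All within-table statistics — the
#' Spearman correlations between overall and third-position composition
#' and the column means — are recomputable offline from this fixture.
#'
#' @return Tibble with 41 rows and columns `id`, `T`, `T3s`, `C`,
#'   `C3s`, `A`, `A3s`, `G`, `G3s`, `GC`, `GC3s`, `ENC` (percentages on
#'   the 0-100 scale as printed, 2 decimals; GC/GC3s 1 decimal).
#' @examples
#' fx <- ttsuv2_composition_fixture()
#' mean(fx$ENC)
#' @export
ttsuv2_composition_fixture <- function() {
  parts <- strsplit(trimws(.ttsuv2_rows), "[[:space:]]+")
  ids <- vapply(parts, `[[`, character(1), 1L)
  num <- t(vapply(parts, function(p) as.numeric(p[-1]), numeric(11)))
  colnames(num) <- names(.ttsuv2_mean_row)
  tibble::tibble(id = ids, tibble::as_tibble(num))
}

#' Published mean row of the TTSuV2 composition reference
#'
#' @return Named numeric vector of the printed column means.
#' @export
ttsuv2_composition_means <- function() {
  .ttsuv2_mean_row
}
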