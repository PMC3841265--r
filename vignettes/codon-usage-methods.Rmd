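---
title: "Methods: synonymous codon usage analysis for small viral genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synonymous codon usage analysis for small viral genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codonbias)
```

## The problem

Synonymous codons — codons encoding the same amino acid — are not used
at random. The usage pattern of a genome reflects the balance between
mutational pressure (which shapes the nucleotide pool, especially at
the weakly constrained third codon position) and natural selection
(e.g. for translational efficiency against the host's tRNA pool). For
small DNA viruses such as the two Torque teno sus virus species
(TTSuV1/TTSuV2; ~1.9 kb circular ssDNA genomes of swine), quantifying
codon usage bias and dissecting its causes is one of the few windows
into their molecular evolution, since little else about their biology
is experimentally tractable.

This package implements the complete analysis workflow for such a
study: nucleotide composition, relative synonymous codon usage (RSCU),
the effective number of codons (ENC) with its compositional null
curve, correspondence analysis of RSCU matrices, hierarchical
clustering of genomes by RSCU, Spearman correlation tables with the
significance banding used in this literature, and a sliding-window
identity scan for recombination screening. A synthetic CDS generator
with known ground truth validates every stage, and a 41-genome TTSuV2
composition reference table is embedded so the published per-genome
statistics are reproducible offline.

## Composition statistics

For a CDS read in frame, the package reports overall base percentages
(A%, T%, G%, C%, GC%), base percentages at the third position of
*synonymous sense codons* (A3s ... GC3s), and positional GC (GC1, GC2,
GC3). Three exclusion rules matter and are easy to conflate:

* **Overall composition** uses every non-N base.
* **Third-position "3s" statistics** use only the 59 sense codons that
  have synonymous alternatives: ATG (Met), TGG (Trp) and the three
  stop codons contribute to neither numerator nor denominator. The
  restriction is stated explicitly for GC3s in the field's tool
  conventions (CodonW, MEGA) and is applied uniformly to A3s/T3s/
  G3s/C3s here.
* **Positional GC (GC1/GC2/GC3)** excludes stop codons but keeps ATG
  and TGG — GC3 and GC3s are therefore different columns.

Codons containing N are skipped and tallied (`n_skipped`); terminal
stop codons are detected by `validate_cds()` and excluded from all
codon statistics by default.

## RSCU

For codon $j$ of an amino acid with $n$ synonymous codons observed
$X_1,\dots,X_n$ times,

$$\mathrm{RSCU}_j = \frac{X_j}{\frac{1}{n}\sum_{k} X_k},$$

i.e. the observed count over the family mean. RSCU is 1 under equal
usage, $>1$ for over-used codons, and sums to the family size within
each family (a tested invariant). Unobserved families are emitted as
zeros with a `missing_families` flag rather than NA, so per-genome
RSCU matrices stay rectangular for ordination. Preferred codons are
the per-family RSCU maxima; exact ties are broken alphabetically and
flagged.

## ENC and the expected-ENC curve

Wright's effective number of codons estimates how many equally-used
codons would produce the observed usage: 20 when one codon is used per
amino acid, 61 under uniform usage. Per family with $n \ge 2$
observations the codon homozygosity is
$\hat F = (n\sum p_i^2 - 1)/(n-1)$; averaging $\hat F$ within
degeneracy classes gives

$$\mathrm{ENC} = 2 + \frac{9}{\bar F_2} + \frac{1}{\bar F_3}
  + \frac{5}{\bar F_4} + \frac{3}{\bar F_6}.$$

Numerical choices, following the CodonW conventions this literature
relies on:

* Leu, Ser and Arg are intact six-fold families (not split 2+4).
* Families with $n<2$ or $\hat F \le 0$ are omitted from their class
  mean; if Ile (the only three-fold family) is unusable,
  $\bar F_3 := (\bar F_2 + \bar F_4)/2$; any other empty class is an
  error rather than a silent guess.
* Sampling noise can push the estimate above 61; it is capped at 61.
  Values below 20 are mathematically possible for tiny samples and
  raise a warning instead of being capped, so the anomaly stays
  visible.

The compositional null for the ENC plot is Wright's curve
$\mathrm{ENC}(s) = 2 + s + 29/(s^2 + (1-s)^2)$ with $s$ = GC3s as a
fraction. Genes on the curve are consistent with composition alone
driving bias; genes below it suggest additional forces such as
translational selection.

## Correspondence analysis

Each genome is a 59-dimensional RSCU vector; correspondence analysis
(CA) ordinates the genomes along axes of decreasing inertia. The
implementation is the standard chi-square-metric SVD: relative
frequencies $P$, masses $r, c$, standardized residuals
$S = D_r^{-1/2}(P - rc^\top)D_c^{-1/2}$, SVD of $S$; principal row
coordinates scale left singular vectors by $\sigma_k/\sqrt{r_i}$, and
axis $k$ carries inertia fraction $\sigma_k^2/\sum\sigma^2$. Total
inertia equals the table's Pearson chi-square over its grand total — a
tested identity, alongside equivalence with an explicitly-constructed
oracle and with `vegan::cca`.

Applying CA to RSCU values (not raw counts) follows the convention of
this literature. Two numerical decisions: axis signs, which are not
identifiable, are fixed so each axis's largest-magnitude column
loading is positive, making runs and platforms comparable; all-zero
codon columns (never used in any genome) are dropped with a warning
because their column mass would be zero. Singular values below an
absolute floor of about $10^{-13}$ are treated as zero so that
exact-independence tables report zero axes rather than noise.

## Clustering and correlation

Genome clustering uses pairwise Euclidean distances between RSCU rows
under unweighted pair-group average linkage — the "between-groups"
default of the classic statistics packages this literature used —
with complete and Ward linkage selectable. Merge heights are verified
against a naive $O(n^3)$ re-implementation. `cut_tree()` renumbers
clusters by first leaf appearance so cluster ids are deterministic.
Trees export as Newick.

`spearman()` computes rho as the Pearson correlation of average
ranks. The two-sided p-value uses the t approximation with $n-2$
degrees of freedom; below $n = 10$ the full permutation distribution
is enumerated instead (at most $9! = 362{,}880$ orderings), since the
t approximation is poor there. Results carry the three significance
bands used in the source tables: NS ($p>0.05$), `*`
($0.01<p<0.05$), `**` ($p<0.01$). Band edges are assigned by strict
inequality on the lower bound ($p < 0.01$ is `**`).

## Recombination scan

`distance_profiles()` computes, for each sequence in an alignment,
the fraction of bases identical to a chosen reference in sliding
windows (default 60 nt wide, step 30 — resolving a ~1.9 kb genome
into ~60 windows). Identity rather than distance is reported; the two
are monotone-equivalent views of the same graph. Columns with a gap
or N in either sequence are excluded from numerator and denominator;
windows with fewer than 10 comparable columns give NA. Only full
windows are profiled.

`detect_crossovers()` flags the visual signature of recombination:
two query lines swapping rank against the reference. A crossover is a
sign flip of the identity difference between consecutive windows
where the lines are separated by at least `min_gap` (default 0.05),
with sub-threshold windows — the transition zone around a genuine
breakpoint — skipped. Two guards keep noise out: isolated
opposite-sign excursions farther apart than `max_span` (default twice
the window width) are not joined, and the breakpoint coordinate is
interpolated linearly between the flanking window centers. On planted
mosaics the junction is recovered within one window; lines of
near-coincident sequences can still produce occasional
threshold-level crossings, which is why flagged events should be read
alongside the profile table, exactly as with the interactive tools
this scan emulates.

## The synthetic generator

`simulate_cds()` emits i.i.d.-codon sequences with controlled usage
structure: per sequence and per synonymous family, a codon-preference
vector is drawn from a Dirichlet distribution whose mean is tilted
towards G/C third bases by $e^{\beta}$ and whose total concentration
`dirichlet_conc` sets between-sequence noise; amino acids are drawn
i.i.d. from `aa_weights`; a TAA stop is appended. A truth sidecar
records every realized preference vector.

Defaults describe a study-shaped dataset: 41 sequences of 625 codons
(~1.9 kb), uniform amino-acid weights (the pooled amino-acid
composition of the real genomes is not recoverable from published
per-codon summaries, so no attempt is made to imitate it), $\beta=0$,
concentration 50 (visible but moderate between-genome preference
variation). The generator's limits are exact and tested: ENC tends to
61 as concentration grows at $\beta=0$, to 20 as it shrinks; realized
GC3s is monotone in $\beta$; identical seeds give byte-identical
FASTA.

What the generator does *not* emulate: dinucleotide/codon-pair
structure (the downstream statistics only consume codon counts),
ORF overlap and UTRs of real anellovirus genomes, and — importantly —
phylogenetic relatedness: sequences are independent draws, so there
is no shared ancestry. Passing tests on synthetic data therefore
validate the statistical machinery, not claims about real-genome
structure. For the recombination scan, where descent matters, the
workflow builds populations by mutating two diverged ancestors
instead of using the i.i.d. generator.

## The embedded reference table

`ttsuv2_composition_fixture()` returns the published per-genome
composition statistics (T/T3s/C/C3s/A/A3s/G/G3s/GC/GC3s/ENC) for the
41 complete TTSuV2 CDS, keyed by isolate name. Every statistic
computed *from* that table — the six composition Spearman
correlations and the column means — reproduces offline:

```{r fixture}
fx <- ttsuv2_composition_fixture()
round(c(r_gc3s_enc = spearman(fx$GC3s, fx$ENC)$r,
        r_a_a3s = spearman(fx$A, fx$A3s)$r,
        mean_enc = mean(fx$ENC), mean_gc3s = mean(fx$GC3s)), 3)
```

Two caveats found while validating the transcription: the published
mean row's A and C entries are off by 0.02/0.01 from the true column
means (rounding slips in the source), so the fixture's self-check
uses a 0.025 tolerance; and two entries of the published composition
correlation table disagree with recomputation from the published
per-genome values themselves (G~T3s prints -0.391 where the data give
-0.319; GC~T3s prints +0.434 where the data give -0.434), which the
workflow reports as computed.

Per-genome statistics recomputed from raw GenBank sequences (and the
CA axis inertia of the real 41-genome RSCU matrix) are outside the
offline scope: they require the accession downloads and a resolution
of which overlapping ORF(s) the original CDS extraction used.

## Problem sizes and determinism

All simulations in the tests and the workflow are sized desk-scale:
up to ~40 sequences of 600-625 codons, which keeps the full test
suite under half a minute while leaving sampling noise well below the
tested effect sizes. Every stochastic step takes an explicit integer
seed, and `simulate_cds()` restores the caller's RNG state, so
workflows are reproducible end to end.
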