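#' Specification for a synthetic CDS set
#'
#' Describes a set of i.i.d.-codon coding sequences with controllable
#' codon-usage structure, used to validate the analysis pipeline.
#' Within each synonymous family, a sequence draws its codon-preference
#' vector from a Dirichlet distribution whose mean is tilted towards
#' G/C third bases by `exp(beta)` and whose concentration
#' (`dirichlet_conc`, total alpha mass per family) controls
#' between-sequence preference noise: large values give near-identical
#' preferences close to the tilted mean, values near zero give
#' one-codon-per-family sequences (maximal bias, ENC near 20).
#'
#' @param n_seqs Number of sequences.
#' @param n_codons Amino-acid codons per sequence (>= 50); a stop codon
#'   is appended, so emitted sequences have `3 * (n_codons + 1)` bases.
#'   Default 625 codons gives ~1.9 kb sequences, the size of a small
#'   circular ssDNA viral CDS.
#' @param aa_weights Named probabilities over the 18 amino acids with
#'   synonymous families plus Met and Trp; default uniform over 20.
#' @param beta Log-linear weight on a G or C third base (0 = unbiased).
#' @param dirichlet_conc Family-level Dirichlet concentration (> 0).
#' @param seed Integer seed; generation is fully reproducible.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_seqs = 41L, n_codons = 625L,
                           aa_weights = NULL, beta = 0,
                           dirichlet_conc = 50, seed = 1L) {
  aas <- sort(unique(GENETIC_CODE_DNA[GENETIC_CODE_DNA != "*"]))
  if (is.null(aa_weights)) {
    aa_weights <- stats::setNames(rep(1 / length(aas), length(aas)), aas)
  }
  if (!setequal(names(aa_weights), aas)) {
    stop("aa_weights must be named by the 20 standard amino acids")
  }
  if (any(aa_weights < 0) || abs(sum(aa_weights) - 1) > 1e-8) {
    stop("aa_weights must be non-negative and sum to 1")
  }
  if (n_codons < 50L) stop("n_codons must be >= 50")
  if (dirichlet_conc <= 0) stop("dirichlet_conc must be > 0")
  structure(list(n_seqs = as.integer(n_seqs),
                 n_codons = as.integer(n_codons),
                 aa_weights = aa_weights[aas], beta = beta,
                 dirichlet_conc = dirichlet_conc,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Simulate coding sequences with known codon-usage structure
#'
#' For each sequence: per-family codon preferences are drawn from the
#' spec's tilted Dirichlet, amino acids are drawn i.i.d. from
#' `aa_weights`, codons are emitted from the realized preferences, and
#' a TAA stop codon is appended. The returned truth sidecar records
#' every realized preference, so pipeline closure (RSCU recovering the
#' generating preferences) is testable.
#'
#' @param spec A `synthetic_spec`.
#' @return List with `seqs` (named character vector of CDS) and `truth`
#'   (tibble: `id`, `aa`, `codon`, `preference`).
#' @examples
#' sim <- simulate_cds(synthetic_spec(n_seqs = 2, n_codons = 60, seed = 7))
#' nchar(sim$seqs)
#' @export
simulate_cds <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  aas <- names(spec$aa_weights)
  # Family Dirichlet means: tilt codon c by exp(beta * [third base G/C])
  fam_alpha <- lapply(SYNONYMOUS_FAMILIES, function(fam) {
    tilt <- exp(spec$beta * (codon_third_base(fam) %in% c("G", "C")))
    spec$dirichlet_conc * tilt / sum(tilt)
  })
  ids <- sprintf("sim%03d", seq_len(spec$n_seqs))
  truth <- list()
  seqs <- character(spec$n_seqs)
  for (i in seq_len(spec$n_seqs)) {
    prefs <- lapply(fam_alpha, rdirichlet1)
    for (aa in names(prefs)) names(prefs[[aa]]) <- SYNONYMOUS_FAMILIES[[aa]]
    prefs[["M"]] <- c(ATG = 1)
    prefs[["W"]] <- c(TGG = 1)
    aa_draw <- sample(aas, spec$n_codons, replace = TRUE,
                      prob = spec$aa_weights)
    codons <- vapply(aa_draw, function(aa) {
      p <- prefs[[aa]]
      names(p)[sample.int(length(p), 1L, prob = p)]
    }, character(1))
    seqs[i] <- paste0(paste(codons, collapse = ""), "TAA")
    truth[[i]] <- tibble::tibble(
      id = ids[i],
      aa = rep(names(SYNONYMOUS_FAMILIES),
               lengths(SYNONYMOUS_FAMILIES)),
      codon = unlist(SYNONYMOUS_FAMILIES, use.names = FALSE),
      preference = unlist(prefs[names(SYNONYMOUS_FAMILIES)],
                          use.names = FALSE))
  }
  names(seqs) <- ids
  list(seqs = seqs, truth = do.call(rbind, truth))
}

# One Dirichlet draw via normalized gammas; degenerate all-zero draws
# (possible for tiny concentrations) fall back to a single random codon.
#' @keywords internal
rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) <= 0) {
    g <- as.numeric(seq_along(alpha) == sample.int(length(alpha), 1L))
  }
  g / sum(g)
}

#' @keywords internal
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

#' @keywords internal
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Simulate two populations differing in third-position GC bias
#'
#' Convenience wrapper generating two labelled populations (e.g.
#' TTSuV1-like and TTSuV2-like) at different `beta`, sharing all other
#' settings, for between-population comparisons and the recombination
#' scan's no-recombination scenario.
#'
#' @param n_each Sequences per population.
#' @param beta_a,beta_b Third-position GC bias of each population.
#' @param n_codons Codons per sequence.
#' @param seed Integer seed.
#' @return List with `seqs` (named vector, prefixes "A_" / "B_"),
#'   `population` (named factor) and the two truth tibbles.
#' @export
simulate_two_populations <- function(n_each = 20L, beta_a = 0,
                                     beta_b = 1, n_codons = 625L,
                                     seed = 1L) {
  sim_a <- simulate_cds(synthetic_spec(n_seqs = n_each, n_codons = n_codons,
                                       beta = beta_a, seed = seed))
  sim_b <- simulate_cds(synthetic_spec(n_seqs = n_each, n_codons = n_codons,
                                       beta = beta_b, seed = seed + 1L))
  seqs <- c(stats::setNames(sim_a$seqs, paste0("A_", names(sim_a$seqs))),
            stats::setNames(sim_b$seqs, paste0("B_", names(sim_b$seqs))))
  pop <- factor(rep(c("A", "B"), each = n_each))
  names(pop) <- names(seqs)
  list(seqs = seqs, population = pop,
       truth_a = sim_a$truth, truth_b = sim_b$truth)
}
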