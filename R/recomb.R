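#' Sliding-window identity profiles against a reference
#'
#' For each non-reference record in an alignment, computes the fraction
#' of identical bases to the reference in sliding windows — the
#' distance-to-reference graph used for visual recombination screening.
#' Similarity (identity) is reported rather than distance; the two are
#' monotone-equivalent. Columns where either sequence carries a gap or N
#' are excluded from both numerator and denominator; windows retaining
#' fewer than 10 comparable columns yield `NA`. Only full windows are
#' profiled, so a tail shorter than `window` is not covered.
#'
#' @param aln Alignment from [read_alignment()], or a list with `seqs`
#'   (named equal-length character vector) and `ncol`.
#' @param reference Id of the reference record.
#' @param window Window width in alignment columns (>= 10).
#' @param step Step between window starts (>= 1).
#' @return Tibble with columns `query`, `reference`, `start`, `end`,
#'   `center`, `identity` (1-based inclusive coordinates).
#' @export
distance_profiles <- function(aln, reference, window = 60L, step = 30L) {
  stopifnot(is.list(aln), !is.null(aln$seqs))
  if (window < 10L) stop("window must be >= 10")
  if (step < 1L) stop("step must be >= 1")
  seqs <- aln$seqs
  if (!reference %in% names(seqs)) {
    stop("reference id '", reference, "' not present in alignment")
  }
  ncol <- nchar(seqs[[1]])
  starts <- seq.int(1L, ncol - window + 1L, by = step)
  ends <- starts + window - 1L
  centers <- (starts + ends) / 2
  ref_chars <- strsplit(seqs[[reference]], "")[[1]]
  ref_ok <- ref_chars %in% c("A", "C", "G", "T")
  queries <- setdiff(names(seqs), reference)
  rows <- lapply(queries, function(q) {
    q_chars <- strsplit(seqs[[q]], "")[[1]]
    comparable <- ref_ok & q_chars %in% c("A", "C", "G", "T")
    match_col <- comparable & (q_chars == ref_chars)
    cum_c <- cumsum(comparable)
    cum_m <- cumsum(match_col)
    n_comp <- cum_c[ends] - c(0, cum_c)[starts]
    n_match <- cum_m[ends] - c(0, cum_m)[starts]
    identity <- ifelse(n_comp >= 10L, n_match / n_comp, NA_real_)
    tibble::tibble(query = q, reference = reference,
                   start = starts, end = ends, center = centers,
                   identity = identity)
  })
  do.call(rbind, rows)
}

#' Flag crossovers between identity profiles
#'
#' Scans every pair of query profiles for alignment intervals where the
#' two lines of the distance-to-reference graph intersect: the sign of
#' the identity difference flips between consecutive windows whose
#' absolute difference is at least `min_gap`. Windows where the lines
#' are closer than `min_gap` (the transition zone around a breakpoint,
#' or plain noise) and windows with missing identity are skipped, so a
#' flip is flagged between the last clearly-separated window on one
#' side and the first on the other. A crossing pair of lines is the
#' classic visual signature of a recombination breakpoint. The
#' intersection coordinate is interpolated linearly between the two
#' flagged window centers.
#'
#' @param profiles Tibble from [distance_profiles()] (all queries must
#'   share the window grid and reference).
#' @param min_gap Minimum identity difference on each side of a flip
#'   (default 0.05, suppressing noise crossings).
#' @param max_span Maximum distance in alignment columns between the
#'   two flanking windows of a flip; default twice the window width. A
#'   genuine breakpoint's clearly-separated flanks sit just outside the
#'   transition zone, whereas isolated noise excursions of opposite
#'   sign far apart do not mark a crossover.
#' @return Tibble with columns `query_a`, `query_b`, `position`,
#'   `gap_before`, `gap_after`; zero rows when no crossover is found.
#' @export
detect_crossovers <- function(profiles, min_gap = 0.05, max_span = NULL) {
  stopifnot(is.data.frame(profiles))
  if (is.null(max_span)) {
    max_span <- 2 * (profiles$end[1] - profiles$start[1] + 1)
  }
  queries <- unique(profiles$query)
  grids <- lapply(queries, function(q) profiles$center[profiles$query == q])
  if (length(queries) >= 2L &&
      !all(vapply(grids[-1], identical, logical(1), grids[[1]]))) {
    stop("profiles do not share a common window grid")
  }
  out <- list()
  if (length(queries) >= 2L) {
    for (i in seq_len(length(queries) - 1L)) {
      for (j in seq.int(i + 1L, length(queries))) {
        a <- profiles[profiles$query == queries[i], ]
        b <- profiles[profiles$query == queries[j], ]
        d <- a$identity - b$identity
        ok <- which(!is.na(d) & abs(d) >= min_gap)
        if (length(ok) < 2L) next
        d_ok <- d[ok]
        cen <- a$center[ok]
        for (w in seq_len(length(ok) - 1L)) {
          d1 <- d_ok[w]
          d2 <- d_ok[w + 1L]
          if (sign(d1) * sign(d2) < 0 &&
              cen[w + 1L] - cen[w] <= max_span) {
            pos <- cen[w] + (cen[w + 1L] - cen[w]) * abs(d1) / (abs(d1) + abs(d2))
            out[[length(out) + 1L]] <- tibble::tibble(
              query_a = queries[i], query_b = queries[j],
              position = pos, gap_before = abs(d1), gap_after = abs(d2))
          }
        }
      }
    }
  }
  if (length(out) == 0L) {
    return(tibble::tibble(query_a = character(0), query_b = character(0),
                          position = numeric(0), gap_before = numeric(0),
                          gap_after = numeric(0)))
  }
  do.call(rbind, out)
}
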