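#' Correspondence analysis of a non-negative table
#'
#' Chi-square-metric ordination, as conventionally applied to per-gene
#' RSCU matrices: relative frequencies `P = X / N`, row and column
#' masses `r`, `c`, standardized residuals
#' `S = Dr^-1/2 (P - r c') Dc^-1/2`, singular value decomposition of S.
#' Principal row coordinates scale the left singular vectors by the
#' singular values over the root row masses (and columns analogously);
#' axis k carries inertia fraction `sigma_k^2 / sum(sigma^2)`, and total
#' inertia equals the table's Pearson chi-square over its grand total.
#'
#' Axis signs are not identifiable; they are fixed so each axis's
#' largest-magnitude column loading is positive. All-zero columns are
#' dropped with a warning (their column mass would be zero).
#'
#' @param x Non-negative numeric matrix (e.g. genes x 59 RSCU values),
#'   no all-zero rows.
#' @return Object of class `coa_result`: list with `row_coords`,
#'   `col_coords` (principal coordinates, axes in columns),
#'   `inertia_fraction`, `total_inertia`, and `dropped_cols`.
#' @export
correspondence_analysis <- function(x) {
  x <- as.matrix(x)
  if (any(x < 0)) stop("correspondence analysis input must be non-negative")
  if (any(rowSums(x) == 0)) {
    stop("all-zero row(s): ",
         paste(utils::head(which(rowSums(x) == 0)), collapse = ", "))
  }
  dropped <- colnames(x)[colSums(x) == 0]
  if (length(dropped) > 0L) {
    warning("dropping ", length(dropped), " all-zero column(s) before CA")
    x <- x[, colSums(x) > 0, drop = FALSE]
  }
  n_axes <- min(nrow(x), ncol(x)) - 1L
  p <- x / sum(x)
  r <- rowSums(p)
  cc <- colSums(p)
  s <- diag(1 / sqrt(r)) %*% (p - tcrossprod(r, cc)) %*% diag(1 / sqrt(cc))
  sv <- svd(s)
  d <- sv$d[seq_len(n_axes)]
  # absolute floor: S entries are O(1), so singular values ~1e-15 are
  # numerically zero (exact-independence tables)
  tol <- max(dim(x)) * max(sv$d, 1) * .Machine$double.eps * 100
  keep <- which(d > tol)
  d <- d[keep]
  u <- sv$u[, keep, drop = FALSE]
  v <- sv$v[, keep, drop = FALSE]
  # col standard coordinates decide the sign convention
  for (k in seq_along(d)) {
    load <- v[, k] / sqrt(cc)
    if (load[which.max(abs(load))] < 0) {
      u[, k] <- -u[, k]
      v[, k] <- -v[, k]
    }
  }
  row_coords <- if (length(d)) sweep(u, 2, d, `*`) / sqrt(r) else
    matrix(0, nrow(x), 0)
  col_coords <- if (length(d)) sweep(v, 2, d, `*`) / sqrt(cc) else
    matrix(0, ncol(x), 0)
  axis_names <- if (length(d)) paste0("Axis", seq_along(d)) else character(0)
  dimnames(row_coords) <- list(rownames(x), axis_names)
  dimnames(col_coords) <- list(colnames(x), axis_names)
  total <- sum(sv$d[seq_len(n_axes)]^2)
  frac <- if (total > 0) d^2 / total else numeric(0)
  structure(list(row_coords = row_coords, col_coords = col_coords,
                 inertia_fraction = frac, total_inertia = total,
                 dropped_cols = dropped),
            class = "coa_result")
}

#' @export
print.coa_result <- function(x, ...) {
  k <- min(4L, length(x$inertia_fraction))
  cat("Correspondence analysis:", nrow(x$row_coords), "rows,",
      nrow(x$col_coords), "columns; total inertia",
      format(x$total_inertia, digits = 4), "\n")
  if (k > 0) {
    cat("Leading axis inertia:",
        paste0(round(100 * x$inertia_fraction[seq_len(k)], 2), "%",
               collapse = ", "), "\n")
  }
  invisible(x)
}

#' Hierarchical clustering of genomes by RSCU
#'
#' Pairwise Euclidean distances between rows, agglomerated by
#' unweighted pair-group average linkage (UPGMA), the default
#' "between-groups" method of classic statistics packages. Complete and
#' Ward linkage are selectable for sensitivity checks.
#'
#' @param x Numeric matrix with unique row labels (e.g. from
#'   [rscu_matrix()]).
#' @param method Linkage: "average" (default), "complete" or "ward.D2".
#' @return An object of class [stats::hclust].
#' @export
hierarchical_cluster <- function(x, method = c("average", "complete",
                                               "ward.D2")) {
  method <- match.arg(method)
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need at least 2 rows to cluster")
  if (is.null(rownames(x)) || anyDuplicated(rownames(x))) {
    stop("rows must carry unique labels")
  }
  stats::hclust(stats::dist(x, method = "euclidean"), method = method)
}

#' Cut a dendrogram into k clusters
#'
#' Clusters are re-numbered by first leaf appearance in the input order,
#' so cluster 1 always contains the first row.
#'
#' @param tree An [stats::hclust] object.
#' @param k Number of clusters, between 1 and the number of leaves.
#' @return Named integer vector mapping leaf label to cluster id.
#' @export
cut_tree <- function(tree, k) {
  stopifnot(inherits(tree, "hclust"))
  n <- length(tree$labels)
  if (k < 1L || k > n) stop("k must be between 1 and ", n)
  cl <- stats::cutree(tree, k = k)
  relabel <- stats::setNames(seq_along(unique(cl)), unique(cl))
  stats::setNames(as.integer(relabel[as.character(cl)]), names(cl))
}

#' Write a dendrogram as Newick
#'
#' @param tree An [stats::hclust] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(tree, path) {
  stopifnot(inherits(tree, "hclust"))
  ape::write.tree(ape::as.phylo(tree), file = path)
  invisible(path)
}
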