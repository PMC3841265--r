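#' Spearman rank correlation with significance banding
#'
#' Spearman's rho as the Pearson correlation of average-rank vectors.
#' The two-sided p-value comes from the t approximation with n - 2
#' degrees of freedom; for n < 10 the exact permutation distribution of
#' rho is enumerated instead. Significance is reported in the three
#' bands conventional in the virology literature: `NS` (p > 0.05), `*`
#' (0.01 < p < 0.05) and `**` (p < 0.01).
#'
#' @param x,y Numeric vectors of equal length >= 3, no missing values.
#' @return Object of class `correlation_result`: list with `r`, `p`,
#'   `n`, `band` (one of "NS", "0.01<p<0.05", "p<0.01") and `stars`
#'   ("NS", "*", "**").
#' @examples
#' spearman(1:5, c(2, 1, 4, 3, 5))
#' @export
spearman <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3L) stop("need at least 3 paired observations")
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for a constant vector")
  }
  rx <- rank(x)
  ry <- rank(y)
  r <- stats::cor(rx, ry)
  p <- if (n < 10L) {
    perm_spearman_p(rx, ry, r)
  } else {
    if (abs(r) >= 1) {
      0
    } else {
      tstat <- r * sqrt((n - 2) / (1 - r^2))
      2 * stats::pt(-abs(tstat), df = n - 2)
    }
  }
  band <- if (p < 0.01) "p<0.01" else if (p < 0.05) "0.01<p<0.05" else "NS"
  stars <- c("p<0.01" = "**", "0.01<p<0.05" = "*", NS = "NS")[[band]]
  structure(list(r = r, p = p, n = n, band = band, stars = stars),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Spearman r = %.3f (n = %d, p = %.4g, %s)\n",
              x$r, x$n, x$p, x$band))
  invisible(x)
}

# Exact two-sided permutation p-value for |rho| >= |observed|,
# enumerating all n! orderings of one rank vector. Used for n < 10.
#' @keywords internal
perm_spearman_p <- function(rx, ry, r_obs) {
  perms <- all_permutations(length(rx))
  rx_c <- rx - mean(rx)
  denom_x <- sqrt(sum(rx_c^2))
  r_all <- apply(perms, 1, function(idx) {
    yy <- ry[idx]
    yy_c <- yy - mean(yy)
    sum(rx_c * yy_c) / (denom_x * sqrt(sum(yy_c^2)))
  })
  mean(abs(r_all) >= abs(r_obs) - 1e-12)
}

#' @keywords internal
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  for (i in seq_len(n)) {
    rows <- (i - 1L) * nrow(sub) + seq_len(nrow(sub))
    out[rows, 1L] <- i
    rest <- seq_len(n)[-i]
    out[rows, -1L] <- matrix(rest[sub], nrow(sub), n - 1L)
  }
  out
}

#' Pairwise Spearman correlation matrix over composition profiles
#'
#' All row-variable by column-variable Spearman correlations across a
#' set of per-sequence composition profiles, with the significance
#' banding used in published composition-correlation tables.
#'
#' @param profiles Data frame / tibble of per-sequence statistics, e.g.
#'   from [composition_profile()] or [ttsuv2_composition_fixture()].
#' @param rows,cols Character vectors of column names in `profiles`.
#' @return Tibble with columns `row`, `col`, `r`, `p`, `n`, `band`,
#'   `stars`.
#' @export
correlation_matrix <- function(profiles, rows, cols) {
  stopifnot(is.data.frame(profiles), nrow(profiles) >= 3L)
  unknown <- setdiff(c(rows, cols), names(profiles))
  if (length(unknown) > 0L) {
    stop("unknown variable(s): ", paste(unknown, collapse = ", "))
  }
  grid <- expand.grid(row = rows, col = cols, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    cr <- spearman(profiles[[grid$row[i]]], profiles[[grid$col[i]]])
    tibble::tibble(row = grid$row[i], col = grid$col[i],
                   r = cr$r, p = cr$p, n = cr$n,
                   band = cr$band, stars = cr$stars)
  })
  do.call(rbind, res)
}
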