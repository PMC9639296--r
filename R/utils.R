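#' Log2 transform of TPM with pseudocount 1
#'
#' The analysis scale used throughout the package for expression values.
#'
#' @param x numeric vector or matrix of TPM values (non-negative).
#' @return `log2(x + 1)`, same shape as `x`.
#' @export
log2p1 <- function(x) log2(x + 1)

#' @keywords internal
#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Membership of 0-based positions in disjoint sorted 0-based half-open
# intervals on one chromosome. starts/ends must come from merged intervals.
#' @noRd
.points_in_sorted_intervals <- function(pos, starts, ends) {
  if (length(starts) == 0L) return(rep(FALSE, length(pos)))
  idx <- findInterval(pos, starts)
  ok <- idx > 0L
  ok[ok] <- pos[ok] < ends[idx[ok]]
  ok
}

# Count positions falling in [ws, ws + width) for many window starts.
# pos must be sorted. Positions and starts are 0-based integers.
#' @noRd
.window_point_counts <- function(pos, ws, width) {
  findInterval(ws + width - 0.5, pos) - findInterval(ws - 0.5, pos)
}

#' @noRd
.chrom_lengths <- function(genome) {
  stats::setNames(genome$chroms$length, genome$chroms$name)
}

# Column standard deviations of a matrix (denominator n - 1).
#' @noRd
.col_sds <- function(m) {
  n <- nrow(m)
  mu <- colMeans(m)
  sqrt(pmax(colSums(m^2) - n * mu^2, 0) / (n - 1))
}

# Pearson correlation of paired columns: cor(a[, i], b[, i]) for each i.
#' @noRd
.paired_col_cor <- function(a, b) {
  n <- nrow(a)
  ac <- sweep(a, 2L, colMeans(a))
  bc <- sweep(b, 2L, colMeans(b))
  num <- colSums(ac * bc)
  den <- sqrt(colSums(ac^2) * colSums(bc^2))
  ifelse(den > 0, num / den, NA_real_)
}

# Two-sided p-value for a correlation r at sample size n via the t transform.
#' @noRd
.cor_pvalue <- function(r, n) {
  r2 <- pmin(r^2, 1 - 1e-12)
  tt <- abs(r) * sqrt((n - 2) / (1 - r2))
  pmax(2 * stats::pt(-tt, df = n - 2), 1e-300)
}

# Deterministic derived seed, kept well below 2^31.
#' @noRd
.sub_seed <- function(seed, k) (as.integer(seed) %% 1000000L) * 1000L + (k %% 1000L)
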