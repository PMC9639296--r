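#' Merge open-chromatin peak sets
#'
#' Union of all input intervals with overlapping or book-ended intervals
#' merged (gap 0), the standard multi-sample peak merge.
#'
#' @param peak_sets a [bn_intervals] or list of them.
#' @return merged [bn_intervals].
#' @export
merge_peaks <- function(peak_sets) {
  if (is.data.frame(peak_sets)) peak_sets <- list(peak_sets)
  all <- do.call(rbind, lapply(peak_sets, function(x)
    as.data.frame(x)[, c("chrom", "start", "end")]))
  if (nrow(all) == 0L) return(bn_intervals(all))
  out <- lapply(unique(all$chrom), function(nm) {
    d <- all[all$chrom == nm, , drop = FALSE]
    ir <- IRanges::reduce(IRanges::IRanges(d$start + 1, d$end))
    data.frame(chrom = nm, start = IRanges::start(ir) - 1, end = IRanges::end(ir))
  })
  bn_intervals(do.call(rbind, out))
}

#' Membership of lead SNPs in open-chromatin regions
#'
#' A lead at 0-based position p is inside `[start, end)` iff
#' `start <= p < end`; equivalently, a lead at 1-based position equal to an
#' interval's `end` is outside (half-open convention).
#'
#' @param leads data.frame with `chrom`, `pos` (0-based).
#' @param ocr a [bn_intervals] (merged internally if overlapping).
#' @return list with `n_in` and `flags` (the input plus logical `in_ocr`).
#' @export
leads_in_ocr <- function(leads, ocr) {
  ocr <- merge_peaks(ocr)
  flag <- rep(FALSE, nrow(leads))
  for (nm in unique(leads$chrom)) {
    li <- which(leads$chrom == nm)
    oi <- ocr$chrom == nm
    flag[li] <- .points_in_sorted_intervals(leads$pos[li],
                                            ocr$start[oi], ocr$end[oi])
  }
  leads$in_ocr <- flag
  list(n_in = sum(flag), flags = leads, in_ocr = flag)
}

#' Permutation test for lead-SNP enrichment in OCRs
#'
#' Default mode reshuffles lead positions uniformly per chromosome
#' (preserving per-chromosome lead counts) while the OCR set stays fixed;
#' `shuffle = "both"` additionally reshuffles OCR interval starts preserving
#' their lengths. `empirical_p = (1 + #\{null >= observed\}) / (n_perm + 1)`;
#' the CI is the 2.5/97.5 percentile band of the null counts.
#'
#' @param leads data.frame with `chrom`, `pos` (0-based).
#' @param ocr a [bn_intervals].
#' @param genome a [bn_genome] (chromosome lengths).
#' @param n_perm number of permutations (default 1000).
#' @param seed optional integer to seed the RNG locally.
#' @param shuffle `"leads"` (default) or `"both"`.
#' @return list with `observed`, `null_mean`, `ci` (length 2), `p`, `null`.
#' @export
ocr_permutation_test <- function(leads, ocr, genome, n_perm = 1000,
                                 seed = NULL, shuffle = c("leads", "both")) {
  shuffle <- match.arg(shuffle)
  if (!is.null(seed)) set.seed(seed)
  ocr <- merge_peaks(ocr)
  len <- .chrom_lengths(genome)
  observed <- leads_in_ocr(leads, ocr)$n_in
  n_per <- table(leads$chrom)
  chroms <- names(n_per)
  null <- vapply(seq_len(n_perm), function(i) {
    oc <- ocr
    if (shuffle == "both") {
      w <- oc$end - oc$start
      oc$start <- floor(runif(nrow(oc), 0, len[oc$chrom] - w))
      oc$end <- oc$start + w
      oc <- merge_peaks(oc)
    }
    tot <- 0L
    for (nm in chroms) {
      pos <- floor(runif(n_per[[nm]], 0, len[[nm]]))
      oi <- oc$chrom == nm
      o <- order(oc$start[oi])
      tot <- tot + sum(.points_in_sorted_intervals(
        pos, oc$start[oi][o], oc$end[oi][o]))
    }
    tot
  }, integer(1))
  list(observed = observed, null_mean = mean(null),
       ci = stats::quantile(null, c(0.025, 0.975), names = FALSE),
       p = (1 + sum(null >= observed)) / (n_perm + 1),
       null = null)
}

#' Compare explained variance of in-OCR versus out-of-OCR eQTLs
#'
#' Two-sample KS test of lead `r2` split by OCR membership. The one-sided
#' P (`alternative = "less"` with in-OCR as the first sample) tests whether
#' in-OCR eQTLs have stochastically larger explained variance.
#'
#' @param eqtls eQTL data.frame with `lead_r2`.
#' @param in_ocr logical vector aligned with `eqtls` rows (see
#'   [leads_in_ocr()]).
#' @return list with `ks_stat`, `p` (two-sided), `p_one_sided`,
#'   `mean_in`, `mean_out`, `direction`.
#' @export
r2_in_vs_out <- function(eqtls, in_ocr) {
  x <- eqtls$lead_r2[in_ocr]
  y <- eqtls$lead_r2[!in_ocr]
  if (length(x) < 2L || length(y) < 2L)
    stop("need at least two eQTLs on each side of the OCR split")
  two <- suppressWarnings(stats::ks.test(x, y))
  one <- suppressWarnings(stats::ks.test(x, y, alternative = "less"))
  list(ks_stat = unname(two$statistic), p = two$p.value,
       p_one_sided = one$p.value, mean_in = mean(x), mean_out = mean(y),
       direction = if (mean(x) >= mean(y)) "in_ocr_larger" else "out_ocr_larger")
}
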