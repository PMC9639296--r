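#' Census of local-eGene pairs by intervening gene count
#'
#' For `k = 0..max_intervening`, counts pairs of local-eQTL genes on the same
#' chromosome separated by exactly `k` genes (ordinal difference `k + 1`);
#' `k = 0` are adjacent pairs. Each unordered pair is counted once.
#'
#' @param local_genes character vector of gene ids with a local eQTL.
#' @param genome a [bn_genome].
#' @param max_intervening largest `k` reported (default 10).
#' @return data.frame with `intervening` (0..max) and `n_pairs`.
#' @export
adjacency_census <- function(local_genes, genome, max_intervening = 10L) {
  g <- genome$genes
  sel <- g[g$gene_id %in% local_genes, c("chrom", "ordinal")]
  counts <- integer(max_intervening + 1L)
  for (nm in unique(sel$chrom)) {
    o <- sort(sel$ordinal[sel$chrom == nm])
    if (length(o) < 2L) next
    for (k in 0:max_intervening) {
      # pairs with ordinal difference exactly k + 1
      counts[k + 1L] <- counts[k + 1L] + sum((o + k + 1L) %in% o)
    }
  }
  data.frame(intervening = 0:max_intervening, n_pairs = counts)
}

#' Permutation test for adjacency enrichment of local eGenes
#'
#' Each permutation draws the same number of genes uniformly without
#' replacement and counts adjacent (`k = 0`) pairs; the empirical P is the
#' fraction of permutations reaching the observed adjacent-pair count.
#'
#' @inheritParams adjacency_census
#' @param n_perm number of permutations (default 1000).
#' @param seed optional integer to seed the RNG locally.
#' @return list with `observed`, `null` (integer vector) and `p`.
#' @export
adjacency_permutation <- function(local_genes, genome, n_perm = 1000,
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- genome$genes
  n_local <- sum(g$gene_id %in% local_genes)
  observed <- adjacency_census(local_genes, genome, 0L)$n_pairs[1L]
  # genes are stored in coordinate order, so row adjacency within a
  # chromosome is exactly ordinal adjacency
  null <- vapply(seq_len(n_perm), function(i) {
    pick <- sort(sample.int(nrow(g), n_local))
    d <- diff(pick) == 1L
    sum(d & g$chrom[pick[-length(pick)]] == g$chrom[pick[-1L]])
  }, integer(1))
  list(observed = observed, null = null, p = mean(null >= observed))
}

#' Classify adjacent gene pairs by local-eQTL status
#'
#' Adjacent pairs (consecutive gene ordinals on one chromosome, strand
#' ignored) are labeled `I` (both genes have a local eQTL), `II` (exactly
#' one) or `III` (neither). Class `IV` is a random sample of non-adjacent
#' pairs with local eQTLs on both genes, the comparison baseline.
#'
#' @inheritParams adjacency_census
#' @param n_class_iv size of the class-IV sample (default: the class-I
#'   count).
#' @param seed optional integer to seed the RNG locally (class-IV sampling).
#' @return data.frame with `gene_a`, `gene_b`, `intervening`, `pair_class`.
#' @export
classify_pairs <- function(local_genes, genome, n_class_iv = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- genome$genes
  is_local <- g$gene_id %in% local_genes
  adj <- which(diff(g$ordinal) == 1L & g$chrom[-nrow(g)] == g$chrom[-1L])
  a <- adj; b <- adj + 1L
  n_loc_pair <- is_local[a] + is_local[b]
  pairs <- data.frame(gene_a = g$gene_id[a], gene_b = g$gene_id[b],
                      intervening = 0L,
                      pair_class = c("III", "II", "I")[n_loc_pair + 1L])
  n_iv <- n_class_iv %||% sum(pairs$pair_class == "I")
  loc_idx <- which(is_local)
  if (n_iv > 0 && length(loc_idx) >= 2L) {
    got <- 0L; rows <- list()
    while (got < n_iv) {
      ij <- sample(loc_idx, 2L)
      ij <- ij[order(ij)]
      adjacent <- g$chrom[ij[1]] == g$chrom[ij[2]] &&
        abs(g$ordinal[ij[1]] - g$ordinal[ij[2]]) == 1L
      if (adjacent) next
      got <- got + 1L
      rows[[got]] <- data.frame(
        gene_a = g$gene_id[ij[1]], gene_b = g$gene_id[ij[2]],
        intervening = if (g$chrom[ij[1]] == g$chrom[ij[2]])
          abs(g$ordinal[ij[1]] - g$ordinal[ij[2]]) - 1L else NA_integer_,
        pair_class = "IV")
    }
    pairs <- rbind(pairs, do.call(rbind, rows))
  }
  rownames(pairs) <- NULL
  pairs
}

#' Expression correlation of gene pairs and between-class KS tests
#'
#' Computes the Pearson correlation of `log2(TPM+1)` across accessions for
#' each pair and compares the per-class correlation distributions with
#' two-sample Kolmogorov-Smirnov tests.
#'
#' @param pairs data.frame from [classify_pairs()].
#' @param expr a [bn_expr].
#' @return list with `pairs` (plus `pcc`) and `ks`, one row per class pair
#'   (`class_a`, `class_b`, `ks_stat`, `ks_p`).
#' @export
pair_correlations <- function(pairs, expr) {
  A <- log2p1(expr$tpm[, pairs$gene_a, drop = FALSE])
  B <- log2p1(expr$tpm[, pairs$gene_b, drop = FALSE])
  pairs$pcc <- .paired_col_cor(A, B)
  cls <- sort(unique(pairs$pair_class))
  ks <- list()
  if (length(cls) > 1L) {
    cmb <- utils::combn(cls, 2L)
    for (j in seq_len(ncol(cmb))) {
      x <- pairs$pcc[pairs$pair_class == cmb[1, j]]
      y <- pairs$pcc[pairs$pair_class == cmb[2, j]]
      if (length(x) < 2L || length(y) < 2L) next
      kt <- suppressWarnings(stats::ks.test(x, y))
      ks[[j]] <- data.frame(class_a = cmb[1, j], class_b = cmb[2, j],
                            ks_stat = unname(kt$statistic), ks_p = kt$p.value)
    }
  }
  list(pairs = pairs,
       ks = if (length(ks)) do.call(rbind, ks) else
         data.frame(class_a = character(), class_b = character(),
                    ks_stat = numeric(), ks_p = numeric()))
}

#' Chromatin-state strata of class-I adjacent pairs
#'
#' Each class-I gene is represented by the lead SNP of its minimum-P local
#' eQTL; the pair's stratum is `both_open`, `one_open` or `both_closed`
#' according to OCR membership of the two leads. Welch t-tests compare the
#' pair correlation between same-state strata and `one_open`.
#'
#' @param pairs data.frame of class-I pairs with a `pcc` column (see
#'   [pair_correlations()]).
#' @param eqtls classified eQTL data.frame (local records used).
#' @param ocr OCR [bn_intervals].
#' @return list with `pairs` (plus `stratum`) and `tests` (Welch t-tests,
#'   possibly empty when a stratum is too small).
#' @export
chromatin_strata <- function(pairs, eqtls, ocr) {
  pairs <- pairs[pairs$pair_class == "I", , drop = FALSE]
  loc <- eqtls[eqtls$category == "local", , drop = FALSE]
  loc <- loc[order(loc$lead_p), , drop = FALSE]
  loc <- loc[!duplicated(loc$gene_id), , drop = FALSE]  # min-P lead per gene
  lead_of <- function(ids) loc[match(ids, loc$gene_id), c("chrom", "pos")]
  in_ocr <- function(ld) leads_in_ocr(ld, ocr)$in_ocr
  open_a <- in_ocr(lead_of(pairs$gene_a))
  open_b <- in_ocr(lead_of(pairs$gene_b))
  n_open <- open_a + open_b
  pairs$stratum <- c("both_closed", "one_open", "both_open")[n_open + 1L]
  welch <- function(sa, sb) {
    x <- pairs$pcc[pairs$stratum == sa]
    y <- pairs$pcc[pairs$stratum == sb]
    if (length(x) < 2L || length(y) < 2L) return(NULL)
    tt <- stats::t.test(x, y)  # Welch by default
    data.frame(stratum_a = sa, stratum_b = sb, mean_a = mean(x),
               mean_b = mean(y), t = unname(tt$statistic), p = tt$p.value)
  }
  tests <- rbind(welch("both_open", "one_open"), welch("both_closed", "one_open"))
  list(pairs = pairs,
       tests = tests %||% data.frame(stratum_a = character(),
                                     stratum_b = character(), mean_a = numeric(),
                                     mean_b = numeric(), t = numeric(),
                                     p = numeric()))
}
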