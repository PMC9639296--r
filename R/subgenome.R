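#' Homoeolog pairing by reciprocal best hit
#'
#' Pair (a, c) is kept iff c is a's best-scoring Cn hit AND a is c's
#' best-scoring An hit. Score ties are broken by lexicographic gene id, so a
#' tie at the best hit that breaks reciprocity simply yields no pair.
#'
#' @param similarity data.frame with `an_gene`, `cn_gene`, `score` (may be
#'   sparse; missing combinations score -Inf).
#' @return data.frame of pairs: `an_gene`, `cn_gene`, `score`. The output is
#'   a matching: each gene appears at most once.
#' @export
rbh_pairs <- function(similarity) {
  s <- as.data.frame(similarity)[, c("an_gene", "cn_gene", "score")]
  s <- s[order(s$an_gene, -s$score, s$cn_gene), ]
  best_an <- s[!duplicated(s$an_gene), ]            # best Cn hit per An gene
  s2 <- s[order(s$cn_gene, -s$score, s$an_gene), ]
  best_cn <- s2[!duplicated(s2$cn_gene), ]          # best An hit per Cn gene
  m <- match(best_an$cn_gene, best_cn$cn_gene)
  recip <- !is.na(m) & best_cn$an_gene[m] == best_an$an_gene
  out <- best_an[recip, , drop = FALSE]
  out <- out[order(out$an_gene), ]
  rownames(out) <- NULL
  out
}

#' Regulation direction of homoeolog pairs from distant eQTLs
#'
#' Gene X is deemed to regulate its homoeolog Y when X's TSS lies within
#' `window` bp (inclusive) of any distant-eQTL lead of Y on X's chromosome.
#' Classes: `An_reg_Cn` / `Cn_reg_An` (asymmetric, aHGP), `mutual` and
#' `none` (symmetric, sHGP).
#'
#' @param pairs homoeolog pairs from [rbh_pairs()].
#' @param eqtls classified eQTL data.frame (distant records used).
#' @param genome a [bn_genome].
#' @param window TSS flank in bp (default 150 kb).
#' @return `pairs` with `reg_class` and `symmetric` (TRUE for sHGP) columns.
#' @export
regulation_class <- function(pairs, eqtls, genome, window = 1.5e5) {
  g <- genome$genes
  dist_eq <- eqtls[eqtls$category == "distant", , drop = FALSE]
  regulates <- function(x_ids, y_ids) {
    xi <- match(x_ids, g$gene_id)
    vapply(seq_along(x_ids), function(i) {
      ld <- dist_eq[dist_eq$gene_id == y_ids[i] &
                      dist_eq$chrom == g$chrom[xi[i]], , drop = FALSE]
      nrow(ld) > 0L && any(abs(ld$pos - g$tss[xi[i]]) <= window)
    }, logical(1))
  }
  an_reg <- regulates(pairs$an_gene, pairs$cn_gene)
  cn_reg <- regulates(pairs$cn_gene, pairs$an_gene)
  pairs$reg_class <- ifelse(an_reg & cn_reg, "mutual",
                     ifelse(an_reg, "An_reg_Cn",
                     ifelse(cn_reg, "Cn_reg_An", "none")))
  pairs$symmetric <- pairs$reg_class %in% c("none", "mutual")
  pairs
}

#' Expression propensity of homoeolog pairs
#'
#' Per pair: `log2fc = mean over accessions of log2(TPM_An + 1) -
#' log2(TPM_Cn + 1)` (positive = An-biased), with a paired two-sided t-test
#' across accessions and BH adjustment across all pairs. A pair is
#' imbalanced when `padj < 0.05`.
#'
#' @param pairs homoeolog pairs (needs `an_gene`, `cn_gene`).
#' @param expr a [bn_expr] covering both genes of every pair.
#' @return `pairs` with `log2fc`, `p`, `padj`, `imbalanced`.
#' @export
expression_propensity <- function(pairs, expr) {
  A <- log2p1(expr$tpm[, pairs$an_gene, drop = FALSE])
  C <- log2p1(expr$tpm[, pairs$cn_gene, drop = FALSE])
  n <- nrow(A)
  if (n < 30L) stop("need at least 30 accessions for propensity testing")
  d <- A - C
  mu <- colMeans(d)
  sdd <- .col_sds(d)
  tt <- mu / (sdd / sqrt(n))
  p <- pmax(2 * stats::pt(-abs(tt), df = n - 1), 1e-300)
  # degenerate zero-variance differences: no evidence either way when the
  # mean difference is also zero, overwhelming evidence otherwise
  p[sdd == 0 & mu == 0] <- 1
  p[sdd == 0 & mu != 0] <- 1e-300
  pairs$log2fc <- mu
  pairs$p <- p
  pairs$padj <- stats::p.adjust(p, method = "BH")
  pairs$imbalanced <- pairs$padj < 0.05
  pairs
}

#' Cross-homoeolog correlation and feedback grouping
#'
#' Computes the Pearson correlation of `log2(TPM+1)` between the two
#' homoeologs of each pair and groups pairs as `BG` (all), `Local`
#' (asymmetric pairs whose regulating gene carries a local eQTL) and
#' `NoLocal` (asymmetric pairs without), then compares the groups with
#' two-sample KS tests. Negative Local correlations are the signature of
#' feedback regulation maintaining partial expression dosage.
#'
#' @param pairs pairs with `reg_class` (from [regulation_class()]).
#' @param expr a [bn_expr].
#' @param eqtls classified eQTL data.frame supplying local eGenes.
#' @param condition_on `"regulating"` (default) or `"regulated"`: which gene
#'   of an asymmetric pair must carry the local eQTL to join `Local`.
#' @return list with `pairs` (plus `cross_pcc`, `group`), `tests` (KS rows)
#'   and `group_means`.
#' @export
feedback_analysis <- function(pairs, expr, eqtls,
                              condition_on = c("regulating", "regulated")) {
  condition_on <- match.arg(condition_on)
  loc_genes <- local_egenes(eqtls)
  A <- log2p1(expr$tpm[, pairs$an_gene, drop = FALSE])
  C <- log2p1(expr$tpm[, pairs$cn_gene, drop = FALSE])
  pairs$cross_pcc <- .paired_col_cor(A, C)
  a_is_reg <- pairs$reg_class == "An_reg_Cn"
  c_is_reg <- pairs$reg_class == "Cn_reg_An"
  key_gene <- ifelse(xor(a_is_reg, condition_on == "regulated"),
                     pairs$an_gene, pairs$cn_gene)
  ahgp <- a_is_reg | c_is_reg
  pairs$group <- ifelse(!ahgp, "BG",
                        ifelse(key_gene %in% loc_genes, "Local", "NoLocal"))
  ks_row <- function(ga, gb, x, y) {
    if (length(x) < 2L || length(y) < 2L) return(NULL)
    kt <- suppressWarnings(stats::ks.test(x, y))
    data.frame(group_a = ga, group_b = gb, ks_stat = unname(kt$statistic),
               ks_p = kt$p.value)
  }
  pl <- pairs$cross_pcc[pairs$group == "Local"]
  pn <- pairs$cross_pcc[pairs$group == "NoLocal"]
  tests <- rbind(ks_row("Local", "NoLocal", pl, pn),
                 ks_row("Local", "BG", pl, pairs$cross_pcc),
                 ks_row("NoLocal", "BG", pn, pairs$cross_pcc))
  gm <- tapply(pairs$cross_pcc, pairs$group, mean)
  list(pairs = pairs, tests = tests, group_means = gm)
}

#' TF enrichment among a gene set by permutation
#'
#' Compares the observed number of TF genes in `gene_ids` with null draws of
#' equally many genes taken uniformly from the genome.
#'
#' @param gene_ids character vector (e.g. both genes of all feedback pairs).
#' @param genome a [bn_genome] with `is_tf` flags.
#' @param n_perm number of permutations (default 1000).
#' @param seed optional integer to seed the RNG locally.
#' @return list with `observed`, `null`, `p` (fraction of null counts at or
#'   above the observed count).
#' @export
tf_enrichment <- function(gene_ids, genome, n_perm = 1000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- genome$genes
  gene_ids <- unique(gene_ids)
  observed <- sum(g$is_tf[match(gene_ids, g$gene_id)], na.rm = TRUE)
  k <- length(gene_ids)
  null <- vapply(seq_len(n_perm), function(i)
    sum(g$is_tf[sample.int(nrow(g), k)]), 0L)
  list(observed = observed, null = null, p = mean(null >= observed))
}

#' Full homoeolog-pair analysis
#'
#' Convenience wrapper chaining [rbh_pairs()], [regulation_class()],
#' [expression_propensity()], [feedback_analysis()] and [tf_enrichment()] on
#' the feedback-candidate pairs (aHGPs in the `Local` group).
#'
#' @param similarity similarity score table (see [rbh_pairs()]).
#' @param eqtls classified eQTL data.frame.
#' @param expr a [bn_expr].
#' @param genome a [bn_genome].
#' @param window regulation TSS window in bp (default 150 kb).
#' @param n_perm permutations for the TF enrichment.
#' @param seed optional integer seed for the TF enrichment permutations.
#' @return list with `pairs` (annotated HGP table), `feedback_tests`,
#'   `group_means`, `tf_enrichment`.
#' @export
subgenome_analysis <- function(similarity, eqtls, expr, genome,
                               window = 1.5e5, n_perm = 1000, seed = NULL) {
  pairs <- rbh_pairs(similarity)
  pairs <- pairs[pairs$an_gene %in% expr$gene_ids &
                   pairs$cn_gene %in% expr$gene_ids, , drop = FALSE]
  pairs <- regulation_class(pairs, eqtls, genome, window = window)
  pairs <- expression_propensity(pairs, expr)
  fb <- feedback_analysis(pairs, expr, eqtls)
  local_pairs <- fb$pairs[fb$pairs$group == "Local", , drop = FALSE]
  tfe <- tf_enrichment(c(local_pairs$an_gene, local_pairs$cn_gene),
                       genome, n_perm = n_perm, seed = seed)
  list(pairs = fb$pairs, feedback_tests = fb$tests,
       group_means = fb$group_means, tf_enrichment = tfe)
}
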