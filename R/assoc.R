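#' LD between two dosage vectors
#'
#' Squared Pearson correlation of additive dosages, the r-squared used for
#' clumping significant SNPs into eQTLs.
#'
#' @param a,b numeric dosage vectors of equal length.
#' @return r-squared in `[0, 1]`; 0 with a warning when either vector is
#'   constant.
#' @export
ld_r2 <- function(a, b) {
  if (length(a) != length(b)) stop("dosage vectors differ in length")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("ld_r2: constant dosage vector, returning 0")
    return(0)
  }
  stats::cor(a, b)^2
}

# Residualize a matrix of responses on covariates (with intercept).
#' @noRd
.residualize <- function(y, covariates) {
  if (is.null(covariates)) return(y)
  X <- cbind(1, as.matrix(covariates))
  y - X %*% qr.coef(qr(X), y)
}

# Core scan: marginal association of every SNP column with every gene column.
# X: accessions x SNPs dosage (complete); Y: accessions x genes log2(TPM+1),
# already covariate-residualized. Returns list(r, beta, p), SNPs x genes.
#' @noRd
.scan_core <- function(X, Y) {
  n <- nrow(X)
  sx <- .col_sds(X)
  sy <- .col_sds(Y)
  r <- suppressWarnings(stats::cor(X, Y))
  r[is.na(r)] <- 0
  p <- .cor_pvalue(r, n)
  const_gene <- sy == 0
  if (any(const_gene)) {
    warning("scan: ", sum(const_gene), " gene(s) with zero expression variance")
    p[, const_gene] <- 1
    r[, const_gene] <- 0
  }
  beta <- r * outer(1 / ifelse(sx > 0, sx, Inf), sy)
  list(r = r, beta = beta, p = p)
}

#' Per-gene association scan
#'
#' Ordinary least squares of `log2(TPM+1)` on additive dosage at every SNP:
#' `r2` is the squared Pearson correlation between dosage and (optionally
#' covariate-residualized) expression, `p` the two-sided t-test on the slope.
#'
#' @param gm a [bn_geno] with complete dosages (see [impute_mean()]).
#' @param expr a [bn_expr]; at least 30 accessions must be shared with `gm`.
#' @param gene_id gene to scan (a column of `expr`).
#' @param covariates optional numeric matrix (rows = accessions of the shared
#'   set, e.g. genotype PCs); expression is residualized on them.
#' @return data.frame with one row per SNP: `gene_id`, `snp_id`, `chrom`,
#'   `pos`, `beta`, `p`, `r2`.
#' @export
scan_gene <- function(gm, expr, gene_id, covariates = NULL) {
  acc <- .shared_accessions(gm, expr)
  y <- log2p1(expr$tpm[acc, gene_id, drop = FALSE])
  y <- .residualize(y, covariates)
  st <- .scan_core(gm$dosage[acc, , drop = FALSE], y)
  data.frame(gene_id = gene_id, snp_id = gm$snps$id, chrom = gm$snps$chrom,
             pos = gm$snps$pos, beta = st$beta[, 1L], p = st$p[, 1L],
             r2 = st$r[, 1L]^2, row.names = NULL)
}

#' Filter association statistics to the significant set
#'
#' @param stats data.frame with a `p` column (e.g. from [scan_gene()]).
#' @param threshold significance threshold on P (default `1e-6`, the
#'   effective-test-count-corrected genome-wide level).
#' @return rows with `p <= threshold`.
#' @export
significant_snps <- function(stats, threshold = 1e-6) {
  stats[stats$p <= threshold, , drop = FALSE]
}

#' Clump significant SNPs of one gene into eQTLs
#'
#' Greedy linkage clumping: the smallest-P SNP becomes the lead; every
#' remaining significant SNP with `ld_r2(lead, snp) > r2_min` joins it as a
#' member; repeat until no SNP is left. Every significant SNP ends up in
#' exactly one eQTL. P ties are broken by larger r2, then lower coordinate.
#'
#' @param sig_stats significant AssocStat rows for a single gene
#'   (from [significant_snps()]), carrying `snp_id`, `chrom`, `pos`, `p`,
#'   `r2`, `beta`.
#' @param gm the [bn_geno] the scan used (for member LD).
#' @param r2_min clumping threshold, strict inequality (default 0.2).
#' @return data.frame of eQTL records: `gene_id`, `lead_snp`, `chrom`, `pos`,
#'   `lead_p`, `lead_r2`, `lead_beta`, `n_members`, `members`
#'   (comma-separated snp ids).
#' @export
clump <- function(sig_stats, gm, r2_min = 0.2) {
  if (nrow(sig_stats) == 0L) return(.empty_eqtl_df())
  stopifnot(length(unique(sig_stats$gene_id)) == 1L)
  o <- order(sig_stats$p, -sig_stats$r2, sig_stats$chrom, sig_stats$pos)
  s <- sig_stats[o, , drop = FALSE]
  col <- match(s$snp_id, gm$snps$id)
  acc <- rownames(gm$dosage)
  out <- list()
  remaining <- seq_len(nrow(s))
  while (length(remaining)) {
    lead <- remaining[1L]
    lead_dos <- gm$dosage[, col[lead]]
    others <- remaining[-1L]
    if (length(others)) {
      r2 <- suppressWarnings(
        as.numeric(stats::cor(lead_dos, gm$dosage[, col[others], drop = FALSE]))^2)
      r2[is.na(r2)] <- 0
      absorbed <- others[r2 > r2_min]
    } else absorbed <- integer(0)
    grp <- c(lead, absorbed)
    out[[length(out) + 1L]] <- data.frame(
      gene_id = s$gene_id[lead], lead_snp = s$snp_id[lead],
      chrom = s$chrom[lead], pos = s$pos[lead],
      lead_p = s$p[lead], lead_r2 = s$r2[lead], lead_beta = s$beta[lead],
      n_members = length(grp),
      members = paste(s$snp_id[sort(grp)], collapse = ","))
    remaining <- setdiff(remaining, grp)
  }
  do.call(rbind, out)
}

#' @noRd
.empty_eqtl_df <- function() {
  data.frame(gene_id = character(), lead_snp = character(), chrom = character(),
             pos = numeric(), lead_p = numeric(), lead_r2 = numeric(),
             lead_beta = numeric(), n_members = integer(), members = character())
}

#' Classify an eQTL as local or distant
#'
#' Local iff the lead SNP is on the gene's chromosome and within `window` bp
#' of the gene body, boundaries inclusive: a lead exactly 500 kb before the
#' gene start is still local.
#'
#' @param eqtls eQTL data.frame from [clump()] (needs `chrom`, `pos`).
#' @param genome a [bn_genome].
#' @param window flank in bp on either side of the gene (default 500 kb, the
#'   approximate LD-decay distance).
#' @return `eqtls` with a `category` column, `"local"` or `"distant"`.
#' @export
classify_eqtl <- function(eqtls, genome, window = 5e5) {
  g <- genome$genes
  gi <- match(eqtls$gene_id, g$gene_id)
  if (anyNA(gi)) stop("eQTL for gene absent from genome")
  same <- eqtls$chrom == g$chrom[gi]
  # gene body [start, end) 0-based; inclusive +-window in 1-based terms
  inside <- eqtls$pos >= g$start[gi] - window & eqtls$pos <= g$end[gi] - 1L + window
  eqtls$category <- ifelse(same & inside, "local", "distant")
  eqtls
}

#' Map eQTLs for all genes of a study stage
#'
#' Runs the association scan over every (gene, SNP) pair, keeps associations
#' with `p <= threshold`, clumps them per gene by LD and classifies each
#' eQTL as local or distant. Genes whose 95th percentile of `log2(TPM+1)`
#' does not exceed `expr_floor` are excluded as low-expressed.
#'
#' @inheritParams scan_gene
#' @param genome a [bn_genome].
#' @param threshold significance threshold on P (default 1e-6).
#' @param r2_min LD clumping threshold (default 0.2).
#' @param window local/distant window in bp (default 500 kb).
#' @param expr_floor low-expression floor on the per-gene 95th percentile of
#'   `log2(TPM+1)` (default 0; genes at or below it are dropped).
#' @return data.frame of classified eQTL records, one row per eQTL, with a
#'   `stage` column from `expr$stage`.
#' @export
eqtl_map <- function(gm, expr, genome, threshold = 1e-6, r2_min = 0.2,
                     window = 5e5, expr_floor = 0, covariates = NULL) {
  acc <- .shared_accessions(gm, expr)
  Y <- log2p1(expr$tpm[acc, , drop = FALSE])
  q95 <- apply(Y, 2L, stats::quantile, probs = 0.95, names = FALSE)
  keep_gene <- which(q95 > expr_floor)
  Y <- .residualize(Y[, keep_gene, drop = FALSE], covariates)
  X <- gm$dosage[acc, , drop = FALSE]
  st <- .scan_core(X, Y)
  res <- list()
  for (j in seq_along(keep_gene)) {
    hit <- which(st$p[, j] <= threshold)
    if (!length(hit)) next
    gene <- colnames(Y)[j]
    sig <- data.frame(gene_id = gene, snp_id = gm$snps$id[hit],
                      chrom = gm$snps$chrom[hit], pos = gm$snps$pos[hit],
                      beta = st$beta[hit, j], p = st$p[hit, j],
                      r2 = st$r[hit, j]^2)
    res[[length(res) + 1L]] <- clump(sig, gm, r2_min = r2_min)
  }
  eqtls <- if (length(res)) do.call(rbind, res) else .empty_eqtl_df()
  eqtls <- classify_eqtl(eqtls, genome, window = window)
  eqtls$stage <- expr$stage
  rownames(eqtls) <- NULL
  eqtls
}

#' Per-gene eQTL summary
#'
#' @param eqtls classified eQTL data.frame (e.g. from [eqtl_map()]).
#' @return data.frame per eGene: `gene_id`, `n_eqtl`, `n_local`, `n_distant`,
#'   `min_p`.
#' @export
egene_summary <- function(eqtls) {
  if (nrow(eqtls) == 0L)
    return(data.frame(gene_id = character(), n_eqtl = integer(),
                      n_local = integer(), n_distant = integer(),
                      min_p = numeric()))
  sp <- split(eqtls, eqtls$gene_id)
  out <- do.call(rbind, lapply(sp, function(d) data.frame(
    gene_id = d$gene_id[1L], n_eqtl = nrow(d),
    n_local = sum(d$category == "local"),
    n_distant = sum(d$category == "distant"),
    min_p = min(d$lead_p))))
  rownames(out) <- NULL
  out
}

#' Gene ids with at least one local eQTL
#'
#' @param eqtls classified eQTL data.frame.
#' @return character vector of local eGene ids.
#' @export
local_egenes <- function(eqtls) {
  unique(eqtls$gene_id[eqtls$category == "local"])
}

#' Match eQTLs across two developmental stages
#'
#' Two eQTLs of the same gene match across stages when their lead SNPs are on
#' the same chromosome within `match_window` bp, or (when `gm` is given) in
#' LD r-squared > 0.2.
#'
#' @param eqtls_s1,eqtls_s2 classified eQTL data.frames for the two stages.
#' @param gm optional [bn_geno] for the LD fallback.
#' @param match_window lead-distance window in bp (default 100 kb).
#' @return list with `s1` and `s2` (the inputs plus a `status` column taking
#'   `both` / `s1_only` / `s2_only`) and `summary`, the status tally.
#' @export
stage_overlap <- function(eqtls_s1, eqtls_s2, gm = NULL, match_window = 1e5) {
  match_one <- function(a, b) {
    # for each eQTL row in a: does any eQTL of the same gene in b match?
    vapply(seq_len(nrow(a)), function(i) {
      cand <- b[b$gene_id == a$gene_id[i] & b$chrom == a$chrom[i], , drop = FALSE]
      if (nrow(cand) == 0L) return(FALSE)
      if (any(abs(cand$pos - a$pos[i]) <= match_window)) return(TRUE)
      if (!is.null(gm)) {
        da <- gm$dosage[, match(a$lead_snp[i], gm$snps$id)]
        for (s in cand$lead_snp) {
          r2 <- suppressWarnings(stats::cor(da, gm$dosage[, match(s, gm$snps$id)])^2)
          if (!is.na(r2) && r2 > 0.2) return(TRUE)
        }
      }
      FALSE
    }, logical(1))
  }
  s1 <- eqtls_s1; s2 <- eqtls_s2
  s1$status <- ifelse(match_one(s1, s2), "both", "s1_only")
  s2$status <- ifelse(match_one(s2, s1), "both", "s2_only")
  list(s1 = s1, s2 = s2,
       summary = c(both = sum(s1$status == "both"),
                   s1_only = sum(s1$status == "s1_only"),
                   s2_only = sum(s2$status == "s2_only")))
}

#' Transcriptome-wide association study
#'
#' Per-gene ordinary least squares of the trait on `log2(TPM+1)` with
#' Benjamini-Hochberg FDR control; genes with `fdr_q <= fdr` are the TWAS
#' significant set.
#'
#' @param expr a [bn_expr].
#' @param trait data.frame with `accession` and `trait` columns; at least 30
#'   accessions must be shared with `expr`.
#' @param fdr FDR level defining `significant` (default 0.05).
#' @return data.frame per gene: `gene_id`, `beta`, `p`, `fdr_q`,
#'   `significant`.
#' @export
twas <- function(expr, trait, fdr = 0.05) {
  acc <- intersect(expr$accessions, trait$accession)
  if (length(acc) < 30L) stop("need at least 30 shared accessions for TWAS")
  y <- trait$trait[match(acc, trait$accession)]
  X <- log2p1(expr$tpm[acc, , drop = FALSE])
  n <- length(acc)
  r <- suppressWarnings(as.numeric(stats::cor(X, y)))
  r[is.na(r)] <- 0
  p <- .cor_pvalue(r, n)
  beta <- r * stats::sd(y) / ifelse(.col_sds(X) > 0, .col_sds(X), Inf)
  q <- stats::p.adjust(p, method = "BH")
  data.frame(gene_id = colnames(X), beta = beta, p = p, fdr_q = q,
             significant = q <= fdr, row.names = NULL)
}
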