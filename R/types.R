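#' Construct a genome object
#'
#' A genome is the shared coordinate frame of the pipeline: an ordered set of
#' chromosomes tagged with their subgenome of origin (An or Cn) plus gene
#' models. Gene coordinates are 0-based half-open; `tss` is the transcription
#' start (the `start` coordinate for `+` strand genes, `end - 1` for `-`).
#'
#' @param chroms data.frame with columns `name`, `length` (bp), `subgenome`
#'   (`"An"` or `"Cn"`).
#' @param genes data.frame with columns `gene_id`, `chrom`, `strand`
#'   (`"+"`/`"-"`), `start`, `end` (0-based half-open), optional `tss`,
#'   `is_tf`. TSS and per-chromosome ordinal indices are (re)computed.
#' @return An object of class `bn_genome` with elements `chroms` and `genes`;
#'   `genes` gains a 0-based `ordinal` column giving the gene's rank in
#'   coordinate order on its chromosome.
#' @export
bn_genome <- function(chroms, genes) {
  stopifnot(is.data.frame(chroms), is.data.frame(genes))
  chroms <- as.data.frame(chroms)[, c("name", "length", "subgenome")]
  if (anyDuplicated(chroms$name)) stop("duplicate chromosome names")
  if (!all(chroms$subgenome %in% c("An", "Cn")))
    stop("subgenome tags must be 'An' or 'Cn'")
  genes <- as.data.frame(genes)
  if (anyDuplicated(genes$gene_id)) stop("duplicate gene ids")
  if (!all(genes$chrom %in% chroms$name))
    stop("gene on unknown chromosome: ",
         paste(unique(setdiff(genes$chrom, chroms$name)), collapse = ", "))
  if (any(genes$start >= genes$end)) stop("gene with start >= end")
  len <- stats::setNames(chroms$length, chroms$name)
  bad <- genes$start < 0 | genes$end > len[genes$chrom]
  if (any(bad))
    stop("gene interval outside chromosome bounds: ",
         paste(utils::head(genes$gene_id[bad], 3), collapse = ", "))
  if (is.null(genes$is_tf)) genes$is_tf <- FALSE
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  genes <- genes[order(match(genes$chrom, chroms$name), genes$start), ]
  genes$ordinal <- as.integer(stats::ave(genes$start, genes$chrom,
                                         FUN = function(x) seq_along(x) - 1L))
  rownames(genes) <- NULL
  structure(list(chroms = chroms, genes = genes), class = "bn_genome")
}

#' @export
print.bn_genome <- function(x, ...) {
  cat(sprintf("bn_genome: %d chromosomes (%d An / %d Cn), %d genes (%d TFs)\n",
              nrow(x$chroms), sum(x$chroms$subgenome == "An"),
              sum(x$chroms$subgenome == "Cn"), nrow(x$genes),
              sum(x$genes$is_tf)))
  invisible(x)
}

#' Construct a genotype matrix
#'
#' Holds additive dosage codes (0/1/2 copies of the alternate allele, NA for
#' missing) for a set of accessions at biallelic SNPs. SNP positions are
#' 0-based. SNPs are stored sorted by (chrom, pos).
#'
#' @param accessions character vector of accession ids (rows of `dosage`).
#' @param snps data.frame with columns `chrom`, `pos` (0-based), `ref`, `alt`.
#' @param dosage integer matrix, accessions x SNPs, values in {0,1,2,NA}.
#' @return Object of class `bn_geno` with elements `accessions`, `snps`
#'   (gains an `id` column `chrom:pos1` with 1-based position), `dosage`.
#' @export
bn_geno <- function(accessions, snps, dosage) {
  snps <- as.data.frame(snps)
  dosage <- as.matrix(dosage)
  stopifnot(nrow(dosage) == length(accessions), ncol(dosage) == nrow(snps))
  if (!all(dosage %in% c(0L, 1L, 2L) | is.na(dosage)))
    stop("dosage values must be 0, 1, 2 or NA")
  o <- order(snps$chrom, snps$pos)
  snps <- snps[o, , drop = FALSE]
  dosage <- dosage[, o, drop = FALSE]
  snps$id <- if (nrow(snps)) paste0(snps$chrom, ":", snps$pos + 1L)
             else character(0)
  rownames(snps) <- NULL
  dimnames(dosage) <- list(accessions, snps$id)
  structure(list(accessions = accessions, snps = snps, dosage = dosage),
            class = "bn_geno")
}

#' @export
print.bn_geno <- function(x, ...) {
  cat(sprintf("bn_geno: %d accessions x %d SNPs (%d missing calls)\n",
              length(x$accessions), nrow(x$snps), sum(is.na(x$dosage))))
  invisible(x)
}

#' Minor allele frequency per SNP
#'
#' MAF is computed from non-missing dosages as
#' `min(p, 1 - p)` with `p = sum(dosage) / (2 * n_called)`.
#'
#' @param gm a [bn_geno] object.
#' @return numeric vector of MAFs, one per SNP (NA when no calls).
#' @export
snp_maf <- function(gm) {
  n2 <- 2 * colSums(!is.na(gm$dosage))
  p <- colSums(gm$dosage, na.rm = TRUE) / n2
  ifelse(n2 > 0, pmin(p, 1 - p), NA_real_)
}

#' Construct an expression matrix
#'
#' @param accessions character vector (rows).
#' @param gene_ids character vector (columns).
#' @param tpm numeric accessions x genes matrix of TPM values (>= 0).
#' @param stage free-text stage label, e.g. `"20DAF"`.
#' @return Object of class `bn_expr`.
#' @export
bn_expr <- function(accessions, gene_ids, tpm, stage = NA_character_) {
  tpm <- as.matrix(tpm)
  stopifnot(nrow(tpm) == length(accessions), ncol(tpm) == length(gene_ids))
  if (any(tpm < 0, na.rm = TRUE)) stop("TPM values must be non-negative")
  dimnames(tpm) <- list(accessions, gene_ids)
  structure(list(accessions = accessions, gene_ids = gene_ids,
                 tpm = tpm, stage = stage), class = "bn_expr")
}

#' @export
print.bn_expr <- function(x, ...) {
  cat(sprintf("bn_expr [%s]: %d accessions x %d genes\n",
              x$stage, length(x$accessions), length(x$gene_ids)))
  invisible(x)
}

#' Construct an interval set
#'
#' Genomic intervals in the package-wide 0-based half-open convention (the
#' BED convention). Used for open-chromatin regions and hotspot intervals.
#'
#' @param df data.frame with columns `chrom`, `start`, `end` (start < end);
#'   extra columns are kept as metadata.
#' @param genome optional [bn_genome]; when given, intervals are checked
#'   against chromosome bounds.
#' @return data.frame of class `bn_intervals`, sorted by (chrom, start).
#' @export
bn_intervals <- function(df, genome = NULL) {
  df <- as.data.frame(df)
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  if (any(df$start >= df$end)) stop("interval with start >= end")
  if (!is.null(genome)) {
    len <- .chrom_lengths(genome)
    if (!all(df$chrom %in% names(len))) stop("interval on unknown chromosome")
    bad <- df$start < 0 | df$end > len[df$chrom]
    if (any(bad))
      stop("interval outside chromosome bounds at row ", which(bad)[1])
  }
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("bn_intervals", "data.frame")
  df
}

# Shared accessions of a genotype and an expression object, in a stable order.
#' @noRd
.shared_accessions <- function(gm, expr, min_n = 30L) {
  acc <- intersect(gm$accessions, expr$accessions)
  if (length(acc) < min_n)
    stop("need at least ", min_n, " shared accessions, got ", length(acc))
  acc
}
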