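#' Read genotypes from a VCF file
#'
#' Parses biallelic SNP records into additive dosages (count of ALT alleles,
#' heterozygotes coded 1). Records with a non-SNP or multi-allelic ALT are
#' skipped with a message giving the count. `./.` genotypes become NA.
#' Positions are converted from VCF 1-based to the internal 0-based frame.
#'
#' @param path path to a VCF 4.x file (plain text or gzipped).
#' @param multiallelic `"drop"` (default) to skip multi-allelic records,
#'   `"error"` to fail on them.
#' @return A [bn_geno] object.
#' @export
read_vcf <- function(path, multiallelic = c("drop", "error")) {
  multiallelic <- match.arg(multiallelic)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) stop("no records in VCF: ", path)
  is_snp <- nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  if (any(multi) && multiallelic == "error")
    stop("multi-allelic record at ", fix$CHROM[multi][1], ":", fix$POS[multi][1])
  keep <- is_snp & !multi
  n_skip <- sum(!keep)
  if (n_skip > 0)
    message("read_vcf: skipped ", n_skip, " non-SNP or multi-allelic record(s)")
  if (!any(keep)) stop("no biallelic SNP records in VCF: ", path)
  gt <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
  code <- function(g) {
    g <- sub("\\|", "/", g)
    out <- rep(NA_integer_, length(g))
    out[g == "0/0"] <- 0L
    out[g %in% c("0/1", "1/0")] <- 1L
    out[g == "1/1"] <- 2L
    out
  }
  dosage <- t(apply(gt, 2L, code))  # accession x snp
  snps <- data.frame(chrom = fix$CHROM[keep],
                     pos = as.integer(fix$POS[keep]) - 1L,
                     ref = fix$REF[keep], alt = fix$ALT[keep])
  bn_geno(colnames(v@gt)[-1L], snps, dosage)
}

#' Write genotypes to a VCF file
#'
#' Plain-text VCF 4.2 with GT-only genotype fields; inverse of [read_vcf()].
#'
#' @param gm a [bn_geno] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  gt_str <- c("0/0", "0/1", "1/1")
  body <- matrix("./.", nrow(gm$snps), length(gm$accessions))
  d <- t(gm$dosage)  # snp x accession
  ok <- !is.na(d)
  body[ok] <- gt_str[d[ok] + 1L]
  lines <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$accessions), collapse = "\t"),
    paste(gm$snps$chrom, gm$snps$pos + 1L, gm$snps$id, gm$snps$ref,
          gm$snps$alt, ".", "PASS", ".", "GT",
          apply(body, 1L, paste, collapse = "\t"), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Filter SNPs on minor allele frequency
#'
#' Retains SNPs with MAF strictly greater than `maf_min` (the conventional
#' `MAF > 0.05` filter); a SNP exactly at the threshold is removed.
#'
#' @param gm a [bn_geno] object.
#' @param maf_min MAF threshold (strict inequality). Default 0.05.
#' @return Filtered [bn_geno]. Warns (does not error) when nothing survives.
#' @export
filter_maf <- function(gm, maf_min = 0.05) {
  keep <- which(snp_maf(gm) > maf_min)
  if (length(keep) == 0L) warning("filter_maf: no SNPs pass MAF > ", maf_min)
  bn_geno(gm$accessions, gm$snps[keep, c("chrom", "pos", "ref", "alt")],
          gm$dosage[, keep, drop = FALSE])
}

#' Mean-impute missing dosages
#'
#' Replaces missing calls by the per-SNP mean dosage (a continuous value);
#' provided for inputs with sporadic missingness. The association scan
#' otherwise requires complete dosages.
#'
#' @param gm a [bn_geno] object.
#' @return list-based object like [bn_geno] but with a numeric dosage matrix.
#' @export
impute_mean <- function(gm) {
  d <- gm$dosage * 1.0
  mu <- colMeans(d, na.rm = TRUE)
  idx <- which(is.na(d), arr.ind = TRUE)
  if (nrow(idx)) d[idx] <- mu[idx[, 2L]]
  out <- gm
  out$dosage <- d
  out
}

#' Read a genome from GFF3
#'
#' Reads `gene` features (1-based inclusive in the file, converted to the
#' internal 0-based half-open frame). Chromosome lengths are taken from
#' `##sequence-region` pragmas; the subgenome tag is derived from the first
#' letter of the chromosome name (`A*` = An, `C*` = Cn). TF status comes from
#' an optional TF list (one gene id per line, or a character vector).
#'
#' @param path GFF3 file with `##sequence-region` pragmas and gene features.
#' @param tf_list optional path to a TF id list, or a character vector of ids.
#' @return A [bn_genome].
#' @export
read_gff3 <- function(path, tf_list = NULL) {
  hdr <- grep("^##sequence-region", readLines(path), value = TRUE)
  if (length(hdr) == 0L)
    stop("GFF3 lacks ##sequence-region pragmas: ", path)
  parts <- strsplit(trimws(hdr), "\\s+")
  chroms <- data.frame(name = vapply(parts, `[`, "", 2L),
                       length = as.numeric(vapply(parts, `[`, "", 4L)))
  chroms$subgenome <- ifelse(startsWith(chroms$name, "A"), "An", "Cn")
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "gene"]
  if (length(gr) == 0L) stop("no gene features in GFF3: ", path)
  len <- stats::setNames(chroms$length, chroms$name)
  g_end <- GenomicRanges::end(gr)
  if (any(g_end > len[as.character(GenomicRanges::seqnames(gr))]))
    stop("gene feature beyond chromosome bounds in ", path)
  genes <- data.frame(
    gene_id = gr$ID,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr) - 1L,  # to 0-based half-open
    end = g_end)
  if (!is.null(tf_list)) {
    ids <- if (length(tf_list) == 1L && file.exists(tf_list))
      readLines(tf_list) else as.character(tf_list)
    genes$is_tf <- genes$gene_id %in% ids
  }
  bn_genome(chroms, genes)
}

#' Write a genome to GFF3
#'
#' @param genome a [bn_genome].
#' @param path output path; `##sequence-region` pragmas carry the chromosome
#'   lengths so that [read_gff3()] round-trips the object.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genome, path) {
  g <- genome$genes
  gr <- GenomicRanges::GRanges(
    g$chrom, IRanges::IRanges(g$start + 1L, g$end), strand = g$strand,
    type = "gene", ID = g$gene_id)
  tmp <- paste0(path, ".body")
  on.exit(unlink(tmp), add = TRUE)
  rtracklayer::export(gr, tmp, format = "gff3")
  body <- readLines(tmp)
  pragma <- sprintf("##sequence-region %s 1 %.0f",
                    genome$chroms$name, genome$chroms$length)
  writeLines(c(body[1L], pragma, body[-1L]), path)
  invisible(path)
}

#' Read intervals from a BED file
#'
#' BED is already 0-based half-open, so coordinates pass through unchanged:
#' the line `A09  100  200` covers 1-based positions 101..200.
#'
#' @param path BED3+ file.
#' @param genome optional [bn_genome] for bounds checking.
#' @return A [bn_intervals] data.frame (with a `name` column when BED4+).
#' @export
read_bed <- function(path, genome = NULL) {
  gr <- rtracklayer::import(path, format = "bed")
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,  # undo 1-based lift
                   end = GenomicRanges::end(gr))
  if (!is.null(gr$name)) df$name <- gr$name
  bn_intervals(df, genome)
}

#' Write intervals to a BED file
#'
#' @param x a [bn_intervals] data.frame (or any data.frame with `chrom`,
#'   `start`, `end` in 0-based half-open coordinates); extra columns beyond an
#'   optional `name` are dropped, as BED has no schema for them.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  cols <- c("chrom", "start", "end", intersect("name", names(x)))
  df <- as.data.frame(x)[, cols, drop = FALSE]
  df$start <- format(df$start, scientific = FALSE, trim = TRUE)
  df$end <- format(df$end, scientific = FALSE, trim = TRUE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an expression matrix from TSV
#'
#' Expects a header row of gene ids and a first column of accession ids
#' (accessions x genes, TPM).
#'
#' @param path TSV path.
#' @param stage stage label to attach (e.g. `"20DAF"`).
#' @return A [bn_expr].
#' @export
read_expression_tsv <- function(path, stage = NA_character_) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  acc <- as.character(dt[[1L]])
  m <- as.matrix(dt[, -1L, drop = FALSE])
  bn_expr(acc, colnames(m), m, stage = stage)
}

#' Write an expression matrix to TSV
#'
#' @param expr a [bn_expr].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(expr, path) {
  dt <- data.table::data.table(accession = expr$accessions)
  dt <- cbind(dt, data.table::as.data.table(expr$tpm))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Read and write plain result tables
#'
#' Thin TSV helpers used for all tabular results (traits, similarity scores,
#' eQTL/TWAS/hotspot tables). `read_tsv_table` returns a plain data.frame.
#'
#' @param path file path.
#' @return `read_tsv_table`: data.frame. `write_tsv_table`: `path`, invisibly.
#' @export
read_tsv_table <- function(path) {
  data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
}

#' @rdname read_tsv_table
#' @param df data.frame to write. List columns are collapsed with commas.
#' @export
write_tsv_table <- function(df, path) {
  df <- as.data.frame(df)
  for (j in seq_along(df))
    if (is.list(df[[j]]))
      df[[j]] <- vapply(df[[j]], paste, "", collapse = ",")
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' Read a TF list (one gene id per line)
#'
#' @param path text file path.
#' @return character vector of gene ids.
#' @export
read_tf_list <- function(path) {
  ids <- trimws(readLines(path))
  ids[nzchar(ids)]
}
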