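# Shared fixtures and independent brute-force oracles.
# Oracles use explicit loops and elementary arithmetic only, so they stay
# independent of the package implementation they check.

# Scaled-down study configuration for module tests.
test_cfg <- function(...) {
  sim_config(n_accessions = 120L, chrom_len = 4e6, genes_per_chrom = 40L,
             snps_per_chrom = 120L, ld_block_len = 1e5,
             n_local_eqtl = 8L, n_adjacent_coexpressed = 6L,
             hotspot_targets = 12L, n_hgp_feedback = 6L, n_hgp_direct = 6L,
             n_hgp_biased = 6L, n_trait_causal_genes = 3L, ...)
}

# A small hand-built genome: 2 chromosomes, genes every 100 kb.
toy_genome <- function(n_genes = 10L, chrom_len = 2e6,
                       chroms = c("A01", "C01")) {
  genes <- do.call(rbind, lapply(chroms, function(nm) {
    start <- seq(50e3, by = 1e5, length.out = n_genes)
    data.frame(gene_id = sprintf("%s_g%02d", nm, seq_len(n_genes)),
               chrom = nm, strand = "+", start = start, end = start + 3e3,
               is_tf = FALSE)
  }))
  bn_genome(data.frame(name = chroms, length = chrom_len,
                       subgenome = ifelse(startsWith(chroms, "A"), "An", "Cn")),
            genes)
}

# Hand-written 5-record VCF used by the formats tests (includes an indel,
# a multi-allelic record and missing genotypes).
write_toy_vcf <- function(path) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2\ts3",
    "A01\t101\t.\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "A01\t205\t.\tC\tT\t.\tPASS\t.\tGT\t./.\t0/0\t1/1",
    "A01\t300\t.\tG\tGA\t.\tPASS\t.\tGT\t0/0\t0/0\t0/1",
    "A01\t450\t.\tT\tA,C\t.\tPASS\t.\tGT\t0/0\t0/1\t0/2",
    "C01\t50\t.\tG\tC\t.\tPASS\t.\tGT\t1/1\t0|1\t0/0"),
    path)
  path
}

## ---- oracles --------------------------------------------------------------

# Sliding-window counts by explicit containment loop.
oracle_window_counts <- function(leads, genome, window, step) {
  out <- list()
  for (ci in seq_len(nrow(genome$chroms))) {
    nm <- genome$chroms$name[ci]
    len <- genome$chroms$length[ci]
    ws <- seq(0, max(0, len - 1), by = step)
    pos <- leads$pos[leads$chrom == nm]
    cnt <- integer(length(ws))
    for (i in seq_along(ws))
      for (p in pos) if (p >= ws[i] && p < ws[i] + window)
        cnt[i] <- cnt[i] + 1L
    out[[nm]] <- cnt
  }
  unlist(out, use.names = FALSE)
}

# Greedy clump partition on precomputed pairwise r2 (explicit loops).
oracle_clump_partition <- function(p, r2mat, r2_min = 0.2) {
  remaining <- order(p)  # assume no ties in tests
  groups <- list()
  while (length(remaining)) {
    lead <- remaining[1L]
    absorbed <- integer(0)
    for (j in remaining[-1L])
      if (r2mat[lead, j] > r2_min) absorbed <- c(absorbed, j)
    groups[[length(groups) + 1L]] <- sort(c(lead, absorbed))
    remaining <- setdiff(remaining, c(lead, absorbed))
  }
  groups
}

# Interval union via a per-bp boolean mask (one chromosome, small ranges).
oracle_merge_mask <- function(starts, ends, len) {
  mask <- logical(len)
  for (i in seq_along(starts)) mask[(starts[i] + 1):ends[i]] <- TRUE
  r <- rle(mask)
  stops <- cumsum(r$lengths)
  begins <- stops - r$lengths + 1L
  data.frame(start = begins[r$values] - 1L, end = stops[r$values])
}

# Adjacency census by O(n^2) double loop over selected genes.
oracle_census <- function(local_ids, genome, max_k) {
  g <- genome$genes
  sel <- which(g$gene_id %in% local_ids)
  cnt <- integer(max_k + 1L)
  if (length(sel) > 1L)
    for (a in seq_along(sel))
      for (b in seq_along(sel))
        if (a < b && g$chrom[sel[a]] == g$chrom[sel[b]]) {
          k <- abs(g$ordinal[sel[a]] - g$ordinal[sel[b]]) - 1L
          if (k <= max_k) cnt[k + 1L] <- cnt[k + 1L] + 1L
        }
  data.frame(intervening = 0:max_k, n_pairs = cnt)
}

# Reciprocal best hit by double argmax over a dense score matrix.
oracle_rbh <- function(m) {
  # m: An x Cn score matrix with dimnames
  out <- list()
  for (i in seq_len(nrow(m))) {
    j <- which(m[i, ] == max(m[i, ]))[1L]  # ties: first (lexicographic cols)
    i2 <- which(m[, j] == max(m[, j]))[1L]
    if (i2 == i)
      out[[length(out) + 1L]] <- data.frame(an_gene = rownames(m)[i],
                                            cn_gene = colnames(m)[j])
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(an_gene = character(), cn_gene = character())
}

# Hypergeometric upper tail by explicit combinatorial sum.
oracle_hyper_tail <- function(q, m, n, k) {
  tot <- 0
  for (x in q:min(m, k))
    tot <- tot + choose(m, x) * choose(n, k - x)
  tot / choose(m + n, k)
}

# Top-k tally by explicit counting.
oracle_tally <- function(topk_lists) {
  tf <- sort(unique(unlist(topk_lists)))
  topk <- first <- stats::setNames(integer(length(tf)), tf)
  for (l in topk_lists) {
    for (t in l) topk[t] <- topk[t] + 1L
    if (length(l)) first[l[1L]] <- first[l[1L]] + 1L
  }
  list(topk = topk, first = first)
}

# Random dosage matrix with no constant columns.
random_dosage <- function(n, m, maf = 0.3) {
  repeat {
    d <- matrix(rbinom(n * m, 2L, maf), n, m)
    if (all(apply(d, 2L, function(x) length(unique(x)) > 1L))) return(d)
  }
}
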