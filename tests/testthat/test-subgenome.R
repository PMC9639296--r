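test_that("reciprocal best hit matches the double-argmax oracle", {
  # diagonal-dominant matrix pairs the diagonal
  m <- matrix(runif(25, 0, 50), 5, 5,
              dimnames = list(paste0("a", 1:5), paste0("c", 1:5)))
  diag(m) <- 90 + 1:5
  sim <- data.frame(an_gene = rep(rownames(m), 5),
                    cn_gene = rep(colnames(m), each = 5),
                    score = as.vector(m))
  got <- rbh_pairs(sim)
  expect_equal(got$an_gene, paste0("a", 1:5))
  expect_equal(got$cn_gene, paste0("c", 1:5))

  # a's best is c but c's best is a different gene: no pair for a
  sim2 <- data.frame(an_gene = c("a1", "a2", "a2"),
                     cn_gene = c("c1", "c1", "c2"),
                     score = c(5, 9, 1))
  got2 <- rbh_pairs(sim2)
  expect_false("a1" %in% got2$an_gene)
  expect_equal(got2$an_gene, "a2")
  expect_equal(got2$cn_gene, "c1")

  set.seed(181)
  for (rep in 1:20) {
    m <- matrix(sample.int(1e6, 400), 20, 20,
                dimnames = list(sprintf("a%02d", 1:20), sprintf("c%02d", 1:20)))
    sim_r <- data.frame(an_gene = rep(rownames(m), 20),
                        cn_gene = rep(colnames(m), each = 20),
                        score = as.vector(m))
    got_r <- rbh_pairs(sim_r)
    oracle <- oracle_rbh(m)
    oracle <- oracle[order(oracle$an_gene), ]
    expect_equal(got_r$an_gene, oracle$an_gene)
    expect_equal(got_r$cn_gene, oracle$cn_gene)
    # matching property and row/column permutation invariance
    expect_false(any(duplicated(got_r$an_gene)) || any(duplicated(got_r$cn_gene)))
    got_p <- rbh_pairs(sim_r[sample(nrow(sim_r)), ])
    expect_equal(got_p, got_r)
  }
})

test_that("regulation classes follow the TSS window rule and are antisymmetric", {
  genome <- toy_genome(n_genes = 10)  # A01/C01 genes at 50 kb + k*100 kb
  pairs <- data.frame(an_gene = "A01_g03", cn_gene = "C01_g03", score = 95)
  an_tss <- genome$genes$tss[genome$genes$gene_id == "A01_g03"]
  d_eq <- function(gene, chrom, pos)
    data.frame(gene_id = gene, lead_snp = "s", chrom = chrom, pos = pos,
               category = "distant")
  # no distant eQTLs at all
  none <- regulation_class(pairs, d_eq("x", "A01", 0)[0, ], genome)
  expect_equal(none$reg_class, "none")
  expect_true(none$symmetric)
  # Cn gene has a distant lead 100 kb from the An TSS: An regulates Cn
  an_reg <- regulation_class(pairs, d_eq("C01_g03", "A01", an_tss + 1e5), genome)
  expect_equal(an_reg$reg_class, "An_reg_Cn")
  expect_false(an_reg$symmetric)
  # boundary: exactly 150 kb away is still inside (inclusive)
  expect_equal(regulation_class(pairs, d_eq("C01_g03", "A01", an_tss + 1.5e5),
                                genome)$reg_class, "An_reg_Cn")
  expect_equal(regulation_class(pairs, d_eq("C01_g03", "A01", an_tss + 1.5e5 + 1),
                                genome)$reg_class, "none")
  # same position on the wrong chromosome does not count
  expect_equal(regulation_class(pairs, d_eq("C01_g03", "C01", an_tss + 1e5),
                                genome)$reg_class, "none")
  # swapping the regulated gene swaps the class
  cn_tss <- genome$genes$tss[genome$genes$gene_id == "C01_g03"]
  cn_reg <- regulation_class(pairs, d_eq("A01_g03", "C01", cn_tss + 1e5), genome)
  expect_equal(cn_reg$reg_class, "Cn_reg_An")
  # both directions: mutual (symmetric)
  mut <- regulation_class(pairs, rbind(d_eq("C01_g03", "A01", an_tss + 1e5),
                                       d_eq("A01_g03", "C01", cn_tss + 1e5)),
                          genome)
  expect_equal(mut$reg_class, "mutual")
  expect_true(mut$symmetric)
})

test_that("expression propensity has the documented arithmetic and sign", {
  acc <- sprintf("a%03d", 1:60)
  pairs <- data.frame(an_gene = "an1", cn_gene = "cn1", score = 95)
  # identical expression: log2fc 0, padj about 1
  tpm <- cbind(an1 = rexp(60, 0.1), cn1 = 0)
  tpm[, "cn1"] <- tpm[, "an1"]
  ep <- expression_propensity(pairs, bn_expr(acc, colnames(tpm), tpm, "s"))
  expect_equal(ep$log2fc, 0)
  expect_equal(ep$padj, 1)
  expect_false(ep$imbalanced)
  # TPM_An + 1 = 2 * (TPM_Cn + 1) with TPM_Cn constant: log2fc exactly 1
  tpm2 <- cbind(an1 = rep(7, 60), cn1 = rep(3, 60))
  ep2 <- expression_propensity(pairs, bn_expr(acc, colnames(tpm2), tpm2, "s"))
  expect_equal(ep2$log2fc, 1)
  expect_true(ep2$imbalanced)

  # planted An-biased pairs: positive log2fc, high sensitivity; neutral
  # (direct/feedback) pairs rarely called imbalanced
  st <- simulate_study(test_cfg(seed = 191, n_accessions = 300L))
  hgp <- st$truth$hgp
  ep3 <- expression_propensity(hgp, st$expr1)
  biased <- ep3$type == "biased"
  expect_true(all(ep3$log2fc[biased] > 0))
  expect_gte(mean(ep3$imbalanced[biased]), 0.9)
  # unplanted pairs are a propensity null: low false-call rate
  planted <- unique(c(hgp$an_gene, st$truth$local$gene_id,
                      st$truth$hotspot_targets$gene_id,
                      st$truth$adjacent_pairs$gene_a,
                      st$truth$adjacent_pairs$gene_b))
  all_pairs <- sim_homoeolog_pairs(st$genome)
  neutral <- all_pairs[!(all_pairs$an_gene %in% planted |
                           all_pairs$cn_gene %in% planted), ]
  ep_n <- expression_propensity(cbind(neutral, score = 95), st$expr1)
  expect_lte(mean(ep_n$imbalanced), 0.1)
})

test_that("feedback coupling separates Local from NoLocal correlations", {
  truth_eqtls <- function(st) {
    # local records for planted cis effects; distant records for regulated
    # partners at the causal SNP, straight from the ground truth
    tl <- st$truth$local
    hgp <- st$truth$hgp
    fb <- hgp[hgp$type == "feedback", ]
    di <- hgp[hgp$type == "direct", ]
    reg_gene <- function(d) ifelse(d$regulator == "An", d$an_gene, d$cn_gene)
    tgt_gene <- function(d) ifelse(d$regulator == "An", d$cn_gene, d$an_gene)
    snp_pos <- function(sid) st$gm$snps$pos[match(sid, st$gm$snps$id)]
    snp_chr <- function(sid) st$gm$snps$chrom[match(sid, st$gm$snps$id)]
    rbind(
      data.frame(gene_id = tl$gene_id, lead_snp = tl$snp_id, chrom = tl$chrom,
                 pos = tl$pos, category = "local"),
      data.frame(gene_id = c(tgt_gene(fb), tgt_gene(di)),
                 lead_snp = c(fb$snp_id, di$snp_id),
                 chrom = snp_chr(c(fb$snp_id, di$snp_id)),
                 pos = snp_pos(c(fb$snp_id, di$snp_id)), category = "distant"))
  }
  run_one <- function(seed, ...) {
    st <- simulate_study(test_cfg(seed = seed, ...))
    eq <- truth_eqtls(st)
    pairs <- regulation_class(st$truth$hgp[, c("an_gene", "cn_gene")],
                              eq, st$genome)
    feedback_analysis(pairs, st$expr1, eq)
  }
  # feedback -0.8: Local well below NoLocal, KS highly significant
  fa <- run_one(201)
  expect_lt(fa$group_means[["Local"]], fa$group_means[["NoLocal"]] - 0.3)
  ks <- fa$tests
  expect_lt(ks$ks_p[ks$group_a == "Local" & ks$group_b == "NoLocal"], 0.01)
  # a pair with identical expression would have correlation one
  st <- simulate_study(test_cfg(seed = 202))
  p1 <- st$truth$hgp[1, c("an_gene", "cn_gene")]
  tpm <- st$expr1$tpm
  tpm[, p1$cn_gene] <- tpm[, p1$an_gene]
  fa2 <- feedback_analysis(cbind(p1, reg_class = "An_reg_Cn"),
                           bn_expr(st$expr1$accessions, st$expr1$gene_ids,
                                   tpm, "s"),
                           data.frame(gene_id = character(),
                                      category = character()))
  expect_equal(fa2$pairs$cross_pcc, 1)

  # no coupling: the two groups are indistinguishable
  ps <- sapply(1:5, function(s) {
    fa0 <- run_one(210 + s, feedback_strength = 0)
    k <- fa0$tests
    k$ks_p[k$group_a == "Local" & k$group_b == "NoLocal"]
  })
  expect_gt(median(ps), 0.05)
})

test_that("aHGP regulation directions are recovered from a full scan", {
  rates <- sapply(1:3, function(seed) {
    st <- simulate_study(test_cfg(seed = 220 + seed, n_accessions = 300L))
    gm <- filter_maf(st$gm, 0.05)
    eq <- rbind(eqtl_map(gm, st$expr1, st$genome),
                eqtl_map(gm, st$expr2, st$genome))
    sub <- subgenome_analysis(st$similarity, eq, st$expr1, st$genome,
                              n_perm = 200, seed = 1)
    recover_hgp_direction(sub$pairs, st$truth)$rate
  })
  expect_gte(mean(rates), 0.9)
})

test_that("TF enrichment is exact in corner cases and detects planted bias", {
  genome <- toy_genome(n_genes = 10)
  # no TFs anywhere: observed 0, P = 1
  r0 <- tf_enrichment(genome$genes$gene_id[1:4], genome, n_perm = 100, seed = 1)
  expect_equal(r0$observed, 0L)
  expect_equal(r0$p, 1)
  # every gene a TF: P = 1 as well
  all_tf <- genome
  all_tf$genes$is_tf <- TRUE
  r1 <- tf_enrichment(genome$genes$gene_id[1:4], all_tf, n_perm = 100, seed = 1)
  expect_equal(r1$p, 1)

  # feedback pairs are planted TF-rich (sampling weight 4)
  hits <- sapply(1:5, function(seed) {
    st <- simulate_study(sim_config(seed = 230 + seed))
    fb <- st$truth$hgp[st$truth$hgp$type == "feedback", ]
    tf_enrichment(c(fb$an_gene, fb$cn_gene), st$genome,
                  n_perm = 500, seed = 1)$p < 0.05
  })
  expect_gte(mean(hits), 0.8)
})
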